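#' Assemble normalized observations for model fitting
#'
#' Selects the single-ligand, self-pair and pair conditions of a ligand
#' subset from a processed screen, collapses replicates to medians, and
#' applies the max-1 normalization: responses are divided by the maximum
#' response across the selected contexts, and receptor expression levels by
#' the maximum expression value across contexts. Any global rescaling of
#' either is absorbed by the model's free activity parameters, so the
#' normalization fixes units without constraining the fit.
#'
#' @param processed a processed table (see [preprocess_dataset()]).
#' @param ligands ligand subset to fit.
#' @param receptor_expr named list (per context) of lists with raw `A0`,
#'   `B0` named expression vectors.
#' @param contexts contexts to include (default: names of
#'   `receptor_expr`).
#' @return object of class `fit_observations`: list with `obs` (data.frame:
#'   context, row, ratio, doses, normalized response `y`), `contexts`
#'   (normalized receptor levels), `ligands`, `type1`, `type2`, and the
#'   normalization constants (`y_scale`, `r_scale`).
#' @export
assemble_observations <- function(processed, ligands, receptor_expr,
                                  contexts = names(receptor_expr)) {
  if (is.null(names(receptor_expr))) .stopf("receptor_expr must be named by context")
  keep <- !processed$dropped & !processed$tech_rep &
    processed$context_id %in% contexts &
    processed$ligand_a %in% ligands &
    (is.na(processed$ligand_b) | processed$ligand_b %in% ligands) &
    processed$ratio_index > 0L
  p <- processed[keep, , drop = FALSE]
  if (!nrow(p)) .stopf("no observations for the requested ligands/contexts")
  key <- paste(p$context_id, p$row_id, p$ratio_index)
  med <- tapply(p$response, key, median)
  first <- p[!duplicated(key), , drop = FALSE]
  obs <- data.frame(context_id = first$context_id, row_id = first$row_id,
                    row_kind = first$row_kind, ligand_a = first$ligand_a,
                    ligand_b = first$ligand_b, ratio_index = first$ratio_index,
                    conc_a = first$conc_a, conc_b = first$conc_b,
                    y = as.numeric(med[paste(first$context_id, first$row_id,
                                             first$ratio_index)]),
                    stringsAsFactors = FALSE)
  # completeness: every subset row must appear at every ratio in every context
  n_ratios <- max(obs$ratio_index)
  for (cx in contexts) {
    oc <- obs[obs$context_id == cx, ]
    cnt <- table(oc$row_id)
    if (any(cnt != n_ratios))
      .stopf("context %s: condition row %s has %d of %d ratios", cx,
             names(cnt)[cnt != n_ratios][1L], min(cnt), n_ratios)
  }
  y_scale <- max(obs$y)
  if (y_scale <= 0) .stopf("all responses nonpositive; nothing to fit")
  obs$y <- obs$y / y_scale
  r_scale <- max(unlist(lapply(receptor_expr[contexts], unlist)))
  ctxs <- lapply(receptor_expr[contexts], function(e)
    receptor_context(e$A0 / r_scale, e$B0 / r_scale))
  type1 <- names(ctxs[[1L]]$A0)
  type2 <- names(ctxs[[1L]]$B0)
  structure(list(obs = obs, contexts = ctxs, ligands = ligands,
                 type1 = type1, type2 = type2, y_scale = y_scale,
                 r_scale = r_scale, n_ratios = n_ratios),
            class = "fit_observations")
}

# dose matrix + context matrices for a fit_observations object
.fit_matrices <- function(fo) {
  obs <- fo$obs
  nE <- nrow(obs)
  L <- matrix(0, nE, length(fo$ligands), dimnames = list(NULL, fo$ligands))
  ia <- match(obs$ligand_a, fo$ligands)
  L[cbind(seq_len(nE), ia)] <- obs$conc_a
  isp <- !is.na(obs$ligand_b)
  ib <- match(obs$ligand_b[isp], fo$ligands)
  idx <- cbind(which(isp), ib)
  L[idx] <- L[idx] + obs$conc_b[isp]
  A0 <- t(vapply(obs$context_id, function(cx) fo$contexts[[cx]]$A0[fo$type1],
                 numeric(length(fo$type1))))
  B0 <- t(vapply(obs$context_id, function(cx) fo$contexts[[cx]]$B0[fo$type2],
                 numeric(length(fo$type2))))
  list(L = L, A0 = A0, B0 = B0)
}

.par_to_params <- function(par, fo, nc) {
  dn <- list(fo$ligands, fo$type1, fo$type2)
  K <- array(10^par[seq_len(nc)], dim = lengths(dn), dimnames = dn)
  E <- array(10^par[nc + seq_len(nc)], dim = lengths(dn), dimnames = dn)
  structure(list(K = K, eps = E, ligands = fo$ligands, type1 = fo$type1,
                 type2 = fo$type2), class = "bmp_params")
}

#' Multi-start bounded least-squares fit of the equilibrium model
#'
#' Fits affinities and activities (bounded within `10^-4`--`10^2`) plus
#' per-receptor expression rescalings (bounded `[1/3, 3]`) to normalized
#' observations by Levenberg-Marquardt least squares in log-parameter
#' space. Each start draws affinities and rescalings log-uniformly within
#' bounds and is then improved in two inexpensive stages before the joint
#' fit: the activities, which enter the output linearly once the binding
#' equilibrium is solved, are set to their non-negative least-squares
#' optimum (variable projection), and each ligand's affinity/activity
#' block is pre-fitted against that ligand's own single-ligand rows
#' (hierarchical initialization). Every start then runs a coarse joint
#' descent with an activity re-profile in the middle, and the best
#' `n_polish` starts are polished to convergence. Random starts without
#' these stages stall in poor basins on this strongly multimodal
#' objective. Fully reproducible for a given seed.
#'
#' @param fo a [assemble_observations()] object.
#' @param n_starts number of random starts.
#' @param seed RNG seed for the start draws.
#' @param k_bounds,eps_bounds bounds for affinities and activities.
#' @param rho_bounds bounds for the receptor rescaling factors.
#' @param maxit_coarse,maxit_polish Levenberg-Marquardt iteration caps.
#' @param n_polish how many of the best coarse fits to polish.
#' @return object of class `bmp_fit_list`: list of fit results sorted by
#'   residual, each with `params` ([model_params()] object), `rho` (named),
#'   `residual` (sum of squared errors), `start` (start index), `converged`.
#' @export
fit_multistart <- function(fo, n_starts = 50L, seed = 1L,
                           k_bounds = c(1e-4, 1e2), eps_bounds = c(1e-4, 1e2),
                           rho_bounds = c(1 / 3, 3),
                           maxit_coarse = 25L, maxit_polish = 200L,
                           n_polish = 5L) {
  stopifnot(inherits(fo, "fit_observations"))
  if (n_starts < 1L) .stopf("n_starts must be >= 1")
  mats <- .fit_matrices(fo)
  nc <- length(fo$ligands) * length(fo$type1) * length(fo$type2)
  nr <- length(fo$type1) + length(fo$type2)
  lower <- c(rep(log10(k_bounds[1]), nc), rep(log10(eps_bounds[1]), nc),
             rep(log10(rho_bounds[1]), nr))
  upper <- c(rep(log10(k_bounds[2]), nc), rep(log10(eps_bounds[2]), nc),
             rep(log10(rho_bounds[2]), nr))
  warm <- new.env()
  resid_fun <- function(par, rows = NULL) {
    params <- .par_to_params(par, fo, nc)
    rho <- 10^par[2 * nc + seq_len(nr)]
    A0 <- mats$A0 * rep(rho[seq_along(fo$type1)], each = nrow(mats$A0))
    B0 <- mats$B0 * rep(rho[length(fo$type1) + seq_along(fo$type2)],
                        each = nrow(mats$B0))
    sol <- solve_equilibrium_batch(params, mats$L, A0, B0, tol = 1e-11,
                                   warm = warm$state)
    warm$state <- list(a = sol$a, b = sol$b)
    r <- fo$obs$y - sol$S
    if (is.null(rows)) r else r[rows]
  }
  # hierarchical initialization: each ligand's K/eps block is pre-fitted
  # against the rows that involve only that ligand (gradient + self-pair),
  # with the other ligands held at the drawn values
  nL <- length(fo$ligands)
  npc <- length(fo$type1) * length(fo$type2)
  single_rows <- lapply(fo$ligands, function(l)
    which(fo$obs$ligand_a == l &
            (is.na(fo$obs$ligand_b) | fo$obs$ligand_b == l)))
  refine_ligand <- function(par, i) {
    idxK <- (seq_len(npc) - 1) * nL + i
    idx <- c(idxK, nc + idxK)
    rows <- single_rows[[i]]
    if (!length(rows)) return(par)
    fn <- function(sub) {
      p <- par
      p[idx] <- sub
      resid_fun(p, rows)
    }
    r <- tryCatch(
      minpack.lm::nls.lm(par[idx], lower = lower[idx], upper = upper[idx],
                         fn = fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 60L, ptol = 1e-11, ftol = 1e-13)),
      error = function(e) NULL)
    if (!is.null(r)) par[idx] <- r$par
    par
  }
  # per-observation complex abundances at unit activity, for the linear
  # activity profiling (variable projection)
  abundance_matrix <- function(parK, rho) {
    params <- .par_to_params(c(parK, rep(0, nc)), fo, nc)
    A0 <- mats$A0 * rep(rho[seq_along(fo$type1)], each = nrow(mats$A0))
    B0 <- mats$B0 * rep(rho[length(fo$type1) + seq_along(fo$type2)],
                        each = nrow(mats$B0))
    sol <- solve_equilibrium_batch(params, mats$L, A0, B0, tol = 1e-10)
    X <- matrix(0, nrow(mats$L), nc)
    dims <- dim(params$K)
    for (cc in seq_len(nc)) {
      idx <- arrayInd(cc, dims)
      X[, cc] <- params$K[cc] * mats$L[, idx[1]] * sol$a[, idx[2]] *
        sol$b[, idx[3]]
    }
    X
  }
  # reset the activities of a parameter vector to their constrained linear
  # optimum given its affinities and rescalings
  profile_eps <- function(par) {
    X <- abundance_matrix(par[seq_len(nc)], 10^par[2 * nc + seq_len(nr)])
    eps <- tryCatch(pracma::lsqnonneg(X, fo$obs$y)$x,
                    error = function(e) 10^par[nc + seq_len(nc)])
    par[nc + seq_len(nc)] <- log10(pmin(pmax(eps, eps_bounds[1]),
                                        eps_bounds[2]))
    par
  }
  set.seed(seed)
  starts <- lapply(seq_len(n_starts), function(i) {
    parK <- runif(nc, lower[1], upper[1])
    rho_log <- runif(nr, lower[2 * nc + 1], upper[2 * nc + 1])
    par <- profile_eps(c(parK, rep(0, nc), rho_log))
    for (l in seq_len(nL)) par <- refine_ligand(par, l)
    par
  })
  run <- function(p0, maxit) {
    warm$state <- NULL
    tryCatch(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxit, ptol = 1e-10, ftol = 1e-12)),
      error = function(e) NULL)
  }
  # one coarse stage = a short descent, an activity re-profile (which can
  # hop out of an activity-miscalibrated basin), and a second descent
  coarse_run <- function(p0) {
    f <- run(p0, maxit_coarse)
    if (is.null(f)) return(NULL)
    f2 <- run(profile_eps(f$par), maxit_coarse)
    if (is.null(f2) || sum(f2$fvec^2) >= sum(f$fvec^2)) f else f2
  }
  coarse <- vector("list", n_starts)
  for (i in seq_len(n_starts)) coarse[[i]] <- coarse_run(starts[[i]])
  rss <- vapply(coarse, function(f)
    if (is.null(f)) Inf else sum(f$fvec^2), numeric(1))
  top <- order(rss)[seq_len(min(n_polish, n_starts))]
  for (i in top) {
    if (is.null(coarse[[i]])) next
    cur <- coarse[[i]]
    for (round in 1:2) {
      pol <- run(profile_eps(cur$par), maxit_polish)
      if (!is.null(pol) && sum(pol$fvec^2) < sum(cur$fvec^2)) cur <- pol
    }
    if (sum(cur$fvec^2) < rss[i]) {
      coarse[[i]] <- cur
      rss[i] <- sum(cur$fvec^2)
    }
  }
  # deep-polish the incumbent: keep alternating re-profile + descent while
  # it still improves appreciably
  ib <- which.min(rss)
  if (is.finite(rss[ib])) {
    cur <- coarse[[ib]]
    for (round in seq_len(4L)) {
      pol <- run(profile_eps(cur$par), maxit_polish)
      if (is.null(pol)) break
      improved <- sum(pol$fvec^2) < 0.99 * sum(cur$fvec^2)
      if (sum(pol$fvec^2) < sum(cur$fvec^2)) cur <- pol
      if (!improved) break
    }
    if (sum(cur$fvec^2) < rss[ib]) {
      coarse[[ib]] <- cur
      rss[ib] <- sum(cur$fvec^2)
    }
  }
  results <- lapply(order(rss), function(i) {
    f <- coarse[[i]]
    if (is.null(f)) return(NULL)
    list(params = .par_to_params(f$par, fo, nc),
         rho = setNames(10^f$par[2 * nc + seq_len(nr)],
                        c(fo$type1, fo$type2)),
         residual = sum(f$fvec^2), start = i,
         converged = f$info %in% 1:4)
  })
  structure(Filter(Negate(is.null), results), class = "bmp_fit_list")
}

#' Predict normalized responses from a fit result
#'
#' @param fit one element of a `bmp_fit_list`.
#' @param fo the [assemble_observations()] object it was fitted to.
#' @return numeric vector of predicted responses, aligned with `fo$obs`.
#' @export
predict_fit <- function(fit, fo) {
  mats <- .fit_matrices(fo)
  rho <- fit$rho
  A0 <- mats$A0 * rep(rho[fo$type1], each = nrow(mats$A0))
  B0 <- mats$B0 * rep(rho[fo$type2], each = nrow(mats$B0))
  solve_equilibrium_batch(fit$params, mats$L, A0, B0, tol = 1e-10)$S
}

# per-pair summary interaction categories from a noiseless response table
# (columns: context_id, row_id, row_kind, ligand_a, ligand_b, ratio_index,
# value); reuses the gated pipeline with duplicated pseudo-replicates, so
# the theta effect-size rule applies identically
.noiseless_categories <- function(tab, n_ratios, split = 0.5) {
  pseudo <- rbind(cbind(tab, replicate_id = 1L), cbind(tab, replicate_id = 2L))
  pseudo$response <- pseudo$value
  pseudo$dropped <- FALSE
  pseudo$tech_rep <- FALSE
  interaction_table(pseudo, n_ratios = n_ratios, split = split)$pairs
}

#' Interaction categories implied by noiseless responses
#'
#' Runs the IC computation and effect-size gating directly on noiseless
#' response values (ground truth from [design_truth()], or model
#' predictions), giving the reference categories that a pipeline run on
#' noisy data is trying to recover.
#'
#' @param tab data.frame with `context_id`, `row_id`, `row_kind`,
#'   `ligand_a`, `ligand_b`, `ratio_index` and a value column.
#' @param value name of the value column (default `"S_true"`).
#' @param n_ratios ratios per row.
#' @param split weak/strong antagonism threshold.
#' @return per-pair summary data.frame as in [interaction_table()].
#' @export
noiseless_interactions <- function(tab, value = "S_true", n_ratios = 9L,
                                   split = 0.5) {
  tab$value <- tab[[value]]
  .noiseless_categories(tab, n_ratios, split)
}

#' Filter fitted solutions by qualitative agreement
#'
#' Accepts only fits that reproduce required interaction categories for
#' named (context, pair) entries -- the hard-to-fit suppressive and
#' synergistic pairs -- and whose residual is within a cap (default twice
#' the best residual). Category predictions are computed from each fit's
#' noiseless predicted responses with the same IC and effect-size rules as
#' the data pipeline.
#'
#' @param fits a `bmp_fit_list`.
#' @param fo the [assemble_observations()] object.
#' @param criteria data.frame with `context_id`, `ligand_a`, `ligand_b`,
#'   `required_category`; an empty/NULL criteria set accepts all fits with
#'   a warning.
#' @param residual_cap multiplier of the best residual.
#' @return list with `accepted` (`bmp_fit_list`), `pass` (logical matrix:
#'   fits x criteria), `predicted_pairs` (list of per-fit category tables).
#' @export
filter_solutions <- function(fits, fo, criteria = NULL, residual_cap = 2) {
  if (is.null(criteria) || !nrow(criteria)) {
    warning("no filtering criteria supplied; accepting all fits")
    return(list(accepted = fits,
                pass = matrix(TRUE, length(fits), 0),
                predicted_pairs = NULL))
  }
  best <- min(vapply(fits, `[[`, numeric(1), "residual"))
  pred_pairs <- lapply(fits, function(f) {
    tab <- fo$obs
    tab$value <- predict_fit(f, fo)
    .noiseless_categories(tab, fo$n_ratios)
  })
  pass <- matrix(FALSE, length(fits), nrow(criteria))
  for (i in seq_along(fits)) {
    pp <- pred_pairs[[i]]
    for (j in seq_len(nrow(criteria))) {
      cr <- criteria[j, ]
      hit <- pp$context_id == cr$context_id &
        ((pp$ligand_a == cr$ligand_a & pp$ligand_b == cr$ligand_b) |
           (pp$ligand_a == cr$ligand_b & pp$ligand_b == cr$ligand_a))
      pass[i, j] <- any(hit) && all(pp$category[hit] == cr$required_category)
    }
  }
  resid_ok <- vapply(fits, `[[`, numeric(1), "residual") <= residual_cap * best
  acc <- which(apply(pass, 1, all) & resid_ok)
  list(accepted = structure(fits[acc], class = "bmp_fit_list"),
       pass = pass, residual_ok = resid_ok,
       predicted_pairs = pred_pairs)
}

#' Recovery report against a known synthetic truth
#'
#' For each accepted fit reports the response-space R-squared, the fraction
#' of the truth's summary interaction categories it reproduces, and the
#' correlation between log10 affinity and log10 activity across complexes
#' (competitive fits tend to trade the two off, giving negative
#' correlations).
#'
#' @param truth_categories per-pair category table of the generating truth
#'   (from [noiseless_interactions()] on the truth ledger, restricted to
#'   the fitted ligands/contexts).
#' @param accepted a `bmp_fit_list` of accepted fits.
#' @param fo the [assemble_observations()] object.
#' @return data.frame: one row per accepted fit with `r_squared`,
#'   `category_agreement`, `k_eps_correlation`, `residual`.
#' @export
evaluate_recovery <- function(truth_categories, accepted, fo) {
  if (!length(accepted))
    return(data.frame(r_squared = numeric(0), category_agreement = numeric(0),
                      k_eps_correlation = numeric(0), residual = numeric(0)))
  y <- fo$obs$y
  sst <- sum((y - mean(y))^2)
  key <- function(d) paste(d$context_id, pmin(d$ligand_a, d$ligand_b),
                           pmax(d$ligand_a, d$ligand_b))
  tc <- setNames(truth_categories$category, key(truth_categories))
  out <- lapply(accepted, function(f) {
    pred <- predict_fit(f, fo)
    tab <- fo$obs
    tab$value <- pred
    pp <- .noiseless_categories(tab, fo$n_ratios)
    pc <- setNames(pp$category, key(pp))
    shared <- intersect(names(tc), names(pc))
    data.frame(r_squared = 1 - sum((y - pred)^2) / sst,
               category_agreement = mean(pc[shared] == tc[shared]),
               k_eps_correlation = cor(log10(pmax(as.vector(f$params$K), 1e-4)),
                                       log10(pmax(as.vector(f$params$eps), 1e-4))),
               residual = f$residual)
  })
  do.call(rbind, out)
}
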