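#' Construct a competitive-binding model parameter set
#'
#' Affinities \eqn{K_{ijk}} and activities \eqn{\epsilon_{ijk}} for every
#' (ligand i, Type I receptor j, Type II receptor k) triple. One ligand bound
#' to one receptor of each class forms a trimeric signaling complex
#' \eqn{T_{ijk} = K_{ijk} L_i A_j B_k} that contributes
#' \eqn{\epsilon_{ijk} T_{ijk}} to the total pathway output \eqn{S}.
#'
#' @param table long-format data.frame with columns `ligand`, `type1`,
#'   `type2`, `K`, `eps`. Triples absent from the table get K = eps = 0.
#' @param ligands,type1,type2 optional component orderings; defaults to the
#'   order of first appearance in `table`.
#' @return an object of class `bmp_params`: a list with 3-d arrays `K` and
#'   `eps` (dimensions ligand x Type I x Type II, dimnames set) and the
#'   component name vectors.
#' @examples
#' p <- model_params(data.frame(ligand = "L1", type1 = "A1", type2 = "B1",
#'                              K = 1, eps = 1))
#' @export
model_params <- function(table, ligands = NULL, type1 = NULL, type2 = NULL) {
  need <- c("ligand", "type1", "type2", "K", "eps")
  if (!all(need %in% names(table)))
    .stopf("parameter table must have columns %s", paste(need, collapse = ", "))
  if (any(!is.finite(table$K)) || any(!is.finite(table$eps)) ||
      any(table$K < 0) || any(table$eps < 0))
    .stopf("K and eps must be finite and nonnegative")
  if (is.null(ligands)) ligands <- unique(as.character(table$ligand))
  if (is.null(type1))   type1   <- unique(as.character(table$type1))
  if (is.null(type2))   type2   <- unique(as.character(table$type2))
  bad <- setdiff(unique(as.character(table$ligand)), ligands)
  if (length(bad)) .stopf("ligand(s) %s not in declared ligand set",
                          paste(bad, collapse = ", "))
  dn <- list(ligands, type1, type2)
  K <- array(0, dim = lengths(dn), dimnames = dn)
  E <- K
  idx <- cbind(match(as.character(table$ligand), ligands),
               match(as.character(table$type1), type1),
               match(as.character(table$type2), type2))
  if (anyNA(idx)) .stopf("parameter table names receptors outside the declared sets")
  K[idx] <- table$K
  E[idx] <- table$eps
  structure(list(K = K, eps = E, ligands = ligands, type1 = type1,
                 type2 = type2),
            class = "bmp_params")
}

#' @export
as.data.frame.bmp_params <- function(x, ...) {
  g <- expand.grid(ligand = x$ligands, type1 = x$type1, type2 = x$type2,
                   stringsAsFactors = FALSE)
  g$K <- as.vector(x$K)
  g$eps <- as.vector(x$eps)
  g
}

#' @export
print.bmp_params <- function(x, ...) {
  cat(sprintf("bmp_params: %d ligands x %d Type I x %d Type II (%d complexes)\n",
              length(x$ligands), length(x$type1), length(x$type2),
              length(x$K)))
  invisible(x)
}

#' Receptor expression context
#'
#' Total Type I (`A0`) and Type II (`B0`) receptor levels for one cell
#' context, in relative expression units. Optional rescaling factors `rho`
#' (one per receptor, bounded 3-fold either way) absorb measurement
#' uncertainty in the expression estimates.
#'
#' @param A0,B0 named nonnegative numeric vectors of total receptor levels.
#' @param rho1,rho2 optional named rescaling factors in `[1/3, 3]` applied
#'   multiplicatively to `A0` and `B0`.
#' @return object of class `receptor_context`.
#' @export
receptor_context <- function(A0, B0, rho1 = NULL, rho2 = NULL) {
  if (is.null(names(A0)) || is.null(names(B0)))
    .stopf("A0 and B0 must be named vectors")
  if (any(A0 < 0) || any(B0 < 0)) .stopf("receptor levels must be nonnegative")
  apply_rho <- function(x, rho, what) {
    if (is.null(rho)) return(x)
    if (any(rho < 1 / 3 - 1e-12) || any(rho > 3 + 1e-12))
      .stopf("%s rescaling factors must lie in [1/3, 3]", what)
    x[names(rho)] <- x[names(rho)] * rho
    x
  }
  structure(list(A0 = apply_rho(A0, rho1, "Type I"),
                 B0 = apply_rho(B0, rho2, "Type II")),
            class = "receptor_context")
}

.check_components <- function(params, env, ctx) {
  if (is.null(names(env))) .stopf("ligand environment must be a named vector")
  bad <- setdiff(names(env), params$ligands)
  if (length(bad)) .stopf("no parameters for ligand(s): %s",
                          paste(bad, collapse = ", "))
  if (!setequal(names(ctx$A0), params$type1) ||
      !setequal(names(ctx$B0), params$type2))
    .stopf("context receptors do not match parameter set receptors")
}

# Dense dose matrix (environments x ligands) in params ligand order
.env_matrix <- function(params, envs) {
  L <- matrix(0, length(envs), length(params$ligands),
              dimnames = list(NULL, params$ligands))
  for (e in seq_along(envs)) {
    v <- envs[[e]]
    L[e, names(v)] <- v
  }
  L
}

#' Solve the binding equilibrium for a batch of ligand environments
#'
#' Vectorized engine behind [solve_equilibrium()]: one call solves every row
#' of a dose matrix in its (possibly row-specific) receptor context. Used by
#' the synthetic-data generator and the parameter-fitting objective, where
#' hundreds of environments are solved per evaluation.
#'
#' @param params a [model_params()] object.
#' @param L dose matrix (environments x ligands), columns in params ligand
#'   order.
#' @param A0,B0 receptor level matrices (environments x receptors), or single
#'   rows recycled to all environments.
#' @param tol relative convergence tolerance on free-receptor levels.
#' @param maxit iteration cap for the damped fixed point; environments that
#'   fail are retried with a Newton fallback.
#' @param warm optional list with `a`, `b` matrices from a previous solve of
#'   the same environments, used as the starting point.
#' @return list with free-receptor matrices `a`, `b`, output vector `S`, and
#'   solver diagnostics.
#' @export
solve_equilibrium_batch <- function(params, L, A0, B0, tol = 1e-12,
                                    maxit = 100000L, warm = NULL) {
  nE <- nrow(L)
  if (is.null(dim(A0)) || nrow(A0) == 1L)
    A0 <- matrix(as.numeric(A0), nE, length(params$type1), byrow = TRUE)
  if (is.null(dim(B0)) || nrow(B0) == 1L)
    B0 <- matrix(as.numeric(B0), nE, length(params$type2), byrow = TRUE)
  use_warm <- !is.null(warm) && nrow(warm$a) == nE
  a0 <- if (use_warm) warm$a else matrix(0, nE, ncol(A0))
  b0 <- if (use_warm) warm$b else matrix(0, nE, ncol(B0))
  sol <- solve_equilibrium_batch_cpp(params$K, L, A0, B0, tol,
                                     as.integer(maxit), a0, b0, use_warm)
  if (!all(sol$converged)) {
    for (e in which(!sol$converged)) {
      nf <- .newton_free_receptors(params, L[e, ], A0[e, ], B0[e, ], tol)
      if (is.null(nf))
        .stopf("equilibrium solver failed to converge for environment %d (fixed point and Newton fallback); max relative update %.3g",
               e, tol)
      sol$a[e, ] <- nf$a
      sol$b[e, ] <- nf$b
      sol$converged[e] <- TRUE
    }
  }
  S <- pathway_output_cpp(params$K, params$eps, L, sol$a, sol$b)
  list(a = sol$a, b = sol$b, S = S, iterations = sol$iterations,
       converged = sol$converged)
}

# Newton fallback on x = (a, b) with analytic Jacobian; small systems only.
.newton_free_receptors <- function(params, Lrow, A0, B0, tol) {
  nI <- length(A0); nII <- length(B0)
  # C[j,k] = sum_i K_ijk L_i
  C <- apply(params$K * Lrow, c(2, 3), sum)
  C <- matrix(C, nI, nII)
  x <- c(A0, B0) * 0.5
  for (it in seq_len(200L)) {
    a <- x[seq_len(nI)]; b <- x[nI + seq_len(nII)]
    Fa <- a * (1 + C %*% b) - A0
    Fb <- b * (1 + t(C) %*% a) - B0
    J <- matrix(0, nI + nII, nI + nII)
    diag(J)[seq_len(nI)] <- 1 + C %*% b
    diag(J)[nI + seq_len(nII)] <- 1 + t(C) %*% a
    J[seq_len(nI), nI + seq_len(nII)] <- C * a
    J[nI + seq_len(nII), seq_len(nI)] <- t(C) * b
    step <- tryCatch(solve(J, c(Fa, Fb)), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    xn <- pmin(pmax(x - step, 0), c(A0, B0))
    if (max(abs(xn - x) / pmax(x, 1e-300)) < tol) {
      return(list(a = xn[seq_len(nI)], b = xn[nI + seq_len(nII)]))
    }
    x <- xn
  }
  NULL
}

#' Solve the competitive binding equilibrium for one ligand environment
#'
#' Finds the unique nonnegative steady state of the mass-action binding
#' network in which every ligand competes for every Type I / Type II receptor
#' pair, under the reservoir assumption (ligand concentrations held
#' constant). Free receptors satisfy
#' \deqn{A_j (1 + \sum_{ik} K_{ijk} L_i B_k) = A_j^0, \quad
#'       B_k (1 + \sum_{ij} K_{ijk} L_i A_j) = B_k^0.}
#'
#' @param params a [model_params()] object.
#' @param env named nonnegative vector of ligand concentrations.
#' @param ctx a [receptor_context()].
#' @inheritParams solve_equilibrium_batch
#' @return object of class `equilibrium_state`: free receptors `A`, `B`,
#'   complex array `T` (ligand x Type I x Type II), total output `S`, solver
#'   diagnostics (`iterations`, `residual` = max relative conservation
#'   error).
#' @examples
#' p <- model_params(data.frame(ligand = "L", type1 = "A", type2 = "B",
#'                              K = 1, eps = 1))
#' st <- solve_equilibrium(p, c(L = 1), receptor_context(c(A = 1), c(B = 1)))
#' st$A  # (sqrt(5) - 1) / 2
#' @export
solve_equilibrium <- function(params, env, ctx, tol = 1e-12, maxit = 100000L) {
  .check_components(params, env, ctx)
  if (any(env < 0) || any(!is.finite(env))) .stopf("doses must be finite and nonnegative")
  L <- .env_matrix(params, list(env))
  A0 <- ctx$A0[params$type1]
  B0 <- ctx$B0[params$type2]
  sol <- solve_equilibrium_batch(params, L, A0, B0, tol = tol, maxit = maxit)
  a <- setNames(drop(sol$a), params$type1)
  b <- setNames(drop(sol$b), params$type2)
  Tarr <- params$K * rep(L[1, ], times = length(a) * length(b)) *
    rep(a, each = length(params$ligands)) *
    rep(b, each = length(params$ligands) * length(a))
  consA <- a + apply(Tarr, 2, sum) - A0
  consB <- b + apply(Tarr, 3, sum) - B0
  residual <- max(abs(c(consA / pmax(A0, 1e-300), consB / pmax(B0, 1e-300))))
  structure(list(A = a, B = b, T = Tarr, S = sol$S[1],
                 iterations = sol$iterations[1], residual = residual),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("equilibrium_state: S = %.6g (%d iterations, conservation residual %.2g)\n",
              x$S, x$iterations, x$residual))
  invisible(x)
}

#' Kinetic-relaxation oracle for the binding equilibrium
#'
#' Independent check on [solve_equilibrium()]: integrates the mass-action
#' kinetics \eqn{dT_{ijk}/dt = k_{off} (K_{ijk} L_i A_j B_k - T_{ijk})} with
#' conservation-derived free receptors until relaxed, using a stiff ODE
#' integrator. Shares no code with the fixed-point solver.
#'
#' @inheritParams solve_equilibrium
#' @param koff unbinding rate setting the relaxation timescale.
#' @param tol relative change per unit time below which the state is
#'   considered relaxed.
#' @return an `equilibrium_state` (diagnostics: integration time reached).
#' @export
steady_state_oracle <- function(params, env, ctx, koff = 1, tol = 1e-10) {
  .check_components(params, env, ctx)
  Lv <- setNames(numeric(length(params$ligands)), params$ligands)
  Lv[names(env)] <- env
  A0 <- ctx$A0[params$type1]
  B0 <- ctx$B0[params$type2]
  K <- params$K
  nL <- length(Lv); nI <- length(A0); nII <- length(B0)
  Lrep <- array(Lv, dim = dim(K))
  deriv <- function(t, y, parms) {
    Tarr <- array(pmax(y, 0), dim = dim(K))
    a <- pmax(A0 - apply(Tarr, 2, sum), 0)
    b <- pmax(B0 - apply(Tarr, 3, sum), 0)
    ab <- outer(a, b)
    target <- K * Lrep * aperm(array(ab, c(nI, nII, nL)), c(3, 1, 2))
    list(koff * (as.vector(target) - y))
  }
  y0 <- numeric(length(K))
  t_end <- 40 / koff
  repeat {
    out <- deSolve::ode(y0, times = c(0, t_end / 2, t_end), func = deriv,
                        parms = NULL, method = "lsoda",
                        rtol = 1e-12, atol = 1e-14)
    yl <- out[nrow(out), -1]
    ym <- out[nrow(out) - 1, -1]
    if (max(abs(yl - ym) / pmax(abs(yl), 1e-300)) < tol || t_end > 1e7 / koff)
      break
    y0 <- yl
    t_end <- t_end * 4
  }
  Tarr <- array(pmax(yl, 0), dim = dim(K), dimnames = dimnames(K))
  a <- A0 - apply(Tarr, 2, sum)
  b <- B0 - apply(Tarr, 3, sum)
  structure(list(A = a, B = b, T = Tarr,
                 S = sum(params$eps * Tarr), iterations = NA_integer_,
                 residual = 0),
            class = "equilibrium_state")
}

#' Decompose total output by signaling complex
#'
#' For a solved state, reports each complex's share of total complex
#' abundance and of total output, plus the cumulative-output curve over
#' complexes sorted by increasing abundance share. A minority of complexes
#' carrying a majority of the output is the signature of anti-correlated
#' affinity and activity.
#'
#' @param state an `equilibrium_state`.
#' @param params the [model_params()] used to solve it.
#' @return data.frame with one row per complex: `ligand`, `type1`, `type2`,
#'   `abundance_share`, `output_share`, `cum_abundance`, `cum_output`
#'   (cumulative over complexes sorted by abundance share). If `S` is zero,
#'   output shares are `NA` and the attribute `degenerate` is set.
#' @export
complex_output_decomposition <- function(state, params) {
  g <- expand.grid(ligand = params$ligands, type1 = params$type1,
                   type2 = params$type2, stringsAsFactors = FALSE)
  Tv <- as.vector(state$T)
  out <- as.vector(params$eps * state$T)
  totT <- sum(Tv)
  g$abundance_share <- if (totT > 0) Tv / totT else rep(NA_real_, length(Tv))
  degenerate <- state$S <= 0
  g$output_share <- if (!degenerate) out / state$S else rep(NA_real_, length(out))
  o <- order(g$abundance_share)
  g <- g[o, , drop = FALSE]
  g$cum_abundance <- cumsum(ifelse(is.na(g$abundance_share), 0, g$abundance_share))
  g$cum_output <- cumsum(ifelse(is.na(g$output_share), 0, g$output_share))
  rownames(g) <- NULL
  attr(g, "degenerate") <- degenerate
  g
}

#' Attribute pathway output to ligands and Type I receptors
#'
#' Solves the model for each ligand alone and for the full combined
#' environment, attributing output to ligand i as
#' \eqn{\sum_{jk} \epsilon_{ijk} T_{ijk}} and to Type I receptor j as
#' \eqn{\sum_{ik} \epsilon_{ijk} T_{ijk}}, and reports the percent change of
#' each ligand's attributed output between the single-ligand and combined
#' environments. With `ctx2`, also reports the percent change of each
#' ligand's and receptor's single-environment output between the two
#' contexts (receptor-perturbation redistribution).
#'
#' @inheritParams solve_equilibrium
#' @param ctx2 optional second [receptor_context()] to compare against.
#' @return list with data.frames `ligands` (individual vs combined output and
#'   percent change) and `type1` (per-receptor attribution), and, when `ctx2`
#'   is given, `context_change` (percent change across contexts, per ligand
#'   and Type I receptor, single-ligand environments). Percent changes with a
#'   zero baseline are `NA` (flagged in `undefined`).
#' @export
ligand_output_attribution <- function(params, env, ctx, ctx2 = NULL) {
  env <- env[env > 0]
  if (!length(env)) .stopf("environment has no ligand at positive dose")
  attrib <- function(state) {
    out <- params$eps * state$T
    list(ligand = setNames(apply(out, 1, sum), params$ligands),
         type1 = setNames(apply(out, 2, sum), params$type1))
  }
  solo <- lapply(names(env), function(l)
    attrib(solve_equilibrium(params, env[l], ctx)))
  names(solo) <- names(env)
  comb <- attrib(solve_equilibrium(params, env, ctx))
  indiv <- vapply(names(env), function(l) solo[[l]]$ligand[l], numeric(1))
  paired <- comb$ligand[names(env)]
  pct <- ifelse(indiv > 0, 100 * (paired - indiv) / indiv, NA_real_)
  lig <- data.frame(ligand = names(env), individual = unname(indiv),
                    combined = unname(paired),
                    pct_change = unname(pct),
                    undefined = unname(indiv <= 0))
  t1 <- data.frame(type1 = params$type1,
                   combined = unname(comb$type1))
  res <- list(ligands = lig, type1 = t1)
  if (!is.null(ctx2)) {
    solo2 <- lapply(names(env), function(l)
      attrib(solve_equilibrium(params, env[l], ctx2)))
    names(solo2) <- names(env)
    indiv2 <- vapply(names(env), function(l) solo2[[l]]$ligand[l], numeric(1))
    lp <- ifelse(indiv > 0, 100 * (indiv2 - indiv) / indiv, NA_real_)
    r1 <- vapply(params$type1, function(j)
      sum(vapply(solo, function(s) s$type1[j], numeric(1))), numeric(1))
    r2 <- vapply(params$type1, function(j)
      sum(vapply(solo2, function(s) s$type1[j], numeric(1))), numeric(1))
    rp <- ifelse(r1 > 0, 100 * (r2 - r1) / r1, NA_real_)
    res$context_change <- list(
      ligands = data.frame(ligand = names(env), baseline = unname(indiv),
                           perturbed = unname(indiv2),
                           pct_change = unname(lp),
                           undefined = unname(indiv <= 0)),
      type1 = data.frame(type1 = params$type1, baseline = unname(r1),
                         perturbed = unname(r2), pct_change = unname(rp),
                         undefined = unname(r1 <= 0)))
  }
  res
}
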