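#' Fit a Hill dose-response curve
#'
#' Minimizes the total squared error of \eqn{y = y_{max} c^n / (EC_{50}^n +
#' c^n)} over all replicate points jointly, with the baseline fixed at 0
#' (responses are background subtracted). `ymax` is profiled out in closed
#' form at every step, and a deterministic 3x3 grid of (EC50, n) starts
#' feeds a bounded local minimization, so the fit involves no randomness.
#'
#' @param doses nonnegative dose vector (one entry per point; replicate
#'   points repeat the dose).
#' @param responses responses, same length as `doses`.
#' @param n_bounds bounds on the Hill coefficient.
#' @param ec50_bounds bounds on EC50; default `[min dose / 100, max dose *
#'   100]` over nonzero doses.
#' @return object of class `hill_fit`: list with `ymax`, `ec50`, `n`,
#'   `rss`, and `non_activator` (TRUE when all responses are <= 0, in which
#'   case `ymax = 0` and the other parameters are `NA`).
#' @examples
#' d <- 10^seq(-1, 2, length.out = 8)
#' fit_hill(d, 1000 * d / (10 + d))
#' @export
fit_hill <- function(doses, responses, n_bounds = c(0.1, 10),
                     ec50_bounds = NULL) {
  ok <- is.finite(doses) & is.finite(responses)
  doses <- doses[ok]; responses <- responses[ok]
  nz <- unique(doses[doses > 0])
  if (length(nz) < 4L) .stopf("fit_hill needs >= 4 distinct nonzero doses")
  if (all(responses <= 0)) {
    return(structure(list(ymax = 0, ec50 = NA_real_, n = NA_real_,
                          rss = sum(responses^2), non_activator = TRUE),
                     class = "hill_fit"))
  }
  if (is.null(ec50_bounds)) ec50_bounds <- c(min(nz) / 100, max(nz) * 100)
  obj <- function(par) {
    ec50 <- exp(par[1]); n <- exp(par[2])
    h <- doses^n / (ec50^n + doses^n)
    h[doses == 0] <- 0
    ym <- max(sum(responses * h) / max(sum(h^2), 1e-300), 0)
    sum((responses - ym * h)^2)
  }
  lower <- log(c(ec50_bounds[1], n_bounds[1]))
  upper <- log(c(ec50_bounds[2], n_bounds[2]))
  starts <- expand.grid(
    ec50 = log(exp(seq(log(min(nz)), log(max(nz)), length.out = 3))),
    n = log(c(0.5, 1, 2)))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[s, ]), lower), upper)
    fit <- optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ec50 <- exp(best$par[1]); n <- exp(best$par[2])
  h <- doses^n / (ec50^n + doses^n)
  h[doses == 0] <- 0
  ymax <- max(sum(responses * h) / max(sum(h^2), 1e-300), 0)
  structure(list(ymax = ymax, ec50 = ec50, n = n, rss = best$value,
                 non_activator = FALSE),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$non_activator) cat("hill_fit: non-activator (ymax = 0)\n")
  else cat(sprintf("hill_fit: ymax = %.4g, EC50 = %.4g, n = %.3g, RSS = %.4g\n",
                   x$ymax, x$ec50, x$n, x$rss))
  invisible(x)
}

#' Relative Ligand Strength (RLS)
#'
#' A ligand's pathway activity at saturating (top-dose) concentration
#' normalized by the activity of the strongest ligand: the median top-dose
#' response of each ligand divided by the maximum of those medians across
#' the panel. Negative medians are clipped to zero, so RLS lies in [0, 1]
#' with the strongest ligand at exactly 1. The measured top-dose median is
#' used rather than the fitted Hill plateau so that non-saturating ligands
#' still receive a defined RLS.
#'
#' @param top_responses named list: per ligand, the numeric vector of
#'   retained top-dose responses (all replicates).
#' @return named numeric vector of RLS values.
#' @examples
#' relative_ligand_strength(list(A = c(990, 1010), B = 500, C = 10))
#' @export
relative_ligand_strength <- function(top_responses) {
  if (!length(top_responses)) .stopf("relative_ligand_strength: empty input")
  med <- vapply(top_responses, function(v) {
    if (!length(v)) .stopf("a ligand has no retained top-dose measurement")
    max(median(v), 0)
  }, numeric(1))
  m <- max(med)
  if (m == 0) return(med)  # no activator anywhere; all RLS 0
  med / m
}

#' Per-ligand dose-response summary of a processed screen
#'
#' Fits a Hill curve to every ligand's gradient (all replicates jointly) and
#' computes RLS from the top-dose wells, per context.
#'
#' @param processed a processed table (see [preprocess_dataset()]).
#' @param panel the [ligand_panel()] (provides each ligand's top dose).
#' @return data.frame: `context_id`, `ligand`, `ymax`, `ec50`, `n`, `rss`,
#'   `non_activator`, `rls`.
#' @export
dose_response_table <- function(processed, panel) {
  keep <- !processed$dropped & !processed$tech_rep &
    processed$row_kind == "gradient"
  g <- processed[keep, , drop = FALSE]
  out <- list()
  for (cx in unique(g$context_id)) {
    gc <- g[g$context_id == cx, , drop = FALSE]
    tops <- list()
    fits <- list()
    for (lig in panel$ligand) {
      gl <- gc[gc$ligand_a == lig, , drop = FALSE]
      if (!nrow(gl)) .stopf("no gradient wells for ligand %s in context %s",
                            lig, cx)
      fits[[lig]] <- fit_hill(gl$conc_a, gl$response)
      top <- panel$top[panel$ligand == lig]
      tops[[lig]] <- gl$response[gl$conc_a == top]
    }
    rls <- relative_ligand_strength(tops)
    out[[cx]] <- data.frame(
      context_id = cx, ligand = panel$ligand,
      ymax = vapply(fits, `[[`, numeric(1), "ymax"),
      ec50 = vapply(fits, `[[`, numeric(1), "ec50"),
      n = vapply(fits, `[[`, numeric(1), "n"),
      rss = vapply(fits, `[[`, numeric(1), "rss"),
      non_activator = vapply(fits, `[[`, logical(1), "non_activator"),
      rls = as.numeric(rls[panel$ligand]), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
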