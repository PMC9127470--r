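#' Define a ligand panel
#'
#' A panel is the ordered set of ligands in the screen, each with the top
#' (near-saturating) concentration used in its dose grid and the fold
#' dilution of the geometric ladder below it.
#'
#' @param ligands character vector of unique ligand identifiers; their order
#'   is the canonical ligand order used everywhere downstream.
#' @param top per-ligand top concentration (mass/volume units, e.g. ng/mL);
#'   recycled if scalar.
#' @param fold per-ligand dilution fold (> 1); recycled if scalar.
#' @return object of class `ligand_panel` (a data.frame).
#' @examples
#' ligand_panel(paste0("L", 1:10), top = 100, fold = 3)
#' @export
ligand_panel <- function(ligands, top = 100, fold = 3) {
  ligands <- as.character(ligands)
  if (anyDuplicated(ligands)) .stopf("ligand identifiers must be unique")
  if (length(ligands) < 1L) .stopf("panel needs at least one ligand")
  top <- rep_len(top, length(ligands))
  fold <- rep_len(fold, length(ligands))
  if (any(top <= 0)) .stopf("top concentrations must be positive")
  if (any(fold <= 1)) .stopf("dilution folds must exceed 1")
  structure(data.frame(ligand = ligands, top = top, fold = fold,
                       stringsAsFactors = FALSE),
            class = c("ligand_panel", "data.frame"))
}

#' Trapezoid concentration-ratio sweep for a ligand pair
#'
#' Returns `n_ratios` dose pairs sweeping from A-dominant to B-dominant while
#' keeping at least one ligand at its top (near-saturating) dose in every
#' pair: A is held at `topA` for the first `ceiling(n/2)` ratios while B
#' climbs a geometric ladder to `topB`, then B is held at `topB` while A
#' descends the mirrored ladder. The center ratio of an odd-length sweep has
#' both ligands at their top dose.
#'
#' @param topA,topB top doses of the two ligands (> 0).
#' @param n_ratios number of ratios (>= 1).
#' @param foldA,foldB dilution fold of each ladder step.
#' @return data.frame with columns `ratio_index`, `dose_a`, `dose_b`.
#' @examples
#' ratio_concentrations(100, 100, 9)
#' @export
ratio_concentrations <- function(topA, topB, n_ratios = 9L, foldA = 3,
                                 foldB = foldA) {
  if (n_ratios < 1L) .stopf("n_ratios must be >= 1")
  if (topA <= 0 || topB <= 0) .stopf("top doses must be positive")
  n <- as.integer(n_ratios)
  mid <- ceiling(n / 2)
  t <- seq_len(n)
  dose_a <- ifelse(t <= mid, topA, topA * foldA^(mid - t))
  dose_b <- ifelse(t >= mid, topB, topB * foldB^(t - mid))
  data.frame(ratio_index = t, dose_a = dose_a, dose_b = dose_b)
}

#' Enumerate the pairwise-titration screen design
#'
#' For a panel of N ligands the design has one single-ligand gradient per
#' ligand, one self-pair (the ligand combined with itself, the
#' saturated-additivity control) per ligand, and every unordered pair of
#' distinct ligands: `2N + choose(N, 2)` rows. Each row carries `n_ratios`
#' dose pairs from [ratio_concentrations()] plus a zero-dose control at
#' ratio index 0. Gradient rows use the A-side trapezoid profile with the
#' partner dose fixed at zero, so a gradient holds the top dose for the
#' first half of the sweep and titrates down across the second half.
#'
#' @param panel a [ligand_panel()].
#' @param n_ratios ratios per row (default 9).
#' @return data.frame of class `condition_design` with one row per
#'   (condition row, ratio): columns `row_id`, `row_kind`
#'   (gradient/self_pair/pair), `ligand_a`, `ligand_b` (`NA` for gradients),
#'   `ratio_index` (0 = control), `conc_a`, `conc_b`.
#' @examples
#' d <- enumerate_design(ligand_panel(paste0("L", 1:10)), 9)
#' length(unique(d$row_id))  # 65
#' @export
enumerate_design <- function(panel, n_ratios = 9L) {
  stopifnot(inherits(panel, "ligand_panel"))
  if (n_ratios < 1L) .stopf("n_ratios must be >= 1")
  N <- nrow(panel)
  rows <- data.frame(row_kind = c(rep("gradient", N), rep("self_pair", N)),
                     ligand_a = c(panel$ligand, panel$ligand),
                     ligand_b = c(rep(NA_character_, N), panel$ligand),
                     stringsAsFactors = FALSE)
  if (N >= 2L) {
    pr <- t(combn(panel$ligand, 2L))
    rows <- rbind(rows, data.frame(row_kind = "pair", ligand_a = pr[, 1],
                                   ligand_b = pr[, 2],
                                   stringsAsFactors = FALSE))
  }
  rows$row_id <- sprintf("row%03d", seq_len(nrow(rows)))
  per_row <- lapply(seq_len(nrow(rows)), function(r) {
    a <- rows$ligand_a[r]
    pa <- panel[panel$ligand == a, ]
    if (rows$row_kind[r] == "gradient") {
      rc <- ratio_concentrations(pa$top, pa$top, n_ratios, pa$fold, pa$fold)
      rc$dose_b <- 0
      b <- NA_character_
    } else {
      b <- rows$ligand_b[r]
      pb <- panel[panel$ligand == b, ]
      rc <- ratio_concentrations(pa$top, pb$top, n_ratios, pa$fold, pb$fold)
    }
    rc <- rbind(data.frame(ratio_index = 0L, dose_a = 0, dose_b = 0), rc)
    data.frame(row_id = rows$row_id[r], row_kind = rows$row_kind[r],
               ligand_a = a, ligand_b = b, ratio_index = rc$ratio_index,
               conc_a = rc$dose_a, conc_b = rc$dose_b,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_row)
  rownames(out) <- NULL
  attr(out, "panel") <- panel
  attr(out, "n_ratios") <- as.integer(n_ratios)
  class(out) <- c("condition_design", "data.frame")
  out
}
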