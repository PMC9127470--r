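#' The Interaction Coefficient (IC)
#'
#' Places a pairwise ligand response on a single piecewise-linear scale by
#' comparing the combined response `fAB` to three references: the weaker
#' individual response `fA`, the stronger individual response `fB`, and
#' their sum. With `fB >= fA >= 0` (the function reorders internally and
#' clips negative inputs to zero):
#' \deqn{IC = fAB / (fA + fB) \quad (fAB \ge fA + fB)}
#' \deqn{IC = fAB / fB - 1 \quad (fA \le fAB < fA + fB)}
#' \deqn{IC = fAB / fA - 2 \quad (fAB < fA)}
#' so IC = 0 is saturated additivity (the null for a ligand combined with
#' itself at saturation), IC = 1 linear additivity, IC in (0, 1) additive,
#' IC in [-1, 0) antagonistic, IC < -1 suppressive (combination weaker than
#' both individuals), IC > 1 synergistic. IC is bounded below by -2 and
#' unbounded above, and is invariant to a global positive rescaling of all
#' three responses.
#'
#' @param fA,fB,fAB nonnegative responses (background subtracted);
#'   vectorized.
#' @param details if TRUE return a data.frame with the regime label and
#'   degenerate flag instead of a bare numeric.
#' @return numeric IC values, or a data.frame (`ic`, `regime`,
#'   `degenerate`). `fA = fB = 0` is degenerate (no signal anywhere) and
#'   yields IC = 0.
#' @examples
#' interaction_coefficient(1000, 1000, 1000)  # 0, saturated additive
#' interaction_coefficient(300, 700, 1000)    # 1, linear additive
#' interaction_coefficient(400, 800, 200)     # -1.5, suppressive
#' @export
interaction_coefficient <- function(fA, fB, fAB, details = FALSE) {
  n <- max(length(fA), length(fB), length(fAB))
  fA <- pmax(rep_len(as.numeric(fA), n), 0)
  fB <- pmax(rep_len(as.numeric(fB), n), 0)
  fAB <- pmax(rep_len(as.numeric(fAB), n), 0)
  lo <- pmin(fA, fB)
  hi <- pmax(fA, fB)
  degenerate <- lo == 0 & hi == 0
  ic <- numeric(n)
  syn <- !degenerate & fAB >= lo + hi
  mid <- !degenerate & fAB >= lo & fAB < lo + hi
  sup <- !degenerate & fAB < lo
  ic[syn] <- fAB[syn] / (lo[syn] + hi[syn])
  ic[mid] <- fAB[mid] / hi[mid] - 1
  ic[sup] <- fAB[sup] / lo[sup] - 2
  if (!details) return(ic)
  data.frame(ic = ic, regime = ic_category(ic), degenerate = degenerate)
}

#' Interaction category of an IC value
#'
#' @param ic numeric IC values.
#' @param split threshold on `|ic|` separating weak from strong antagonism
#'   (annotation only; does not affect the category).
#' @return character vector in `{suppressive, antagonistic,
#'   saturated_additive, additive, synergistic}`. With `strength = TRUE`
#'   (attribute request via `attr`), see [summarize_pair()].
#' @export
ic_category <- function(ic, split = 0.5) {
  out <- character(length(ic))
  out[ic > 1] <- "synergistic"
  out[ic > 0 & ic <= 1] <- "additive"
  out[ic == 0] <- "saturated_additive"
  out[ic < 0 & ic >= -1] <- "antagonistic"
  out[ic < -1] <- "suppressive"
  out
}

#' Replicate-noise threshold for interaction gating
#'
#' The minimum effect size a claimed interaction must exceed: the maximum
#' background-subtracted response observed anywhere in a cell context's
#' dataset divided by 30 (about 3% of the context's dynamic range).
#'
#' @param values all background-subtracted responses of one context (a
#'   numeric vector or a processed table's response column).
#' @return the threshold theta (>= 0).
#' @export
noise_threshold <- function(values) {
  if (!length(values)) .stopf("noise_threshold: empty input")
  max(max(values, na.rm = TRUE), 0) / 30
}

# signed replicate-range gap: positive when x lies entirely above ref
.range_gap_above <- function(x, ref) min(x) - max(ref)

#' Noise-gated Interaction Coefficient at one concentration ratio
#'
#' Computes the candidate IC from replicate medians, then retains a nonzero
#' value only when the replicate evidence supports it: the combination
#' replicate range must be disjoint from the gating reference's range by a
#' gap exceeding `theta`. The reference for any deviation from the
#' saturated-additive null is the stronger individual response `fB`; a
#' synergy claim (IC > 1) additionally requires separation from the
#' replicate-index-paired sums `fA + fB`; a suppression claim (IC < -1)
#' additionally requires separation from the weaker individual `fA`. When
#' the stricter regime's evidence fails but the `fB` evidence passes, the IC
#' is recomputed against the boundary of the best-supported regime
#' (`fAB/fB - 1`, clamped to `[-1, 1]`). If no gate passes the gated IC
#' is 0.
#'
#' @param fA,fB,fAB numeric replicate vectors for the weaker individual,
#'   stronger individual (ordering is internal, by median), and combined
#'   responses at one ratio.
#' @param theta noise threshold from [noise_threshold()].
#' @return list with `ic` (gated value), `ic_raw` (ungated candidate), and
#'   `flag` (`"ok"`, `"gated"`, `"regime_downgraded"`, `"too_few_replicates"`,
#'   `"degenerate"`).
#' @export
gated_ic <- function(fA, fB, fAB, theta) {
  if (length(fA) < 2L || length(fB) < 2L || length(fAB) < 2L) {
    warning("gated_ic: fewer than 2 replicates in a response set; returning 0")
    return(list(ic = 0, ic_raw = NA_real_, flag = "too_few_replicates"))
  }
  # order so B is the stronger individual by median
  if (median(fB) < median(fA)) { tmp <- fA; fA <- fB; fB <- tmp }
  mA <- max(median(fA), 0)
  mB <- max(median(fB), 0)
  mAB <- max(median(fAB), 0)
  raw <- interaction_coefficient(mA, mB, mAB)
  if (mA == 0 && mB == 0)
    return(list(ic = 0, ic_raw = raw, flag = "degenerate"))
  if (raw == 0) return(list(ic = 0, ic_raw = raw, flag = "ok"))
  base_gap <- if (mAB >= mB) .range_gap_above(fAB, fB) else .range_gap_above(fB, fAB)
  if (!(base_gap > theta))
    return(list(ic = 0, ic_raw = raw, flag = "gated"))
  if (raw > 1) {
    m <- min(length(fA), length(fB))
    sums <- fA[seq_len(m)] + fB[seq_len(m)]
    if (.range_gap_above(fAB, sums) > theta)
      return(list(ic = raw, ic_raw = raw, flag = "ok"))
    return(list(ic = min(mAB / mB - 1, 1), ic_raw = raw,
                flag = "regime_downgraded"))
  }
  if (raw < -1) {
    if (.range_gap_above(fA, fAB) > theta)
      return(list(ic = raw, ic_raw = raw, flag = "ok"))
    return(list(ic = max(min(mAB / mB - 1, 1), -1), ic_raw = raw,
                flag = "regime_downgraded"))
  }
  list(ic = raw, ic_raw = raw, flag = "ok")
}

#' Summarize a ligand pair's interaction across concentration ratios
#'
#' The reported IC for a pair is the gated IC of largest magnitude across
#' the sampled ratios; magnitude ties are broken toward the ratio nearest
#' 1:1 (the center of the sweep), then toward the negative value.
#'
#' @param ics numeric vector of gated ICs, one per ratio.
#' @param ratio_index ratio indices corresponding to `ics`.
#' @param n_ratios total ratios in the sweep (locates the 1:1 center).
#' @param split weak/strong antagonism threshold on `|IC|`.
#' @return list with `summary_ic`, `category`, `strength` (`"strong"` or
#'   `"weak"` for non-additive categories, `NA` otherwise), `ratio_index`
#'   of the reported value.
#' @export
summarize_pair <- function(ics, ratio_index = seq_along(ics),
                           n_ratios = max(ratio_index), split = 0.5) {
  if (!length(ics)) .stopf("summarize_pair: empty IC vector")
  amax <- max(abs(ics))
  cand <- which(abs(ics) == amax)
  if (length(cand) > 1L) {
    center <- (n_ratios + 1) / 2
    d <- abs(ratio_index[cand] - center)
    cand <- cand[d == min(d)]
    if (length(cand) > 1L) {
      neg <- cand[ics[cand] < 0]
      cand <- if (length(neg)) neg[1L] else cand[1L]
    }
  }
  ic <- ics[cand[1L]]
  category <- ic_category(ic)
  strength <- if (category %in% c("antagonistic", "synergistic", "suppressive",
                                  "additive") && ic != 0) {
    if (abs(ic) >= split) "strong" else "weak"
  } else NA_character_
  list(summary_ic = ic, category = category, strength = strength,
       ratio_index = ratio_index[cand[1L]])
}

# mirror index: the gradient ratio index holding the B-side dose of a pair
# row's ratio t (the trapezoid is symmetric under A <-> B)
.mirror_index <- function(t, n_ratios) n_ratios + 1L - t

#' Compute gated interaction records for every pair row of a screen
#'
#' Runs the full per-context interaction analysis on a processed table: the
#' context noise threshold, per-ratio gated ICs for every self-pair and pair
#' row (individual references taken from the matching gradient rows at the
#' same doses), and the per-pair summary. Manual overrides, mirroring rim
#' reclassification, can replace the automatic summary for named
#' (context, pair) entries.
#'
#' @param processed a processed well table (see [preprocess_dataset()]),
#'   with per-replicate responses.
#' @param n_ratios ratios per row.
#' @param split weak/strong antagonism threshold.
#' @param overrides optional data.frame with columns `context_id`,
#'   `ligand_a`, `ligand_b` and any of `forced_ic`, `forced_category`,
#'   `forced_ratio_index`; matching pairs get the forced summary and an
#'   override flag.
#' @return list with `ratios` (per-ratio table: context, pair, ratio, raw
#'   and gated IC, gate flag) and `pairs` (per-pair summary: summary IC,
#'   category, strength, override flag) data.frames; the per-context theta
#'   values are attached as attribute `theta`.
#' @export
interaction_table <- function(processed, n_ratios = 9L, split = 0.5,
                              overrides = NULL) {
  keep <- !processed$dropped & !processed$tech_rep
  pt <- processed[keep, , drop = FALSE]
  contexts <- unique(pt$context_id)
  rat_list <- list()
  pair_list <- list()
  for (cx in contexts) {
    cxt <- pt[pt$context_id == cx, , drop = FALSE]
    theta <- noise_threshold(cxt$response)
    # replicate vectors of gradient responses: [[ligand]][[ratio]] -> numeric
    grads <- cxt[cxt$row_kind == "gradient", , drop = FALSE]
    grad_reps <- function(lig, t) {
      v <- grads$response[grads$ligand_a == lig & grads$ratio_index == t]
      if (!length(v)) .stopf("missing gradient wells for ligand %s ratio %d in context %s",
                             lig, t, cx)
      v
    }
    prow <- cxt[cxt$row_kind %in% c("self_pair", "pair"), , drop = FALSE]
    for (rid in unique(prow$row_id)) {
      rr <- prow[prow$row_id == rid, , drop = FALSE]
      la <- rr$ligand_a[1L]; lb <- rr$ligand_b[1L]
      ics <- numeric(n_ratios); raws <- numeric(n_ratios)
      flags <- character(n_ratios)
      for (t in seq_len(n_ratios)) {
        fab <- rr$response[rr$ratio_index == t]
        fa <- grad_reps(la, t)
        fb <- grad_reps(lb, .mirror_index(t, n_ratios))
        g <- gated_ic(fa, fb, fab, theta)
        ics[t] <- g$ic; raws[t] <- g$ic_raw; flags[t] <- g$flag
      }
      s <- summarize_pair(ics, seq_len(n_ratios), n_ratios, split)
      rat_list[[length(rat_list) + 1L]] <- data.frame(
        context_id = cx, row_id = rid, row_kind = rr$row_kind[1L],
        ligand_a = la, ligand_b = lb, ratio_index = seq_len(n_ratios),
        ic_raw = raws, ic_gated = ics, gate_flag = flags,
        stringsAsFactors = FALSE)
      pair_list[[length(pair_list) + 1L]] <- data.frame(
        context_id = cx, row_id = rid, row_kind = rr$row_kind[1L],
        ligand_a = la, ligand_b = lb, summary_ic = s$summary_ic,
        category = s$category, strength = s$strength,
        summary_ratio = s$ratio_index, override = FALSE,
        stringsAsFactors = FALSE)
    }
    attr(rat_list, "theta") <- c(attr(rat_list, "theta"), setNames(theta, cx))
  }
  ratios <- do.call(rbind, rat_list)
  pairs <- do.call(rbind, pair_list)
  if (!is.null(overrides) && nrow(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      ov <- overrides[i, ]
      hit <- pairs$context_id == ov$context_id &
        ((pairs$ligand_a == ov$ligand_a & pairs$ligand_b == ov$ligand_b) |
           (pairs$ligand_a == ov$ligand_b & pairs$ligand_b == ov$ligand_a))
      if (!any(hit)) next
      if (!is.null(ov$forced_ratio_index) && !is.na(ov$forced_ratio_index)) {
        sel <- ratios$context_id == ov$context_id &
          ratios$row_id %in% pairs$row_id[hit] &
          ratios$ratio_index == ov$forced_ratio_index
        pairs$summary_ic[hit] <- ratios$ic_gated[sel][1L]
        pairs$category[hit] <- ic_category(pairs$summary_ic[hit])
      }
      if (!is.null(ov$forced_ic) && !is.na(ov$forced_ic)) {
        pairs$summary_ic[hit] <- ov$forced_ic
        pairs$category[hit] <- ic_category(ov$forced_ic)
      }
      if (!is.null(ov$forced_category) && !is.na(ov$forced_category))
        pairs$category[hit] <- as.character(ov$forced_category)
      pairs$override[hit] <- TRUE
    }
  }
  structure(list(ratios = ratios, pairs = pairs),
            theta = attr(rat_list, "theta"))
}
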