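#' Filter low-count wells and subtract per-plate background
#'
#' Wells with fewer than `min_cells` cells are dropped (flagged, not
#' deleted); from every retained well the plate background -- the median of
#' that plate's zero-dose control wells -- is subtracted. Rows are re-sorted
#' into canonical (design) order. Negative post-subtraction values are
#' retained; they are clipped only at IC computation.
#'
#' @param wells a well table as emitted by [generate_dataset()] (or read
#'   from CSV with the same columns).
#' @param min_cells cell-count threshold; wells with exactly `min_cells`
#'   cells are retained.
#' @return a processed table: the well table with `response`
#'   (background-subtracted fluorescence), `dropped` flag, and
#'   `plate_background` recording the subtracted value.
#' @export
filter_and_subtract <- function(wells, min_cells = 500L) {
  if (!nrow(wells)) .stopf("empty well table")
  w <- wells
  w$dropped <- w$cell_count < min_cells
  bg <- numeric(nrow(w))
  for (p in unique(w$plate_id)) {
    on_plate <- w$plate_id == p
    ctrl <- on_plate & w$ratio_index == 0L & !w$dropped
    if (!any(ctrl))
      .stopf("plate %s has no surviving zero-dose control wells", p)
    bg[on_plate] <- median(w$median_yfp[ctrl])
  }
  w$plate_background <- bg
  w$response <- w$median_yfp - bg
  o <- order(w$context_id, w$replicate_id, w$row_id, w$ratio_index,
             w$tech_rep)
  w <- w[o, , drop = FALSE]
  rownames(w) <- NULL
  w
}

# closed-form least-squares scale: alpha minimizing sum (ref - alpha x)^2
.ls_scale <- function(ref, x) {
  denom <- sum(x^2)
  if (denom == 0) .stopf("degenerate rescaling: shared values are all zero")
  sum(ref * x) / denom
}

#' Rescale plates to a common reference within each biological replicate
#'
#' Within every (context, replicate) group, each plate's responses are
#' multiplied by the scalar minimizing the total least-squares error against
#' the reference plate over the conditions shared between the two plates
#' (the technical-replicate wells): `alpha = sum(x_ref x_plate) /
#' sum(x_plate^2)`. The reference plate is left unchanged.
#'
#' @param table a processed table from [filter_and_subtract()].
#' @param reference_plate optional plate id (or function of the group's
#'   plate ids); default picks, per group, the plate sharing the most
#'   conditions with the others, ties broken by lowest id.
#' @return the table with rescaled `response` and a `plate_scale` column;
#'   the per-plate factors are attached as attribute `plate_factors`.
#' @export
rescale_plates <- function(table, reference_plate = NULL) {
  w <- table
  w$plate_scale <- 1
  keep <- !w$dropped
  fac <- list()
  for (grp in split(seq_len(nrow(w)),
                    list(w$context_id, w$replicate_id), drop = TRUE)) {
    g <- w[grp, , drop = FALSE]
    plates <- sort(unique(g$plate_id))
    if (length(plates) < 2L) next
    cond <- paste(g$row_id, g$ratio_index)
    shared_n <- vapply(plates, function(p) {
      on <- g$plate_id == p & !g$dropped
      length(intersect(unique(cond[on]),
                       unique(cond[g$plate_id != p & !g$dropped])))
    }, numeric(1))
    ref <- if (!is.null(reference_plate) && reference_plate %in% plates)
      reference_plate else plates[which.max(shared_n)]
    ref_on <- g$plate_id == ref & !g$dropped
    ref_med <- tapply(g$response[ref_on], cond[ref_on], median)
    for (p in setdiff(plates, ref)) {
      on <- g$plate_id == p & !g$dropped
      pl_med <- tapply(g$response[on], cond[on], median)
      shared <- intersect(names(ref_med), names(pl_med))
      if (!length(shared))
        .stopf("plate %s shares no conditions with reference plate %s", p, ref)
      alpha <- .ls_scale(as.numeric(ref_med[shared]),
                         as.numeric(pl_med[shared]))
      sel <- grp[g$plate_id == p]
      w$response[sel] <- w$response[sel] * alpha
      w$plate_scale[sel] <- alpha
      fac[[length(fac) + 1L]] <- data.frame(
        context_id = g$context_id[1L], replicate_id = g$replicate_id[1L],
        plate_id = p, reference_plate = ref, alpha = alpha,
        n_shared = length(shared), stringsAsFactors = FALSE)
    }
  }
  attr(w, "plate_factors") <- if (length(fac)) do.call(rbind, fac) else NULL
  w
}

#' Rescale biological replicates to a common reference
#'
#' Within every context, each non-reference replicate is multiplied by the
#' single scalar minimizing total least-squares error against the reference
#' replicate over all shared conditions. Per-replicate values are retained
#' (not averaged).
#'
#' @param table a processed table (after [rescale_plates()]).
#' @param reference_replicate optional replicate id; default is the
#'   replicate with the most retained conditions, ties broken by lowest id.
#' @return the table with rescaled `response` and a `replicate_scale`
#'   column; factors attached as attribute `replicate_factors`.
#' @export
rescale_replicates <- function(table, reference_replicate = NULL) {
  w <- table
  w$replicate_scale <- 1
  fac <- list()
  for (cx in unique(w$context_id)) {
    gsel <- which(w$context_id == cx)
    g <- w[gsel, , drop = FALSE]
    reps <- sort(unique(g$replicate_id))
    if (length(reps) < 2L) next
    cond <- paste(g$row_id, g$ratio_index, g$tech_rep)
    n_cond <- vapply(reps, function(r)
      length(unique(cond[g$replicate_id == r & !g$dropped])), numeric(1))
    ref <- if (!is.null(reference_replicate)) reference_replicate
      else reps[which.max(n_cond)]
    ref_on <- g$replicate_id == ref & !g$dropped
    ref_med <- tapply(g$response[ref_on], cond[ref_on], median)
    for (r in setdiff(reps, ref)) {
      on <- g$replicate_id == r & !g$dropped
      r_med <- tapply(g$response[on], cond[on], median)
      shared <- intersect(names(ref_med), names(r_med))
      if (!length(shared))
        .stopf("replicate %s shares no conditions with reference replicate %s",
               r, ref)
      alpha <- .ls_scale(as.numeric(ref_med[shared]),
                         as.numeric(r_med[shared]))
      sel <- gsel[g$replicate_id == r]
      w$response[sel] <- w$response[sel] * alpha
      w$replicate_scale[sel] <- alpha
      fac[[length(fac) + 1L]] <- data.frame(
        context_id = cx, replicate_id = r, reference_replicate = ref,
        alpha = alpha, n_shared = length(shared), stringsAsFactors = FALSE)
    }
  }
  attr(w, "replicate_factors") <- if (length(fac)) do.call(rbind, fac) else NULL
  w
}

#' Full preprocessing: filter, subtract, harmonize plates and replicates
#'
#' Convenience wrapper chaining [filter_and_subtract()], [rescale_plates()]
#' and [rescale_replicates()].
#'
#' @inheritParams filter_and_subtract
#' @inheritParams rescale_plates
#' @inheritParams rescale_replicates
#' @return the harmonized processed table, with the provenance attributes of
#'   both rescaling steps.
#' @export
preprocess_dataset <- function(wells, min_cells = 500L,
                               reference_plate = NULL,
                               reference_replicate = NULL) {
  out <- filter_and_subtract(wells, min_cells)
  out <- rescale_plates(out, reference_plate)
  rescale_replicates(out, reference_replicate)
}
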