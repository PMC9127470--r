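#' Measurement noise model for the synthetic screen
#'
#' Describes how noiseless model output becomes a measured per-well median
#' fluorescence: plate-to-plate multiplicative factors (emulating staggered
#' incubation times), a per-biological-replicate factor, mean-one lognormal
#' per-well noise, an additive fluorescence background, and a per-well cell
#' count with an occasional low-count well that the 500-cell filter should
#' drop.
#'
#' @param plate_factor_range,replicate_factor_range uniform ranges of the
#'   multiplicative plate and replicate factors.
#' @param cv coefficient of variation of the per-well lognormal noise.
#' @param gain fluorescence units per model output unit.
#' @param background_level,background_sd additive background fluorescence
#'   (mean, spread) per well.
#' @param mean_cells Poisson mean of the per-well cell count.
#' @param low_count_fraction fraction of wells drawn as low-count failures
#'   (uniform below 500 cells).
#' @param seed integer seed making the generated table reproducible.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(plate_factor_range = c(0.8, 1.2),
                        replicate_factor_range = c(0.7, 1.3),
                        cv = 0.1, gain = 1000, background_level = 50,
                        background_sd = 5, mean_cells = 3000,
                        low_count_fraction = 0.02, seed = 1L) {
  if (any(c(plate_factor_range, replicate_factor_range) <= 0))
    .stopf("factor ranges must be positive")
  if (cv < 0 || background_sd < 0) .stopf("noise spreads must be >= 0")
  structure(list(plate_factor_range = plate_factor_range,
                 replicate_factor_range = replicate_factor_range,
                 cv = cv, gain = gain, background_level = background_level,
                 background_sd = background_sd, mean_cells = mean_cells,
                 low_count_fraction = low_count_fraction,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Zero-noise measurement model
#'
#' Identity measurement: all factors 1, no lognormal noise, no background,
#' gain 1, no low-count wells. Under this model the emitted fluorescence
#' equals the noiseless model output everywhere.
#'
#' @param seed seed (still fixed for cell-count draws).
#' @return a [noise_model()].
#' @export
noise_free <- function(seed = 1L) {
  noise_model(plate_factor_range = c(1, 1), replicate_factor_range = c(1, 1),
              cv = 0, gain = 1, background_level = 0, background_sd = 0,
              low_count_fraction = 0, seed = seed)
}

# ligand environment of one design row at one ratio
.design_env <- function(row) {
  if (row$row_kind == "gradient") {
    env <- setNames(row$conc_a, row$ligand_a)
  } else if (row$row_kind == "self_pair") {
    env <- setNames(row$conc_a + row$conc_b, row$ligand_a)
  } else {
    env <- setNames(c(row$conc_a, row$conc_b), c(row$ligand_a, row$ligand_b))
  }
  env[env > 0]
}

#' Noiseless model responses for a whole screen design
#'
#' Solves the equilibrium model for every (context, row, ratio) condition of
#' a design in one vectorized call.
#'
#' @param design a [enumerate_design()] table.
#' @param truth a [model_params()] object covering all panel ligands.
#' @param contexts named list of [receptor_context()] objects.
#' @return data.frame: `context_id`, `row_id`, `row_kind`, `ligand_a`,
#'   `ligand_b`, `ratio_index`, `conc_a`, `conc_b`, `S_true`.
#' @export
design_truth <- function(design, truth, contexts) {
  if (is.null(names(contexts))) .stopf("contexts must be a named list")
  panel <- attr(design, "panel")
  missing <- setdiff(panel$ligand, truth$ligands)
  if (length(missing))
    .stopf("truth parameters missing for ligand(s): %s",
           paste(missing, collapse = ", "))
  nL <- length(truth$ligands)
  L <- matrix(0, nrow(design), nL, dimnames = list(NULL, truth$ligands))
  ia <- match(design$ligand_a, truth$ligands)
  L[cbind(seq_len(nrow(design)), ia)] <- design$conc_a
  isp <- !is.na(design$ligand_b)
  ib <- match(design$ligand_b[isp], truth$ligands)
  idx <- cbind(which(isp), ib)
  L[idx] <- L[idx] + design$conc_b[isp]
  out <- do.call(rbind, lapply(names(contexts), function(cx) {
    ctx <- contexts[[cx]]
    .check_components(truth, setNames(1, truth$ligands[1]), ctx)
    sol <- solve_equilibrium_batch(truth, L,
                                   matrix(ctx$A0[truth$type1], 1),
                                   matrix(ctx$B0[truth$type2], 1))
    cbind(data.frame(context_id = cx, stringsAsFactors = FALSE),
          design[, c("row_id", "row_kind", "ligand_a", "ligand_b",
                     "ratio_index", "conc_a", "conc_b")],
          data.frame(S_true = sol$S))
  }))
  rownames(out) <- NULL
  out
}

#' Generate a synthetic pairwise-titration screen
#'
#' Emulates the combinatorial screen: enumerates the design
#' ([enumerate_design()]), computes ground-truth responses from the
#' equilibrium model, assigns condition rows to plates (6 rows per plate,
#' round-robin in row order, optionally shuffled per replicate), duplicates
#' a reference condition and a no-ligand control on every plate as technical
#' replicates (making plate rescaling identifiable), and applies the
#' measurement model: `median_yfp = plate_factor * replicate_factor *
#' (gain * S + background) * lognormal(cv)`, with a Poisson cell count per
#' well and an occasional low-count failure. Identical inputs and seed
#' reproduce the table exactly.
#'
#' @param panel a [ligand_panel()].
#' @param contexts named list of [receptor_context()] objects.
#' @param truth a [model_params()] object (the planted ground truth).
#' @param noise a [noise_model()].
#' @param n_replicates biological replicates per context.
#' @param n_ratios ratios per condition row.
#' @param rows_per_plate condition rows per plate.
#' @param shuffle_rows randomize row-to-plate assignment between replicates
#'   (seeded), as robotic screens randomize row order between biological
#'   repeats. Must not change analysis results.
#' @return list with `wells` (the measurement table: `context_id`,
#'   `plate_id`, `row_id`, `row_kind`, `ligand_a`, `ligand_b`, `conc_a`,
#'   `conc_b`, `ratio_index`, `replicate_id`, `median_yfp`, `cell_count`,
#'   `tech_rep`), `truth` (noiseless ledger from [design_truth()]),
#'   `factors` (drawn plate/replicate factors), `design`, and the seed.
#' @export
generate_dataset <- function(panel, contexts, truth, noise = noise_model(),
                             n_replicates = 4L, n_ratios = 9L,
                             rows_per_plate = 6L, shuffle_rows = TRUE) {
  stopifnot(inherits(noise, "noise_model"))
  if (n_replicates < 1L) .stopf("n_replicates must be >= 1")
  design <- enumerate_design(panel, n_ratios)
  ledger <- design_truth(design, truth, contexts)
  row_ids <- unique(design$row_id)
  n_rows <- length(row_ids)
  ref_row <- row_ids[1L]
  ref_ratio <- ceiling(n_ratios / 2)
  sdlog <- sqrt(log(1 + noise$cv^2))
  set.seed(noise$seed)
  wells <- list()
  factors <- list()
  for (cx in names(contexts)) {
    led <- ledger[ledger$context_id == cx, , drop = FALSE]
    key <- paste(led$row_id, led$ratio_index)
    for (r in seq_len(n_replicates)) {
      rep_f <- runif(1, noise$replicate_factor_range[1],
                     noise$replicate_factor_range[2])
      ord <- if (shuffle_rows) sample(n_rows) else seq_len(n_rows)
      # row ord[p] sits at position p of the (shuffled) plate layout
      plate_of_row <- setNames(ceiling(order(ord) / rows_per_plate), row_ids)
      n_plates <- max(plate_of_row)
      plate_f <- runif(n_plates, noise$plate_factor_range[1],
                       noise$plate_factor_range[2])
      plate_ids <- sprintf("%s_r%d_p%02d", cx, r, seq_len(n_plates))
      factors[[length(factors) + 1L]] <- data.frame(
        context_id = cx, replicate_id = r, plate_id = plate_ids,
        plate_factor = plate_f, replicate_factor = rep_f,
        stringsAsFactors = FALSE)
      # primary wells: every (row, ratio) on the row's plate
      w <- led
      w$plate <- plate_of_row[w$row_id]
      w$tech_rep <- FALSE
      # technical replicates: the reference condition (in quadruplicate, so
      # single low-count wells cannot leave a plate without shared signal
      # wells) + a no-ligand control, duplicated on every plate
      ref <- led[led$row_id == ref_row &
                   led$ratio_index %in% c(0L, ref_ratio), , drop = FALSE]
      ref <- ref[c(which(ref$ratio_index == 0L),
                   rep(which(ref$ratio_index == ref_ratio), 4L)), ,
                 drop = FALSE]
      for (p in seq_len(n_plates)) {
        tr <- ref
        tr$plate <- p
        tr$tech_rep <- TRUE
        w <- rbind(w, tr)
      }
      nw <- nrow(w)
      bg <- noise$background_level +
        if (noise$background_sd > 0) rnorm(nw, 0, noise$background_sd) else 0
      lnoise <- if (sdlog > 0) rlnorm(nw, -sdlog^2 / 2, sdlog) else rep(1, nw)
      yfp <- plate_f[w$plate] * rep_f *
        (noise$gain * w$S_true + pmax(bg, 0)) * lnoise
      low <- runif(nw) < noise$low_count_fraction
      counts <- rpois(nw, noise$mean_cells)
      counts[low] <- floor(runif(sum(low), 0, 500))
      wells[[length(wells) + 1L]] <- data.frame(
        context_id = cx, plate_id = plate_ids[w$plate], row_id = w$row_id,
        row_kind = w$row_kind, ligand_a = w$ligand_a, ligand_b = w$ligand_b,
        conc_a = w$conc_a, conc_b = w$conc_b, ratio_index = w$ratio_index,
        replicate_id = r, median_yfp = yfp, cell_count = counts,
        tech_rep = w$tech_rep, stringsAsFactors = FALSE)
    }
  }
  wells <- do.call(rbind, wells)
  rownames(wells) <- NULL
  list(wells = wells, truth = ledger, factors = do.call(rbind, factors),
       design = design, seed = noise$seed)
}
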