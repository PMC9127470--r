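# minimal hand-built well tables for unit checks
make_wells <- function(values, plates = "p1", counts = 3000) {
  n <- length(values)
  data.frame(context_id = "c1", plate_id = rep_len(plates, n),
             row_id = sprintf("row%03d", seq_len(n)), row_kind = "gradient",
             ligand_a = "A", ligand_b = NA_character_,
             conc_a = 1, conc_b = 0, ratio_index = 1L,
             replicate_id = 1L, median_yfp = values,
             cell_count = rep_len(counts, n), tech_rep = FALSE,
             stringsAsFactors = FALSE)
}

test_that("cell-count filter drops below 500 and keeps exactly 500", {
  w <- make_wells(c(100, 200, 300, 400))
  w$cell_count <- c(499, 500, 501, 3000)
  # add a control well so background is defined
  ctrl <- w[1, ]; ctrl$ratio_index <- 0L; ctrl$median_yfp <- 50
  ctrl$cell_count <- 1000
  out <- filter_and_subtract(rbind(w, ctrl), min_cells = 500)
  expect_equal(out$dropped[match(c(499, 500, 501, 3000), out$cell_count)],
               c(TRUE, FALSE, FALSE, FALSE))
})

test_that("background is the per-plate median of zero-dose controls", {
  w <- make_wells(c(220, 300))
  ctrls <- make_wells(c(100, 120, 140))
  ctrls$ratio_index <- 0L
  out <- filter_and_subtract(rbind(w, ctrls))
  expect_equal(sort(out$response[out$ratio_index == 1]), c(100, 180))
  # self-subtraction: a control equal to the median goes to zero
  expect_true(0 %in% out$response[out$ratio_index == 0])
  # a plate without surviving controls errors
  w2 <- make_wells(c(100, 200))
  expect_error(filter_and_subtract(w2), "control")
})

test_that("plate rescaling uses the closed-form least-squares factor", {
  # two plates sharing two conditions; plate 2 doubled
  shared <- data.frame(context_id = "c1", row_id = c("r1", "r2"),
                       row_kind = "pair", ligand_a = "A", ligand_b = "B",
                       conc_a = 1, conc_b = 1, ratio_index = 1L,
                       replicate_id = 1L, tech_rep = TRUE,
                       cell_count = 3000, stringsAsFactors = FALSE)
  p1 <- shared; p1$plate_id <- "p1"; p1$median_yfp <- c(1, 2)
  p2 <- shared; p2$plate_id <- "p2"; p2$median_yfp <- c(2, 4)
  w <- rbind(p1, p2)
  w$dropped <- FALSE; w$response <- w$median_yfp
  out <- rescale_plates(w, reference_plate = "p1")
  # alpha = (1*2 + 2*4) / (4 + 16) = 0.5
  expect_equal(attr(out, "plate_factors")$alpha, 0.5)
  expect_equal(out$response[out$plate_id == "p2"], c(1, 2))
  expect_equal(out$response[out$plate_id == "p1"], c(1, 2))
})

test_that("plate rescaling inverts a known simulated plate factor", {
  tr <- example_screen_truth()
  small <- ligand_panel(tr$panel$ligand[1:3], top = 100, fold = 3)
  nm <- noise_model(cv = 0, background_sd = 0, low_count_fraction = 0,
                    plate_factor_range = c(0.8, 1.25),
                    replicate_factor_range = c(1, 1), seed = 4)
  ds <- generate_dataset(small, tr$contexts["ctx_wt"], tr$params, nm,
                         n_replicates = 1, rows_per_plate = 3)
  out <- rescale_plates(filter_and_subtract(ds$wells))
  pf <- attr(out, "plate_factors")
  truef <- ds$factors$plate_factor[match(pf$plate_id, ds$factors$plate_id)]
  reff <- ds$factors$plate_factor[match(pf$reference_plate,
                                        ds$factors$plate_id)]
  expect_equal(pf$alpha, reff / truef, tolerance = 1e-9)
})

test_that("replicate rescaling inverts known replicate factors exactly", {
  tr <- example_screen_truth()
  small <- ligand_panel(tr$panel$ligand[1:3], top = 100, fold = 3)
  nm <- noise_model(cv = 0, background_sd = 0, low_count_fraction = 0,
                    plate_factor_range = c(1, 1),
                    replicate_factor_range = c(0.7, 1.3), seed = 9)
  ds <- generate_dataset(small, tr$contexts["ctx_wt"], tr$params, nm,
                         n_replicates = 3)
  out <- rescale_replicates(filter_and_subtract(ds$wells))
  # all replicates collapse onto the reference: per-condition spread ~ 0
  key <- paste(out$row_id, out$ratio_index, out$tech_rep)
  spread <- tapply(out$response, key, function(v) diff(range(v)))
  scale <- max(abs(out$response))
  expect_lt(max(spread) / scale, 1e-9)
  # identical replicates give factors of exactly 1
  w <- out
  w$response <- rep(1:10, length.out = nrow(w))
  ww <- rescale_replicates(w)
  expect_true(all(abs(ww$replicate_scale - 1) < 1e-12))
})

test_that("plate rescaling is idempotent and scale-equivariant", {
  tr <- example_screen_truth()
  small <- ligand_panel(tr$panel$ligand[1:3], top = 100, fold = 3)
  nm <- noise_model(cv = 0.1, seed = 2)
  ds <- generate_dataset(small, tr$contexts["ctx_wt"], tr$params, nm,
                         n_replicates = 1, rows_per_plate = 3)
  once <- rescale_plates(filter_and_subtract(ds$wells))
  twice <- rescale_plates(once)
  expect_equal(twice$response, once$response, tolerance = 1e-12)
  # multiplying one plate's raw inputs by c leaves post-rescale values alone
  w <- filter_and_subtract(ds$wells)
  target <- unique(w$plate_id)[2]
  w2 <- w
  w2$response[w2$plate_id == target] <- w2$response[w2$plate_id == target] * 5
  r1 <- rescale_plates(w)
  r2 <- rescale_plates(w2)
  expect_equal(r2$response, r1$response, tolerance = 1e-9)
})

test_that("filtering never alters retained values", {
  tr <- example_screen_truth()
  small <- ligand_panel(tr$panel$ligand[1:2], top = 100, fold = 3)
  nm <- noise_model(cv = 0.1, low_count_fraction = 0.1, seed = 6)
  ds <- generate_dataset(small, tr$contexts["ctx_wt"], tr$params, nm,
                         n_replicates = 2)
  out <- filter_and_subtract(ds$wells)
  kept <- out[!out$dropped, ]
  expect_equal(kept$response, kept$median_yfp - kept$plate_background)
})
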