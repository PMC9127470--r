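# small fit problems keep these tests fast; the full-scale recovery runs
# live in test-acceptance.R

tiny_setup <- function(n_replicates = 2, seed = 1) {
  ft <- example_fit_truth()
  ds <- generate_dataset(ft$panel, ft$contexts["fit_wt"], ft$params,
                         noise_free(seed), n_replicates = n_replicates)
  proc <- preprocess_dataset(ds$wells)
  fo <- assemble_observations(proc, ft$panel$ligand,
                              ft$receptor_expr["fit_wt"])
  list(ft = ft, fo = fo)
}

test_that("observation assembly selects, normalizes and bookkeeps", {
  s <- tiny_setup()
  fo <- s$fo
  # 5 gradients + 5 self-pairs + 10 pairs at 9 ratios in one context
  expect_equal(nrow(fo$obs), 20 * 9)
  expect_equal(max(fo$obs$y), 1)
  expect_true(all(fo$obs$y >= 0 | fo$obs$y > -0.05))
  expect_equal(max(unlist(lapply(fo$contexts, function(cx)
    c(cx$A0, cx$B0)))), 1)
  # ledger round-trip: every observation maps to its generating condition
  d <- enumerate_design(s$ft$panel, 9)
  key_d <- paste(d$row_id, d$ratio_index)
  key_o <- paste(fo$obs$row_id, fo$obs$ratio_index)
  expect_true(all(key_o %in% key_d))
  m <- match(key_o, key_d)
  expect_equal(fo$obs$conc_a, d$conc_a[m])
  expect_equal(fo$obs$conc_b, d$conc_b[m])
  # a missing condition is an error naming the incomplete row
  ds <- generate_dataset(s$ft$panel, s$ft$contexts["fit_wt"], s$ft$params,
                         noise_free(1), n_replicates = 2)
  proc <- preprocess_dataset(ds$wells)
  broken <- proc[!(proc$row_id == "row003" & proc$ratio_index == 4), ]
  expect_error(assemble_observations(broken, s$ft$panel$ligand,
                                     s$ft$receptor_expr["fit_wt"]),
               "ratios")
})

test_that("a fit started from the truth has near-zero residual", {
  s <- tiny_setup()
  fo <- s$fo
  truth_fit <- list(params = s$ft$params,
                    rho = setNames(rep(1, 5), c(fo$type1, fo$type2)),
                    residual = NA)
  pred <- predict_fit(truth_fit, fo)
  # the normalization is a pure rescaling, absorbed into the activities
  scale <- sum(pred * fo$obs$y) / sum(pred^2)
  rescaled <- truth_fit
  rescaled$params$eps <- rescaled$params$eps * scale
  pred2 <- predict_fit(rescaled, fo)
  expect_lt(sum((fo$obs$y - pred2)^2), 1e-10 * sum(fo$obs$y^2))
})

test_that("multi-start fitting is deterministic and respects bounds", {
  s <- tiny_setup()
  f1 <- suppressWarnings(fit_multistart(s$fo, n_starts = 2, seed = 7,
                                        maxit_coarse = 5, n_polish = 1,
                                        maxit_polish = 5))
  f2 <- suppressWarnings(fit_multistart(s$fo, n_starts = 2, seed = 7,
                                        maxit_coarse = 5, n_polish = 1,
                                        maxit_polish = 5))
  expect_equal(f1[[1]]$params$K, f2[[1]]$params$K)
  expect_equal(f1[[1]]$residual, f2[[1]]$residual)
  for (f in f1) {
    expect_true(all(f$params$K >= 1e-4 - 1e-12 & f$params$K <= 1e2 + 1e-8))
    expect_true(all(f$params$eps >= 1e-4 - 1e-12 &
                      f$params$eps <= 1e2 + 1e-8))
    expect_true(all(f$rho >= 1 / 3 - 1e-9 & f$rho <= 3 + 1e-9))
    expect_gte(f$residual, 0)
  }
  # results sorted by residual
  expect_true(!is.unsorted(vapply(f1, `[[`, numeric(1), "residual")))
})

test_that("solution filtering enforces category requirements", {
  s <- tiny_setup()
  fo <- s$fo
  # a 'fit' that is the truth itself (activities rescaled to the data)
  truth_fit <- list(params = s$ft$params,
                    rho = setNames(rep(1, 5), c(fo$type1, fo$type2)),
                    residual = 0.001, start = 1L, converged = TRUE)
  pred <- predict_fit(truth_fit, fo)
  scale <- sum(pred * fo$obs$y) / sum(pred^2)
  truth_fit$params$eps <- truth_fit$params$eps * scale
  fits <- structure(list(truth_fit), class = "bmp_fit_list")
  good <- data.frame(context_id = "fit_wt", ligand_a = "F2", ligand_b = "F3",
                     required_category = "suppressive")
  flt <- filter_solutions(fits, fo, good)
  expect_length(flt$accepted, 1)
  bad <- good
  bad$required_category <- "synergistic"
  flt2 <- filter_solutions(fits, fo, bad)
  expect_length(flt2$accepted, 0)
  expect_warning(filter_solutions(fits, fo, NULL), "criteria")
})

test_that("recovery report scores the truth fit perfectly", {
  s <- tiny_setup()
  fo <- s$fo
  truth_fit <- list(params = s$ft$params,
                    rho = setNames(rep(1, 5), c(fo$type1, fo$type2)),
                    residual = 0, start = 1L, converged = TRUE)
  pred <- predict_fit(truth_fit, fo)
  scale <- sum(pred * fo$obs$y) / sum(pred^2)
  truth_fit$params$eps <- truth_fit$params$eps * scale
  tt <- fo$obs; tt$value <- fo$obs$y
  truth_cats <- noiseless_interactions(tt, value = "value",
                                       n_ratios = fo$n_ratios)
  rep <- evaluate_recovery(truth_cats,
                           structure(list(truth_fit), class = "bmp_fit_list"),
                           fo)
  expect_gt(rep$r_squared, 1 - 1e-8)
  expect_equal(rep$category_agreement, 1)
})

test_that("planted anti-correlated affinities and activities are detected", {
  s <- tiny_setup()
  fo <- s$fo
  anti <- s$ft$params
  nc <- length(anti$K)
  anti$K <- array(10^seq(-2, 2, length.out = nc), dim = dim(anti$K),
                  dimnames = dimnames(anti$K))
  anti$eps <- array(10^seq(2, -2, length.out = nc), dim = dim(anti$K),
                    dimnames = dimnames(anti$K))
  fit <- list(params = anti, rho = setNames(rep(1, 5), c(fo$type1, fo$type2)),
              residual = 1, start = 1L, converged = TRUE)
  tt <- fo$obs; tt$value <- fo$obs$y
  truth_cats <- noiseless_interactions(tt, value = "value",
                                       n_ratios = fo$n_ratios)
  rep <- evaluate_recovery(truth_cats,
                           structure(list(fit), class = "bmp_fit_list"), fo)
  expect_lt(rep$k_eps_correlation, -0.99)
})
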