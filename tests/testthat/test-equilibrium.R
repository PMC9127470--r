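# random small model instances for property checks
random_instance <- function(nL, nI, nII) {
  g <- expand.grid(ligand = paste0("L", seq_len(nL)),
                   type1 = paste0("A", seq_len(nI)),
                   type2 = paste0("B", seq_len(nII)),
                   stringsAsFactors = FALSE)
  g$K <- 10^runif(nrow(g), -2, 1.5)
  g$eps <- 10^runif(nrow(g), -2, 1)
  params <- model_params(g)
  env <- setNames(10^runif(nL, -1, 1), paste0("L", seq_len(nL)))
  ctx <- receptor_context(setNames(runif(nI, 0.1, 1), paste0("A", seq_len(nI))),
                          setNames(runif(nII, 0.1, 1), paste0("B", seq_len(nII))))
  list(params = params, env = env, ctx = ctx)
}

test_that("1x1x1 equilibrium matches the closed-form quadratic", {
  p <- model_params(data.frame(ligand = "L", type1 = "A", type2 = "B",
                               K = 1, eps = 1))
  st <- solve_equilibrium(p, c(L = 1), receptor_context(c(A = 1), c(B = 1)))
  golden <- (sqrt(5) - 1) / 2  # a (1 + a) = 1
  expect_equal(unname(st$A), golden, tolerance = 1e-10)
  expect_equal(unname(st$B), golden, tolerance = 1e-10)
  expect_equal(st$S, 1 - golden, tolerance = 1e-10)
})

test_that("zero affinity leaves receptors free and output zero", {
  p <- model_params(data.frame(ligand = "L", type1 = "A", type2 = "B",
                               K = 0, eps = 1))
  st <- solve_equilibrium(p, c(L = 5), receptor_context(c(A = 2), c(B = 3)))
  expect_equal(unname(st$A), 2)
  expect_equal(unname(st$B), 3)
  expect_equal(st$S, 0)
})

test_that("weak-binding limit is linear in K L A0 B0", {
  p <- model_params(data.frame(ligand = "L", type1 = "A", type2 = "B",
                               K = 1e-6, eps = 2))
  st <- solve_equilibrium(p, c(L = 1), receptor_context(c(A = 1), c(B = 1)))
  expect_equal(st$S, 2e-6, tolerance = 1e-3)
  expect_equal(st$T[1, 1, 1], 1e-6, tolerance = 1e-3)
})

test_that("conservation holds on random instances", {
  set.seed(11)
  for (i in 1:25) {
    inst <- random_instance(sample(1:5, 1), sample(1:3, 1), sample(1:3, 1))
    st <- solve_equilibrium(inst$params, inst$env, inst$ctx)
    expect_lt(st$residual, 1e-9)
    expect_true(all(st$A >= 0 & st$A <= inst$ctx$A0 + 1e-12))
    expect_true(all(st$B >= 0 & st$B <= inst$ctx$B0 + 1e-12))
    # complex law of mass action
    expect_equal(st$T, inst$params$K *
                   as.vector(inst$env[inst$params$ligands]) *
                   rep(st$A, each = length(inst$params$ligands)) *
                   rep(st$B, each = length(inst$params$ligands) * length(st$A)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("fixed-point solver agrees with the kinetic-relaxation oracle", {
  set.seed(7)
  for (i in 1:12) {
    inst <- random_instance(sample(1:5, 1), sample(1:3, 1), sample(1:3, 1))
    st <- solve_equilibrium(inst$params, inst$env, inst$ctx)
    or <- steady_state_oracle(inst$params, inst$env, inst$ctx)
    denom <- pmax(abs(or$T), 1e-12)
    expect_lt(max(abs(st$T - or$T) / denom), 1e-6)
  }
})

test_that("batch solver matches the single-environment solver", {
  set.seed(3)
  inst <- random_instance(4, 2, 3)
  envs <- lapply(1:6, function(i)
    setNames(10^runif(4, -1, 1), inst$params$ligands))
  L <- do.call(rbind, envs)
  colnames(L) <- inst$params$ligands
  sol <- solve_equilibrium_batch(inst$params, L,
                                 matrix(inst$ctx$A0, 1), matrix(inst$ctx$B0, 1))
  for (i in seq_along(envs)) {
    st <- solve_equilibrium(inst$params, envs[[i]], inst$ctx)
    expect_equal(sol$S[i], st$S, tolerance = 1e-8)
  }
})

test_that("output decomposition shares sum to one", {
  set.seed(5)
  inst <- random_instance(3, 2, 2)
  st <- solve_equilibrium(inst$params, inst$env, inst$ctx)
  dec <- complex_output_decomposition(st, inst$params)
  expect_equal(sum(dec$abundance_share), 1, tolerance = 1e-9)
  expect_equal(sum(dec$output_share), 1, tolerance = 1e-9)
  expect_equal(max(dec$cum_output), 1, tolerance = 1e-9)
  # single complex carries everything
  p1 <- model_params(data.frame(ligand = "L", type1 = "A", type2 = "B",
                                K = 1, eps = 1))
  st1 <- solve_equilibrium(p1, c(L = 1), receptor_context(c(A = 1), c(B = 1)))
  d1 <- complex_output_decomposition(st1, p1)
  expect_equal(d1$abundance_share, 1)
  expect_equal(d1$output_share, 1)
})

test_that("equal-T complexes split output by activity ratio", {
  # two ligands with identical K and eps ratio 3:1 on a single receptor pair
  p <- model_params(data.frame(ligand = c("X", "Y"), type1 = "A", type2 = "B",
                               K = c(1, 1), eps = c(3, 1)))
  st <- solve_equilibrium(p, c(X = 1, Y = 1),
                          receptor_context(c(A = 1), c(B = 1)))
  dec <- complex_output_decomposition(st, p)
  expect_equal(sort(dec$output_share), c(0.25, 0.75), tolerance = 1e-9)
})

test_that("ligand attribution is complete and symmetric", {
  p <- model_params(data.frame(ligand = "L", type1 = "A", type2 = "B",
                               K = 1, eps = 1))
  att <- ligand_output_attribution(p, c(L = 1),
                                   receptor_context(c(A = 1), c(B = 1)))
  expect_equal(att$ligands$combined, att$ligands$individual)
  # two symmetric ligands at equal saturating doses split 50/50 and halve
  # each other's attributed output
  p2 <- model_params(data.frame(ligand = c("X", "Y"), type1 = "A",
                                type2 = "B", K = c(1e6, 1e6), eps = c(1, 1)))
  att2 <- ligand_output_attribution(p2, c(X = 1, Y = 1),
                                    receptor_context(c(A = 1), c(B = 1)))
  expect_equal(att2$ligands$combined[1], att2$ligands$combined[2])
  expect_equal(att2$ligands$pct_change, rep(-50, 2), tolerance = 1e-3)
})

test_that("receptor rescaling factors are bounded and applied", {
  ctx <- receptor_context(c(A = 1), c(B = 2), rho1 = c(A = 2),
                          rho2 = c(B = 1 / 2))
  expect_equal(unname(ctx$A0), 2)
  expect_equal(unname(ctx$B0), 1)
  expect_error(receptor_context(c(A = 1), c(B = 1), rho1 = c(A = 4)),
               "1/3, 3")
})
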