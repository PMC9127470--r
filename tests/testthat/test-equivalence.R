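# assemble a small synthetic feature setting: per-context pair table +
# strengths for N ligands
toy_pairs <- function(ligs, ics, cx = "c1") {
  pr <- t(combn(ligs, 2))
  data.frame(context_id = cx, ligand_a = pr[, 1], ligand_b = pr[, 2],
             row_kind = "pair",
             summary_ic = ics, stringsAsFactors = FALSE)
}

test_that("feature vectors have N+1 entries per context with doubled RLS", {
  ligs <- paste0("L", 1:10)
  pairs <- rbind(toy_pairs(ligs, rep(0, 45)),
                 data.frame(context_id = "c1", ligand_a = ligs,
                            ligand_b = ligs, row_kind = "self_pair",
                            summary_ic = 0, stringsAsFactors = FALSE))
  strengths <- data.frame(context_id = "c1", ligand = ligs, rls = 0.5)
  f <- build_feature_vectors(strengths, pairs, ligs)
  expect_equal(dim(f), c(10, 11))
  expect_true(all(f[, 11] == 1))  # 2 x 0.5
  # seven contexts concatenate to 77 features
  pairs7 <- do.call(rbind, lapply(paste0("c", 1:7), function(cx) {
    p <- pairs; p$context_id <- cx; p
  }))
  strengths7 <- do.call(rbind, lapply(paste0("c", 1:7), function(cx) {
    s <- strengths; s$context_id <- cx; s
  }))
  f7 <- build_feature_vectors(strengths7, pairs7, ligs, paste0("c", 1:7))
  expect_equal(ncol(f7), 77)
})

test_that("a 0.5 RLS difference alone gives Euclidean distance exactly 1", {
  ligs <- c("A", "B")
  pairs <- rbind(toy_pairs(ligs, 0),
                 data.frame(context_id = "c1", ligand_a = ligs,
                            ligand_b = ligs, row_kind = "self_pair",
                            summary_ic = 0, stringsAsFactors = FALSE))
  strengths <- data.frame(context_id = "c1", ligand = ligs,
                          rls = c(1, 0.5))
  f <- build_feature_vectors(strengths, pairs, ligs)
  expect_equal(as.numeric(dist(f)), 1)
  # and the pair separates at the default cut
  map <- cluster_equivalence(f, threshold = 1)
  expect_length(map$groups, 2)
})

test_that("missing interactions are reported, not imputed", {
  ligs <- c("A", "B", "C")
  pairs <- toy_pairs(ligs, c(0, 0, 0))[-2, ]
  strengths <- data.frame(context_id = "c1", ligand = ligs, rls = 1)
  expect_error(build_feature_vectors(strengths, pairs, ligs), "missing")
})

test_that("clustering separates at the cut and recovers planted groups", {
  set.seed(14)
  # three planted groups of feature vectors: tight within, > 1 apart
  centers <- rbind(rep(0, 11), c(rep(0, 5), rep(2, 6)), rep(c(0, 3), c(3, 8)))
  feats <- centers[rep(1:3, times = c(4, 3, 3)), ] +
    matrix(rnorm(110, 0, 0.05), 10, 11)
  rownames(feats) <- paste0("L", 1:10)
  map <- cluster_equivalence(feats, threshold = 1)
  expect_length(map$groups, 3)
  expect_equal(unname(vapply(map$groups, length, integer(1))), c(4, 3, 3))
  # identical vectors collapse to one group
  same <- matrix(1, 4, 11, dimnames = list(paste0("S", 1:4), NULL))
  expect_length(cluster_equivalence(same)$groups, 1)
  # a 1.2 difference in one IC feature separates two ligands
  two <- rbind(A = rep(0, 11), B = c(1.2, rep(0, 10)))
  expect_length(cluster_equivalence(two, threshold = 1)$groups, 2)
})

test_that("monochromaticity splits groups with discordant partners", {
  ligs <- c("A", "B", "C")
  feats <- rbind(A = rep(0, 4), B = rep(0.1, 4), C = rep(5, 4))
  rownames(feats) <- ligs
  # A and B are close but interact differently with outside ligand C
  cats <- data.frame(ligand_a = c("A", "B", "A"), ligand_b = c("C", "C", "B"),
                     category = c("antagonistic", "saturated_additive",
                                  "saturated_additive"))
  map <- cluster_equivalence(feats, threshold = 1, categories = cats)
  expect_length(map$groups, 3)
  # concordant categories keep them together
  cats2 <- cats; cats2$category[1] <- "saturated_additive"
  map2 <- cluster_equivalence(feats, threshold = 1, categories = cats2)
  expect_length(map2$groups, 2)
})

test_that("groups partition the ligand set regardless of input order", {
  set.seed(9)
  feats <- matrix(rnorm(44), 4, 11,
                  dimnames = list(c("A", "B", "C", "D"), NULL))
  m1 <- cluster_equivalence(feats)
  m2 <- cluster_equivalence(feats[c(3, 1, 4, 2), ])
  expect_setequal(unlist(m1$groups), rownames(feats))
  norm_groups <- function(m) sort(vapply(m$groups, function(g)
    paste(sort(g), collapse = "+"), character(1)))
  expect_identical(norm_groups(m1), norm_groups(m2))
})

test_that("global cut follows the concatenated-distance arithmetic", {
  # 7 contexts each contributing the same two-group structure at
  # per-context distance 3: global distance 3 * sqrt(7) ~ 7.94 > 7
  blk <- rbind(A = rep(0, 11), B = c(3, rep(0, 10)))
  feats <- do.call(cbind, rep(list(blk), 7))
  expect_length(global_equivalence(feats, threshold = 7)$groups, 2)
  # a single context's distance-3 split stays merged at the global cut
  expect_length(global_equivalence(blk, threshold = 7)$groups, 1)
})

test_that("profile correlation matches a direct Pearson computation", {
  set.seed(2)
  n <- 6
  feats <- matrix(rnorm(n * 11), n, 11,
                  dimnames = list(paste0("L", 1:n), NULL))
  D <- as.matrix(dist(matrix(rnorm(n * 3), n, 3)))
  dimnames(D) <- list(rownames(feats), rownames(feats))
  r <- correlate_profiles(D, feats)
  fd <- as.numeric(dist(feats))
  sd_ <- as.numeric(as.dist(D))
  expect_equal(r$r_global, cor(sd_, fd))
  # perfect and anti-perfect alignment
  D2 <- as.matrix(dist(feats)); dimnames(D2) <- dimnames(D)
  expect_equal(correlate_profiles(D2, feats)$r_global, 1)
  expect_equal(suppressWarnings(
    correlate_profiles(-D2 + max(D2), feats)$r_global), -1)
})

test_that("newick export round-trips through ape", {
  feats <- matrix(rnorm(33), 3, 11,
                  dimnames = list(c("A", "B", "C"), NULL))
  map <- cluster_equivalence(feats)
  nwk <- equivalence_newick(map)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
})
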