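#' Build per-ligand interaction feature vectors
#'
#' For each ligand and context the feature vector holds its summary IC with
#' each of the other N-1 ligands (canonical order), its self-pair IC, and
#' twice its RLS -- N+1 features per context (11 for a 10-ligand panel).
#' The RLS doubling calibrates the scale so that a 0.5 difference in RLS
#' contributes a Euclidean distance of 1, the same as a whole-regime
#' difference in one IC value. For a global analysis the per-context blocks
#' are concatenated in declared context order.
#'
#' @param strengths data.frame with `context_id`, `ligand`, `rls` (e.g.
#'   from [dose_response_table()]).
#' @param pairs per-pair summary data.frame from [interaction_table()]
#'   (`context_id`, `ligand_a`, `ligand_b`, `row_kind`, `summary_ic`).
#' @param ligands canonical ligand order.
#' @param contexts contexts to include, in order; default all in
#'   `strengths`.
#' @return numeric matrix, one row per ligand, `contexts x (N+1)` columns;
#'   missing pair or RLS entries are an error.
#' @export
build_feature_vectors <- function(strengths, pairs, ligands,
                                  contexts = unique(strengths$context_id)) {
  N <- length(ligands)
  blocks <- lapply(contexts, function(cx) {
    p <- pairs[pairs$context_id == cx, , drop = FALSE]
    s <- strengths[strengths$context_id == cx, , drop = FALSE]
    icmat <- matrix(NA_real_, N, N, dimnames = list(ligands, ligands))
    for (i in seq_len(nrow(p))) {
      a <- p$ligand_a[i]; b <- p$ligand_b[i]
      icmat[a, b] <- p$summary_ic[i]
      icmat[b, a] <- p$summary_ic[i]
    }
    if (anyNA(icmat)) {
      miss <- which(is.na(icmat), arr.ind = TRUE)[1L, ]
      .stopf("missing interaction for pair (%s, %s) in context %s",
             ligands[miss[1]], ligands[miss[2]], cx)
    }
    rls <- setNames(s$rls[match(ligands, s$ligand)], ligands)
    if (anyNA(rls)) .stopf("missing RLS for ligand %s in context %s",
                           ligands[which(is.na(rls))[1L]], cx)
    blk <- cbind(icmat, 2 * rls)
    colnames(blk) <- paste(cx, c(paste0("ic_", ligands), "rls2"), sep = ":")
    blk
  })
  do.call(cbind, blocks)
}

# restriction of a complete-linkage hierarchy to a subset equals clustering
# the subset alone, so splitting proceeds by re-clustering the group
.split_monochromatic <- function(members, feats, cat_of) {
  is_mono <- function(grp) {
    if (length(grp) < 2L) return(TRUE)
    outside <- setdiff(rownames(feats), grp)
    for (m in outside) {
      cats <- vapply(grp, function(g) cat_of(g, m), character(1))
      if (length(unique(cats)) > 1L) return(FALSE)
    }
    TRUE
  }
  if (is_mono(members)) return(list(members))
  hc <- hclust(dist(feats[members, , drop = FALSE]), method = "complete")
  halves <- split(members, cutree(hc, k = 2L))
  c(.split_monochromatic(halves[[1L]], feats, cat_of),
    .split_monochromatic(halves[[2L]], feats, cat_of))
}

#' Cluster ligands into equivalence groups for one context
#'
#' Agglomerative complete-linkage clustering on Euclidean distances between
#' feature vectors; groups merge only while the linkage distance is
#' strictly below `threshold` (so a pure 0.5-RLS difference, distance
#' exactly 1, separates at the default cut). When interaction categories
#' are supplied, groups are then split top-down along the linkage until
#' every group is monochromatic: all members share the same summary
#' interaction category with every ligand outside the group.
#'
#' @param features feature matrix from [build_feature_vectors()] (rows =
#'   ligands).
#' @param threshold linkage cut (strict).
#' @param categories optional per-pair category table (`ligand_a`,
#'   `ligand_b`, `category`) for the monochromaticity rule; omit to skip it.
#' @param strengths optional named RLS vector; adds per-group mean RLS.
#' @return object of class `equivalence_map`: list with `groups` (list of
#'   ligand character vectors, a partition), `membership` (named integer
#'   vector), `tree` (the hclust object), `group_rls` (mean RLS per group,
#'   if given), `threshold`.
#' @export
cluster_equivalence <- function(features, threshold = 1, categories = NULL,
                                strengths = NULL) {
  ligs <- rownames(features)
  if (is.null(ligs)) .stopf("feature matrix must have ligand rownames")
  if (length(ligs) < 2L) {
    return(structure(list(groups = list(ligs),
                          membership = setNames(1L, ligs), tree = NULL,
                          group_rls = NULL, threshold = threshold),
                     class = "equivalence_map"))
  }
  hc <- hclust(dist(features), method = "complete")
  cut <- cutree(hc, h = threshold * (1 - 1e-9))
  groups <- split(ligs, cut)
  if (!is.null(categories)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    cat_map <- setNames(categories$category,
                        key(categories$ligand_a, categories$ligand_b))
    cat_of <- function(a, b) {
      v <- cat_map[key(a, b)]
      if (is.na(v)) .stopf("missing interaction category for pair (%s, %s)", a, b)
      unname(v)
    }
    groups <- do.call(c, lapply(groups, .split_monochromatic,
                                feats = features, cat_of = cat_of))
  }
  groups <- unname(groups[order(vapply(groups, function(g)
    min(match(g, ligs)), numeric(1)))])
  membership <- setNames(rep(seq_along(groups), lengths(groups)),
                         unlist(groups))[ligs]
  group_rls <- if (!is.null(strengths))
    vapply(groups, function(g) mean(strengths[g]), numeric(1)) else NULL
  structure(list(groups = groups, membership = membership, tree = hc,
                 group_rls = group_rls, threshold = threshold),
            class = "equivalence_map")
}

#' @export
print.equivalence_map <- function(x, ...) {
  cat(sprintf("equivalence_map: %d group(s) at cut %g\n",
              length(x$groups), x$threshold))
  for (i in seq_along(x$groups))
    cat(sprintf("  [%s]\n", paste(x$groups[[i]], collapse = ", ")))
  invisible(x)
}

#' Global equivalence groups across all contexts
#'
#' Clusters the concatenated per-context feature vectors with complete
#' linkage and cuts at the global threshold (default: Euclidean distance
#' 7). Monochromaticity is deliberately not enforced globally: with many
#' contexts a single discordant pairwise call should not split a group.
#'
#' @param features concatenated feature matrix (all contexts) from
#'   [build_feature_vectors()].
#' @param threshold global cut; the default follows the literal Euclidean
#'   distance of 7. Set `threshold = sqrt(7)` to interpret the seven-fold
#'   increase as applying to the squared distance instead.
#' @param strengths optional named RLS vector (e.g. averaged over contexts).
#' @return an `equivalence_map`.
#' @export
global_equivalence <- function(features, threshold = 7, strengths = NULL) {
  cluster_equivalence(features, threshold = threshold, categories = NULL,
                      strengths = strengths)
}

#' Pairwise sequence distances from a gap-free BLOSUM50 comparison
#'
#' Computes, over the columns of a multiple global alignment that contain
#' no gap in any sequence, the summed BLOSUM50 score \eqn{s_{ij}} between
#' every pair, and converts scores to distances as \eqn{d_{ij} = 1 -
#' s_{ij} / \min(s_{ii}, s_{jj})}, so identical sequences are at distance 0
#' and dissimilar pairs can exceed 1. Sequences of unequal length are
#' aligned first with the `mafft` command-line aligner (default
#' parameters); equal-length inputs are taken as already aligned.
#'
#' @param sequences named character vector of protein sequences, a FASTA
#'   file path, or a `Biostrings::AAStringSet`.
#' @return list with `distance` (symmetric matrix), `score` (raw summed
#'   scores), `tree` (average-linkage hclust), `n_columns` (gap-free
#'   columns used).
#' @export
sequence_distance_matrix <- function(sequences) {
  seqs <- .as_protein_strings(sequences)
  if (length(seqs) < 2L) .stopf("need at least 2 sequences")
  if (length(unique(nchar(seqs))) > 1L) seqs <- .mafft_align(seqs)
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  aa <- rownames(.blosum50())
  bad <- setdiff(unique(as.vector(mat)), c(aa, "-", "."))
  if (length(bad))
    .stopf("non-amino-acid symbol(s) in sequences: %s",
           paste(bad, collapse = ", "))
  keep <- colSums(mat == "-" | mat == ".") == 0
  if (!any(keep)) .stopf("no gap-free alignment columns")
  mat <- mat[, keep, drop = FALSE]
  B <- .blosum50()
  n <- nrow(mat)
  S <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n))
    for (j in i:n)
      S[i, j] <- S[j, i] <- sum(B[cbind(mat[i, ], mat[j, ])])
  D <- 1 - S / outer(diag(S), diag(S), pmin)
  diag(D) <- 0
  tree <- hclust(as.dist(D), method = "average")
  list(distance = D, score = S, tree = tree, n_columns = ncol(mat))
}

.as_protein_strings <- function(x) {
  if (inherits(x, "AAStringSet")) return(setNames(as.character(x), names(x)))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    if (!requireNamespace("Biostrings", quietly = TRUE))
      .stopf("reading FASTA requires the Biostrings package")
    s <- Biostrings::readAAStringSet(x)
    return(setNames(as.character(s), sub("\\s.*$", "", names(s))))
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  .stopf("sequences must be a named character vector, FASTA path, or AAStringSet")
}

.mafft_align <- function(seqs) {
  if (Sys.which("mafft") == "")
    .stopf("sequences are unaligned and mafft is not on the PATH; supply pre-aligned (equal-length) sequences")
  fin <- tempfile(fileext = ".fasta"); fout <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(">", names(seqs), "\n", seqs), fin)
  system2("mafft", c("--auto", "--quiet", fin), stdout = fout)
  lines <- readLines(fout)
  hd <- grepl("^>", lines)
  id <- cumsum(hd)
  out <- tapply(lines[!hd], id[!hd], paste, collapse = "")
  setNames(as.character(out), sub("^>", "", lines[hd]))
}

# BLOSUM50 substitution matrix, from Biostrings
.blosum50 <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    if (!requireNamespace("Biostrings", quietly = TRUE))
      .stopf("sequence comparison requires the Biostrings package")
    env <- new.env()
    utils::data("BLOSUM50", package = "Biostrings", envir = env)
    cache <<- env$BLOSUM50
    cache
  }
})

#' Correlate sequence distances with interaction-profile distances
#'
#' Pearson correlation over the off-diagonal ligand pairs between a
#' sequence distance matrix and the Euclidean distances of interaction
#' feature vectors, per context set. Optionally sweeps random context
#' subsets and reports the maximum subset correlation.
#'
#' @param seq_dist symmetric sequence distance matrix (ligands in rows).
#' @param features concatenated feature matrix (same ligands).
#' @param context_blocks optional named list mapping context id to its
#'   column indices in `features`; enables per-context and subset
#'   correlations.
#' @param n_subsets number of random context subsets to sample (0 = none).
#' @param seed seed for subset sampling.
#' @return list with `r_global`, optional `r_context` (named vector),
#'   `subsets` (data.frame of sampled subsets and their r, plus `r_max`).
#'   Constant distance vectors give `NA` with a warning.
#' @export
correlate_profiles <- function(seq_dist, features, context_blocks = NULL,
                               n_subsets = 0L, seed = 1L) {
  ligs <- rownames(features)
  if (!all(ligs %in% rownames(seq_dist))) .stopf("ligand sets do not match")
  sd_v <- as.dist(seq_dist[ligs, ligs])
  pear <- function(fd) {
    if (stats::sd(fd) == 0 || stats::sd(sd_v) == 0) {
      warning("constant distance vector; correlation undefined")
      return(NA_real_)
    }
    cor(as.numeric(sd_v), as.numeric(fd))
  }
  out <- list(r_global = pear(dist(features)))
  if (!is.null(context_blocks)) {
    out$r_context <- vapply(context_blocks, function(cols)
      pear(dist(features[, cols, drop = FALSE])), numeric(1))
    if (n_subsets > 0L) {
      set.seed(seed)
      ctx <- names(context_blocks)
      rows <- lapply(seq_len(n_subsets), function(i) {
        k <- sample(seq_along(ctx), 1L)
        pick <- sort(sample(ctx, k))
        cols <- unlist(context_blocks[pick], use.names = FALSE)
        data.frame(subset = paste(pick, collapse = "+"),
                   r = pear(dist(features[, cols, drop = FALSE])),
                   stringsAsFactors = FALSE)
      })
      subs <- do.call(rbind, rows)
      out$subsets <- subs
      out$r_max <- max(subs$r, na.rm = TRUE)
    }
  }
  out
}

#' Export an equivalence map's linkage tree as Newick
#'
#' @param map an `equivalence_map` (with a non-NULL tree).
#' @param file optional path; when omitted the Newick string is returned.
#' @return the Newick string, invisibly when written to file.
#' @export
equivalence_newick <- function(map, file = NULL) {
  if (is.null(map$tree)) .stopf("map has no linkage tree (single ligand)")
  phy <- ape::as.phylo(map$tree)
  if (is.null(file)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = file)
  invisible(ape::write.tree(phy))
}
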