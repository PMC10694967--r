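# Detection of population structure in the sampled cohort (PCA of the
# dosage matrix + k-means grouping) and the remedy: restrict the LD-based
# Ne estimation to one inferred group.

#' Principal component analysis of genotype dosages
#'
#' Columns are centered and unit-variance scaled (non-constant columns; the
#' matrix invariant guarantees none are constant) and the top-`k`
#' components are taken by singular value.  For determinism each component
#' is oriented so its largest-|loading| SNP has a positive loading.
#'
#' @param gm A `genotype_matrix`.
#' @param k Number of components (reduced with a warning if it exceeds the
#'   matrix rank).
#' @return An object of class `pca_result`: list with `coordinates`
#'   (individuals x k), `explained` (variance fractions), `loadings`, and
#'   `group_labels` (`NULL` until [assign_groups()]).
#' @export
genotype_pca <- function(gm, k = 10L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (n_individuals(gm) < 2 || n_snps(gm) < 2)
    stop("need at least 2 individuals and 2 SNPs")
  X <- gm$dosages
  sdv <- apply(X, 2, stats::sd)
  X <- scale(X, center = TRUE, scale = ifelse(sdv > 0, sdv, 1))
  pr <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  rank <- sum(pr$sdev > pr$sdev[1] * 1e-12)
  if (k > rank) {
    warning(sprintf("k = %d exceeds rank %d; using %d", k, rank, rank))
    k <- rank
  }
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  coords <- pr$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    top <- which.max(abs(rot[, j]))
    if (rot[top, j] < 0) {
      rot[, j] <- -rot[, j]
      coords[, j] <- -coords[, j]
    }
  }
  rownames(coords) <- gm$sample_ids
  structure(list(coordinates = coords,
                 explained = pr$sdev^2 / sum(pr$sdev^2),
                 loadings = rot,
                 group_labels = NULL,
                 deme_ids = gm$deme_ids),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result: %d individuals, %d components; PC1 explains %.1f%%>\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$explained[1]))
  invisible(x)
}

#' Cluster individuals on the leading principal components
#'
#' Seeded multi-start k-means on the top two components (one if only one is
#' available).  Labels are canonicalized by decreasing group size, ties
#' broken by increasing mean PC1, so repeated runs agree.  A gap-statistic
#' style hint (total within-group sum of squares for 1..5 groups) is
#' printed when `verbose = TRUE`, but never auto-applied.
#'
#' @param pca A `pca_result`.
#' @param n_groups Number of groups (default 2).
#' @param seed Seed for the k-means starts.
#' @param verbose Print the within-group sum-of-squares hint.
#' @return Integer vector of group labels (1-based), also stored back in
#'   the returned `pca_result` when assigned.
#' @export
assign_groups <- function(pca, n_groups = 2L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(pca, "pca_result"))
  n <- nrow(pca$coordinates)
  if (n_groups > n) stop("fewer individuals than groups")
  if (n_groups == 1L) return(rep(1L, n))
  Y <- pca$coordinates[, seq_len(min(2L, ncol(pca$coordinates))),
                       drop = FALSE]
  km <- with_local_seed(seed, function()
    stats::kmeans(Y, centers = n_groups, nstart = 25L, iter.max = 100L))
  if (verbose) {
    wss <- vapply(seq_len(min(5L, n - 1L)), function(kk)
      with_local_seed(seed, function()
        stats::kmeans(Y, kk, nstart = 10L, iter.max = 100L)$tot.withinss),
      numeric(1))
    message("within-group SS for k = 1..", length(wss), ": ",
            paste(signif(wss, 4), collapse = ", "))
  }
  raw <- km$cluster
  size <- tabulate(raw, n_groups)
  pc1_mean <- vapply(seq_len(n_groups), function(g)
    mean(Y[raw == g, 1]), numeric(1))
  ord <- order(-size, pc1_mean)
  relabel <- integer(n_groups)
  relabel[ord] <- seq_len(n_groups)
  relabel[raw]
}

#' Restrict to one inferred group and re-estimate Ne
#'
#' Subsets the cohort to the individuals of `chosen_group`, re-filters
#' monomorphic and low-MAF sites, and re-runs the full LD estimation --
#' the remedy for the sampling-across-subpopulations artifact.
#'
#' @param gm A `genotype_matrix`.
#' @param labels Group labels from [assign_groups()] (length = number of
#'   individuals).
#' @param chosen_group Label of the group to keep (>= 10 individuals).
#' @param cfg An [estimator_config()].
#' @param maf_min MAF threshold re-applied after subsetting.
#' @param reference Optional `nevk_reference` attached to the trajectory.
#' @return An `ne_trajectory` for the restricted cohort.
#' @export
restrict_and_reestimate <- function(gm, labels, chosen_group,
                                    cfg = estimator_config(),
                                    maf_min = 0.05, reference = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"),
            length(labels) == n_individuals(gm))
  keep <- labels == chosen_group
  if (sum(keep) < 10)
    stop(sprintf("group %s has only %d individuals (need >= 10)",
                 format(chosen_group), sum(keep)))
  sub <- subset_individuals(gm, keep, maf_min = maf_min)
  estimate_ne(sub, cfg, reference = reference)
}

#' Write PCA coordinates and labels as a TSV table
#'
#' @param pca A `pca_result`.
#' @param labels Optional group labels.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_pca <- function(pca, labels = NULL, path) {
  df <- data.frame(id = rownames(pca$coordinates), pca$coordinates)
  if (!is.null(pca$deme_ids)) df$deme <- pca$deme_ids
  if (!is.null(labels)) df$group <- labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
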