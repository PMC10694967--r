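# Moment-based estimation of the historical Ne trajectory from
# genetic-distance-binned composite r-squared.
#
# The LD at recombination distance c Morgan reflects the effective size
# roughly t = 1/(2c) generations before present.  For unphased random-
# mating data the expected composite r2 at equilibrium is approximately
#     E[r2] = 1/(alpha + 4 Ne c) + 1/n,      alpha = 2,
# with n the number of diploid individuals, so each genetic-distance bin
# inverts to
#     Ne_hat(c) = (1/(r2_bar - 1/n) - alpha) / (4 c),
# reported at the bin's mapped time 1/(2c).

#' Estimator configuration
#'
#' @param c_min,c_max Genetic-distance window in Morgan over which SNP
#'   pairs are used (defaults 0.001 and 0.05; the corresponding time
#'   horizon is 1/(2c), i.e. 10 to 500 generations).
#' @param n_bins Number of log-spaced distance bins.
#' @param max_pairs_per_bin Cap on pairs retained per bin per chromosome
#'   (uniform seeded subsample above the cap).
#' @param alpha Constant in the Sved-type denominator; 2 for unphased
#'   composite LD under random mating.
#' @param sample_correction Subtract `1/n` (n diploid individuals) from the
#'   binned mean r2 before inversion.
#' @param seed Seed for the pair subsampling.
#' @return An object of class `estimator_config`.
#' @export
estimator_config <- function(c_min = 0.001, c_max = 0.05, n_bins = 30L,
                             max_pairs_per_bin = 100000L, alpha = 2,
                             sample_correction = TRUE, seed = 1L) {
  if (!(c_min > 0 && c_min < c_max && c_max <= 0.5))
    stop("need 0 < c_min < c_max <= 0.5")
  n_bins <- as.integer(n_bins)
  if (n_bins < 3L) stop("n_bins must be >= 3")
  structure(list(c_min = c_min, c_max = c_max, n_bins = n_bins,
                 max_pairs_per_bin = as.integer(max_pairs_per_bin),
                 alpha = alpha,
                 sample_correction = isTRUE(sample_correction),
                 seed = as.integer(seed)),
            class = "estimator_config")
}

#' Composite r-squared of two dosage vectors
#'
#' The squared Pearson correlation of unphased genotype dosages -- the
#' standard phase-free surrogate for haplotype r2.
#'
#' @param x,y Integer dosage vectors in `{0, 1, 2}` of equal length >= 3.
#' @return r2 in `[0, 1]`, or `NA` if either vector is constant.
#' @export
dosage_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Map a genetic distance to a historical generation
#'
#' The LD between SNP pairs at recombination distance `c` Morgan reflects
#' Ne about `t = 1/(2c)` generations before present; the default minimum
#' distance 0.001 Morgan therefore gives a horizon of 500 generations.
#'
#' @param c_mid Genetic distance in Morgan, `0 < c_mid <= 0.5` (vectorized).
#' @return Generations before present.
#' @export
bin_to_time <- function(c_mid) {
  if (any(c_mid <= 0) || any(c_mid > 0.5))
    stop("c_mid must satisfy 0 < c_mid <= 0.5")
  1 / (2 * c_mid)
}

log_bin_breaks <- function(cfg) {
  exp(seq(log(cfg$c_min), log(cfg$c_max), length.out = cfg$n_bins + 1L))
}

# run fn with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# All intra-chromosome SNP pairs of one chromosome with genetic distance in
# [c_min, c_max], binned; r2 from chunked dosage correlations.
bin_pairs_one_chrom <- function(dos, g, cfg, chrom_seed) {
  breaks <- log_bin_breaks(cfg)
  nb <- cfg$n_bins
  p <- length(g)
  out <- data.frame(bin = seq_len(nb),
                    c_lo = breaks[-(nb + 1L)], c_hi = breaks[-1L],
                    c_mid = sqrt(breaks[-(nb + 1L)] * breaks[-1L]),
                    pair_count = 0L, sum_r2 = 0, skipped = 0L)
  if (p < 2) return(out)

  tol <- 1e-12
  hi <- findInterval(g + cfg$c_max + tol, g)
  lo <- findInterval(g + cfg$c_min - tol, g) + 1L
  lo <- pmax(lo, seq_len(p) + 1L)
  cnt <- pmax(hi - lo + 1L, 0L)
  if (sum(cnt) == 0) return(out)
  i_idx <- rep.int(seq_len(p), cnt)
  j_idx <- sequence(cnt, from = lo)
  d <- g[j_idx] - g[i_idx]
  ok <- d >= cfg$c_min - tol & d <= cfg$c_max + tol
  i_idx <- i_idx[ok]; j_idx <- j_idx[ok]; d <- d[ok]
  if (!length(d)) return(out)

  bin <- findInterval(d, breaks, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L
  bin[bin > nb] <- nb

  # per-bin cap, uniform seeded subsample
  keep <- with_local_seed(chrom_seed, function() {
    unlist(lapply(split(seq_along(bin), bin), function(ix) {
      if (length(ix) > cfg$max_pairs_per_bin)
        sample(ix, cfg$max_pairs_per_bin) else ix
    }), use.names = FALSE)
  })
  i_idx <- i_idx[keep]; j_idx <- j_idx[keep]; bin <- bin[keep]

  # standardized dosages: r = z_i . z_j / (n - 1)
  n <- nrow(dos)
  mu <- colMeans(dos)
  sdv <- sqrt(colMeans(dos^2) - mu^2) * sqrt(n / (n - 1))
  Z <- sweep(dos, 2L, mu, "-")
  nonconst <- sdv > 0
  Z[, nonconst] <- sweep(Z[, nonconst, drop = FALSE], 2L, sdv[nonconst], "/")

  r2 <- numeric(length(i_idx))
  chunk <- 50000L
  for (s in seq(1L, length(i_idx), by = chunk)) {
    e <- min(s + chunk - 1L, length(i_idx))
    ii <- i_idx[s:e]; jj <- j_idx[s:e]
    r2[s:e] <- (colSums(Z[, ii, drop = FALSE] * Z[, jj, drop = FALSE]) /
                  (n - 1))^2
  }
  bad <- !nonconst[i_idx] | !nonconst[j_idx]
  for (b in seq_len(nb)) {
    sel <- bin == b & !bad
    out$pair_count[b] <- sum(sel)
    out$sum_r2[b] <- sum(r2[sel])
    out$skipped[b] <- sum(bin == b & bad)
  }
  out$pair_count <- as.integer(out$pair_count)
  out$skipped <- as.integer(out$skipped)
  out
}

#' Bin SNP pairs by genetic distance and average r2
#'
#' Considers intra-chromosome pairs only; genetic distance is map distance
#' in Morgan (`|delta bp| * map_rate`).  Pairs outside `[c_min, c_max]` are
#' excluded; within each log-spaced bin, pairs beyond `max_pairs_per_bin`
#' are uniformly subsampled (seeded).  Bins are pooled across chromosomes
#' by pair-count-weighted average.
#'
#' @param gm A `genotype_matrix`.
#' @param cfg An [estimator_config()].
#' @param pool Pool chromosomes (default); if `FALSE`, returns a list of
#'   per-chromosome bin tables.
#' @return An object of class `ld_bins`: a data frame with columns `bin`,
#'   `c_lo`, `c_hi`, `c_mid`, `pair_count`, `mean_r2` (and `skipped`).
#' @export
bin_pairs_by_distance <- function(gm, cfg = estimator_config(), pool = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(cfg, "estimator_config"))
  chroms <- sort(unique(gm$chromosome))
  per <- lapply(seq_along(chroms), function(k) {
    sel <- gm$chromosome == chroms[k]
    raw <- bin_pairs_one_chrom(gm$dosages[, sel, drop = FALSE],
                               gm$genetic_morgan[sel], cfg,
                               chrom_seed = cfg$seed + k)
    finish_bins(raw, cfg)
  })
  if (!pool) return(per)
  pooled <- pool_chromosomes(per)
  if (sum(pooled$pair_count) == 0)
    stop("no SNP pairs fall in [c_min, c_max] on any chromosome")
  pooled
}

finish_bins <- function(raw, cfg) {
  raw$mean_r2 <- ifelse(raw$pair_count > 0, raw$sum_r2 / raw$pair_count,
                        NA_real_)
  out <- raw[, c("bin", "c_lo", "c_hi", "c_mid", "pair_count", "mean_r2",
                 "skipped")]
  attr(out, "cfg") <- cfg
  class(out) <- c("ld_bins", "data.frame")
  out
}

#' Pool per-chromosome LD bins
#'
#' Pair-count-weighted average of `mean_r2` on an identical bin grid.
#'
#' @param bin_list A list of `ld_bins` tables on the same grid.
#' @return A pooled `ld_bins` table.
#' @export
pool_chromosomes <- function(bin_list) {
  if (inherits(bin_list, "ld_bins")) return(bin_list)
  stopifnot(length(bin_list) >= 1)
  ref <- bin_list[[1]]
  for (b in bin_list[-1]) {
    if (nrow(b) != nrow(ref) ||
        any(abs(b$c_mid - ref$c_mid) > 1e-12 * ref$c_mid))
      stop("mismatched bin grids cannot be pooled")
  }
  out <- ref
  w <- Reduce(`+`, lapply(bin_list, function(b) b$pair_count))
  s <- Reduce(`+`, lapply(bin_list, function(b) {
    x <- b$mean_r2 * b$pair_count
    x[is.na(x)] <- 0
    x
  }))
  out$pair_count <- w
  out$mean_r2 <- ifelse(w > 0, s / w, NA_real_)
  out$skipped <- Reduce(`+`, lapply(bin_list, function(b) b$skipped))
  out
}

#' Invert binned r2 into an Ne trajectory
#'
#' Applies the sample-size correction (`r2_adj = mean_r2 - 1/n`), drops
#' bins whose adjusted r2 leaves the invertible range `(0, 1/alpha)`, and
#' maps each remaining bin to `Ne_hat = (1/r2_adj - alpha)/(4 c)` at time
#' `t = 1/(2c)` generations before present.
#'
#' @param bins An `ld_bins` table (pooled).
#' @param n_individuals Number of diploid individuals genotyped.
#' @param cfg An [estimator_config()].
#' @param reference Optional `nevk_reference` from [expected_nevk()];
#'   adds `expected_nevk` (total line) and `expected_nevk_focal` columns.
#' @return An object of class `ne_trajectory`: a data frame with columns
#'   `t`, `c_mid`, `pair_count`, `mean_r2`, `r2_adj`, `Ne_hat`, sorted by
#'   increasing `t`.  Dropped bins are kept in the `dropped` attribute.
#' @export
estimate_ne_curve <- function(bins, n_individuals, cfg = estimator_config(),
                              reference = NULL) {
  if (!nrow(bins)) stop("empty bin table")
  r2_adj <- bins$mean_r2 - if (cfg$sample_correction) 1 / n_individuals else 0
  usable <- !is.na(r2_adj) & r2_adj > 0 & r2_adj < 1 / cfg$alpha &
    bins$pair_count > 0
  if (!any(usable))
    stop(sprintf(
      "all bins dropped: adjusted r2 range [%.4g, %.4g] outside (0, %.3g)",
      suppressWarnings(min(r2_adj, na.rm = TRUE)),
      suppressWarnings(max(r2_adj, na.rm = TRUE)), 1 / cfg$alpha))
  out <- data.frame(t = bin_to_time(bins$c_mid),
                    c_mid = bins$c_mid,
                    pair_count = bins$pair_count,
                    mean_r2 = bins$mean_r2,
                    r2_adj = r2_adj,
                    Ne_hat = (1 / r2_adj - cfg$alpha) / (4 * bins$c_mid))
  dropped <- out[!usable, , drop = FALSE]
  out <- out[usable, , drop = FALSE]
  out <- out[order(out$t), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(reference)) {
    out$expected_nevk <- nevk_at(reference, out$t, "total")
    out$expected_nevk_focal <- nevk_at(reference, out$t, "focal")
  }
  attr(out, "dropped") <- dropped
  attr(out, "n_individuals") <- n_individuals
  attr(out, "cfg") <- cfg
  class(out) <- c("ne_trajectory", "data.frame")
  out
}

#' Estimate the historical Ne trajectory from a genotype matrix
#'
#' Convenience wrapper: bins pairs by genetic distance (pooled across
#' chromosomes, or in two chromosome halves whose estimates are averaged)
#' and inverts the binned r2 into an Ne trajectory.
#'
#' @param gm A `genotype_matrix`.
#' @param cfg An [estimator_config()].
#' @param reference Optional `nevk_reference`.
#' @param split_halves If `TRUE`, chromosomes are split into two pools,
#'   a trajectory is estimated from each, and the two `Ne_hat` curves are
#'   averaged per bin.
#' @return An `ne_trajectory`.
#' @export
estimate_ne <- function(gm, cfg = estimator_config(), reference = NULL,
                        split_halves = FALSE) {
  per <- bin_pairs_by_distance(gm, cfg, pool = FALSE)
  n <- n_individuals(gm)
  if (split_halves && length(per) >= 2) {
    h <- length(per) %/% 2L
    t1 <- estimate_ne_curve(pool_chromosomes(per[seq_len(h)]), n, cfg,
                            reference)
    t2 <- estimate_ne_curve(pool_chromosomes(per[(h + 1L):length(per)]), n,
                            cfg, reference)
    common <- intersect(round(t1$t, 9), round(t2$t, 9))
    t1 <- t1[round(t1$t, 9) %in% common, , drop = FALSE]
    t2 <- t2[round(t2$t, 9) %in% common, , drop = FALSE]
    t1$Ne_hat <- (t1$Ne_hat + t2$Ne_hat) / 2
    t1$mean_r2 <- (t1$mean_r2 + t2$mean_r2) / 2
    t1$r2_adj <- (t1$r2_adj + t2$r2_adj) / 2
    t1$pair_count <- t1$pair_count + t2$pair_count
    return(t1)
  }
  estimate_ne_curve(pool_chromosomes(per), n, cfg, reference)
}

#' Write an Ne trajectory as a TSV table
#'
#' @param traj An `ne_trajectory`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.ne_trajectory <- function(x, ...) {
  cat(sprintf("<ne_trajectory: %d bins, t in [%.3g, %.3g] generations>\n",
              nrow(x), min(x$t), max(x$t)))
  print.data.frame(utils::head(as.data.frame(x), 8), digits = 4)
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}
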