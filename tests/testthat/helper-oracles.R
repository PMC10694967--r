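# Independent oracles and small fixture builders used across the suite.

# Brute-force all-pairs binned mean r2: enumerates every intra-chromosome
# SNP pair, computes cor()^2 directly, and averages per log-spaced bin.
# Independent of the package's vectorized/chunked binning path.
brute_force_bins <- function(gm, cfg) {
  breaks <- exp(seq(log(cfg$c_min), log(cfg$c_max), length.out = cfg$n_bins + 1))
  sums <- numeric(cfg$n_bins)
  counts <- integer(cfg$n_bins)
  for (ch in unique(gm$chromosome)) {
    sel <- which(gm$chromosome == ch)
    g <- gm$genetic_morgan[sel]
    X <- gm$dosages[, sel, drop = FALSE]
    p <- length(sel)
    if (p < 2) next
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        d <- abs(g[j] - g[i])
        if (d < cfg$c_min - 1e-12 || d > cfg$c_max + 1e-12) next
        b <- findInterval(d, breaks, rightmost.closed = TRUE)
        b <- min(max(b, 1L), cfg$n_bins)
        r2 <- suppressWarnings(stats::cor(X[, i], X[, j])^2)
        if (is.na(r2)) next
        sums[b] <- sums[b] + r2
        counts[b] <- counts[b] + 1L
      }
    }
  }
  list(mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
       pair_count = counts)
}

# Nei-style G_ST from census allele frequencies (ratio of averages over all
# sites segregating in the metapopulation).
fst_gst <- function(state) {
  demes <- state$demes
  pos <- sort(unique(unlist(lapply(demes, function(d) unlist(d$haplotypes)))))
  P <- sapply(demes, function(d)
    tabulate(match(unlist(d$haplotypes), pos), length(pos)) /
      length(d$haplotypes))
  pbar <- rowMeans(P)
  seg <- pbar > 0 & pbar < 1
  P <- P[seg, , drop = FALSE]
  pbar <- pbar[seg]
  1 - sum(rowMeans(2 * P * (1 - P))) / sum(2 * pbar * (1 - pbar))
}

# Census nucleotide diversity per site of deme 1 (unbiased pairwise form).
pi_per_site <- function(state, L) {
  d <- state$demes[[1]]
  H <- length(d$haplotypes)
  pos <- sort(unique(unlist(d$haplotypes)))
  if (!length(pos)) return(0)
  cnt <- tabulate(match(unlist(d$haplotypes), pos), length(pos))
  p <- cnt / H
  sum(2 * p * (1 - p)) * H / (H - 1) / L
}

# Fabricate a genotype_matrix directly (bypasses simulation) for estimator
# and I/O fixtures.
make_gm <- function(dosages, positions_bp, chromosome = NULL,
                    map_rate = 1e-8) {
  if (is.null(chromosome)) chromosome <- rep(1L, length(positions_bp))
  ldnesim:::new_genotype_matrix(
    dosages = dosages,
    positions_bp = as.integer(positions_bp),
    chromosome = as.integer(chromosome),
    map_rate = map_rate,
    sample_ids = sprintf("ind%03d", seq_len(nrow(dosages))),
    deme_ids = rep(1L, nrow(dosages)))
}

# Random non-constant dosage matrix fixture.
random_gm <- function(n_ind, n_snp, map_rate = 1e-8, L = 250e6, seed = 1) {
  set.seed(seed)
  repeat {
    dos <- matrix(rbinom(n_ind * n_snp, 2, runif(n_snp, 0.1, 0.9)[
      rep(seq_len(n_snp), each = n_ind)]), n_ind, n_snp)
    if (all(apply(dos, 2, stats::sd) > 0)) break
  }
  make_gm(dos, sort(sample.int(L, n_snp)), map_rate = map_rate)
}

median_ne <- function(traj, lo, hi) {
  stats::median(traj$Ne_hat[traj$t > lo & traj$t <= hi])
}
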