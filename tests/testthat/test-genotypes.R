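# Cohort sampling, genotype matrix construction, masking, PED/MAP/VCF I/O.

tiny_cohort <- function() {
  # 2 individuals, one chromosome: ind1 = {}/{}, ind2 = {}/{5}
  structure(list(
    chromosomes = list(list(
      haplotypes = list(integer(0), integer(0), integer(0), c(5L)),
      inversion = rep(FALSE, 4))),
    deme_ids = c(1L, 1L),
    sample_ids = c("a", "b"),
    indices = list(1:2),
    n_individuals = 2L,
    genome = genome_config(100L, 1e-3, 1e-4, 1L)),
    class = "sampled_cohort")
}

test_that("hand-built cohort yields one SNP at position 5 with dosages (0, 1)", {
  gm <- build_genotype_matrix(tiny_cohort(), maf_min = 0)
  expect_identical(n_snps(gm), 1L)
  expect_identical(gm$positions_bp, 5L)
  expect_identical(as.integer(gm$dosages), c(0L, 1L))
  expect_equal(gm$genetic_morgan, 5 * 1e-4)
})

test_that("sites below the MAF threshold are removed", {
  # 20 individuals; site A at derived freq 1/40 = 0.025, site B at 0.5
  haps <- replicate(40, integer(0), simplify = FALSE)
  haps[[1]] <- c(10L)                      # singleton
  for (i in 1:20) haps[[i]] <- sort(unique(c(haps[[i]], 50L)))
  cohort <- structure(list(
    chromosomes = list(list(haplotypes = haps, inversion = rep(FALSE, 40))),
    deme_ids = rep(1L, 20), sample_ids = sprintf("i%02d", 1:20),
    indices = list(1:20), n_individuals = 20L,
    genome = genome_config(100L, 1e-3, 1e-4, 1L)), class = "sampled_cohort")
  gm <- build_genotype_matrix(cohort, maf_min = 0.05)
  expect_identical(gm$positions_bp, 50L)
  gm0 <- build_genotype_matrix(cohort, maf_min = 0)
  expect_identical(gm0$positions_bp, c(10L, 50L))
})

test_that("matrix MAFs respect the threshold and no column is constant on simulated data", {
  gm <- panmictic_gm()
  n <- n_individuals(gm)
  ac <- colSums(gm$dosages)
  f <- ac / (2 * n)
  expect_true(all(pmin(f, 1 - f) >= 0.05))
  expect_true(all(ac > 0 & ac < 2 * n))
  expect_false(is.unsorted(order(gm$chromosome, gm$positions_bp)))
  # dosages recount exactly from the sampled haplotypes (brute force)
  run <- panmictic_run()
  cohort <- draw_sample(run, seed = 3)  # same seed as the cached fixture
  ch1 <- which(gm$chromosome == 1L)
  for (j in ch1[seq(1, length(ch1), length.out = 25)]) {
    pos <- gm$positions_bp[j]
    cnt <- vapply(seq_len(n), function(i) {
      h <- cohort$chromosomes[[1]]$haplotypes
      sum(pos %in% h[[2 * i - 1]]) + sum(pos %in% h[[2 * i]])
    }, numeric(1))
    expect_identical(as.integer(gm$dosages[, j]), as.integer(cnt))
  }
})

test_that("sampling schemes draw the right counts and reuse indices across chromosomes", {
  run <- two_demes_run()
  co <- draw_sample(run, spec = sample_spec(100, "pooled_equal"),
                    genome = run$scenario$genome, seed = 5)
  expect_identical(co$n_individuals, 100L)
  expect_identical(as.integer(table(co$deme_ids)), c(50L, 50L))
  # identical indices reused on every chromosome
  expect_identical(length(unique(lapply(co$chromosomes, function(ch)
    length(ch$haplotypes)))), 1L)
  co1 <- draw_sample(run, spec = sample_spec(80, "single_deme", 2),
                     genome = run$scenario$genome, seed = 6)
  expect_true(all(co1$deme_ids == 2L))
  expect_error(draw_sample(run, spec = sample_spec(101, "pooled_equal"),
                           genome = run$scenario$genome),
               "divisible")
  expect_error(draw_sample(run, spec = sample_spec(150, "single_deme", 1),
                           genome = run$scenario$genome),
               "requested")
})

test_that("within-deme sampling is uniform over individuals", {
  # frequency of each individual over repeated seeded draws (chi-square)
  st <- metapop_state(list(list(
    haplotypes = replicate(40, integer(0), simplify = FALSE))))
  run <- list(st)
  spec <- sample_spec(5, "single_deme", 1)
  g <- genome_config(100L, 1e-3, 1e-4, 1L)
  set.seed(13)
  counts <- integer(20)
  for (r in 1:2000) {
    co <- draw_sample(run, spec = spec, genome = g)
    counts[unlist(co$indices)] <- counts[unlist(co$indices)] + 1L
  }
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)
})

test_that("mask_region removes exactly the SNPs inside the closed interval", {
  gm <- panmictic_gm()
  expect_identical(mask_region(gm, c(2e7, 3e7)), gm)  # beyond the sequence
  iv <- c(4e6, 6e6)
  masked <- mask_region(gm, iv)
  expect_identical(sum(masked$positions_bp >= iv[1] &
                         masked$positions_bp <= iv[2]), 0L)
  removed <- n_snps(gm) - n_snps(masked)
  expect_identical(removed,
                   sum(gm$positions_bp >= iv[1] & gm$positions_bp <= iv[2]))
  # uniform SNP positions: ~20% of a 10-Mb genome masked by a 2-Mb interval
  expect_gt(removed / n_snps(gm), 0.12)
  expect_lt(removed / n_snps(gm), 0.28)
})

test_that("PED/MAP layout matches the PLINK text format", {
  gm <- build_genotype_matrix(tiny_cohort(), maf_min = 0)
  prefix <- file.path(tempdir(), "tiny")
  write_ped_map(gm, prefix)
  ped <- readLines(paste0(prefix, ".ped"))
  map <- readLines(paste0(prefix, ".map"))
  expect_length(ped, 2L)
  expect_length(map, 1L)
  expect_identical(lengths(strsplit(ped, " ")), rep(6L + 2L, 2))
  mf <- strsplit(map, "\t")[[1]]
  expect_identical(mf[1], "1")
  expect_equal(as.numeric(mf[3]), 5 * 1e-4 * 100)  # cM = bp * map * 100
  expect_identical(mf[4], "6")                     # 1-based position
})

test_that("PED/MAP round-trip preserves dosages, positions and labels exactly", {
  gm <- random_gm(12, 40, map_rate = 1e-8, seed = 21)
  gm$chromosome <- rep(c(1L, 2L), each = 20)[order(order(gm$chromosome,
                                                         gm$positions_bp))]
  gm <- ldnesim:::new_genotype_matrix(gm$dosages, gm$positions_bp,
                                      rep(c(1L, 2L), each = 20), 1e-8,
                                      gm$sample_ids, gm$deme_ids)
  prefix <- file.path(tempdir(), "rt")
  write_ped_map(gm, prefix)
  back <- read_ped_map(prefix)
  expect_identical(back$dosages, gm$dosages)
  expect_identical(back$positions_bp, gm$positions_bp)
  expect_identical(back$chromosome, gm$chromosome)
  expect_identical(back$sample_ids, gm$sample_ids)
  # column allele counts conserved exactly
  expect_identical(colSums(back$dosages), colSums(gm$dosages))
})

test_that("read_ped_map reports malformed input with the line number", {
  prefix <- file.path(tempdir(), "bad")
  writeLines(c("1\tsnp1\t0.1\t100"), paste0(prefix, ".map"))
  writeLines(c("FAM1 a 0 0 0 -9 A T",
               "FAM1 b 0 0 0 -9 A"), paste0(prefix, ".ped"))
  expect_error(read_ped_map(prefix), "line 2")
  writeLines(c("FAM1 a 0 0 0 -9 A G"), paste0(prefix, ".ped"))
  expect_error(read_ped_map(prefix), "allele")
})

test_that("VCF export has one record per SNP and round-trips through vcfR", {
  gm <- random_gm(8, 25, seed = 22)
  path <- file.path(tempdir(), "rt.vcf")
  write_vcf(gm, path)
  lines <- readLines(path)
  n_header <- sum(startsWith(lines, "#"))
  expect_identical(length(lines) - n_header, n_snps(gm))
  back <- read_vcf(path, map_rate = gm$map_rate)
  expect_identical(back$dosages, gm$dosages)
  expect_identical(back$positions_bp, gm$positions_bp)
  expect_identical(back$sample_ids, gm$sample_ids)
})
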