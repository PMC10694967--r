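# Sampling of individuals, construction of the biallelic dosage matrix,
# region masking, and PLINK PED/MAP + VCF text I/O.
#
# Coordinates are 0-based half-open internally; PED/MAP and VCF are
# exported 1-based.  Alleles are written A (ancestral, REF) / T (derived),
# an arbitrary but fixed encoding.

#' Sample individuals from the final generation
#'
#' Uniform sampling without replacement within each targeted deme.  The
#' same individual indices are reused across all replicate chromosomes of
#' the run, mimicking one genotyped cohort whose genome is made of the
#' pooled chromosomes.
#'
#' @param run A `sim_run` from [run_scenario()], or a bare list of
#'   `metapop_state` objects (then `genome` must be supplied).
#' @param spec A [sample_spec()]; defaults to the scenario's own.
#' @param genome A [genome_config()]; defaults to the scenario's own.
#' @param seed Optional seed for the sampling draw.
#' @return An object of class `sampled_cohort`.
#' @export
draw_sample <- function(run, spec = NULL, genome = NULL, seed = NULL) {
  if (inherits(run, "sim_run")) {
    states <- run$states
    if (is.null(spec)) spec <- run$scenario$sample
    if (is.null(genome)) genome <- run$scenario$genome
  } else {
    states <- run
  }
  stopifnot(inherits(spec, "sample_spec"), inherits(genome, "genome_config"))
  if (!length(states)) stop("no replicate states to sample from")
  if (!is.null(seed)) set.seed(seed)

  sizes <- vapply(states[[1]]$demes, function(d)
    length(d$haplotypes) %/% 2L, integer(1))
  n_demes <- length(sizes)
  counts <- integer(n_demes)
  if (spec$scheme == "single_deme") {
    fd <- spec$focal_deme
    if (fd < 1 || fd > n_demes) stop("focal_deme out of range")
    counts[fd] <- spec$total_sample
  } else {
    if (spec$total_sample %% n_demes != 0)
      stop(sprintf(
        "pooled_equal requires total_sample (%d) divisible by deme count (%d)",
        spec$total_sample, n_demes))
    counts[] <- spec$total_sample %/% n_demes
  }
  if (any(counts > sizes))
    stop(sprintf("deme %d has %d individuals, %d requested",
                 which(counts > sizes)[1], sizes[which(counts > sizes)[1]],
                 counts[which(counts > sizes)[1]]))

  idx <- lapply(seq_len(n_demes), function(d)
    if (counts[d] > 0) sort(sample.int(sizes[d], counts[d])) else integer(0))
  deme_ids <- rep(seq_len(n_demes), counts)
  sample_ids <- unlist(lapply(seq_len(n_demes), function(d)
    sprintf("d%d_i%04d", d, idx[[d]])))

  chromosomes <- lapply(states, function(st) {
    haps <- vector("list", 2L * sum(counts))
    inv <- logical(2L * sum(counts))
    k <- 0L
    for (d in seq_len(n_demes)) {
      for (i in idx[[d]]) {
        for (s in 1:2) {
          k <- k + 1L
          haps[[k]] <- st$demes[[d]]$haplotypes[[2L * (i - 1L) + s]]
          inv[k] <- st$demes[[d]]$inversion[2L * (i - 1L) + s]
        }
      }
    }
    list(haplotypes = haps, inversion = inv)
  })

  structure(list(chromosomes = chromosomes,
                 deme_ids = deme_ids,
                 sample_ids = sample_ids,
                 indices = idx,
                 n_individuals = sum(counts),
                 genome = genome),
            class = "sampled_cohort")
}

new_genotype_matrix <- function(dosages, positions_bp, chromosome, map_rate,
                                sample_ids, deme_ids) {
  ord <- order(chromosome, positions_bp)
  dimnames(dosages) <- NULL
  structure(list(dosages = dosages[, ord, drop = FALSE],
                 positions_bp = positions_bp[ord],
                 chromosome = chromosome[ord],
                 genetic_morgan = positions_bp[ord] * map_rate,
                 map_rate = map_rate,
                 sample_ids = sample_ids,
                 deme_ids = deme_ids,
                 alleles = c(ancestral = "A", derived = "T")),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix: %d individuals x %d SNPs on %d chromosome(s)>\n",
              nrow(x$dosages), ncol(x$dosages),
              length(unique(x$chromosome))))
  invisible(x)
}

#' Number of individuals / SNPs of a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Integer count.
#' @export
n_individuals <- function(gm) nrow(gm$dosages)

#' @rdname n_individuals
#' @export
n_snps <- function(gm) ncol(gm$dosages)

#' Build the biallelic dosage matrix from a sampled cohort
#'
#' Takes the union of segregating positions across the sampled haplotypes
#' of each chromosome, counts derived alleles per individual (dosage 0/1/2),
#' and removes monomorphic sites and sites below the minor-allele-frequency
#' threshold.
#'
#' @param cohort A `sampled_cohort` from [draw_sample()].
#' @param maf_min Minimum sample minor-allele frequency (default 0.05).
#' @return A `genotype_matrix` with columns sorted by (chromosome,
#'   position).
#' @export
build_genotype_matrix <- function(cohort, maf_min = 0.05) {
  stopifnot(inherits(cohort, "sampled_cohort"))
  n <- cohort$n_individuals
  per_chrom <- lapply(seq_along(cohort$chromosomes), function(ci) {
    haps <- cohort$chromosomes[[ci]]$haplotypes
    pos <- sort(unique(unlist(haps)))
    if (!length(pos)) return(NULL)
    M <- matrix(0L, n, length(pos))
    for (j in seq_along(haps)) {
      ind <- (j + 1L) %/% 2L
      ii <- match(haps[[j]], pos)
      if (length(ii)) M[ind, ii] <- M[ind, ii] + 1L
    }
    ac <- colSums(M)
    f <- ac / (2 * n)
    keep <- ac > 0L & ac < 2L * n & pmin(f, 1 - f) >= maf_min
    if (!any(keep)) return(NULL)
    list(M = M[, keep, drop = FALSE], pos = pos[keep],
         chrom = rep(ci, sum(keep)))
  })
  per_chrom <- Filter(Negate(is.null), per_chrom)
  if (!length(per_chrom))
    stop("no SNPs survive filtering; simulate a larger genome or lower maf_min")
  new_genotype_matrix(
    dosages = do.call(cbind, lapply(per_chrom, `[[`, "M")),
    positions_bp = unlist(lapply(per_chrom, `[[`, "pos")),
    chromosome = as.integer(unlist(lapply(per_chrom, `[[`, "chrom"))),
    map_rate = cohort$genome$map_rate,
    sample_ids = cohort$sample_ids,
    deme_ids = cohort$deme_ids)
}

#' Keep only segregating SNPs above a MAF threshold
#'
#' @param gm A `genotype_matrix`.
#' @param maf_min Minimum sample minor-allele frequency.
#' @return The filtered `genotype_matrix`.
#' @export
filter_segregating <- function(gm, maf_min = 0) {
  n <- n_individuals(gm)
  ac <- colSums(gm$dosages)
  f <- ac / (2 * n)
  keep <- ac > 0L & ac < 2L * n & pmin(f, 1 - f) >= maf_min
  subset_snps(gm, keep)
}

subset_snps <- function(gm, keep) {
  if (!any(keep)) stop("no SNPs left after subsetting")
  gm$dosages <- gm$dosages[, keep, drop = FALSE]
  gm$positions_bp <- gm$positions_bp[keep]
  gm$chromosome <- gm$chromosome[keep]
  gm$genetic_morgan <- gm$genetic_morgan[keep]
  gm
}

#' Subset individuals of a genotype matrix
#'
#' Monomorphic sites and sites below `maf_min` in the subset are removed.
#'
#' @param gm A `genotype_matrix`.
#' @param which Logical or integer index of individuals to keep.
#' @param maf_min MAF threshold re-applied after subsetting.
#' @return A `genotype_matrix`.
#' @export
subset_individuals <- function(gm, which, maf_min = 0.05) {
  gm$dosages <- gm$dosages[which, , drop = FALSE]
  gm$sample_ids <- gm$sample_ids[which]
  gm$deme_ids <- gm$deme_ids[which]
  filter_segregating(gm, maf_min)
}

#' Mask a genomic region
#'
#' Removes all SNPs whose position falls inside the closed bp interval on
#' every chromosome (used to discard an inversion region before LD-based
#' estimation).
#'
#' @param gm A `genotype_matrix`.
#' @param interval_bp Numeric `c(start, end)` in bp (0-based positions).
#' @return A `genotype_matrix` without the masked SNPs.
#' @export
mask_region <- function(gm, interval_bp) {
  stopifnot(length(interval_bp) == 2, interval_bp[1] <= interval_bp[2])
  keep <- gm$positions_bp < interval_bp[1] | gm$positions_bp > interval_bp[2]
  if (all(keep)) return(gm)
  subset_snps(gm, keep)
}

# ---------------------------------------------------------------------------
# PLINK PED/MAP text format

#' Write PLINK text PED/MAP files
#'
#' PED: one row per individual, six leading columns (family id, individual
#' id, father, mother, sex, phenotype -- the last four filled with 0/-9),
#' then two allele columns per SNP, unphased, A = ancestral, T = derived.
#' MAP: chromosome, SNP id, genetic position in cM, 1-based bp position.
#'
#' @param gm A `genotype_matrix`.
#' @param prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_ped_map <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")

  snp_id <- sprintf("snp%d_%d", gm$chromosome, gm$positions_bp + 1L)
  map_df <- data.frame(chrom = gm$chromosome, id = snp_id,
                       cm = formatC(gm$genetic_morgan * 100, format = "g",
                                    digits = 12),
                       bp = gm$positions_bp + 1L)
  utils::write.table(map_df, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)

  anc <- gm$alleles[["ancestral"]]
  der <- gm$alleles[["derived"]]
  geno_str <- c(paste(anc, anc), paste(anc, der), paste(der, der))
  con <- file(ped_path, "w")
  on.exit(close(con))
  fam <- sprintf("FAM%d", gm$deme_ids)
  for (i in seq_len(n_individuals(gm))) {
    row <- geno_str[gm$dosages[i, ] + 1L]
    writeLines(paste(c(fam[i], gm$sample_ids[i], "0", "0", "0", "-9", row),
                     collapse = " "), con)
  }
  invisible(c(ped = ped_path, map = map_path))
}

#' Read PLINK text PED/MAP files
#'
#' Reads files in the encoding produced by [write_ped_map()] (alleles A =
#' ancestral/reference, T = derived): the dosage is the count of derived
#' alleles.  Malformed lines raise an error naming the file and line.
#'
#' @param prefix Path prefix of the `.ped`/`.map` pair (or the path of
#'   either file).
#' @return A `genotype_matrix`.
#' @export
read_ped_map <- function(prefix) {
  prefix <- sub("\\.(ped|map)$", "", prefix)
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  for (p in c(ped_path, map_path))
    if (!file.exists(p)) stop("file not found: ", p)

  map_lines <- readLines(map_path)
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  for (i in seq_along(map_fields))
    if (length(map_fields[[i]]) != 4)
      stop(sprintf("%s: line %d: expected 4 fields, found %d",
                   map_path, i, length(map_fields[[i]])))
  chrom <- as.integer(vapply(map_fields, `[[`, "", 1))
  cm <- as.numeric(vapply(map_fields, `[[`, "", 3))
  bp <- as.integer(vapply(map_fields, `[[`, "", 4))
  if (anyNA(chrom) || anyNA(cm) || anyNA(bp))
    stop(map_path, ": non-numeric chromosome/position field")
  p <- length(bp)
  morgan <- cm / 100
  map_rate <- if (any(bp > 1)) {
    stats::median((morgan / pmax(bp - 1L, 1L))[bp > 1])
  } else 1e-8

  ped_lines <- readLines(ped_path)
  n <- length(ped_lines)
  if (!n) stop(ped_path, ": empty file")
  dos <- matrix(0L, n, p)
  sample_ids <- character(n)
  deme_ids <- integer(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * p)
      stop(sprintf("%s: line %d: expected %d fields, found %d",
                   ped_path, i, 6 + 2 * p, length(f)))
    sample_ids[i] <- f[2]
    deme_ids[i] <- if (grepl("^FAM[0-9]+$", f[1]))
      as.integer(sub("^FAM", "", f[1])) else NA_integer_
    al <- f[-(1:6)]
    bad <- !al %in% c("A", "T")
    if (any(bad))
      stop(sprintf("%s: line %d: unsupported allele code '%s'",
                   ped_path, i, al[bad][1]))
    dos[i, ] <- (al[c(TRUE, FALSE)] == "T") + (al[c(FALSE, TRUE)] == "T")
  }
  new_genotype_matrix(dosages = dos, positions_bp = bp - 1L,
                      chromosome = chrom, map_rate = map_rate,
                      sample_ids = sample_ids, deme_ids = deme_ids)
}

# ---------------------------------------------------------------------------
# VCF

#' Write an unphased VCF v4.2 file
#'
#' One contig per replicate chromosome; REF = A (ancestral), ALT = T
#' (derived); genotypes unphased (`0/1`).
#'
#' @param gm A `genotype_matrix`.
#' @param path Output file path.
#' @param contig_length_bp Optional contig length recorded in the header.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(gm, path, contig_length_bp = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(contig_length_bp))
    contig_length_bp <- max(gm$positions_bp) + 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=ldnesim-%s",
                       as.character(utils::packageVersion("ldnesim"))),
               sprintf("##contig=<ID=%d,length=%d>",
                       sort(unique(gm$chromosome)),
                       as.integer(contig_length_bp)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")),
             con)
  gt_str <- c("0/0", "0/1", "1/1")
  for (j in seq_len(n_snps(gm))) {
    writeLines(paste(c(gm$chromosome[j], gm$positions_bp[j] + 1L,
                       sprintf("snp%d_%d", gm$chromosome[j],
                               gm$positions_bp[j] + 1L),
                       "A", "T", ".", "PASS", ".", "GT",
                       gt_str[gm$dosages[, j] + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an unphased VCF file into a genotype matrix
#'
#' Uses \pkg{vcfR} to parse the file; the dosage is the ALT-allele count of
#' the GT field (biallelic sites only).
#'
#' @param path VCF file path.
#' @param map_rate Morgan per bp used to assign genetic positions.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, map_rate = 1e-8) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")  # SNPs x individuals
  if (is.null(gt) || !nrow(gt)) stop(path, ": no genotype records")
  alt_count <- function(g) {
    a <- strsplit(g, "[/|]")
    vapply(a, function(x) sum(x == "1"), integer(1))
  }
  dos <- t(apply(gt, 1, alt_count))           # SNPs x individuals
  chrom <- suppressWarnings(as.integer(vcfR::getCHROM(vcf)))
  if (anyNA(chrom)) chrom <- as.integer(factor(vcfR::getCHROM(vcf)))
  bp <- as.integer(vcfR::getPOS(vcf))
  new_genotype_matrix(dosages = t(dos), positions_bp = bp - 1L,
                      chromosome = chrom, map_rate = map_rate,
                      sample_ids = colnames(gt),
                      deme_ids = rep(NA_integer_, ncol(gt)))
}
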