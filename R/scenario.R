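# Declarative demographic scenarios: constructors, validation, YAML
# round-trip, expected-NeVk reference baselines, and desk-scale rescaling.
#
# Time convention: every event time is stated in generations before present
# (gbp); generation 0 is the sampled generation.  The simulator converts to
# forward indices internally (forward = total_generations - gbp), so an
# event at gbp t produces the new configuration at generation t before
# present.

scenario_families <- c("panmictic", "synthetic", "reciprocal_migration",
                       "source_sink", "inversion")
event_kinds <- c("split", "admix", "resize", "introduce_inversion")

stop_invalid <- function(field, msg) {
  stop(errorCondition(sprintf("invalid scenario: field '%s': %s", field, msg),
                      field = field,
                      class = c("ldnesim_validation_error", "error",
                                "condition")))
}

#' Genome configuration
#'
#' Describes the simulated sequence: its physical length, the per-bp
#' per-generation mutation rate, the uniform genetic map (Morgan per bp;
#' 1 cM/Mb corresponds to `1e-8`), and how many independent replicate
#' chromosomes are pooled into one analysis.
#'
#' @param sequence_length_bp Sequence length in base pairs.
#' @param mutation_rate Mutation probability per bp per generation.
#' @param map_rate Morgan per bp (uniform recombination map).
#' @param n_chromosomes Number of replicate chromosomes pooled per run.
#' @return An object of class `genome_config`.
#' @export
genome_config <- function(sequence_length_bp = 250e6,
                          mutation_rate = 5e-9,
                          map_rate = 1e-8,
                          n_chromosomes = 20) {
  sequence_length_bp <- as.numeric(sequence_length_bp)
  if (length(sequence_length_bp) != 1 || is.na(sequence_length_bp) ||
      sequence_length_bp <= 0)
    stop_invalid("sequence_length_bp", "must be a positive number")
  # zero rates are permitted for degenerate (mutation-free / map-length-0)
  # test configurations
  if (!is.numeric(mutation_rate) || mutation_rate < 0 || mutation_rate >= 1)
    stop_invalid("mutation_rate", "must be in [0, 1)")
  if (!is.numeric(map_rate) || map_rate < 0)
    stop_invalid("map_rate", "must be >= 0")
  n_chromosomes <- as.integer(n_chromosomes)
  if (is.na(n_chromosomes) || n_chromosomes < 1)
    stop_invalid("n_chromosomes", "must be a positive integer")
  structure(list(sequence_length_bp = sequence_length_bp,
                 mutation_rate = as.numeric(mutation_rate),
                 map_rate = as.numeric(map_rate),
                 n_chromosomes = n_chromosomes),
            class = "genome_config")
}

#' Sampling specification
#'
#' How the genotyped cohort is drawn at generation 0: all individuals from
#' one focal deme (`single_deme`) or an equal number from every deme
#' (`pooled_equal`, requiring divisibility).
#'
#' @param total_sample Total number of diploid individuals sampled.
#' @param scheme `"single_deme"` or `"pooled_equal"`.
#' @param focal_deme 1-based deme index used by `single_deme`.
#' @return An object of class `sample_spec`.
#' @export
sample_spec <- function(total_sample = 100L,
                        scheme = c("single_deme", "pooled_equal"),
                        focal_deme = 1L) {
  scheme <- match.arg(scheme)
  total_sample <- as.integer(total_sample)
  if (is.na(total_sample) || total_sample < 2)
    stop_invalid("total_sample", "must be an integer >= 2")
  structure(list(total_sample = total_sample, scheme = scheme,
                 focal_deme = as.integer(focal_deme)),
            class = "sample_spec")
}

#' Demographic event
#'
#' @param generations_before_present Non-negative integer time of the event.
#' @param kind One of `"split"`, `"admix"`, `"resize"`,
#'   `"introduce_inversion"`.
#' @param ... Kind-specific parameters: `split` takes `from` (ancestral deme
#'   index, default 1) and `sizes` (daughter deme sizes); `admix` takes
#'   `size` (admixed deme size) and optionally `sources` (deme indices,
#'   default all demes alive at the event); `resize` takes `deme` and
#'   `size`.
#' @return An object of class `demography_event`.
#' @export
demography_event <- function(generations_before_present, kind, ...) {
  gbp <- as.integer(generations_before_present)
  if (is.na(gbp) || gbp < 0)
    stop_invalid("generations_before_present", "must be a non-negative integer")
  if (!kind %in% event_kinds)
    stop_invalid("kind", paste("must be one of",
                               paste(event_kinds, collapse = ", ")))
  params <- list(...)
  if (kind == "split") {
    if (is.null(params$sizes)) stop_invalid("sizes", "split requires 'sizes'")
    params$sizes <- as.integer(params$sizes)
    params$from <- as.integer(if (is.null(params$from)) 1L else params$from)
  } else if (kind == "admix") {
    if (is.null(params$size)) stop_invalid("size", "admix requires 'size'")
    params$size <- as.integer(params$size)
    if (!is.null(params$sources)) params$sources <- as.integer(params$sources)
  } else if (kind == "resize") {
    if (is.null(params$deme) || is.null(params$size))
      stop_invalid("deme", "resize requires 'deme' and 'size'")
    params$deme <- as.integer(params$deme)
    params$size <- as.integer(params$size)
  }
  structure(list(generations_before_present = gbp, kind = kind,
                 params = params),
            class = "demography_event")
}

#' Full scenario configuration
#'
#' Bundles the demography (deme sizes, migration, events), the genome, the
#' optional chromosomal inversion, and the sampling scheme into one
#' validated object consumed by [run_scenario()].
#'
#' `deme_sizes` gives the deme configuration at the start of the
#' simulation (the burn-in population); events then reshape it forward in
#' time.  Migration is backward (an offspring draws its parental deme):
#' `reciprocal_migration` sends lineages to a uniformly chosen other deme
#' with probability `migration_rate`; `source_sink` treats deme 1 as the
#' source, which never receives migrants.  `migration_period > 1` applies
#' migration only in generations whose forward index is divisible by the
#' period (migration pulses).
#'
#' @param family Scenario family: `"panmictic"`, `"synthetic"`,
#'   `"reciprocal_migration"`, `"source_sink"` or `"inversion"`.
#' @param deme_sizes Integer vector of initial diploid deme sizes (>= 2).
#' @param migration_rate Backward migration probability per generation.
#' @param migration_period Generations between migration pulses (1 = every
#'   generation).
#' @param events List of [demography_event()] objects.
#' @param total_generations Total forward generations simulated, burn-in
#'   included.
#' @param genome A [genome_config()].
#' @param inversion `NULL`, or a list with `start_bp`, `end_bp`,
#'   `selection_coefficient` (default 0.2) and `target_mode` (`"balanced"`
#'   or `"recent_low"`).  Unless an `introduce_inversion` event is supplied,
#'   one is added automatically: at 1000 generations before present (or the
#'   earliest representable time) for `balanced`, at 50 for `recent_low`.
#' @param sample A [sample_spec()].
#' @param seed Master integer seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(family,
                            deme_sizes,
                            migration_rate = 0,
                            migration_period = 1L,
                            events = list(),
                            total_generations,
                            genome = genome_config(),
                            inversion = NULL,
                            sample = sample_spec(),
                            seed = 1L) {
  if (!is.character(family) || length(family) != 1 ||
      !family %in% scenario_families)
    stop_invalid("family", paste("must be one of",
                                 paste(scenario_families, collapse = ", ")))
  deme_sizes <- as.integer(deme_sizes)
  if (length(deme_sizes) < 1 || anyNA(deme_sizes) || any(deme_sizes < 2))
    stop_invalid("deme_sizes", "all deme sizes must be integers >= 2")
  if (!is.numeric(migration_rate) || migration_rate < 0 || migration_rate > 1)
    stop_invalid("migration_rate", "must be in [0, 1]")
  migration_period <- as.integer(migration_period)
  if (is.na(migration_period) || migration_period < 1)
    stop_invalid("migration_period", "must be a positive integer")
  total_generations <- as.integer(total_generations)
  if (is.na(total_generations) || total_generations < 1)
    stop_invalid("total_generations", "must be a positive integer")
  if (!inherits(genome, "genome_config"))
    stop_invalid("genome", "must be a genome_config object")
  if (!inherits(sample, "sample_spec"))
    stop_invalid("sample", "must be a sample_spec object")

  if (!is.null(inversion)) {
    if (is.null(inversion$start_bp) || is.null(inversion$end_bp))
      stop_invalid("inversion", "requires start_bp and end_bp")
    inversion$start_bp <- as.numeric(inversion$start_bp)
    inversion$end_bp <- as.numeric(inversion$end_bp)
    if (inversion$start_bp < 0 ||
        inversion$end_bp >= genome$sequence_length_bp ||
        inversion$start_bp >= inversion$end_bp)
      stop_invalid("inversion",
                   "interval must satisfy 0 <= start < end < sequence length")
    if (is.null(inversion$selection_coefficient))
      inversion$selection_coefficient <- 0.2
    inversion$selection_coefficient <-
      as.numeric(inversion$selection_coefficient)
    if (is.null(inversion$target_mode)) inversion$target_mode <- "balanced"
    if (!inversion$target_mode %in% c("balanced", "recent_low"))
      stop_invalid("inversion$target_mode",
                   "must be 'balanced' or 'recent_low'")
  }

  events <- lapply(events, function(e) {
    if (!inherits(e, "demography_event"))
      stop_invalid("events", "every element must be a demography_event")
    e
  })

  # auto-schedule the inversion introduction
  if (!is.null(inversion) &&
      !any(vapply(events, function(e) e$kind == "introduce_inversion",
                  logical(1)))) {
    intro <- if (inversion$target_mode == "balanced")
      min(1000L, total_generations - 1L) else
      min(50L, total_generations - 1L)
    events <- c(events, list(demography_event(intro, "introduce_inversion")))
  }

  gbp <- vapply(events, function(e) e$generations_before_present, integer(1))
  if (length(gbp) && any(gbp >= total_generations))
    stop_invalid("events",
                 "event times must be earlier than total_generations")
  split_t <- gbp[vapply(events, function(e) e$kind == "split", logical(1))]
  admix_t <- gbp[vapply(events, function(e) e$kind == "admix", logical(1))]
  if (length(split_t) && length(admix_t) && min(split_t) <= max(admix_t))
    stop_invalid("events",
                 "split time T must be strictly greater than admix time t")

  structure(list(family = family,
                 deme_sizes = deme_sizes,
                 migration_rate = as.numeric(migration_rate),
                 migration_period = migration_period,
                 events = events,
                 total_generations = total_generations,
                 genome = genome,
                 inversion = inversion,
                 sample = sample,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config: %s>\n", x$family))
  cat(sprintf("  demes: %s diploid individuals\n",
              paste(x$deme_sizes, collapse = ", ")))
  if (x$migration_rate > 0)
    cat(sprintf("  migration: m = %g every %d generation(s)\n",
                x$migration_rate, x$migration_period))
  cat(sprintf("  genome: %.3g bp, mu = %.3g, map = %.3g M/bp, %d chromosome(s)\n",
              x$genome$sequence_length_bp, x$genome$mutation_rate,
              x$genome$map_rate, x$genome$n_chromosomes))
  cat(sprintf("  total generations: %d; sample: %d (%s); seed %d\n",
              x$total_generations, x$sample$total_sample, x$sample$scheme,
              x$seed))
  if (!is.null(x$inversion))
    cat(sprintf("  inversion: [%.4g, %.4g] bp, s = %g, mode %s\n",
                x$inversion$start_bp, x$inversion$end_bp,
                x$inversion$selection_coefficient, x$inversion$target_mode))
  for (e in x$events)
    cat(sprintf("  event at %d gbp: %s\n", e$generations_before_present,
                e$kind))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Expected-NeVk baselines

# Replays the demographic events forward and returns the deme-size
# configuration for every epoch between events.
deme_size_epochs <- function(scenario) {
  evs <- Filter(function(e) e$kind %in% c("split", "admix", "resize"),
                scenario$events)
  ord <- order(vapply(evs, function(e) e$generations_before_present,
                      integer(1)), decreasing = TRUE)
  evs <- evs[ord]
  cur <- scenario$deme_sizes
  hi <- scenario$total_generations
  out <- list()
  for (e in evs) {
    t_ev <- e$generations_before_present
    if (t_ev + 1L <= hi)
      out[[length(out) + 1L]] <- list(t_min = t_ev + 1L, t_max = hi,
                                      sizes = cur)
    if (e$kind == "split") {
      from <- e$params$from
      cur <- append(cur[-from], e$params$sizes, after = from - 1L)
    } else if (e$kind == "admix") {
      sources <- if (is.null(e$params$sources)) seq_along(cur) else
        e$params$sources
      cur <- c(e$params$size, cur[-sources])
    } else if (e$kind == "resize") {
      cur[e$params$deme] <- e$params$size
    }
    hi <- t_ev
  }
  out[[length(out) + 1L]] <- list(t_min = 0L, t_max = hi, sizes = cur)
  out
}

#' Expected NeVk reference trajectory
#'
#' For a panmictic Wright-Fisher deme, the effective size defined from the
#' variance of progeny number (NeVk) equals its diploid census size N.  When
#' several demes are contemporaneous, the "all demes" reference is the sum
#' of their sizes; the "focal" line is the size of one deme (deme 1).  The
#' trajectory is piecewise constant between demographic events.
#'
#' @param scenario A [scenario_config()].
#' @return An object of class `nevk_reference`: a data frame with one row
#'   per epoch and columns `t_min`, `t_max` (generations before present,
#'   inclusive), `n_demes`, `total` and `focal`.
#' @export
expected_nevk <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  ep <- deme_size_epochs(scenario)
  out <- data.frame(
    t_min = vapply(ep, function(x) x$t_min, integer(1)),
    t_max = vapply(ep, function(x) x$t_max, integer(1)),
    n_demes = vapply(ep, function(x) length(x$sizes), integer(1)),
    total = vapply(ep, function(x) as.numeric(sum(x$sizes)), numeric(1)),
    focal = vapply(ep, function(x) as.numeric(x$sizes[1]), numeric(1)))
  out <- out[order(out$t_min), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nevk_reference", "data.frame")
  out
}

#' Look up the expected NeVk at given times
#'
#' @param ref An `nevk_reference` from [expected_nevk()].
#' @param t Vector of generations before present.
#' @param line `"total"` (sum of contemporaneous demes) or `"focal"` (one
#'   deme).
#' @return Numeric vector of expected NeVk values.
#' @export
nevk_at <- function(ref, t, line = c("total", "focal")) {
  line <- match.arg(line)
  vapply(t, function(ti) {
    row <- which(ref$t_min <= ti & ref$t_max >= ti)
    if (!length(row)) return(NA_real_)
    ref[[line]][row[1]]
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Desk-scale rescaling

#' Rescale a scenario to desk scale
#'
#' Divides all deme sizes by `factor` and multiplies the mutation rate, the
#' map rate and the migration rate by `factor`, while dividing event times,
#' the migration period and the total run length by `factor` (rounded).
#' This preserves the compound parameters N*mu (theta/4 per site), N*c and
#' N*m, and event times measured in units of N generations, so the rescaled
#' scenario exhibits the same population-genetic regime at a fraction of the
#' computational cost.  The input object is not modified.
#'
#' @param scenario A [scenario_config()].
#' @param factor Rescaling factor >= 1.
#' @return A new `scenario_config`.
#' @export
rescale_scenario <- function(scenario, factor) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (!is.numeric(factor) || length(factor) != 1 || factor < 1)
    stop_invalid("factor", "must be a single number >= 1")
  if (factor == 1) return(scenario)
  sizes <- as.integer(round(scenario$deme_sizes / factor))
  if (any(sizes < 2))
    stop_invalid("factor", "rescaled deme sizes would fall below 2")
  m <- scenario$migration_rate * factor
  if (m > 1)
    stop_invalid("factor", "rescaled migration rate would exceed 1")
  genome <- scenario$genome
  genome$mutation_rate <- genome$mutation_rate * factor
  genome$map_rate <- genome$map_rate * factor
  if (genome$mutation_rate >= 1)
    stop_invalid("factor", "rescaled mutation rate would reach 1")
  events <- lapply(scenario$events, function(e) {
    e$generations_before_present <-
      as.integer(round(e$generations_before_present / factor))
    if (!is.null(e$params[["sizes"]])) {
      e$params$sizes <- as.integer(round(e$params[["sizes"]] / factor))
      if (any(e$params$sizes < 2))
        stop_invalid("factor", "rescaled event deme sizes would fall below 2")
    }
    if (!is.null(e$params[["size"]])) {
      e$params$size <- as.integer(round(e$params[["size"]] / factor))
      if (e$params$size < 2)
        stop_invalid("factor", "rescaled event deme sizes would fall below 2")
    }
    e
  })
  out <- scenario
  out$deme_sizes <- sizes
  out$migration_rate <- m
  out$migration_period <- max(1L,
    as.integer(round(scenario$migration_period / factor)))
  out$genome <- genome
  out$events <- events
  out$total_generations <-
    max(1L, as.integer(round(scenario$total_generations / factor)))
  out
}

# ---------------------------------------------------------------------------
# YAML round-trip

#' Serialize a scenario to YAML
#'
#' @param scenario A [scenario_config()].
#' @return A single YAML string; `parse_scenario()` of the result
#'   reconstructs an identical object.
#' @export
serialize_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  x <- list(
    family = scenario$family,
    deme_sizes = as.list(scenario$deme_sizes),
    migration_rate = scenario$migration_rate,
    migration_period = scenario$migration_period,
    total_generations = scenario$total_generations,
    seed = scenario$seed,
    genome = list(
      sequence_length_bp = scenario$genome$sequence_length_bp,
      mutation_rate = scenario$genome$mutation_rate,
      map_rate = scenario$genome$map_rate,
      n_chromosomes = scenario$genome$n_chromosomes),
    sample = list(
      total_sample = scenario$sample$total_sample,
      scheme = scenario$sample$scheme,
      focal_deme = scenario$sample$focal_deme),
    events = lapply(scenario$events, function(e) {
      p <- e$params
      p <- lapply(p, function(v) if (length(v) > 1) as.list(v) else v)
      c(list(generations_before_present = e$generations_before_present,
             kind = e$kind), p)
    }))
  if (!is.null(scenario$inversion))
    x$inversion <- list(
      start_bp = scenario$inversion$start_bp,
      end_bp = scenario$inversion$end_bp,
      selection_coefficient = scenario$inversion$selection_coefficient,
      target_mode = scenario$inversion$target_mode)
  yaml::as.yaml(x, precision = 15)
}

#' Parse a scenario from YAML
#'
#' @param config_text A YAML string, or the path of a YAML file.
#' @return A validated [scenario_config()].
#' @export
parse_scenario <- function(config_text) {
  looks_like_path <- length(config_text) == 1 && !grepl("\n", config_text) &&
    grepl("[/\\\\]|\\.ya?ml$", config_text)
  if (looks_like_path && !file.exists(config_text))
    stop("scenario file not found: ", config_text)
  if (looks_like_path) {
    x <- yaml::read_yaml(config_text)
  } else {
    x <- yaml::yaml.load(paste(config_text, collapse = "\n"))
  }
  if (!is.list(x)) stop_invalid("(document)", "not a YAML mapping")
  req <- c("family", "deme_sizes", "total_generations")
  for (f in req) if (is.null(x[[f]])) stop_invalid(f, "missing required field")
  genome <- if (is.null(x$genome)) genome_config() else
    do.call(genome_config, x$genome)
  smp <- if (is.null(x$sample)) sample_spec() else do.call(sample_spec, x$sample)
  events <- lapply(x$events %||% list(), function(e) {
    if (is.null(e$generations_before_present) || is.null(e$kind))
      stop_invalid("events", "each event needs generations_before_present and kind")
    args <- e
    args$generations_before_present <- NULL
    args$kind <- NULL
    args <- lapply(args, function(v) if (is.list(v)) unlist(v) else v)
    do.call(demography_event,
            c(list(e$generations_before_present, e$kind), args))
  })
  scenario_config(
    family = x$family,
    deme_sizes = unlist(x$deme_sizes),
    migration_rate = x$migration_rate %||% 0,
    migration_period = x$migration_period %||% 1L,
    events = events,
    total_generations = x$total_generations,
    genome = genome,
    inversion = x$inversion,
    sample = smp,
    seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
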