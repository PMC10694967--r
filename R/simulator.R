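# R surface of the Wright-Fisher engine: single operations (fitness,
# meiosis, parental-deme choice), one-step state advancement, and the full
# multi-chromosome scenario runner.

#' Frequency-dependent fitness of the inversion
#'
#' Relative fitness of inversion carriers when the inversion segregates at
#' frequency `q`: `w(q) = 1 - (q - 0.5) * 0.2`.  The inversion is
#' advantageous below frequency 0.5 and deleterious above it, which holds
#' it near a balanced polymorphism.
#'
#' @param q Inversion frequency, in `[0, 1]` (vectorized).
#' @param selection_coefficient Strength of the frequency dependence.
#' @return Fitness multiplier applied to inversion-carrying individuals.
#' @export
inversion_fitness <- function(q, selection_coefficient = 0.2) {
  if (!is.numeric(q) || anyNA(q) || any(q < 0) || any(q > 1))
    stop("q must be a frequency in [0, 1]")
  1 - (q - 0.5) * selection_coefficient
}

#' Simulate one meiosis
#'
#' Draws a Poisson number of crossovers (mean = map length in Morgans) at
#' uniform positions, discards crossovers inside the inversion interval if
#' the parent is heterozygous for the inversion, recombines the two
#' parental haplotypes, and adds Poisson(`L * mu`) new mutations at uniform
#' positions (collisions resampled).  The gamete carries the inversion flag
#' of the haplotype that contributed the midpoint of the inversion
#' interval.
#'
#' @param parent A list with `haplotypes` (list of two sorted integer
#'   position vectors) and `inversion` (logical length 2).
#' @param genome A [genome_config()].
#' @param inversion_interval `NULL`, or `c(start_bp, end_bp)`.
#' @return A list with `mutations`, `carries_inversion` and the realized
#'   `crossovers` positions.
#' @export
make_gamete <- function(parent, genome, inversion_interval = NULL) {
  stopifnot(inherits(genome, "genome_config"))
  inv_active <- !is.null(inversion_interval)
  iv <- if (inv_active) as.numeric(inversion_interval) else c(0, 0)
  inv_flags <- if (is.null(parent$inversion)) c(FALSE, FALSE) else
    as.logical(parent$inversion)
  cpp_make_gamete(as.integer(parent$haplotypes[[1]]), inv_flags[1],
                  as.integer(parent$haplotypes[[2]]), inv_flags[2],
                  genome$sequence_length_bp, genome$map_rate,
                  genome$mutation_rate,
                  inv_active, iv[1], iv[2])
}

#' Choose the parental deme of an offspring (backward migration)
#'
#' With probability `m` the parents come from another deme: uniform among
#' the other demes under the reciprocal/island model, or from the source
#' (deme 1) under the source-sink model, in which the source itself never
#' receives migrants.  Migration applies only in generations whose forward
#' index is divisible by `migration_period`.
#'
#' @param deme_id 1-based focal deme index of the offspring.
#' @param scenario A [scenario_config()].
#' @param generation Forward generation index being produced.
#' @return 1-based parental deme index.
#' @export
choose_parent_deme <- function(deme_id, scenario, generation = 1L) {
  stopifnot(inherits(scenario, "scenario_config"))
  n <- length(scenario$deme_sizes)
  model <- migration_model_code(scenario)
  active <- model > 0 && scenario$migration_rate > 0 &&
    (scenario$migration_period <= 1L ||
       generation %% scenario$migration_period == 0L)
  cpp_choose_parent_deme(deme_id - 1L, n, model, scenario$migration_rate,
                         active) + 1L
}

migration_model_code <- function(scenario) {
  if (scenario$family == "source_sink") return(2L)
  if (scenario$migration_rate > 0) return(1L)
  0L
}

# ---------------------------------------------------------------------------
# Metapopulation state

#' Construct a metapopulation state
#'
#' @param demes A list of demes; each deme is a list with `haplotypes`
#'   (list of sorted integer position vectors, two consecutive entries per
#'   individual) and optionally `inversion` (logical, one flag per
#'   haplotype).
#' @param generation Forward generation index the state represents.
#' @return An object of class `metapop_state`.
#' @export
metapop_state <- function(demes, generation = 0L) {
  demes <- lapply(demes, function(d) {
    if (!is.list(d) || is.null(d$haplotypes))
      stop("each deme needs a 'haplotypes' list")
    n2 <- length(d$haplotypes)
    if (n2 %% 2 != 0) stop("haplotype count must be even (diploids)")
    if (is.null(d$inversion)) d$inversion <- rep(FALSE, n2)
    d$haplotypes <- lapply(d$haplotypes, function(h) as.integer(sort(h)))
    d[c("haplotypes", "inversion")]
  })
  q <- vapply(demes, function(d) mean(d$inversion), numeric(1))
  structure(list(generation = as.integer(generation), demes = demes,
                 inversion_frequency = q),
            class = "metapop_state")
}

#' @export
print.metapop_state <- function(x, ...) {
  sizes <- vapply(x$demes, function(d) length(d$haplotypes) / 2, numeric(1))
  nmut <- sum(vapply(x$demes, function(d)
    sum(lengths(d$haplotypes)), numeric(1)))
  cat(sprintf("<metapop_state: generation %d, demes [%s], %d mutation copies>\n",
              x$generation, paste(sizes, collapse = ", "), nmut))
  invisible(x)
}

#' Per-deme inversion frequency of a state
#' @param state A `metapop_state`.
#' @return Numeric vector of inversion frequencies q, one per deme.
#' @export
inversion_frequency <- function(state) {
  vapply(state$demes, function(d) mean(d$inversion), numeric(1))
}

as_metapop_state <- function(raw) {
  structure(list(generation = as.integer(raw$generation),
                 demes = raw$demes,
                 inversion_frequency = raw$inversion_frequency),
            class = "metapop_state")
}

# ---------------------------------------------------------------------------
# Plan construction (scenario -> C++ parameter list)

build_sim_plan <- function(scenario) {
  G <- scenario$total_generations
  evs <- scenario$events
  fwd <- vapply(evs, function(e) G - e$generations_before_present, integer(1))
  ord <- order(fwd)
  evs <- evs[ord]
  fwd <- fwd[ord]

  # replay to resolve default admixture sources (all demes alive)
  n_demes <- length(scenario$deme_sizes)
  enc <- vector("list", length(evs))
  for (i in seq_along(evs)) {
    e <- evs[[i]]
    if (e$kind == "resize") {
      enc[[i]] <- list(gen = fwd[i], kind = 0L,
                       params = c(e$params$deme - 1L, e$params$size))
    } else if (e$kind == "split") {
      enc[[i]] <- list(gen = fwd[i], kind = 1L,
                       params = c(e$params$from - 1L, e$params$sizes))
      n_demes <- n_demes + length(e$params$sizes) - 1L
    } else if (e$kind == "admix") {
      sources <- if (is.null(e$params$sources)) seq_len(n_demes) else
        e$params$sources
      enc[[i]] <- list(gen = fwd[i], kind = 2L,
                       params = c(e$params$size, sources - 1L))
      n_demes <- 1L
    } else if (e$kind == "introduce_inversion") {
      enc[[i]] <- list(gen = fwd[i], kind = 3L, params = integer(0))
    }
  }

  inv <- scenario$inversion
  list(sequence_length_bp = scenario$genome$sequence_length_bp,
       mutation_rate = scenario$genome$mutation_rate,
       map_rate = scenario$genome$map_rate,
       migration_model = migration_model_code(scenario),
       migration_rate = scenario$migration_rate,
       migration_period = scenario$migration_period,
       inversion_active = !is.null(inv),
       inversion_start = if (is.null(inv)) 0 else inv$start_bp,
       inversion_end = if (is.null(inv)) 0 else inv$end_bp,
       inversion_sel = if (is.null(inv)) 0 else inv$selection_coefficient,
       # pruning bounds memory under recurrent mutation; with mu = 0 it
       # would only erase standing fixed variants an observer may track
       prune_every = if (scenario$genome$mutation_rate > 0) 64L else 0L,
       events = enc,
       init_deme_sizes = scenario$deme_sizes,
       total_generations = G)
}

#' Advance a metapopulation state
#'
#' Produces the next generation(s): each offspring picks a parental deme
#' (backward migration), then two distinct parents within it with
#' probability proportional to fitness (inversion carriers are weighted by
#' [inversion_fitness()] at the deme's current inversion frequency), and
#' receives one recombinant gamete from each.  Demographic events scheduled
#' at the generations passed through are applied.
#'
#' @param state A [metapop_state()] consistent with `scenario` at its
#'   forward generation index.
#' @param scenario A [scenario_config()].
#' @param n_generations Number of generations to advance.
#' @return The advanced `metapop_state`.
#' @export
advance_generation <- function(state, scenario, n_generations = 1L) {
  stopifnot(inherits(state, "metapop_state"),
            inherits(scenario, "scenario_config"))
  plan <- build_sim_plan(scenario)
  as_metapop_state(cpp_advance(unclass(state), plan,
                               as.integer(n_generations)))
}

#' Run a full scenario
#'
#' Simulates `n_chromosomes` independent replicate chromosomes of the
#' scenario (burn-in included) and returns their final states at
#' generation 0.  Chromosome seeds are drawn from the master seed with
#' `sample.int` so replicates are reproducible and order-independent; if a
#' scheduled inversion is lost before the end of a replicate (or, in
#' balanced mode, lost or fixed -- either absorbing state abolishes the
#' balanced polymorphism the scenario studies), that chromosome is re-run
#' on the continuation of its own RNG stream (up to `max_retries`
#' attempts).
#'
#' @param scenario A [scenario_config()].
#' @param seed Master seed; defaults to the scenario's own.
#' @param n_chromosomes Override for `scenario$genome$n_chromosomes`.
#' @param max_retries Maximum re-runs of a chromosome whose inversion was
#'   lost.
#' @return An object of class `sim_run`: a list with `states` (one
#'   `metapop_state` per chromosome), `scenario`, `chrom_seeds`, and
#'   `attempts`.
#' @export
run_scenario <- function(scenario, seed = scenario$seed,
                         n_chromosomes = scenario$genome$n_chromosomes,
                         max_retries = 25L) {
  stopifnot(inherits(scenario, "scenario_config"))
  plan <- build_sim_plan(scenario)
  set.seed(seed)
  chrom_seeds <- sample.int(.Machine$integer.max - 1L, n_chromosomes)
  states <- vector("list", n_chromosomes)
  attempts <- integer(n_chromosomes)
  need_inversion <- !is.null(scenario$inversion)
  for (i in seq_len(n_chromosomes)) {
    set.seed(chrom_seeds[i])
    balanced <- need_inversion &&
      identical(scenario$inversion$target_mode, "balanced")
    for (a in seq_len(max_retries + 1L)) {
      st <- as_metapop_state(cpp_run_chromosome(plan))
      attempts[i] <- a
      q <- st$inversion_frequency
      ok <- !need_inversion ||
        (if (balanced) any(q > 0 & q < 1) else any(q > 0))
      if (ok) break
      if (a == max_retries + 1L)
        warning(sprintf(
          "chromosome %d: inversion lost/fixed in all %d attempts; keeping last run",
          i, a))
    }
    states[[i]] <- st
  }
  structure(list(states = states, scenario = scenario,
                 chrom_seeds = chrom_seeds, attempts = attempts),
            class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<sim_run: %s, %d chromosome(s), seed %s>\n",
              x$scenario$family, length(x$states),
              format(x$scenario$seed)))
  invisible(x)
}
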