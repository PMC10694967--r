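# Scenario presets: the study's four demographic families at full scale,
# plus desk-scale variants produced by rescale_scenario() with a smaller
# pooled genome so a laptop core can run them in minutes.

#' Names of the shipped scenario presets
#' @return Character vector of preset names accepted by [scenario_preset()].
#' @export
preset_names <- function() {
  c("panmictic", "synthetic_small", "synthetic_large",
    "two_demes", "two_demes_pulse", "ten_demes",
    "source_sink", "inversion")
}

#' Build a preset scenario
#'
#' Full-scale presets use N = 500-1000 diploids, a 250-Mb sequence at
#' 1 cM/Mb, mutation rate 5e-9 (which yields on the order of half a million
#' segregating SNPs over 20 pooled chromosomes), and 10,000 total
#' generations.  `desk = TRUE` rescales by `scale` (default 10) via
#' [rescale_scenario()] and swaps in a 10-Mb, 5-chromosome genome; the
#' inversion interval is shrunk proportionally so it still covers the
#' middle fifth of the sequence, and the run length is raised, if needed,
#' to give at least 10*N generations of burn-in before the earliest event.
#' For the balanced-inversion preset the introduction time is pinned at
#' 1000 generations before present even at desk scale: it is an
#' equilibration pre-period (time for the frequency-dependent balancing to
#' settle near q = 0.5), not part of the studied demography, so it is not
#' shortened with the event times.
#'
#' @param name One of [preset_names()].
#' @param desk Build the desk-scale variant.
#' @param scale Rescaling factor used when `desk = TRUE`.
#' @param seed Master seed stored in the scenario.
#' @param nm Migrants per deme per generation (migration presets); the
#'   migration rate is `nm / N`.
#' @param t_admix,t_split Admixture and divergence times, generations
#'   before present (synthetic presets).
#' @param n_sources Number of diverged source populations (synthetic).
#' @param variant Demographic variant for `source_sink` and `inversion`:
#'   `"constant"`, `"decline"`, `"bottleneck"` or (source_sink only)
#'   `"expansion"`.
#' @param inversion_mode `"balanced"` (frequency-dependent balancing around
#'   q = 0.5) or `"recent_low"` (introduced 50 generations before present,
#'   reaching a low frequency of about 0.15).
#' @param sample_scheme Overrides the preset's default sampling scheme.
#' @return A [scenario_config()].
#' @export
scenario_preset <- function(name,
                            desk = FALSE,
                            scale = 10,
                            seed = 1L,
                            nm = 1,
                            t_admix = 10L,
                            t_split = 1000L,
                            n_sources = 5L,
                            variant = c("constant", "decline", "bottleneck",
                                        "expansion"),
                            inversion_mode = c("balanced", "recent_low"),
                            sample_scheme = NULL) {
  variant <- match.arg(variant)
  inversion_mode <- match.arg(inversion_mode)
  name <- match.arg(name, preset_names())
  genome <- genome_config()  # 250 Mb, mu 5e-9, 1 cM/Mb, 20 chromosomes
  G <- 10000L

  sc <- switch(name,
    panmictic = scenario_config(
      family = "panmictic", deme_sizes = 1000L, total_generations = G,
      genome = genome, seed = seed),
    synthetic_small = ,
    synthetic_large = {
      n_mix <- if (name == "synthetic_small") 100L else 1000L
      scenario_config(
        family = "synthetic", deme_sizes = 1000L,
        events = list(
          demography_event(t_split, "split",
                           sizes = rep(1000L, n_sources)),
          demography_event(t_admix, "admix", size = n_mix)),
        total_generations = G, genome = genome, seed = seed)
    },
    two_demes = scenario_config(
      family = "reciprocal_migration", deme_sizes = c(1000L, 1000L),
      migration_rate = nm / 1000, total_generations = G, genome = genome,
      sample = sample_spec(scheme = "pooled_equal"), seed = seed),
    two_demes_pulse = scenario_config(
      family = "reciprocal_migration", deme_sizes = c(1000L, 1000L),
      migration_rate = 0.01, migration_period = 10L,
      total_generations = G, genome = genome,
      sample = sample_spec(scheme = "pooled_equal"), seed = seed),
    ten_demes = scenario_config(
      family = "reciprocal_migration", deme_sizes = rep(500L, 10),
      migration_rate = nm / 500, total_generations = G, genome = genome,
      sample = sample_spec(scheme = "pooled_equal"), seed = seed),
    source_sink = {
      evs <- switch(variant,
        constant = list(),
        decline = list(demography_event(10L, "resize", deme = 2L,
                                        size = 100L)),
        bottleneck = list(
          demography_event(30L, "resize", deme = 2L, size = 100L),
          demography_event(10L, "resize", deme = 2L, size = 1000L)),
        expansion = list(demography_event(10L, "resize", deme = 2L,
                                          size = 10000L)))
      scenario_config(
        family = "source_sink", deme_sizes = c(10000L, 1000L),
        migration_rate = nm / 1000, events = evs,
        total_generations = G, genome = genome,
        sample = sample_spec(scheme = "single_deme", focal_deme = 2L),
        seed = seed)
    },
    inversion = {
      evs <- switch(variant,
        constant = list(),
        decline = list(demography_event(10L, "resize", deme = 1L,
                                        size = 100L)),
        bottleneck = list(
          demography_event(30L, "resize", deme = 1L, size = 100L),
          demography_event(10L, "resize", deme = 1L, size = 1000L)),
        expansion = stop_invalid("variant",
                                 "expansion is not an inversion variant"))
      scenario_config(
        family = "inversion", deme_sizes = 1000L, events = evs,
        total_generations = G, genome = genome,
        inversion = list(start_bp = 100e6, end_bp = 150e6,
                         selection_coefficient = 0.2,
                         target_mode = inversion_mode),
        seed = seed)
    })

  if (!is.null(sample_scheme))
    sc$sample <- sample_spec(total_sample = sc$sample$total_sample,
                             scheme = sample_scheme,
                             focal_deme = sc$sample$focal_deme)

  if (desk) sc <- desk_variant(sc, scale)
  sc
}

# Rescale to desk size and swap in the small pooled genome.
desk_variant <- function(sc, scale) {
  sc <- rescale_scenario(sc, scale)
  rho <- 1e7 / sc$genome$sequence_length_bp
  sc$genome$sequence_length_bp <- 1e7
  sc$genome$n_chromosomes <- 5L
  if (!is.null(sc$inversion)) {
    sc$inversion$start_bp <- sc$inversion$start_bp * rho
    sc$inversion$end_bp <- sc$inversion$end_bp * rho
    # keep the balancing pre-period at its full 1000 generations
    for (i in seq_along(sc$events)) {
      if (sc$events[[i]]$kind == "introduce_inversion" &&
          sc$inversion$target_mode == "balanced")
        sc$events[[i]]$generations_before_present <- 1000L
    }
  }
  gbp <- vapply(sc$events, function(e) e$generations_before_present,
                integer(1))
  earliest <- if (length(gbp)) max(gbp) else 0L
  floor_g <- 10L * max(sc$deme_sizes) + earliest + 1L
  if (sc$total_generations < floor_g) sc$total_generations <- floor_g
  sc
}
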