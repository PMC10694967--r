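# Wright-Fisher engine: fitness model, meiosis, migration, drift, events.

test_that("inversion fitness follows 1 - (q - 0.5) * 0.2", {
  expect_identical(inversion_fitness(0.5), 1)
  expect_equal(inversion_fitness(0.4), 1.02)
  expect_equal(inversion_fitness(1.0), 0.9)
  expect_equal(inversion_fitness(0), 1.1)
  # monotone decreasing with slope exactly -0.2
  q <- seq(0, 1, by = 0.05)
  w <- inversion_fitness(q)
  expect_true(all(diff(w) < 0))
  expect_equal(diff(w) / diff(q), rep(-0.2, length(q) - 1))
  expect_error(inversion_fitness(-0.1), "frequency")
  expect_error(inversion_fitness(1.2), "frequency")
})

test_that("meiosis of a parent with identical haplotypes returns that haplotype when mu = 0", {
  g <- genome_config(1e6, 0, 2e-6)  # 2 Morgans: crossovers happen
  hap <- c(10L, 5000L, 99999L, 500000L)
  parent <- list(haplotypes = list(hap, hap))
  set.seed(1)
  for (i in 1:50) {
    gam <- make_gamete(parent, g)
    expect_identical(gam$mutations, hap)
  }
})

test_that("crossovers are absolutely suppressed inside the inversion in heterozygotes", {
  g <- genome_config(1e6, 0, 3e-6)  # mean 3 crossovers per meiosis
  iv <- c(250000, 750000)
  het <- list(haplotypes = list(c(1000L), c(900000L)),
              inversion = c(TRUE, FALSE))
  hom <- list(haplotypes = list(c(1000L), c(900000L)),
              inversion = c(TRUE, TRUE))
  set.seed(2)
  n_inside_het <- 0L
  n_inside_hom <- 0L
  for (i in seq_len(10000)) {
    cx <- make_gamete(het, g, inversion_interval = iv)$crossovers
    n_inside_het <- n_inside_het + sum(cx >= iv[1] & cx <= iv[2])
  }
  for (i in seq_len(2000)) {
    cx <- make_gamete(hom, g, inversion_interval = iv)$crossovers
    n_inside_hom <- n_inside_hom + sum(cx >= iv[1] & cx <= iv[2])
  }
  expect_identical(n_inside_het, 0L)     # exact suppression over 1e4 meioses
  expect_gt(n_inside_hom, 0L)            # homozygotes recombine freely
})

test_that("the gamete inherits the inversion flag of the midpoint haplotype", {
  g <- genome_config(1e6, 0, 0)  # no crossovers: midpoint hap = start hap
  parent <- list(haplotypes = list(c(5L), c(10L)),
                 inversion = c(TRUE, FALSE))
  set.seed(3)
  flags <- muts <- logical(200)
  for (i in 1:200) {
    gam <- make_gamete(parent, g, inversion_interval = c(4e5, 6e5))
    flags[i] <- gam$carries_inversion
    muts[i] <- identical(gam$mutations, c(5L))
  }
  expect_identical(flags, muts)  # inverted copy iff haplotype 1 transmitted
  expect_gt(mean(flags), 0.3)
  expect_lt(mean(flags), 0.7)
})

test_that("crossover count is Poisson with mean = map length", {
  g <- genome_config(1e6, 0, 1e-6)  # 1 Morgan
  parent <- list(haplotypes = list(integer(0), integer(0)))
  set.seed(4)
  counts <- vapply(seq_len(1e5), function(i)
    length(make_gamete(parent, g)$crossovers), numeric(1))
  se <- sqrt(1 / length(counts))  # Poisson(1): sd = 1
  expect_lt(abs(mean(counts) - 1), 3 * se)
  expect_lt(abs(stats::var(counts) - 1), 4 * se)
})

test_that("parental deme choice matches the backward migration model", {
  sc0 <- scenario_config("reciprocal_migration", deme_sizes = c(10L, 10L),
                         migration_rate = 0, total_generations = 10L)
  expect_true(all(vapply(1:100, function(i)
    choose_parent_deme(1L, sc0, i), numeric(1)) == 1L))

  sc_half <- scenario_config("reciprocal_migration",
                             deme_sizes = c(10L, 10L),
                             migration_rate = 0.5, total_generations = 10L)
  set.seed(5)
  draws <- vapply(seq_len(4e4), function(i)
    choose_parent_deme(1L, sc_half, 1L), numeric(1))
  p <- mean(draws == 2L)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / length(draws)))

  # island model, n = 10, m = 0.04: each foreign deme at 0.04/9
  sc10 <- scenario_config("reciprocal_migration", deme_sizes = rep(10L, 10),
                          migration_rate = 0.04, total_generations = 10L)
  set.seed(6)
  draws <- vapply(seq_len(2e5), function(i)
    choose_parent_deme(3L, sc10, 1L), numeric(1))
  probs <- c(0.96, rep(0.04 / 9, 9))
  obs <- c(sum(draws == 3L), tabulate(draws, 10)[-3])
  gof <- stats::chisq.test(obs, p = probs)
  expect_gt(gof$p.value, 1e-3)
  for (k in seq_along(probs)[-1]) {
    se <- sqrt(length(draws) * probs[k] * (1 - probs[k]))
    expect_lt(abs(obs[k] - length(draws) * probs[k]), 4 * se)
  }

  # source-sink: the source (deme 1) never receives migrants
  scss <- scenario_config("source_sink", deme_sizes = c(100L, 10L),
                          migration_rate = 0.3, total_generations = 10L)
  set.seed(7)
  src <- vapply(seq_len(2000), function(i)
    choose_parent_deme(1L, scss, 1L), numeric(1))
  snk <- vapply(seq_len(2000), function(i)
    choose_parent_deme(2L, scss, 1L), numeric(1))
  expect_true(all(src == 1L))
  expect_true(all(snk %in% c(1L, 2L)))
  expect_lt(abs(mean(snk == 1L) - 0.3), 3 * sqrt(0.21 / 2000))
})

test_that("with no variation operators offspring haplotypes are parental copies", {
  g <- genome_config(1e5, 0, 0)
  sc <- scenario_config("panmictic", deme_sizes = 2L,
                        total_generations = 10L, genome = g,
                        sample = sample_spec(2, "single_deme"))
  st <- metapop_state(list(list(haplotypes = list(
    c(1L, 10L), c(2L, 20L), c(3L, 30L), c(4L, 40L)))))
  set.seed(8)
  nxt <- advance_generation(st, sc)
  parental <- st$demes[[1]]$haplotypes
  for (h in nxt$demes[[1]]$haplotypes)
    expect_true(any(vapply(parental, identical, logical(1), y = h)))
})

test_that("pure-drift fixation probability equals the starting frequency", {
  N <- 20L
  p0 <- 0.3
  g <- genome_config(1e5, 0, 0)
  sc <- scenario_config("panmictic", deme_sizes = N,
                        total_generations = 100000L, genome = g,
                        sample = sample_spec(5, "single_deme"))
  k0 <- as.integer(round(p0 * 2 * N))
  haps <- c(replicate(k0, c(100L), simplify = FALSE),
            replicate(2L * N - k0, integer(0), simplify = FALSE))
  base <- metapop_state(list(list(haplotypes = haps)))
  set.seed(9)
  n_rep <- 2000L
  fixed <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    st <- base
    repeat {
      st <- advance_generation(st, sc, n_generations = 25L)
      cnt <- sum(vapply(st$demes[[1]]$haplotypes, length, integer(1)))
      if (cnt == 0L) { fixed[r] <- FALSE; break }
      if (cnt == 2L * N) { fixed[r] <- TRUE; break }
    }
  }
  se <- sqrt(p0 * (1 - p0) / n_rep)
  expect_lt(abs(mean(fixed) - p0), 3 * se)
})

test_that("inversion frequency change opposes (q - 0.5) under the balancing model", {
  N <- 60L
  g <- genome_config(1e6, 0, 0)
  sc <- scenario_config("inversion", deme_sizes = N,
                        total_generations = 100000L, genome = g,
                        inversion = list(start_bp = 2e5, end_bp = 8e5),
                        sample = sample_spec(10, "single_deme"))
  set.seed(10)
  for (q0 in c(0.2, 0.35, 0.65, 0.8)) {
    k0 <- as.integer(round(q0 * 2 * N))
    st <- metapop_state(list(list(
      haplotypes = replicate(2L * N, integer(0), simplify = FALSE),
      inversion = c(rep(TRUE, k0), rep(FALSE, 2L * N - k0)))))
    dq <- vapply(seq_len(2600), function(i)
      inversion_frequency(advance_generation(st, sc))[1] - q0, numeric(1))
    tt <- stats::t.test(dq, alternative = if (q0 < 0.5) "greater" else "less")
    expect_lt(tt$p.value, 1e-4)
  }
})

test_that("admixture draws parental demes uniformly over the sources", {
  # one admix generation over five demes: offspring parental-deme counts
  # uniform (multinomial test)
  nd <- 5L
  N <- 12L
  g <- genome_config(1e5, 0, 0)
  sc <- scenario_config("synthetic", deme_sizes = rep(N, nd),
                        events = list(demography_event(
                          0L, "admix", size = 4000L)),
                        total_generations = 1L, genome = g,
                        sample = sample_spec(10, "single_deme"))
  # tag deme d with a private variant at position d
  demes <- lapply(seq_len(nd), function(d)
    list(haplotypes = replicate(2L * N, c(d), simplify = FALSE)))
  st <- metapop_state(demes)
  set.seed(11)
  nxt <- advance_generation(st, sc)
  expect_length(nxt$demes, 1L)
  # each offspring haplotype carries its parental deme's tag
  tags <- unlist(nxt$demes[[1]]$haplotypes)
  expect_length(tags, 2L * 4000L)
  gof <- stats::chisq.test(tabulate(tags, nd))
  expect_gt(gof$p.value, 1e-3)
})

test_that("deme trajectories are independent when m = 0", {
  g <- genome_config(1e5, 1e-6, 1e-7)
  sc <- scenario_config("reciprocal_migration", deme_sizes = c(40L, 40L),
                        migration_rate = 0, total_generations = 100000L,
                        genome = g, sample = sample_spec(20, "pooled_equal"))
  set.seed(12)
  st <- metapop_state(lapply(1:2, function(d)
    list(haplotypes = replicate(80L, integer(0), simplify = FALSE))))
  st <- advance_generation(st, sc, 400L)
  # track, per deme, the frequency of the variant nearest 0.5 in that deme
  track_site <- function(deme) {
    pos <- sort(unique(unlist(deme$haplotypes)))
    cnt <- tabulate(match(unlist(deme$haplotypes), pos), length(pos))
    pos[which.min(abs(cnt / length(deme$haplotypes) - 0.5))]
  }
  sites <- vapply(st$demes, track_site, integer(1))
  freq <- function(state) vapply(1:2, function(d)
    mean(vapply(state$demes[[d]]$haplotypes, function(h)
      sites[d] %in% h, logical(1))), numeric(1))
  n_steps <- 150L
  fmat <- matrix(NA_real_, n_steps + 1L, 2L)
  fmat[1, ] <- freq(st)
  for (i in seq_len(n_steps)) {
    st <- advance_generation(st, sc)
    fmat[i + 1L, ] <- freq(st)
  }
  inc <- diff(fmat)
  ok <- stats::sd(inc[, 1]) > 0 && stats::sd(inc[, 2]) > 0
  expect_true(ok)
  expect_lt(abs(stats::cor(inc[, 1], inc[, 2])), 0.25)  # ~3 SE at n = 150
})

test_that("run_scenario is deterministic given the master seed", {
  sc <- scenario_config("panmictic", deme_sizes = 20L,
                        total_generations = 300L,
                        genome = genome_config(1e5, 1e-6, 1e-7, 2),
                        sample = sample_spec(10, "single_deme"), seed = 77L)
  r1 <- run_scenario(sc)
  r2 <- run_scenario(sc)
  expect_identical(lapply(r1$states, `[[`, "demes"),
                   lapply(r2$states, `[[`, "demes"))
  # different seeds give different mutation sets
  r3 <- run_scenario(sc, seed = 78L)
  expect_false(identical(lapply(r1$states, `[[`, "demes"),
                         lapply(r3$states, `[[`, "demes")))
})
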