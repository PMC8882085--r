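# Generative model: pools, cleavage, RT bias, droplet partitioning.

test_that("simulate_pool draws binomial molecule counts, reproducibly", {
  design <- fixture_design()
  cfg <- sim_config(seed = 3, total_copies = 1e6,
                    induction_profile = fixture_profile(f_minus = 0.75))
  pool <- simulate_pool(cfg, design, "Met_minus", 0)
  expect_equal(pool$n_full_length + pool$n_terminated, 1e6)
  # binomial oracle: within 3 SD of n * f
  sd3 <- 3 * sqrt(1e6 * 0.75 * 0.25)
  expect_lt(abs(pool$n_terminated - 750000), sd3)
  # extremes
  cfg0 <- sim_config(seed = 3, induction_profile = fixture_profile(f_minus = 0))
  expect_equal(simulate_pool(cfg0, design, "Met_minus", 0)$n_terminated, 0)
  cfg1 <- sim_config(seed = 3, induction_profile = fixture_profile(f_minus = 1))
  expect_equal(simulate_pool(cfg1, design, "Met_minus", 0)$n_full_length, 0)
  # reproducible at fixed seed
  expect_identical(simulate_pool(cfg, design, "Met_minus", 0),
                   simulate_pool(cfg, design, "Met_minus", 0))
  # missing profile entry
  expect_error(simulate_pool(cfg, design, "Met_minus", 7),
               class = "pttq_config_error")
})

test_that("cleave_pool conserves molecules and respects e = 0, 1, 0.97", {
  design <- fixture_design()
  cfg <- sim_config(seed = 4, total_copies = 1e5,
                    induction_profile = fixture_profile(f_minus = 0))
  pool <- simulate_pool(cfg, design, "Met_minus", 0) # 1e5 full-length
  sp <- function(p, s) p$species$count[p$species$species == s]

  none <- cleave_pool(pool, design, e = 0, seed = 1)
  expect_equal(sp(none, "full_length"), 1e5)
  expect_equal(sp(none, "fragment_5p"), 0)

  all_cut <- cleave_pool(pool, design, e = 1, seed = 1)
  expect_equal(sp(all_cut, "full_length"), 0)
  expect_equal(sp(all_cut, "fragment_5p"), 1e5)
  expect_equal(sp(all_cut, "fragment_5p"), sp(all_cut, "fragment_3p"))

  part <- cleave_pool(pool, design, e = 0.97, seed = 1)
  # binomial oracle on survivors: 3 SD around 3000
  expect_lt(abs(sp(part, "full_length") - 3000), 3 * sqrt(1e5 * 0.97 * 0.03))
  # conservation: intact + 5' fragments = original full-length count
  expect_equal(sp(part, "full_length") + sp(part, "fragment_5p"), 1e5)
})

test_that("expected cDNA copies follow the 3'-distance law", {
  rho <- 0.01
  mol <- data.frame(species = "m", start = 1, end = 2000, count = 100)
  # sigma = 1: equal 3'-distances get equal coverage
  near_a <- expected_amplicon_copies(mol, c(100, 180), rho, 1)
  near_b <- expected_amplicon_copies(mol, c(1700, 1780), rho, 1)
  expect_equal(three_prime_distance(c(100, 180), 2000) /
                 three_prime_distance(c(1700, 1780), 2000), 1821 / 221)
  expect_equal(near_a / near_b, 1821 / 221) # proportional to 3'-distance
  # closed-form rho * d proportionality: distances 1000 vs 200 => ratio 5
  a5 <- expected_amplicon_copies(mol, c(931, 1001), rho, 1)   # d = 1000
  a1 <- expected_amplicon_copies(mol, c(1731, 1801), rho, 1)  # d = 200
  expect_equal(a5 / a1, 5)
  expect_equal(a1, rho * 200 * 100) # rho * d per molecule
  # sigma = 0: no extension ever reaches the amplicon start
  expect_equal(expected_amplicon_copies(mol, c(100, 180), rho, 0), 0)
  # amplicon outside the molecule contributes zero, never an error
  expect_equal(expected_amplicon_copies(mol, c(1990, 2050), rho, 1), 0)
})

test_that("geometric-extension expectation matches a brute-force oracle", {
  # oracle: enumerate every priming site p = b..l and sum sigma^(p - a)
  rho <- 0.02
  brute <- function(a, b, l, sigma) rho * sum(sigma^((b:l) - a))
  mol <- data.frame(species = "m", start = 1, end = 700, count = 1)
  for (sigma in c(0.9, 0.99, 0.999)) {
    got <- expected_amplicon_copies(mol, c(101, 180), rho, sigma)
    expect_equal(got, brute(101, 180, 700, sigma), tolerance = 1e-10)
  }
  # sigma = 1 limit continuous with the geometric branch
  expect_equal(expected_amplicon_copies(mol, c(101, 180), rho, 1 - 1e-12),
               expected_amplicon_copies(mol, c(101, 180), rho, 1),
               tolerance = 1e-6)
})

test_that("reverse_transcribe draws Poisson realizations around the expectation", {
  design <- fixture_design()
  cfg <- sim_config(seed = 5, induction_profile = fixture_profile(f_minus = 0.3))
  pool <- simulate_pool(cfg, design, "Met_minus", 0)
  rt <- reverse_transcribe(pool, design, cfg$priming_rate_rho, 1, seed = 99)
  expect_named(rt$expected, c("P1", "P2", "P3"))
  # realized counts within 5 Poisson SDs of expectation (loose, deterministic seed)
  for (p in c("P1", "P2", "P3")) {
    expect_lt(abs(rt$realized[[p]] - rt$expected[[p]]), 5 * sqrt(rt$expected[[p]]))
  }
  expect_identical(rt$realized,
                   reverse_transcribe(pool, design, cfg$priming_rate_rho, 1, seed = 99)$realized)
})

test_that("uncleaved full-length pools over-represent P1 (the 5'-end bias)", {
  design <- fixture_design()
  mol <- data.frame(species = "fl", start = 1, end = design$full_length, count = 1000)
  p1 <- expected_amplicon_copies(mol, design$amplicon_P1, 0.01, 1)
  p3 <- expected_amplicon_copies(mol, design$amplicon_P3, 0.01, 1)
  expect_gt(p1, p3) # strict: P1 sits farther from the 3' end
  # after cleavage the two amplicons sit at equal 3'-distances: equal coverage
  frags <- data.frame(species = c("f5", "f3"),
                      start = c(1, design$cleavage_site + 1),
                      end = c(design$cleavage_site, design$full_length),
                      count = c(1000, 1000))
  expect_equal(expected_amplicon_copies(frags, design$amplicon_P1, 0.01, 1),
               expected_amplicon_copies(frags, design$amplicon_P3, 0.01, 1))
})

test_that("partition_droplets behaves like multinomial occupancy", {
  expect_equal(partition_droplets(0, 20000, seed = 1)$positives, 0L)
  # lambda > 20: every droplet positive, exercising the saturation path
  sat <- partition_droplets(21 * 20000, 20000, seed = 2)
  expect_equal(sat$positives, 20000L)
  # Poisson oracle at lambda = 1: mean positive fraction ~ 1 - exp(-1)
  n <- 20000
  fr <- vapply(1:200, function(s) {
    partition_droplets(n, n, seed = s)$positives / n
  }, numeric(1))
  p <- 1 - exp(-1)
  se <- sqrt(p * (1 - p) / n) / sqrt(200)
  expect_lt(abs(mean(fr) - (1 - (1 - 1 / n)^n)), 3 * se)
})

test_that("simulate_experiment is deterministic and structurally complete", {
  cfg <- sim_config(seed = 42)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$droplets, b$droplets)
  expect_identical(a$samples, b$samples)
  # 5 genes x 4 timepoints x 2 conditions x 2 arms x 3 amplicons
  expect_equal(nrow(a$droplets), 5 * 4 * 2 * 2 * 3)
  expect_equal(nrow(a$samples), 5 * 4 * 2 * 2)
  expect_false(any(a$droplets$positives > a$droplets$total))
})

test_that("parameter recovery: termination fraction at e = 1, sigma = 1", {
  # with complete cleavage and equal 3'-distances the pipeline's
  # termination-fraction estimate should cover the truth
  design <- fixture_design()
  f_true <- 0.6
  cfg <- sim_config(seed = 8, cleavage_efficiency_e = 1,
                    induction_profile = fixture_profile(f_minus = f_true))
  pool <- simulate_pool(cfg, design, "Met_minus", 0)
  wells <- simulate_measurement(pool, design, cfg, cleaved = TRUE)
  estd <- quantify_wells(wells)
  p1 <- estd$copies_per_ul[grepl("_P1$", estd$assay_id)]
  p3 <- estd$copies_per_ul[grepl("_P3$", estd$assay_id)]
  f_hat <- ptt_estimate(list(P1 = p1, P3 = p3))$termination_fraction
  # P1 weighs terminated molecules at d = 190 vs 200 for fragments: correct
  # for the small known geometry factor, then require agreement within the
  # sampling scale (percent-level at these copy numbers)
  d_term <- design$ptt_site - design$amplicon_P1[2] + 1
  d_frag <- design$cleavage_site - design$amplicon_P1[2] + 1
  f_adj <- f_hat / (d_term / d_frag + f_hat * (1 - d_term / d_frag))
  expect_equal(f_adj, f_true, tolerance = 0.05)
})
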