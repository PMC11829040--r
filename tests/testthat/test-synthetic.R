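# Seeded simulators: determinism, distributional correctness, degradation
# guard rails.

test_that("identical seeds give byte-identical outputs", {
  o <- tokenize("UGAGGCAGGAGGUUGAAUAG")
  cond <- treatment_condition(30)
  s1 <- simulate_treatment(o, cond, n = 2000, seed = 42)
  s2 <- simulate_treatment(o, cond, n = 2000, seed = 42)
  expect_identical(s1, s2)
  p1 <- simulate_peaklist(s1$species, charges = 1, ppm_sigma = 5, seed = 9)
  p2 <- simulate_peaklist(s2$species, charges = 1, ppm_sigma = 5, seed = 9)
  expect_identical(p1, p2)
  # a different seed changes the draw
  s3 <- simulate_treatment(o, cond, n = 2000, seed = 43)
  expect_false(identical(s1$conversions, s3$conversions))
  # the caller's RNG stream is not disturbed
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_treatment(o, cond, n = 10, seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("degenerate conversion probabilities behave deterministically", {
  o <- rna_oligo(c("U", "A", "U"))
  none <- simulate_treatment(o, treatment_condition(0), n = 100, seed = 1)
  expect_equal(none$species$count, 100)
  expect_equal(none$species$k, 0)
  # p = 1 on all U via a saturating concentration and long incubation
  all_conv <- simulate_treatment(o, treatment_condition(50, time_h = 6),
                                 n = 100, seed = 1)
  expect_equal(all_conv$species$count, 100)
  expect_equal(all_conv$species$k, 2)
})

test_that("per-molecule conversion counts are Binomial(r, p)", {
  # 16-U oligo at p = 0.25: mean conversions 4, chi-square GOF at alpha 0.01
  tokens <- c(rep("U", 16), rep("A", 4))
  o <- rna_oligo(sample(tokens))
  cond <- treatment_condition(27.43)  # p_U ~ 0.25 on the registry curve
  p <- reactivity("U", cond)
  expect_equal(p, 0.25, tolerance = 0.01)
  sim <- simulate_treatment(o, cond, n = 1e4, seed = 314)
  expect_equal(mean(sim$conversions), 16 * p, tolerance = 0.05)
  obs <- table(factor(sim$conversions, levels = 0:16))
  expected <- dbinom(0:16, 16, p) * 1e4
  keep <- expected >= 5  # pool sparse tails for a valid chi-square
  chi <- sum((as.numeric(obs[keep]) - expected[keep])^2 / expected[keep]) +
    (sum(obs[!keep]) - sum(expected[!keep]))^2 / max(sum(expected[!keep]), 1)
  df <- sum(keep)  # pooled tail contributes one cell, minus one constraint
  expect_gt(pchisq(chi, df), 0.01)
})

test_that("simulated peaks land on theoretical m/z and within jitter bounds", {
  o <- rna_oligo(c(rep("U", 3), "A", "C", "A"))
  cond <- treatment_condition(50, time_h = 6)  # saturating
  sim <- simulate_treatment(rna_oligo(c("U", "A", "U", "C", "U", "A")),
                            treatment_condition(30), n = 500, seed = 8)
  # zero jitter, no noise: peaks exactly at theoretical m/z
  clean <- simulate_peaklist(sim$species, charges = 1, ppm_sigma = 0,
                             noise_peaks = 0, seed = 2)
  lad <- conversion_ladder(rna_oligo(c("U", "A", "U", "C", "U", "A")),
                           condition = treatment_condition(30))
  theo <- theoretical_peaks(lad, charges = 1)
  expect_true(all(vapply(clean$mz, function(m)
    min(abs(m - theo$mz)) < 1e-9, logical(1))))
  # 5 ppm jitter: >= 95% of simulated peaks match within 10 ppm (the
  # two-sided 2-sigma normal tail is 95.45%; enough draws keep the realized
  # fraction above the 95% line)
  theo4 <- theoretical_peaks(lad, charges = 1:4)
  hits <- 0; total <- 0
  for (s in 1:625) {
    noisy <- simulate_peaklist(sim$species, charges = 1:4, ppm_sigma = 5,
                               seed = 100 + s)
    res <- match_peaks(noisy, theo4, tolerance = 10)
    hits <- hits + nrow(res$assignments)
    total <- total + nrow(noisy)
  }
  expect_gte(hits / total, 0.95)
  # a MALDI profile reproduces a 4-peak -52 ladder from a 3-U fragment
  sim3 <- simulate_treatment(o, treatment_condition(40), n = 5000, seed = 21)
  expect_equal(nrow(sim3$species), 4)
  maldi <- simulate_peaklist(sim3$species, charges = 1, kind = "average",
                             da_sigma = 0.3, seed = 4)
  expect_equal(nrow(maldi), 4)
  # pyrazolone loss spaced by ~52 on the average-mass scale (52.03),
  # blurred by the 0.3 Da MALDI jitter
  spacings <- diff(sort(maldi$mz))
  expect_equal(spacings, rep(52.03, 3), tolerance = 0.03)
})

test_that("calibration simulator reproduces the dilution design", {
  # per-class maxima: canonicals 100 pmol, Psi/D 20 pmol, other mods 5 pmol
  expect_equal(calibration_max_pmol("U"), 100)
  expect_equal(calibration_max_pmol("Psi"), 20)
  expect_equal(calibration_max_pmol("D"), 20)
  expect_equal(calibration_max_pmol("m7G"), 5)
  s <- simulate_calibration("m7G", seed = 3)
  expect_equal(nrow(s), 12)
  expect_equal(s$amount, 5 / 2^(0:11))
  # noise-free series is an exact line
  s0 <- simulate_calibration("U", noise = 0, seed = 1)
  expect_equal(s0$response, 0.02 * s0$amount, tolerance = 1e-12)
  # fitted slope within 3 sigma of truth
  fit <- fit_calibration(simulate_calibration("U", noise = 0.05, seed = 17))
  expect_lt(abs(fit$slope - 0.02), 3 * 0.05 * 0.02)
})

test_that("concentration-series simulator hits the registry anchors", {
  conc <- c(0, 10, 50)
  tab <- simulate_concentration_series(c("U", "s4U", "Psi"), conc,
                                       noise = 0, seed = 1)
  at <- function(code, cc) tab$remaining[tab$code == code & tab$concentration == cc]
  expect_equal(at("U", 0), 1)
  expect_equal(at("s4U", 0), 1)
  expect_equal(at("U", 50), 0.5, tolerance = 0.02)
  expect_lte(at("s4U", 10), 0.05)
  expect_equal(at("Psi", 50), 1)
  expect_error(simulate_concentration_series("U", c(10, 50)), "include 0")
})

test_that("degradation map follows the temperature/time stability windows", {
  f <- function(pct, T, t) degradation_flag(treatment_condition(pct, T, t))
  expect_false(f(30, 0, 24)$degraded)    # ice, 24 h: intact
  expect_false(f(30, 10, 6)$degraded)    # 10 degC, 6 h: intact
  r20 <- f(30, 20, 1)                    # 20 degC, 1 h: caution, not degraded
  expect_false(r20$degraded)
  expect_identical(r20$severity, "caution")
  expect_true(f(30, 20, 6)$degraded)     # 20 degC, 6 h: fragmenting
  expect_true(f(30, 30, 1)$degraded)     # 30 degC: degraded at any time
  r50 <- f(30, 50, 1)
  expect_true(r50$degraded)
  expect_identical(r50$severity, "severe")
  # quantitative simulation refuses degrading conditions unless overridden
  o <- rna_oligo(c("U", "A", "G"))
  expect_error(simulate_treatment(o, treatment_condition(30, 50, 1), n = 10),
               "degrades RNA")
  forced <- suppressWarnings(  # 50 degC also warns: outside calibrated range
    simulate_treatment(o, treatment_condition(30, 50, 1), n = 10,
                       seed = 1, allow_degradation = TRUE))
  expect_equal(sum(forced$species$count), 10)
})
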