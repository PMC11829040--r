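# Conversion ladders, theoretical peaks, matching and Ψ inference.

test_that("ladders of the worked tRNA fragments have the documented states", {
  # one U among non-reactive residues: exactly one converted species
  lad1 <- conversion_ladder(tokenize("[m1A]UCCACAG"))
  expect_equal(sort(lad1$delta_nominal), c(-52, 0))
  # two Us + one Psi: conversions stop at -104
  lad2 <- conversion_ladder(tokenize("A[Cm]U[Gm]AA[Y]A[Psi][m5C]UG"))
  expect_equal(sort(lad2$delta_nominal), c(-104, -52, 0))
  expect_equal(max(abs(lad2$delta_nominal)), 104)
  # three reactive Us collapse to four mass states
  lad3 <- conversion_ladder(rna_oligo(c("U", "A", "U", "C", "U")))
  expect_equal(nrow(lad3), 4)
  expect_equal(sort(lad3$delta_nominal), c(-156, -104, -52, 0))
})

test_that("ladder enumeration equals the 2^r brute-force oracle up to r = 10", {
  reg <- default_registry("ecoli")
  set.seed(23)
  reactive_pool <- c("U", "D", "s4U", "ac4C", "m7G", "m3C")
  filler <- c("A", "C", "Psi", "m5C")
  for (r in 1:10) {
    reactive <- sample(reactive_pool, r, replace = TRUE)
    tokens <- sample(c(reactive, sample(filler, 3, replace = TRUE)))
    oligo <- rna_oligo(tokens)
    cond <- treatment_condition(sample(c(10, 30, 50), 1))
    lad <- conversion_ladder(oligo, reg, cond)
    deltas <- vapply(tokens[tokens %in% reactive_pool], function(cd)
      mono_mass(reaction_rules(cd, reg)[[1]]$delta), numeric(1))
    p <- vapply(tokens[tokens %in% reactive_pool], function(cd)
      reactivity(cd, cond, reg), numeric(1))
    # the oracle must see identical per-position probabilities to collapse
    # identical-delta species the same way; same-code positions share p
    oracle <- oracle_ladder(deltas, p)
    expect_equal(nrow(lad), nrow(oracle), label = paste("r =", r))
    expect_equal(sort(round(lad$delta_mono, 6)), oracle$delta,
                 tolerance = 1e-6)
    m <- match(round(lad$delta_mono, 6), oracle$delta)
    expect_equal(lad$probability, oracle$prob[m], tolerance = 1e-9)
  }
})

test_that("ladder probabilities sum to one and masses decrease with k", {
  cond <- treatment_condition(30)
  lad <- conversion_ladder(tokenize("GUAGUCGUGGCCGAGUGGUU"),
                           condition = cond)
  expect_equal(sum(lad$probability), 1, tolerance = 1e-9)
  # single uridine-family rule: r+1 states, strictly decreasing mass in k
  expect_equal(nrow(lad), sum(tokenize("GUAGUCGUGGCCGAGUGGUU")$tokens == "U") + 1)
  expect_true(all(diff(lad$mass_mono[order(lad$k)]) < 0))
})

test_that("unknown-product positions are flagged and excluded from masses", {
  o <- rna_oligo(c("U", "mcm5s2U", "A"))
  expect_warning(lad <- conversion_ladder(o), "unknown product mass")
  expect_equal(sort(lad$delta_nominal), c(-52, 0))
  expect_equal(attr(lad, "flagged_positions"), 2L)
})

test_that("theoretical peaks cover charges and one-cation substitutions", {
  lad <- conversion_ladder(tokenize("GUAGUCGUGGCCGAGUGGUU"))
  tp <- theoretical_peaks(lad, charges = 4, adducts = c("Na", "K"))
  k0 <- tp[tp$k == 0, ]
  expect_equal(k0$mz[k0$adduct == "4H"], 1614.2203, tolerance = 2e-4)
  expect_equal(sort(k0$adduct), sort(c("4H", "3H+Na", "3H+K")))
  expect_equal(k0$mz[k0$adduct == "3H+Na"] - k0$mz[k0$adduct == "4H"],
               (22.989218 - 1.007276) / 4, tolerance = 1e-9)
  # k = 2 state lands on the printed peak within instrument rounding
  expect_equal(tp$mz[tp$k == 2 & tp$adduct == "4H"], 1588.22, tolerance = 0.02)
  # MALDI-style singly protonated average masses
  tpa <- theoretical_peaks(conversion_ladder(tokenize("UGAGGCAGGAGGUUGAAUAG")),
                           charges = 1, kind = "average")
  expect_equal(tpa$mz[tpa$k == 0], 6550, tolerance = 2)
  expect_error(theoretical_peaks(lad, charges = 4, adducts = "Cs"),
               "unsupported")
})

test_that("matching assigns the printed HRMS ladder and respects tolerance", {
  lad <- conversion_ladder(tokenize("GUAGUCGUGGCCGAGUGGUU"))
  theo <- theoretical_peaks(lad, charges = 4)
  obs <- data.frame(mz = c(1614.23, 1601.22, 1588.22), intensity = c(100, 60, 20))
  res <- match_peaks(obs, theo, tolerance = 20, unit = "ppm")
  expect_equal(nrow(res$assignments), 3)
  expect_equal(sort(res$assignments$k), c(0, 1, 2))
  expect_true(all(abs(res$assignments$ppm) <= 20))
  expect_equal(nrow(res$unassigned), 0)
  # a far-off peak stays unassigned
  res2 <- match_peaks(data.frame(mz = 52.0), theo, tolerance = 20)
  expect_equal(nrow(res2$assignments), 0)
  expect_equal(nrow(res2$unassigned), 1)
  # an exact hit has zero ppm error and rank 1
  res3 <- match_peaks(data.frame(mz = theo$mz[1]), theo, tolerance = 10)
  expect_equal(res3$assignments$ppm, 0)
  expect_equal(res3$assignments$rank, 1L)
  expect_error(match_peaks(obs, theo[0, ], tolerance = 10), "empty")
  expect_error(match_peaks(obs, theo, tolerance = 0), "positive")
})

test_that("matching is stable under peak-list permutation", {
  lad <- conversion_ladder(tokenize("GUAGUCGUGGCCGAGUGGUU"))
  theo <- theoretical_peaks(lad, charges = c(3, 4), adducts = "Na")
  set.seed(5)
  obs <- data.frame(mz = theo$mz * (1 + rnorm(nrow(theo), 0, 3e-6)))
  res1 <- match_peaks(obs, theo, tolerance = 10)
  perm <- sample(nrow(obs))
  res2 <- match_peaks(obs[perm, , drop = FALSE], theo, tolerance = 10)
  a1 <- res1$assignments[order(res1$assignments$mz), ]
  a2 <- res2$assignments[order(res2$assignments$mz), ]
  rownames(a1) <- rownames(a2) <- NULL
  expect_equal(a1, a2)
})

test_that("non-reactive site inference follows the u - kmax logic table", {
  # u = 3 (U, U, Psi), conversions reach k = 2: one site inferred Psi
  frag <- tokenize("A[Cm]U[Gm]AA[Y]A[Psi][m5C]UG")
  lad <- conversion_ladder(frag)
  theo <- theoretical_peaks(lad, charges = 1)
  obs <- data.frame(mz = theo$mz)  # all ladder states observed
  asg <- match_peaks(obs, theo, tolerance = 10)
  inf <- infer_nonreactive_sites(asg, frag)
  expect_equal(inf$u, 3)
  expect_equal(inf$kmax, 2L)
  expect_equal(inf$n_nonreactive, 1L)
  expect_false(inf$localized)  # cannot say which of the three positions
  # u = 1, kmax = 1: no Psi
  frag2 <- tokenize("[m1A]UCCACAG")
  lad2 <- conversion_ladder(frag2)
  theo2 <- theoretical_peaks(lad2, charges = 1)
  asg2 <- match_peaks(data.frame(mz = theo2$mz), theo2, tolerance = 10)
  inf2 <- infer_nonreactive_sites(asg2, frag2)
  expect_equal(inf2$n_nonreactive, 0L)
  expect_true(inf2$localized)
  # u = 2, kmax = 0 at weak conversion: two candidates, low confidence
  frag3 <- rna_oligo(c("U", "A", "U"))
  lad3 <- conversion_ladder(frag3)
  theo3 <- theoretical_peaks(lad3, charges = 1)
  asg3 <- match_peaks(data.frame(mz = theo3$mz[lad3$k == 0]), theo3,
                      tolerance = 10)
  inf3 <- infer_nonreactive_sites(asg3, frag3,
                                  condition = treatment_condition(10))
  expect_equal(inf3$n_nonreactive, 2L)
  expect_identical(inf3$confidence, "low")
  inf3b <- infer_nonreactive_sites(asg3, frag3)
  expect_identical(inf3b$confidence, "high")
})

test_that("neutral-loss annotation labels the classic nucleobase losses", {
  res <- annotate_neutral_losses(c(17.03, 43.01, 32.04, 18.01, 33.99, 132.04, 99.9))
  expect_identical(res$label,
                   c("NH3", "HNCO", "N2H4", "H2O", "H2S", "ribose", "unknown"))
  expect_true(all(abs(res$error_da[res$label != "unknown"]) <= 0.02))
})
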