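test_that("sham self-combinations score CI50 = 1 across Hill slopes", {
  for (s in c(0.5, 1, 2, 3)) {
    m <- sham_matrix(slope = s)
    f <- fit_margins(m)
    r <- ci50(m, f$fitA, f$fitB)
    expect_equal(r$ci50, 1.0, tolerance = 0.02)
    expect_equal(r$class, "additive")
    # the crossing sits at half the monotherapy IC50 on each axis
    expect_equal(r$a, r$A / 2, tolerance = 0.02)
  }
})

test_that("a uniform potency boost moves CI50 to 1/(1+boost)", {
  for (boost in c(1, 3)) {
    m <- simulate_dose_matrix(surface_spec(interaction = "boosted",
                                           boost = boost))
    f <- fit_margins(m)
    r <- ci50(m, f$fitA, f$fitB)
    # combination reaches 50% kill at a = A/(2(1+boost)) per drug
    expect_equal(r$ci50, 1 / (1 + boost), tolerance = 0.02)
  }
  m1 <- simulate_dose_matrix(surface_spec(interaction = "boosted", boost = 1))
  f1 <- fit_margins(m1)
  expect_equal(ci50(m1, f1$fitA, f1$fitB)$class, "synergy")
})

test_that("CI50 is undefined when monotherapy IC50s are censored", {
  doses <- default_doses()
  flat <- matrix(1, 7, 7)
  m <- dose_matrix("A", "B", c(0, rev(doses)), c(0, rev(doses)), flat)
  f <- fit_margins(m)
  r <- ci50(m, f$fitA, f$fitB)
  expect_equal(r$class, "undefined")
  expect_match(r$reason, "censored")
  expect_equal(classify_interaction(r), "undefined")
})

test_that("relabeling all doses by a common factor leaves CI50 unchanged", {
  m <- simulate_dose_matrix(surface_spec(interaction = "boosted", boost = 1))
  f <- fit_margins(m)
  r <- ci50(m, f$fitA, f$fitB)
  m2 <- dose_matrix(m$drugA, m$drugB, 2 * m$doses_A, 2 * m$doses_B,
                    m$viability)
  f2 <- fit_margins(m2)
  r2 <- ci50(m2, f2$fitA, f2$fitB)
  expect_equal(r2$ci50, r$ci50, tolerance = 1e-6)
})

test_that("bliss excess is zero under independence and the product under full kill", {
  pA <- full_kill(slope = 1.4, ec50 = 0.5)
  pB <- full_kill(slope = 0.7, ec50 = 3)
  m <- simulate_dose_matrix(surface_spec(drugA = pA, drugB = pB,
                                         interaction = "bliss_independent"))
  bm <- bliss_excess_map(m)
  expect_lt(max(abs(bm$excess)), 1e-12)
  expect_equal(classify_interaction(bm), "additive")

  # interior forced to zero viability: excess equals the margin product
  m0 <- m
  m0$viability[-1, -1] <- 0
  b0 <- bliss_excess_map(dose_matrix(m$drugA, m$drugB, m$doses_A, m$doses_B,
                                     m0$viability))
  VA <- m$viability[-1, 1]
  VB <- m$viability[1, -1]
  expect_equal(b0$excess, outer(VA, VB), ignore_attr = TRUE)
})

test_that("loewe excess vanishes on additive and sham surfaces", {
  pA <- full_kill(slope = 0.8, ec50 = 0.6)
  pB <- full_kill(slope = 2.2, ec50 = 2)
  m <- simulate_dose_matrix(surface_spec(drugA = pA, drugB = pB))
  f <- fit_margins(m)
  lw <- loewe_excess_map(m, f$fitA, f$fitB)
  expect_lt(max(abs(lw$excess)), 1e-3)

  sham <- sham_matrix(slope = 1.5)
  fs <- fit_margins(sham)
  expect_lt(max(abs(loewe_excess_map(sham, fs$fitA, fs$fitB)$excess)), 1e-3)
})

test_that("excess-map signs track the boosted ground truth", {
  syn <- simulate_dose_matrix(surface_spec(interaction = "boosted",
                                           boost = 2, noise_cv = 0.05,
                                           seed = 13))
  fsyn <- fit_margins(syn)
  expect_gt(loewe_excess_map(syn, fsyn$fitA, fsyn$fitB)$summary_score, 0)
  expect_gt(bliss_excess_map(syn)$summary_score, 0)

  ant <- simulate_dose_matrix(surface_spec(interaction = "boosted",
                                           boost = -0.6, noise_cv = 0.05,
                                           seed = 14))
  fant <- fit_margins(ant)
  expect_lt(loewe_excess_map(ant, fant$fitA, fant$fitB)$summary_score, 0)
  expect_lt(bliss_excess_map(ant)$summary_score, 0)
})

test_that("interaction classes follow the CI and score bands", {
  expect_equal(classify_interaction(0.5, type = "ci"), "synergy")
  expect_equal(classify_interaction(1.0, type = "ci"), "additive")
  expect_equal(classify_interaction(1.05, type = "ci"), "additive")
  expect_equal(classify_interaction(1.2, type = "ci"), "antagonism")
  expect_equal(classify_interaction(12, type = "score"), "synergy")
  expect_equal(classify_interaction(-25, type = "score"), "antagonism")
  expect_equal(classify_interaction(5, type = "score"), "additive")
  expect_equal(classify_interaction(NA_real_, type = "ci"), "undefined")
})

test_that("waterfall ranking is deterministic and order-invariant", {
  sc <- data.frame(sample = c("P1", "P2", "P1", "P3"),
                   combination = c("x", "y", "z", "x"),
                   summary_score = c(5, -3, 12, 5),
                   note = letters[1:4])
  rk <- rank_combinations(sc)
  expect_equal(rk$combination, c("z", "x", "x", "y"))
  expect_equal(rk$sample[2:3], c("P1", "P3"))  # lexicographic tiebreak
  expect_equal(rk$note, c("c", "a", "d", "b"))  # annotations pass through
  shuffled <- sc[c(3, 1, 4, 2), ]
  expect_equal(rank_combinations(shuffled), rk)
  expect_error(rank_combinations(sc[0, ]), "empty")
})
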