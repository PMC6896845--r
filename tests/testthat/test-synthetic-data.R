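test_that("mixture panel matches its closed form in the noise-free limit", {
  # pure tumor with a vimentin-null tumor population: index is exactly 1
  sp <- mixture_panel_spec(fractions = 1, replicates = 2,
                           tumor_channel_means = c(EpCAM = 800, vimentin = 0),
                           stroma_channel_means = c(EpCAM = 0, vimentin = 999),
                           noise_cv = 0)
  tb <- make_mixture_panel(sp)
  expect_equal(tb$vimentin, c(0, 0))
  expect_equal(purity_index(tb$epcam, tb$vimentin), c(1, 1))

  # f = 0.3 with equal channel gains and no cross-channel background:
  # index = f*mu / (f*mu + (1-f)*mu) = f
  sp <- mixture_panel_spec(fractions = 0.3, replicates = 1,
                           tumor_channel_means = c(EpCAM = 600, vimentin = 0),
                           stroma_channel_means = c(EpCAM = 0, vimentin = 600),
                           noise_cv = 0)
  tb <- make_mixture_panel(sp)
  expect_equal(purity_index(tb$epcam, tb$vimentin), 0.3)
})

test_that("generators are pure functions of spec and seed", {
  sp <- mixture_panel_spec(seed = 11)
  expect_identical(make_mixture_panel(sp), make_mixture_panel(sp))
  sp2 <- mixture_panel_spec(seed = 12)
  expect_false(identical(make_mixture_panel(sp), make_mixture_panel(sp2)))

  ss <- surface_spec(noise_cv = 0.1, seed = 5)
  expect_identical(simulate_dose_matrix(ss), simulate_dose_matrix(ss))

  ms <- mixed_population_spec(0.4, seed = 9)
  expect_identical(simulate_mixed_population_response(ms),
                   simulate_mixed_population_response(ms))

  # global RNG stream is left untouched
  set.seed(99); ref <- runif(1)
  set.seed(99); invisible(make_mixture_panel(sp)); after <- runif(1)
  expect_identical(ref, after)
})

test_that("replicate intensity CV converges to the specified noise CV", {
  sp <- mixture_panel_spec(fractions = 0.5, replicates = 1000,
                           noise_cv = 0.2, seed = 21)
  tb <- make_mixture_panel(sp)
  cv_hat <- sd(tb$epcam) / mean(tb$epcam)
  expect_lt(abs(cv_hat - 0.2) / 0.2, 0.2)
})

test_that("bliss surfaces equal the product of their monotherapy curves", {
  pA <- full_kill(slope = 1.5, ec50 = 0.7)
  pB <- full_kill(slope = 0.8, ec50 = 3, bottom = 0.1)
  m <- simulate_dose_matrix(surface_spec(drugA = pA, drugB = pB,
                                         interaction = "bliss_independent"))
  VA <- hill_viability(m$doses_A, pA$top, pA$bottom, pA$ec50, pA$slope)
  VB <- hill_viability(m$doses_B, pB$top, pB$bottom, pB$ec50, pB$slope)
  interior <- outer(VA, VB)[-1, -1]
  expect_equal(m$viability[-1, -1], interior, ignore_attr = TRUE)
})

test_that("loewe-additive surfaces satisfy the Loewe equation cellwise", {
  pA <- full_kill(slope = 0.9, ec50 = 0.6)
  pB <- full_kill(slope = 2.1, ec50 = 2.5)
  m <- simulate_dose_matrix(surface_spec(drugA = pA, drugB = pB))
  for (i in c(2, 4, 7)) for (j in c(2, 5, 7)) {
    v <- m$viability[i, j]
    Av <- hill_inverse(v, pA$top, pA$bottom, pA$ec50, pA$slope)
    Bv <- hill_inverse(v, pB$top, pB$bottom, pB$ec50, pB$slope)
    expect_equal(m$doses_A[i] / Av + m$doses_B[j] / Bv, 1, tolerance = 1e-4)
  }
})

test_that("sham loewe surfaces are symmetric with exact monotherapy margins", {
  m <- sham_matrix(slope = 1.3)
  expect_equal(m$viability, t(m$viability), ignore_attr = TRUE)
  p <- full_kill(1.3)
  expect_equal(m$viability[, 1],
               hill_viability(m$doses_A, p$top, p$bottom, p$ec50, p$slope),
               ignore_attr = TRUE)
  expect_equal(m$viability[1, ],
               hill_viability(m$doses_B, p$top, p$bottom, p$ec50, p$slope),
               ignore_attr = TRUE)
})

test_that("mixed-population viability has the purity-dependent kill floor", {
  # no tumor cells: flat at 1
  s0 <- mixed_population_spec(0, noise_cv = 0)
  expect_equal(simulate_mixed_population_response(s0)$viability,
               rep(1, 18))
  # pure tumor: Hill midpoint at ec50
  s1 <- mixed_population_spec(1, doses = c(4, 2, 1, 0.5, 0.25),
                              noise_cv = 0, replicates = 1)
  r1 <- simulate_mixed_population_response(s1)
  expect_equal(r1$viability[r1$dose_uM == 1], 0.5)
  # 30% purity: saturating-dose floor 0.70
  s3 <- mixed_population_spec(0.3, doses = c(1e6, 20, 5), noise_cv = 0,
                              replicates = 1)
  r3 <- simulate_mixed_population_response(s3)
  expect_equal(min(r3$viability), 0.3 * hill_viability(1e6, 1, 0, 1, 1) + 0.7,
               tolerance = 1e-6)
})

test_that("generator specs reject invalid inputs", {
  expect_error(mixture_panel_spec(fractions = numeric(0)), "non-empty")
  expect_error(mixture_panel_spec(fractions = 1.2), "\\[0, 1\\]")
  expect_error(mixture_panel_spec(noise_cv = -0.1), "noise_cv")
  expect_error(surface_spec(drugA = full_kill(ec50 = -1)), "ec50")
  expect_error(surface_spec(boost = 0.5), "boost")
  expect_error(surface_spec(doses_A = c(10, 0)), "positive")
  expect_error(mixed_population_spec(1.5), "purity")
})

test_that("simulated tables round-trip through CSV with a spec sidecar", {
  sp <- mixed_population_spec(0.5, seed = 3)
  tb <- simulate_mixed_population_response(sp)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sim_table(tb, path, sp)
  back <- read.csv(path)
  expect_equal(back$viability, tb$viability, tolerance = 1e-12)
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(sidecar$seed, 3L)
  expect_equal(sidecar$purity, 0.5)
})
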