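# Seeded synthetic-data generators emulating the chip readouts: co-culture
# mixture panels (EpCAM/vimentin), two-drug dose-response surfaces with known
# interaction ground truth, and mixed tumor/stroma viability curves.
# All generators are pure functions of (spec, seed); noise is multiplicative
# lognormal with unit mean and stated CV.

.check_hill_params <- function(p, what) {
  need <- c("top", "bottom", "ec50", "slope")
  if (!is.list(p) || !all(need %in% names(p)))
    abort("%s must be a list with top, bottom, ec50, slope", what)
  if (p$ec50 <= 0) abort("%s: ec50 must be > 0", what)
  if (p$bottom > p$top) abort("%s: bottom must be <= top", what)
  if (p$slope <= 0) abort("%s: slope must be > 0", what)
  invisible(p)
}

#' Specify a tumor/fibroblast co-culture titration panel
#'
#' Describes the calibration experiment in which carcinoma cells (EpCAM-high,
#' vimentin-low) are mixed with fibroblasts (EpCAM-low, vimentin-high) at
#' known fractions and stained for both markers. Per-spot channel intensity is
#' the fraction-weighted mean of the two population means, times lognormal
#' noise.
#'
#' @param fractions true tumor fractions in \[0, 1\] (one condition each).
#' @param replicates spots per fraction, >= 1.
#' @param tumor_channel_means,stroma_channel_means named numeric
#'   `c(EpCAM=, vimentin=)` mean RFU per population; all >= 0.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   intensity noise, >= 0.
#' @param seed integer RNG seed.
#' @return a `mixture_panel_spec` list.
#' @export
mixture_panel_spec <- function(fractions = seq(0, 0.9, by = 0.1),
                               replicates = 3,
                               tumor_channel_means = c(EpCAM = 1000,
                                                       vimentin = 50),
                               stroma_channel_means = c(EpCAM = 50,
                                                        vimentin = 1000),
                               noise_cv = 0.05, seed = 1) {
  if (length(fractions) == 0) abort("fractions must be non-empty")
  if (any(fractions < 0 | fractions > 1)) abort("fractions must be in [0, 1]")
  if (replicates < 1) abort("replicates must be >= 1")
  for (m in list(tumor_channel_means, stroma_channel_means)) {
    if (!all(c("EpCAM", "vimentin") %in% names(m)) || any(m < 0))
      abort("channel means must be named c(EpCAM=, vimentin=) and >= 0")
  }
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  structure(list(fractions = fractions, replicates = as.integer(replicates),
                 tumor_channel_means = tumor_channel_means,
                 stroma_channel_means = stroma_channel_means,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "mixture_panel_spec")
}

#' Generate a co-culture mixture panel
#'
#' One row per fraction x replicate. Noise-free expected intensity in channel
#' c is `f * mu_c(tumor) + (1 - f) * mu_c(stroma)`; with `noise_cv > 0` each
#' intensity is multiplied by an independent unit-mean lognormal factor.
#' Identical spec (including seed) gives an identical table.
#'
#' @param spec a [mixture_panel_spec()].
#' @return data.frame with columns `spot_id`, `true_fraction`, `replicate`,
#'   `epcam`, `vimentin`.
#' @export
#' @examples
#' head(make_mixture_panel(mixture_panel_spec(seed = 7)))
make_mixture_panel <- function(spec) {
  stopifnot(inherits(spec, "mixture_panel_spec"))
  f <- rep(spec$fractions, each = spec$replicates)
  rep_id <- rep(seq_len(spec$replicates), times = length(spec$fractions))
  mu_e <- f * spec$tumor_channel_means[["EpCAM"]] +
    (1 - f) * spec$stroma_channel_means[["EpCAM"]]
  mu_v <- f * spec$tumor_channel_means[["vimentin"]] +
    (1 - f) * spec$stroma_channel_means[["vimentin"]]
  with_seed(spec$seed, {
    data.frame(
      spot_id = sprintf("S%03d", seq_along(f)),
      true_fraction = f,
      replicate = rep_id,
      epcam = mu_e * lognormal_noise(length(f), spec$noise_cv),
      vimentin = mu_v * lognormal_noise(length(f), spec$noise_cv),
      stringsAsFactors = FALSE)
  })
}

#' Specify a two-drug response surface with known interaction ground truth
#'
#' @param drugA,drugB monotherapy 4PL parameter lists
#'   (`top`, `bottom`, `ec50`, `slope`).
#' @param interaction ground-truth reference: `"loewe_additive"` (implicit
#'   Loewe equation solved per cell), `"bliss_independent"` (viability
#'   product), or `"boosted"` (Loewe surface with both effective ec50s divided
#'   by `1 + boost` inside the combination region only; `boost > 0` is
#'   synergy, `boost < 0` antagonism).
#' @param boost signed potency-shift factor; must be 0 unless
#'   `interaction = "boosted"`, and > -1.
#' @param doses_A,doses_B positive concentration vectors (uM, descending);
#'   a zero-dose monotherapy margin is added automatically.
#' @param noise_cv lognormal viability noise CV, >= 0.
#' @param seed integer RNG seed.
#' @return a `surface_spec` list.
#' @export
surface_spec <- function(drugA = list(top = 1, bottom = 0, ec50 = 1,
                                      slope = 1),
                         drugB = drugA,
                         interaction = c("loewe_additive",
                                         "bliss_independent", "boosted"),
                         boost = 0,
                         doses_A = dose_ladder(20, 3, 6)$concentrations,
                         doses_B = doses_A,
                         noise_cv = 0, seed = 1) {
  interaction <- match.arg(interaction)
  .check_hill_params(drugA, "drugA")
  .check_hill_params(drugB, "drugB")
  if (any(doses_A <= 0) || any(doses_B <= 0))
    abort("doses must be strictly positive (the zero margin is implicit)")
  if (interaction != "boosted" && boost != 0)
    abort("boost applies only when interaction = 'boosted'")
  if (boost <= -1) abort("boost must be > -1")
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  structure(list(drugA = drugA, drugB = drugB, interaction = interaction,
                 boost = boost,
                 doses_A = sort(doses_A, decreasing = TRUE),
                 doses_B = sort(doses_B, decreasing = TRUE),
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "surface_spec")
}

#' Simulate a two-drug dose-response matrix
#'
#' Builds the full checkerboard including the zero-dose monotherapy margins.
#' Before noise: margins are the exact monotherapy Hill values; interior cells
#' follow the ground-truth reference in the spec (Loewe equation solved by
#' bisection, Bliss viability product, or a potency-boosted Loewe surface).
#' Lognormal noise (if any) multiplies every cell.
#'
#' @param spec a [surface_spec()].
#' @return a [dose_matrix()] (doses ascending with 0 first).
#' @export
#' @examples
#' m <- simulate_dose_matrix(surface_spec(interaction = "bliss_independent"))
#' m$viability[1, ]  # drug-B monotherapy margin
simulate_dose_matrix <- function(spec) {
  stopifnot(inherits(spec, "surface_spec"))
  dA <- c(0, sort(spec$doses_A))
  dB <- c(0, sort(spec$doses_B))
  pA <- spec$drugA
  pB <- spec$drugB
  hillA <- function(d) hill_viability(d, pA$top, pA$bottom, pA$ec50, pA$slope)
  hillB <- function(d) hill_viability(d, pB$top, pB$bottom, pB$ec50, pB$slope)
  V <- matrix(NA_real_, length(dA), length(dB))
  V[, 1] <- hillA(dA)
  V[1, ] <- hillB(dB)
  V[1, 1] <- (pA$top + pB$top) / 2
  if (spec$interaction == "boosted") {
    pA_in <- pA; pA_in$ec50 <- pA$ec50 / (1 + spec$boost)
    pB_in <- pB; pB_in$ec50 <- pB$ec50 / (1 + spec$boost)
  } else {
    pA_in <- pA; pB_in <- pB
  }
  for (i in 2:length(dA)) for (j in 2:length(dB)) {
    V[i, j] <- switch(spec$interaction,
      bliss_independent = hillA(dA[i]) * hillB(dB[j]),
      loewe_additive = loewe_viability(dA[i], dB[j], pA, pB),
      boosted = loewe_viability(dA[i], dB[j], pA_in, pB_in))
  }
  if (spec$noise_cv > 0) {
    V <- with_seed(spec$seed,
                   V * matrix(lognormal_noise(length(V), spec$noise_cv),
                              nrow(V), ncol(V)))
  }
  dose_matrix("drugA", "drugB", dA, dB, V)
}

#' Specify a mixed tumor/stroma population dose-response experiment
#'
#' Tumor cells follow a Hill curve; stromal cells do not respond (flat at
#' viability 1). Expected mixed viability before noise is
#' `purity * Hill(dose) + (1 - purity)`, so the saturating-dose viability
#' floor equals `1 - purity` for a full-kill tumor curve.
#'
#' @param purity tumor fraction in \[0, 1\].
#' @param tumor tumor 4PL parameter list (default full kill: top 1, bottom 0,
#'   ec50 1 uM, slope 1).
#' @param doses positive dose vector (uM).
#' @param noise_cv lognormal viability noise CV.
#' @param replicates wells per dose.
#' @param seed integer RNG seed.
#' @return a `mixed_population_spec` list.
#' @export
mixed_population_spec <- function(purity,
                                  tumor = list(top = 1, bottom = 0,
                                               ec50 = 1, slope = 1),
                                  doses = dose_ladder(20, 3, 6)$concentrations,
                                  noise_cv = 0.05, replicates = 3, seed = 1) {
  if (!is.numeric(purity) || length(purity) != 1 || purity < 0 || purity > 1)
    abort("purity must be a single value in [0, 1]")
  .check_hill_params(tumor, "tumor")
  if (any(doses <= 0)) abort("doses must be strictly positive")
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  if (replicates < 1) abort("replicates must be >= 1")
  structure(list(purity = purity, tumor = tumor, doses = doses,
                 noise_cv = noise_cv, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "mixed_population_spec")
}

#' Simulate viability of a mixed tumor/stroma population under treatment
#'
#' @param spec a [mixed_population_spec()].
#' @return data.frame with columns `dose_uM`, `replicate`, `viability`.
#' @export
#' @examples
#' # 30% purity: noise-free saturating-dose viability floor is 0.70
#' s <- mixed_population_spec(0.3, noise_cv = 0)
#' min(simulate_mixed_population_response(s)$viability)
simulate_mixed_population_response <- function(spec) {
  stopifnot(inherits(spec, "mixed_population_spec"))
  d <- rep(spec$doses, each = spec$replicates)
  p <- spec$tumor
  expected <- spec$purity *
    hill_viability(d, p$top, p$bottom, p$ec50, p$slope) + (1 - spec$purity)
  with_seed(spec$seed, {
    data.frame(dose_uM = d,
               replicate = rep(seq_len(spec$replicates),
                               times = length(spec$doses)),
               viability = expected * lognormal_noise(length(d),
                                                      spec$noise_cv))
  })
}

#' Write a simulated table with a JSON sidecar recording spec and seed
#'
#' @param x data.frame to write.
#' @param path CSV output path; the sidecar is written to `<path>.json`.
#' @param spec the generator spec (recorded verbatim, including its seed).
#' @return `path`, invisibly.
#' @export
write_sim_table <- function(x, path, spec) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(list(class = class(spec)[1]), unclass(spec)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
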