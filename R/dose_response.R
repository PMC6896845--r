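# Viability normalization, bounded 4PL fitting on log10 dose, absolute IC50
# with censoring, and the minimal-purity detectability simulation.

#' Normalize raw viability against plate controls
#'
#' Linear rescale so the negative-control (untreated) mean maps to 1 and the
#' positive-control (full-kill, staurosporine) mean to 0:
#' `(raw - pos) / (neg - pos)`, capped to \[0, 1.5\]. Adding a constant to
#' raw and both controls leaves the result unchanged.
#'
#' @param raw raw viability readout(s) (calcein RFU).
#' @param neg_ctrl_mean mean of negative-control spots (must exceed
#'   `pos_ctrl_mean`; otherwise the plate has failed and is rejected).
#' @param pos_ctrl_mean mean of positive-control spots.
#' @return normalized viability fraction(s) in \[0, 1.5\].
#' @export
#' @examples
#' normalize_viability(c(900, 500, 100), neg_ctrl_mean = 900,
#'                     pos_ctrl_mean = 100)
normalize_viability <- function(raw, neg_ctrl_mean, pos_ctrl_mean) {
  if (neg_ctrl_mean <= pos_ctrl_mean)
    abort(paste0("control failure: negative-control mean (%g) must exceed ",
                 "positive-control mean (%g); plate rejected"),
          neg_ctrl_mean, pos_ctrl_mean)
  pmin(pmax((raw - pos_ctrl_mean) / (neg_ctrl_mean - pos_ctrl_mean), 0), 1.5)
}

# pseudo-dose for zero-dose points: (min positive dose) / ratio^2, with the
# ladder ratio estimated from the positive doses themselves
.pseudo_zero_dose <- function(doses) {
  pos <- sort(unique(doses[doses > 0]))
  if (length(pos) >= 2) {
    ratio <- median(pos[-1] / pos[-length(pos)])
  } else ratio <- 10
  pos[1] / ratio^2
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Bounded least squares of the decreasing 4PL on log10 dose
#' (`viability = bottom + (top - bottom) / (1 + 10^(slope * (log10(d) -
#' log10(ec50))))`) via Levenberg-Marquardt ([minpack.lm::nls.lm]) with three
#' deterministic starts (ec50 at the minimum, median and maximum tested
#' dose); the lowest-RSS converged fit wins. Parameter bounds:
#' `0 <= bottom <= top <= 1.5`, slope in \[0.2, 5\], ec50 within two decades
#' of the tested range. Zero-dose points are placed at
#' `(min positive dose) / ratio^2` on the log axis. Degenerate (constant)
#' responses return a flat fit with censored IC50 rather than an error.
#'
#' @param dose dose vector (uM, >= 0; replicate rows allowed).
#' @param viability matching normalized viabilities.
#' @return a `hill_fit`: list with `top`, `bottom`, `ec50`, `slope`,
#'   `ic50_abs` (absolute IC50 within the tested range, `NA` if censored),
#'   `rss`, `converged`, `dose_range`, `n`.
#' @export
#' @examples
#' d <- dose_ladder(20, 3, 6)$concentrations
#' f <- fit_hill(d, hill_viability(d, 1, 0, 1, 1))
#' c(f$ec50, f$ic50_abs)  # both 1
fit_hill <- function(dose, viability) {
  if (length(dose) != length(viability))
    abort("dose and viability differ in length")
  keep <- complete.cases(dose, viability)
  dose <- dose[keep]; viability <- viability[keep]
  if (length(unique(dose)) < 4) abort("fit_hill needs >= 4 distinct doses")
  d_fit <- dose
  if (any(dose == 0)) d_fit[dose == 0] <- .pseudo_zero_dose(dose)
  l <- log10(d_fit)
  pos <- sort(unique(dose[dose > 0]))
  dose_range <- range(pos)

  flat_fit <- function() {
    structure(list(top = mean(viability), bottom = mean(viability),
                   ec50 = NA_real_, slope = NA_real_, ic50_abs = NA_real_,
                   rss = sum((viability - mean(viability))^2),
                   converged = TRUE, flat = TRUE, dose_range = dose_range,
                   n = length(dose)),
              class = "hill_fit")
  }
  if (sd(viability) < 1e-9) return(flat_fit())

  lower <- c(top = 0, bottom = 0, le50 = min(l) - 2, slope = 0.2)
  upper <- c(top = 1.5, bottom = 1.5, le50 = max(l) + 2, slope = 5)
  resid_fn <- function(par) {
    viability - (par[["bottom"]] + (par[["top"]] - par[["bottom"]]) /
                   (1 + 10^(par[["slope"]] * (l - par[["le50"]]))))
  }
  starts <- lapply(log10(c(min(pos), median(pos), max(pos))), function(s) {
    c(top = min(max(max(viability), 0.01), 1.5),
      bottom = max(min(viability), 0), le50 = s, slope = 1)
  })
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par,
                                                      rss = rss)
  }
  if (is.null(best)) return(flat_fit())
  cf <- best$par
  if (cf[["bottom"]] > cf[["top"]]) return(flat_fit())
  out <- structure(list(top = cf[["top"]], bottom = cf[["bottom"]],
                        ec50 = 10^cf[["le50"]], slope = cf[["slope"]],
                        ic50_abs = NA_real_, rss = best$rss,
                        converged = TRUE, flat = FALSE,
                        dose_range = dose_range, n = length(dose)),
                   class = "hill_fit")
  out$ic50_abs <- absolute_ic50(out, dose_range)
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  if (isTRUE(x$flat)) {
    cat(sprintf("<hill_fit> flat at %.3f (IC50 censored, n = %d)\n", x$top,
                x$n))
  } else {
    cat(sprintf(
      "<hill_fit> top %.3f bottom %.3f ec50 %.4g uM slope %.2f | IC50 %s (n = %d)\n",
      x$top, x$bottom, x$ec50, x$slope,
      if (is.na(x$ic50_abs)) "censored" else sprintf("%.4g uM", x$ic50_abs),
      x$n))
  }
  invisible(x)
}

#' Absolute IC50 of a fitted curve
#'
#' Solves the fitted 4PL for viability 0.5 analytically:
#' `ic50 = ec50 * ((top - 0.5) / (0.5 - bottom))^(1/slope)`. The IC50 is
#' censored (`NA`, with the reason in the `"censored"` attribute) when the
#' fitted curve never crosses 0.5 — flat fit, floor above 0.5, ceiling below
#' 0.5 — or when the crossing lies outside the tested dose range
#' (extrapolated IC50s are unstable and are not reported).
#'
#' @param fit a converged `hill_fit`.
#' @param dose_range `c(min, max)` tested positive doses (uM); defaults to
#'   the fit's own range.
#' @return IC50 in uM, or `NA_real_` with a `"censored"` reason attribute.
#' @export
absolute_ic50 <- function(fit, dose_range = fit$dose_range) {
  stopifnot(inherits(fit, "hill_fit"))
  if (!isTRUE(fit$converged)) abort("fit did not converge; no IC50")
  censor <- function(why) structure(NA_real_, censored = why)
  if (isTRUE(fit$flat)) return(censor("flat response"))
  if (fit$bottom >= 0.5) return(censor("floor above 50% viability"))
  if (fit$top <= 0.5) return(censor("ceiling below 50% viability"))
  ic50 <- fit$ec50 * ((fit$top - 0.5) / (0.5 - fit$bottom))^(1 / fit$slope)
  if (ic50 < dose_range[1] || ic50 > dose_range[2])
    return(censor("crossing outside tested dose range"))
  ic50
}

# invert a fitted 4PL at viability v (NA when not attained)
.invert_hill_fit <- function(fit, v) {
  if (isTRUE(fit$flat)) return(NA_real_)
  hill_inverse(v, fit$top, fit$bottom, fit$ec50, fit$slope)
}

#' Minimal tumor purity at which the tumor IC50 is recoverable
#'
#' Simulation sweep over a purity grid: at each purity, mixed tumor/stroma
#' viability data are generated (`purity * Hill + (1 - purity)`, lognormal
#' noise), a 4PL is fitted, and the tumor-subpopulation IC50 is read off as
#' the dose where the fitted curve crosses the tumor half-kill level
#' `purity * (top + bottom)/2 + (1 - purity)` (for a full-kill tumor this
#' true dose is the tumor ec50). A purity is declared reliable when the
#' recovered IC50 is defined, inside the tested range, and within
#' `fold`-fold of truth in at least `success_rate` of the simulation runs.
#'
#' @param purities ascending purity grid in (0, 1\].
#' @param tumor tumor 4PL parameter list.
#' @param doses positive dose vector (uM).
#' @param noise_cv lognormal viability noise CV.
#' @param replicates wells per dose in each simulated experiment.
#' @param n_runs simulation runs per purity.
#' @param fold fold-tolerance on the recovered IC50 (default 3).
#' @param success_rate required success fraction (default 0.9).
#' @param seed integer base seed; run `r` at purity index `i` uses seed
#'   `seed + 1000 * i + r`.
#' @return a `purity_detectability`: list with `min_purity` (smallest
#'   reliable grid purity, `NA` if none), `rates` data.frame
#'   (`purity`, `success_rate`), and the rule parameters.
#' @export
min_detectable_purity <- function(purities,
                                  tumor = list(top = 1, bottom = 0,
                                               ec50 = 1, slope = 1),
                                  doses = dose_ladder(20, 3, 6)$concentrations,
                                  noise_cv = 0.05, replicates = 3,
                                  n_runs = 20, fold = 3, success_rate = 0.9,
                                  seed = 1) {
  if (is.unsorted(purities)) abort("purity grid must be ascending")
  true_ic50 <- tumor$ec50  # tumor half-kill dose of a symmetric 4PL
  rates <- numeric(length(purities))
  for (i in seq_along(purities)) {
    p <- purities[i]
    target <- p * (tumor$top + tumor$bottom) / 2 + (1 - p)
    ok <- logical(n_runs)
    for (r in seq_len(n_runs)) {
      sim <- simulate_mixed_population_response(mixed_population_spec(
        purity = p, tumor = tumor, doses = doses, noise_cv = noise_cv,
        replicates = replicates, seed = seed + 1000L * i + r))
      fit <- fit_hill(sim$dose_uM, sim$viability)
      est <- if (isTRUE(fit$converged)) .invert_hill_fit(fit, target)
             else NA_real_
      ok[r] <- !is.na(est) && est >= min(doses) && est <= max(doses) &&
        est / true_ic50 <= fold && true_ic50 / est <= fold
    }
    rates[i] <- mean(ok)
  }
  reliable <- purities[rates >= success_rate]
  structure(list(
    min_purity = if (length(reliable)) min(reliable) else NA_real_,
    rates = data.frame(purity = purities, success_rate = rates),
    fold = fold, required_rate = success_rate, n_runs = n_runs,
    noise_cv = noise_cv),
    class = "purity_detectability")
}

#' @export
print.purity_detectability <- function(x, ...) {
  if (is.na(x$min_purity)) {
    cat("<purity_detectability> no purity on the grid is reliable\n")
  } else {
    cat(sprintf(
      "<purity_detectability> min reliable purity %.2f (IC50 within %g-fold in >= %.0f%% of %d runs)\n",
      x$min_purity, x$fold, 100 * x$required_rate, x$n_runs))
  }
  print(x$rates)
  invisible(x)
}
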