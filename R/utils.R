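# Shared numerics: Hill model, lognormal noise, Loewe solver, logit
# interpolation. Internal only.

#' Four-parameter logistic (Hill) viability curve
#'
#' Viability as a function of dose for the standard decreasing 4PL:
#' `bottom + (top - bottom) / (1 + (dose / ec50)^slope)`. At dose 0 the value
#' is `top`; as dose grows it approaches `bottom`.
#'
#' @param dose numeric vector of concentrations (same units as `ec50`,
#'   conventionally uM); zeros allowed.
#' @param top,bottom upper and lower viability asymptotes, `bottom <= top`.
#' @param ec50 dose of half-maximal effect, > 0.
#' @param slope Hill slope, > 0 for a decreasing curve.
#' @return numeric vector of viabilities.
#' @export
#' @examples
#' hill_viability(1, top = 1, bottom = 0, ec50 = 1, slope = 1)  # 0.5
hill_viability <- function(dose, top, bottom, ec50, slope) {
  stopifnot(ec50 > 0)
  bottom + (top - bottom) / (1 + (dose / ec50)^slope)
}

#' Invert a 4PL curve at a viability level
#'
#' Dose at which the curve crosses viability `v`; `NA` where `v` is outside
#' the open interval (`bottom`, `top`).
#'
#' @inheritParams hill_viability
#' @param v target viability level(s).
#' @return numeric vector of doses (NA where the level is not attained).
#' @export
hill_inverse <- function(v, top, bottom, ec50, slope) {
  out <- rep(NA_real_, length(v))
  ok <- !is.na(v) & v > bottom & v < top
  out[ok] <- ec50 * ((top - v[ok]) / (v[ok] - bottom))^(1 / slope)
  out
}

# Multiplicative lognormal noise factors with unit mean and coefficient of
# variation `cv` (sigma^2 = log(1 + cv^2), mu = -sigma^2/2).
lognormal_noise <- function(n, cv) {
  if (cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log1p(cv^2))
  exp(rnorm(n, mean = -sigma^2 / 2, sd = sigma))
}

# Dose of drug with Hill params `p` achieving viability v, extended per the
# Loewe convention: 0 when the drug attains v at zero dose (v >= top), Inf
# when it can never attain v (v <= bottom).
.loewe_equivalent_dose <- function(v, p) {
  if (v >= p$top) return(0)
  if (v <= p$bottom) return(Inf)
  p$ec50 * ((p$top - v) / (v - p$bottom))^(1 / p$slope)
}

#' Loewe-additive expected viability for a dose pair
#'
#' Solves the implicit Loewe additivity equation `a/A_v + b/B_v = 1` for the
#' viability `v` at combination dose (`a`, `b`), where `A_v` and `B_v` are the
#' monotherapy doses of each drug producing viability `v` under its 4PL.
#' There is no closed form for unequal Hill slopes, so the equation is solved
#' by bisection on `v` (the dose sum `a/A_v + b/B_v` is strictly increasing in
#' `v`). If even the shallowest attainable effect over-satisfies (or the
#' deepest under-satisfies) the equation, the corresponding boundary viability
#' is returned.
#'
#' @param a,b nonnegative combination doses of drugs A and B.
#' @param paramsA,paramsB lists with elements `top`, `bottom`, `ec50`,
#'   `slope` for each monotherapy curve.
#' @param tol bisection tolerance on viability (default 1e-6).
#' @return expected viability under Loewe additivity (scalar).
#' @export
#' @examples
#' p <- list(top = 1, bottom = 0, ec50 = 1, slope = 1)
#' # a drug is Loewe-additive with itself: V(a, b) = Hill(a + b)
#' loewe_viability(0.5, 0.5, p, p)          # == hill_viability(1, 1, 0, 1, 1)
loewe_viability <- function(a, b, paramsA, paramsB, tol = 1e-6) {
  stopifnot(a >= 0, b >= 0)
  if (a == 0 && b == 0) return((paramsA$top + paramsB$top) / 2)
  if (b == 0) return(hill_viability(a, paramsA$top, paramsA$bottom,
                                    paramsA$ec50, paramsA$slope))
  if (a == 0) return(hill_viability(b, paramsB$top, paramsB$bottom,
                                    paramsB$ec50, paramsB$slope))
  g <- function(v) {
    da <- .loewe_equivalent_dose(v, paramsA)
    db <- .loewe_equivalent_dose(v, paramsB)
    (if (da == 0) Inf else a / da) + (if (db == 0) Inf else b / db)
  }
  lo <- min(paramsA$bottom, paramsB$bottom)
  hi <- min(paramsA$top, paramsB$top)
  eps <- 1e-12
  vlo <- lo + eps
  vhi <- hi - eps
  if (g(vhi) <= 1) return(vhi)  # doses too small to move off the top
  if (g(vlo) >= 1) return(vlo)  # deeper than either curve can describe
  while (vhi - vlo > tol) {
    vm <- (vlo + vhi) / 2
    if (g(vm) > 1) vhi <- vm else vlo <- vm
  }
  (vlo + vhi) / 2
}

# Clamped logit/inverse-logit used for interpolating viability surfaces: a
# Hill curve with top 1 / bottom 0 is exactly linear in (log dose, logit v).
.logit <- function(v, eps = 1e-6) {
  v <- pmin(pmax(v, eps), 1 - eps)
  log(v / (1 - v))
}
.inv_logit <- function(x) 1 / (1 + exp(-x))

# Run expr with a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# stop() with sprintf formatting, no call
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
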