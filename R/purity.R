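# Tumor-purity estimation: EpCAM/(EpCAM+vimentin) index, linear calibration
# to true tumor fraction, screen-validity gate, marker-positive fraction.

#' EpCAM/vimentin tumor-purity index
#'
#' The purity index of a spot is the ratio of its background-corrected EpCAM
#' intensity to the combined EpCAM + vimentin intensity:
#' `r = E / (E + V)`, dimensionless in \[0, 1\]. Carcinoma cells are
#' EpCAM-high, fibroblasts vimentin-high, so `r` rises with tumor content.
#' The index is scale-invariant: multiplying both channels by the same
#' positive gain leaves it unchanged.
#'
#' @param epcam_corrected,vimentin_corrected background-corrected channel
#'   intensities (RFU), both >= 0; vectors are processed elementwise.
#' @return numeric vector of indices in \[0, 1\].
#' @export
#' @examples
#' purity_index(700, 300)  # 0.7
purity_index <- function(epcam_corrected, vimentin_corrected) {
  e <- epcam_corrected
  v <- vimentin_corrected
  if (length(e) != length(v)) abort("channel vectors differ in length")
  if (any(e < 0) || any(v < 0)) abort("corrected intensities must be >= 0")
  dead <- e + v == 0
  if (any(dead))
    abort("undefined purity index: EpCAM and vimentin both 0 at position(s) %s",
          paste(utils::head(which(dead), 5), collapse = ", "))
  e / (e + v)
}

#' Fit the purity calibration line
#'
#' Ordinary least squares of true tumor fraction on purity index
#' (`fraction ~ index`). Regressing fraction on index (rather than inverting
#' an index-on-fraction line) makes prediction of unknown samples a direct
#' application of the fitted coefficients.
#'
#' @param true_fractions known tumor fractions in \[0, 1\] (>= 3 points).
#' @param indices matching purity indices.
#' @return a `calibration_model`: list with `intercept`, `slope`,
#'   `r_squared`, `n_points`.
#' @export
#' @examples
#' m <- fit_calibration(c(0, .5, 1), c(.1, .5, .9))
#' m$r_squared  # 1: collinear
fit_calibration <- function(true_fractions, indices) {
  if (length(true_fractions) != length(indices))
    abort("fraction and index vectors differ in length")
  if (length(indices) < 3) abort("calibration needs >= 3 points")
  if (any(true_fractions < 0 | true_fractions > 1))
    abort("true fractions must be in [0, 1]")
  if (sd(indices) == 0) abort("indices have zero variance; cannot calibrate")
  fit <- lm(true_fractions ~ indices)
  rss <- sum(residuals(fit)^2)
  tss <- sum((true_fractions - mean(true_fractions))^2)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 r_squared = if (tss > 0) 1 - rss / tss else 1,
                 n_points = length(indices)),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model> fraction = %.4f + %.4f * index  (R^2 = %.4f, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Predict tumor purity from the calibration model
#'
#' Applies `intercept + slope * index` and clips to \[0, 1\]; clipped entries
#' are flagged in the `"clipped"` attribute of the result.
#'
#' @param model a fitted [fit_calibration()] model.
#' @param index purity index value(s).
#' @return predicted tumor fraction(s) in \[0, 1\], with a logical
#'   `"clipped"` attribute.
#' @export
predict_purity <- function(model, index) {
  if (!inherits(model, "calibration_model"))
    abort("model must be a fitted calibration_model")
  raw <- model$intercept + model$slope * index
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "clipped") <- raw < 0 | raw > 1
  out
}

#' Purity gate for screen validity
#'
#' A screen is considered interpretable only when the predicted tumor purity
#' strictly exceeds the threshold (default 0.30): below ~30% tumor content
#' the drug response of the tumor subpopulation is swamped by non-responding
#' stroma. The boundary itself warns (strict `>`).
#'
#' @param predicted_fraction predicted purity value(s) in \[0, 1\].
#' @param threshold gate threshold (default 0.30).
#' @return data.frame with columns `predicted_purity`, `status`
#'   (`"valid"`/`"warn"`) and `message`.
#' @export
#' @examples
#' qc_purity_gate(c(0.55, 0.30, 0.01))
qc_purity_gate <- function(predicted_fraction, threshold = 0.30) {
  if (any(predicted_fraction < 0 | predicted_fraction > 1))
    abort("predicted fractions must be in [0, 1]")
  valid <- predicted_fraction > threshold
  data.frame(
    predicted_purity = as.numeric(predicted_fraction),
    status = ifelse(valid, "valid", "warn"),
    message = ifelse(valid,
      sprintf("purity %.2f > %.2f: drug response interpretable",
              predicted_fraction, threshold),
      sprintf("purity %.2f <= %.2f: tumor signal may be masked by stroma",
              predicted_fraction, threshold)),
    stringsAsFactors = FALSE)
}

#' Fraction of marker-positive spots
#'
#' Share of spots whose background-corrected marker intensity (e.g. HER2 or
#' MET staining) strictly exceeds the positivity threshold.
#'
#' @param marker_corrected per-spot corrected marker intensities (RFU),
#'   nonempty.
#' @param positivity_threshold RFU cutoff, >= 0; see
#'   [marker_positivity_threshold()] for a data-driven default.
#' @return fraction in \[0, 1\].
#' @export
marker_positive_fraction <- function(marker_corrected, positivity_threshold) {
  if (length(marker_corrected) == 0) abort("marker vector is empty")
  if (positivity_threshold < 0) abort("threshold must be >= 0")
  mean(marker_corrected > positivity_threshold)
}

#' Marker positivity threshold from negative-control spots
#'
#' `median + 3 * MAD` of the corrected marker intensity over a
#' negative-control spot set — a robust upper envelope of the background
#' population.
#'
#' @param negative_corrected corrected marker intensities of
#'   negative-control spots.
#' @return RFU threshold.
#' @export
marker_positivity_threshold <- function(negative_corrected) {
  if (length(negative_corrected) == 0) abort("no negative-control spots")
  median(negative_corrected) + 3 * mad(negative_corrected)
}
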