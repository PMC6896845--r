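# Two-drug interaction scoring: Loewe combination index at 50% effect,
# Loewe/Bliss synergy-excess maps, interaction classification, waterfall
# ranking.

#' Construct a two-drug dose-response matrix
#'
#' @param drugA,drugB compound ids.
#' @param doses_A,doses_B ascending dose vectors (uM) including 0 (the
#'   monotherapy margins).
#' @param viability complete numeric grid, rows indexed by `doses_A`,
#'   columns by `doses_B`.
#' @return a `dose_matrix`.
#' @export
dose_matrix <- function(drugA, drugB, doses_A, doses_B, viability) {
  if (!0 %in% doses_A || !0 %in% doses_B)
    abort("dose vectors must include the zero-dose monotherapy margin")
  if (is.unsorted(doses_A) || is.unsorted(doses_B))
    abort("dose vectors must be ascending")
  if (!all(dim(viability) == c(length(doses_A), length(doses_B))))
    abort("viability grid is %d x %d but doses imply %d x %d",
          nrow(viability), ncol(viability), length(doses_A), length(doses_B))
  if (any(is.na(viability))) abort("viability grid has missing cells")
  dimnames(viability) <- list(format(doses_A, trim = TRUE),
                              format(doses_B, trim = TRUE))
  structure(list(drugA = drugA, drugB = drugB,
                 doses_A = as.numeric(doses_A),
                 doses_B = as.numeric(doses_B),
                 viability = viability),
            class = "dose_matrix")
}

#' @export
print.dose_matrix <- function(x, ...) {
  cat(sprintf("<dose_matrix> %s x %s, %d x %d doses (incl. zero margins)\n",
              x$drugA, x$drugB, length(x$doses_A), length(x$doses_B)))
  print(round(x$viability, 3))
  invisible(x)
}

#' Long-format view of a dose matrix
#'
#' @param x a `dose_matrix`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns `drugA`, `drugB`, `doseA_uM`, `doseB_uM`,
#'   `viability`.
#' @export
as.data.frame.dose_matrix <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  g <- expand.grid(doseA_uM = x$doses_A, doseB_uM = x$doses_B)
  data.frame(drugA = x$drugA, drugB = x$drugB, g,
             viability = as.vector(x$viability), stringsAsFactors = FALSE)
}

#' Assemble a dose matrix from a long-format viability table
#'
#' Replicate rows for the same dose pair are averaged.
#'
#' @param df data.frame with columns `doseA_uM`, `doseB_uM`, `viability`
#'   (and optionally `drugA`, `drugB`).
#' @return a `dose_matrix`.
#' @export
dose_matrix_from_long <- function(df) {
  need <- c("doseA_uM", "doseB_uM", "viability")
  if (!all(need %in% names(df)))
    abort("long table needs columns %s", paste(need, collapse = ", "))
  dA <- sort(unique(df$doseA_uM))
  dB <- sort(unique(df$doseB_uM))
  agg <- tapply(df$viability, list(factor(df$doseA_uM, levels = dA),
                                   factor(df$doseB_uM, levels = dB)),
                mean)
  if (any(is.na(agg))) abort("incomplete dose grid (missing dose pairs)")
  dose_matrix(df$drugA[1] %||% "A", df$drugB[1] %||% "B", dA, dB,
              unclass(agg))
}

# Interpolate the positive-dose viability surface at (a, b), bilinearly in
# (log dose, logit viability). A Hill margin with top 1 / bottom 0 is exactly
# linear in logit-vs-log-dose, which keeps ray interpolation consistent with
# the sham (drug-with-itself) identity on coarse dilution grids.
.surface_interpolator <- function(mat) {
  ia <- which(mat$doses_A > 0)
  ib <- which(mat$doses_B > 0)
  la <- log(mat$doses_A[ia])
  lb <- log(mat$doses_B[ib])
  Z <- .logit(mat$viability[ia, ib, drop = FALSE])
  function(a, b) {
    x <- log(a); y <- log(b)
    if (x < la[1] || x > la[length(la)] || y < lb[1] || y > lb[length(lb)])
      return(NA_real_)
    i <- findInterval(x, la, rightmost.closed = TRUE)
    j <- findInterval(y, lb, rightmost.closed = TRUE)
    i2 <- min(i + 1, length(la)); j2 <- min(j + 1, length(lb))
    tx <- if (i2 == i) 0 else (x - la[i]) / (la[i2] - la[i])
    ty <- if (j2 == j) 0 else (y - lb[j]) / (lb[j2] - lb[j])
    z <- (1 - tx) * (1 - ty) * Z[i, j] + tx * (1 - ty) * Z[i2, j] +
      (1 - tx) * ty * Z[i, j2] + tx * ty * Z[i2, j2]
    .inv_logit(z)
  }
}

#' Fit the monotherapy margins of a dose matrix
#'
#' Fits a 4PL to each zero-dose margin of the checkerboard using the
#' positive doses only: the dose-0 margin cell is the normalization anchor
#' of the plate, not a point on the log-dose curve, and anchoring it at a
#' pseudo-dose biases shallow-slope fits.
#'
#' @param matrix a `dose_matrix`.
#' @return list with `fitA` and `fitB` ([fit_hill()] objects).
#' @export
fit_margins <- function(matrix) {
  stopifnot(inherits(matrix, "dose_matrix"))
  iA0 <- which(matrix$doses_A == 0)
  iB0 <- which(matrix$doses_B == 0)
  ia <- which(matrix$doses_A > 0)
  ib <- which(matrix$doses_B > 0)
  list(fitA = fit_hill(matrix$doses_A[ia], matrix$viability[ia, iB0]),
       fitB = fit_hill(matrix$doses_B[ib], matrix$viability[iA0, ib]))
}

#' Loewe combination index at 50% effect (CI50)
#'
#' `CI50 = a/A + b/B`, where `A` and `B` are the monotherapy absolute IC50s
#' and `(a, b)` is the combination dose pair on a fixed-ratio ray through
#' the checkerboard at which interpolated combination viability equals 0.5.
#' `CI50 < 1` means the combination reaches half-kill at lower doses than
#' Loewe additivity predicts (synergy); `CI50 > 1` means antagonism. The
#' default ray is the equipotency diagonal `b/a = B/A`; the 50% crossing is
#' located by monotone piecewise-linear interpolation of logit viability in
#' log total dose, without extrapolating beyond the tested doses.
#'
#' @param matrix a `dose_matrix` (normalized viability, zero margins
#'   present).
#' @param fitA,fitB converged [fit_hill()] monotherapy fits for drugs A
#'   and B.
#' @param ray dose ratio `b/a` defining the ray; `NULL` (default) uses the
#'   equipotency ratio `B/A`.
#' @param bands additivity band on CI: `c(lower, upper)` (default 0.9-1.1);
#'   see [classify_interaction()].
#' @return a `ci50_result`: list with `a`, `b`, `A`, `B`, `ci50`, `class`
#'   (`synergy`/`additive`/`antagonism`/`undefined`) and `reason` when
#'   undefined.
#' @export
ci50 <- function(matrix, fitA, fitB, ray = NULL, bands = c(0.9, 1.1)) {
  stopifnot(inherits(matrix, "dose_matrix"))
  undef <- function(why, A = NA_real_, B = NA_real_) {
    structure(list(a = NA_real_, b = NA_real_, A = A, B = B,
                   ci50 = NA_real_, class = "undefined", reason = why,
                   drugA = matrix$drugA, drugB = matrix$drugB),
              class = "ci50_result")
  }
  posA <- matrix$doses_A[matrix$doses_A > 0]
  posB <- matrix$doses_B[matrix$doses_B > 0]
  A <- tryCatch(absolute_ic50(fitA, range(posA)), error = function(e) NA_real_)
  B <- tryCatch(absolute_ic50(fitB, range(posB)), error = function(e) NA_real_)
  if (is.na(A) || is.na(B))
    return(undef("monotherapy IC50 censored", A, B))
  if (is.null(ray)) ray <- B / A
  interp <- .surface_interpolator(matrix)
  # ray: (a, b) = (t, ray * t); t limited to doses covered by both drugs
  t_lo <- max(min(posA), min(posB) / ray)
  t_hi <- min(max(posA), max(posB) / ray)
  if (t_lo >= t_hi) return(undef("ray does not intersect the tested grid", A, B))
  # sample the ray where it crosses the tested dose levels of either drug:
  # there the surface interpolation reduces to (at worst) 1-D interpolation
  # along a grid line and is exact at checkerboard nodes
  tt <- sort(unique(signif(c(posA, posB / ray, t_lo, t_hi), 12)))
  tt <- tt[tt >= t_lo & tt <= t_hi]
  vv <- vapply(tt, function(t) interp(t, ray * t), numeric(1))
  below <- which(vv <= 0.5)
  if (length(below) == 0)
    return(undef("combination never reaches 50% viability on the ray", A, B))
  k <- below[1]
  if (k == 1) {
    t_star <- tt[1]
  } else {
    z1 <- .logit(vv[k - 1]); z2 <- .logit(vv[k])
    w <- (z1 - 0) / (z1 - z2)
    t_star <- exp(log(tt[k - 1]) + w * (log(tt[k]) - log(tt[k - 1])))
  }
  a <- t_star; b <- ray * t_star
  ci <- a / A + b / B
  structure(list(a = a, b = b, A = A, B = B, ci50 = ci,
                 class = .classify_ci(ci, bands), reason = NA_character_,
                 drugA = matrix$drugA, drugB = matrix$drugB),
            class = "ci50_result")
}

#' @export
print.ci50_result <- function(x, ...) {
  if (x$class == "undefined") {
    cat(sprintf("<ci50_result> %s + %s: undefined (%s)\n", x$drugA, x$drugB,
                x$reason))
  } else {
    cat(sprintf(
      "<ci50_result> %s + %s: CI50 = %.3f (a %.3g/A %.3g + b %.3g/B %.3g) -> %s\n",
      x$drugA, x$drugB, x$ci50, x$a, x$A, x$b, x$B, x$class))
  }
  invisible(x)
}

.classify_ci <- function(ci, bands = c(0.9, 1.1)) {
  if (is.na(ci)) return("undefined")
  if (ci < bands[1]) "synergy" else if (ci > bands[2]) "antagonism"
  else "additive"
}

.classify_score <- function(score, bands = c(-10, 10)) {
  if (is.na(score)) return("undefined")
  if (score > bands[2]) "synergy" else if (score < bands[1]) "antagonism"
  else "additive"
}

.new_synergy_map <- function(reference, excess, doses_A, doses_B, drugA,
                             drugB) {
  structure(list(reference = reference, excess = excess,
                 doses_A = doses_A, doses_B = doses_B,
                 summary_score = 100 * mean(excess),
                 drugA = drugA, drugB = drugB),
            class = "synergy_map")
}

#' @export
print.synergy_map <- function(x, ...) {
  cat(sprintf("<synergy_map> %s reference, %s + %s: summary score %.2f\n",
              x$reference, x$drugA, x$drugB, x$summary_score))
  print(round(x$excess, 3))
  invisible(x)
}

#' Bliss-independence synergy-excess map
#'
#' Expected viability at each positive dose pair is the product of the
#' observed monotherapy margins, `V_A(a) * V_B(b)`; excess is
#' `expected - observed`, so positive values mean more kill than independence
#' predicts (synergy). The summary score is 100 times the mean excess over
#' positive-dose cells.
#'
#' @param matrix a `dose_matrix` with zero-dose margins.
#' @return a `synergy_map` (fields `reference`, `excess`, `summary_score`).
#' @export
bliss_excess_map <- function(matrix) {
  stopifnot(inherits(matrix, "dose_matrix"))
  iA0 <- which(matrix$doses_A == 0)
  iB0 <- which(matrix$doses_B == 0)
  if (length(iA0) != 1 || length(iB0) != 1)
    abort("dose matrix lacks zero-dose monotherapy margins")
  ia <- which(matrix$doses_A > 0)
  ib <- which(matrix$doses_B > 0)
  VA <- matrix$viability[ia, iB0]
  VB <- matrix$viability[iA0, ib]
  observed <- matrix$viability[ia, ib, drop = FALSE]
  expected <- outer(VA, VB)
  .new_synergy_map("bliss", expected - observed, matrix$doses_A[ia],
                   matrix$doses_B[ib], matrix$drugA, matrix$drugB)
}

#' Loewe-additivity synergy-excess map
#'
#' Expected viability at each positive dose pair solves the implicit Loewe
#' equation from the fitted monotherapy curves (bisection, tolerance 1e-6);
#' excess is `expected - observed` (positive = synergy). Fitted margins are
#' used (rather than observed ones) because the Loewe equation needs
#' invertible dose-response curves.
#'
#' @param matrix a `dose_matrix`.
#' @param fitA,fitB converged, non-flat [fit_hill()] monotherapy fits.
#' @return a `synergy_map`.
#' @export
loewe_excess_map <- function(matrix, fitA, fitB) {
  stopifnot(inherits(matrix, "dose_matrix"))
  for (f in list(fitA, fitB)) {
    if (!inherits(f, "hill_fit") || !isTRUE(f$converged) || isTRUE(f$flat))
      abort("Loewe reference needs converged, non-flat monotherapy fits")
  }
  pA <- list(top = fitA$top, bottom = fitA$bottom, ec50 = fitA$ec50,
             slope = fitA$slope)
  pB <- list(top = fitB$top, bottom = fitB$bottom, ec50 = fitB$ec50,
             slope = fitB$slope)
  ia <- which(matrix$doses_A > 0)
  ib <- which(matrix$doses_B > 0)
  observed <- matrix$viability[ia, ib, drop = FALSE]
  expected <- observed
  for (i in seq_along(ia)) for (j in seq_along(ib)) {
    expected[i, j] <- loewe_viability(matrix$doses_A[ia[i]],
                                      matrix$doses_B[ib[j]], pA, pB)
  }
  .new_synergy_map("loewe", expected - observed, matrix$doses_A[ia],
                   matrix$doses_B[ib], matrix$drugA, matrix$drugB)
}

#' Classify a drug-drug interaction
#'
#' For a [ci50()] result: CI50 < 0.9 synergy, within \[0.9, 1.1\] additive,
#' > 1.1 antagonism (the additivity band absorbs noise around the theoretical
#' boundary CI = 1). For a synergy map (or bare summary score): score > 10
#' synergy, within \[-10, 10\] additive, < -10 antagonism. Undefined inputs
#' classify as `"undefined"`.
#'
#' @param x a `ci50_result`, `synergy_map`, or numeric score.
#' @param ... passed to methods.
#' @return one of `"synergy"`, `"additive"`, `"antagonism"`, `"undefined"`.
#' @export
classify_interaction <- function(x, ...) UseMethod("classify_interaction")

#' @rdname classify_interaction
#' @param bands classification band: `c(0.9, 1.1)` for CI,
#'   `c(-10, 10)` for summary scores.
#' @export
classify_interaction.ci50_result <- function(x, bands = c(0.9, 1.1), ...) {
  .classify_ci(x$ci50, bands)
}

#' @rdname classify_interaction
#' @export
classify_interaction.synergy_map <- function(x, bands = c(-10, 10), ...) {
  .classify_score(x$summary_score, bands)
}

#' @rdname classify_interaction
#' @param type `"ci"` or `"score"`, required for bare numerics.
#' @export
classify_interaction.numeric <- function(x, type = c("ci", "score"),
                                         bands = NULL, ...) {
  type <- match.arg(type)
  if (type == "ci") .classify_ci(x, bands %||% c(0.9, 1.1))
  else .classify_score(x, bands %||% c(-10, 10))
}

#' Rank combinations into a waterfall table
#'
#' Orders per-sample, per-combination summary scores descending; ties are
#' broken lexicographically by (sample, combination) so the ordering is
#' deterministic and invariant to input row order. Extra annotation columns
#' pass through.
#'
#' @param scores data.frame with columns `sample`, `combination`,
#'   `summary_score` (plus any annotation columns).
#' @return the same data.frame, reordered, with a `rank` column prepended.
#' @export
rank_combinations <- function(scores) {
  need <- c("sample", "combination", "summary_score")
  if (!all(need %in% names(scores)))
    abort("scores needs columns %s", paste(need, collapse = ", "))
  if (nrow(scores) == 0) abort("scores table is empty")
  ord <- order(-scores$summary_score, scores$sample, scores$combination)
  out <- scores[ord, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}
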