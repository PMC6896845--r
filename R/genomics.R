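# Variant-table filtering and permutation-based association of alteration
# status with combination-synergy scores.

.VARIANT_TYPES <- c("SNV", "indel", "amplification", "deletion")

#' Filter a variant table by VAF and read support
#'
#' SNVs and indels pass when variant allele frequency strictly exceeds
#' `vaf_min` AND alternate-read count strictly exceeds `reads_min`
#' (defaults: VAF > 5% and > 20 reads; both boundaries are strict, mirroring
#' the ">" wording of the filter). Copy-number records (amplification,
#' deletion) have no VAF and pass unconditionally. Filtering is idempotent.
#'
#' @param records data.frame with columns `sample`, `gene`, `type`
#'   (`SNV`/`indel`/`amplification`/`deletion`), `vaf` (fraction in
#'   \[0, 1\], `NA` for CNVs), `alt_reads` (`NA` for CNVs).
#' @param vaf_min VAF threshold (default 0.05).
#' @param reads_min alternate-read threshold (default 20).
#' @return the passing subset of `records`.
#' @export
#' @examples
#' v <- data.frame(sample = "P1", gene = "TP53", type = "SNV",
#'                 vaf = c(0.04, 0.5), alt_reads = c(100, 100))
#' filter_variants(v)  # only the VAF 0.5 row passes
filter_variants <- function(records, vaf_min = 0.05, reads_min = 20) {
  need <- c("sample", "gene", "type", "vaf", "alt_reads")
  if (!all(need %in% names(records)))
    abort("variant table needs columns %s", paste(need, collapse = ", "))
  is_snv <- records$type %in% c("SNV", "indel")
  bad <- which(
    !records$type %in% .VARIANT_TYPES |
      (is_snv & (is.na(records$vaf) | records$vaf < 0 | records$vaf > 1)) |
      (is_snv & (is.na(records$alt_reads) | records$alt_reads < 0)))
  if (length(bad) > 0)
    abort("malformed variant record(s) at row(s): %s",
          paste(utils::head(bad, 10), collapse = ", "))
  pass <- !is_snv |
    (records$vaf > vaf_min & records$alt_reads > reads_min)
  out <- records[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Associate alteration status with combination-synergy scores
#'
#' Compares summary synergy scores between altered and wild-type samples by
#' the difference of group medians, with a two-sided permutation test
#' (add-one smoothed: `p = (1 + #{|delta_perm| >= |delta_obs|}) /
#' (n_perm + 1)`). Median/permutation inference is used because PDC panels
#' are tiny and score distributions unknown. With fewer than two samples in
#' either group the result is descriptive only (`p` is `NA`).
#'
#' @param status named logical vector: `TRUE` = altered, names are sample
#'   ids.
#' @param scores named numeric vector of summary synergy scores; names must
#'   cover those of `status`.
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer RNG seed.
#' @return an `association_result`: list with `delta_median`,
#'   `permutation_p`, `scores_altered`, `scores_wildtype`, `n_perm`.
#' @export
associate <- function(status, scores, n_perm = 1000, seed = 1) {
  if (is.null(names(status)) || is.null(names(scores)))
    abort("status and scores must be named by sample id")
  common <- intersect(names(status), names(scores))
  if (length(common) == 0) abort("no samples shared between status and scores")
  status <- status[common]
  scores <- scores[common]
  alt <- scores[status]
  wt <- scores[!status]
  delta <- median(alt) - median(wt)  # NA if a group is empty
  res <- list(delta_median = delta,
              permutation_p = NA_real_,
              scores_altered = unname(alt), scores_wildtype = unname(wt),
              n_altered = length(alt), n_wildtype = length(wt),
              n_perm = as.integer(n_perm))
  if (length(alt) >= 2 && length(wt) >= 2) {
    n <- length(scores)
    k <- length(alt)
    obs <- abs(delta)
    perm_delta <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n, k)
        median(scores[idx]) - median(scores[-idx])
      }, numeric(1))
    })
    res$permutation_p <- (1 + sum(abs(perm_delta) >= obs)) / (n_perm + 1)
  }
  structure(res, class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result> delta median %.3f (altered n=%d, wildtype n=%d), p = %s\n",
    x$delta_median, x$n_altered, x$n_wildtype,
    if (is.na(x$permutation_p)) "NA (descriptive only)"
    else sprintf("%.4f (%d permutations)", x$permutation_p, x$n_perm)))
  invisible(x)
}

#' Association report across alteration x combination pairs
#'
#' Runs [associate()] for every (gene alteration, combination) pair and
#' adjusts the permutation p-values across pairs by Benjamini-Hochberg.
#'
#' @param variants a *filtered* variant table (see [filter_variants()]).
#' @param scores data.frame with columns `sample`, `combination`,
#'   `summary_score`.
#' @param n_perm,seed passed to [associate()].
#' @return data.frame with one row per alteration x combination:
#'   `gene`, `type`, `combination`, `n_altered`, `n_wildtype`,
#'   `delta_median`, `p`, `p_adj`.
#' @export
association_report <- function(variants, scores, n_perm = 1000, seed = 1) {
  need <- c("sample", "combination", "summary_score")
  if (!all(need %in% names(scores)))
    abort("scores needs columns %s", paste(need, collapse = ", "))
  alts <- unique(variants[, c("gene", "type")])
  combos <- unique(scores$combination)
  rows <- list()
  for (i in seq_len(nrow(alts))) for (cb in combos) {
    sub <- scores[scores$combination == cb, ]
    sc <- setNames(sub$summary_score, sub$sample)
    altered_samples <- variants$sample[variants$gene == alts$gene[i] &
                                         variants$type == alts$type[i]]
    st <- setNames(names(sc) %in% altered_samples, names(sc))
    a <- associate(st, sc, n_perm = n_perm,
                   seed = seed + length(rows))
    rows[[length(rows) + 1]] <- data.frame(
      gene = alts$gene[i], type = alts$type[i], combination = cb,
      n_altered = a$n_altered, n_wildtype = a$n_wildtype,
      delta_median = a$delta_median, p = a$permutation_p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
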