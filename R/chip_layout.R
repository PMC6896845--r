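# Chip/plate layouts: dose ladders, compound/dose/replicate assignment,
# layout CSV round trip.

#' Geometric dose ladder
#'
#' Builds the descending geometric dilution series used on the screening
#' plates: `concentrations[i] = max_conc / ratio^(i-1)`. The default screen
#' design is a 6-dose, 3-fold ladder from 20 uM.
#'
#' @param max_conc top concentration (uM), > 0.
#' @param ratio fold-dilution between consecutive doses, > 1.
#' @param n number of doses, >= 1.
#' @return an object of class `dose_series`: list with `max_conc`, `ratio`,
#'   `n` and the descending `concentrations` vector.
#' @export
#' @examples
#' dose_ladder(20, 3, 6)$concentrations
dose_ladder <- function(max_conc = 20, ratio = 3, n = 6) {
  if (!is.numeric(max_conc) || max_conc <= 0) abort("max_conc must be > 0")
  if (!is.numeric(ratio) || ratio <= 1) abort("ratio must be > 1")
  if (n < 1 || n != round(n)) abort("n must be a positive integer")
  structure(
    list(max_conc = max_conc, ratio = ratio, n = as.integer(n),
         concentrations = max_conc / ratio^(seq_len(n) - 1)),
    class = "dose_series")
}

#' @export
print.dose_series <- function(x, ...) {
  cat(sprintf("<dose_series> %d doses, %g-fold from %g uM:\n", x$n, x$ratio,
              x$max_conc))
  print(signif(x$concentrations, 4))
  invisible(x)
}

.position_label <- function(row, col) sprintf("R%02dC%02d", row, col)

#' Build a deterministic chip layout
#'
#' Assigns compounds, doses, replicates and controls to the positions of a
#' pillar chip, filling row-major. The default instantiates the 532-position
#' micropillar chip (19 x 28 logical grid) designed for 12 compounds; when
#' `replicates` is `NULL` the replicate count is computed to maximally fill
#' the chip after reserving control positions (chips are printed full), which
#' for the default gives 12 compounds x 6 doses x 7 replicates + 28 controls
#' = 532 with no unused position.
#'
#' @param n_compounds number of test compounds (>= 0).
#' @param doses a [dose_ladder()] object or numeric dose vector (uM).
#' @param replicates replicates per compound-dose condition, or `NULL` to
#'   fill capacity.
#' @param n_negative,n_positive number of negative (untreated/vehicle) and
#'   positive (full-kill, e.g. staurosporine) control positions.
#' @param capacity total pillar positions on the chip.
#' @param grid integer `c(rows, cols)` with `prod(grid) == capacity`.
#' @param compounds optional character vector of compound ids (length
#'   `n_compounds`); defaults to `"C01"`, `"C02"`, ...
#' @return an object of class `chip_layout`: list with `capacity`, `grid` and
#'   an `assignments` data.frame (one row per position) with columns
#'   `position_label`, `row`, `col`, `role`
#'   (compound/negative_control/positive_control/unused), `compound`,
#'   `dose_uM`, `replicate`.
#' @export
#' @examples
#' lay <- build_default_layout()
#' lay$capacity                        # 532
#' table(lay$assignments$role)
build_default_layout <- function(n_compounds = 12,
                                 doses = dose_ladder(20, 3, 6),
                                 replicates = NULL,
                                 n_negative = 14, n_positive = 14,
                                 capacity = 532, grid = c(19, 28),
                                 compounds = NULL) {
  if (length(grid) != 2 || prod(grid) != capacity)
    abort("grid (%d x %d) does not match capacity %d", grid[1], grid[2],
          capacity)
  if (n_negative < 1 || n_positive < 1)
    abort("at least one negative and one positive control are required")
  conc <- if (inherits(doses, "dose_series")) doses$concentrations else doses
  n_doses <- length(conc)
  n_controls <- n_negative + n_positive
  if (is.null(replicates)) {
    replicates <- if (n_compounds > 0)
      max(1L, (capacity - n_controls) %/% (n_compounds * n_doses)) else 1L
  }
  n_cmpd_pos <- n_compounds * n_doses * replicates
  if (n_cmpd_pos + n_controls > capacity)
    abort(paste0("layout needs %d positions (%d compound + %d control) but ",
                 "capacity is %d: %d over"),
          n_cmpd_pos + n_controls, n_cmpd_pos, n_controls, capacity,
          n_cmpd_pos + n_controls - capacity)
  if (is.null(compounds)) compounds <- sprintf("C%02d", seq_len(n_compounds))
  stopifnot(length(compounds) == n_compounds)

  rows <- rep(seq_len(grid[1]), each = grid[2])
  cols <- rep(seq_len(grid[2]), times = grid[1])
  asg <- data.frame(
    position_label = .position_label(rows, cols),
    row = rows, col = cols,
    role = "unused", compound = NA_character_,
    dose_uM = NA_real_, replicate = NA_integer_,
    stringsAsFactors = FALSE)

  i <- 1L
  if (n_compounds > 0) {
    for (cm in compounds) for (d in seq_len(n_doses)) for (r in seq_len(replicates)) {
      asg$role[i] <- "compound"
      asg$compound[i] <- cm
      asg$dose_uM[i] <- conc[d]
      asg$replicate[i] <- r
      i <- i + 1L
    }
  }
  for (r in seq_len(n_negative)) {
    asg$role[i] <- "negative_control"; asg$replicate[i] <- r; i <- i + 1L
  }
  for (r in seq_len(n_positive)) {
    asg$role[i] <- "positive_control"; asg$replicate[i] <- r; i <- i + 1L
  }
  structure(list(capacity = as.integer(capacity), grid = as.integer(grid),
                 assignments = asg),
            class = "chip_layout")
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf("<chip_layout> %d positions (%d x %d)\n", x$capacity,
              x$grid[1], x$grid[2]))
  print(table(x$assignments$role))
  invisible(x)
}

#' Write a chip layout to CSV
#'
#' Columns: `position_label,row,col,role,compound,dose_uM,replicate`.
#' [read_layout_csv()] reconstructs an identical layout (round trip is
#' identity).
#'
#' @param layout a `chip_layout`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_layout_csv <- function(layout, path) {
  stopifnot(inherits(layout, "chip_layout"))
  write.csv(layout$assignments, path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

#' Read a chip layout from CSV
#'
#' @param path CSV written by [write_layout_csv()].
#' @return a `chip_layout`.
#' @export
read_layout_csv <- function(path) {
  asg <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(position_label = "character",
                                 row = "integer", col = "integer",
                                 role = "character", compound = "character",
                                 dose_uM = "numeric", replicate = "integer"))
  asg$compound[asg$compound == ""] <- NA_character_
  grid <- c(max(asg$row), max(asg$col))
  if (nrow(asg) != prod(grid))
    abort("layout CSV has %d rows but grid %d x %d", nrow(asg), grid[1],
          grid[2])
  structure(list(capacity = nrow(asg), grid = as.integer(grid),
                 assignments = asg),
            class = "chip_layout")
}
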