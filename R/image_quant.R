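# Synthetic chip-scan rendering and fixed-grid spot quantification.
# Spots sit on a regular grid known from the layout, so segmentation is
# geometric (no blob detection); the per-spot summary is the median (robust
# to debris) with a local annulus background.

.CHANNELS <- c("DAPI", "EpCAM", "vimentin", "marker", "calcein")

#' Construct a single-channel chip image
#'
#' @param pixels integer-valued matrix in the 16-bit range \[0, 65535\].
#' @param channel one of `"DAPI"`, `"EpCAM"`, `"vimentin"`, `"marker"`,
#'   `"calcein"`.
#' @param pixel_size physical size of a pixel (arbitrary units, metadata
#'   only).
#' @return a `channel_image` (matrix with `channel` and `pixel_size`
#'   attributes).
#' @export
channel_image <- function(pixels, channel, pixel_size = 1) {
  channel <- match.arg(channel, .CHANNELS)
  if (any(pixels < 0) || any(pixels > 65535))
    abort("pixel values must be within the 16-bit range [0, 65535]")
  structure(pixels, channel = channel, pixel_size = pixel_size,
            class = c("channel_image", "matrix", "array"))
}

# spot centers (px) for a layout on a regular grid with given pitch
.spot_centers <- function(layout, pitch) {
  asg <- layout$assignments
  data.frame(position_label = asg$position_label,
             y = (asg$row - 0.5) * pitch,
             x = (asg$col - 0.5) * pitch)
}

#' Render synthetic per-channel chip scans
#'
#' Draws one circular spot per layout position at the requested intensity on
#' a constant background, applies a Gaussian point-spread blur, and (when
#' `noise = TRUE`) replaces each pixel by a Poisson draw with that mean —
#' the shot-noise model of a photon-counting scanner. Deterministic per seed.
#'
#' @param layout a `chip_layout`.
#' @param intensities data.frame with columns `position_label`, `channel`,
#'   `rfu`; every layout position must appear once per rendered channel.
#' @param spot_radius spot radius in px; must be < `pitch / 2`.
#' @param psf_sigma Gaussian blur sigma in px (0 disables blur).
#' @param background_level constant background (RFU).
#' @param pitch center-to-center spot spacing in px.
#' @param noise add Poisson shot noise?
#' @param seed integer RNG seed.
#' @return named list of `channel_image`s, one per channel present in
#'   `intensities`.
#' @export
render_chip_image <- function(layout, intensities, spot_radius = 8,
                              psf_sigma = 1, background_level = 100,
                              pitch = 24, noise = TRUE, seed = 1) {
  stopifnot(inherits(layout, "chip_layout"))
  need <- c("position_label", "channel", "rfu")
  if (!all(need %in% names(intensities)))
    abort("intensities needs columns %s", paste(need, collapse = ", "))
  if (spot_radius >= pitch / 2)
    abort("spot_radius %g too large for grid pitch %g (needs < pitch/2)",
          spot_radius, pitch)
  centers <- .spot_centers(layout, pitch)
  dims <- c(layout$grid[1] * pitch, layout$grid[2] * pitch)
  # disk pixel offsets, reused for every spot
  off <- expand.grid(dy = -ceiling(spot_radius):ceiling(spot_radius),
                     dx = -ceiling(spot_radius):ceiling(spot_radius))
  off <- off[off$dy^2 + off$dx^2 <= spot_radius^2, ]

  out <- list()
  for (ch in unique(intensities$channel)) {
    sub <- intensities[intensities$channel == ch, ]
    missing <- setdiff(centers$position_label, sub$position_label)
    if (length(missing) > 0)
      abort("channel %s: no intensity for position(s) %s", ch,
            paste(utils::head(missing, 3), collapse = ", "))
    img <- matrix(background_level, dims[1], dims[2])
    rfu <- sub$rfu[match(centers$position_label, sub$position_label)]
    for (k in seq_len(nrow(centers))) {
      if (rfu[k] == 0) next
      yy <- round(centers$y[k] + off$dy)
      xx <- round(centers$x[k] + off$dx)
      keep <- yy >= 1 & yy <= dims[1] & xx >= 1 & xx <= dims[2]
      img[cbind(yy[keep], xx[keep])] <- img[cbind(yy[keep], xx[keep])] +
        rfu[k]
    }
    if (psf_sigma > 0)
      img <- as.matrix(EBImage::gblur(img, sigma = psf_sigma,
                                      boundary = background_level))
    if (noise)
      img <- with_seed(seed + match(ch, .CHANNELS),
                       matrix(rpois(length(img), pmax(img, 0)),
                              dims[1], dims[2]))
    img <- pmin(pmax(round(img), 0), 65535)
    out[[ch]] <- channel_image(img, ch)
  }
  out
}

#' Quantify per-spot fluorescence on a fixed grid
#'
#' For every layout position: `raw_median` is the median pixel inside the
#' spot disk, `background` the median of a concentric annulus, and
#' `corrected = max(raw_median - background, 0)`. Quantification is invariant
#' to adding a constant to the whole image, and the median summary tolerates
#' up to half the spot pixels being corrupted by saturating debris.
#'
#' @param image a `channel_image` (or plain matrix).
#' @param layout the `chip_layout` the image was rendered from.
#' @param spot_radius spot mask radius (px).
#' @param bg_annulus `c(inner, outer)` annulus radii (px); `outer` must not
#'   reach a neighbouring spot, i.e. `outer <= pitch - spot_radius`.
#' @param pitch grid pitch used at render time (px).
#' @return data.frame with columns `position_label`, `channel`, `role`,
#'   `raw_median`, `background`, `corrected`.
#' @export
quantify_spots <- function(image, layout, spot_radius = 8,
                           bg_annulus = c(10, 14), pitch = 24) {
  stopifnot(inherits(layout, "chip_layout"))
  if (bg_annulus[1] <= spot_radius)
    abort("annulus inner radius must exceed spot_radius")
  if (bg_annulus[2] <= bg_annulus[1])
    abort("annulus outer radius must exceed inner radius")
  if (bg_annulus[2] > pitch - spot_radius)
    abort("annulus (outer %g px) overlaps a neighbouring spot at pitch %g",
          bg_annulus[2], pitch)
  dims <- dim(image)
  if (dims[1] < layout$grid[1] * pitch || dims[2] < layout$grid[2] * pitch)
    abort("grid (%d x %d, pitch %g) does not fit inside the %d x %d image",
          layout$grid[1], layout$grid[2], pitch, dims[1], dims[2])
  centers <- .spot_centers(layout, pitch)
  rmax <- ceiling(bg_annulus[2])
  off <- expand.grid(dy = -rmax:rmax, dx = -rmax:rmax)
  r2 <- off$dy^2 + off$dx^2
  spot_off <- off[r2 <= spot_radius^2, ]
  ann_off <- off[r2 > bg_annulus[1]^2 & r2 <= bg_annulus[2]^2, ]

  grab <- function(cy, cx, o) {
    yy <- round(cy + o$dy); xx <- round(cx + o$dx)
    keep <- yy >= 1 & yy <= dims[1] & xx >= 1 & xx <= dims[2]
    image[cbind(yy[keep], xx[keep])]
  }
  raw <- bg <- numeric(nrow(centers))
  for (k in seq_len(nrow(centers))) {
    raw[k] <- median(grab(centers$y[k], centers$x[k], spot_off))
    bg[k] <- median(grab(centers$y[k], centers$x[k], ann_off))
  }
  data.frame(position_label = centers$position_label,
             channel = attr(image, "channel") %||% NA_character_,
             role = layout$assignments$role,
             raw_median = raw, background = bg,
             corrected = pmax(raw - bg, 0),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a channel image as 16-bit grayscale TIFF
#'
#' @param image a `channel_image`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(image, path) {
  tiff::writeTIFF(unclass(image) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a 16-bit grayscale TIFF as a channel image
#'
#' @param path TIFF path.
#' @param channel channel name to attach.
#' @return a `channel_image`.
#' @export
read_channel_tiff <- function(path, channel = "calcein") {
  px <- tiff::readTIFF(path)
  channel_image(round(px * 65535), channel)
}
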