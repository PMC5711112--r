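.film_models <- c("XRQA2", "EBT3")
.timepoints  <- c("before", "after")
.channels    <- c("red", "green", "blue")

#' Construct a film scan object
#'
#' A `film_scan` holds one flatbed-scanner image of a film piece as three
#' 16-bit channel planes plus the metadata needed for dosimetry: spatial
#' resolution, film model, scan timepoint (before or 24 h after exposure),
#' and production lot.
#'
#' @param pixels numeric array `[rows, cols, 3]` (red, green, blue), values
#'   in `[0, 65535]`.
#' @param resolution_mm_per_px scan resolution, mm per pixel (reference
#'   protocol value 0.2).
#' @param film_model `"XRQA2"` (reflective, kV) or `"EBT3"` (transmissive, MV).
#' @param timepoint `"before"` or `"after"`.
#' @param lot_id film production lot identifier.
#' @return object of class `film_scan`.
#' @export
film_scan <- function(pixels, resolution_mm_per_px, film_model, timepoint,
                      lot_id = "") {
  film_model <- match.arg(film_model, .film_models)
  timepoint <- match.arg(timepoint, .timepoints)
  if (length(dim(pixels)) == 2)
    pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  if (!is.finite(resolution_mm_per_px) || resolution_mm_per_px <= 0)
    stop("resolution_mm_per_px must be strictly positive", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 65535)
    stop("pixel values must lie in [0, 65535]", call. = FALSE)
  structure(list(pixels = pixels,
                 resolution_mm_per_px = resolution_mm_per_px,
                 film_model = film_model,
                 timepoint = timepoint,
                 lot_id = lot_id),
            class = "film_scan")
}

#' @export
print.film_scan <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("film_scan: %s (%s), %d x %d px at %.3g mm/px (%.1f x %.1f mm), lot '%s'\n",
              x$film_model, x$timepoint, d[1], d[2], x$resolution_mm_per_px,
              (d[1] - 1) * x$resolution_mm_per_px + x$resolution_mm_per_px,
              (d[2] - 1) * x$resolution_mm_per_px + x$resolution_mm_per_px,
              x$lot_id))
  invisible(x)
}

#' Physical extent of a scan in mm
#'
#' @param scan a `film_scan`.
#' @return c(width_mm, height_mm), pixel-extent convention (n * resolution).
#' @export
scan_extent_mm <- function(scan) {
  d <- dim(scan$pixels)
  c(width_mm = d[2] * scan$resolution_mm_per_px,
    height_mm = d[1] * scan$resolution_mm_per_px)
}

#' Read a 48-bit RGB scanner image
#'
#' Decodes a TIFF scan, checks it carries 16 bits per channel, separates the
#' colour planes, and attaches dosimetry metadata.  Resolution is taken from
#' the file's resolution tags when present (unit inch), otherwise from the
#' `resolution_mm_per_px` argument, which is then required.
#'
#' @param path TIFF file path.
#' @inheritParams film_scan
#' @param resolution_mm_per_px fallback resolution when the file has no
#'   usable resolution tag.
#' @return a [film_scan].
#' @export
load_scan <- function(path, film_model, timepoint,
                      resolution_mm_per_px = NULL, lot_id = "") {
  if (!file.exists(path)) stop("cannot read scan file: ", path, call. = FALSE)
  img <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(img, "bits.per.sample")
  if (is.null(bits) || any(bits != 16))
    stop("expected 16 bits per sample, found ",
         paste(unique(bits), collapse = "/"), "-bit data", call. = FALSE)
  if (length(dim(img)) != 3 || dim(img)[3] < 3)
    stop("expected an RGB image, found ",
         if (length(dim(img)) == 2) 1 else dim(img)[3], " channel(s)",
         call. = FALSE)
  res <- resolution_mm_per_px
  xres <- attr(img, "x.resolution")
  unit <- attr(img, "resolution.unit")
  if (!is.null(xres) && is.finite(xres) && xres > 0 &&
      (is.null(unit) || identical(unit, "inch")))
    res <- 25.4 / xres
  if (is.null(res))
    stop("file carries no resolution tag; supply resolution_mm_per_px",
         call. = FALSE)
  # readTIFF scales to [0, 1]; restore the native 16-bit integer scale
  film_scan(round(img[, , 1:3, drop = FALSE] * 65535), res, film_model,
            timepoint, lot_id)
}

#' Write a film scan as a 16-bit RGB TIFF
#'
#' @param scan a [film_scan].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "film_scan"))
  tiff::writeTIFF(scan$pixels / 65535, path, bits.per.sample = 16,
                  compression = "none")
  invisible(path)
}

#' Sample pixel statistics over a square ROI
#'
#' Computes the mean and population SD of pixel values of one channel over
#' an axis-aligned square region of interest.  A pixel belongs to the ROI
#' iff its centre lies in the closed square.  Coordinates: origin at the
#' top-left pixel centre, x rightward, y downward, in mm.  The reference
#' protocol samples the red channel over a 1 x 1 mm ROI (25 pixels at
#' 0.2 mm/px).
#'
#' @param scan a [film_scan].
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @param center_mm numeric length-2, ROI centre `(x, y)` in mm.
#' @param side_mm ROI edge length in mm (default 1).
#' @return object of class `roi_sample` with `mean_pv`, `sd_pv`
#'   (population SD), `n_px`, geometry, and scan metadata.
#' @export
sample_roi <- function(scan, channel = "red", center_mm, side_mm = 1) {
  stopifnot(inherits(scan, "film_scan"), length(center_mm) == 2, side_mm > 0)
  channel <- match.arg(channel, .channels)
  res <- scan$resolution_mm_per_px
  d <- dim(scan$pixels)
  half <- side_mm / 2
  # ROI must lie fully inside the physical pixel extent (no silent clipping)
  lim_x <- c(-res / 2, (d[2] - 1) * res + res / 2)
  lim_y <- c(-res / 2, (d[1] - 1) * res + res / 2)
  if (center_mm[1] - half < lim_x[1] - 1e-9 || center_mm[1] + half > lim_x[2] + 1e-9 ||
      center_mm[2] - half < lim_y[1] - 1e-9 || center_mm[2] + half > lim_y[2] + 1e-9)
    stop("ROI extends beyond the scanned area", call. = FALSE)
  xc <- (seq_len(d[2]) - 1) * res
  yc <- (seq_len(d[1]) - 1) * res
  jx <- which(xc >= center_mm[1] - half - 1e-9 & xc <= center_mm[1] + half + 1e-9)
  iy <- which(yc >= center_mm[2] - half - 1e-9 & yc <= center_mm[2] + half + 1e-9)
  px <- scan$pixels[iy, jx, match(channel, .channels)]
  n <- length(px)
  m <- mean(px)
  structure(list(center_mm = as.numeric(center_mm), side_mm = side_mm,
                 mean_pv = m,
                 sd_pv = sqrt(mean((px - m)^2)),  # population SD
                 n_px = n,
                 channel = channel,
                 film_model = scan$film_model,
                 timepoint = scan$timepoint,
                 lot_id = scan$lot_id),
            class = "roi_sample")
}

#' @export
print.roi_sample <- function(x, ...) {
  cat(sprintf("roi_sample: %s/%s %s channel, %d px at (%.1f, %.1f) mm: PV %.1f +/- %.1f\n",
              x$film_model, x$timepoint, x$channel, x$n_px,
              x$center_mm[1], x$center_mm[2], x$mean_pv, x$sd_pv))
  invisible(x)
}

#' Read a ROI manifest
#'
#' JSON array of objects with fields `label`, `before`, `after` (scan file
#' names), `center_mm` (length-2), `side_mm`, and optional `channel`.
#'
#' @param path manifest file path.
#' @return data.frame, one row per ROI.
#' @export
read_roi_manifest <- function(path) {
  m <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  need <- c("label", "before", "after", "center_mm", "side_mm")
  if (!all(need %in% names(m)))
    stop("manifest missing fields: ",
         paste(setdiff(need, names(m)), collapse = ", "), call. = FALSE)
  if (is.null(m$channel)) m$channel <- "red"
  m
}
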