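# 1D dose profiles from film strips, surface-dose tables, extrema and
# asymmetry summaries.

.aspects <- c("Ant", "Post", "Left", "Right")
.machines <- c("OBI_21eX", "OBI_TrueBeam", "CyberKnife", "TomoTherapy")
.sites <- c("head", "thorax", "pelvis")

#' Assemble a 1D dose profile
#'
#' Orders dose points by position along the strip axis.  Positions are mm
#' from the machine isocenter projected onto the strip; on the vertical
#' axis positive is anterior, on the lateral axis positive is the
#' phantom's left.
#'
#' @param points data.frame of dose-point rows with `position_mm` set.
#' @param axis `"lateral"` or `"vertical"`.
#' @param site anatomical site tag.
#' @param origin position-convention tag.
#' @return object of class `dose_profile`.
#' @export
build_profile <- function(points, axis = c("lateral", "vertical"),
                          site = NA_character_, origin = "isocenter") {
  axis <- match.arg(axis)
  stopifnot(is.data.frame(points), nrow(points) >= 2)
  if (any(!is.finite(points$position_mm)))
    stop("profile points need finite positions", call. = FALSE)
  if (anyDuplicated(points$position_mm))
    stop("duplicate profile positions", call. = FALSE)
  if (any(points$dose_cgy < 0))
    stop("profile doses must be nonnegative", call. = FALSE)
  pts <- points[order(points$position_mm), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(axis = axis, site = site, origin = origin, points = pts),
            class = "dose_profile")
}

#' @export
print.dose_profile <- function(x, ...) {
  ex <- profile_extrema(x)
  cat(sprintf("dose_profile (%s, %s): %d points on [%.1f, %.1f] mm, max %.3g cGy at %.1f mm\n",
              x$axis, x$site, nrow(x$points), min(x$points$position_mm),
              max(x$points$position_mm), ex$max$dose_cgy, ex$max$position_mm))
  invisible(x)
}

#' Profile extrema
#'
#' @param profile a [build_profile()] result.
#' @return list with `min` and `max` dose-point rows; ties broken by the
#'   smallest position.
#' @export
profile_extrema <- function(profile) {
  stopifnot(inherits(profile, "dose_profile"))
  p <- profile$points  # already position-sorted, so which.min/max take
  list(min = p[which.min(p$dose_cgy), , drop = FALSE],   # the smallest position
       max = p[which.max(p$dose_cgy), , drop = FALSE])
}

#' Signed profile asymmetry statistic
#'
#' `(mean dose at positive positions - mean at negative) / overall mean`.
#' Positive values mean anterior (vertical axis) or left (lateral axis)
#' excess.  A mirrored profile flips the sign exactly.
#'
#' @param profile a [build_profile()] result spanning both sides of the
#'   origin.
#' @return signed dimensionless statistic.
#' @export
asymmetry_summary <- function(profile) {
  stopifnot(inherits(profile, "dose_profile"))
  p <- profile$points
  pos <- p$dose_cgy[p$position_mm > 0]
  neg <- p$dose_cgy[p$position_mm < 0]
  if (!length(pos) || !length(neg))
    stop("profile must span both sides of the origin", call. = FALSE)
  (mean(pos) - mean(neg)) / mean(p$dose_cgy)
}

# decimal rounding, half away from zero (ordinary table rounding)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-6) / p
}

#' Format a surface-dose cell as mean +/- SE
#'
#' Two decimals, half-up rounding, e.g. `"0.50±0.01"`.
#'
#' @param dose_cgy,sigma_cgy mean dose and standard error in cGy.
#' @return character cell.
#' @export
format_dose_cell <- function(dose_cgy, sigma_cgy) {
  sprintf("%.2f±%.2f", round_half_up(dose_cgy), round_half_up(sigma_cgy))
}

#' Parse a formatted surface-dose cell
#'
#' @param cell character like `"0.50±0.01"`.
#' @return numeric c(dose_cgy, sigma_cgy).
#' @export
parse_dose_cell <- function(cell) {
  parts <- strsplit(cell, "±", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed dose cell: ", cell, call. = FALSE)
  c(dose_cgy = as.numeric(parts[1]), sigma_cgy = as.numeric(parts[2]))
}

#' Surface-dose table
#'
#' Lays out aggregated surface dose points as a site x aspect by machine
#' table of formatted `mean±SE` cells (two decimals).  Missing
#' machine/site/aspect combinations become empty cells with a warning.
#'
#' @param points data.frame of aggregated dose-point rows with `machine`,
#'   `site`, `aspect`, `dose_cgy`, `sigma_cgy`; one row per combination.
#' @param machines column order (default the four reference systems).
#' @return data.frame with columns `site`, `aspect`, and one formatted
#'   column per machine.
#' @export
surface_dose_table <- function(points, machines = .machines) {
  stopifnot(is.data.frame(points))
  sites <- intersect(.sites, unique(points$site))
  grid <- expand.grid(aspect = .aspects, site = sites,
                      stringsAsFactors = FALSE)[, c("site", "aspect")]
  out <- grid
  for (m in machines) {
    cells <- character(nrow(grid))
    for (i in seq_len(nrow(grid))) {
      row <- points[points$machine == m & points$site == grid$site[i] &
                    points$aspect == grid$aspect[i], ]
      if (nrow(row) == 1) {
        cells[i] <- format_dose_cell(row$dose_cgy, row$sigma_cgy)
      } else if (nrow(row) == 0) {
        warning("no surface dose for ", m, "/", grid$site[i], "/",
                grid$aspect[i], call. = FALSE)
        cells[i] <- ""
      } else {
        stop("multiple unaggregated rows for ", m, "/", grid$site[i], "/",
             grid$aspect[i], call. = FALSE)
      }
    }
    out[[m]] <- cells
  }
  out
}

#' Render a surface-dose table as plain text
#'
#' @param table output of [surface_dose_table()].
#' @return character vector of lines, invisibly; printed to the console.
#' @export
render_surface_dose_table <- function(table) {
  widths <- vapply(names(table), function(n) max(nchar(c(n, table[[n]]))),
                   numeric(1))
  fmt_row <- function(vals) paste(mapply(formatC, vals, width = widths,
                                         flag = "-"), collapse = "  ")
  lines <- c(fmt_row(names(table)),
             apply(table, 1, fmt_row))
  cat(lines, sep = "\n")
  invisible(lines)
}
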