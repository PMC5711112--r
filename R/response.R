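# film response extraction: netDeltaR (XRQA2, reflective) and netDeltaOD
# (EBT3, transmissive) from paired before/after ROI statistics.

.check_pair <- function(before, after, film_model) {
  stopifnot(inherits(before, "roi_sample"), inherits(after, "roi_sample"))
  if (before$film_model != film_model || after$film_model != film_model)
    stop("ROI pair is not from ", film_model, " scans", call. = FALSE)
  if (!identical(before$lot_id, after$lot_id))
    stop("before/after ROIs come from different film lots ('",
         before$lot_id, "' vs '", after$lot_id, "')", call. = FALSE)
  if (before$timepoint != "before" || after$timepoint != "after")
    stop("ROI pair must be one 'before' and one 'after' sample", call. = FALSE)
  if (before$channel != "red" || after$channel != "red")
    warning("film response is defined on the red channel; got ",
            before$channel, "/", after$channel, call. = FALSE)
}

.response_measurement <- function(kind, value, sigma, before, after, label) {
  structure(list(response_kind = kind, value = value, sigma_y = sigma,
                 before = before, after = after, label = label),
            class = "response_measurement")
}

#' Net reflectance change of an XRQA2 film piece
#'
#' `netDeltaR = (PV_before - PV_after) / 2^16` on the red channel, with the
#' one-sigma response uncertainty from the two ROI-mean standard errors
#' (`sd/sqrt(n)` each, independent pixels) summed in quadrature.
#'
#' @param before,after red-channel [sample_roi()] results from the
#'   before/after scans of the same XRQA2 piece.
#' @param label measurement label.
#' @return object of class `response_measurement` with `value` and `sigma_y`.
#' @export
net_delta_R <- function(before, after, label = "") {
  .check_pair(before, after, "XRQA2")
  value <- (before$mean_pv - after$mean_pv) / 65536
  sigma <- sqrt(before$sd_pv^2 / before$n_px + after$sd_pv^2 / after$n_px) / 65536
  .response_measurement("net_delta_R", value, sigma, before, after, label)
}

#' Net optical density change of an EBT3 film piece
#'
#' `netDeltaOD = log10(PV_before / PV_after)` on the red channel;
#' `sigma_y` by first-order propagation of the two ROI-mean standard errors
#' through the log ratio.
#'
#' @inheritParams net_delta_R
#' @return object of class `response_measurement`.
#' @export
net_delta_OD <- function(before, after, label = "") {
  .check_pair(before, after, "EBT3")
  if (after$mean_pv <= 0)
    stop("after-exposure mean PV must be positive for an optical density",
         call. = FALSE)
  value <- log10(before$mean_pv / after$mean_pv)
  se_b <- before$sd_pv / sqrt(before$n_px)
  se_a <- after$sd_pv / sqrt(after$n_px)
  sigma <- sqrt((se_b / before$mean_pv)^2 + (se_a / after$mean_pv)^2) / log(10)
  .response_measurement("net_delta_OD", value, sigma, before, after, label)
}

#' @export
print.response_measurement <- function(x, ...) {
  cat(sprintf("%s '%s': %.6g +/- %.2g\n", x$response_kind, x$label,
              x$value, x$sigma_y))
  invisible(x)
}

#' Film response for a given film model
#'
#' Dispatches to [net_delta_R()] (XRQA2) or [net_delta_OD()] (EBT3).
#'
#' @inheritParams net_delta_R
#' @param film_model `"XRQA2"` or `"EBT3"`.
#' @return object of class `response_measurement`.
#' @export
film_response <- function(before, after, film_model, label = "") {
  switch(match.arg(film_model, .film_models),
         XRQA2 = net_delta_R(before, after, label),
         EBT3 = net_delta_OD(before, after, label))
}

#' Write a response table to CSV
#'
#' @param responses list of `response_measurement` objects.
#' @param path output CSV path.
#' @return the table, invisibly.
#' @export
write_response_table <- function(responses, path) {
  tab <- do.call(rbind, lapply(responses, function(r)
    data.frame(label = r$label, kind = r$response_kind,
               value = r$value, sigma = r$sigma_y,
               before_mean_pv = r$before$mean_pv,
               after_mean_pv = r$after$mean_pv)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
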