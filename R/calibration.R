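# dose-response calibration: y = (a + c x) / (1 + b x)
#
# "general" fits all three parameters; "constrained" forces a = 0, the
# physically motivated form (zero dose must give zero response).  The
# constrained form removes the poorly determined intercept and markedly
# reduces the propagated dose uncertainty at low dose.

.model_forms <- c("constrained", "general")
.response_kinds <- c("net_delta_R", "net_delta_OD")
.dose_quantities <- c("air_kerma_in_air", "dose_to_water")

#' Construct a calibration model
#'
#' @param form `"constrained"` (a fixed at 0) or `"general"`.
#' @param a,b,c rational-function parameters; `a` must be 0 when
#'   `form = "constrained"`.
#' @param covariance symmetric covariance matrix over the free parameters,
#'   dimnames `c("b","c")` (constrained) or `c("a","b","c")` (general).
#'   Defaults to zero (an exact model).
#' @param response_kind `"net_delta_R"` or `"net_delta_OD"`.
#' @param dose_quantity `"air_kerma_in_air"` (XRQA2) or `"dose_to_water"`
#'   (EBT3).
#' @param valid_dose_range numeric length-2, calibrated dose range in cGy.
#' @return object of class `calibration_model`.
#' @export
calibration_model <- function(form, a = 0, b, c, covariance = NULL,
                              response_kind = "net_delta_R",
                              dose_quantity = "air_kerma_in_air",
                              valid_dose_range = c(0, 10)) {
  form <- match.arg(form, .model_forms)
  response_kind <- match.arg(response_kind, .response_kinds)
  dose_quantity <- match.arg(dose_quantity, .dose_quantities)
  if (form == "constrained" && a != 0)
    stop("constrained form requires a = 0", call. = FALSE)
  free <- if (form == "constrained") c("b", "c") else c("a", "b", "c")
  if (is.null(covariance)) {
    covariance <- matrix(0, length(free), length(free),
                         dimnames = list(free, free))
  }
  covariance <- as.matrix(covariance)
  if (!isTRUE(all.equal(dim(covariance), rep(length(free), 2))))
    stop("covariance must be ", length(free), "x", length(free),
         " for the ", form, " form", call. = FALSE)
  if (max(abs(covariance - t(covariance))) > 1e-12 * max(1, max(abs(covariance))))
    stop("covariance must be symmetric", call. = FALSE)
  if (any(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values <
          -1e-10 * max(1, max(abs(covariance)))))
    stop("covariance must be positive semi-definite", call. = FALSE)
  dimnames(covariance) <- list(free, free)
  if (c <= 0) stop("parameter c must be positive", call. = FALSE)
  hi <- max(valid_dose_range)
  if (1 + b * hi <= 0)
    stop("1 + b*x must stay positive over the valid dose range", call. = FALSE)
  if (c - a * b <= 0)
    stop("model must be strictly increasing over the valid range (c - a*b > 0)",
         call. = FALSE)
  structure(list(form = form, a = a, b = b, c = c, covariance = covariance,
                 response_kind = response_kind, dose_quantity = dose_quantity,
                 valid_dose_range = as.numeric(sort(valid_dose_range))),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("calibration_model (%s): y = (a + c x)/(1 + b x)\n", x$form))
  cat(sprintf("  a = %.6g  b = %.6g  c = %.6g\n", x$a, x$b, x$c))
  cat(sprintf("  %s vs %s, valid on [%.3g, %.3g] cGy, saturation at c/b = %.4g\n",
              x$response_kind, x$dose_quantity,
              x$valid_dose_range[1], x$valid_dose_range[2],
              if (x$b > 0) x$c / x$b else Inf))
  invisible(x)
}

.free_params <- function(model) {
  if (model$form == "constrained") c(b = model$b, c = model$c)
  else c(a = model$a, b = model$b, c = model$c)
}

#' Fit the rational dose-response calibration
#'
#' Weighted nonlinear least squares of `y = (a + c x)/(1 + b x)` with
#' weights `1/sigma_y^2` (unweighted when all `sigma_y` are zero or
#' missing).  Starting values come from the exact linearisation
#' `y = a + c x - b (x y)` solved by ordinary least squares; the
#' Levenberg-Marquardt refinement then minimises the weighted residual.
#' The parameter covariance is `(J' W J)^{-1}` from the analytic Jacobian
#' at the optimum; for unweighted fits it is scaled by the reduced
#' chi-square, for weighted fits the supplied `sigma_y` already set the
#' scale and no rescaling is applied.
#'
#' @param points data.frame with columns `dose` (cGy), `response`, and
#'   optionally `sigma_y`.
#' @param form `"constrained"` (a = 0) or `"general"`.
#' @param response_kind,dose_quantity stored on the returned model.
#' @return a [calibration_model] with `fit` attributes: per-parameter
#'   one-sigma uncertainties (`sigma_params`), relative uncertainties in
#'   percent (`rel_unc_pct`), residual norm and degrees of freedom.
#' @export
fit_calibration <- function(points, form = c("constrained", "general"),
                            response_kind = "net_delta_R",
                            dose_quantity = "air_kerma_in_air") {
  form <- match.arg(form)
  stopifnot(is.data.frame(points), all(c("dose", "response") %in% names(points)))
  x <- points$dose; y <- points$response
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x < 0))
    stop("doses must be finite and nonnegative, responses finite", call. = FALSE)
  n_min <- if (form == "constrained") 3L else 4L
  if (length(x) < n_min)
    stop("need at least ", n_min, " calibration points for the ", form,
         " form", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("degenerate calibration design: all doses equal", call. = FALSE)
  sy <- points$sigma_y
  weighted <- !is.null(sy) && any(sy > 0)
  if (weighted && any(sy <= 0))
    stop("weighting requires sigma_y > 0 for every point (or all zero for ",
         "an unweighted fit)", call. = FALSE)
  w <- if (weighted) 1 / sy^2 else rep(1, length(x))

  # start values from the exact linearisation y (1 + b x) = a + c x
  xy <- x * y
  start <- tryCatch({
    if (form == "constrained") {
      cf <- stats::coef(stats::lm(y ~ 0 + x + xy, weights = w))
      list(b = unname(-cf["xy"]), c = unname(cf["x"]))
    } else {
      cf <- stats::coef(stats::lm(y ~ x + xy, weights = w))
      list(a = unname(cf["(Intercept)"]), b = unname(-cf["xy"]),
           c = unname(cf["x"]))
    }
  }, error = function(e) if (form == "constrained") list(b = 0.1, c = 0.1)
                         else list(a = 0, b = 0.1, c = 0.1))
  if (!all(vapply(start, is.finite, logical(1))))
    start <- if (form == "constrained") list(b = 0.1, c = 0.1)
             else list(a = 0, b = 0.1, c = 0.1)

  dat <- data.frame(x = x, y = y)
  fit <- tryCatch({
    if (form == "constrained")
      minpack.lm::nlsLM(y ~ c * x / (1 + b * x), data = dat, start = start,
                        weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ (a + c * x) / (1 + b * x), data = dat,
                        start = start, weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) {
    res0 <- sqrt(sum(w * y^2))
    stop("calibration fit failed to converge (", conditionMessage(e),
         "); weighted residual norm at zero: ", signif(res0, 4), call. = FALSE)
  })
  cf <- stats::coef(fit)
  a <- if (form == "constrained") 0 else unname(cf["a"])
  b <- unname(cf["b"]); cc <- unname(cf["c"])

  den <- 1 + b * x
  if (any(den <= 0))
    stop("fitted model has a pole inside the calibrated range", call. = FALSE)
  if (cc - a * b <= 0)
    stop("fitted model rejected: not strictly increasing over the ",
         "calibrated range", call. = FALSE)

  # analytic Jacobian at the optimum, free-parameter order per form
  J <- if (form == "constrained")
    cbind(b = -cc * x^2 / den^2, c = x / den)
  else
    cbind(a = 1 / den, b = -(a + cc * x) * x / den^2, c = x / den)
  JtWJ <- crossprod(J * sqrt(w))
  cov_unscaled <- tryCatch(solve(JtWJ), error = function(e)
    stop("singular calibration design; parameter covariance undefined",
         call. = FALSE))
  resid <- y - (a + cc * x) / den
  dof <- length(x) - ncol(J)
  red_chisq <- if (dof > 0) sum(w * resid^2) / dof else NA_real_
  covm <- if (weighted) cov_unscaled else cov_unscaled * red_chisq
  covm <- (covm + t(covm)) / 2

  model <- calibration_model(form, a = a, b = b, c = cc, covariance = covm,
                             response_kind = response_kind,
                             dose_quantity = dose_quantity,
                             valid_dose_range = range(x))
  sig <- sqrt(diag(covm))
  model$fit <- list(sigma_params = sig,
                    rel_unc_pct = 100 * sig / abs(.free_params(model)),
                    residual_norm = sqrt(sum(w * resid^2)),
                    reduced_chisq = red_chisq,
                    n_points = length(x), weighted = weighted)
  model
}

#' Predicted film response at a dose
#'
#' Evaluates `(a + c x)/(1 + b x)`.  Doses outside the calibrated range are
#' allowed with a warning (imaging doses can sit near or below the bottom
#' of the calibrated range).
#'
#' @param model a [calibration_model].
#' @param dose dose in cGy (vectorised).
#' @return predicted response(s).
#' @export
predict_response <- function(model, dose) {
  stopifnot(inherits(model, "calibration_model"))
  den <- 1 + model$b * dose
  if (any(den <= 0))
    stop("dose beyond the model pole (1 + b*x <= 0)", call. = FALSE)
  out <- any(dose < model$valid_dose_range[1] - 1e-12 |
             dose > model$valid_dose_range[2] + 1e-12)
  if (out)
    warning("dose outside the calibrated range [",
            model$valid_dose_range[1], ", ", model$valid_dose_range[2],
            "] cGy; extrapolating", call. = FALSE)
  (model$a + model$c * dose) / den
}

#' Invert a response to dose (closed form)
#'
#' General form: `x = (y - a)/(c - b y)`; constrained: `x = y/(c - b y)`.
#' Responses at or beyond the saturation asymptote `c/b` are rejected.
#'
#' @param model a [calibration_model].
#' @param response measured response (vectorised).
#' @return dose(s) in cGy.
#' @export
invert_dose <- function(model, response) {
  stopifnot(inherits(model, "calibration_model"))
  den <- model$c - model$b * response
  if (any(den <= 0))
    stop("response at or beyond the saturation asymptote c/b = ",
         signif(model$c / model$b, 6), call. = FALSE)
  x <- (response - model$a) / den
  lo <- predict_response(model, model$valid_dose_range[1])
  hi <- predict_response(model, model$valid_dose_range[2])
  if (any(response < lo - 1e-12 | response > hi + 1e-12))
    warning("response outside the calibrated range; extrapolated dose",
            call. = FALSE)
  x
}

.calibration_schema <- "filmdose-calibration/1"

#' Save / load a calibration model as JSON
#'
#' Doubles are serialised at full precision, so save -> load -> save
#' round-trips to identical bytes.
#'
#' @param model a [calibration_model].
#' @param path JSON file path.
#' @return `save_calibration`: `path` invisibly; `load_calibration`: the
#'   restored [calibration_model].
#' @export
save_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  obj <- list(schema = .calibration_schema,
              form = model$form, a = model$a, b = model$b, c = model$c,
              covariance = model$covariance,
              free_params = colnames(model$covariance),
              response_kind = model$response_kind,
              dose_quantity = model$dose_quantity,
              valid_dose_range = model$valid_dose_range)
  # digits = I(17): shortest-unique decimal is not guaranteed by this
  # serializer, but 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$schema, .calibration_schema))
    stop("unrecognised calibration schema: ",
         if (is.null(obj$schema)) "<missing>" else obj$schema,
         " (expected ", .calibration_schema, ")", call. = FALSE)
  need <- c("form", "a", "b", "c", "covariance", "response_kind",
            "dose_quantity", "valid_dose_range")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("calibration file missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  covm <- as.matrix(obj$covariance)
  dimnames(covm) <- list(obj$free_params, obj$free_params)
  calibration_model(obj$form, a = obj$a, b = obj$b, c = obj$c,
                    covariance = covm, response_kind = obj$response_kind,
                    dose_quantity = obj$dose_quantity,
                    valid_dose_range = obj$valid_dose_range)
}
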