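#' Fit a lateral-flow standard curve
#'
#' Fits the line-intensity vs concentration dose-response for one hormone
#' from a spiked QC panel.  Two forms cover the two assay geometries:
#' \describe{
#'   \item{`"linear"`}{intensity = m*c + b, for sandwich-format strips (LH,
#'     FSH) whose line darkens with concentration; ordinary least squares.}
#'   \item{`"exponential"`}{intensity = A*exp(-k*c), for competitive-format
#'     strips (E1G, PdG) whose line fades with concentration; fitted by
#'     ordinary least squares on log-intensity vs concentration, so a single
#'     correlation coefficient is well defined for the fit.}
#' }
#' `r_value` is the signed Pearson correlation between concentration and the
#' (possibly log-transformed) intensity; competitive curves therefore have
#' negative `r_value`, and QC gates are applied to `|r|`.
#'
#' For the exponential form, points with non-positive intensity have no
#' log-transform and are rejected.
#'
#' @param concentration numeric vector of spiked concentrations (>= 0), at
#'   least 3 distinct values.
#' @param intensity numeric vector of line intensities, same length.
#' @param form `"linear"` or `"exponential"`.
#' @param hormone optional hormone label carried on the object.
#' @return An object of class `standard_curve` with fields `form`, `hormone`,
#'   `params` (named: `m`, `b` or `A`, `k`), `r_value`, `n`, `data`.
#' @examples
#' conc <- c(0, 5, 10, 20, 30, 40, 50)
#' sc <- fit_standard_curve(conc, 0.005 * conc + 0.05, form = "linear")
#' coef(sc)
#' predict(sc, concentration = 25)
#' @export
fit_standard_curve <- function(concentration, intensity,
                               form = c("linear", "exponential"),
                               hormone = NA_character_) {
  form <- match.arg(form)
  if (length(concentration) != length(intensity))
    stop("concentration and intensity must have the same length",
         call. = FALSE)
  ok <- is.finite(concentration) & is.finite(intensity)
  concentration <- concentration[ok]; intensity <- intensity[ok]
  if (any(concentration < 0))
    stop("negative concentration in panel", call. = FALSE)
  if (length(unique(concentration)) < 3L)
    stop("degenerate panel: fewer than 3 distinct concentrations",
         call. = FALSE)
  if (form == "exponential") {
    if (any(intensity <= 0))
      stop("non-positive intensity under exponential form", call. = FALSE)
    y <- log(intensity)
    fit <- stats::lm(y ~ concentration)
    params <- c(A = unname(exp(stats::coef(fit)[1L])),
                k = unname(-stats::coef(fit)[2L]))
    r <- stats::cor(concentration, y)
  } else {
    fit <- stats::lm(intensity ~ concentration)
    params <- c(m = unname(stats::coef(fit)[2L]),
                b = unname(stats::coef(fit)[1L]))
    r <- stats::cor(concentration, intensity)
  }
  structure(list(form = form, hormone = hormone, params = params,
                 r_value = r, n = length(concentration),
                 data = data.frame(concentration = concentration,
                                   intensity = intensity)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  eq <- if (x$form == "linear")
    sprintf("intensity = %.6g * c + %.6g", x$params["m"], x$params["b"])
  else
    sprintf("intensity = %.6g * exp(-%.6g * c)", x$params["A"], x$params["k"])
  cat(sprintf("Standard curve (%s%s, n = %d)\n  %s\n  r = %.6f  (|r| %s 0.9)\n",
              x$form,
              if (is.na(x$hormone)) "" else paste0(", ", x$hormone),
              x$n, eq, x$r_value,
              if (abs(x$r_value) > 0.9) ">" else "<="))
  invisible(x)
}

#' @export
coef.standard_curve <- function(object, ...) object$params

#' Predict line intensity from concentration
#'
#' @param object a [fit_standard_curve()] result.
#' @param concentration numeric vector of concentrations.
#' @param ... unused.
#' @return Predicted intensities.
#' @export
predict.standard_curve <- function(object, concentration, ...) {
  p <- object$params
  if (object$form == "linear") p["m"] * concentration + p["b"]
  else p["A"] * exp(-p["k"] * concentration)
}

#' @export
plot.standard_curve <- function(x, ...) {
  d <- x$data
  plot(d$concentration, d$intensity,
       xlab = "concentration", ylab = "line intensity",
       main = sprintf("%s standard curve%s", x$form,
                      if (is.na(x$hormone)) "" else paste0(" (", x$hormone, ")")),
       ...)
  cs <- seq(min(d$concentration), max(d$concentration), length.out = 200)
  graphics::lines(cs, predict(x, cs))
  invisible(x)
}

#' Invert a standard curve: concentration from line intensity
#'
#' Linear: c = (I - b) / m.  Exponential: c = log(A / I) / k.  The result is
#' clamped below at 0 (an intensity beyond the blank reads as concentration
#' zero, not negative).
#'
#' @param curve a [fit_standard_curve()] result.
#' @param intensity numeric vector of line intensities (>= 0; strictly
#'   positive under the exponential form).
#' @return Concentrations on the hormone's scale.
#' @examples
#' sc <- fit_standard_curve(c(0, 10, 20, 30, 40), 0.005 * c(0, 10, 20, 30, 40) + 0.05)
#' invert_curve(sc, 0.175)   # 25
#' @export
invert_curve <- function(curve, intensity) {
  if (!inherits(curve, "standard_curve"))
    stop("invert_curve() expects a standard_curve", call. = FALSE)
  if (any(intensity < 0)) stop("negative intensity", call. = FALSE)
  p <- curve$params
  if (curve$form == "linear") {
    if (p["m"] == 0) stop("degenerate curve: zero slope", call. = FALSE)
    conc <- (intensity - p["b"]) / p["m"]
  } else {
    if (any(intensity == 0))
      stop("undefined inverse: zero intensity under exponential form",
           call. = FALSE)
    conc <- log(p["A"] / intensity) / p["k"]
  }
  unname(pmax(conc, 0))
}
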