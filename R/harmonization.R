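# Cross-assay harmonization of succinylacetone (SA).
#
# The Dutch screening programme measured SA with the NeoBase assay
# (2008-2017) and the NeoBase 2 assay (2018-). The two assays differ
# systematically, so NeoBase-era concentrations must be placed on the
# NeoBase 2 scale before they can be compared against current cut-off
# values. The published mapping, obtained by Deming method-comparison
# regression on 1093 residual screening specimens and QC samples, is
#   NeoBase2 = 0.019 + 0.572 x NeoBase.

#' Linear cross-assay conversion model
#'
#' A straight-line mapping from one assay scale to another, as produced by
#' method-comparison (Deming) regression in clinical chemistry.
#'
#' @param slope dimensionless slope; must be positive.
#' @param intercept intercept in umol/L blood.
#' @param variance_ratio assumed ratio of measurement-error variances
#'   (y-error over x-error) under which the line was fitted; must be
#'   positive. 1 corresponds to orthogonal regression.
#' @param n_pairs optional number of calibration pairs (provenance only).
#' @return an object of class `conversion_model`.
#' @seealso [neobase_conversion()], [fit_deming()], [convert_sa()]
#' @export
conversion_model <- function(slope, intercept, variance_ratio = 1,
                             n_pairs = NA_integer_) {
  stopifnot(is.numeric(slope), length(slope) == 1, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1, is.finite(intercept),
            is.numeric(variance_ratio), length(variance_ratio) == 1)
  if (slope <= 0) fail("conversion_model: slope must be > 0 (got %g)", slope)
  if (variance_ratio <= 0)
    fail("conversion_model: variance_ratio must be > 0 (got %g)", variance_ratio)
  structure(
    list(slope = slope, intercept = intercept,
         variance_ratio = variance_ratio, n_pairs = as.integer(n_pairs)),
    class = "conversion_model"
  )
}

#' @export
print.conversion_model <- function(x, ...) {
  cat(sprintf("Linear conversion model: y = %g + %g * x\n", x$intercept, x$slope))
  cat(sprintf("  assumed error-variance ratio: %g", x$variance_ratio))
  if (!is.na(x$n_pairs)) cat(sprintf("  (fitted on %d pairs)", x$n_pairs))
  cat("\n")
  invisible(x)
}

#' Published NeoBase to NeoBase 2 conversion for SA
#'
#' The conversion reported for the Dutch programme,
#' `NeoBase2 = 0.019 + 0.572 * NeoBase`, fitted by Deming regression on 1093
#' residual dried-blood-spot and quality-control samples. Shipped as a
#' constant because the underlying calibration pairs are not public.
#'
#' @return a [conversion_model()] with slope 0.572 and intercept 0.019.
#' @export
neobase_conversion <- function() {
  conversion_model(slope = 0.572, intercept = 0.019,
                   variance_ratio = 1, n_pairs = 1093L)
}

#' Deming errors-in-variables regression
#'
#' Closed-form Deming estimator for a method-comparison line when both the
#' reference (`x`) and the test (`y`) measurements carry error. With
#' `variance_ratio = 1` this is orthogonal regression; as
#' `variance_ratio` grows the estimate tends to ordinary least squares of
#' `y` on `x` (all error attributed to `y`).
#'
#' @param x,y paired non-negative measurements of the same specimens on the
#'   two assays (umol/L). At least 3 pairs, and `x` must vary.
#' @param variance_ratio assumed ratio of the y-measurement error variance
#'   to the x-measurement error variance.
#' @return a [conversion_model()] with the fitted slope and intercept.
#' @details
#' With centred second moments \eqn{s_{xx}, s_{yy}, s_{xy}} and error-variance
#' ratio \eqn{\delta}, the slope is
#' \deqn{\hat b = \frac{s_{yy} - \delta s_{xx} +
#'   \sqrt{(s_{yy} - \delta s_{xx})^2 + 4 \delta s_{xy}^2}}{2 s_{xy}},}
#' and the intercept is \eqn{\bar y - \hat b \bar x}. Noiseless collinear
#' input reproduces the generating line exactly for any `variance_ratio`.
#' @examples
#' x <- c(0.5, 1, 2, 4, 8)
#' fit_deming(x, 0.019 + 0.572 * x)
#' @export
fit_deming <- function(x, y, variance_ratio = 1) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y))
    fail("fit_deming: x and y must have equal length (%d vs %d)",
         length(x), length(y))
  keep <- is.finite(x) & is.finite(y)
  if (!all(keep)) fail("fit_deming: non-finite values in calibration pairs")
  if (any(x < 0) || any(y < 0))
    fail("fit_deming: measurements must be non-negative")
  n <- length(x)
  if (n < 3) fail("fit_deming: need at least 3 pairs, got %d", n)
  if (variance_ratio <= 0) fail("fit_deming: variance_ratio must be > 0")

  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2) / (n - 1)
  syy <- sum((y - my)^2) / (n - 1)
  sxy <- sum((x - mx) * (y - my)) / (n - 1)
  if (sxx <= 0)
    fail("fit_deming: x values are all identical; slope is unidentifiable")
  if (abs(sxy) < .Machine$double.eps * max(sxx, syy, 1))
    fail("fit_deming: zero covariance between methods; no line can be fitted")

  d <- variance_ratio
  # two algebraically equal forms; pick the one without cancellation so the
  # estimate stays accurate at extreme variance ratios (OLS limits)
  D <- syy - d * sxx
  R <- sqrt(D^2 + 4 * d * sxy^2)
  slope <- if (D >= 0) (D + R) / (2 * sxy) else (2 * d * sxy) / (R - D)
  intercept <- my - slope * mx
  conversion_model(slope = slope, intercept = intercept,
                   variance_ratio = variance_ratio, n_pairs = n)
}

#' Convert an SA concentration between assay scales
#'
#' Applies a linear conversion model and rounds half-up to two decimals, the
#' precision at which converted SA concentrations are reported and at which
#' all downstream ratios and products are computed.
#'
#' @param sa non-negative SA concentration(s), umol/L blood.
#' @param model a [conversion_model()]; defaults to the published
#'   NeoBase-to-NeoBase 2 mapping.
#' @return converted SA, umol/L blood, rounded to two decimals.
#' @examples
#' convert_sa(4.93)  # 2.84
#' convert_sa(1.08)  # 0.64
#' @export
convert_sa <- function(sa, model = neobase_conversion()) {
  stopifnot(inherits(model, "conversion_model"), is.numeric(sa))
  if (any(!is.na(sa) & sa < 0))
    fail("convert_sa: SA concentrations must be non-negative")
  round_half_up(model$intercept + model$slope * sa, 2)
}

#' Write / read a conversion model as a plain key-value config block
#'
#' @param model a [conversion_model()].
#' @param path file path.
#' @return `write_conversion_model` returns `path` invisibly;
#'   `read_conversion_model` returns a [conversion_model()].
#' @export
write_conversion_model <- function(model, path) {
  stopifnot(inherits(model, "conversion_model"))
  writeLines(c(
    sprintf("slope: %.17g", model$slope),
    sprintf("intercept: %.17g", model$intercept),
    sprintf("variance_ratio: %.17g", model$variance_ratio)
  ), path)
  invisible(path)
}

#' @rdname write_conversion_model
#' @export
read_conversion_model <- function(path) {
  lines <- grep("^\\s*(#|$)", readLines(path), value = TRUE, invert = TRUE)
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[`, "", 2))))
  need <- c("slope", "intercept", "variance_ratio")
  if (!all(need %in% keys))
    fail("conversion model config missing key(s): %s",
         paste(setdiff(need, keys), collapse = ", "))
  v <- stats::setNames(vals, keys)
  conversion_model(v[["slope"]], v[["intercept"]], v[["variance_ratio"]])
}
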