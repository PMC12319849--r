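# Internal helpers: angle conventions and small validators.
#
# Convention used package-wide: optic-axis orientations are axial (180-degree
# periodic) angles in degrees, stored in [0, 180), NaN where undefined.
# Coordinates are 0-based pixel centers, column = x (right), row = y (down),
# theta measured from +x toward +y.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [0, period)
#'
#' @param x numeric vector of angles in degrees.
#' @param period wrapping period in degrees (180 for axial data).
#' @return angles wrapped into `[0, period)`; NaN propagates.
#' @keywords internal
wrap_deg <- function(x, period = 180) {
  out <- x %% period
  # guard against -1e-17 %% 180 == 180 from floating point
  out[out >= period] <- 0
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_num <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min)
    stop(sprintf("`%s` must be a finite scalar >= %g", name, min), call. = FALSE)
  invisible(x)
}

# population (divide by n) or sample (n-1) standard deviation
.sd_by <- function(x, type = c("population", "sample")) {
  type <- match.arg(type)
  n <- length(x)
  if (n == 0L) return(NaN)
  m <- mean(x)
  v <- sum((x - m)^2) / if (type == "population") n else max(n - 1L, 1L)
  sqrt(v)
}
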