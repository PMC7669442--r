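# Shared helpers: night frames, clamping, small distribution utilities.
# All timestamps in the package are POSIXct in UTC; a "night" is the
# noon-to-noon frame labelled by the calendar date of its first half, so a
# sleep period spanning midnight stays in one night.

#' Assign timestamps to noon-to-noon nights
#'
#' A timestamp between noon of day `d` and noon of day `d + 1` belongs to
#' night `d`. This is the standard actigraphy convention and is shared by
#' every device module so that night matching is well defined.
#'
#' @param time A `POSIXct` vector (UTC).
#' @return A `Date` vector of night labels.
#' @export
#' @examples
#' night_date(as.POSIXct("2019-07-02 01:30:00", tz = "UTC")) # night of Jul 1
night_date <- function(time) {
  stopifnot(inherits(time, "POSIXct"))
  as.Date(time - 12 * 3600, tz = "UTC")
}

#' Noon-to-noon frame of a night
#'
#' @param night A `Date` (night label).
#' @return A list with `start` and `end` `POSIXct` (UTC), 24 h apart.
#' @export
night_frame <- function(night) {
  start <- as.POSIXct(paste(night, "12:00:00"), tz = "UTC")
  list(start = start, end = start + 86400)
}

clamp <- function(x, lower = -Inf, upper = Inf) pmin(pmax(x, lower), upper)

# Truncated-normal draws by rejection; sd = 0 collapses to the clamped mean.
rtnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(rep(clamp(mean, lower, upper), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
  }
  out
}

# Mean and variance of a normal truncated below at `lower`.
tnorm_moments <- function(mean, sd, lower = 0) {
  if (sd == 0) {
    return(list(mean = max(mean, lower), var = 0))
  }
  a <- (lower - mean) / sd
  lam <- dnorm(a) / (1 - pnorm(a))
  m <- mean + sd * lam
  v <- sd^2 * (1 + a * lam - lam^2)
  list(mean = m, var = v)
}

# Gamma draws parameterised by mean and variance; var = 0 (or mean <= 0)
# degenerates to a point mass at max(mean, 0). Vectorised over `mean`.
rgamma_mv <- function(n, mean, var) {
  mean <- rep_len(mean, n)
  out <- pmax(mean, 0)
  if (var <= 0) return(out)
  pos <- mean > 0
  if (any(pos)) {
    shape <- mean[pos]^2 / var
    rate <- mean[pos] / var
    out[pos] <- rgamma(sum(pos), shape = shape, rate = rate)
  }
  out
}

# Stop unless `x` is a single finite number satisfying `ok`.
check_scalar <- function(x, name, ok = function(v) TRUE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || !ok(x)) {
    stop(sprintf("invalid value for `%s`", name), call. = FALSE)
  }
  invisible(x)
}
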