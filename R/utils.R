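#' @keywords internal
"_PACKAGE"

# Rating scale bounds used throughout: sliders run 1 (very bad) .. 11 (very good).
RATING_MIN <- 1L
RATING_MAX <- 11L

#' Clip and round a value onto the integer rating grid
#'
#' @param x numeric vector of latent ratings
#' @param integer_grid round to the nearest integer before clipping?
#' @return numeric (integer-valued if `integer_grid`) vector in \[1, 11\]
#' @keywords internal
clip_rating <- function(x, integer_grid = TRUE) {
  if (integer_grid) x <- round(x)
  pmin(pmax(x, RATING_MIN), RATING_MAX)
}

assert_ratings <- function(..., .what = "ratings") {
  vals <- c(...)
  vals <- vals[!is.na(vals)]
  if (length(vals) && (any(vals < RATING_MIN) || any(vals > RATING_MAX))) {
    stop(.what, " must lie on the 1-11 rating scale", call. = FALSE)
  }
  invisible(TRUE)
}

#' Check that a data frame has the required columns
#'
#' Used by every stage that consumes CSV input so schema violations surface
#' as a named-column error before any computation runs.
#'
#' @param df data frame
#' @param required character vector of column names
#' @param name label used in the error message
#' @keywords internal
check_columns <- function(df, required, name = deparse(substitute(df))) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Draws from a truncated normal via inverse-CDF
#' @keywords internal
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

truncnorm_mean <- function(mu, sd, lo = 0, hi = 1) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
}

#' Unit-interval truncated-normal draws with a calibrated mean
#'
#' Samples adjustment weights from a normal distribution truncated to
#' \[0, 1\], with the location parameter solved (by `uniroot`) so that the
#' mean of the *truncated* distribution equals `mean`. Used to simulate
#' per-condition adjustment weights whose population mean matches a stated
#' condition mean.
#'
#' @param n number of draws
#' @param mean target mean of the truncated distribution, in \[0.06, 0.94\]
#'   (outside this the location search underflows)
#' @param sd scale parameter of the underlying normal (default 0.25)
#' @return numeric vector in \[0, 1\]
#' @export
rtrunc_unit <- function(n, mean, sd = 0.25) {
  stopifnot(mean >= 0.06, mean <= 0.94, sd > 0)
  mu <- stats::uniroot(function(m) truncnorm_mean(m, sd) - mean,
                       lower = -1, upper = 2, tol = 1e-10)$root
  rtruncnorm1(n, mu, sd, 0, 1)
}

# Expected value of a normal draw clipped to the rating scale (rounding to
# the integer grid is mean-preserving away from the bounds, so the clip
# expectation is the dominant term).
clipped_normal_mean <- function(mu, sd, lo = RATING_MIN, hi = RATING_MAX) {
  zl <- (lo - mu) / sd
  zh <- (hi - mu) / sd
  lo * stats::pnorm(zl) + hi * stats::pnorm(zh, lower.tail = FALSE) +
    mu * (stats::pnorm(zh) - stats::pnorm(zl)) +
    sd * (stats::dnorm(zl) - stats::dnorm(zh))
}

# Latent location whose clipped expectation equals `target`: the configured
# domain means describe observed (scale-limited) ratings, so latent item
# means are shifted to compensate for floor/ceiling compression.
latent_location <- function(target, sd) {
  if (sd < 1e-9) return(target)
  stats::uniroot(function(m) clipped_normal_mean(m, sd) - target,
                 lower = target - 3 * sd, upper = target + 3 * sd,
                 tol = 1e-9)$root
}

# Deterministic child seeds so pipeline stages can be re-run in isolation.
# child = (seed + 1000003 * stage_index) mod (2^31 - 1), always a valid R seed.
stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) + 1000003 * stage_index) %% 2147483647)
}
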