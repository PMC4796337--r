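#' Read a skyline curve of effective population size
#'
#' Reads an externally estimated effective-population-size trajectory (for
#' example the median curve of a Bayesian skyline plot) from a TSV with two
#' numeric columns: time before present and effective size. The curve is
#' normalised to run from oldest to youngest.
#'
#' @param path TSV file (header tolerated); the first column is time, the
#'   second effective size. Extra columns (e.g. credible bounds) are kept
#'   but unused.
#' @param units `"years"` or `"ka"`; times in ka are converted to years.
#' @return An object of class `ne_curve`: data frame with columns `time`
#'   (years before present) and `ne`.
#' @export
read_skyline <- function(path, units = c("years", "ka")) {
  units <- match.arg(units)
  raw <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("skyline TSV needs at least two columns",
                           call. = FALSE)
  tm <- suppressWarnings(as.numeric(raw[[1]]))
  ne <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(tm) | is.na(ne))
  if (length(bad)) {
    stop("non-numeric skyline value in data row ", bad[1], call. = FALSE)
  }
  ne_curve(if (units == "ka") tm * 1000 else tm, ne)
}

#' Construct an effective-size curve
#'
#' @param time Times before present in years (distinct).
#' @param ne Effective sizes (strictly positive).
#' @return An object of class `ne_curve`, sorted oldest to youngest.
#' @export
ne_curve <- function(time, ne) {
  stopifnot(length(time) == length(ne), length(time) >= 1L)
  if (anyDuplicated(time)) stop("duplicated time values in skyline curve",
                                call. = FALSE)
  if (any(ne <= 0)) stop("effective sizes must be strictly positive",
                         call. = FALSE)
  o <- order(time, decreasing = TRUE)
  structure(data.frame(time = time[o], ne = ne[o]),
            class = c("ne_curve", "data.frame"))
}

#' Increment ratio of effective population size over a period
#'
#' The number of times the effective population size increased during a
#' period: `Ne(t_young) / Ne(t_old)`, reading the curve by linear
#' interpolation on the Ne scale (or on log Ne with `log_scale = TRUE`).
#'
#' @param curve An `ne_curve`.
#' @param period Numeric `c(t_old, t_young)` in years, `t_old > t_young >=
#'   0`, both within the curve's support.
#' @param log_scale Interpolate on the log-Ne scale.
#' @return The fold change as a single number.
#' @examples
#' cv <- ne_curve(time = c(10000, 5000, 0), ne = c(100, 1000, 1000))
#' increment_ratio(cv, c(10000, 5000))
#' @export
increment_ratio <- function(curve, period, log_scale = FALSE) {
  stopifnot(inherits(curve, "ne_curve"), length(period) == 2L)
  t_old <- period[1]; t_young <- period[2]
  if (!(t_old > t_young && t_young >= 0)) {
    stop("period must be c(t_old, t_young) with t_old > t_young >= 0",
         call. = FALSE)
  }
  rng <- range(curve$time)
  if (t_old > rng[2] || t_young < rng[1]) {
    stop(sprintf("period [%g, %g] outside curve support [%g, %g]",
                 t_old, t_young, rng[1], rng[2]), call. = FALSE)
  }
  y <- if (log_scale) log(curve$ne) else curve$ne
  vals <- approx(curve$time, y, xout = c(t_young, t_old))$y
  if (log_scale) vals <- exp(vals)
  vals[1] / vals[2]
}
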