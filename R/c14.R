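#' Ward-Wilson combination of replicate radiocarbon measurements
#'
#' Pools replicate measurements of the same event by the inverse-variance
#' weighted mean and tests their consistency with the Ward-Wilson
#' chi-square statistic T = sum((x_i - pooled)^2 / sigma_i^2) on n - 1
#' degrees of freedom; replicates are consistent at 5% when T is below
#' the upper critical value.
#'
#' @param age_bp radiocarbon ages (years BP), length >= 2.
#' @param sigma 1-sigma errors (> 0), same length.
#' @return one-row tibble: `pooled_bp`, `pooled_sigma`, `t_stat`, `df`,
#'   `consistent`.
#' @export
ward_wilson_combine <- function(age_bp, sigma) {
  n <- length(age_bp)
  if (n < 2) stop("need at least 2 measurements to combine")
  stopifnot(length(sigma) == n, all(sigma > 0))
  w <- 1 / sigma^2
  pooled <- sum(w * age_bp) / sum(w)
  pooled_sigma <- 1 / sqrt(sum(w))
  t_stat <- sum(((age_bp - pooled) / sigma)^2)
  df <- n - 1
  tibble::tibble(pooled_bp = pooled, pooled_sigma = pooled_sigma,
                 t_stat = t_stat, df = df,
                 consistent = t_stat < stats::qchisq(0.95, df))
}

#' Read a radiocarbon calibration curve (.14c format)
#'
#' Accepts the standard comma- or whitespace-separated layout with
#' `#`-prefixed header lines; the first three columns are calendar age
#' (cal BP), conventional radiocarbon age, and 1-sigma curve error.
#'
#' @param path file path.
#' @return A tibble of class `cal_curve` with `cal_bp`, `c14_bp`, `sigma`,
#'   sorted by increasing cal BP.
#' @export
read_cal_curve <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  tab <- utils::read.table(text = gsub(",", " ", lines))
  curve <- tibble::tibble(cal_bp = tab[[1]], c14_bp = tab[[2]],
                          sigma = tab[[3]])
  if (any(curve$sigma < 0)) stop("negative curve sigma")
  curve <- curve[order(curve$cal_bp), ]
  structure(curve, class = c("cal_curve", class(curve)))
}

#' Build a calibration curve from vectors
#'
#' Convenience constructor (used for synthetic curves in tests and
#' examples).
#'
#' @param cal_bp,c14_bp,sigma numeric vectors of equal length.
#' @return A `cal_curve` tibble.
#' @export
cal_curve <- function(cal_bp, c14_bp, sigma = 0) {
  curve <- tibble::tibble(cal_bp = cal_bp, c14_bp = c14_bp,
                          sigma = rep_len(sigma, length(cal_bp)))
  curve <- curve[order(curve$cal_bp), ]
  structure(curve, class = c("cal_curve", class(curve)))
}

#' Calibrate a radiocarbon date
#'
#' Evaluates the calendar posterior on a 1-year grid: the likelihood of
#' the measurement at calendar year theta is the normal density of the
#' measured age at the curve mean with variance sigma_m^2 +
#' sigma_curve(theta)^2 (curve linearly interpolated between knots). The
#' report is the highest-posterior-density set at `level` (default the
#' conventional 95.4%), as maximal contiguous cal BP intervals.
#'
#' @param age_bp,sigma the measurement.
#' @param curve a `cal_curve`.
#' @param level HPD mass (default 0.954).
#' @return An object of class `cal_result`: tibble of intervals
#'   (`start_cal_bp` older end, `end_cal_bp`, `prob`) with the full
#'   posterior in the `posterior` attribute.
#' @export
calibrate_c14 <- function(age_bp, sigma, curve, level = 0.954) {
  stopifnot(inherits(curve, "cal_curve"), sigma > 0)
  rng <- range(curve$c14_bp)
  if (age_bp < rng[1] - 10 * sigma || age_bp > rng[2] + 10 * sigma)
    stop("age ", age_bp, " BP lies outside the calibration curve span")
  grid <- seq(ceiling(min(curve$cal_bp)), floor(max(curve$cal_bp)), by = 1)
  mu <- stats::approx(curve$cal_bp, curve$c14_bp, grid)$y
  sg <- stats::approx(curve$cal_bp, curve$sigma, grid)$y
  dens <- stats::dnorm(age_bp, mean = mu, sd = sqrt(sigma^2 + sg^2))
  if (sum(dens) == 0) stop("posterior has no support on the curve grid")
  post <- dens / sum(dens)
  # HPD: smallest set of grid years with total mass >= level
  ord <- order(post, decreasing = TRUE)
  cum <- cumsum(post[ord])
  n_in <- which(cum >= level)[1]
  included <- sort(grid[ord[seq_len(n_in)]])
  breaks <- which(diff(included) > 1)
  starts <- c(1, breaks + 1)
  ends <- c(breaks, length(included))
  intervals <- tibble::tibble(
    start_cal_bp = included[ends],   # older endpoint (larger cal BP)
    end_cal_bp = included[starts],
    prob = vapply(seq_along(starts), function(k)
      sum(post[grid %in% included[starts[k]:ends[k]]]), 0))
  intervals <- intervals[order(-intervals$start_cal_bp), ]
  structure(intervals,
            posterior = tibble::tibble(cal_bp = grid, prob = post),
            age_bp = age_bp, sigma = sigma, level = level,
            class = c("cal_result", class(intervals)))
}

#' Convert cal BP to a calendar year with era tag
#'
#' cal BP counts years before 1950 CE; BCE years follow the no-year-zero
#' historical convention (1950 cal BP is 1 BCE).
#'
#' @param cal_bp integer cal BP value(s).
#' @return tibble `cal_bp`, `year`, `era` ("CE"/"BCE").
#' @export
calbp_to_calendar <- function(cal_bp) {
  ce <- 1950 - cal_bp
  year <- ifelse(ce >= 1, ce, cal_bp - 1949)
  tibble::tibble(cal_bp = cal_bp, year = as.integer(year),
                 era = ifelse(ce >= 1, "CE", "BCE"))
}
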