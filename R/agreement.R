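# Expert-agreement statistics over paired measurement tables: the CI
# half-width formula Z*s/sqrt(n-1), mean absolute relative error, Pearson
# correlation with Fisher-z confidence intervals, and Bland-Altman limits
# of agreement.

#' Confidence interval with the sqrt(n-1) half-width
#'
#' Half-width `Z * s / sqrt(n - 1)` around the mean. This form (with
#' `sqrt(n - 1)` rather than `sqrt(n)`) is the convention this package
#' reports by default; set `denominator = "n"` for the standard-error form.
#'
#' @param x_mean Sample mean.
#' @param s Sample standard deviation (>= 0).
#' @param n Sample count (>= 2).
#' @param z Z-score (1.96 for a 95% interval).
#' @param denominator `"n-1"` (default) or `"n"`.
#' @return Named vector `c(low, high)`.
#' @export
ci_eq1 <- function(x_mean, s, n, z = 1.96, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  if (n < 2) stop("confidence interval requires n >= 2", call. = FALSE)
  if (s < 0) stop("standard deviation must be >= 0", call. = FALSE)
  hw <- z * s / sqrt(if (denominator == "n-1") n - 1 else n)
  c(low = x_mean - hw, high = x_mean + hw)
}

#' Mean absolute relative error between two raters
#'
#' Per case `e = |a - b| / |b| * 100` (the second vector is the reference),
#' averaged, with a [ci_eq1()] confidence interval over the per-case errors.
#' Cases with a zero reference are excluded with a count.
#'
#' @param a Measured values (e.g. automatic).
#' @param b Reference values (e.g. expert), same length.
#' @param z Z-score for the CI.
#' @param denominator CI denominator convention, see [ci_eq1()].
#' @return List with `mare` (%), `ci` (low/high), `n`, `n_excluded`,
#'   and the per-case errors `e`.
#' @export
mean_abs_rel_error <- function(a, b, z = 1.96, denominator = "n-1") {
  stopifnot(length(a) == length(b))
  keep <- b != 0
  n_excl <- sum(!keep)
  if (n_excl > 0) {
    warning(n_excl, " case(s) with zero reference value excluded")
  }
  e <- abs(a[keep] - b[keep]) / abs(b[keep]) * 100
  if (length(e) < 2) stop("need at least 2 usable cases", call. = FALSE)
  list(mare = mean(e),
       ci = ci_eq1(mean(e), stats::sd(e), length(e), z, denominator),
       n = length(e), n_excluded = n_excl, e = e)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' Sample Pearson correlation; the interval back-transforms
#' `atanh(r) +/- z / sqrt(n - 3)`.
#'
#' @param a,b Paired vectors, length >= 4, each with nonzero variance.
#' @param z Z-score for the CI.
#' @return List with `r`, `ci` (low/high) and `n`.
#' @export
pearson_ci <- function(a, b, z = 1.96) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 4) stop("Pearson CI requires n >= 4", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  r <- stats::cor(a, b)
  if (abs(r) >= 1) {
    ci <- c(low = r, high = r)
  } else {
    fz <- atanh(r) + c(-1, 1) * z / sqrt(n - 3)
    ci <- c(low = tanh(fz[1]), high = tanh(fz[2]))
  }
  list(r = r, ci = ci, n = n)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`, their mean, and 95% limits of agreement
#' `mean(d) +/- 1.96 * sd(d)` (sample sd, n-1 denominator). Also returns the
#' per-case `(mean, difference)` pairs for plotting.
#'
#' @param a,b Paired vectors, length >= 3.
#' @param z Multiplier for the limits (1.96 by default).
#' @return List with `mean_diff`, `loa_low`, `loa_high`, `sd_diff`, and a
#'   data frame `points` with columns `mean` and `diff`.
#' @export
bland_altman <- function(a, b, z = 1.96) {
  stopifnot(length(a) == length(b))
  if (length(a) < 3) stop("Bland-Altman requires n >= 3", call. = FALSE)
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  list(mean_diff = md, loa_low = md - z * sdd, loa_high = md + z * sdd,
       sd_diff = sdd,
       points = data.frame(mean = (a + b) / 2, diff = d))
}

#' Read paired measurement tables
#'
#' Two CSVs with a `case_id` column and one column per measurement are
#' aligned on `case_id`; only measurements present in both tables are kept.
#'
#' @param path_a,path_b CSV paths (rater A and rater B).
#' @return Object of class `paired_measurements`: list with `case_id` and
#'   per-measurement data frames `a`, `b`.
#' @export
read_paired_measurements <- function(path_a, path_b) {
  ta <- utils::read.csv(path_a, check.names = FALSE)
  tb <- utils::read.csv(path_b, check.names = FALSE)
  if (!"case_id" %in% names(ta) || !"case_id" %in% names(tb)) {
    stop("both tables need a case_id column", call. = FALSE)
  }
  common <- intersect(ta$case_id, tb$case_id)
  if (length(common) < 3) {
    stop("fewer than 3 shared case_ids between the two tables", call. = FALSE)
  }
  if (length(common) < length(ta$case_id) || length(common) < length(tb$case_id)) {
    warning(length(common), " shared cases kept; unmatched case_ids dropped")
  }
  meas <- setdiff(intersect(names(ta), names(tb)), "case_id")
  if (length(meas) == 0) stop("no shared measurement columns", call. = FALSE)
  ia <- match(common, ta$case_id)
  ib <- match(common, tb$case_id)
  a <- ta[ia, meas, drop = FALSE]
  b <- tb[ib, meas, drop = FALSE]
  if (anyNA(a) || anyNA(b)) {
    stop("missing values within paired measurements are not allowed", call. = FALSE)
  }
  structure(list(case_id = common, a = a, b = b, measurements = meas),
            class = "paired_measurements")
}

#' Agreement analysis over all paired measurements
#'
#' Runs [mean_abs_rel_error()], [pearson_ci()] and [bland_altman()] for each
#' measurement column of a pair of raters.
#'
#' @param paired A [read_paired_measurements()] result, or a list with
#'   aligned data frames `a` and `b`.
#' @param z Z-score for all intervals.
#' @param denominator CI denominator convention, see [ci_eq1()].
#' @return Data frame of class `agreement_result` with one row per
#'   measurement: mean absolute relative error (% + CI), signed mean error,
#'   Pearson r (+ CI), Bland-Altman mean difference and limits, and n. The
#'   CI method is recorded in attribute `"methods"`.
#' @export
agreement_analysis <- function(paired, z = 1.96, denominator = "n-1") {
  meas <- paired$measurements %||% names(paired$a)
  rows <- lapply(meas, function(m) {
    a <- paired$a[[m]]; b <- paired$b[[m]]
    mare <- mean_abs_rel_error(a, b, z, denominator)
    pc <- pearson_ci(a, b, z)
    ba <- bland_altman(a, b, z)
    data.frame(measurement = m,
               n = pc$n,
               mare_pct = mare$mare,
               mare_low = unname(mare$ci["low"]), mare_high = unname(mare$ci["high"]),
               mean_error = mean(a - b),
               pearson_r = pc$r,
               pearson_low = unname(pc$ci["low"]), pearson_high = unname(pc$ci["high"]),
               ba_mean_diff = ba$mean_diff,
               ba_loa_low = ba$loa_low, ba_loa_high = ba$loa_high)
  })
  out <- do.call(rbind, rows)
  attr(out, "methods") <- list(ci = paste0("z*s/sqrt(", denominator, ")"),
                               pearson_ci = "Fisher z, se 1/sqrt(n-3)",
                               z = z)
  class(out) <- c("agreement_result", class(out))
  out
}

#' Bland-Altman plot
#'
#' @param ba A [bland_altman()] result.
#' @param main Plot title.
#' @param xlab,ylab Axis labels.
#' @return Invisibly, `ba`.
#' @export
plot_bland_altman <- function(ba, main = "Bland-Altman",
                              xlab = "mean of raters (mm)",
                              ylab = "difference (mm)") {
  graphics::plot(ba$points$mean, ba$points$diff, pch = 19,
                 main = main, xlab = xlab, ylab = ylab)
  graphics::abline(h = ba$mean_diff, lwd = 2)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2, col = "red")
  invisible(ba)
}
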