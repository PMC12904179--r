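#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate select filter arrange group_by ungroup summarise
#'   across left_join bind_rows bind_cols n rename pull distinct count if_else
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile median sd cor qnorm rnorm rbinom runif rexp
#'   setNames complete.cases pchisq coef vcov ks.test
NULL

# derive a reproducible child seed (< 2^31) from a root seed and a stream label,
# so adding one component's draws never perturbs another's
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 1103515245 + h * 12345) %% 2147483647L)
}

with_stream_seed <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(child_seed(seed, stream))
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Assign cohort-relative quantile-group points with a fixed tie rule
#'
#' Ranks `values` within the cohort (optionally within sex strata), breaks ties
#' by average rank, and maps ranks to `n_groups` near-equal groups via
#' `ceiling(n_groups * rank / n)`. All tied values receive identical points, so
#' group sizes are equal up to ties. With `reverse = TRUE` group `g` maps to
#' `n_groups + 1 - g` (used for adverse components such as red meat or sodium).
#'
#' @param values Numeric vector of cohort-wide amounts.
#' @param sex Optional factor/character of the same length; when supplied,
#'   ranking is performed within each sex stratum separately.
#' @param reverse Reverse the point order (adverse component).
#' @param n_groups Number of groups (5 for quintiles, 3 for tertiles).
#' @return Integer vector of points in `1:n_groups`.
#' @export
quintile_rank <- function(values, sex = NULL, reverse = FALSE, n_groups = 5L) {
  if (!is.numeric(values)) abort("`values` must be numeric.")
  if (anyNA(values)) abort("`values` contains missing values; impute or drop upstream.")
  assign_one <- function(v) {
    if (length(v) == 0) abort("Empty stratum: cannot assign quantile groups.")
    if (length(unique(v)) < n_groups) {
      abort(paste0(
        "Fewer than ", n_groups, " distinct values in a stratum (",
        length(unique(v)), " found); use threshold-based scoring instead."
      ))
    }
    r <- rank(v, ties.method = "average")
    g <- as.integer(ceiling(n_groups * r / length(v)))
    pmin(pmax(g, 1L), n_groups)
  }
  out <- integer(length(values))
  if (is.null(sex)) {
    out <- assign_one(values)
  } else {
    if (length(sex) != length(values)) abort("`sex` and `values` lengths differ.")
    for (s in unique(sex)) {
      idx <- which(sex == s)
      out[idx] <- assign_one(values[idx])
    }
  }
  if (reverse) out <- n_groups + 1L - out
  out
}

# piecewise-linear interpolation between a worst and a best anchor, clamped,
# scaled to [0, max_points]; handles both higher-better and lower-better anchors
anchor_points <- function(x, worst, best, max_points = 10) {
  frac <- (x - worst) / (best - worst)
  max_points * pmin(pmax(frac, 0), 1)
}

# tent (intermediate-best) scoring: `zero_pts` at intake 0, rising linearly to
# max over [opt_lo, opt_hi], falling to 0 at `upper`; anchors may be per-element
tent_points <- function(x, zero_pts, opt_lo, opt_hi, upper, max_points = 10) {
  n <- length(x)
  opt_lo <- rep_len(opt_lo, n); opt_hi <- rep_len(opt_hi, n)
  upper <- rep_len(upper, n)
  out <- rep(max_points, n)
  below <- x < opt_lo
  out[below] <- zero_pts + (max_points - zero_pts) * x[below] / opt_lo[below]
  above <- x > opt_hi
  out[above] <- max_points *
    pmax(0, (upper[above] - x[above]) / (upper[above] - opt_hi[above]))
  out
}

stop_missing_fields <- function(data, fields, context) {
  missing <- setdiff(fields, names(data))
  if (length(missing)) {
    abort(paste0(context, ": missing field(s) ", paste(missing, collapse = ", "), "."))
  }
  invisible(TRUE)
}
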