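# Dosimetric evaluation: cumulative DVHs, dose statistics, goal checks,
# percentage-to-goal and cohort comparison.

#' Cumulative dose-volume histogram
#'
#' `V(d)` is the fraction of structure voxels receiving at least dose `d`;
#' `V` is non-increasing and `V(0) = 1`.
#'
#' @param dose Per-voxel dose vector for one structure (or over the body with
#'   `idx` selecting the structure's voxels).
#' @param idx Optional voxel index set.
#' @param bin Dose bin width (% units, default 0.1).
#' @param structure Optional structure name carried into the output.
#' @return A tibble with columns `structure`, `dose`, `volume` (fraction).
#' @export
dose_dvh <- function(dose, idx = NULL, bin = 0.1, structure = NA_character_) {
  d <- if (is.null(idx)) dose else dose[idx]
  if (length(d) == 0) abort("Empty structure.", class = "fuzzyplan_error_eval")
  grid <- seq(0, max(d) + bin, by = bin)
  sorted <- sort(d)
  n <- length(sorted)
  # voxels with dose >= g: n minus the count strictly below g
  below <- findInterval(grid - bin * 1e-6, sorted)
  tibble(structure = structure, dose = grid, volume = (n - below) / n)
}

#' Dose to the hottest q% of a structure
#'
#' `Dq` is the minimum dose received by the hottest q% of the volume (the
#' inverse cumulative DVH); `D0` is the maximum dose.
#'
#' @param dose Structure dose vector.
#' @param q Volume percentage in `[0, 100]`.
#' @return Scalar dose.
#' @export
dose_at_volume <- function(dose, q) {
  if (q < 0 || q > 100) abort("q must be in [0, 100].",
                              class = "fuzzyplan_error_eval")
  s <- sort(dose, decreasing = TRUE)
  k <- max(1L, ceiling(q / 100 * length(s)))
  s[k]
}

#' Volume fraction receiving at least a dose
#'
#' @param dose Structure dose vector.
#' @param x Dose threshold.
#' @return Fraction of voxels with dose >= x, in `[0, 1]`.
#' @export
volume_at_dose <- function(dose, x) {
  mean(dose >= x)
}

#' Dose statistics for one structure
#'
#' @param dose Structure dose vector.
#' @param q Volume percentages for dose-at-volume statistics.
#' @param vx Dose thresholds for volume-at-dose statistics.
#' @param structure Optional structure name.
#' @return One-row tibble: `mean`, `std`, one `D{q}` column per `q`, one
#'   `V{x}` column per `vx` (volume as a percentage).
#' @export
dose_stats <- function(dose, q = c(95, 30, 10, 5), vx = numeric(),
                       structure = NA_character_) {
  if (length(dose) == 0) abort("Empty structure.", class = "fuzzyplan_error_eval")
  if (any(q <= 0 | q > 100)) abort("q must be in (0, 100].",
                                   class = "fuzzyplan_error_eval")
  out <- tibble(structure = structure, mean = mean(dose),
                std = stats::sd(dose))
  for (qq in q) out[[paste0("D", qq)]] <- dose_at_volume(dose, qq)
  for (xx in vx) out[[paste0("V", xx)]] <- 100 * volume_at_dose(dose, xx)
  out
}

#' Signed percentage deviation from a dosimetric goal
#'
#' `100 * (achieved - goal) / goal`; positive values mean the achieved mean
#' dose exceeds the goal, negative that it is below.
#'
#' @param achieved Achieved mean dose(s).
#' @param goal Goal dose(s), > 0.
#' @return Signed percentage(s).
#' @export
percent_to_goal <- function(achieved, goal) {
  if (any(goal <= 0)) abort("Goals must be positive.",
                            class = "fuzzyplan_error_eval")
  100 * (achieved - goal) / goal
}

#' Round half away from zero
#'
#' Matches the convention of printed dosimetric tables (e.g. -3.25 -> -3.3).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # the tiny offset keeps values that are exactly on a half boundary in
  # decimal (but fractionally below it in binary) rounding away from zero
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Protocol goal sets
#'
#' Goals in relative dose units (% of the target prescription). The C-shape
#' set follows the TG-119 commissioning goals (target prescription 50 Gy):
#' target V100 >= 95%, target V110 <= 10%, core V50 <= 5%. The prostate set
#' follows RTOG 0126-style goals (prescription 75.6 Gy) for target coverage
#' and rectum/bladder dose-volume limits.
#'
#' @return Tibble with columns `structure`, `metric` (`"V"`, `"mean"` or
#'   `"Dmax"`), `dose` (threshold dose for `V`), `limit` (volume % or dose),
#'   `direction` (`">="` or `"<="`).
#' @export
goals_tg119 <- function() {
  tibble(
    structure = c("ptv", "ptv", "core"),
    metric = c("V", "V", "V"),
    dose = c(100, 110, 50),
    limit = c(95, 10, 5),
    direction = c(">=", "<=", "<=")
  )
}

#' @rdname goals_tg119
#' @export
goals_rtog0126 <- function() {
  p <- 75.6
  tibble(
    structure = c("ptv", "ptv",
                  rep("rectum", 4), rep("bladder", 4)),
    metric = c("V", "Dmax", rep("V", 8)),
    dose = c(100, NA, 100 * c(75, 70, 65, 60) / p, 100 * c(80, 75, 70, 65) / p),
    limit = c(98, 107, 15, 25, 25, 50, 15, 25, 35, 50),
    direction = c(">=", "<=", rep("<=", 8))
  )
}

#' Evaluate a goal set against a dose distribution
#'
#' @param dose Per-voxel dose over the body voxels.
#' @param omega Named list of structure voxel index sets.
#' @param goals Goal tibble as from [goals_tg119()].
#' @return The goal tibble with `value` and `pass` columns; attribute
#'   `all_pass` gives the aggregate verdict.
#' @export
check_goals <- function(dose, omega, goals) {
  miss <- setdiff(unique(goals$structure), names(omega))
  if (length(miss)) {
    abort(paste("Unknown structures:", paste(miss, collapse = ", ")),
          class = "fuzzyplan_error_eval")
  }
  value <- numeric(nrow(goals))
  for (i in seq_len(nrow(goals))) {
    d <- dose[omega[[goals$structure[i]]]]
    value[i] <- switch(goals$metric[i],
      V = 100 * volume_at_dose(d, goals$dose[i]),
      mean = mean(d),
      Dmax = max(d),
      abort(sprintf("Unknown metric '%s'.", goals$metric[i]),
            class = "fuzzyplan_error_eval")
    )
  }
  pass <- ifelse(goals$direction == ">=", value >= goals$limit,
                 value <= goals$limit)
  out <- dplyr::mutate(goals, value = value, pass = pass)
  attr(out, "all_pass") <- all(pass)
  out
}

#' Unpaired two-sample comparison of cohort means
#'
#' Welch's unequal-variance t-test on the difference of means. The fully
#' degenerate case (both samples constant and equal) returns p = 1 by
#' convention.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return One-row tibble: `estimate` (mean of `a` minus mean of `b`),
#'   `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_cohorts <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    diff <- mean(a) - mean(b)
    return(tibble(estimate = diff,
                  statistic = if (diff == 0) 0 else Inf * sign(diff),
                  p_value = if (diff == 0) 1 else 0,
                  n_a = length(a), n_b = length(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  tibble(estimate = unname(tt$estimate[1] - tt$estimate[2]),
         statistic = unname(tt$statistic),
         p_value = tt$p.value,
         n_a = length(a), n_b = length(b))
}

#' @method autoplot dvh_set
#' @export
autoplot.dvh_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$dose, 100 * .data$volume,
                                       colour = .data$structure)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "dose (% of prescription)", y = "volume (%)")
}

#' DVHs for all structures of a plan
#'
#' @param plan A `dose_plan` from [optimize_fluence()].
#' @param bin Dose bin width.
#' @return A tibble of class `dvh_set` (one row per structure/dose bin).
#' @export
plan_dvh <- function(plan, bin = 0.1) {
  sets <- setdiff(names(plan$omega), "body")
  out <- dplyr::bind_rows(lapply(sets, function(nm) {
    dose_dvh(plan$dose, plan$omega[[nm]], bin = bin, structure = nm)
  }))
  class(out) <- c("dvh_set", class(out))
  out
}
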