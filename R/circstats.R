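## Circular statistics used for evaluating phase predictions: Fisher-Lee
## circular correlation, circular errors in hours, within-participant order
## recall, and the paired amplitude test.

#' Circular correlation between two samples of angles
#'
#' Computes a circular association coefficient between two vectors of angles.
#' The default is the Fisher--Lee T-linear association coefficient
#' \deqn{r = \frac{\sum_{i<j} \sin(a_i-a_j)\sin(b_i-b_j)}
#'                {\sqrt{\sum_{i<j}\sin^2(a_i-a_j)\sum_{i<j}\sin^2(b_i-b_j)}}}
#' which is invariant under rotation of either argument and changes sign
#' under reflection of one argument. The Jammalamadaka--SenGupta coefficient
#' (deviations from the circular means) is available as an alternative.
#'
#' @param a,b numeric vectors of angles in radians, equal length >= 3.
#' @param method `"fisher_lee"` (default) or `"js"`.
#' @return a single correlation value in `[-1, 1]`.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 13)[-13]
#' circ_corr(th, th + pi / 3)   # rotation invariance: 1
#' circ_corr(th, -th)           # reflection: -1
#' @export
circ_corr <- function(a, b, method = c("fisher_lee", "js")) {
  method <- match.arg(method)
  fail_unless(length(a) == length(b), "circ_corr: lengths differ (%d vs %d)",
              length(a), length(b))
  fail_unless(length(a) >= 3, "circ_corr: need at least 3 pairs, got %d",
              length(a))
  a <- wrap_angle(as.numeric(a))
  b <- wrap_angle(as.numeric(b))
  if (method == "fisher_lee") {
    da <- sin(outer(a, a, "-"))
    db <- sin(outer(b, b, "-"))
    lt <- lower.tri(da)
    num <- sum(da[lt] * db[lt])
    den <- sqrt(sum(da[lt]^2) * sum(db[lt]^2))
    fail_unless(den > 0, "circ_corr: angularly constant input")
    num / den
  } else {
    ma <- circular_mean(a)
    mb <- circular_mean(b)
    fail_unless(is.finite(ma) && is.finite(mb),
                "circ_corr: degenerate input (zero resultant)")
    sa <- sin(a - ma)
    sb <- sin(b - mb)
    den <- sqrt(sum(sa^2) * sum(sb^2))
    fail_unless(den > 0, "circ_corr: angularly constant input")
    sum(sa * sb) / den
  }
}

#' Absolute circular error in hours
#'
#' Shortest-arc distance between predicted and true phases, expressed in
#' hours of the given period; always in `[0, period_h/2]`.
#'
#' @param pred,true angles in radians (recycled to common length).
#' @param period_h period in hours (default 24).
#' @return numeric vector of absolute errors in hours.
#' @examples
#' abs_err_hours(hours_to_rad(23), hours_to_rad(1))  # 2, not 22
#' @export
abs_err_hours <- function(pred, true, period_h = 24) {
  d <- abs(wrap_angle(pred) - wrap_angle(true))
  d <- pmin(d, 2 * pi - d)
  d * period_h / (2 * pi)
}

## Best global rotation (circular mean of differences) aligning pred to true.
align_rotation <- function(pred, true) {
  circular_mean(wrap_angle(pred) - wrap_angle(true))
}

#' Does a participant's predicted phase sequence recall the known order?
#'
#' A participant's stamped samples are recalled when the circular sequence of
#' predicted phases, read from the earliest-collected sample, visits the
#' samples in their known time order. Predicted phases from a registered
#' ordering or a trained phase model have a fixed direction, so the default
#' reads the circle forward (a clock running backwards is a failure). With
#' `direction = "auto"` the reading direction is instead chosen to minimize
#' the total circular error against the known times (after an optimal global
#' rotation, ties broken toward forward), which makes the recall invariant
#' to reflection of the predictions.
#'
#' @param theta_pred predicted phases in radians, one per sample.
#' @param times_h known collection times in hours (same length, >= 3).
#' @param period_h period in hours (default 24).
#' @param direction `"forward"` (default) or `"auto"`.
#' @return `TRUE` if the known order is recalled, else `FALSE`.
#' @export
order_recall <- function(theta_pred, times_h, period_h = 24,
                         direction = c("forward", "auto")) {
  direction <- match.arg(direction)
  n <- length(theta_pred)
  fail_unless(length(times_h) == n, "order_recall: lengths differ")
  fail_unless(n >= 3, "order_recall: need >= 3 stamped samples, got %d", n)
  ord <- order(times_h)
  th <- wrap_angle(theta_pred)[ord]
  tt <- hours_to_rad(times_h[ord], period_h)
  dir <- 1
  if (direction == "auto") {
    err_for <- function(sign_dir) {
      x <- wrap_angle(sign_dir * th)
      rot <- align_rotation(x, tt)
      if (!is.finite(rot)) rot <- 0
      sum(abs_err_hours(x - rot, tt, period_h))
    }
    if (err_for(-1) < err_for(1) - 1e-9) dir <- -1
  }
  ang <- wrap_angle(dir * (th - th[1]))
  all(diff(ang) > 0)
}

#' Paired amplitude difference test between two layers
#'
#' Two-tailed Wilcoxon signed-rank test of paired relative amplitudes
#' (e.g., the same genes' rAMP in epidermis vs dermis). Exact when the number
#' of non-zero differences is <= 25 and there are no ties; otherwise the
#' normal approximation with continuity correction.
#'
#' @param ramp1,ramp2 paired numeric vectors (>= 5 pairs).
#' @return the two-tailed p-value.
#' @export
amplitude_diff_test <- function(ramp1, ramp2) {
  fail_unless(length(ramp1) == length(ramp2), "amplitude_diff_test: lengths differ")
  fail_unless(length(ramp1) >= 5, "amplitude_diff_test: need >= 5 pairs")
  d <- ramp1 - ramp2
  if (all(d == 0)) return(1)
  nz <- d[d != 0]
  use_exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  suppressWarnings(
    stats::wilcox.test(ramp1, ramp2, paired = TRUE, exact = use_exact,
                       correct = TRUE, alternative = "two.sided")$p.value
  )
}

#' Correlate per-participant predicted phases with physiological markers
#'
#' Circular correlation between predicted anchor-gene phases (hours) and
#' each participant's melatonin / cortisol phase markers.
#'
#' @param pred_phase_h named numeric vector: predicted anchor phase (hours)
#'   per participant id.
#' @param truth a truth table with columns `participant_id`,
#'   `melatonin_phase_h`, `cortisol_phase_h` (one row per participant or per
#'   sample; duplicates collapsed).
#' @return list with elements `melatonin` and `cortisol` (each a circular
#'   correlation or `NA` with a warning when fewer than 5 participants have
#'   both values).
#' @export
marker_phase_corr <- function(pred_phase_h, truth) {
  tt <- unique(truth[, c("participant_id", "melatonin_phase_h", "cortisol_phase_h")])
  out <- list(melatonin = NA_real_, cortisol = NA_real_)
  for (mk in names(out)) {
    col <- paste0(mk, "_phase_h")
    m <- tt[match(names(pred_phase_h), tt$participant_id), col]
    keep <- is.finite(m) & is.finite(pred_phase_h)
    if (sum(keep) < 5) {
      warning(sprintf("marker_phase_corr: <5 participants with %s phase", mk))
      next
    }
    out[[mk]] <- tryCatch(
      circ_corr(hours_to_rad(pred_phase_h[keep]), hours_to_rad(m[keep])),
      error = function(e) {
        warning(sprintf("marker_phase_corr: %s phases degenerate (%s)", mk,
                        conditionMessage(e)))
        NA_real_
      })
  }
  out
}
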