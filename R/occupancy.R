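#' Lassen occupancy plot
#'
#' Across brain regions scanned at baseline and after blockade, the
#' reduction in distribution volume is regressed on the baseline value:
#' \deqn{V_T^{base} - V_T^{block} = occ \cdot (V_T^{base} - V_{ND}).}
#' The slope of the ordinary least-squares line is the occupancy and the
#' x-intercept is the nondisplaceable distribution volume V_ND, assumed
#' shared across regions. A fit with `r_squared` below `r2_min` or a
#' non-positive slope is flagged unreliable (some animals' plots do not
#' support a straight-line fit); occupancy outside `[0, 1]` is flagged
#' but not constrained.
#'
#' @param baseline,blocked named numeric vectors of V_T (mL cm-3) per
#'   region; the two conditions must cover the same at-least-3 regions.
#' @param r2_min reliability gate on r-squared (default 0.5).
#' @param surrogate set to `TRUE` by [lassen_suv_surrogate()].
#' @return A `lassen_fit` list: `occupancy` (fraction), `v_nd`
#'   (mL cm-3, `NA` when the slope is not positive), `slope_se`,
#'   `r_squared`, `p_value` (two-sided t test on the slope), `points`,
#'   `reliable`, `occupancy_in_range`, `surrogate`.
#' @export
lassen <- function(baseline, blocked, r2_min = 0.5, surrogate = FALSE) {
  if (is.null(names(baseline)) || is.null(names(blocked))) {
    stop("baseline and blocked must be named by region", call. = FALSE)
  }
  if (!setequal(names(baseline), names(blocked))) {
    stop("baseline and blocked must cover the same regions", call. = FALSE)
  }
  if (length(baseline) < 3L) {
    stop("need at least 3 regions for a Lassen fit", call. = FALSE)
  }
  blocked <- blocked[names(baseline)]
  x <- as.numeric(baseline)
  y <- x - as.numeric(blocked)
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact forward-model points are legal
  slope <- unname(coef(fit)[2L])
  slope_se <- sm$coefficients[2L, 2L]
  p_value <- sm$coefficients[2L, 4L]
  r2 <- sm$r.squared
  v_nd <- if (is.finite(slope) && slope > 0) {
    -unname(coef(fit)[1L]) / slope
  } else NA_real_
  reliable <- is.finite(slope) && slope > 0 && is.finite(r2) && r2 >= r2_min
  structure(list(occupancy = slope,
                 v_nd = v_nd,
                 slope_se = slope_se,
                 r_squared = r2,
                 p_value = p_value,
                 points = data.frame(region = names(baseline),
                                     baseline = x, delta = y),
                 reliable = reliable,
                 occupancy_in_range = is.finite(slope) && slope >= 0 && slope <= 1,
                 surrogate = surrogate),
            class = "lassen_fit")
}

#' @export
print.lassen_fit <- function(x, ...) {
  cat(sprintf(
    "<lassen_fit>%s occupancy = %.1f%%, V_ND = %s (r2 = %.3f, p = %.2g, %s)\n",
    if (x$surrogate) " [SUV surrogate]" else "",
    100 * x$occupancy,
    if (is.na(x$v_nd)) "NA" else sprintf("%.3g", x$v_nd),
    x$r_squared, x$p_value,
    if (x$reliable) "reliable" else "UNRELIABLE"))
  invisible(x)
}

#' Lassen plot on SUV as a surrogate for V_T
#'
#' Identical arithmetic to [lassen()] with regional SUVs in place of
#' fully quantified distribution volumes, used when no arterial input
#' is available. The result is only meaningful if SUV is proportional
#' to V_T across regions — an assumption that cannot be checked without
#' arterial data, so the fit is labelled as a surrogate.
#'
#' @param baseline_suv,blocked_suv named regional SUVs.
#' @inheritParams lassen
#' @return A `lassen_fit` with `surrogate = TRUE`; `v_nd` is in SUV
#'   units.
#' @export
lassen_suv_surrogate <- function(baseline_suv, blocked_suv, r2_min = 0.5) {
  lassen(baseline_suv, blocked_suv, r2_min = r2_min, surrogate = TRUE)
}

#' Binding potential relative to the nondisplaceable compartment
#'
#' `BP_ND = (V_T - V_ND) / V_ND`, the ratio of specific to
#' nondisplaceable uptake.
#'
#' @param v_t total distribution volume (mL cm-3).
#' @param v_nd nondisplaceable distribution volume (> 0).
#' @return Unitless binding potential (>= -1 whenever `v_t >= 0`).
#' @export
bp_nd <- function(v_t, v_nd) {
  assert_scalar_num(v_t, "v_t")
  assert_scalar_num(v_nd, "v_nd")
  if (v_nd <= 0) stop("v_nd must be > 0", call. = FALSE)
  (v_t - v_nd) / v_nd
}

#' Percent change between two values
#'
#' `100 * (after - before) / before`; rounding happens only at
#' presentation, never here.
#'
#' @param before,after values in the same units; `before` non-zero.
#' @return Percent change (signed).
#' @export
percent_change <- function(before, after) {
  assert_scalar_num(before, "before")
  assert_scalar_num(after, "after")
  if (before == 0) stop("percent change undefined for before = 0", call. = FALSE)
  100 * (after - before) / before
}

#' Arithmetic mean of per-animal values
#'
#' @param values non-empty numeric vector.
#' @return The mean (full precision; round at presentation).
#' @export
group_mean <- function(values) {
  if (!length(values)) stop("cannot average an empty set", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  mean(values)
}

#' Right-to-left uptake ratio
#'
#' @param right,left uptake values; `left > 0`.
#' @return `right / left`.
#' @export
rl_ratio <- function(right, left) {
  assert_scalar_num(right, "right")
  assert_scalar_num(left, "left")
  if (left <= 0) stop("left-side value must be > 0", call. = FALSE)
  right / left
}
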