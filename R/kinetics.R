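#' Regional time-activity curve
#'
#' @param region region label.
#' @param schedule a [frame_schedule()].
#' @param values frame-averaged activity concentration (kBq/mL), one per
#'   frame, finite.
#' @param weights optional positive per-frame weights (carried for
#'   downstream fitters; the Logan fit here is unweighted).
#' @return An object of class `tac`.
#' @export
tac <- function(region, schedule, values, weights = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(values) != n_frames(schedule)) {
    stop("values must have one entry per frame", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("TAC values must be finite", call. = FALSE)
  if (!is.null(weights)) {
    if (length(weights) != length(values) || any(weights <= 0)) {
      stop("weights must be positive and match the frame count", call. = FALSE)
    }
  }
  structure(list(region = as.character(region), schedule = schedule,
                 values = as.numeric(values), weights = weights),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> region '%s', %d frames to %g min, peak %.3g kBq/mL\n",
              x$region, n_frames(x$schedule), max(x$schedule$end),
              max(x$values)))
  invisible(x)
}

# Logan transformed coordinates at frame midpoints:
#   x = int_0^t Cp / C_tissue,  y = int_0^t C_tissue / C_tissue
# Integrals by trapezoid on the frame grid with the input resampled to
# frame midpoints and both curves taken as 0 at injection.
logan_points <- function(tc, input) {
  mid <- frame_midpoints(tc$schedule)
  cp <- input_value(input, mid)
  grid <- c(0, mid)
  icp <- cumtrapz0(grid, c(input_value(input, 0), cp))[-1L]
  ict <- cumtrapz0(grid, c(0, tc$values))[-1L]
  data.frame(mid = mid, ct = tc$values,
             x = icp / tc$values, y = ict / tc$values)
}

#' Logan graphical estimation of the distribution volume
#'
#' The Logan plot transforms a time-activity curve and the
#' metabolite-corrected arterial input into coordinates
#' \eqn{x(t) = \int_0^t C_p / C_T(t)} and
#' \eqn{y(t) = \int_0^t C_T / C_T(t)} that become linear for reversible
#' tracers once equilibration is reached; the asymptotic slope is the
#' total distribution volume V_T. Ordinary least squares is fitted to
#' the points with frame midpoint at or after `t_star`.
#'
#' @param tc a [tac()].
#' @param input an [input_function()].
#' @param t_star start of the linear segment (minutes); must leave at
#'   least 3 frames in the fit and lie within the scan.
#' @return A `logan_fit` list: `v_t` (mL cm-3), `intercept` (minutes),
#'   `t_star`, `r_squared`, `n_points`, and the point table.
#' @export
logan_vt <- function(tc, input, t_star = 30) {
  stopifnot(inherits(tc, "tac"), inherits(input, "input_function"))
  scan_end <- max(tc$schedule$end)
  assert_scalar_num(t_star, "t_star", lower = 0, upper = scan_end)
  pts <- logan_points(tc, input)
  sel <- pts$mid >= t_star
  if (sum(sel) < 3L) {
    stop(sprintf("only %d frames at/after t* = %g min; need at least 3",
                 sum(sel), t_star), call. = FALSE)
  }
  bad <- which(sel & pts$ct <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive tissue value in the fit window at frame %d (midpoint %g min)",
                 bad[1L], pts$mid[bad[1L]]), call. = FALSE)
  }
  fit <- lm(y ~ x, data = pts[sel, ])
  sm <- suppressWarnings(summary(fit))  # exact proportional curves are legal
  structure(list(v_t = unname(coef(fit)[2L]),
                 intercept = unname(coef(fit)[1L]),
                 t_star = t_star,
                 r_squared = sm$r.squared,
                 n_points = sum(sel),
                 points = pts),
            class = "logan_fit")
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf("<logan_fit> V_T = %.4g mL/cm3 (t* = %g min, n = %d, r2 = %.4f)\n",
              x$v_t, x$t_star, x$n_points, x$r_squared))
  invisible(x)
}

#' Choose the start of the linear Logan segment
#'
#' Fits a reference line to the final third of the Logan points (at
#' least 3) and returns the earliest frame midpoint from which every
#' later point deviates from that line by at most `max_rel_err`
#' (relative to the point's ordinate). Falls back to mid-scan with a
#' warning when no midpoint qualifies or the points are unusable.
#'
#' @inheritParams logan_vt
#' @param max_rel_err maximum tolerated relative deviation (> 0).
#' @return t* in minutes.
#' @export
select_t_star <- function(tc, input, max_rel_err = 0.10) {
  stopifnot(inherits(tc, "tac"), inherits(input, "input_function"))
  assert_scalar_num(max_rel_err, "max_rel_err")
  if (max_rel_err <= 0) stop("max_rel_err must be > 0", call. = FALSE)
  fallback <- max(tc$schedule$end) / 2
  if (any(tc$values <= 0)) {
    warning("non-positive tissue values; falling back to mid-scan t*")
    return(fallback)
  }
  pts <- logan_points(tc, input)
  n <- nrow(pts)
  if (n < 4L) {
    warning("too few frames to assess linearity; falling back to mid-scan t*")
    return(fallback)
  }
  n_ref <- max(3L, ceiling(n / 3))
  ref <- pts[(n - n_ref + 1L):n, ]
  fit <- lm(y ~ x, data = ref)
  pred <- predict(fit, newdata = pts)
  dev <- abs(pts$y - pred) / pmax(abs(pts$y), .Machine$double.eps)
  ok_from <- rev(cumprod(rev(dev <= max_rel_err))) > 0  # all later points ok
  candidates <- which(ok_from)
  candidates <- candidates[candidates <= n - 2L]  # keep >= 3 fit points
  if (!length(candidates)) {
    warning("no midpoint satisfies the linearity tolerance; falling back to mid-scan t*")
    return(fallback)
  }
  pts$mid[candidates[1L]]
}

#' Standardized uptake value over a time window
#'
#' SUV = mean tissue concentration over the window divided by injected
#' dose per body weight, with the 1 mL = 1 g mass convention (no tissue
#' density correction). The mean is weighted by each frame's overlap
#' with the window.
#'
#' @param tc a [tac()].
#' @param injected_dose injected activity in MBq (> 0).
#' @param body_weight body weight in kg (> 0).
#' @param window `c(start, end)` minutes, within the scan; default the
#'   60-90 min window used for cross-comparison when arterial data are
#'   unavailable.
#' @return A `suv_measure` list: `suv`, `window`, `mean_conc`.
#' @export
suv <- function(tc, injected_dose, body_weight, window = c(60, 90)) {
  stopifnot(inherits(tc, "tac"))
  assert_scalar_num(injected_dose, "injected_dose")
  assert_scalar_num(body_weight, "body_weight")
  if (injected_dose <= 0 || body_weight <= 0) {
    stop("injected_dose and body_weight must be > 0", call. = FALSE)
  }
  if (length(window) != 2L || window[1L] >= window[2L]) {
    stop("window must be c(start, end) with start < end", call. = FALSE)
  }
  if (window[1L] < min(tc$schedule$start) - 1e-9 ||
      window[2L] > max(tc$schedule$end) + 1e-9) {
    stop(sprintf("window [%g, %g] lies outside the scan [%g, %g]",
                 window[1L], window[2L], min(tc$schedule$start),
                 max(tc$schedule$end)), call. = FALSE)
  }
  overlap <- pmax(0, pmin(tc$schedule$end, window[2L]) -
                     pmax(tc$schedule$start, window[1L]))
  if (sum(overlap) <= 0) stop("window overlaps no frame", call. = FALSE)
  mean_conc <- sum(tc$values * overlap) / sum(overlap)
  # kBq/mL / (MBq*1000 kBq / (kg*1000 g)) = conc * kg / MBq
  structure(list(suv = mean_conc * body_weight / injected_dose,
                 window = window, mean_conc = mean_conc),
            class = "suv_measure")
}

as_suv_value <- function(x) {
  if (inherits(x, "suv_measure")) x$suv else {
    assert_scalar_num(x, "suv", lower = 0); x
  }
}

#' Specific uptake as a baseline-minus-blocked SUV ratio difference
#'
#' When blood limits preclude full arterial quantification, specific
#' binding is summarized as the difference of the brain-to-blood SUV
#' ratio between baseline and (self-)blocked conditions:
#' `(brain/blood)_baseline - (brain/blood)_blocked`.
#'
#' @param brain_suv_base,blood_suv_base,brain_suv_block,blood_suv_block
#'   SUVs (numbers or `suv_measure` objects); blood SUVs must be > 0.
#' @return The unitless ratio difference.
#' @export
suv_ratio_specific <- function(brain_suv_base, blood_suv_base,
                               brain_suv_block, blood_suv_block) {
  b0 <- as_suv_value(blood_suv_base); b1 <- as_suv_value(blood_suv_block)
  if (b0 <= 0 || b1 <= 0) stop("blood SUV must be > 0", call. = FALSE)
  as_suv_value(brain_suv_base) / b0 - as_suv_value(brain_suv_block) / b1
}

#' Read / write time-activity curve tables
#'
#' Delimited text with columns `frame_start_min`, `frame_end_min`, then
#' one column of kBq/mL values per region.
#'
#' @param path file path.
#' @param tacs a single [tac()] or a list of `tac`s sharing a schedule.
#' @param sep field separator (default tab).
#' @return `read_tacs()` returns a named list of [tac()] objects.
#' @export
read_tacs <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (!all(c("frame_start_min", "frame_end_min") %in% names(d))) {
    stop("TAC file must have frame_start_min and frame_end_min columns",
         call. = FALSE)
  }
  sch <- frame_schedule(d$frame_start_min, d$frame_end_min)
  regions <- setdiff(names(d), c("frame_start_min", "frame_end_min"))
  if (!length(regions)) stop("TAC file contains no region columns", call. = FALSE)
  setNames(lapply(regions, function(r) tac(r, sch, d[[r]])), regions)
}

#' @rdname read_tacs
#' @export
write_tacs <- function(tacs, path, sep = "\t") {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  stopifnot(all(vapply(tacs, inherits, logical(1), "tac")))
  sch <- tacs[[1L]]$schedule
  d <- data.frame(frame_start_min = sch$start, frame_end_min = sch$end)
  for (tc in tacs) {
    if (!isTRUE(all.equal(tc$schedule$start, sch$start))) {
      stop("all TACs in one file must share a schedule", call. = FALSE)
    }
    d[[tc$region]] <- tc$values
  }
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
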