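#' Metabolite-corrected arterial input function
#'
#' The input function is the concentration of unmetabolized (parent)
#' radioligand in arterial plasma over time — the driving term of all
#' kinetic analyses. The plasma free fraction `f_p` is carried as
#' metadata only (it is measured by ultrafiltration upstream and not
#' used by the graphical analyses here).
#'
#' @param times minutes, strictly ascending, non-negative.
#' @param parent_plasma parent radioligand concentration (kBq/mL),
#'   non-negative, same length as `times`.
#' @param whole_blood optional whole-blood (or total plasma) activity
#'   curve at the same times, used for blood-volume terms and SUV
#'   ratios.
#' @param f_p plasma free fraction in `(0, 1]`, or `NA`.
#' @return An object of class `input_function`.
#' @export
input_function <- function(times, parent_plasma, whole_blood = NULL,
                           f_p = NA_real_) {
  if (length(times) != length(parent_plasma)) {
    stop("times and parent_plasma must have the same length", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  assert_ascending(times)
  if (any(parent_plasma < -1e-9)) {
    stop("parent_plasma must be non-negative", call. = FALSE)
  }
  if (!is.null(whole_blood) && length(whole_blood) != length(times)) {
    stop("whole_blood must match times in length", call. = FALSE)
  }
  if (!is.na(f_p) && (f_p <= 0 || f_p > 1)) {
    stop("f_p must be in (0, 1]", call. = FALSE)
  }
  structure(list(times = as.numeric(times),
                 parent_plasma = pmax(as.numeric(parent_plasma), 0),
                 whole_blood = if (!is.null(whole_blood)) as.numeric(whole_blood),
                 f_p = f_p),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("<input_function> %d samples, %g-%g min, peak %.3g kBq/mL\n",
              length(x$times), min(x$times), max(x$times),
              max(x$parent_plasma)))
  invisible(x)
}

#' Evaluate an input function at arbitrary times
#'
#' Linear interpolation between samples; before the first sample the
#' curve rises linearly from (0, 0).
#'
#' @param input an [input_function()].
#' @param t times in minutes within the support.
#' @return Parent plasma concentration at `t`.
#' @export
input_value <- function(input, t) {
  stopifnot(inherits(input, "input_function"))
  x <- input$times; y <- input$parent_plasma
  if (x[1L] > 0) { x <- c(0, x); y <- c(0, y) }
  interp_strict(x, y, t, "input function")
}

#' Arterial blood sampling schedule of the reference protocol
#'
#' Rapid sampling at 15-second intervals for the first 120 seconds,
#' followed by discrete samples at 3, 5, 10, 30, 60, 90 and 120 minutes
#' — 15 draw times in total.
#'
#' @return Numeric vector of sample times in minutes.
#' @export
default_sampling_times <- function() {
  c(seq(0.25, 2, by = 0.25), 3, 5, 10, 30, 60, 90, 120)
}

#' Timed arterial blood samples
#'
#' @param time draw times (minutes, midpoint of the draw), ascending.
#' @param whole_blood,plasma activity concentrations (kBq/mL).
#' @param parent_fraction measured parent fraction in `[0, 1]`; `NA`
#'   where not assayed (late thin samples are often skipped).
#' @return A `data.frame` of class `blood_samples`.
#' @export
blood_samples <- function(time, whole_blood, plasma,
                          parent_fraction = NA_real_) {
  n <- length(time)
  parent_fraction <- rep_len(parent_fraction, n)
  if (length(whole_blood) != n || length(plasma) != n) {
    stop("all sample columns must share the length of 'time'", call. = FALSE)
  }
  if (any(time < 0)) stop("sample times must be non-negative", call. = FALSE)
  assert_ascending(time, "sample times")
  if (any(whole_blood < 0) || any(plasma < 0)) {
    stop("activity concentrations must be non-negative", call. = FALSE)
  }
  pf <- parent_fraction[!is.na(parent_fraction)]
  if (any(pf < 0 | pf > 1)) {
    stop("parent_fraction values must lie in [0, 1]", call. = FALSE)
  }
  structure(data.frame(time = time, whole_blood = whole_blood,
                       plasma = plasma, parent_fraction = parent_fraction),
            class = c("blood_samples", "data.frame"))
}

#' Fit a smooth parent-fraction curve to measured fractions
#'
#' The fraction of plasma activity that is unmetabolized parent is
#' modelled as a single decaying exponential with plateau,
#' \eqn{pf(t) = (1 - c) e^{-\lambda t} + c}, with \eqn{0 \le c \le 1}
#' and \eqn{\lambda \ge 0}, fitted by least squares to the samples that
#' carry a measured fraction. The model is 1 at injection and
#' non-increasing by construction.
#'
#' @param samples a [blood_samples()] with at least 3 measured
#'   parent fractions.
#' @return A function of time (minutes) returning the fitted fraction,
#'   with attributes `coef` (`lambda`, `plateau`) and `residuals`.
#' @export
fit_parent_fraction <- function(samples) {
  stopifnot(inherits(samples, "blood_samples"))
  ok <- !is.na(samples$parent_fraction)
  if (sum(ok) < 3L) {
    stop("need at least 3 samples with a measured parent fraction",
         call. = FALSE)
  }
  t <- samples$time[ok]; f <- samples$parent_fraction[ok]
  sse <- function(p) {
    lam <- exp(p[1]); c0 <- stats::plogis(p[2])
    sum((f - ((1 - c0) * exp(-lam * t) + c0))^2)
  }
  # two starts guard against the plateau/decay trade-off local minimum
  starts <- list(c(log(0.05), stats::qlogis(0.2)),
                 c(log(0.005), stats::qlogis(0.01)))
  fits <- lapply(starts, function(s) optim(s, sse, method = "Nelder-Mead",
                                           control = list(maxit = 2000)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  lam <- exp(best$par[1]); c0 <- stats::plogis(best$par[2])
  fitted <- (1 - c0) * exp(-lam * t) + c0
  curve <- function(tt) {
    v <- (1 - c0) * exp(-lam * tt) + c0
    pmin(pmax(v, 0), 1)
  }
  attr(curve, "coef") <- c(lambda = lam, plateau = c0)
  attr(curve, "residuals") <- f - fitted
  class(curve) <- c("parent_fraction_fit", "function")
  curve
}

#' Build a metabolite-corrected input function from blood samples
#'
#' Parent plasma concentration at each sample time is
#' `plasma * pf(time)`; between samples the curve is linearly
#' interpolated, and before the first sample it rises linearly from
#' (0, 0). Linear (not spline) interpolation avoids overshoot on the
#' sparse late samples.
#'
#' @param samples a [blood_samples()].
#' @param pf_curve a parent-fraction curve, e.g. from
#'   [fit_parent_fraction()]; defaults to no metabolite correction
#'   (fraction 1 everywhere).
#' @param f_p plasma free fraction metadata.
#' @return An [input_function()] carrying the whole-blood curve.
#' @export
build_input <- function(samples, pf_curve = function(t) rep(1, length(t)),
                        f_p = NA_real_) {
  stopifnot(inherits(samples, "blood_samples"))
  if (nrow(samples) == 0L) stop("no blood samples supplied", call. = FALSE)
  pf <- pf_curve(samples$time)
  if (any(pf < -1e-9 | pf > 1 + 1e-9)) {
    warning("parent-fraction curve left [0, 1]; values clamped")
    pf <- pmin(pmax(pf, 0), 1)
  }
  input_function(samples$time, samples$plasma * pf,
                 whole_blood = samples$whole_blood, f_p = f_p)
}

#' Read / write blood sample tables
#'
#' Delimited text with columns `time_min`, `whole_blood_kBq_per_mL`,
#' `plasma_kBq_per_mL`, `parent_fraction` (blank where not assayed).
#'
#' @param path file path.
#' @param samples a [blood_samples()].
#' @param sep field separator (default tab).
#' @return `read_blood_samples()` returns a [blood_samples()];
#'   `write_blood_samples()` returns `path` invisibly.
#' @export
read_blood_samples <- function(path, sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         na.strings = c("NA", ""))
  need <- c("time_min", "whole_blood_kBq_per_mL", "plasma_kBq_per_mL",
            "parent_fraction")
  if (!all(need %in% names(d))) {
    stop("blood file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  blood_samples(d$time_min, d$whole_blood_kBq_per_mL, d$plasma_kBq_per_mL,
                d$parent_fraction)
}

#' @rdname read_blood_samples
#' @export
write_blood_samples <- function(samples, path, sep = "\t") {
  stopifnot(inherits(samples, "blood_samples"))
  d <- data.frame(time_min = samples$time,
                  whole_blood_kBq_per_mL = samples$whole_blood,
                  plasma_kBq_per_mL = samples$plasma,
                  parent_fraction = samples$parent_fraction)
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
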