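#' Rate constants of a reversible one- or two-tissue compartment model
#'
#' `K1` (mL cm-3 min-1) is the plasma-to-tissue delivery constant, `k2`
#' (min-1) the tissue-to-plasma washout, `k3`/`k4` (min-1) the exchange
#' with the specifically bound compartment, and `vB` the fractional blood
#' volume contributing to the measured signal. Setting `k3 = 0` gives the
#' one-tissue model.
#'
#' @param K1,k2,k3,k4 rate constants; `K1, k2 > 0`, `k3, k4 >= 0`, and
#'   `k4 > 0` whenever `k3 > 0` (otherwise the distribution volume is
#'   undefined).
#' @param vB blood-volume fraction in `[0, 0.2)`; default 0 (regional
#'   curves are assumed blood-corrected unless stated).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, k3 = 0, k4 = 0, vB = 0) {
  assert_scalar_num(K1, "K1"); assert_scalar_num(k2, "k2")
  assert_scalar_num(k3, "k3"); assert_scalar_num(k4, "k4")
  assert_scalar_num(vB, "vB")
  if (K1 <= 0 || k2 <= 0) stop("K1 and k2 must be > 0", call. = FALSE)
  if (k3 < 0 || k4 < 0) stop("k3 and k4 must be >= 0", call. = FALSE)
  if (k3 > 0 && k4 == 0) {
    stop("k3 > 0 requires k4 > 0: V_T is undefined for an irreversible trap",
         call. = FALSE)
  }
  if (vB < 0 || vB >= 0.2) stop("vB must be in [0, 0.2)", call. = FALSE)
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB),
            class = "kinetic_params")
}

#' Analytic distribution volume of a compartment model
#'
#' Total distribution volume `V_T = K1/k2 * (1 + k3/k4)` for the
#' two-tissue model, reducing to `K1/k2` when `k3 = 0`. This is the
#' equilibrium tissue-to-plasma concentration ratio that the Logan plot
#' estimates as its slope.
#'
#' @param params a [kinetic_params()].
#' @return V_T in mL cm-3.
#' @examples
#' analytic_vt(kinetic_params(0.1, 0.1, 0.05, 0.05)) # 2.0
#' @export
analytic_vt <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  with(params, if (k3 == 0) K1 / k2 else K1 / k2 * (1 + k3 / k4))
}

#' Parametric model of a metabolite-corrected arterial input function
#'
#' Parent plasma concentration is modelled as a peaked tri-exponential,
#' \deqn{C_p(t) = A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}
#'   - (A_1 + A_2) e^{-\lambda_0 t},}
#' which is zero at injection, rises with rate `rise` (\eqn{\lambda_0}) to
#' a single early peak and decays through a fast and a slow clearance
#' term. The companion parent-fraction model
#' \eqn{pf(t) = (1 - c) e^{-\lambda_{pf} t} + c} describes the fraction of
#' plasma activity that is unmetabolized radioligand, used when a total
#' plasma curve is needed alongside the parent curve.
#'
#' Defaults give a peak of about 30 kBq/mL within the first minute and a
#' terminal level below 10% of the peak at 120 min, resembling a
#' carbon-11 radioligand after bolus injection.
#'
#' @param amplitudes two decay-term amplitudes `c(A1, A2)` (kBq/mL),
#'   non-negative.
#' @param decay two decay rates `c(lambda1, lambda2)` (min-1), positive,
#'   fast then slow.
#' @param rise rate of the rising term (min-1), larger than both decays.
#' @param pf_lambda,pf_plateau parent-fraction decay rate (min-1) and
#'   plateau `c` in `[0, 1]`.
#' @return An object of class `input_model_params`.
#' @export
input_model_params <- function(amplitudes = c(35, 3),
                               decay = c(0.25, 0.0015),
                               rise = 4,
                               pf_lambda = 0.04,
                               pf_plateau = 0.15) {
  if (length(amplitudes) != 2L || any(amplitudes < 0)) {
    stop("amplitudes must be two non-negative numbers", call. = FALSE)
  }
  if (length(decay) != 2L || any(decay <= 0)) {
    stop("decay must be two positive rates", call. = FALSE)
  }
  assert_scalar_num(rise, "rise", lower = 0)
  if (rise <= max(decay)) stop("rise rate must exceed both decay rates", call. = FALSE)
  assert_scalar_num(pf_lambda, "pf_lambda", lower = 0)
  assert_scalar_num(pf_plateau, "pf_plateau", lower = 0, upper = 1)
  structure(list(amplitudes = amplitudes, decay = decay, rise = rise,
                 pf_lambda = pf_lambda, pf_plateau = pf_plateau),
            class = "input_model_params")
}

# closed-form evaluation of the tri-exponential parent curve
eval_input_model <- function(params, t) {
  A <- params$amplitudes; l <- params$decay
  v <- A[1] * exp(-l[1] * t) + A[2] * exp(-l[2] * t) -
    sum(A) * exp(-params$rise * t)
  pmax(v, 0)
}

#' Parent-fraction curve of an input model
#'
#' @param params an [input_model_params()].
#' @return A function of time (minutes) returning the modelled parent
#'   fraction in `[0, 1]`.
#' @export
model_parent_fraction <- function(params) {
  stopifnot(inherits(params, "input_model_params"))
  c0 <- params$pf_plateau; lam <- params$pf_lambda
  function(t) (1 - c0) * exp(-lam * t) + c0
}

#' Simulate a metabolite-corrected arterial input function
#'
#' Evaluates the closed-form tri-exponential parent plasma curve at the
#' given times. A whole-blood curve (total plasma back-computed from the
#' parent-fraction model, with unit plasma-to-blood ratio) is carried
#' along for blood-volume correction and SUV-ratio work.
#'
#' @param params an [input_model_params()].
#' @param times sample times in minutes, strictly ascending, `>= 0`.
#' @param f_p plasma free fraction metadata in `(0, 1]`, or `NA` if not
#'   measured.
#' @return An [input_function()].
#' @export
simulate_input <- function(params = input_model_params(),
                           times = seq(0, 120, by = 0.1),
                           f_p = NA_real_) {
  stopifnot(inherits(params, "input_model_params"))
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  assert_ascending(times)
  parent <- eval_input_model(params, times)
  pf <- model_parent_fraction(params)(times)
  total_plasma <- ifelse(pf > 0, parent / pf, parent)
  input_function(times, parent, whole_blood = total_plasma, f_p = f_p)
}

# impulse response (tissue concentration after a unit plasma impulse)
tissue_irf <- function(params, t) {
  with(params, {
    if (k3 == 0) return(K1 * exp(-k2 * t))
    s <- k2 + k3 + k4
    d <- sqrt(s^2 - 4 * k2 * k4)
    th1 <- (s + d) / 2
    th2 <- (s - d) / 2
    K1 * ((th1 - k3 - k4) * exp(-th1 * t) +
          (k3 + k4 - th2) * exp(-th2 * t)) / (th1 - th2)
  })
}

#' Frame-level noise model for simulated time-activity curves
#'
#' With `kind = "proportional"`, zero-mean Gaussian noise with standard
#' deviation `coefficient * value / sqrt(frame duration)` is added per
#' frame, mimicking how count statistics improve with frame length.
#' `kind = "none"` is fully deterministic.
#'
#' @param kind `"none"` or `"proportional"`.
#' @param coefficient non-negative noise scale.
#' @param seed integer seed used when noise is drawn.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "proportional"),
                        coefficient = 0, seed = 1L) {
  kind <- match.arg(kind)
  assert_scalar_num(coefficient, "coefficient", lower = 0)
  structure(list(kind = kind, coefficient = coefficient,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Simulate a regional time-activity curve
#'
#' Solves the compartment system by convolving the analytic impulse
#' response with the input function on a fine time grid (trapezoidal
#' rule), averages the solution within each frame, adds the fractional
#' blood-volume signal `vB * whole_blood`, and applies the noise model.
#'
#' @param params a [kinetic_params()].
#' @param input an [input_function()] whose support covers the schedule.
#' @param schedule a [frame_schedule()].
#' @param noise a [noise_model()]; default none.
#' @param region region label attached to the returned curve.
#' @param dt fine-grid resolution in minutes (default 0.1).
#' @return A [tac()] with one value per frame (kBq/mL).
#' @export
simulate_tac <- function(params, input, schedule,
                         noise = noise_model(), region = "region",
                         dt = 0.1) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(input, "input_function"),
            inherits(schedule, "frame_schedule"),
            inherits(noise, "noise_model"))
  t_end <- max(schedule$end)
  if (max(input$times) < t_end - 1e-9) {
    stop(sprintf(
      "schedule extends to %g min but input support ends at %g min",
      t_end, max(input$times)), call. = FALSE)
  }
  grid <- seq(0, t_end, by = dt)
  cp <- interp_strict(input$times, input$parent_plasma, grid, "input function")
  h <- tissue_irf(params, grid)
  n <- length(grid)
  ct <- stats::convolve(cp, rev(h), type = "open")[seq_len(n)] * dt
  # trapezoid end-correction of the Riemann convolution
  ct <- ct - dt * 0.5 * (cp[1L] * h + cp * h[1L])
  ct <- pmax(ct, 0)
  if (params$vB > 0) {
    wb <- if (!is.null(input$whole_blood)) input$whole_blood else input$parent_plasma
    wbg <- interp_strict(input$times, wb, grid, "whole-blood curve")
    ct <- (1 - params$vB) * ct + params$vB * wbg
  }
  vals <- vapply(seq_len(n_frames(schedule)), function(i) {
    sel <- grid >= schedule$start[i] - 1e-9 & grid <= schedule$end[i] + 1e-9
    mean(ct[sel])
  }, numeric(1))
  if (noise$kind == "proportional" && noise$coefficient > 0) {
    durs <- frame_durations(schedule)
    withr::local_seed(noise$seed)
    vals <- vals + rnorm(length(vals),
                         sd = noise$coefficient * vals / sqrt(durs))
    vals <- pmax(vals, 0)
  }
  tac(region = region, schedule = schedule, values = vals)
}

#' Scale specific binding by a target occupancy
#'
#' Forward model of pharmacological blockade: returns rate constants
#' whose distribution volume equals
#' `V_ND + (1 - occupancy) * (V_T - V_ND)`, where `V_T` is the analytic
#' distribution volume of `params` and `V_ND` that of `vnd_params` (the
#' nondisplaceable component). The adjustment is carried by `k3` when the
#' target V_T stays at or above the region's own `K1/k2`; otherwise `k3`
#' is set to 0 and `k2` rescaled so the analytic V_T still matches the
#' target.
#'
#' @param params baseline [kinetic_params()].
#' @param occupancy fraction of sites blocked, in `[0, 1]`.
#' @param vnd_params [kinetic_params()] describing the nondisplaceable
#'   distribution volume.
#' @return Blocked [kinetic_params()].
#' @export
apply_blocking <- function(params, occupancy, vnd_params) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(vnd_params, "kinetic_params"))
  assert_scalar_num(occupancy, "occupancy", lower = 0, upper = 1)
  v_t <- analytic_vt(params)
  v_nd <- analytic_vt(vnd_params)
  target <- v_nd + (1 - occupancy) * (v_t - v_nd)
  own_nd <- params$K1 / params$k2
  if (target >= own_nd && params$k4 > 0) {
    k3 <- params$k4 * (target * params$k2 / params$K1 - 1)
    kinetic_params(params$K1, params$k2, k3, params$k4, params$vB)
  } else {
    kinetic_params(params$K1, params$K1 / target, 0, 0, params$vB)
  }
}
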