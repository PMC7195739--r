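test_that("kinetic parameter validation catches unphysical rate constants", {
  expect_error(kinetic_params(0, 0.1), "K1 and k2")
  expect_error(kinetic_params(0.1, 0.1, k3 = 0.05, k4 = 0), "irreversible")
  expect_error(kinetic_params(0.1, 0.1, vB = 0.3), "vB")
  expect_s3_class(kinetic_params(0.1, 0.1, 0.05, 0.05), "kinetic_params")
})

test_that("analytic V_T follows the compartmental closed form", {
  expect_equal(analytic_vt(kinetic_params(0.1, 0.1)), 1.0)
  expect_equal(analytic_vt(kinetic_params(0.1, 0.1, 0.05, 0.05)), 2.0)
  expect_equal(analytic_vt(kinetic_params(0.3, 0.1, 0.2, 0.1)), 9.0)
})

test_that("analytic V_T is monotone in each rate constant", {
  base <- list(K1 = 0.1, k2 = 0.1, k3 = 0.05, k4 = 0.05)
  vt <- function(p) analytic_vt(do.call(kinetic_params, p))
  eps <- 1e-4
  for (par in c("K1", "k3")) {
    up <- base; up[[par]] <- up[[par]] + eps
    expect_gt(vt(up), vt(base))
  }
  for (par in c("k2", "k4")) {
    up <- base; up[[par]] <- up[[par]] + eps
    expect_lt(vt(up), vt(base))
  }
})

test_that("simulated input is zero at injection, peaks early, decays", {
  t <- seq(0, 120, by = 0.05)
  inp <- simulate_input(input_model_params(), t)
  expect_equal(inp$parent_plasma[1L], 0)
  expect_true(all(inp$parent_plasma >= 0))
  t_peak <- t[which.max(inp$parent_plasma)]
  expect_lt(t_peak, 3)
  expect_lt(inp$parent_plasma[length(t)], 0.10 * max(inp$parent_plasma))

  # zero amplitudes give a flat zero curve
  z <- simulate_input(input_model_params(amplitudes = c(0, 0)), t)
  expect_equal(z$parent_plasma, rep(0, length(t)))

  # deterministic: identical calls give identical output
  expect_identical(simulate_input(input_model_params(), t)$parent_plasma,
                   inp$parent_plasma)

  expect_error(simulate_input(input_model_params(), c(0, 2, 1)),
               "index 3")
})

test_that("simulated TACs match an independent ODE solution", {
  # independent oracle: solve the 2TCM state equations with deSolve
  inp <- ref_input()
  sch <- ref_schedule()
  p <- ref_2t()
  tc <- simulate_tac(p, inp, sch)

  cp_fun <- approxfun(inp$times, inp$parent_plasma, rule = 2)
  rhs <- function(t, y, parms) {
    with(as.list(parms), {
      cp <- cp_fun(t)
      dc1 <- K1 * cp - (k2 + k3) * y[1] + k4 * y[2]
      dc2 <- k3 * y[1] - k4 * y[2]
      list(c(dc1, dc2))
    })
  }
  grid <- seq(0, 120, by = 0.05)
  sol <- deSolve::ode(c(0, 0), grid, rhs,
                      c(K1 = p$K1, k2 = p$k2, k3 = p$k3, k4 = p$k4),
                      method = "lsoda", rtol = 1e-8, atol = 1e-10)
  ct <- rowSums(sol[, 2:3])
  frame_ref <- vapply(seq_along(sch$start), function(i) {
    sel <- grid >= sch$start[i] & grid <= sch$end[i]
    mean(ct[sel])
  }, numeric(1))
  expect_lt(max(abs(tc$values - frame_ref)) / max(frame_ref), 0.01)
})

test_that("TAC simulation honours delivery, determinism and support checks", {
  inp <- ref_input()
  sch <- ref_schedule()
  # (near-)zero delivery: K1 at the validity boundary gives a null TAC
  tiny <- simulate_tac(kinetic_params(1e-12, 0.05), inp, sch)
  expect_lt(max(tiny$values), 1e-9)

  a <- simulate_tac(ref_2t(), inp, sch)
  b <- simulate_tac(ref_2t(), inp, sch)
  expect_identical(a$values, b$values)

  expect_error(simulate_tac(ref_2t(), ref_input(60), sch), "support ends")

  noisy <- simulate_tac(ref_2t(), inp, sch,
                        noise = noise_model("proportional", 0.05, seed = 9))
  noisy2 <- simulate_tac(ref_2t(), inp, sch,
                         noise = noise_model("proportional", 0.05, seed = 9))
  expect_identical(noisy$values, noisy2$values)
  expect_false(identical(noisy$values, a$values))
})

test_that("noise-free frame-averaged TACs are non-negative across kinetics", {
  inp <- ref_input()
  sch <- ref_schedule()
  for (K1 in c(0.05, 0.3)) for (k2 in c(0.05, 0.2)) {
    for (k3 in c(0, 0.1)) for (k4 in c(0.05)) {
      tc <- simulate_tac(kinetic_params(K1, k2, k3, k4), inp, sch)
      expect_true(all(tc$values >= 0))
    }
  }
})

test_that("one-tissue terminal tissue/plasma ratio approaches K1/k2", {
  p <- ref_1t()  # K1/k2 = 2
  ratios <- vapply(c(60, 120, 240), function(total) {
    inp <- ref_input(total)
    sch <- ref_schedule(total)
    tc <- simulate_tac(p, inp, sch)
    n <- length(tc$values)
    mid <- frame_midpoints(sch)[n]
    tc$values[n] / input_value(inp, mid)
  }, numeric(1))
  err <- abs(ratios - 2.0) / 2.0
  expect_true(all(diff(err) < 0))   # converging as the scan lengthens
  expect_lt(err[2L], 0.05)          # within 5% by 120 min
})

test_that("blocking scales specific binding by the occupancy fraction", {
  vnd <- kinetic_params(0.25, 0.25 / 4.3)
  base <- kinetic_params(0.25, 0.1, k3 = 0.3, k4 = 0.1)  # V_T = 10
  expect_equal(analytic_vt(base), 10)

  expect_equal(analytic_vt(apply_blocking(base, 0, vnd)), 10)
  expect_equal(analytic_vt(apply_blocking(base, 1, vnd)), 4.3)
  expect_equal(analytic_vt(apply_blocking(base, 0.78, vnd)), 5.554,
               tolerance = 1e-12)
  expect_error(apply_blocking(base, 1.2, vnd), "occupancy")
})
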