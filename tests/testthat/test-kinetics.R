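test_that("a tissue curve proportional to the input gives an exact Logan line", {
  inp <- ref_input()
  sch <- ref_schedule()
  mid <- frame_midpoints(sch)
  V <- 3.7
  tc <- tac("prop", sch, V * input_value(inp, mid))
  fit <- logan_vt(tc, inp, t_star = 30)
  expect_equal(fit$v_t, V, tolerance = 1e-9)
  expect_equal(fit$intercept, 0, tolerance = 1e-7)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("Logan slope recovers the analytic V_T of noise-free simulations", {
  inp <- ref_input()
  sch <- ref_schedule()
  fit2 <- logan_vt(simulate_tac(ref_2t(), inp, sch), inp, t_star = 30)
  expect_lt(abs(fit2$v_t - 2.0) / 2.0, 0.02)
  fit1 <- logan_vt(simulate_tac(ref_1t(), inp, sch), inp, t_star = 30)
  expect_lt(abs(fit1$v_t - 2.0) / 2.0, 0.01)
})

test_that("Logan rejects unusable fit windows by name", {
  inp <- ref_input()
  sch <- ref_schedule()
  vals <- simulate_tac(ref_2t(), inp, sch)$values
  vals[25L] <- 0
  expect_error(logan_vt(tac("r", sch, vals), inp, 30), "frame 25")
  expect_error(logan_vt(tac("r", sch, vals), inp, 118), "at least 3")
})

test_that("Logan analysis across the kinetic parameter box stays within 2%", {
  # slow washout corners need longer equilibration: 240-min scans, t* 120
  inp <- ref_input(240)
  sch <- ref_schedule(240)
  for (K1 in c(0.05, 0.3)) for (k2 in c(0.05, 0.2)) {
    for (k3 in c(0, 0.1)) for (k4 in c(0.02, 0.1)) {
      p <- kinetic_params(K1, k2, k3, k4)
      fit <- logan_vt(simulate_tac(p, inp, sch), inp, t_star = 120)
      expect_lt(abs(fit$v_t - analytic_vt(p)) / analytic_vt(p), 0.02)
    }
  }
})

test_that("Logan V_T is invariant under joint scaling of tissue and input", {
  inp <- ref_input()
  sch <- ref_schedule()
  tc <- simulate_tac(ref_2t(), inp, sch)
  v0 <- logan_vt(tc, inp, 30)$v_t
  c_scale <- 3.2
  inp_s <- input_function(inp$times, c_scale * inp$parent_plasma)
  tc_s <- tac(tc$region, sch, c_scale * tc$values)
  expect_equal(logan_vt(tc_s, inp_s, 30)$v_t, v0, tolerance = 1e-10)
})

test_that("Logan V_T under proportional noise is unbiased within 5%", {
  inp <- ref_input()
  sch <- ref_schedule()
  vts <- vapply(1:200, function(s) {
    tc <- simulate_tac(ref_2t(), inp, sch,
                       noise = noise_model("proportional", 0.05, seed = s))
    logan_vt(tc, inp, 30)$v_t
  }, numeric(1))
  expect_lt(abs(mean(vts) - 2.0) / 2.0, 0.05)
})

test_that("t* selection finds the linear segment and falls back on noise", {
  inp <- ref_input()
  sch <- ref_schedule()
  mid <- frame_midpoints(sch)

  tc_prop <- tac("prop", sch, 2 * input_value(inp, mid))
  expect_equal(select_t_star(tc_prop, inp), mid[1L])  # linear throughout

  tc2 <- simulate_tac(ref_2t(), inp, sch)
  expect_lte(select_t_star(tc2, inp, max_rel_err = 0.10), 40)

  noise_tac <- tac("noise", sch,
                   withr::with_seed(1, abs(rnorm(length(mid)))))
  expect_warning(ts <- select_t_star(noise_tac, inp, max_rel_err = 0.001),
                 "falling back")
  expect_equal(ts, 60)
})

test_that("SUV arithmetic follows the dose-per-weight convention", {
  sch <- ref_schedule()
  flat <- tac("r", sch, rep(18.5, length(sch$start)))
  m <- suv(flat, injected_dose = 185, body_weight = 10, window = c(60, 90))
  expect_equal(m$suv, 1.0)

  zero <- tac("r", sch, rep(0, length(sch$start)))
  expect_equal(suv(zero, 185, 10)$suv, 0)

  # duration-weighted mean over a window spanning unequal frames
  sch2 <- frame_schedule(c(0, 10), c(10, 30))
  two <- tac("r", sch2, c(2.0, 1.4))
  m2 <- suv(two, 100, 10, window = c(0, 30))
  expect_equal(m2$mean_conc, (10 * 2.0 + 20 * 1.4) / 30)
  expect_equal(m2$suv, 1.6 * 10 / 100)

  expect_error(suv(flat, 185, 10, window = c(60, 150)), "outside the scan")
})

test_that("specific uptake is the baseline-minus-blocked SUV ratio difference", {
  expect_equal(suv_ratio_specific(2, 1, 2, 1), 0)
  expect_equal(suv_ratio_specific(6.25, 1.0, 1.04, 1.0), 5.21)
  expect_equal(suv_ratio_specific(4.0, 2.0, 3.0, 2.0), 0.5)
  expect_error(suv_ratio_specific(1, 0, 1, 1), "blood SUV")
})

test_that("TAC tables survive a write/read round trip", {
  sch <- ref_schedule(90)
  t1 <- tac("putamen", sch, seq_along(sch$start) * 1.5)
  t2 <- tac("cerebellum", sch, seq_along(sch$start) * 0.9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tacs(list(t1, t2), path)
  back <- read_tacs(path)
  expect_named(back, c("putamen", "cerebellum"))
  expect_equal(back$putamen$values, t1$values)
  expect_equal(back$cerebellum$schedule$end, sch$end)
})
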