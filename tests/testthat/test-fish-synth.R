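test_that("scenes are reproducible and degenerate cases are clean", {
  p0 <- scene_params(n_nuclei = 0, n_autofluor = 0, size = c(64, 64))
  empty <- generate_scene(p0)
  expect_equal(nrow(empty$truth_nuclei), 0)
  expect_equal(nrow(empty$truth_spots), 0)
  expect_true(all(empty$images$dapi >= 0))

  p <- scene_params(n_nuclei = 30, size = c(192, 192), seed = 5L)
  a <- generate_scene(p)
  b <- generate_scene(p)
  expect_identical(a$images, b$images)
  expect_identical(a$truth_spots, b$truth_spots)
  c2 <- generate_scene(scene_params(n_nuclei = 30, size = c(192, 192),
                                    seed = 6L))
  expect_false(identical(a$images$cy3, c2$images$cy3))
})

test_that("every planted feature lies inside the image and is consistent", {
  sc <- generate_scene(scene_params(seed = 3L))
  nr <- nrow(sc$images$dapi); nc <- ncol(sc$images$dapi)
  with(sc$truth_spots, {
    expect_true(all(row >= 1 & row <= nr & col >= 1 & col <= nc))
    expect_true(all(nucleus_id %in% sc$truth_nuclei$id))
  })
  # per-nucleus truth counts equal the planted spot lists
  tally <- table(factor(sc$truth_spots$nucleus_id[sc$truth_spots$channel == "cy3"],
                        levels = sc$truth_nuclei$id))
  expect_equal(as.integer(tally), sc$truth_nuclei$n_cy3)
})

test_that("truth spot totals follow the Poisson sum", {
  p <- scene_params(size = c(768, 768), n_nuclei = 500, lambda_cy3 = 4,
                    lambda_cy5 = 0, coexpression = "independent",
                    n_autofluor = 0, seed = 21L)
  sc <- generate_scene(p)
  n <- nrow(sc$truth_nuclei)
  expect_gte(n, 450)  # placement succeeds for nearly all requested nuclei
  total <- sum(sc$truth_nuclei$n_cy3)
  expect_lt(abs(total - 4 * n), 3 * sqrt(4 * n))
})

test_that("per-cell counts at fixed lambda are exchangeable across cells", {
  p <- scene_params(size = c(768, 768), n_nuclei = 500, lambda_cy3 = 2,
                    lambda_cy5 = 0, coexpression = "independent",
                    n_autofluor = 0, seed = 22L)
  counts <- generate_scene(p)$truth_nuclei$n_cy3
  expected <- dpois(0:6, 2) * length(counts)
  observed <- vapply(0:6, function(k) sum(counts == k), numeric(1))
  # fold the tail so expected cells stay > 5
  observed[7] <- observed[7] + sum(counts > 6)
  expected[7] <- expected[7] + (1 - ppois(6, 2)) * length(counts)
  chi2 <- sum((observed - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 6))
})

test_that("truth summaries follow the closed-form Poisson tail", {
  mk <- function(lambda, seed) {
    generate_scene(scene_params(size = c(768, 768), n_nuclei = 500,
                                lambda_cy3 = lambda, lambda_cy5 = 0,
                                coexpression = "independent",
                                n_autofluor = 0, seed = seed))
  }
  s0 <- generate_scene(scene_params(lambda_cy3 = 0, lambda_cy5 = 0,
                                    coexpression = "independent", seed = 1L))
  expect_equal(scene_truth_summary(s0)$frac_cy3, 0)

  s10 <- mk(10, 31L)
  expect_gt(scene_truth_summary(s10)$frac_cy3, 0.99)

  s1 <- mk(1, 32L)
  f <- scene_truth_summary(s1)$frac_cy3
  p_true <- 1 - exp(-1) * 2  # P(N >= 2) at lambda 1
  n <- scene_truth_summary(s1)$n_cells
  expect_lt(abs(f - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
})

test_that("lambda inversion matches the Poisson expressing fraction", {
  for (f in c(0.05, 0.264, 0.6)) {
    lam <- lambda_for_expressing_fraction(f)
    expect_equal(expressing_fraction_for_lambda(lam), f, tolerance = 1e-9)
  }
  expect_equal(expressing_fraction_for_lambda(1), 1 - exp(-1) * 2)
})

test_that("fold scenarios plant the requested truth contrast", {
  for (fold in c(6, 20)) {
    sc <- fish_scenario(fold, size = c(512, 512), n_nuclei = 220)
    truth_frac <- function(params, seeds) {
      fr <- vapply(seeds, function(s) {
        params$seed <- s
        scene_truth_summary(generate_scene(params))$frac_cy3
      }, numeric(1))
      mean(fr)
    }
    f_ctrl <- truth_frac(sc$control, 1:4)
    f_trt <- truth_frac(sc$treated, 5:8)
    # binomial sampling error at ~880 cells per condition
    expect_lt(abs(f_ctrl - sc$control_fraction),
              3 * sqrt(sc$control_fraction * (1 - sc$control_fraction) / 880))
    expect_lt(abs(f_trt - sc$treated_fraction),
              3 * sqrt(sc$treated_fraction * (1 - sc$treated_fraction) / 880))
  }
})

test_that("scenes round-trip through TIFF plus truth sidecar", {
  sc <- generate_scene(scene_params(n_nuclei = 15, size = c(96, 96),
                                    seed = 12L))
  path <- withr::local_tempfile(fileext = ".tif")
  write_scene(sc, path)
  back <- read_scene(path)
  expect_named(back$images, c("dapi", "cy3", "cy5"))
  # 16-bit storage: recover within quantization of the global scale
  top <- max(unlist(sc$images))
  expect_lt(max(abs(back$images$cy3 - sc$images$cy3)), top / 65535 + 1e-9)
  expect_equal(back$truth_nuclei$n_cy3, sc$truth_nuclei$n_cy3)
  expect_equal(nrow(back$truth_autofluor), nrow(sc$truth_autofluor))
})
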