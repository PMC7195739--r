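test_that("segmentation finds isolated nuclei and splits touching pairs", {
  # one high-SNR elliptical nucleus away from the border
  img1 <- draw_nuclei_image(matrix(c(60, 60), 1), radii = 11)
  m1 <- segment_nuclei(img1, pixel_size = 0.31)
  expect_equal(nrow(m1$masks), 1L)
  expect_lt(abs(m1$masks$row - 60) + abs(m1$masks$col - 60), 3)

  # two nuclei overlapping by less than 30% of a radius: watershed splits
  img2 <- draw_nuclei_image(rbind(c(50, 50), c(50, 67)), radii = c(11, 11))
  m2 <- segment_nuclei(img2, pixel_size = 0.31)
  expect_equal(nrow(m2$masks), 2L)
  got <- m2$masks[order(m2$masks$col), ]
  expect_lt(max(abs(got$row - 50)), 2)
  expect_lt(max(abs(got$col - c(50, 67))), 2)

  # a nucleus crossing the border is excluded as an edge object
  img3 <- draw_nuclei_image(rbind(c(4, 60), c(70, 60)), radii = c(11, 11))
  m3 <- segment_nuclei(img3, pixel_size = 0.31)
  expect_equal(nrow(m3$masks), 1L)
  expect_gt(m3$masks$row, 30)
  expect_equal(m3$counts$edge_removed, 1L)

  # blank image: empty result, not an error
  blank <- matrix(100, 64, 64)
  expect_equal(nrow(segment_nuclei(blank, 0.31)$masks), 0L)
  expect_error(segment_nuclei(img1, pixel_size = 0), "pixel_size")
})

test_that("the area filter honours both reading directions of the 20 um2 rule", {
  img <- draw_nuclei_image(matrix(c(60, 60), 1), radii = 11)  # ~36 um2
  keep <- segment_nuclei(img, 0.31, fish_config(min_area_um2 = 20))
  expect_equal(nrow(keep$masks), 1L)
  literal <- segment_nuclei(img, 0.31,
                            fish_config(min_area_um2 = 0, max_area_um2 = 20))
  expect_equal(nrow(literal$masks), 0L)  # the literal exclusion kills it
})

test_that("search regions partition space without double assignment", {
  sc <- generate_scene(scene_params(seed = 4L))
  m <- segment_nuclei(sc$images$dapi, 0.31)
  # original mask pixels always keep their own label
  own <- m$label > 0
  expect_true(all(m$search_label[own] == m$label[own]))
  # search regions contain the masks and only kept ids
  expect_setequal(setdiff(unique(as.integer(m$search_label)), 0L),
                  m$masks$id)
  expect_true(all(m$search_label[m$label > 0] > 0))
})

test_that("spot detection thresholds, size-filters and assigns correctly", {
  img1 <- draw_nuclei_image(matrix(c(60, 60), 1), radii = 11)
  masks <- segment_nuclei(img1, 0.31)

  # uniform image: degenerate SD, zero spots
  flat <- matrix(100, 128, 128)
  expect_equal(nrow(detect_spots(flat, masks)), 0L)

  # one planted blob at SNR 10 inside the mask: exactly one assigned call
  spot <- draw_spot_image(60, 63, amp = 100, sigma = 1.2)
  calls <- detect_spots(spot, masks, channel = "cy3")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$nucleus_id, 1L)
  expect_equal(calls$status, "assigned")
  expect_lt(abs(calls$row - 60) + abs(calls$col - 63), 2)

  # a 1-px speck dies on the minimum-size criterion
  speck <- withr::with_seed(2, matrix(rnorm(128 * 128, 100, 10), 128, 128))
  speck[60, 55] <- 400
  none <- detect_spots(speck, masks, fish_config(spot_min_px = 2))
  expect_equal(nrow(none), 0L)
})

test_that("spot counts are conserved across filtering stages", {
  sc <- generate_scene(scene_params(seed = 8L))
  m <- segment_nuclei(sc$images$dapi, 0.31)
  for (ch in c("cy3", "cy5")) {
    calls <- detect_spots(sc$images[[ch]], m, channel = ch)
    k <- attr(calls, "counts")
    expect_equal(k$candidates, k$assigned + k$outside + k$size_filtered)
    expect_equal(nrow(calls), k$assigned + k$outside)
  }
})

test_that("raising the minimum spot size never increases the spot count", {
  sc <- generate_scene(scene_params(seed = 9L))
  m <- segment_nuclei(sc$images$dapi, 0.31)
  counts <- vapply(c(2, 4, 6, 9, 14), function(ms) {
    nrow(detect_spots(sc$images$cy3, m, fish_config(spot_min_px = ms)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("autofluorescence exclusion removes coincident pairs only once", {
  c3 <- make_spot_calls("cy3", row = c(10, 40, 70), col = c(10, 40, 70),
                        nucleus_id = c(1L, 2L, 3L))
  c5 <- make_spot_calls("cy5", row = c(10, 90), col = c(10.5, 90),
                        nucleus_id = c(1L, 4L))
  out <- remove_autofluorescence(c3, c5, tol = 1)
  expect_equal(out$n_removed, 1L)
  expect_equal(nrow(out$cy3), 2L)
  expect_equal(nrow(out$cy5), 1L)
  expect_true(all(out$removed_cy3$autofluor))

  # disjoint sets: nothing removed
  far <- remove_autofluorescence(c3, make_spot_calls("cy5", 100, 100, 5L), 1)
  expect_equal(far$n_removed, 0L)

  # two Cy3 spots exactly at tolerance from one Cy5: lowest index wins
  c3t <- make_spot_calls("cy3", row = c(20, 24), col = c(30, 30),
                         nucleus_id = c(1L, 1L))
  c5t <- make_spot_calls("cy5", row = 22, col = 30, nucleus_id = 1L)
  tie <- remove_autofluorescence(c3t, c5t, tol = 2)
  expect_equal(tie$n_removed, 1L)
  expect_equal(tie$removed_cy3$row, 20)  # first spot removed
  expect_equal(tie$cy3$row, 24)
})

test_that("cells are scored expressing at two or more dots", {
  img1 <- draw_nuclei_image(matrix(c(60, 60), 1), radii = 11)
  masks <- segment_nuclei(img1, 0.31)
  two <- make_spot_calls("cy3", c(58, 62), c(60, 60), c(1L, 1L))
  one <- make_spot_calls("cy5", 60, 58, 1L)
  sc <- score_cells(masks, two, one)
  expect_true(sc$expressing_cy3)
  expect_false(sc$expressing_cy5)
  expect_equal(sc$n_cy3, 2L)

  none <- score_cells(masks, two[0, ], one[0, ])
  expect_false(none$expressing_cy3)
  expect_false(none$expressing_cy5)

  rogue <- make_spot_calls("cy3", 60, 60, 99L)
  expect_error(score_cells(masks, rogue, one), "unknown nucleus id")
})

test_that("summaries compute fractions, colocalization and fold change", {
  mk_scores <- function(n3, n5) {
    data.frame(nucleus_id = seq_along(n3), area_um2 = rep(38, length(n3)),
               n_cy3 = n3, n_cy5 = n5,
               expressing_cy3 = n3 >= 2, expressing_cy5 = n5 >= 2)
  }
  all_pos <- summarize_cell_scores(mk_scores(c(2, 3), c(2, 5)))
  expect_equal(all_pos$colocalization, 1.0)

  ctrl <- summarize_cell_scores(mk_scores(c(2, rep(0, 19)), rep(0, 20)), "ctrl")
  expect_equal(ctrl$frac_cy3, 0.05)
  trt <- summarize_cell_scores(mk_scores(c(rep(2, 6), rep(0, 14)), rep(0, 20)),
                               "trt", reference = ctrl)
  expect_equal(trt$fold_cy3, 6.0)

  nopos <- summarize_cell_scores(mk_scores(c(0, 1), c(2, 2)), "x",
                                 reference = ctrl)
  expect_true(is.na(nopos$colocalization))
  expect_equal(nopos$fold_cy3, 0)

  expect_error(summarize_cell_scores(mk_scores(integer(0), integer(0))),
               "no cell scores")
})

test_that("the chained pipeline recovers planted expression fractions", {
  sc <- generate_scene(scene_params(seed = 7L))
  q <- quantify_image(sc)
  truth <- scene_truth_summary(sc)
  expect_lt(abs(q$result$frac_cy3 - truth$frac_cy3), 0.05)
  expect_lt(abs(q$result$frac_cy5 - truth$frac_cy5), 0.05)

  # background-only scene: graceful empty result
  bg <- generate_scene(scene_params(n_nuclei = 0, n_autofluor = 0,
                                    size = c(96, 96)))
  q0 <- quantify_image(bg)
  expect_equal(q0$result$n_cells, 0L)
  expect_identical(q0$result$status, "empty")

  # autofluorescence only: planted artifacts must not score as expression
  af <- generate_scene(scene_params(lambda_cy3 = 0, lambda_cy5 = 0,
                                    coexpression = "independent",
                                    n_autofluor = 25, seed = 13L))
  qa <- quantify_image(af)
  expect_equal(qa$result$frac_cy3, 0)
  expect_equal(qa$result$frac_cy5, 0)
})
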