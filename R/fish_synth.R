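#' Parameters of a synthetic RNAscope-style FISH scene
#'
#' Describes a three-channel 2-D fluorescence field: DAPI-stained nuclei
#' (with a configurable fraction placed as touching pairs to exercise
#' watershed splitting), per-cell transcript spots in Cy3 (Cox2) and
#' Cy5 (Eno2, a neuronal marker) with Poisson-distributed counts, and
#' autofluorescent artifacts planted at identical coordinates in both
#' signal channels.
#'
#' Under the `"neuron_weighted"` coexpression model a `neuron_fraction`
#' subpopulation carries the high Cy5 rate `lambda_cy5`; `lambda_cy3`
#' is the Cy3 rate in neurons, and the non-neuron Cy3 rate is derived
#' so that the expected fraction of Cox2-positive cells that are also
#' Eno2-positive equals `coloc_weight` (default 0.75, the approximate
#' neuronal colocalization seen for this transcript in primate cortex
#' and putamen). Under `"independent"` both channels use their lambda
#' for every cell, independently.
#'
#' @param size image size in pixels `c(rows, cols)`.
#' @param pixel_size microns per pixel (default 0.31, a typical 20x
#'   confocal sampling).
#' @param n_nuclei number of nuclei to place.
#' @param cluster_fraction fraction of nuclei placed as touching pairs.
#' @param nucleus_radius_um,nucleus_radius_sd_um nuclear radius mean/SD
#'   in microns.
#' @param lambda_cy3,lambda_cy5 mean spots per cell (Poisson rates; see
#'   Details for the coexpression model).
#' @param coexpression `"neuron_weighted"` or `"independent"`.
#' @param neuron_fraction fraction of cells in the neuron subpopulation.
#' @param coloc_weight target Cox2+ cells that are Eno2+ fraction.
#' @param lambda_cy5_nonneuron Cy5 rate outside the neuron population.
#' @param n_autofluor number of dual-channel autofluorescent blobs.
#' @param spot_margin_um how far outside the nuclear boundary a spot
#'   may fall (microns); models peripheral labeling, and should stay
#'   below the quantifier's search-region dilation.
#' @param spot_sigma_px Gaussian spot radius (sigma, px).
#' @param spot_snr spot peak amplitude in units of the background noise
#'   SD.
#' @param background,noise_sd background level and Gaussian noise SD
#'   (arbitrary intensity units).
#' @param seed integer seed; scenes are byte-identical for a fixed seed.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(size = c(384, 384),
                         pixel_size = 0.31,
                         n_nuclei = 100,
                         cluster_fraction = 0.25,
                         nucleus_radius_um = 3.5,
                         nucleus_radius_sd_um = 0.5,
                         lambda_cy3 = 1.1,
                         lambda_cy5 = 6,
                         coexpression = c("neuron_weighted", "independent"),
                         neuron_fraction = 0.6,
                         coloc_weight = 0.75,
                         lambda_cy5_nonneuron = 0.05,
                         n_autofluor = 10,
                         spot_margin_um = 1,
                         spot_sigma_px = 1.2,
                         spot_snr = 10,
                         background = 100,
                         noise_sd = 10,
                         seed = 1L) {
  coexpression <- match.arg(coexpression)
  stopifnot(length(size) == 2L, all(size >= 16))
  assert_scalar_num(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  assert_scalar_num(n_nuclei, "n_nuclei", lower = 0)
  assert_scalar_num(cluster_fraction, "cluster_fraction", 0, 1)
  assert_scalar_num(lambda_cy3, "lambda_cy3", lower = 0)
  assert_scalar_num(lambda_cy5, "lambda_cy5", lower = 0)
  assert_scalar_num(neuron_fraction, "neuron_fraction", 0, 1)
  assert_scalar_num(coloc_weight, "coloc_weight", 0, 1)
  assert_scalar_num(n_autofluor, "n_autofluor", lower = 0)
  assert_scalar_num(spot_margin_um, "spot_margin_um", lower = 0)
  assert_scalar_num(spot_snr, "spot_snr", lower = 0)
  assert_scalar_num(noise_sd, "noise_sd", lower = 0)
  structure(as.list(environment()), class = "scene_params")
}

#' Poisson rate giving a target fraction of cells with >= 2 spots
#'
#' Inverts `P(N >= 2) = 1 - e^{-lambda}(1 + lambda)` for `lambda`, the
#' expressing-cell fraction under the >= 2-dot scoring rule.
#'
#' @param fraction target expressing fraction in `(0, 1)`.
#' @return The Poisson rate lambda.
#' @export
lambda_for_expressing_fraction <- function(fraction) {
  assert_scalar_num(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be strictly between 0 and 1", call. = FALSE)
  }
  uniroot(function(l) 1 - exp(-l) * (1 + l) - fraction,
          c(1e-8, 100), tol = 1e-12)$root
}

#' Expressing fraction implied by a Poisson spot rate
#'
#' @param lambda Poisson mean spots per cell.
#' @return `P(N >= 2) = 1 - e^{-lambda}(1 + lambda)`.
#' @export
expressing_fraction_for_lambda <- function(lambda) {
  1 - exp(-lambda) * (1 + lambda)
}

# per-cell (lambda_cy3, lambda_cy5) under the coexpression model
cell_lambdas <- function(params, is_neuron) {
  if (params$coexpression == "independent") {
    return(list(cy3 = rep(params$lambda_cy3, length(is_neuron)),
                cy5 = rep(params$lambda_cy5, length(is_neuron))))
  }
  p <- params$neuron_fraction; cw <- params$coloc_weight
  e_n <- expressing_fraction_for_lambda(params$lambda_cy3)
  # choose the non-neuron rate so P(neuron | Cox2+) equals coloc_weight
  l_nn <- if (p >= 1 || cw >= 1 || e_n == 0) 0 else {
    e_nn <- min(e_n * p * (1 - cw) / (cw * (1 - p)), 0.999)
    if (e_nn <= 0) 0 else lambda_for_expressing_fraction(e_nn)
  }
  list(cy3 = ifelse(is_neuron, params$lambda_cy3, l_nn),
       cy5 = ifelse(is_neuron, params$lambda_cy5,
                    params$lambda_cy5_nonneuron))
}

# additive Gaussian blob into img (matrix), clipped at the borders
add_blob <- function(img, row, col, amp, sigma) {
  r <- ceiling(4 * sigma)
  r0 <- max(1L, round(row) - r); r1 <- min(nrow(img), round(row) + r)
  c0 <- max(1L, round(col) - r); c1 <- min(ncol(img), round(col) + r)
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  g <- exp(-(outer((rr - row)^2, (cc - col)^2, "+")) / (2 * sigma^2))
  img[rr, cc] <- img[rr, cc] + amp * g
  img
}

# hard ellipse fill (rotation theta), returns updated matrix
fill_ellipse <- function(img, row, col, a, b, theta, value) {
  r <- ceiling(max(a, b)) + 1L
  r0 <- max(1L, round(row) - r); r1 <- min(nrow(img), round(row) + r)
  c0 <- max(1L, round(col) - r); c1 <- min(ncol(img), round(col) + r)
  rr <- r0:r1; cc <- c0:c1
  dr <- outer(rr - row, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - col)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  blk <- img[rr, cc]
  blk[inside] <- pmax(blk[inside], value)
  img[rr, cc] <- blk
  img
}

# uniform point in the ellipse dilated by `pad` px (same center/rotation)
sample_in_ellipse <- function(row, col, a, b, theta, pad) {
  repeat {
    u <- runif(1, -1, 1); v <- runif(1, -1, 1)
    if (u^2 + v^2 <= 1) break
  }
  ur <- u * (a + pad); vr <- v * (b + pad)
  c(row + ur * cos(theta) - vr * sin(theta),
    col + ur * sin(theta) + vr * cos(theta))
}

#' Generate a synthetic FISH scene with known ground truth
#'
#' Places nuclei (rejection-sampled to avoid full overlap; clustered
#' pairs are allowed to touch), draws per-cell Poisson spot counts
#' under the coexpression model, renders spots as Gaussian blobs inside
#' the 2-micron-dilated cell footprint, plants autofluorescent blobs at
#' identical coordinates in Cy3 and Cy5, and adds Gaussian background
#' noise. All randomness derives from `params$seed`: the same seed
#' yields an identical scene.
#'
#' @param params a [scene_params()].
#' @return An object of class `synthetic_scene`: `images` (named list
#'   of matrices `dapi`, `cy3`, `cy5`), `truth_nuclei` (data frame:
#'   id, row, col, a_px, b_px, theta, cluster, neuron, n_cy3, n_cy5),
#'   `truth_spots` (channel, row, col, nucleus_id), `truth_autofluor`
#'   (row, col), and `params`.
#' @export
generate_scene <- function(params = scene_params()) {
  stopifnot(inherits(params, "scene_params"))
  withr::local_seed(params$seed)
  nr <- params$size[1L]; nc <- params$size[2L]
  px <- params$pixel_size
  r_px <- function() {
    max(1.5, rnorm(1, params$nucleus_radius_um,
                   params$nucleus_radius_sd_um)) / px
  }

  # --- nucleus placement -------------------------------------------------
  nuclei <- list(); centers <- matrix(numeric(0), ncol = 2)
  radii <- numeric(0); cluster_id <- integer(0)
  n_target <- params$n_nuclei
  n_pairs <- floor(round(params$cluster_fraction * n_target) / 2)
  place_one <- function(r, near = NULL, near_r = NULL) {
    for (try in seq_len(200L)) {
      if (is.null(near)) {
        pos <- c(runif(1, r + 2, nr - r - 1), runif(1, r + 2, nc - r - 1))
      } else {
        ang <- runif(1, 0, 2 * pi)
        d <- 0.75 * (r + near_r)   # overlap < 30% of a radius: splittable
        pos <- near + d * c(cos(ang), sin(ang))
        if (pos[1] < r + 2 || pos[1] > nr - r - 1 ||
            pos[2] < r + 2 || pos[2] > nc - r - 1) next
      }
      if (nrow(centers)) {
        dd <- sqrt((centers[, 1] - pos[1])^2 + (centers[, 2] - pos[2])^2)
        min_sep <- if (is.null(near)) (radii + r) + 2 else (radii + r) * 0.72
        if (is.null(near)) {
          if (any(dd < min_sep)) next
        } else {
          others <- dd < min_sep
          others[nrow(centers)] <- FALSE  # the partner may touch
          if (any(others)) next
        }
      }
      return(pos)
    }
    NULL
  }
  cl <- 0L
  while (length(radii) < n_target) {
    make_pair <- cl < n_pairs && (n_target - length(radii)) >= 2L
    r1 <- r_px()
    p1 <- place_one(r1)
    if (is.null(p1)) break
    centers <- rbind(centers, p1); radii <- c(radii, r1)
    if (make_pair) {
      cl <- cl + 1L
      cluster_id <- c(cluster_id, cl)
      r2 <- r_px()
      p2 <- place_one(r2, near = p1, near_r = r1)
      if (!is.null(p2)) {
        centers <- rbind(centers, p2); radii <- c(radii, r2)
        cluster_id <- c(cluster_id, cl)
      }
    } else {
      cluster_id <- c(cluster_id, 0L)
    }
  }
  n <- length(radii)
  if (n < n_target) {
    log_stage("generate_scene", placed = n, requested = n_target)
  }

  ecc <- runif(n, 0, 0.2)
  theta <- runif(n, 0, pi)
  a_px <- radii * (1 + ecc); b_px <- radii * (1 - ecc)
  is_neuron <- if (n) runif(n) < params$neuron_fraction else logical(0)

  # --- spot counts -------------------------------------------------------
  lam <- cell_lambdas(params, is_neuron)
  n_cy3 <- if (n) rpois(n, lam$cy3) else integer(0)
  n_cy5 <- if (n) rpois(n, lam$cy5) else integer(0)

  dil <- params$spot_margin_um / px  # peripheral labeling margin
  spot_pos <- function(i) {
    for (try in seq_len(50L)) {
      p <- sample_in_ellipse(centers[i, 1], centers[i, 2],
                             a_px[i], b_px[i], theta[i], pad = dil)
      if (p[1] >= 2 && p[1] <= nr - 1 && p[2] >= 2 && p[2] <= nc - 1) return(p)
    }
    c(centers[i, 1], centers[i, 2])
  }
  truth_spots <- data.frame(channel = character(0), row = numeric(0),
                            col = numeric(0), nucleus_id = integer(0))
  for (i in seq_len(n)) {
    for (ch in c("cy3", "cy5")) {
      k <- if (ch == "cy3") n_cy3[i] else n_cy5[i]
      if (k == 0) next
      pos <- t(vapply(seq_len(k), function(j) spot_pos(i), numeric(2)))
      truth_spots <- rbind(truth_spots,
                           data.frame(channel = ch, row = pos[, 1],
                                      col = pos[, 2], nucleus_id = i))
    }
  }

  # --- autofluorescence --------------------------------------------------
  n_af <- params$n_autofluor
  truth_autofluor <- if (n_af > 0) {
    data.frame(row = runif(n_af, 5, nr - 4), col = runif(n_af, 5, nc - 4))
  } else data.frame(row = numeric(0), col = numeric(0))

  # --- rendering ---------------------------------------------------------
  amp <- params$spot_snr * params$noise_sd
  dapi <- matrix(0, nr, nc); cy3 <- matrix(0, nr, nc); cy5 <- matrix(0, nr, nc)
  for (i in seq_len(n)) {
    dapi <- fill_ellipse(dapi, centers[i, 1], centers[i, 2],
                         a_px[i], b_px[i], theta[i], value = 40 * params$noise_sd)
  }
  if (n) dapi <- as.matrix(EBImage::gblur(dapi, sigma = 1))
  for (k in seq_len(nrow(truth_spots))) {
    s <- truth_spots[k, ]
    if (s$channel == "cy3") {
      cy3 <- add_blob(cy3, s$row, s$col, amp, params$spot_sigma_px)
    } else {
      cy5 <- add_blob(cy5, s$row, s$col, amp, params$spot_sigma_px)
    }
  }
  for (k in seq_len(nrow(truth_autofluor))) {
    af <- truth_autofluor[k, ]
    cy3 <- add_blob(cy3, af$row, af$col, 1.2 * amp, 1.5 * params$spot_sigma_px)
    cy5 <- add_blob(cy5, af$row, af$col, 1.2 * amp, 1.5 * params$spot_sigma_px)
  }
  noisy <- function(img) {
    pmax(img + params$background + rnorm(length(img), sd = params$noise_sd), 0)
  }
  images <- list(dapi = noisy(dapi), cy3 = noisy(cy3), cy5 = noisy(cy5))

  truth_nuclei <- data.frame(id = seq_len(n),
                             row = centers[seq_len(n), 1],
                             col = centers[seq_len(n), 2],
                             a_px = a_px, b_px = b_px, theta = theta,
                             cluster = cluster_id,
                             neuron = is_neuron,
                             n_cy3 = n_cy3, n_cy5 = n_cy5)
  structure(list(images = images, truth_nuclei = truth_nuclei,
                 truth_spots = truth_spots,
                 truth_autofluor = truth_autofluor, params = params),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %dx%d px, %d nuclei, %d spots, %d autofluor\n",
              nrow(x$images$dapi), ncol(x$images$dapi),
              nrow(x$truth_nuclei), nrow(x$truth_spots),
              nrow(x$truth_autofluor)))
  invisible(x)
}

#' Ground-truth expression summary of a synthetic scene
#'
#' The recovery target for the quantification pipeline: per channel,
#' the true fraction of cells with at least 2 transcript spots, and the
#' true colocalization fraction (Cox2-positive cells that are also
#' Eno2-positive).
#'
#' @param scene a [generate_scene()] result.
#' @return A one-row data frame: `n_cells`, `frac_cy3`, `frac_cy5`,
#'   `colocalization` (`NA` when no cell is Cy3-positive).
#' @export
scene_truth_summary <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  tn <- scene$truth_nuclei
  n <- nrow(tn)
  pos3 <- tn$n_cy3 >= 2; pos5 <- tn$n_cy5 >= 2
  data.frame(n_cells = n,
             frac_cy3 = if (n) mean(pos3) else NA_real_,
             frac_cy5 = if (n) mean(pos5) else NA_real_,
             colocalization = if (n && any(pos3)) {
               sum(pos3 & pos5) / sum(pos3)
             } else NA_real_)
}

#' Scene parameter pairs for fold-change scenarios
#'
#' Returns control and treated [scene_params()] calibrated so the true
#' expressing-cell fractions differ by the requested fold (under the
#' neuron-weighted coexpression model the Cy3 rates are set from the
#' target overall fractions). The 6- and 20-fold presets emulate the
#' transcript induction contrast between untreated tissue and tissue
#' after an intracerebral LPS challenge, in putamen- and cortex-like
#' magnitude respectively; they are synthetic anchors, not data.
#'
#' @param fold target fold change (> 1).
#' @param control_fraction true expressing fraction in the control
#'   condition; `NULL` (default) uses 0.05 unless the treated fraction
#'   `fold * control_fraction` would exceed 0.4, in which case the
#'   control fraction is lowered so the treated condition sits at 0.4
#'   (e.g. 0.02 at 20-fold).
#' @param seed_control,seed_treated scene seeds.
#' @param ... passed to [scene_params()].
#' @return List with elements `control` and `treated` (the two
#'   [scene_params()]) and the target `control_fraction` and
#'   `treated_fraction`.
#' @export
fish_scenario <- function(fold, control_fraction = NULL,
                          seed_control = 1L, seed_treated = 2L, ...) {
  assert_scalar_num(fold, "fold")
  if (fold <= 1) stop("fold must be > 1", call. = FALSE)
  if (is.null(control_fraction)) {
    control_fraction <- min(0.05, 0.4 / fold)
  }
  f_ctrl <- control_fraction
  f_trt <- fold * control_fraction
  if (f_trt >= 1) stop("fold * control_fraction must be < 1", call. = FALSE)
  base <- scene_params(...)
  rate_for <- function(f_overall) {
    if (base$coexpression == "independent") {
      lambda_for_expressing_fraction(f_overall)
    } else {
      # overall fraction p*e_n + (1-p)*e_nn = p*e_n / coloc_weight
      e_n <- f_overall * base$coloc_weight / base$neuron_fraction
      if (e_n >= 1) stop("target fraction unreachable in the neuron subpopulation",
                         call. = FALSE)
      lambda_for_expressing_fraction(e_n)
    }
  }
  ctrl <- base; ctrl$lambda_cy3 <- rate_for(f_ctrl); ctrl$seed <- as.integer(seed_control)
  trt <- base; trt$lambda_cy3 <- rate_for(f_trt); trt$seed <- as.integer(seed_treated)
  list(control = ctrl, treated = trt,
       control_fraction = f_ctrl, treated_fraction = f_trt)
}

#' Write / read a synthetic scene (TIFF + JSON truth sidecar)
#'
#' Images go to a 16-bit multichannel TIFF (channel order DAPI, Cy3,
#' Cy5); the ground truth goes to a JSON sidecar next to it so that
#' quantification tests never re-derive truth from pixels.
#'
#' @param scene a [generate_scene()] result.
#' @param path output TIFF path; the sidecar is `<path>.truth.json`.
#' @return `write_scene()` the path, invisibly; `read_scene()` a list
#'   with `images` and the truth tables.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "synthetic_scene"))
  top <- max(unlist(lapply(scene$images, max)), 1)
  arr <- lapply(scene$images, function(m) m / top)   # 0-1 for 16-bit storage
  tiff::writeTIFF(arr, path, bits.per.sample = 16L, reduce = FALSE)
  truth <- list(scale = top,
                channels = c("dapi", "cy3", "cy5"),
                pixel_size = scene$params$pixel_size,
                truth_nuclei = scene$truth_nuclei,
                truth_spots = scene$truth_spots,
                truth_autofluor = scene$truth_autofluor)
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "columns")
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".truth.json")
  truth <- if (file.exists(sidecar)) {
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else NULL
  scale <- if (!is.null(truth)) truth$scale else 1
  images <- lapply(frames, function(f) f * scale)
  names(images) <- if (!is.null(truth)) truth$channels else
    paste0("channel", seq_along(images))
  list(images = images,
       pixel_size = truth$pixel_size,
       truth_nuclei = as.data.frame(truth$truth_nuclei),
       truth_spots = as.data.frame(truth$truth_spots),
       truth_autofluor = as.data.frame(truth$truth_autofluor))
}
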