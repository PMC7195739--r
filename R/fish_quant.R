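#' Configuration of the FISH quantification pipeline
#'
#' @param nucleus_threshold `"otsu"` or a numeric intensity threshold
#'   for the DAPI channel.
#' @param min_area_um2,max_area_um2 nuclear area filter in square
#'   microns. The default keeps masks of at least 20 um2 with no upper
#'   bound; setting `min_area_um2 = 0, max_area_um2 = 20` reproduces a
#'   literal "exclude masks greater than 20 um2" reading, which would
#'   discard essentially all intact nuclei (a 3.5-um-radius nucleus
#'   covers ~38 um2) — both directions are supported deliberately.
#' @param cluster_area_um2 components larger than this are treated as
#'   nucleus clusters and split by shape-based watershed.
#' @param watershed_tolerance minimum object-height separation in the
#'   distance map for a watershed split.
#' @param dilation_um mask expansion (microns) defining the per-cell
#'   search region for spot counting.
#' @param threshold_scope `"search_regions"` (spot threshold statistics
#'   over the union of search regions) or `"image"` (whole image).
#' @param threshold_k spot threshold = median + `threshold_k` * SD.
#' @param spot_min_px,spot_max_px spot size filter in pixels.
#' @param autofluor_tol_px centroid distance (px) at or under which
#'   Cy3/Cy5 spots are considered the same autofluorescent artifact.
#' @param min_dots dots required to call a cell expressing (default 2).
#' @return An object of class `fish_config`.
#' @export
fish_config <- function(nucleus_threshold = "otsu",
                        min_area_um2 = 20,
                        max_area_um2 = Inf,
                        cluster_area_um2 = 60,
                        watershed_tolerance = 1,
                        dilation_um = 2,
                        threshold_scope = c("search_regions", "image"),
                        threshold_k = 2,
                        spot_min_px = 4,
                        spot_max_px = 150,
                        autofluor_tol_px = 1,
                        min_dots = 2) {
  threshold_scope <- match.arg(threshold_scope)
  stopifnot(min_area_um2 >= 0, max_area_um2 > min_area_um2,
            cluster_area_um2 > 0, dilation_um >= 0, threshold_k > 0,
            spot_min_px >= 1, spot_max_px >= spot_min_px,
            autofluor_tol_px >= 0, min_dots >= 1)
  structure(as.list(environment()), class = "fish_config")
}

# per-label centroids; optionally intensity-weighted (w >= 0, same dim)
label_centroids <- function(lab, w = NULL) {
  ids <- sort(unique(as.integer(lab[lab > 0])))
  if (!length(ids)) {
    return(data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                      n_px = integer(0)))
  }
  idx <- which(lab > 0)
  l <- as.integer(lab[idx])
  rr <- (idx - 1L) %% nrow(lab) + 1L
  cc <- (idx - 1L) %/% nrow(lab) + 1L
  key <- as.character(ids)
  if (is.null(w)) {
    row <- tapply(rr, l, mean)[key]
    col <- tapply(cc, l, mean)[key]
  } else {
    wt <- pmax(w[idx], 0) + 1e-12
    sw <- tapply(wt, l, sum)[key]
    row <- tapply(rr * wt, l, sum)[key] / sw
    col <- tapply(cc * wt, l, sum)[key] / sw
  }
  data.frame(id = ids, row = as.numeric(row), col = as.numeric(col),
             n_px = as.integer(table(l)[key]))
}

#' Segment nuclei in a DAPI image
#'
#' Global threshold (Otsu by default) followed by connected-component
#' labelling; components larger than `cluster_area_um2` are treated as
#' clusters of touching nuclei and split by watershed on the distance
#' transform. Masks outside the `[min_area_um2, max_area_um2]` band and
#' masks touching the image border are removed. Surviving masks are
#' dilated by `dilation_um` into per-cell search regions; pixels
#' contested between dilated masks go to the nucleus with the nearest
#' centroid, while original mask pixels always keep their own label.
#'
#' @param dapi 2-D numeric matrix (DAPI channel).
#' @param pixel_size microns per pixel (> 0).
#' @param cfg a [fish_config()].
#' @return An object of class `nucleus_masks`: `masks` (data frame: id,
#'   row, col, area_um2, n_px), `label` (matrix of original masks),
#'   `search_label` (matrix of search regions), `pixel_size`, and a
#'   `counts` attribute with per-stage tallies. A blank image yields an
#'   empty (zero-mask) result, not an error.
#' @export
segment_nuclei <- function(dapi, pixel_size, cfg = fish_config()) {
  stopifnot(is.matrix(dapi), inherits(cfg, "fish_config"))
  assert_scalar_num(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  empty <- function(counts) {
    structure(list(masks = data.frame(id = integer(0), row = numeric(0),
                                      col = numeric(0), area_um2 = numeric(0),
                                      n_px = integer(0)),
                   label = matrix(0L, nrow(dapi), ncol(dapi)),
                   search_label = matrix(0L, nrow(dapi), ncol(dapi)),
                   pixel_size = pixel_size, counts = counts),
              class = "nucleus_masks")
  }
  rng <- range(dapi)
  if (diff(rng) <= 0) return(empty(list(components = 0L)))
  img01 <- (dapi - rng[1L]) / diff(rng)
  thr <- if (identical(cfg$nucleus_threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(img01))
  } else {
    (cfg$nucleus_threshold - rng[1L]) / diff(rng)
  }
  bw <- img01 > thr
  lab <- EBImage::bwlabel(bw)
  px_area <- pixel_size^2
  comp <- label_centroids(lab)
  n_components <- nrow(comp)

  # split cluster-sized components along distance-transform basins
  out <- matrix(0L, nrow(dapi), ncol(dapi))
  nxt <- 0L
  n_split <- 0L
  for (i in seq_len(nrow(comp))) {
    id <- comp$id[i]
    idx <- which(lab == id)
    if (comp$n_px[i] * px_area > cfg$cluster_area_um2) {
      rr <- (idx - 1L) %% nrow(lab) + 1L
      cc <- (idx - 1L) %/% nrow(lab) + 1L
      r0 <- max(1L, min(rr) - 2L); r1 <- min(nrow(lab), max(rr) + 2L)
      c0 <- max(1L, min(cc) - 2L); c1 <- min(ncol(lab), max(cc) + 2L)
      sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
      sub[cbind(rr - r0 + 1L, cc - c0 + 1L)] <- 1
      dm <- EBImage::distmap(sub)
      ws <- EBImage::watershed(dm, tolerance = cfg$watershed_tolerance, ext = 1)
      ws <- as.matrix(ws)
      k <- max(ws)
      if (k > 1L) n_split <- n_split + 1L
      sel <- ws > 0
      out[r0:r1, c0:c1][sel] <- nxt + as.integer(ws[sel])
      nxt <- nxt + as.integer(k)
    } else {
      nxt <- nxt + 1L
      out[idx] <- nxt
    }
  }

  info <- label_centroids(out)
  info$area_um2 <- info$n_px * px_area
  edge <- logical(nrow(info))
  if (nrow(info)) {
    border <- unique(as.integer(c(out[1L, ], out[nrow(out), ],
                                  out[, 1L], out[, ncol(out)])))
    edge <- info$id %in% border[border > 0]
  }
  keep_area <- info$area_um2 >= cfg$min_area_um2 &
    info$area_um2 <= cfg$max_area_um2
  keep <- keep_area & !edge
  counts <- list(components = n_components, clusters_split = n_split,
                 candidates = nrow(info),
                 edge_removed = sum(edge),
                 area_removed = sum(!keep_area & !edge),
                 kept = sum(keep))
  log_stage("segment_nuclei", components = n_components,
            split = n_split, kept = sum(keep))
  if (!sum(keep)) return(empty(counts))

  kept_ids <- info$id[keep]
  relab <- integer(max(info$id)); relab[kept_ids] <- seq_along(kept_ids)
  label <- matrix(0L, nrow(out), ncol(out))
  sel <- out > 0 & out %in% kept_ids
  label[sel] <- relab[out[sel]]
  masks <- info[keep, c("id", "row", "col", "area_um2", "n_px")]
  masks$id <- seq_len(nrow(masks))
  rownames(masks) <- NULL

  # search regions: dilate each mask, resolve contested pixels by centroid
  rpx <- max(1L, round(cfg$dilation_um / pixel_size))
  brush <- EBImage::makeBrush(2L * rpx + 1L, shape = "disc")
  nr <- nrow(label); nc <- ncol(label)
  search <- matrix(0L, nr, nc)
  bestd <- matrix(Inf, nr, nc)
  for (i in masks$id) {
    idx <- which(label == i)
    rr <- (idx - 1L) %% nr + 1L
    cc <- (idx - 1L) %/% nr + 1L
    r0 <- max(1L, min(rr) - rpx - 1L); r1 <- min(nr, max(rr) + rpx + 1L)
    c0 <- max(1L, min(cc) - rpx - 1L); c1 <- min(nc, max(cc) + rpx + 1L)
    sub <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(rr - r0 + 1L, cc - c0 + 1L)] <- 1
    dil <- as.matrix(EBImage::dilate(sub, brush)) > 0
    didx <- which(dil)
    drr <- (didx - 1L) %% nrow(dil) + r0
    dcc <- (didx - 1L) %/% nrow(dil) + c0
    gidx <- (dcc - 1L) * nr + drr
    d <- sqrt((drr - masks$row[masks$id == i])^2 +
              (dcc - masks$col[masks$id == i])^2)
    win <- d < bestd[gidx]
    search[gidx[win]] <- i
    bestd[gidx[win]] <- d[win]
  }
  own <- label > 0
  search[own] <- label[own]

  structure(list(masks = masks, label = label, search_label = search,
                 pixel_size = pixel_size, counts = counts),
            class = "nucleus_masks")
}

#' @export
print.nucleus_masks <- function(x, ...) {
  cat(sprintf("<nucleus_masks> %d nuclei (median area %.1f um2)\n",
              nrow(x$masks),
              if (nrow(x$masks)) median(x$masks$area_um2) else NA))
  invisible(x)
}

#' Detect fluorescent spots within nuclear search regions
#'
#' The detection threshold is the median plus `threshold_k` standard
#' deviations of the pixel intensities over the union of search regions
#' (or the whole image, per `cfg$threshold_scope`). Above-threshold
#' connected components are size-filtered to `[spot_min_px,
#' spot_max_px]` pixels; each surviving component becomes a spot call
#' assigned to the search region containing its centroid, or marked
#' `"outside"` when no region contains it. A constant image (zero SD)
#' yields zero spots with a logged note.
#'
#' @param img 2-D numeric matrix (Cy3 or Cy5 channel).
#' @param masks a [segment_nuclei()] result aligned to `img`.
#' @param cfg a [fish_config()].
#' @param channel channel label stored with the calls.
#' @return A `spot_calls` data frame (`channel`, `row`, `col`, `size`,
#'   `nucleus_id`, `status`, `autofluor`) for the size-passing spots,
#'   with a `counts` attribute (`candidates`, `size_filtered`,
#'   `assigned`, `outside`, `threshold`).
#' @export
detect_spots <- function(img, masks, cfg = fish_config(), channel = "cy3") {
  stopifnot(is.matrix(img), inherits(masks, "nucleus_masks"),
            inherits(cfg, "fish_config"))
  if (!all(dim(img) == dim(masks$label))) {
    stop("channel image and masks have different dimensions", call. = FALSE)
  }
  empty_calls <- function(counts) {
    out <- data.frame(channel = character(0), row = numeric(0),
                      col = numeric(0), size = integer(0),
                      nucleus_id = integer(0), status = character(0),
                      autofluor = logical(0))
    attr(out, "counts") <- counts
    class(out) <- c("spot_calls", "data.frame")
    out
  }
  stat_px <- if (cfg$threshold_scope == "search_regions") {
    img[masks$search_label > 0]
  } else {
    as.vector(img)
  }
  if (!length(stat_px)) {
    log_stage("detect_spots", channel = channel, note = "no_search_region")
    return(empty_calls(list(candidates = 0L, size_filtered = 0L,
                            assigned = 0L, outside = 0L,
                            threshold = NA_real_)))
  }
  s <- sd(stat_px)
  if (!is.finite(s) || s == 0) {
    log_stage("detect_spots", channel = channel, note = "degenerate_threshold_sd0")
    return(empty_calls(list(candidates = 0L, size_filtered = 0L,
                            assigned = 0L, outside = 0L,
                            threshold = NA_real_)))
  }
  thr <- median(stat_px) + cfg$threshold_k * s
  bw <- img > thr
  # watershed on the above-threshold intensity relief separates touching
  # spots; only dips deeper than one background SD count as valleys
  lab <- EBImage::watershed(EBImage::Image((img - thr) * bw),
                            tolerance = s, ext = 1)
  lab <- as.matrix(lab)
  comp <- label_centroids(lab, w = (img - thr) * bw)
  n_cand <- nrow(comp)
  if (!n_cand) {
    return(empty_calls(list(candidates = 0L, size_filtered = 0L,
                            assigned = 0L, outside = 0L, threshold = thr)))
  }
  # integrated above-threshold intensity per component, for dot
  # multiplicity: two transcripts closer than the optical merge distance
  # form one component but carry twice the unit intensity
  excess <- (img - thr) * bw
  itotal <- tapply(excess[lab > 0], as.integer(lab[lab > 0]), sum)
  comp$intensity <- as.numeric(itotal[as.character(comp$id)])
  ok_size <- comp$n_px >= cfg$spot_min_px & comp$n_px <= cfg$spot_max_px
  comp <- comp[ok_size, , drop = FALSE]
  nid <- integer(nrow(comp))
  if (nrow(comp)) {
    ri <- pmin(pmax(round(comp$row), 1L), nrow(img))
    ci <- pmin(pmax(round(comp$col), 1L), ncol(img))
    nid <- masks$search_label[cbind(ri, ci)]
  }
  out <- data.frame(channel = rep(channel, nrow(comp)),
                    row = comp$row, col = comp$col,
                    size = comp$n_px,
                    intensity = comp$intensity,
                    nucleus_id = ifelse(nid > 0, nid, NA_integer_),
                    status = ifelse(nid > 0, "assigned", "outside"),
                    autofluor = rep(FALSE, nrow(comp)))
  rownames(out) <- NULL
  counts <- list(candidates = n_cand, size_filtered = sum(!ok_size),
                 assigned = sum(nid > 0), outside = sum(nid == 0),
                 threshold = thr)
  log_stage("detect_spots", channel = channel, candidates = n_cand,
            assigned = counts$assigned, outside = counts$outside,
            size_filtered = counts$size_filtered)
  attr(out, "counts") <- counts
  class(out) <- c("spot_calls", "data.frame")
  out
}

#' Exclude dual-channel autofluorescence
#'
#' Spots whose centroids coincide across the Cy3 and Cy5 channels
#' (within `tol` pixels) are treated as autofluorescent artifacts and
#' removed from both channels. Matching is greedy on the nearest pair;
#' each spot can be removed at most once; exact distance ties are
#' broken toward the lowest spot index.
#'
#' @param spots_cy3,spots_cy5 `spot_calls` from [detect_spots()].
#' @param tol centroid distance tolerance in pixels (>= 0).
#' @return List with filtered `cy3` and `cy5` calls, the `removed_cy3`
#'   and `removed_cy5` calls (flagged `autofluor = TRUE`), and
#'   `n_removed` (pairs).
#' @export
remove_autofluorescence <- function(spots_cy3, spots_cy5, tol = 1) {
  assert_scalar_num(tol, "tol", lower = 0)
  n3 <- nrow(spots_cy3); n5 <- nrow(spots_cy5)
  if (n3 == 0L || n5 == 0L) {
    return(list(cy3 = spots_cy3, cy5 = spots_cy5,
                removed_cy3 = spots_cy3[0, ], removed_cy5 = spots_cy5[0, ],
                n_removed = 0L))
  }
  d <- sqrt(outer(spots_cy3$row, spots_cy5$row, "-")^2 +
            outer(spots_cy3$col, spots_cy5$col, "-")^2)
  # when an artifact's counterpart merges with a real spot, its centroid
  # is displaced by up to the component's radius. Widen the gate by the
  # equivalent-radius excess over the unit spot, but only for pairs
  # where BOTH components are oversized — a unit-sized spot has an
  # accurate centroid and keeps the strict tolerance, so genuinely
  # adjacent single spots are not swept up
  r3 <- sqrt(spots_cy3$size / pi)
  r5 <- sqrt(spots_cy5$size / pi)
  r_unit <- median(c(r3, r5))
  s3 <- pmax(0, r3 - r_unit)
  s5 <- pmax(0, r5 - r_unit)
  both_big <- outer(s3 > 0.3, s5 > 0.3, "&")
  gate <- tol + outer(s3, s5, "+") * both_big
  pairs <- which(d <= gate + 1e-12, arr.ind = TRUE)
  if (!nrow(pairs)) {
    return(list(cy3 = spots_cy3, cy5 = spots_cy5,
                removed_cy3 = spots_cy3[0, ], removed_cy5 = spots_cy5[0, ],
                n_removed = 0L))
  }
  ord <- order(d[pairs], pairs[, 1L], pairs[, 2L])
  pairs <- pairs[ord, , drop = FALSE]
  used3 <- logical(n3); used5 <- logical(n5)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (!used3[i] && !used5[j]) { used3[i] <- TRUE; used5[j] <- TRUE }
  }
  rm3 <- spots_cy3[used3, , drop = FALSE]; rm3$autofluor <- TRUE
  rm5 <- spots_cy5[used5, , drop = FALSE]; rm5$autofluor <- TRUE
  log_stage("remove_autofluorescence", pairs = sum(used3))
  list(cy3 = spots_cy3[!used3, , drop = FALSE],
       cy5 = spots_cy5[!used5, , drop = FALSE],
       removed_cy3 = rm3, removed_cy5 = rm5,
       n_removed = sum(used3))
}

#' Score cells by their per-channel spot counts
#'
#' Counts autofluorescence-filtered spots assigned to each nucleus and
#' flags a cell as expressing a transcript when it carries at least
#' `min_dots` spots (default 2) in that channel.
#'
#' @param masks a [segment_nuclei()] result.
#' @param spots_cy3,spots_cy5 filtered `spot_calls`.
#' @param min_dots dots required to call a cell expressing.
#' @return A data frame with one row per nucleus: `nucleus_id`,
#'   `area_um2`, `n_cy3`, `n_cy5`, `expressing_cy3`, `expressing_cy5`.
#' @export
score_cells <- function(masks, spots_cy3, spots_cy5, min_dots = 2) {
  stopifnot(inherits(masks, "nucleus_masks"))
  ids <- masks$masks$id
  count_for <- function(spots) {
    a <- spots[!is.na(spots$nucleus_id) & !spots$autofluor, , drop = FALSE]
    if (nrow(a) && !all(a$nucleus_id %in% ids)) {
      bad <- setdiff(unique(a$nucleus_id), ids)
      stop("spot call references unknown nucleus id: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    # dots per cell = sum of component multiplicities: transcripts closer
    # than the optical merge distance form one component carrying a
    # multiple of the unit (single-spot) integrated intensity. Estimated
    # here, after autofluorescence removal, so artifacts neither pollute
    # the unit estimate nor earn multiplicities.
    m <- rep(1L, nrow(a))
    if ("intensity" %in% names(a) && nrow(a) >= 10L) {
      # the unit needs enough components to calibrate; below that,
      # merging is negligible anyway and every component counts once
      unit <- median(a$intensity)   # most surviving components are single
      if (is.finite(unit) && unit > 0) {
        m <- pmax(1L, as.integer(round(a$intensity / unit)))
      }
    }
    tab <- tapply(m, factor(a$nucleus_id, levels = ids), sum)
    as.integer(ifelse(is.na(tab), 0L, tab))
  }
  n3 <- count_for(spots_cy3); n5 <- count_for(spots_cy5)
  data.frame(nucleus_id = ids,
             area_um2 = masks$masks$area_um2,
             n_cy3 = n3, n_cy5 = n5,
             expressing_cy3 = n3 >= min_dots,
             expressing_cy5 = n5 >= min_dots)
}

#' Summarize cell scores into a regional quantification result
#'
#' @param scores a [score_cells()] data frame (non-empty).
#' @param region_label label attached to the result.
#' @param reference optional `quant_result` (e.g. a control region);
#'   when supplied, per-channel fold changes of the expressing
#'   fractions are reported.
#' @return A `quant_result` list: `region`, `n_cells`, `frac_cy3`,
#'   `frac_cy5`, `colocalization` (Cox2+ cells that are Eno2+; `NA`
#'   when no cell is Cox2+), and `fold_cy3`/`fold_cy5` when a
#'   reference is given.
#' @export
summarize_cell_scores <- function(scores, region_label = "region",
                                  reference = NULL) {
  if (!NROW(scores)) stop("no cell scores to summarize", call. = FALSE)
  pos3 <- scores$expressing_cy3; pos5 <- scores$expressing_cy5
  res <- list(region = region_label,
              n_cells = nrow(scores),
              frac_cy3 = mean(pos3),
              frac_cy5 = mean(pos5),
              colocalization = if (any(pos3)) sum(pos3 & pos5) / sum(pos3)
                               else NA_real_)
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "quant_result"))
    res$fold_cy3 <- if (reference$frac_cy3 > 0) res$frac_cy3 / reference$frac_cy3
                    else NA_real_
    res$fold_cy5 <- if (reference$frac_cy5 > 0) res$frac_cy5 / reference$frac_cy5
                    else NA_real_
  }
  structure(res, class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("<quant_result> '%s': %d cells, Cy3+ %.3f, Cy5+ %.3f, coloc %s%s\n",
              x$region, x$n_cells, x$frac_cy3, x$frac_cy5,
              if (is.na(x$colocalization)) "NA" else sprintf("%.3f", x$colocalization),
              if (!is.null(x$fold_cy3)) sprintf(", fold Cy3 %.2f", x$fold_cy3) else ""))
  invisible(x)
}

#' Quantify a multichannel FISH image end to end
#'
#' Chains nuclear segmentation, per-channel spot detection,
#' dual-channel autofluorescence exclusion and >= `min_dots` cell
#' scoring under one configuration, logging per-stage counts.
#'
#' @param images named list of matrices with elements `dapi`, `cy3`,
#'   `cy5` (a [generate_scene()] result is also accepted).
#' @param pixel_size microns per pixel.
#' @param cfg a [fish_config()].
#' @param region_label label for the summary.
#' @param reference optional reference `quant_result` for fold changes.
#' @return A `fish_quant` list: `result` (a `quant_result`, or an
#'   empty-status result when no nucleus survives), `cells`, `masks`,
#'   `spots` (filtered per channel), `removed` (autofluorescence), and
#'   `counts` per stage.
#' @export
quantify_image <- function(images, pixel_size = NULL, cfg = fish_config(),
                           region_label = "region", reference = NULL) {
  if (inherits(images, "synthetic_scene")) {
    if (is.null(pixel_size)) pixel_size <- images$params$pixel_size
    images <- images$images
  }
  if (is.null(pixel_size)) stop("pixel_size is required", call. = FALSE)
  if (!all(c("dapi", "cy3", "cy5") %in% names(images))) {
    stop("images must contain 'dapi', 'cy3' and 'cy5'", call. = FALSE)
  }
  masks <- segment_nuclei(images$dapi, pixel_size, cfg)
  if (!nrow(masks$masks)) {
    res <- structure(list(region = region_label, n_cells = 0L,
                          frac_cy3 = NA_real_, frac_cy5 = NA_real_,
                          colocalization = NA_real_, status = "empty"),
                     class = "quant_result")
    return(structure(list(result = res, cells = NULL, masks = masks,
                          spots = NULL, removed = NULL,
                          counts = list(segmentation = masks$counts)),
                     class = "fish_quant"))
  }
  s3 <- detect_spots(images$cy3, masks, cfg, channel = "cy3")
  s5 <- detect_spots(images$cy5, masks, cfg, channel = "cy5")
  af <- remove_autofluorescence(s3, s5, tol = cfg$autofluor_tol_px)
  cells <- score_cells(masks, af$cy3, af$cy5, min_dots = cfg$min_dots)
  res <- summarize_cell_scores(cells, region_label, reference)
  structure(list(result = res, cells = cells, masks = masks,
                 spots = list(cy3 = af$cy3, cy5 = af$cy5),
                 removed = list(cy3 = af$removed_cy3, cy5 = af$removed_cy5),
                 counts = list(segmentation = masks$counts,
                               cy3 = attr(s3, "counts"),
                               cy5 = attr(s5, "counts"),
                               autofluor_pairs = af$n_removed)),
            class = "fish_quant")
}

#' Compare recovered cell classifications with planted truth
#'
#' Matches ground-truth nuclei to detected masks by nearest centroid
#' (greedy, one-to-one, within `match_tol_px`) and tabulates the
#' cell-level expressing classification against the true spot counts.
#'
#' @param scene the [generate_scene()] scene that produced the image.
#' @param quant the [quantify_image()] result for that scene.
#' @param match_tol_px centroid matching tolerance in pixels.
#' @param min_dots truth expressing rule (>= `min_dots` true spots).
#' @return List with `match_rate` and per-channel sensitivity and
#'   specificity (`sens_cy3`, `spec_cy3`, `sens_cy5`, `spec_cy5`),
#'   plus the matched-cell table.
#' @export
score_against_truth <- function(scene, quant, match_tol_px = 5,
                                min_dots = 2) {
  stopifnot(inherits(scene, "synthetic_scene"),
            inherits(quant, "fish_quant"))
  tn <- scene$truth_nuclei
  if (is.null(quant$cells) || !nrow(tn)) {
    return(list(match_rate = 0, matched = NULL,
                sens_cy3 = NA, spec_cy3 = NA, sens_cy5 = NA, spec_cy5 = NA))
  }
  dm <- quant$masks$masks
  d <- sqrt(outer(tn$row, dm$row, "-")^2 + outer(tn$col, dm$col, "-")^2)
  pairs <- which(d <= match_tol_px, arr.ind = TRUE)
  ord <- order(d[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_t <- logical(nrow(tn)); used_d <- logical(nrow(dm))
  match <- integer(0); truth_i <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (!used_t[i] && !used_d[j]) {
      used_t[i] <- TRUE; used_d[j] <- TRUE
      truth_i <- c(truth_i, i); match <- c(match, j)
    }
  }
  cells <- quant$cells
  matched <- data.frame(truth_id = tn$id[truth_i],
                        nucleus_id = dm$id[match],
                        true_cy3 = tn$n_cy3[truth_i] >= min_dots,
                        true_cy5 = tn$n_cy5[truth_i] >= min_dots)
  ix <- base::match(matched$nucleus_id, cells$nucleus_id)
  matched$call_cy3 <- cells$expressing_cy3[ix]
  matched$call_cy5 <- cells$expressing_cy5[ix]
  rate <- function(pred, truth, positive) {
    sel <- truth == positive
    if (!any(sel)) return(NA_real_)
    mean(pred[sel] == positive)
  }
  list(match_rate = nrow(matched) / nrow(tn),
       matched = matched,
       sens_cy3 = rate(matched$call_cy3, matched$true_cy3, TRUE),
       spec_cy3 = rate(matched$call_cy3, matched$true_cy3, FALSE),
       sens_cy5 = rate(matched$call_cy5, matched$true_cy5, TRUE),
       spec_cy5 = rate(matched$call_cy5, matched$true_cy5, FALSE))
}

#' Write the per-cell score table
#'
#' Delimited text with columns `nucleus_id`, `area_um2`, `n_cy3`,
#' `n_cy5`, `expressing_cy3`, `expressing_cy5`.
#'
#' @param cells a [score_cells()] data frame.
#' @param path output path.
#' @param sep separator.
#' @export
write_cell_table <- function(cells, path, sep = "\t") {
  utils::write.table(cells, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
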