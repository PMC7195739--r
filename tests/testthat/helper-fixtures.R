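options(cox2quant.quiet = TRUE)

# dense reference input for simulation-based tests
ref_input <- function(total_min = 120, dt = 0.1) {
  simulate_input(input_model_params(), times = seq(0, total_min, by = dt))
}

# reference two-tissue parameters with analytic V_T = 2.0
ref_2t <- function() kinetic_params(0.1, 0.1, 0.05, 0.05)
ref_1t <- function() kinetic_params(0.1, 0.05)

# framing for arbitrary scan lengths (36 + multiple of 6 minutes)
ref_schedule <- function(total_min = 120) default_frame_schedule(total_min)

# a simple synthetic DAPI field built from scratch: ellipses on noise
draw_nuclei_image <- function(centers, radii, size = c(128, 128),
                              background = 100, noise_sd = 5,
                              amplitude = 400, seed = 42) {
  withr::with_seed(seed, {
    img <- matrix(rnorm(prod(size), background, noise_sd),
                  size[1L], size[2L])
    for (i in seq_len(nrow(centers))) {
      rr <- seq_len(size[1L]); cc <- seq_len(size[2L])
      d2 <- outer((rr - centers[i, 1])^2, (cc - centers[i, 2])^2, "+")
      img[d2 <= radii[i]^2] <- img[d2 <= radii[i]^2] + amplitude
    }
    img
  })
}

# background + one Gaussian blob, for spot-detection tests
draw_spot_image <- function(row, col, amp = 100, sigma = 1.2,
                            size = c(128, 128), background = 100,
                            noise_sd = 10, seed = 43) {
  withr::with_seed(seed, {
    img <- matrix(rnorm(prod(size), background, noise_sd),
                  size[1L], size[2L])
    rr <- seq_len(size[1L]); cc <- seq_len(size[2L])
    g <- exp(-outer((rr - row)^2, (cc - col)^2, "+") / (2 * sigma^2))
    img + amp * g
  })
}

# hand-built spot_calls table (the shape detect_spots() emits)
make_spot_calls <- function(channel, row, col, nucleus_id,
                            size = 8L) {
  n <- length(row)
  out <- data.frame(channel = rep(channel, n), row = row, col = col,
                    size = rep(size, n),
                    nucleus_id = nucleus_id,
                    status = ifelse(is.na(nucleus_id), "outside", "assigned"),
                    autofluor = FALSE)
  class(out) <- c("spot_calls", "data.frame")
  out
}
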