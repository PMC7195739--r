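#' @importFrom stats approx coef convolve lm median optim plogis qlogis
#'   rnorm rpois runif sd setNames uniroot predict
#' @importFrom utils head tail
NULL

# cumulative trapezoid with a leading zero, so result aligns with x
cumtrapz0 <- function(x, y) {
  if (length(x) < 2L) return(rep(0, length(x)))
  c(0, pracma::cumtrapz(x, y)[-1])
}

# linear interpolation that errors outside the support instead of extrapolating
interp_strict <- function(x, y, xout, what = "curve") {
  if (any(xout < min(x) - 1e-9) || any(xout > max(x) + 1e-9)) {
    stop(sprintf("requested times outside the support [%g, %g] of the %s",
                 min(x), max(x), what), call. = FALSE)
  }
  stats::approx(x, y, xout, rule = 2)$y
}

assert_ascending <- function(x, name = "times") {
  d <- diff(x)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    stop(sprintf("%s must be strictly ascending; violation at index %d (%g -> %g)",
                 name, i + 1L, x[i], x[i + 1L]), call. = FALSE)
  }
  invisible(x)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%g, %g], got %g", name, lower, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

# stage logging: machine-parsable counters on stderr, silenced via option
log_stage <- function(stage, ...) {
  if (isTRUE(getOption("cox2quant.quiet", FALSE))) return(invisible(NULL))
  kv <- list(...)
  msg <- paste0("[cox2quant] ", stage,
                if (length(kv)) paste0(" ",
                  paste(names(kv), unlist(kv), sep = "=", collapse = " ")))
  message(msg)
  invisible(NULL)
}
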