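# Internal helpers shared across modules.

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "pillarwrap_validation_error", ...)
}

abort_computation <- function(msg, ...) {
  rlang::abort(msg, class = "pillarwrap_computation_error", ...)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    abort_validation(sprintf("`%s` must be a positive finite number.", name))
  }
  invisible(x)
}

check_non_negative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    abort_validation(sprintf("`%s` must be a non-negative finite number.", name))
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort_validation("`seed` must be a single finite integer.")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Bilinear interpolation of matrix `m` (row = y, col = x, pixel centers at
# (index - 1) * pixel_size) at physical coordinates (x_um, y_um). Points
# outside the raster return NA.
interp_bilinear <- function(m, x_um, y_um, pixel_size_um) {
  xi <- x_um / pixel_size_um
  yi <- y_um / pixel_size_um
  nx <- ncol(m)
  ny <- nrow(m)
  out <- rep(NA_real_, length(xi))
  ok <- xi >= 0 & xi <= nx - 1 & yi >= 0 & yi <= ny - 1
  if (!any(ok)) {
    return(out)
  }
  x0 <- pmin(floor(xi[ok]), nx - 2)
  y0 <- pmin(floor(yi[ok]), ny - 2)
  fx <- xi[ok] - x0
  fy <- yi[ok] - y0
  i0 <- y0 + 1L
  j0 <- x0 + 1L
  v00 <- m[cbind(i0, j0)]
  v01 <- m[cbind(i0, j0 + 1L)]
  v10 <- m[cbind(i0 + 1L, j0)]
  v11 <- m[cbind(i0 + 1L, j0 + 1L)]
  out[ok] <- v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
    v10 * (1 - fx) * fy + v11 * fx * fy
  out
}

# Longest circular run of FALSE in a logical vector, in elements.
longest_false_run_circular <- function(covered) {
  n <- length(covered)
  if (all(covered)) {
    return(0L)
  }
  if (!any(covered)) {
    return(n)
  }
  # unroll the circle at a covered element so runs never wrap
  start <- which(covered)[1]
  v <- covered[c(start:n, seq_len(start - 1L))]
  r <- rle(v)
  max(r$lengths[!r$values])
}

otsu_threshold <- function(m) {
  rng <- range(m, finite = TRUE)
  if (diff(rng) <= 0) {
    return(rng[1])
  }
  scaled <- (m - rng[1]) / diff(rng)
  th <- EBImage::otsu(scaled, range = c(0, 1), levels = 256)
  th * diff(rng) + rng[1]
}

resolve_threshold <- function(threshold, m) {
  if (is.null(threshold) || identical(threshold, "otsu")) {
    otsu_threshold(m)
  } else if (is.numeric(threshold) && length(threshold) == 1L) {
    threshold
  } else {
    abort_validation("`threshold` must be \"otsu\" or a single numeric value.")
  }
}
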