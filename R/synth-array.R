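#' Generate a synthetic bottom-mounted hydrophone array
#'
#' Places `n_phones` hydrophones on a jittered rectangular grid in a local
#' planar frame, emulating a seafloor tracking range with roughly constant
#' hydrophone spacing (~4 km on the range that motivated this package).
#' Jitter is uniform within `jitter_frac * spacing_m` of each grid node, so
#' the mean nearest-neighbour distance stays close to `spacing_m`.
#'
#' @param n_phones Number of hydrophones (>= 4).
#' @param spacing_m Nominal grid spacing in meters.
#' @param extent Optional extent `c(width_m, height_m)` of the available
#'   rectangle. When given, an error is raised if the grid cannot hold
#'   `n_phones` at `spacing_m`. Defaults to a near-square grid sized to fit.
#' @param jitter_frac Maximum jitter as a fraction of `spacing_m` (<= 0.5).
#' @param depth_range_m Range of seafloor depths to draw from, meters.
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @return A tibble with columns `phone_id`, `x_m`, `y_m`, `depth_m`.
#' @examples
#' arr <- generate_array(82, spacing_m = 4000, seed = 1)
#' nrow(arr)
#' @export
generate_array <- function(n_phones, spacing_m = 4000, extent = NULL,
                           jitter_frac = 0.1, depth_range_m = c(800, 2000),
                           seed = NULL) {
  if (!is.numeric(n_phones) || length(n_phones) != 1 || n_phones < 4) {
    abort("`n_phones` must be a single number >= 4.")
  }
  assert_scalar_number(spacing_m, "spacing_m", positive = TRUE)
  if (jitter_frac < 0 || jitter_frac > 0.5) {
    abort("`jitter_frac` must be in [0, 0.5].")
  }
  n_phones <- as.integer(n_phones)
  if (is.null(extent)) {
    nx <- ceiling(sqrt(n_phones))
    ny <- ceiling(n_phones / nx)
  } else {
    if (length(extent) != 2 || any(extent <= 0)) {
      abort("`extent` must be c(width_m, height_m), both > 0.")
    }
    nx <- floor(extent[1] / spacing_m) + 1
    ny <- floor(extent[2] / spacing_m) + 1
    if (nx * ny < n_phones) {
      abort(sprintf(
        "Infeasible geometry: extent holds at most %d phones at %g m spacing, %d requested.",
        nx * ny, spacing_m, n_phones
      ))
    }
    nx <- min(nx, ceiling(sqrt(n_phones)))
    ny <- ceiling(n_phones / nx)
  }
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(ix = seq_len(nx) - 1, iy = seq_len(ny) - 1)
  grid <- grid[seq_len(n_phones), , drop = FALSE]
  jit <- jitter_frac * spacing_m
  tibble(
    phone_id = sprintf("H%03d", seq_len(n_phones)),
    x_m = grid$ix * spacing_m + runif(n_phones, -jit, jit),
    y_m = grid$iy * spacing_m + runif(n_phones, -jit, jit),
    depth_m = runif(n_phones, depth_range_m[1], depth_range_m[2])
  )
}
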