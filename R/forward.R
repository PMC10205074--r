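# Parametric toy forward model: sensors on an upper spherical cap, sources on
# a regular grid, quasi-dipolar leadfield with distance decay and
# orientation dependence. This stands in for an anatomical head model: the
# geometry is invented, but it preserves the properties the beamformer and
# cluster tests rely on (smooth distance-dependent mixing, distinguishable
# columns, labeled ROIs with ground truth).

#' Build a toy MEG forward model
#'
#' Sensors are placed on an upper spherical cap (radius 12 cm) with a small
#' seeded jitter; sources on a regular 3-D grid centred under the cap.
#' The leadfield of source \eqn{p} with orientation \eqn{e} at sensor
#' \eqn{s} with outward normal \eqn{n} is the magnetic-dipole-like term
#' \eqn{(e \times d) \cdot n / |d|^2} with \eqn{d = s - p}, giving
#' distance-decaying, orientation-dependent gains.
#'
#' @param n_sensors Number of sensors (>= 8; default 30).
#' @param grid_shape Integer vector (nx, ny, nz) of grid dimensions with at
#'   least 27 sources in total (default `c(6, 5, 3)`).
#' @param grid_spacing_cm Grid spacing in cm (default 2; a coarse grid
#'   whose leadfield columns stay distinguishable with tens of sensors).
#' @param seed Integer seed.
#' @return An `ft_forward` list: `sensor_positions` (n_sensors x 3, cm),
#'   `sensor_normals`, `source_positions` (n_sources x 3), `leadfield`
#'   (n_sensors x (n_sources * 3)), `n_orient = 3`, `rois` (named list of
#'   source index vectors including `auditory_left`, `auditory_right`,
#'   `frontal_left`, `frontal_right`), `grid_spacing_cm`.
#' @export
make_forward_model <- function(n_sensors = 30, grid_shape = c(6, 5, 3),
                               grid_spacing_cm = 2, seed = 1) {
  if (n_sensors < 8) abort("n_sensors must be >= 8")
  if (prod(grid_shape) < 27) abort("grid must contain at least 27 sources")
  set.seed(seed)

  # sensors: Fibonacci points on an upper cap, radius 12 cm, jittered
  k <- seq_len(n_sensors)
  z <- 0.2 + 0.75 * (k - 0.5) / n_sensors
  phi <- 2 * pi * k * (1 + sqrt(5)) / 2
  dirs <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  dirs <- dirs + matrix(stats::rnorm(3 * n_sensors, 0, 0.01), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  sensor_positions <- 12 * dirs

  gx <- (seq_len(grid_shape[1]) - (grid_shape[1] + 1) / 2) * grid_spacing_cm
  gy <- (seq_len(grid_shape[2]) - (grid_shape[2] + 1) / 2) * grid_spacing_cm
  gz <- 6 + (seq_len(grid_shape[3]) - 1) * grid_spacing_cm
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  dimnames(grid) <- list(NULL, c("x", "y", "z"))
  n_sources <- nrow(grid)

  if (min(.ft_pairwise_min_dist(sensor_positions, grid)) < 1e-6) {
    abort("degenerate geometry: coincident sensor and source positions")
  }

  L <- matrix(0, n_sensors, n_sources * 3)
  for (s in seq_len(n_sources)) {
    d <- sweep(sensor_positions, 2, grid[s, ])         # n_sensors x 3
    r2 <- rowSums(d^2)
    for (o in 1:3) {
      e <- c(0, 0, 0); e[o] <- 1
      cx <- cbind(e[2] * d[, 3] - e[3] * d[, 2],
                  e[3] * d[, 1] - e[1] * d[, 3],
                  e[1] * d[, 2] - e[2] * d[, 1])
      L[, (s - 1) * 3 + o] <- rowSums(cx * dirs) / r2
    }
  }
  if (!all(is.finite(L))) abort("non-finite leadfield")
  col_ok <- colSums(L^2) > 0
  if (!all(col_ok)) abort("all-zero leadfield column")

  rois <- .ft_default_rois(grid, grid_spacing_cm)
  structure(
    list(sensor_positions = sensor_positions, sensor_normals = dirs,
         source_positions = grid, leadfield = L, n_orient = 3L,
         rois = rois, grid_spacing_cm = grid_spacing_cm),
    class = "ft_forward")
}

.ft_pairwise_min_dist <- function(a, b) {
  apply(b, 1, function(p) min(sqrt(colSums((t(a) - p)^2))))
}

# focal ROIs: "auditory" = most lateral source column at mid depth (an
# STG-like patch per hemisphere). The other ROIs ("frontal" anterior,
# "posterior" posterior, split by hemisphere) keep a buffer of at least two
# grid steps from the auditory patches, because the toy beamformer's
# spatial resolution is about one grid step.
.ft_default_rois <- function(grid, spacing = NULL) {
  x <- grid[, 1]; y <- grid[, 2]; z <- grid[, 3]
  if (is.null(spacing)) spacing <- min(dist(unique(x)))
  z_mid <- sort(unique(z))[ceiling(length(unique(z)) / 2)]
  y_mid <- abs(y - stats::median(unique(y))) <= spacing + 1e-9
  aud_l <- which(x == min(x) & z == z_mid & y_mid)
  aud_r <- which(x == max(x) & z == z_mid & y_mid)
  aud <- c(aud_l, aud_r)
  dist_to_aud <- apply(grid, 1, function(p)
    min(sqrt(colSums((t(grid[aud, , drop = FALSE]) - p)^2))))
  far <- dist_to_aud >= 2 * spacing - 1e-9
  list(
    auditory_left   = aud_l,
    auditory_right  = aud_r,
    frontal_left    = which(far & y == max(y) & x < 0),
    frontal_right   = which(far & y == max(y) & x > 0),
    posterior_left  = which(far & y == min(y) & x < 0),
    posterior_right = which(far & y == min(y) & x > 0)
  )
}

#' @export
print.ft_forward <- function(x, ...) {
  cat(sprintf("<ft_forward> %d sensors, %d sources (%.1f cm grid), ROIs: %s\n",
              nrow(x$sensor_positions), nrow(x$source_positions),
              x$grid_spacing_cm, paste(names(x$rois), collapse = ", ")))
  invisible(x)
}

# leadfield columns (n_sensors x 3) of one source
.ft_source_leadfield <- function(forward, s) {
  forward$leadfield[, ((s - 1) * 3 + 1):((s - 1) * 3 + 3), drop = FALSE]
}
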