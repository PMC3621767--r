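#' Spherical volume-conductor head model
#'
#' A homogeneous conducting sphere.  For magnetometers outside the sphere
#' the magnetic field of an internal current dipole has the Sarvas closed
#' form and is independent of the conductivity profile; radial dipoles are
#' magnetically silent.  Optionally a per-channel list of sphere centers can
#' be supplied (local-sphere variant); the default is one common sphere.
#'
#' @param center Sphere center, length-3 numeric (m), head coordinates.
#' @param radius Sphere radius in meters.
#' @param channel_centers Optional `n_channels x 3` matrix of per-channel
#'   sphere centers.
#' @return An object of class `head_model`.
#' @export
head_model <- function(center = c(0, 0, 0), radius = 0.09,
                       channel_centers = NULL) {
  stopifnot(length(center) == 3, is.numeric(radius), radius > 0)
  structure(list(center = as.numeric(center), radius = radius,
                 channel_centers = channel_centers),
            class = "head_model")
}

#' Synthetic 275-channel helmet sensor array
#'
#' Builds a quasi-uniform layout of point magnetometers on a spherical cap
#' (golden-angle spiral), radially oriented, mimicking the coverage of a
#' whole-head axial system.  Head coordinates are right-handed: x to the
#' right, y anterior, z superior, origin at the head-sphere center.
#'
#' Region labels partition the channels by position:
#' `frontal` for y > 0.04 m; `left-temporal` / `right-temporal` for
#' |x| > 0.05 m and y <= 0.04 m (sign of x); `other` for the rest.  These
#' are stated conventions for the synthetic helmet, used by the sensor-
#' subset analyses.
#'
#' @param n_channels Number of channels (default 275).
#' @param helmet_radius Radius of the sensor shell in meters.
#' @param cap_angle_deg Polar opening angle of the cap in degrees, measured
#'   from +z; 115 degrees covers the head down past the ears.
#' @return A data.frame of class `sensor_array` with columns `name`, `x`,
#'   `y`, `z` (m), `ox`, `oy`, `oz` (unit orientation), `region`.
#' @export
make_sensor_array <- function(n_channels = 275L, helmet_radius = 0.12,
                              cap_angle_deg = 115) {
  n <- as.integer(n_channels)
  stopifnot(n >= 4, helmet_radius > 0)
  cmin <- cos(cap_angle_deg * pi / 180)
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n)
  cz <- 1 - (i - 0.5) / n * (1 - cmin)   # cos(theta), quasi-uniform in area
  st <- sqrt(pmax(0, 1 - cz^2))
  phi <- i * golden
  pos <- helmet_radius * cbind(st * cos(phi), st * sin(phi), cz)
  orient <- pos / helmet_radius          # radial pickup direction
  region <- ifelse(pos[, 2] > 0.04, "frontal",
            ifelse(abs(pos[, 1]) > 0.05 & pos[, 2] <= 0.04,
                   ifelse(pos[, 1] < 0, "left-temporal", "right-temporal"),
                   "other"))
  out <- data.frame(
    name = sprintf("M%03d", i),
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    ox = orient[, 1], oy = orient[, 2], oz = orient[, 3],
    region = region, stringsAsFactors = FALSE)
  class(out) <- c("sensor_array", "data.frame")
  out
}

sensor_positions <- function(array) as.matrix(array[, c("x", "y", "z")])
sensor_orientations <- function(array) as.matrix(array[, c("ox", "oy", "oz")])

#' Serialize a sensor array to TSV
#' @param array A `sensor_array`.
#' @param path Output path.
#' @export
write_sensor_array_tsv <- function(array, path) {
  utils::write.table(array, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sensor_array_tsv
#' @export
read_sensor_array_tsv <- function(path) {
  a <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  class(a) <- c("sensor_array", "data.frame")
  a
}

#' Channel indices for a sensor-subset analysis
#'
#' @param array A `sensor_array`.
#' @param region One of `"left-temporal"`, `"right-temporal"`, `"frontal"`,
#'   `"whole-head"`.
#' @return Integer channel indices.
#' @export
subset_channels <- function(array, region) {
  known <- c("left-temporal", "right-temporal", "frontal", "whole-head")
  if (!region %in% known)
    stop("unknown sensor region '", region, "'; expected one of ",
         paste(known, collapse = ", "))
  if (region == "whole-head") return(seq_len(nrow(array)))
  idx <- which(array$region == region)
  if (!length(idx))
    stop("sensor region '", region, "' contains no channels in this array")
  idx
}

#' Magnetic field of a current dipole in a conducting sphere (Sarvas)
#'
#' Evaluates the closed-form external magnetic field of a current dipole
#' inside a homogeneous conducting sphere and projects it onto each
#' channel's pickup orientation.
#'
#' @param dipole_position Length-3, meters, strictly inside the sphere.
#' @param dipole_moment Length-3, A·m.
#' @param head A [head_model()].
#' @param array A `sensor_array` (all sensors must lie outside the sphere).
#' @return Numeric vector of per-channel fields in tesla.
#' @export
sarvas_field <- function(dipole_position, dipole_moment, head, array) {
  stopifnot(inherits(head, "head_model"))
  pos <- sensor_positions(array)
  ori <- sensor_orientations(array)
  n <- nrow(pos)
  centers <- if (!is.null(head$channel_centers)) {
    stopifnot(nrow(head$channel_centers) == n)
    head$channel_centers
  } else matrix(head$center, n, 3, byrow = TRUE)
  q <- as.numeric(dipole_moment)
  r0m <- matrix(as.numeric(dipole_position), n, 3, byrow = TRUE) - centers
  d <- sqrt(rowSums(r0m^2))
  if (any(d < 1e-9))
    stop("degenerate geometry: dipole at sphere center")
  if (any(d >= head$radius))
    stop("degenerate geometry: dipole outside or on the head sphere")
  rm_ <- pos - centers
  R <- sqrt(rowSums(rm_^2))
  if (any(R <= head$radius))
    stop("degenerate geometry: sensor inside the head sphere")
  am <- rm_ - r0m
  a <- sqrt(rowSums(am^2))
  ar <- rowSums(am * rm_)
  F_ <- a * (R * a + R^2 - rowSums(r0m * rm_))
  c1 <- a^2 / R + ar / a + 2 * a + 2 * R
  c2 <- a + 2 * R + ar / a
  gradF <- c1 * rm_ - c2 * r0m
  Qxr0 <- cbind(q[2] * r0m[, 3] - q[3] * r0m[, 2],
                q[3] * r0m[, 1] - q[1] * r0m[, 3],
                q[1] * r0m[, 2] - q[2] * r0m[, 1])
  B <- 1e-7 * (F_ * Qxr0 - rowSums(Qxr0 * rm_) * gradF) / F_^2
  rowSums(B * ori)
}

#' Volumetric source grid inside the head sphere
#'
#' Axis-aligned cubic grid; points are retained if they lie inside the head
#' sphere with a margin of at least one grid spacing (so every retained
#' point is strictly interior and the forward model is well conditioned).
#'
#' @param head A [head_model()].
#' @param spacing_mm Grid spacing in millimeters (3 mm production default;
#'   coarser grids are appropriate for testing).
#' @return An object of class `source_grid` with fields `points`
#'   (`n x 3`, m), `spacing_mm`, `dim`, `origin_mm`, `index` (voxel index of
#'   each point in the full box), `head`.
#' @export
make_source_grid <- function(head, spacing_mm = 3) {
  stopifnot(inherits(head, "head_model"), spacing_mm > 0)
  sp <- spacing_mm / 1000
  r <- head$radius
  ax <- seq(-r, r, by = sp)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  pts <- sweep(pts, 2, head$center, `+`)
  d <- sqrt(rowSums(sweep(pts, 2, head$center, `-`)^2))
  # keep one-spacing margins from both the surface and the (magnetically
  # silent, hence degenerate) sphere center
  keep <- d <= (r - sp) & d >= sp
  dims <- rep(length(ax), 3)
  structure(list(
    points = pts[keep, , drop = FALSE],
    spacing_mm = spacing_mm,
    dim = dims,
    origin_mm = (ax[1] + head$center) * 1000,
    index = which(keep),
    head = head
  ), class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("Source grid: %d points at %g mm spacing (sphere r = %g mm)\n",
              nrow(x$points), x$spacing_mm, x$head$radius * 1000))
  invisible(x)
}

#' Build the leadfield over a source grid
#'
#' For each grid point, the `n_channels x 3` gain matrix whose column j is
#' the sensor field of a unit dipole along Cartesian axis j.  In a sphere
#' the gain has rank 2 (the radial direction is silent).
#'
#' @param grid A [make_source_grid()] result.
#' @param array A `sensor_array`.
#' @param head A [head_model()].
#' @return An object of class `leadfield`: list with `gain` (a
#'   `n_channels x (3 * n_points)` matrix, point-major blocks of 3 columns),
#'   `grid`, `array`.
#' @export
build_leadfield <- function(grid, array, head) {
  npts <- nrow(grid$points)
  if (npts == 0) stop("empty source grid")
  nch <- nrow(array)
  gain <- matrix(0, nch, 3 * npts)
  for (p in seq_len(npts)) {
    for (j in 1:3) {
      q <- c(0, 0, 0); q[j] <- 1
      gain[, 3 * (p - 1) + j] <-
        sarvas_field(grid$points[p, ], q, head, array)
    }
  }
  structure(list(gain = gain, grid = grid, array = array, head = head),
            class = "leadfield")
}

#' Gain matrix at one grid point
#' @param lf A `leadfield`.
#' @param p Grid-point index.
#' @return `n_channels x 3` gain matrix.
#' @export
leadfield_gain <- function(lf, p) {
  lf$gain[, (3 * (p - 1) + 1):(3 * p), drop = FALSE]
}
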