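#' Trial-averaged window covariance
#'
#' For each selected trial, takes the samples of `window` (seconds relative
#' to the deviant-tone onset), removes the per-trial window mean channel by
#' channel, and accumulates the sample covariance; the estimate is the
#' average over trials.  Positive semi-definite by construction.
#'
#' @param epochs An `epoch_set`.
#' @param window Length-2 numeric, seconds relative to the final-tone onset.
#' @param trials Integer epoch indices to use (defaults to all trials of
#'   `condition`).
#' @param condition Optional condition filter applied when `trials` is
#'   missing.
#' @param channels Integer channel subset (default all).
#' @return List of class `cov_estimate`: `matrix` (T^2), `window`,
#'   `n_trials`, `channels`.
#' @export
compute_covariance <- function(epochs, window, trials = NULL,
                               condition = NULL, channels = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (is.null(trials)) {
    trials <- if (is.null(condition)) seq_len(dim(epochs$epochs)[1]) else
      which(epochs$condition == condition)
  }
  if (length(trials) < 1) stop("no trials selected for covariance")
  if (is.null(channels)) channels <- seq_len(dim(epochs$epochs)[2])
  idx <- window_samples(epochs, window)
  nch <- length(channels)
  C <- matrix(0, nch, nch)
  for (tr in trials) {
    X <- epochs$epochs[tr, channels, idx, drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    X <- X - rowMeans(X)
    C <- C + tcrossprod(X) / (length(idx) - 1)
  }
  structure(list(matrix = C / length(trials), window = window,
                 n_trials = length(trials), channels = channels),
            class = "cov_estimate")
}

# Regularized inverse: C + lambda * tr(C)/n * I.
regularize_cov <- function(C, regularization = 0.05) {
  n <- nrow(C)
  C + regularization * sum(diag(C)) / n * diag(n)
}

# Leading generalized eigenvector of (A, B) in a small basis, with a
# tie-break: among (near-)equal ratio maximizers, prefer the direction of
# largest output power u'Au (the ratio is constant e.g. for white
# covariances, where the gain-norm direction is the sensible choice).
gev_direction <- function(A, B) {
  r <- nrow(A)
  if (r == 1L) return(1)
  eg <- eigen(solve(B, A))
  vals <- Re(eg$values)
  cand <- which(vals >= max(vals) * (1 - 1e-6))
  if (length(cand) > 1L) {
    pow <- vapply(cand, function(i) {
      u <- Re(eg$vectors[, i])
      sum(u * (A %*% u)) / sum(u^2)
    }, numeric(1))
    # fully degenerate pair: any basis is eigen; take the power maximizer
    # over the whole subspace instead of arbitrary eigenvectors
    if (max(vals) / min(vals) < 1 + 1e-6) {
      ep <- eigen((A + t(A)) / 2)
      return(Re(ep$vectors[, 1]))
    }
    return(Re(eg$vectors[, cand[which.max(pow)]]))
  }
  Re(eg$vectors[, cand])
}

#' Optimal (maximum output-SNR) source orientation
#'
#' The scalar beamformer needs one orientation per grid point.  We take the
#' orientation maximizing the ratio of beamformer output power to projected
#' sensor-noise power, which is the leading generalized eigenvector of the
#' matrix pair `(G' C^-1 G, G' C^-2 G)` restricted to the effective
#' (tangential) column space of the gain `G`.  This pseudo-Z maximization is
#' deterministic and equivalent to the classical nonlinear orientation
#' search at its optimum.
#'
#' @param gain `n_channels x 3` gain matrix.
#' @param C A `cov_estimate` or plain covariance matrix over the same
#'   channels.
#' @param regularization Diagonal-loading fraction of the mean eigenvalue.
#' @return Unit 3-vector with its first nonzero component positive.
#' @export
optimal_orientation <- function(gain, C, regularization = 0.05) {
  if (inherits(C, "cov_estimate")) C <- C$matrix
  if (all(gain == 0)) stop("zero gain matrix: no orientation is defined")
  Cr <- regularize_cov(C, regularization)
  Ci <- solve(Cr)
  sv <- svd(gain)
  r <- sum(sv$d > 1e-8 * sv$d[1])
  V <- sv$v[, seq_len(r), drop = FALSE]   # effective (tangential) subspace
  Gt <- gain %*% V
  A <- crossprod(Gt, Ci %*% Gt)
  B <- crossprod(Gt, Ci %*% (Ci %*% Gt))
  u <- gev_direction(A, B)
  ori <- as.numeric(V %*% u)
  ori <- ori / vnorm(ori)
  nz <- which(abs(ori) > 1e-12)[1]
  if (ori[nz] < 0) ori <- -ori
  ori
}

#' Unit-gain LCMV spatial filter (SAM weights)
#'
#' Minimum-variance weights with a unit-gain constraint at the target:
#' `w = C^-1 h / (h' C^-1 h)` with `h = gain %*% orientation`, where `C` is
#' diagonally loaded by `regularization * trace(C)/n`.
#'
#' @param gain `n_channels x 3` gain matrix.
#' @param orientation Unit 3-vector.
#' @param C A `cov_estimate` or covariance matrix.
#' @param regularization Diagonal-loading fraction.
#' @return List of class `spatial_filter`: `weights`, `orientation`, `h`,
#'   `channels`.
#' @export
sam_weights <- function(gain, orientation, C, regularization = 0.05) {
  channels <- NULL
  if (inherits(C, "cov_estimate")) { channels <- C$channels; C <- C$matrix }
  h <- as.numeric(gain %*% orientation)
  if (all(h == 0)) stop("forward field is zero for this orientation")
  Ci <- solve(regularize_cov(C, regularization))
  Cih <- Ci %*% h
  w <- as.numeric(Cih / sum(h * Cih))
  structure(list(weights = w, orientation = orientation, h = h,
                 channels = channels),
            class = "spatial_filter")
}

#' Projected sensor-noise power
#'
#' The sensor-noise floor is estimated as the smallest singular value of
#' the data covariance matrix (SVD noise estimate); the beamformer maps it
#' to the source as `n2 = sigma2_min * w'w`.
#'
#' @param C A `cov_estimate` or covariance matrix.
#' @param w A `spatial_filter` or weight vector.
#' @return Scalar noise power `n2`.
#' @export
noise_power <- function(C, w) {
  if (inherits(C, "cov_estimate")) C <- C$matrix
  if (inherits(w, "spatial_filter")) w <- w$weights
  sigma2_min <- min(svd(C, nu = 0, nv = 0)$d)
  sigma2_min * sum(w^2)
}

#' Default active/control analysis windows
#'
#' Both windows are intervals after the deviant (final) tone onset; the
#' control state is the same interval taken on the paired standard epochs.
#' The early window brackets the mismatch peak (~150 ms), the late one
#' catches late components.
#'
#' @param active Length-2 numeric, seconds post-deviant.
#' @return List of class `window_pair`.
#' @export
window_pair <- function(active = c(0.100, 0.200)) {
  stopifnot(length(active) == 2, active[2] > active[1])
  structure(list(active = active, control = active), class = "window_pair")
}

#' Volumetric pseudo-T contrast map
#'
#' The SAM dual-state statistic.  Per grid point (over the chosen sensor
#' subset): weights are computed from the pooled covariance of the active
#' (deviant) and control (paired standard) windows with the optimal
#' orientation; `a2 = w' C_active w`, `c2 = w' C_control w`; the contrast
#' is normalized by the projected sensor noise `n2` (see [noise_power()]):
#' `pseudoT = (a2 - c2) / n2`.
#'
#' @param pairs Data.frame from [select_analysis_trials()] (columns
#'   `run_id`, `standard_trial`, `deviant_trial`), or `NULL` to pair all
#'   deviants/standards present in `epochs` by [select pairs from the
#'   epoch metadata].
#' @param epochs An `epoch_set`.
#' @param leadfield A `leadfield` on the analysis grid (full channel set).
#' @param windows A [window_pair()].
#' @param channels Integer channel subset (e.g. from [subset_channels()]).
#' @param regularization Diagonal-loading fraction (default 0.05).
#' @return Object of class `pseudo_t_map`: `values` (one per grid point),
#'   `grid`, `window`, `channels`, `n_pairs`.
#' @export
pseudo_t_map <- function(pairs, epochs, leadfield,
                         windows = window_pair(),
                         channels = NULL, regularization = 0.05) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(leadfield, "leadfield"))
  if (is.null(channels)) channels <- seq_len(dim(epochs$epochs)[2])
  if (!length(channels)) stop("empty channel subset")
  ep_key <- paste(epochs$run_id, epochs$trial_index)
  dev_rows <- match(paste(pairs$run_id, pairs$deviant_trial), ep_key)
  std_rows <- match(paste(pairs$run_id, pairs$standard_trial), ep_key)
  ok <- !is.na(dev_rows) & !is.na(std_rows)   # both survived rejection
  dev_rows <- dev_rows[ok]; std_rows <- std_rows[ok]
  if (length(dev_rows) < 2) stop("need at least 2 analyzable trial pairs")

  Ca <- compute_covariance(epochs, windows$active, trials = dev_rows,
                           channels = channels)$matrix
  Cc <- compute_covariance(epochs, windows$control, trials = std_rows,
                           channels = channels)$matrix
  Cpool <- (Ca + Cc) / 2
  Creg <- regularize_cov(Cpool, regularization)
  # Noise floor from the SVD of the (loaded) pooled covariance: diagonal
  # loading keeps the estimate meaningful when narrow-band, few-trial
  # covariances are numerically rank-deficient; with regularization = 0
  # this is the plain smallest singular value.
  sigma2_min <- min(svd(Creg, nu = 0, nv = 0)$d)
  Ci <- solve(Creg)

  grid <- leadfield$grid
  npts <- nrow(grid$points)
  G_all <- leadfield$gain[channels, , drop = FALSE]
  CiG <- Ci %*% G_all
  Ci2G <- Ci %*% CiG
  values <- numeric(npts)
  for (p in seq_len(npts)) {
    cols <- (3 * (p - 1) + 1):(3 * p)
    G <- G_all[, cols, drop = FALSE]
    A3 <- crossprod(G, CiG[, cols, drop = FALSE])
    B3 <- crossprod(G, Ci2G[, cols, drop = FALSE])
    # restrict to the effective tangential plane of the gain
    sv <- svd(G)
    r <- sum(sv$d > 1e-8 * sv$d[1])
    if (r == 0L) { values[p] <- 0; next }
    V <- sv$v[, seq_len(r), drop = FALSE]
    A <- crossprod(V, A3 %*% V)
    B <- crossprod(V, B3 %*% V)
    u <- gev_direction(A, B)
    ori <- as.numeric(V %*% u)
    h <- as.numeric(G %*% (ori / vnorm(ori)))
    Cih <- CiG[, cols, drop = FALSE] %*% (ori / vnorm(ori))
    w <- as.numeric(Cih / sum(h * Cih))
    a2 <- sum(w * (Ca %*% w))
    c2 <- sum(w * (Cc %*% w))
    n2 <- sigma2_min * sum(w^2)
    values[p] <- (a2 - c2) / n2
  }
  structure(list(values = values, grid = grid, window = windows$active,
                 channels = channels, n_pairs = length(dev_rows)),
            class = "pseudo_t_map")
}

#' @export
print.pseudo_t_map <- function(x, ...) {
  cat(sprintf("Pseudo-T map: %d grid points, window [%g, %g] s post-deviant, %d channels, %d pairs\n",
              length(x$values), x$window[1], x$window[2],
              length(x$channels), x$n_pairs))
  cat(sprintf("  range [%.3f, %.3f], peak at (%s) mm\n",
              min(x$values), max(x$values),
              paste(sprintf("%.0f", x$grid$points[which.max(x$values), ] * 1000),
                    collapse = ", ")))
  invisible(x)
}

#' Location of the map maximum, in head-frame mm
#' @param map A `pseudo_t_map` (or any list with `values` and `grid`).
#' @export
map_peak_location <- function(map) {
  map$grid$points[which.max(map$values), ] * 1000
}

#' Voxelwise average of maps on the same grid
#'
#' @param maps List of `pseudo_t_map` objects on identical grids (e.g. the
#'   per-run or per-subject maps).
#' @return A `pseudo_t_map` with the voxelwise arithmetic mean.
#' @export
aggregate_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  n <- length(maps[[1]]$values)
  for (m in maps) {
    if (length(m$values) != n ||
        !isTRUE(all.equal(m$grid$spacing_mm, maps[[1]]$grid$spacing_mm)) ||
        nrow(m$grid$points) != nrow(maps[[1]]$grid$points))
      stop("maps are not on identical grids")
  }
  out <- maps[[1]]
  out$values <- Reduce(`+`, lapply(maps, `[[`, "values")) / length(maps)
  out
}
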