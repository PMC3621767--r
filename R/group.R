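#' Maximal-statistic permutation threshold for group pseudo-T maps
#'
#' Nonparametric family-wise-error control: under the null hypothesis the
#' deviant and standard labels are exchangeable, and exchanging them negates
#' each subject's contrast map, so the permutation distribution is built by
#' random sign-flips of the per-subject maps.  The statistic of each
#' permutation is the maximum over voxels of the permuted group mean; the
#' threshold is the `ceil((1 - alpha) * (n_perm + 1))`-th order statistic of
#' the pooled sample {observed maximum, permuted maxima}.  One-sided on
#' positive contrasts by default (activations, `a2 > c2`); set
#' `two_sided = TRUE` to use the maximum absolute statistic.
#'
#' When `n_perm == 2^n_subjects - 1` the full sign-flip set is enumerated
#' and the result is deterministic and seed-independent.
#'
#' @param maps List of per-subject `pseudo_t_map` objects on one grid.
#' @param alpha Significance level (default 0.05).
#' @param n_perm Number of permutations (default 4999).
#' @param seed Integer seed for the random sign-flips.
#' @param two_sided Use max |statistic| instead of max statistic.
#' @param slow_relabel Optional function implementing full subject-level
#'   relabel-and-recompute; when supplied it is called as
#'   `slow_relabel(signs)` for each sign vector and must return a group
#'   mean map vector (validation aid for tiny problems).
#' @return Object of class `group_result`: `mean_map` (a `pseudo_t_map`),
#'   `threshold`, `null_max` (the permuted maxima), `observed_max`,
#'   `significant` (logical per grid point), `alpha`, `n_perm`.
#' @export
permutation_threshold <- function(maps, alpha = 0.05, n_perm = 4999,
                                  seed = 1L, two_sided = FALSE,
                                  slow_relabel = NULL) {
  nsub <- length(maps)
  if (nsub < 2) stop("need at least 2 subjects for permutation inference")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_perm < 1 / alpha - 1)
    stop(sprintf("n_perm = %d too small for alpha = %g (need >= %g)",
                 n_perm, alpha, 1 / alpha - 1))
  mean_map <- aggregate_maps(maps)
  M <- do.call(rbind, lapply(maps, `[[`, "values"))   # nsub x nvox
  stat_of <- function(v) if (two_sided) max(abs(v)) else max(v)
  observed <- stat_of(mean_map$values)

  complete <- (n_perm == 2^nsub - 1)
  signs <- if (complete) {
    # all non-identity sign patterns
    s <- as.matrix(expand.grid(rep(list(c(1, -1)), nsub)))
    s[rowSums(s == 1) != nsub, , drop = FALSE]
  } else {
    with_seed(seed,
      matrix(sample(c(-1, 1), n_perm * nsub, replace = TRUE), n_perm, nsub))
  }
  null_max <- if (is.null(slow_relabel)) {
    perm_means <- (signs %*% M) / nsub       # n_perm x nvox
    if (two_sided) apply(abs(perm_means), 1, max) else
      apply(perm_means, 1, max)
  } else {
    vapply(seq_len(nrow(signs)),
           function(i) stat_of(slow_relabel(signs[i, ])), numeric(1))
  }
  pool <- sort(c(observed, null_max))
  k <- ceiling((1 - alpha) * (n_perm + 1))
  threshold <- pool[k]
  sig <- if (two_sided) abs(mean_map$values) > threshold else
    mean_map$values > threshold
  structure(list(mean_map = mean_map, threshold = threshold,
                 null_max = null_max, observed_max = observed,
                 significant = sig, alpha = alpha, n_perm = n_perm,
                 two_sided = two_sided),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("Group result: %d voxels, alpha = %g, %d permutations\n",
              length(x$significant), x$alpha, x$n_perm))
  cat(sprintf("  observed max %.3f, threshold %.3f, %d significant voxel(s)\n",
              x$observed_max, x$threshold, sum(x$significant)))
  invisible(x)
}

#' Table of significant local maxima
#'
#' Local maxima of the group mean above the permutation threshold, sorted
#' by statistic, with weaker peaks suppressed within `min_separation_mm` of
#' a stronger one.  Coordinates are head-frame millimeters.
#'
#' @param result A `group_result`.
#' @param min_separation_mm Minimum distance between reported peaks.
#' @return Data.frame with columns `x_mm`, `y_mm`, `z_mm`, `statistic`.
#' @export
report_peaks <- function(result, min_separation_mm = 20) {
  grid <- result$mean_map$grid
  vals <- result$mean_map$values
  cand <- which(result$significant)
  empty <- data.frame(x_mm = numeric(0), y_mm = numeric(0),
                      z_mm = numeric(0), statistic = numeric(0))
  if (!length(cand)) return(empty)
  pts_mm <- grid$points * 1000
  # local maximum: value >= every neighbor within ~one grid spacing
  neigh_r <- grid$spacing_mm * sqrt(3) + 1e-6
  is_locmax <- vapply(cand, function(i) {
    d <- sqrt(rowSums(sweep(pts_mm, 2, pts_mm[i, ], `-`)^2))
    nb <- which(d > 0 & d <= neigh_r)
    all(vals[i] >= vals[nb])
  }, logical(1))
  cand <- cand[is_locmax]
  if (!length(cand)) return(empty)
  cand <- cand[order(vals[cand], decreasing = TRUE)]
  acc <- integer(0)
  for (i in cand) {
    if (!length(acc) ||
        all(sqrt(rowSums(sweep(pts_mm[acc, , drop = FALSE], 2,
                               pts_mm[i, ], `-`)^2)) >= min_separation_mm))
      acc <- c(acc, i)
  }
  data.frame(x_mm = pts_mm[acc, 1], y_mm = pts_mm[acc, 2],
             z_mm = pts_mm[acc, 3], statistic = vals[acc])
}

#' Write a peak table as TSV
#' @param peaks Data.frame from [report_peaks()].
#' @param path Output path.
#' @param subset,window Optional labels recorded as columns.
#' @export
write_peaks_tsv <- function(peaks, path, subset = NA, window = NA) {
  if (nrow(peaks)) {
    peaks$subset <- subset
    peaks$window <- if (length(window) == 2)
      sprintf("%g-%g ms", window[1] * 1000, window[2] * 1000) else window
  }
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a map (or significance mask) as NIfTI-1
#'
#' Values are scattered into the full cubic grid box (background 0) and
#' written as float32 with an affine mapping voxel indices to head-frame
#' millimeters.
#'
#' @param map A `pseudo_t_map`, or a `group_result` (writes the mean map).
#' @param path Output `.nii` / `.nii.gz` path.
#' @param what For `group_result`: `"mean"` or `"mask"`.
#' @export
write_map_nifti <- function(map, path, what = c("mean", "mask")) {
  what <- match.arg(what)
  if (inherits(map, "group_result")) {
    vals <- if (what == "mask") as.numeric(map$significant) else
      map$mean_map$values
    grid <- map$mean_map$grid
  } else {
    vals <- map$values
    grid <- map$grid
  }
  vol <- array(0, grid$dim)
  vol[grid$index] <- vals
  sp <- grid$spacing_mm
  attr(vol, "pixdim") <- rep(sp, 3)
  img <- RNifti::asNifti(vol, datatype = "float")
  aff <- diag(c(sp, sp, sp, 1))
  aff[1:3, 4] <- grid$origin_mm       # 0-based voxel (0,0,0) -> first coord
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a map written by [write_map_nifti()] back into a grid vector
#' @param path NIfTI path.
#' @param grid The `source_grid` the map was written from.
#' @export
read_map_nifti <- function(path, grid) {
  vol <- RNifti::readNifti(path)
  as.numeric(vol[grid$index])
}
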