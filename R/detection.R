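# --- small array utilities (2D/3D, replicate padding) ---------------------

# Shift an array by `off` cells along dimension `d`, replicating edges.
shift_array <- function(arr, off, d) {
  dm <- dim(arr)
  idx <- lapply(dm, seq_len)
  idx[[d]] <- pmin(pmax(idx[[d]] + off, 1L), dm[d])
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

# Separable filtering: apply a 1D kernel along every dimension in turn.
sep_filter <- function(arr, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  for (d in seq_along(dim(arr))) {
    acc <- array(0, dim = dim(arr))
    for (i in seq_along(kernel)) {
      acc <- acc + kernel[i] * shift_array(arr, i - 1L - half, d)
    }
    arr <- acc
  }
  arr
}

# Grayscale dilation with a (2w+1)^dim cube: separable running maximum.
max_filter <- function(arr, w) {
  for (d in seq_along(dim(arr))) {
    acc <- arr
    for (off in seq_len(w)) {
      acc <- pmax(acc, shift_array(arr, -off, d), shift_array(arr, off, d))
    }
    arr <- acc
  }
  arr
}

gauss_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-half:half, sd = sigma)
  k / sum(k)
}

# --- detection -------------------------------------------------------------

#' Band-pass restoration of a spot image
#'
#' Prepares an image for spot detection: Gaussian smoothing at scale
#' radius/3 (suppressing pixel noise) minus the local background mean over a
#' (2 radius + 1) box in every dimension (suppressing slowly varying
#' background). A constant image restores to zero everywhere. Edges are
#' handled by replicate padding.
#'
#' @param image 2D or 3D numeric array of intensities.
#' @param radius approximate blob radius w in pixels (>= 1).
#' @return restored array of the same shape.
#' @export
restore_image <- function(image, radius) {
  if (is.null(dim(image))) stop("image must be a 2D or 3D array")
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be at least 1")
  if (any(dim(image) < 2L * radius + 1L)) stop("image smaller than the filter kernel")
  if (any(!is.finite(image))) stop("image must be finite")
  smooth <- sep_filter(image, gauss_kernel(radius / 3))
  background <- sep_filter(image, rep(1 / (2 * radius + 1), 2L * radius + 1L))
  smooth - background
}

#' Detect bright spots in a 2D/3D image
#'
#' Feature-point detection for blob-like objects: the image is band-pass
#' restored ([restore_image()]); local maxima of the restored image within a
#' (2 radius + 1) neighborhood whose restored intensity lies in the upper
#' `percentile` of the restored-intensity histogram become candidates; each
#' candidate is refined to sub-pixel position by an iterated intensity-
#' weighted centroid within `radius` (at most 10 iterations, stopping when
#' the shift drops below 0.01 px); finally non-blob-like candidates are
#' rejected by a score computed from their zeroth (m0) and second (m2)
#' intensity moments.
#'
#' The score is a likeness score in (0, 1]: the Gaussian kernel
#' exp(-(z0^2 + z2^2)/2) of the candidate's robustly standardized (m0, m2)
#' position within the candidate cloud. Candidates scoring below `cutoff`
#' are discarded, so a larger cutoff is more conservative and keeps only
#' objects that look alike; `cutoff = 0` keeps all candidates. Detection is
#' invariant to affine rescaling of the image intensities.
#'
#' Choose `radius` slightly larger than the visible object radius but smaller
#' than the smallest NN separation between objects.
#'
#' @param image 2D or 3D numeric array.
#' @param radius approximate blob radius in pixels (>= 1).
#' @param cutoff score threshold for false-positive rejection (>= 0).
#' @param percentile upper intensity percentile, in (0, 100], defining how
#'   bright a local maximum must be to become a candidate.
#' @return object of class `detections`: `points` (a [point_set()] of 0-based
#'   sub-pixel coordinates, first coordinate along the first array
#'   dimension), `m0`, `m2`, and `scores`. Zero detections yield an empty
#'   `detections` object, not an error.
#' @export
detect_spots <- function(image, radius, cutoff = 0, percentile = 1) {
  radius <- as.integer(radius)
  if (percentile <= 0 || percentile > 100) stop("percentile must be in (0, 100]")
  if (cutoff < 0) stop("cutoff must be nonnegative")
  restored <- restore_image(image, radius)
  rng <- diff(range(restored))
  empty <- structure(list(points = NULL, m0 = numeric(0), m2 = numeric(0),
                          scores = numeric(0), dim = dim(image)),
                     class = "detections")
  if (rng <= 0) return(empty)  # flat image: nothing to detect

  thr <- quantile(restored, 1 - percentile / 100, names = FALSE)
  is_max <- restored >= max_filter(restored, radius) & restored >= thr &
    restored > 0
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)

  pos <- refine_centroids(restored, cand, radius)
  mom <- spot_moments(restored, pos, radius)
  keep <- mom$m0 > 0
  pos <- pos[keep, , drop = FALSE]
  m0 <- mom$m0[keep]
  m2 <- mom$m2[keep]
  if (nrow(pos) == 0L) return(empty)

  scores <- likeness_score(cbind(m0, m2))
  keep <- scores >= cutoff
  structure(list(points = if (any(keep)) point_set(pos[keep, , drop = FALSE]) else NULL,
                 m0 = m0[keep], m2 = m2[keep], scores = scores[keep],
                 dim = dim(image)),
            class = "detections")
}

#' @export
print.detections <- function(x, ...) {
  n <- if (is.null(x$points)) 0L else nrow(x$points)
  cat(sprintf("Detections: %d spots in a %s image\n", n,
              paste(x$dim, collapse = "x")))
  invisible(x)
}

# Iterated intensity-weighted centroid within `radius` of each candidate.
# Positions are 0-based pixel coordinates; negative restored intensities are
# clamped to zero for the weighting.
refine_centroids <- function(restored, cand, radius, max_iter = 10L, tol = 0.01) {
  dm <- dim(restored)
  ndim <- length(dm)
  offs <- as.matrix(expand.grid(rep(list(-radius:radius), ndim)))
  ball <- sqrt(rowSums(offs^2)) <= radius + 1e-9
  offs <- offs[ball, , drop = FALSE]
  out <- matrix(0, nrow(cand), ndim)
  for (i in seq_len(nrow(cand))) {
    ctr <- as.numeric(cand[i, ])  # 1-based integer position
    for (iter in seq_len(max_iter)) {
      cells <- sweep(offs, 2L, round(ctr), `+`)
      ok <- rep(TRUE, nrow(cells))
      for (d in seq_len(ndim)) ok <- ok & cells[, d] >= 1L & cells[, d] <= dm[d]
      cells <- cells[ok, , drop = FALSE]
      wts <- pmax(restored[cells], 0)
      if (sum(wts) <= 0) break
      new_ctr <- colSums(cells * wts) / sum(wts)
      shift <- sqrt(sum((new_ctr - ctr)^2))
      ctr <- new_ctr
      if (shift < tol) break
    }
    out[i, ] <- ctr - 1  # to 0-based coordinates
  }
  out
}

# Zeroth and second intensity moments within `radius` of each refined spot.
spot_moments <- function(restored, pos, radius) {
  dm <- dim(restored)
  ndim <- length(dm)
  offs <- as.matrix(expand.grid(rep(list(-radius:radius), ndim)))
  ball <- sqrt(rowSums(offs^2)) <= radius + 1e-9
  offs <- offs[ball, , drop = FALSE]
  m0 <- m2 <- numeric(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    ctr1 <- pos[i, ] + 1  # back to 1-based
    cells <- sweep(offs, 2L, round(ctr1), `+`)
    ok <- rep(TRUE, nrow(cells))
    for (d in seq_len(ndim)) ok <- ok & cells[, d] >= 1L & cells[, d] <= dm[d]
    cells <- cells[ok, , drop = FALSE]
    wts <- pmax(restored[cells], 0)
    r2 <- rowSums((sweep(cells, 2L, ctr1, `-`))^2)
    m0[i] <- sum(wts)
    m2[i] <- if (m0[i] > 0) sum(wts * r2) / m0[i] else 0
  }
  list(m0 = m0, m2 = m2)
}

# Likeness of each candidate's (m0, m2) pair to the bulk of the cloud:
# Gaussian kernel of the robustly standardized distance from the cloud
# center. Rank/shape based, hence invariant to affine intensity rescaling.
likeness_score <- function(feats) {
  z2 <- numeric(nrow(feats))
  for (j in seq_len(ncol(feats))) {
    v <- feats[, j]
    ctr <- median(v)
    sc <- mad(v)
    if (sc <= 0) sc <- sd(v)
    if (!is.finite(sc) || sc <= 0) sc <- 1
    z2 <- z2 + ((v - ctr) / sc)^2
  }
  exp(-z2 / 2)
}
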