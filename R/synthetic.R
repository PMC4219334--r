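# Uniform draws inside region (rejection against the mask where present).
runif_region <- function(n, region) {
  lo <- region$bounds[1L, ]
  hi <- region$bounds[2L, ]
  draw <- function(k) {
    m <- vapply(seq_len(region$dim), function(d) runif(k, lo[d], hi[d]),
                numeric(k))
    if (k == 1L) m <- matrix(m, nrow = 1L)
    m
  }
  if (is.null(region$mask)) return(draw(n))
  out <- matrix(0, 0L, region$dim)
  tries <- 0L
  while (nrow(out) < n) {
    prop <- draw(max(n, 2L * (n - nrow(out))))
    keep <- mask_lookup(region, prop)
    out <- rbind(out, prop[keep, , drop = FALSE])
    tries <- tries + 1L
    if (tries > 1000L) stop("empty admissible region: mask rejects everything")
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a uniform reference point set
#'
#' M points placed independently and uniformly at random within the region
#' (respecting its mask). This is the reference-set model under which the
#' context construction is exact.
#'
#' @param M number of points (>= 1).
#' @param region a [region()].
#' @param seed integer seed (NULL to use the current RNG state).
#' @return a [point_set()].
#' @export
generate_reference <- function(M, region, seed = NULL) {
  if (M < 1) stop("M must be at least 1")
  pts <- with_seed(seed, runif_region(M, region))
  point_set(pts, label = "Y")
}

#' Generate a dependent point set interacting with a reference set
#'
#' Draws N points whose NN-distance distribution to `y` follows the Gibbs
#' model marginal q(d) exp(-phi(d)) / Z, by exact rejection sampling: a
#' uniform proposal u in the region is accepted with probability
#' exp(-(phi(d_u) - phi_min)) where d_u is its NN distance to `y`. Points are
#' independent given `y`, matching the product form of the model. With
#' epsilon = 0 this reduces to uniform placement.
#'
#' @param y reference point set.
#' @param N number of points to generate.
#' @param potential an `ia_potential` (the ground truth).
#' @param region a [region()].
#' @param seed integer seed.
#' @return a [point_set()].
#' @export
generate_interacting <- function(y, N, potential, region, seed = NULL) {
  stopifnot(inherits(potential, "ia_potential"))
  y <- as_coord_matrix(y)
  pm <- phi_min(potential)
  with_seed(seed, {
    out <- matrix(0, 0L, region$dim)
    proposed <- 0L
    accepted <- 0L
    while (nrow(out) < N) {
      k <- max(4L * N, 256L)
      prop <- runif_region(k, region)
      d <- nn_distances(prop, y)
      acc <- runif(k) < exp(-(potential_value(potential, d) - pm))
      proposed <- proposed + k
      accepted <- accepted + sum(acc)
      out <- rbind(out, prop[acc, , drop = FALSE])
      if (proposed >= 2e4 && accepted / proposed < 1e-4) {
        stop(sprintf(paste0("rejection sampling acceptance rate %.2g after %d ",
                            "proposals: potential too extreme (phi range [%.3g, %.3g])"),
                     accepted / proposed, proposed, pm,
                     max(potential_value(potential, d))))
      }
    }
    point_set(out[seq_len(N), , drop = FALSE], label = "X")
  })
}

#' Render a synthetic blob image
#'
#' Places isotropic Gaussian blobs of unit peak amplitude at the given
#' (sub-pixel, 0-based) positions on a zero background and adds i.i.d.
#' Gaussian noise with standard deviation 1/snr, so `snr` is the peak
#' amplitude over the noise standard deviation. The Gaussian standard
#' deviation is `blob_radius / 2`, making `blob_radius` roughly the visible
#' radius of a blob.
#'
#' @param points matrix of blob centers (0-based pixel coordinates, one blob
#'   per row; first column indexes the first image dimension).
#' @param blob_radius visible blob radius in pixels.
#' @param snr peak signal-to-noise ratio; `Inf` for a noise-free image.
#' @param size integer vector of image dimensions (2D or 3D).
#' @param seed integer seed for the noise.
#' @return numeric array of the given size.
#' @export
generate_blob_image <- function(points, blob_radius, snr, size, seed = NULL) {
  size <- as.integer(size)
  img <- array(0, dim = size)
  sigma <- blob_radius / 2
  if (!is.null(points) && NROW(points) > 0L) {
    points <- as_coord_matrix(points)
    if (ncol(points) != length(size)) stop("points and image size dimensionality differ")
    if (any(points < 0) || any(sweep(points, 2L, size - 1L) > 0)) {
      stop("blob centers must lie inside the image")
    }
    ext <- ceiling(4 * sigma)
    for (b in seq_len(nrow(points))) {
      ctr <- points[b, ]
      rng <- lapply(seq_along(size), function(d) {
        max(0L, floor(ctr[d] - ext)):min(size[d] - 1L, ceiling(ctr[d] + ext))
      })
      ax <- lapply(seq_along(size), function(d) exp(-(rng[[d]] - ctr[d])^2 / (2 * sigma^2)))
      blob <- Reduce(function(a, b) outer(a, b), ax)
      idx <- lapply(rng, function(r) r + 1L)
      patch <- do.call(`[`, c(list(img), idx, list(drop = FALSE)))
      patch <- patch + array(blob, dim = vapply(idx, length, 1L))
      img <- do.call(`[<-`, c(list(img), idx, list(patch)))
    }
  }
  if (is.finite(snr)) {
    img <- img + with_seed(seed, array(rnorm(length(img), sd = 1 / snr), dim = size))
  }
  img
}
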