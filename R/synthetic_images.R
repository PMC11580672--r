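#' Parameters for the synthetic two-channel marker image generator
#'
#' Emulates a field of immunostained cells imaged in two channels (e.g. a
#' disease-associated marker and a signalling marker): both channels share
#' the same blob (cell) geometry, and each blob's per-channel intensities are
#' drawn from a bivariate normal (a Gaussian copula with normal marginals)
#' whose correlation equals `channel_corr` in expectation, so the ground
#' truth inter-channel correlation is controllable.
#'
#' @param shape image (height, width) in pixels.
#' @param n_blobs number of non-overlapping disks to place.
#' @param blob_radius_range (min, max) disk radius in pixels.
#' @param channel_corr target per-blob inter-channel intensity correlation
#'   in \[-1, 1\].
#' @param background_sd standard deviation of the additive Gaussian
#'   background noise (intensity units; blob intensities are ~0.55 +/- 0.1).
#' @param seed integer seed; NULL uses the current RNG stream.
#' @return list of class `image_gen_params`.
#' @export
image_gen_params <- function(shape = c(256L, 256L),
                             n_blobs = 12L,
                             blob_radius_range = c(5, 9),
                             channel_corr = 0.7,
                             background_sd = 0.02,
                             seed = NULL) {
  stopifnot(length(shape) == 2, all(shape >= 16),
            n_blobs >= 1,
            blob_radius_range[1] > 0,
            blob_radius_range[2] >= blob_radius_range[1],
            channel_corr >= -1, channel_corr <= 1,
            background_sd >= 0)
  if (2 * blob_radius_range[2] + 2 > min(shape)) {
    stop("blobs do not fit inside the frame")
  }
  structure(list(shape = as.integer(shape), n_blobs = as.integer(n_blobs),
                 blob_radius_range = blob_radius_range,
                 channel_corr = channel_corr, background_sd = background_sd,
                 seed = seed),
            class = "image_gen_params")
}

#' Generate a synthetic two-channel marker image with ground truth
#'
#' Places `n_blobs` non-overlapping disks uniformly at random (bounded
#' rejection sampling; an error is raised if a non-overlapping placement
#' cannot be found). Per-blob intensity pairs are bivariate normal with
#' mean 0.55, sd 0.1 and correlation `channel_corr`; rendered images add
#' Gaussian background noise and are clamped to \[0, 1\] (the ground-truth
#' table records the drawn, unclamped intensities).
#'
#' @param p an [image_gen_params()].
#' @return list with `channels` (list of two H x W matrices) and `truth`
#'   (data.frame: blob, x (column), y (row), radius, intensity_ch1,
#'   intensity_ch2).
#' @export
generate_marker_image <- function(p = image_gen_params()) {
  stopifnot(inherits(p, "image_gen_params"))
  with_seed(p$seed, {
    H <- p$shape[1]; W <- p$shape[2]
    radii <- stats::runif(p$n_blobs, p$blob_radius_range[1],
                          p$blob_radius_range[2])
    cx <- cy <- numeric(p$n_blobs)
    for (i in seq_len(p$n_blobs)) {
      placed <- FALSE
      for (try in 1:2000) {
        x <- stats::runif(1, radii[i] + 2, W - radii[i] - 1)
        y <- stats::runif(1, radii[i] + 2, H - radii[i] - 1)
        if (i == 1L ||
            all(sqrt((cx[seq_len(i - 1)] - x)^2 +
                     (cy[seq_len(i - 1)] - y)^2) >
                radii[seq_len(i - 1)] + radii[i] + 2)) {
          cx[i] <- x; cy[i] <- y; placed <- TRUE; break
        }
      }
      if (!placed) {
        stop("could not place ", p$n_blobs,
             " non-overlapping blobs; reduce n_blobs or blob radius")
      }
    }
    # Gaussian copula with normal marginals: exact target correlation
    z1 <- stats::rnorm(p$n_blobs)
    z2 <- p$channel_corr * z1 +
      sqrt(max(0, 1 - p$channel_corr^2)) * stats::rnorm(p$n_blobs)
    i1 <- 0.55 + 0.1 * z1
    i2 <- 0.55 + 0.1 * z2

    render <- function(intens) {
      img <- matrix(0, H, W)
      for (i in seq_len(p$n_blobs)) {
        rr <- ceiling(radii[i])
        rows <- max(1, floor(cy[i]) - rr):min(H, ceiling(cy[i]) + rr)
        cols <- max(1, floor(cx[i]) - rr):min(W, ceiling(cx[i]) + rr)
        dy <- (rows - cy[i])^2
        dx <- (cols - cx[i])^2
        disk <- outer(dy, dx, "+") <= radii[i]^2
        img[rows, cols][disk] <- intens[i]
      }
      if (p$background_sd > 0) {
        img <- img + matrix(stats::rnorm(H * W, 0, p$background_sd), H, W)
      }
      pmin(pmax(img, 0), 1)
    }
    list(
      channels = list(ch1 = render(i1), ch2 = render(i2)),
      truth = data.frame(blob = seq_len(p$n_blobs), x = cx, y = cy,
                         radius = radii, intensity_ch1 = i1,
                         intensity_ch2 = i2)
    )
  })
}

#' Write a two-channel image as a multi-page TIFF (one channel per page)
#'
#' @param img result of [generate_marker_image()], or a list of numeric
#'   matrices in \[0,1\].
#' @param path output .tif path.
#' @return `path`, invisibly.
#' @export
write_marker_tiff <- function(img, path) {
  channels <- if (!is.null(img$channels)) img$channels else img
  stopifnot(is.list(channels), all(vapply(channels, is.matrix, logical(1))))
  tiff::writeTIFF(unname(channels), path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a list of channel matrices
#'
#' @param path .tif path.
#' @return list of numeric matrices in \[0,1\].
#' @export
read_marker_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(pg) {
    if (length(dim(pg)) == 3) pg <- pg[, , 1]
    pg
  })
}
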