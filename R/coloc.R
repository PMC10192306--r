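#' Read / write a single-plane grayscale image
#'
#' TIFF IO for channel images, via the tiff package. 8/16-bit integer
#' images are read at their native scale (`as.is = TRUE`); 32-bit float
#' TIFFs are read as stored.
#'
#' @param path TIFF path.
#' @return Numeric matrix of pixel values (rows = image rows).
#' @export
read_image_plane <- function(path) {
  img <- tiff::readTIFF(path, info = TRUE)
  bps <- attr(img, "bits.per.sample")
  if (is.null(bps) || bps < 32L) {
    img <- tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] != 1L) {
      stop("expected a single-plane grayscale image: ", path,
           call. = FALSE)
    }
    img <- img[, , 1L]
  }
  attributes(img) <- list(dim = dim(img))
  check_image(img)
  img
}

#' @rdname read_image_plane
#' @param image Numeric matrix; values above 1 are rescaled by the image
#'   maximum before writing (TIFF float samples are stored in [0, 1]).
#' @export
write_image_plane <- function(image, path) {
  tiff::writeTIFF(image / max(1, max(image)), path,
                  bits.per.sample = 32L)
  invisible(path)
}

check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(image)) || any(image < 0)) {
    stop("image must contain finite, non-negative values", call. = FALSE)
  }
  invisible(image)
}

check_mask <- function(mask, image) {
  if (!identical(dim(mask), dim(image))) {
    stop("mask shape does not match image shape", call. = FALSE)
  }
  m <- mask != 0
  storage.mode(m) <- "logical"
  m
}

#' Subtract a constant background from an image
#'
#' Pixelwise `max(value - constant, 0)`. The same constant should be
#' applied to all images of one experiment so intensities stay
#' comparable across conditions.
#'
#' @param image Numeric matrix.
#' @param constant Non-negative background level.
#' @return Matrix of the same shape.
#' @export
subtract_background <- function(image, constant) {
  check_image(image)
  if (constant < 0) stop("background constant must be >= 0", call. = FALSE)
  pmax(image - constant, 0)
}

#' Pearson correlation between two channels within an ROI
#'
#' The standard Pearson correlation of pixel intensities over the mask
#' support only -- e.g. a protein of interest against a Golgi marker
#' within a manually outlined cell.
#'
#' @param ch1,ch2 Numeric matrices of identical shape.
#' @param mask Binary matrix of the same shape; at least 2 pixels set.
#' @return Correlation in [-1, 1].
#' @details A channel that is constant over the mask has no defined
#'   correlation; that raises an error rather than silently returning 0.
#' @export
pearson_roi <- function(ch1, ch2, mask) {
  check_image(ch1); check_image(ch2)
  if (!identical(dim(ch1), dim(ch2))) {
    stop("channel shapes differ", call. = FALSE)
  }
  m <- check_mask(mask, ch1)
  if (sum(m) < 2L) stop("mask support must be >= 2 pixels", call. = FALSE)
  x <- ch1[m]; y <- ch2[m]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: a channel is constant over the mask",
         call. = FALSE)
  }
  stats::cor(x, y)
}

#' Thresholded Manders colocalization coefficients
#'
#' `M1` is the fraction of channel-1 intensity (within the mask) lying
#' in pixels where channel 2 exceeds its threshold `t2`; `M2` is the
#' symmetric quantity with the roles swapped. With channel 1 the protein
#' of interest and channel 2 an organelle marker, M1 is the
#' colocalization rate of the protein with the marker and M2 that of
#' the marker with the protein.
#'
#' @param ch1,ch2 Numeric matrices of identical shape.
#' @param mask Binary matrix (default: full image).
#' @param t1,t2 Intensity thresholds for channels 1 and 2 (defaults 0,
#'   appropriate after background subtraction; the comparison is strict).
#' @return Named numeric vector `c(M1 = ..., M2 = ...)`, both in [0, 1],
#'   with attributes `n_pixels` (mask support) and `thresholds`.
#' @export
manders <- function(ch1, ch2, mask = NULL, t1 = 0, t2 = 0) {
  check_image(ch1); check_image(ch2)
  if (!identical(dim(ch1), dim(ch2))) {
    stop("channel shapes differ", call. = FALSE)
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(ch1), ncol(ch1))
  m <- check_mask(mask, ch1)
  s1 <- sum(ch1[m]); s2 <- sum(ch2[m])
  if (s1 <= 0 || s2 <= 0) {
    stop("undefined Manders coefficient: zero total intensity in the ",
         "referenced channel over the mask", call. = FALSE)
  }
  m1 <- sum(ch1[m & ch2 > t2]) / s1
  m2 <- sum(ch2[m & ch1 > t1]) / s2
  structure(c(M1 = m1, M2 = m2),
            n_pixels = sum(m), thresholds = c(t1 = t1, t2 = t2))
}

#' Binarize a marker image into an ROI mask
#'
#' Turns a marker channel (e.g. GM130 for the Golgi) into the binary
#' region used to gate intensity quantification. With `method = "otsu"`
#' the threshold maximizes between-class variance on a 256-bin
#' histogram ([EBImage::otsu()]); `method = "fixed"` uses
#' `fixed_threshold`. Pixels strictly above the threshold are in the
#' mask.
#'
#' @param image Numeric matrix.
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_threshold Threshold for `method = "fixed"`.
#' @return Logical matrix, with the threshold used in attribute
#'   `"threshold"`. An all-equal image under Otsu yields an empty mask
#'   with a warning.
#' @export
binarize_marker <- function(image, method = c("otsu", "fixed"),
                            fixed_threshold = NULL) {
  check_image(image)
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_threshold)) {
      stop("fixed_threshold must be given for method = 'fixed'",
           call. = FALSE)
    }
    thr <- fixed_threshold
  } else {
    rng <- range(image)
    if (rng[1L] == rng[2L]) {
      warning("constant image: Otsu threshold undefined, returning ",
              "an empty mask")
      return(structure(matrix(FALSE, nrow(image), ncol(image)),
                       threshold = NA_real_))
    }
    thr <- EBImage::otsu(image, range = rng, levels = 256L)
  }
  structure(image > thr, threshold = thr)
}

#' Mean signal intensity within a mask, per unit area
#'
#' Total signal over the mask divided by the masked area -- the area is
#' the pixel count, scaled by `pixel_size^2` when a physical pixel size
#' is supplied. Used e.g. to quantify Golgi-PtdIns(4)P as the lipid
#' signal within the marker-derived Golgi mask normalized by the Golgi
#' area.
#'
#' @param signal Numeric matrix.
#' @param mask Binary matrix of the same shape, support >= 1 pixel.
#' @param pixel_size Optional physical edge length of a pixel.
#' @return Non-negative scalar (intensity per pixel, or per squared
#'   `pixel_size` unit).
#' @export
masked_mean_intensity <- function(signal, mask, pixel_size = NULL) {
  check_image(signal)
  m <- check_mask(mask, signal)
  n <- sum(m)
  if (n == 0L) stop("empty mask", call. = FALSE)
  area <- if (is.null(pixel_size)) n else n * pixel_size^2
  sum(signal[m]) / area
}

#' Intensity line profile across channels
#'
#' Samples each channel along the segment from `from` to `to` by
#' bilinear interpolation at `step`-pixel spacing, averaging over
#' `width` parallel one-pixel-spaced lines placed symmetrically about
#' the segment. Each channel is normalized by its own maximum along the
#' profile, so profiles from channels of different brightness share a
#' 0-1 axis. Coordinates are `c(row, col)` with pixel centers at
#' integer positions, origin at the top-left.
#'
#' @param channels A named list of numeric matrices (identical shapes).
#' @param from,to Segment endpoints, `c(row, col)`, inside the image.
#' @param step Sampling interval along the line, in pixels (default 1).
#' @param width Averaging width perpendicular to the line, in pixels
#'   (odd; default 1).
#' @param pixel_size Optional physical pixel size scaling the distance
#'   axis.
#' @param normalize `"max"` (default; profile maximum maps to 1) or
#'   `"minmax"` (profile range maps to [0, 1]).
#' @return Data frame with columns `distance`, `channel`, `intensity`.
#' @export
line_profile <- function(channels, from, to, step = 1, width = 1L,
                         pixel_size = NULL,
                         normalize = c("max", "minmax")) {
  normalize <- match.arg(normalize)
  if (!is.list(channels)) channels <- list(ch1 = channels)
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    names(channels) <- paste0("ch", seq_along(channels))
  }
  lapply(channels, check_image)
  dm <- dim(channels[[1L]])
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  if (width < 1L || width %% 2L != 1L) {
    stop("width must be a positive odd integer", call. = FALSE)
  }
  from <- as.numeric(from); to <- as.numeric(to)
  len <- sqrt(sum((to - from)^2))
  if (len == 0) stop("zero-length line", call. = FALSE)
  if (any(c(from, to) < 1) || from[1L] > dm[1L] || to[1L] > dm[1L] ||
      from[2L] > dm[2L] || to[2L] > dm[2L]) {
    stop("line endpoints must lie inside the image", call. = FALSE)
  }
  d <- seq(0, len, by = step)
  dir <- (to - from) / len          # unit vector along the line
  perp <- c(-dir[2L], dir[1L])      # unit normal
  offsets <- seq_len(width) - (width + 1) / 2
  rows_q <- outer(d, rep(1, width)) * dir[1L] + from[1L] +
    outer(rep(1, length(d)), offsets) * perp[1L]
  cols_q <- outer(d, rep(1, width)) * dir[2L] + from[2L] +
    outer(rep(1, length(d)), offsets) * perp[2L]
  # clamp off-grid averaging lines to the image border
  rows_q <- pmin(pmax(rows_q, 1), dm[1L])
  cols_q <- pmin(pmax(cols_q, 1), dm[2L])
  out <- lapply(names(channels), function(nm) {
    z <- channels[[nm]]
    # pracma::interp2 takes x = column coords, y = row coords, Z[y, x]
    v <- pracma::interp2(x = seq_len(dm[2L]), y = seq_len(dm[1L]),
                         Z = z, xp = as.vector(cols_q),
                         yp = as.vector(rows_q), method = "linear")
    v <- rowMeans(matrix(v, nrow = length(d)))
    if (normalize == "max") {
      if (max(v) <= 0) {
        stop("cannot normalize channel '", nm,
             "': all-zero along the profile", call. = FALSE)
      }
      v <- v / max(v)
    } else {
      if (max(v) == min(v)) {
        stop("cannot min-max normalize channel '", nm,
             "': constant along the profile", call. = FALSE)
      }
      v <- (v - min(v)) / (max(v) - min(v))
    }
    data.frame(distance = if (is.null(pixel_size)) d else d * pixel_size,
               channel = nm, intensity = v, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# truncated Gaussian blob kernel on a (2r+1)^2 support, zero outside
blob_kernel <- function(sigma, radius = ceiling(4 * sigma)) {
  g <- stats::dnorm(-radius:radius, sd = sigma)
  outer(g, g)
}

#' Synthetic two-channel colocalization image pair
#'
#' Generates a fixture with known ground truth for the colocalization
#' metrics: channel 1 is a sum of `n_objects` equal-amplitude Gaussian
#' blobs (truncated at 4 sigma) at random non-overlapping positions;
#' channel 2 re-uses the centers of a designed fraction
#' `overlap_fraction` of channel 1's blobs and places the remainder at
#' independent positions, also non-overlapping with every other blob.
#' Because supports are disjoint except for the co-positioned pairs,
#' the zero-threshold Manders M1 of the pair equals `overlap_fraction`
#' up to discretization.
#'
#' @param shape Image dimensions `c(rows, cols)` (default 256 x 256).
#' @param n_objects Number of blobs per channel (default 20).
#' @param overlap_fraction Designed fraction of co-positioned blobs,
#'   in [0, 1].
#' @param object_sigma Blob SD in pixels (default 2).
#' @param noise_sd SD of additive truncated-normal noise (default 0).
#' @param seed Optional local seed.
#' @return List with `ch1`, `ch2` (matrices) and `truth` (list:
#'   `overlap_fraction`, `n_copositioned`, `centers1`, `centers2`).
#' @export
synth_coloc_image <- function(shape = c(256L, 256L), n_objects = 20L,
                              overlap_fraction = 0.5, object_sigma = 2,
                              noise_sd = 0, seed = NULL) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    stop("overlap_fraction must be in [0, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  with_seed(seed, {
    radius <- ceiling(4 * object_sigma)
    n_co <- round(overlap_fraction * n_objects)
    n_indep <- n_objects - n_co
    n_total <- n_objects + n_indep
    # rejection-sample centers pairwise >= 2*radius+1 apart, inside margins
    centers <- matrix(NA_real_, n_total, 2L)
    placed <- 0L
    tries <- 0L
    while (placed < n_total) {
      tries <- tries + 1L
      if (tries > 20000L) {
        stop("could not place non-overlapping blobs; enlarge shape or ",
             "reduce n_objects/object_sigma", call. = FALSE)
      }
      cand <- c(stats::runif(1, radius + 1, shape[1L] - radius),
                stats::runif(1, radius + 1, shape[2L] - radius))
      if (placed == 0L ||
          all(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                                 2L, cand)^2)) >= 2 * radius + 1)) {
        placed <- placed + 1L
        centers[placed, ] <- cand
      }
    }
    centers1 <- centers[seq_len(n_objects), , drop = FALSE]
    centers2 <- rbind(centers1[seq_len(n_co), , drop = FALSE],
                      centers[n_objects + seq_len(n_indep), ,
                              drop = FALSE])
    paint <- function(ctrs) {
      img <- matrix(0, shape[1L], shape[2L])
      k <- blob_kernel(object_sigma, radius)
      for (i in seq_len(nrow(ctrs))) {
        r0 <- round(ctrs[i, 1L]); c0 <- round(ctrs[i, 2L])
        rr <- (r0 - radius):(r0 + radius)
        cc <- (c0 - radius):(c0 + radius)
        img[rr, cc] <- img[rr, cc] + k
      }
      img
    }
    ch1 <- paint(centers1)
    ch2 <- paint(centers2)
    if (noise_sd > 0) {
      ch1 <- ch1 + abs(matrix(stats::rnorm(prod(shape), sd = noise_sd),
                              shape[1L]))
      ch2 <- ch2 + abs(matrix(stats::rnorm(prod(shape), sd = noise_sd),
                              shape[1L]))
    }
    list(ch1 = ch1, ch2 = ch2,
         truth = list(overlap_fraction = overlap_fraction,
                      n_copositioned = n_co,
                      centers1 = centers1, centers2 = centers2))
  })
}

#' Batch colocalization of image/ROI pairs
#'
#' Computes the per-ROI colocalization row the imaging pipeline reports:
#' Pearson within the ROI, thresholded Manders over the marker mask, and
#' the masked mean intensity of channel 1 within the marker-derived
#' mask.
#'
#' @param ch1,ch2 Numeric matrices (channel 1 = protein of interest /
#'   signal; channel 2 = marker).
#' @param roi Binary cell ROI (default full frame).
#' @param background Constant subtracted from both channels first
#'   (default 0).
#' @param t1,t2 Manders thresholds (default 0).
#' @param marker_method Binarization for the marker mask (see
#'   [binarize_marker()]).
#' @return One-row data frame: `pearson_r`, `m1`, `m2`, `n_pixels`,
#'   `masked_intensity`, `marker_threshold`.
#' @export
coloc_stats <- function(ch1, ch2, roi = NULL, background = 0,
                        t1 = 0, t2 = 0, marker_method = "otsu") {
  ch1 <- subtract_background(ch1, background)
  ch2 <- subtract_background(ch2, background)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(ch1), ncol(ch1))
  r <- pearson_roi(ch1, ch2, roi)
  mm <- manders(ch1, ch2, roi, t1 = t1, t2 = t2)
  marker <- binarize_marker(ch2, method = marker_method)
  marker_mask <- marker & (roi != 0)
  mi <- if (sum(marker_mask) > 0L) {
    masked_mean_intensity(ch1, marker_mask)
  } else {
    NA_real_
  }
  data.frame(pearson_r = r, m1 = unname(mm["M1"]), m2 = unname(mm["M2"]),
             n_pixels = sum(roi != 0), masked_intensity = mi,
             marker_threshold = attr(marker, "threshold"))
}
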