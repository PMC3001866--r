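# Image containers, despeckling, thresholding/segmentation, and per-slice
# Euclidean distance maps.
#
# Volumes are arrays indexed [y, x, z]; `voxel_size = c(dx, dy, dz)` in um.
# A voxel (iy, ix, iz) has its physical center at
# ((ix - 0.5) dx, (iy - 0.5) dy, (iz - 0.5) dz) -- the same convention the
# synthetic nucleus generator uses, so measured and planted coordinates are
# directly comparable.

#' Calibrated multi-channel 3D image stack
#'
#' @param channels named list of 3D numeric arrays `[y, x, z]`, equal dims.
#' @param voxel_size numeric `c(dx, dy, dz)` in um (z-step defaults to the
#'   0.12 um optical sectioning of the study design).
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(channels, voxel_size = c(0.08, 0.08, 0.12)) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))),
            length(voxel_size) == 3L, all(voxel_size > 0))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3L)) stop("channels must be 3D arrays")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L) {
    stop("all channels must share the same dimensions")
  }
  structure(list(channels = channels,
                 voxel_size = setNames(as.numeric(voxel_size),
                                       c("dx", "dy", "dz"))),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("voxel_grid: %d x %d x %d voxels (%.3g x %.3g x %.3g um), channels: %s\n",
              d[2L], d[1L], d[3L], x$voxel_size[1L], x$voxel_size[2L],
              x$voxel_size[3L], paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# vectorized medians of 3 and 5 via min/max networks
med3 <- function(a, b, c) pmax(pmin(a, b), pmin(pmax(a, b), c))
med5 <- function(a, b, c, d, e) {
  med3(pmax(pmin(a, b), pmin(c, d)), pmin(pmax(a, b), pmax(c, d)), e)
}

# reflect-101 padding by one pixel (mirror about the border pixel)
pad_reflect1 <- function(m) {
  m <- rbind(m[2L, , drop = FALSE], m, m[nrow(m) - 1L, , drop = FALSE])
  cbind(m[, 2L, drop = FALSE], m, m[, ncol(m) - 1L, drop = FALSE])
}

#' 3x3 hybrid median despeckle filter
#'
#' Edge-preserving speckle removal: each pixel becomes the median of three
#' values -- the median of its "+" neighborhood (N, S, W, E, center), the
#' median of its "x" neighborhood (the four diagonals and the center), and
#' the center pixel itself. Borders are mirror-extended (reflect-101).
#' Inputs smaller than 3x3 are returned unchanged with a warning.
#'
#' @param slice 2D numeric matrix.
#' @return filtered matrix of the same size.
#' @export
hybrid_median_despeckle <- function(slice) {
  stopifnot(is.matrix(slice))
  if (nrow(slice) < 3L || ncol(slice) < 3L) {
    warning("slice smaller than 3x3; returned unchanged")
    return(slice)
  }
  p <- pad_reflect1(slice)
  nr <- nrow(slice)
  nc <- ncol(slice)
  ri <- 2:(nr + 1L)
  ci <- 2:(nc + 1L)
  C <- p[ri, ci]
  N <- p[ri - 1L, ci]; S <- p[ri + 1L, ci]
  W <- p[ri, ci - 1L]; E <- p[ri, ci + 1L]
  NW <- p[ri - 1L, ci - 1L]; NE <- p[ri - 1L, ci + 1L]
  SW <- p[ri + 1L, ci - 1L]; SE <- p[ri + 1L, ci + 1L]
  med3(med5(N, S, W, E, C), med5(NW, NE, SW, SE, C), C)
}

#' Otsu threshold over a pooled intensity sample
#'
#' Classic between-class-variance maximization on a 256-bin histogram of the
#' full sample (the whole volume, not per slice). Returns the intensity cut;
#' foreground is `x > threshold`.
#'
#' @param x numeric vector or array of intensities.
#' @param levels number of histogram bins.
#' @return numeric threshold.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  x <- as.numeric(x)
  rng <- range(x, finite = TRUE)
  if (diff(rng) <= 0) stop("constant intensities: no threshold exists")
  br <- seq(rng[1L], rng[2L], length.out = levels + 1L)
  h <- tabulate(pmin(findInterval(x, br, rightmost.closed = TRUE), levels),
                nbins = levels)
  w <- h / sum(h)
  mids <- (br[-1L] + br[-(levels + 1L)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[levels]
  bcv <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  bcv[!is.finite(bcv)] <- 0
  br[which.max(bcv) + 1L] - diff(br)[1L] / 2
}

#' Threshold a channel volume into a filled binary mask
#'
#' Global threshold (whole-volume Otsu by default), per-slice 2D hole
#' filling, and optionally retention of the largest 3D 6-connected
#' component (the standard choice for nucleus masks, where debris and
#' second objects must be dropped).
#'
#' @param volume 3D numeric array `[y, x, z]`.
#' @param method `"otsu"`, `"fixed"`, `"percentile"`, or `"halfmax"`
#'   (threshold halfway between the minimum and maximum intensity -- the
#'   full-width-at-half-maximum convention, robust for point-like signals
#'   whose foreground is far too small a fraction of the volume for Otsu).
#' @param value the threshold (`"fixed"`) or percentile in (0, 100)
#'   (`"percentile"`); ignored otherwise.
#' @param keep_largest keep only the largest connected component.
#' @param fill_holes fill 2D holes slice by slice.
#' @param despeckle apply [hybrid_median_despeckle()] to every slice first.
#' @return logical 3D array.
#' @export
segment_mask <- function(volume,
                         method = c("otsu", "fixed", "percentile", "halfmax"),
                         value = NULL, keep_largest = FALSE,
                         fill_holes = TRUE, despeckle = FALSE) {
  method <- match.arg(method)
  stopifnot(length(dim(volume)) == 3L)
  if (all(volume == 0)) stop("no foreground: volume is all zero")
  if (despeckle) {
    for (z in seq_len(dim(volume)[3L])) {
      volume[, , z] <- hybrid_median_despeckle(volume[, , z])
    }
  }
  thr <- switch(method,
    otsu = otsu_threshold(volume),
    fixed = {
      if (is.null(value)) stop("method 'fixed' needs a threshold value")
      value
    },
    percentile = {
      if (is.null(value) || value <= 0 || value >= 100) {
        stop("method 'percentile' needs a value in (0, 100)")
      }
      as.numeric(quantile(volume, value / 100))
    },
    halfmax = {
      rng <- range(volume, finite = TRUE)
      rng[1L] + diff(rng) / 2
    })
  mask <- volume > thr
  if (!any(mask)) stop("no foreground: threshold above every voxel")
  if (fill_holes) {
    filled <- EBImage::fillHull(mask * 1L)
    mask <- filled > 0
  }
  if (keep_largest) {
    lab <- cpp_label3d(mask, dim(mask))
    keep <- which.max(tabulate(lab[lab > 0L]))
    mask <- lab == keep
  }
  mask
}

#' Per-slice Euclidean distance map
#'
#' Every foreground pixel is assigned its Euclidean distance (in um,
#' honoring an anisotropic pixel spacing) to the nearest background pixel;
#' background pixels are 0. A slice with no background at all returns `Inf`
#' on the foreground.
#'
#' @param mask_slice logical matrix (foreground TRUE).
#' @param spacing numeric `c(row_step, col_step)` in um.
#' @return numeric matrix of distances.
#' @export
edm_slice <- function(mask_slice, spacing = c(1, 1)) {
  stopifnot(is.matrix(mask_slice), length(spacing) == 2L, all(spacing > 0))
  m <- mask_slice
  storage.mode(m) <- "logical"
  if (!any(m)) return(matrix(0, nrow(m), ncol(m)))
  d <- cpp_edt2d(!m, spacing[1L], spacing[2L])
  d[!m] <- 0
  d
}
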