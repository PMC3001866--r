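# Synthetic 3D nucleus stacks with analytic ground truth: an ellipsoidal
# DAPI-filled nucleus, a thin lamin shell straddling the nuclear surface,
# spherical chromosome territories, and point-like FISH signals; all blurred
# with an isotropic Gaussian PSF and degraded with Poisson-Gaussian noise.
#
# Geometry uses a coordinate frame in um with the nucleus center at the grid
# center; voxel (iy, ix, iz) has center ((ix-.5) dx, (iy-.5) dy, (iz-.5) dz),
# matching the measurement side.

#' Nucleus ground truth for the 3D simulator
#'
#' Validates a planted geometry and records its analytic measurement values:
#' per-territory minimum edge distance (distance from the territory sphere
#' surface to the nuclear surface), the inter-signal pair distance when two
#' signals are given, and territory/nucleus volume ratios. A territory may
#' protrude past the nuclear surface by at most `edge_slack` (how tangency
#' is representable on a voxel grid); its true edge distance is then 0.
#'
#' @param semi_axes_um nucleus ellipsoid semi-axes `(a, b, c)` in um (a
#'   single value gives a sphere).
#' @param territory_specs list of `list(offset_um = c(x, y, z), radius_um)`.
#' @param signal_specs list of `list(pos_um = c(x, y, z), channel)`,
#'   positions relative to the nucleus center.
#' @param lamina_shell_um lamin shell thickness in um.
#' @param psf_sigma_um isotropic Gaussian PSF sigma (0 = no blur).
#' @param snr peak signal-to-noise ratio (`Inf` = noiseless).
#' @param edge_slack_um maximal allowed territory protrusion past the
#'   nuclear surface; defaults to one voxel diagonal of the default grid.
#' @param seed integer seed used when the stack is rendered.
#' @return object of class `nucleus_truth`.
#' @export
nucleus_truth <- function(semi_axes_um, territory_specs = list(),
                          signal_specs = list(), lamina_shell_um = 0.2,
                          psf_sigma_um = 0.08, snr = 20,
                          edge_slack_um = sqrt(sum(c(0.08, 0.08, 0.12)^2)),
                          seed = 1L) {
  ax <- rep_len(as.numeric(semi_axes_um), 3L)
  stopifnot(all(ax > 0), lamina_shell_um > 0, psf_sigma_um >= 0, snr > 0,
            edge_slack_um >= 0)

  # signed distance from a point to the ellipsoid surface (negative inside);
  # exact for spheres, dense direction search otherwise
  surface_distance <- function(p) {
    if (max(ax) - min(ax) < 1e-12) return(ax[1L] - sqrt(sum(p^2)))
    th <- seq(0, pi, length.out = 181L)
    ph <- seq(0, 2 * pi, length.out = 361L)[-361L]
    grid <- expand.grid(th = th, ph = ph)
    sx <- ax[1L] * sin(grid$th) * cos(grid$ph)
    sy <- ax[2L] * sin(grid$th) * sin(grid$ph)
    sz <- ax[3L] * cos(grid$th)
    d <- sqrt((sx - p[1L])^2 + (sy - p[2L])^2 + (sz - p[3L])^2)
    inside <- sum((p / ax)^2) <= 1
    if (inside) min(d) else -min(d)
  }

  terr <- lapply(territory_specs, function(ts) {
    off <- as.numeric(ts$offset_um)
    r <- as.numeric(ts$radius_um)
    stopifnot(length(off) == 3L, r > 0)
    gap <- surface_distance(off) - r  # center-to-surface clearance minus radius
    if (gap < -edge_slack_um) {
      stop("territory extends ", format(-gap), " um beyond the nucleus ",
           "(allowed slack ", format(edge_slack_um), " um)")
    }
    list(offset_um = off, radius_um = r,
         true_min_edge_um = max(0, gap))
  })

  sigs <- lapply(signal_specs, function(ss) {
    pos <- as.numeric(ss$pos_um)
    stopifnot(length(pos) == 3L)
    if (sum((pos / ax)^2) > 1) {
      stop("signal position outside the nucleus ellipsoid")
    }
    list(pos_um = pos,
         channel = if (is.null(ss$channel)) "probe1" else ss$channel)
  })
  pair <- if (length(sigs) == 2L) {
    interlocus_distance(sigs[[1L]]$pos_um, sigs[[2L]]$pos_um)
  } else NA_real_

  nuc_vol <- 4 / 3 * pi * prod(ax)
  ratios <- vapply(terr, function(t) 4 / 3 * pi * t$radius_um^3 / nuc_vol,
                   numeric(1L))

  structure(list(semi_axes_um = ax, territories = terr, signals = sigs,
                 true_pair_distance_um = pair,
                 true_volume_ratios = ratios,
                 lamina_shell_um = lamina_shell_um,
                 psf_sigma_um = psf_sigma_um, snr = snr,
                 edge_slack_um = edge_slack_um, seed = as.integer(seed)),
            class = "nucleus_truth")
}

# separable Gaussian blur along one array axis (sigma in voxels)
blur_axis <- function(a, axis, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  d <- dim(a)
  ord <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(a, ord), nrow = d[axis])
  nr <- nrow(m)
  mp <- m[c(rep(1L, r), seq_len(nr), rep(nr, r)), , drop = FALSE]
  f <- stats::filter(mp, k, sides = 2L)
  out <- array(f[(r + 1L):(r + nr), , drop = FALSE], d[ord])
  aperm(out, order(ord))
}

blur_gauss3d <- function(a, sigma_vox) {
  for (axis in 1:3) a <- blur_axis(a, axis, sigma_vox[axis])
  a
}

#' Render a nucleus truth into a multi-channel voxel stack
#'
#' Channels: `dapi` (filled ellipsoid), `lamin` (thin shell straddling the
#' ellipsoid surface), one `terr<i>` channel per territory (solid sphere),
#' and one channel per FISH signal channel name (small solid spots). Each
#' channel is blurred with the PSF and, at finite `snr`, degraded with
#' Poisson shot noise (peak SNR `snr`) plus a small Gaussian read noise.
#'
#' @param truth a [nucleus_truth()].
#' @param voxel_xy,voxel_z voxel size in um (defaults 0.08 and the study's
#'   0.12 um z-step).
#' @param margin_um padding between nucleus and stack border.
#' @return list with `grid` (a [voxel_grid()]) and `truth` (the input with
#'   rendering metadata attached).
#' @export
make_nucleus_stack <- function(truth, voxel_xy = 0.08, voxel_z = 0.12,
                               margin_um = 0.4) {
  stopifnot(inherits(truth, "nucleus_truth"), voxel_xy > 0, voxel_z > 0)
  ax <- truth$semi_axes_um
  vs <- c(voxel_xy, voxel_xy, voxel_z)
  ext <- 2 * (ax + margin_um + max(0, truth$edge_slack_um))
  nx <- ceiling(ext[1L] / voxel_xy)
  ny <- ceiling(ext[2L] / voxel_xy)
  nz <- ceiling(ext[3L] / voxel_z)
  cen <- c(nx * voxel_xy, ny * voxel_xy, nz * voxel_z) / 2

  xs <- (seq_len(nx) - 0.5) * voxel_xy - cen[1L]
  ys <- (seq_len(ny) - 0.5) * voxel_xy - cen[2L]
  zs <- (seq_len(nz) - 0.5) * voxel_z - cen[3L]
  # squared normalized radius field of the nucleus, [y, x, z]
  q <- outer(outer((ys / ax[2L])^2, (xs / ax[1L])^2, `+`), (zs / ax[3L])^2, `+`)
  rho <- sqrt(q)

  sphere_mask <- function(center, radius) {
    d2 <- outer(outer((ys - center[2L])^2, (xs - center[1L])^2, `+`),
                (zs - center[3L])^2, `+`)
    d2 <= radius^2
  }

  half_shell <- truth$lamina_shell_um / 2
  r_eff <- mean(ax)  # shell thickness expressed in normalized radius units
  channels <- list(
    dapi = (q <= 1) * 1,
    lamin = (rho >= 1 - half_shell / r_eff & rho <= 1 + half_shell / r_eff) * 1)
  for (i in seq_along(truth$territories)) {
    t <- truth$territories[[i]]
    channels[[paste0("terr", i)]] <- sphere_mask(t$offset_um, t$radius_um) * 1
  }
  spot_r <- 0.15
  for (s in truth$signals) {
    ch <- s$channel
    m <- sphere_mask(s$pos_um, spot_r) * 1
    channels[[ch]] <- if (is.null(channels[[ch]])) m else pmax(channels[[ch]], m)
  }

  sigma_vox <- truth$psf_sigma_um / vs
  channels <- with_seed(truth$seed + 7L, {
    lapply(channels, function(v) {
      if (truth$psf_sigma_um > 0) v <- blur_gauss3d(v, sigma_vox)
      if (is.finite(truth$snr)) {
        photons <- truth$snr^2
        v <- rpois(length(v), lambda = pmax(v, 0) * photons) / photons +
          rnorm(length(v), sd = 0.5 / truth$snr)
        v <- array(pmax(v, 0), c(ny, nx, nz))
      }
      v
    })
  })

  truth$voxel_size <- setNames(vs, c("dx", "dy", "dz"))
  truth$grid_center_um <- setNames(cen, c("x", "y", "z"))
  list(grid = voxel_grid(channels, voxel_size = vs), truth = truth)
}

#' Write a voxel grid as per-channel multi-page TIFFs with a sidecar
#'
#' Each channel becomes `<basename>_<channel>.tif` (32-bit float, one page
#' per z-slice, intensities clipped to [0, 1]); voxel sizes and channel
#' names go to `<basename>_meta.tsv`.
#'
#' @param grid a [voxel_grid()].
#' @param dir output directory (created if needed).
#' @param basename file name stem.
#' @return the sidecar path, invisibly.
#' @export
write_voxel_grid <- function(grid, dir, basename = "nucleus") {
  stopifnot(inherits(grid, "voxel_grid"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ch in names(grid$channels)) {
    v <- grid$channels[[ch]]
    pages <- lapply(seq_len(dim(v)[3L]), function(z) {
      pmin(pmax(v[, , z], 0), 1)
    })
    tiff::writeTIFF(pages, file.path(dir, paste0(basename, "_", ch, ".tif")),
                    bits.per.sample = 32L)
  }
  meta <- data.frame(key = c("dx_um", "dy_um", "dz_um", "channels"),
                     value = c(grid$voxel_size,
                               paste(names(grid$channels), collapse = ",")))
  path <- file.path(dir, paste0(basename, "_meta.tsv"))
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a voxel grid written by [write_voxel_grid()]
#'
#' @param dir directory holding the TIFFs and sidecar.
#' @param basename file name stem.
#' @return a [voxel_grid()].
#' @export
read_voxel_grid <- function(dir, basename = "nucleus") {
  meta <- read.delim(file.path(dir, paste0(basename, "_meta.tsv")),
                     stringsAsFactors = FALSE)
  vals <- setNames(meta$value, meta$key)
  chans <- strsplit(vals[["channels"]], ",", fixed = TRUE)[[1L]]
  vs <- as.numeric(vals[c("dx_um", "dy_um", "dz_um")])
  channels <- lapply(chans, function(ch) {
    pages <- tiff::readTIFF(file.path(dir, paste0(basename, "_", ch, ".tif")),
                            all = TRUE)
    array(unlist(pages), c(dim(pages[[1L]]), length(pages)))
  })
  voxel_grid(setNames(channels, chans), voxel_size = vs)
}
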