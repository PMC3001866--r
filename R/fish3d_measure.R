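# Territory-to-edge distances, inter-locus distances, lamina contact
# scoring, volumes, Ki-67 classification, and a per-nucleus measurement
# driver.

#' Minimum territory-to-nuclear-edge distance
#'
#' The study's two-plane procedure: for every x-y slice, the Euclidean
#' distance map of the nucleus mask (spacing dx, dy) is evaluated under the
#' territory mask and the minimum recorded; the stack is then resliced into
#' x-z planes (spacing dx, dz) and the pass repeated; the result is the
#' minimum over both passes. Territory voxels falling outside the nucleus
#' mask contribute 0 (the territory reaches or crosses the nuclear edge).
#' `mode = "3d"` instead evaluates the full anisotropic 3D distance
#' transform -- a cross-check on the two-plane approximation, not the
#' study's procedure; the two-plane result can only exceed it.
#'
#' @param territory,nucleus logical 3D arrays `[y, x, z]`, same dims.
#' @param voxel_size numeric `c(dx, dy, dz)` in um.
#' @param mode `"two-plane"` (default) or `"3d"`.
#' @return minimum distance in um.
#' @export
territory_min_edge_distance <- function(territory, nucleus,
                                        voxel_size = c(0.08, 0.08, 0.12),
                                        mode = c("two-plane", "3d")) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(territory), dim(nucleus)),
            length(voxel_size) == 3L, all(voxel_size > 0))
  if (!any(territory)) stop("empty territory mask")
  dx <- voxel_size[1L]; dy <- voxel_size[2L]; dz <- voxel_size[3L]
  if (any(territory & !nucleus)) return(0)

  if (mode == "3d") {
    d <- cpp_edt3d(!nucleus, dim(nucleus), c(dy, dx, dz))
    return(min(d[territory]))
  }

  best <- Inf
  # pass 1: x-y slices, rows = y (dy), cols = x (dx)
  for (z in seq_len(dim(territory)[3L])) {
    tz <- territory[, , z]
    if (!any(tz)) next
    e <- edm_slice(nucleus[, , z], spacing = c(dy, dx))
    best <- min(best, min(e[tz]))
  }
  # pass 2: x-z slices, rows = x (dx), cols = z (dz)
  for (y in seq_len(dim(territory)[1L])) {
    ty <- territory[y, , ]
    if (!any(ty)) next
    e <- edm_slice(nucleus[y, , ], spacing = c(dx, dz))
    best <- min(best, min(e[ty]))
  }
  best
}

#' Euclidean distance between two FISH signal positions
#'
#' `sqrt(dx^2 + dy^2 + dz^2)` on coordinates already expressed in um.
#'
#' @param p1,p2 numeric length-3 vectors `(x, y, z)` in um.
#' @return distance in um.
#' @export
interlocus_distance <- function(p1, p2) {
  stopifnot(length(p1) == 3L, length(p2) == 3L,
            all(is.finite(p1)), all(is.finite(p2)))
  sqrt(sum((p1 - p2)^2))
}

#' Binary lamina contact score
#'
#' 1 if any signal voxel coincides with, or is 26-adjacent to, a lamin
#' voxel; else 0. 26-adjacency is the most permissive standard voxel
#' connectivity, matching the "physical continuity" reading of contact.
#'
#' @param signal_mask,lamin_mask logical 3D arrays, same dims.
#' @return integer 0 or 1.
#' @export
lamina_contact <- function(signal_mask, lamin_mask) {
  stopifnot(identical(dim(signal_mask), dim(lamin_mask)))
  if (!any(signal_mask)) stop("empty signal mask")
  if (any(signal_mask & lamin_mask)) return(1L)
  d <- dim(signal_mask)
  for (sz in -1:1) for (sy in -1:1) for (sx in -1:1) {
    if (sz == 0 && sy == 0 && sx == 0) next
    yi <- seq_len(d[1L]); xi <- seq_len(d[2L]); zi <- seq_len(d[3L])
    ys <- yi + sy; xs <- xi + sx; zs <- zi + sz
    ok_y <- ys >= 1L & ys <= d[1L]
    ok_x <- xs >= 1L & xs <= d[2L]
    ok_z <- zs >= 1L & zs <= d[3L]
    if (any(signal_mask[yi[ok_y], xi[ok_x], zi[ok_z]] &
            lamin_mask[ys[ok_y], xs[ok_x], zs[ok_z]])) {
      return(1L)
    }
  }
  0L
}

#' Territory and nuclear volumes
#'
#' Voxel counting times the voxel volume; the territory volume is also
#' normalized to the nuclear volume (the dimensionless form the study
#' reports).
#'
#' @param territory,nucleus logical 3D arrays, same dims; nucleus nonempty.
#' @param voxel_size numeric `c(dx, dy, dz)` in um.
#' @return list with `volume_um3`, `nuclear_volume_um3`, `volume_ratio`.
#' @export
territory_volume <- function(territory, nucleus,
                             voxel_size = c(0.08, 0.08, 0.12)) {
  stopifnot(identical(dim(territory), dim(nucleus)), all(voxel_size > 0))
  if (!any(nucleus)) stop("empty nucleus mask")
  vv <- prod(voxel_size)
  vt <- sum(territory) * vv
  vn <- sum(nucleus) * vv
  list(volume_um3 = vt, nuclear_volume_um3 = vn, volume_ratio = vt / vn)
}

#' Intensity-weighted centroid of a segmented signal
#'
#' Deterministic analogue of a 3D ROI-manager position readout: the
#' intensity-weighted mean voxel-center position over the mask, in um.
#'
#' @param volume 3D numeric array `[y, x, z]`.
#' @param mask logical array of the segmented signal (default: positive
#'   voxels).
#' @param voxel_size numeric `c(dx, dy, dz)` in um.
#' @return numeric `(x, y, z)` in um.
#' @export
signal_centroid <- function(volume, mask = NULL,
                            voxel_size = c(0.08, 0.08, 0.12)) {
  stopifnot(length(dim(volume)) == 3L)
  if (is.null(mask)) mask <- volume > 0
  stopifnot(identical(dim(volume), dim(mask)))
  if (!any(mask)) stop("empty signal mask")
  idx <- which(mask, arr.ind = TRUE)
  wts <- volume[mask]
  if (sum(wts) <= 0) wts <- rep(1, length(wts))
  c(x = sum((idx[, 2L] - 0.5) * voxel_size[1L] * wts) / sum(wts),
    y = sum((idx[, 1L] - 0.5) * voxel_size[2L] * wts) / sum(wts),
    z = sum((idx[, 3L] - 0.5) * voxel_size[3L] * wts) / sum(wts))
}

#' Ki-67 proliferation index and culture classification
#'
#' Fraction of Ki-67 positive nuclei; cultures below 0.02 are classed
#' senescent and above 0.4 young/proliferative, with the boundary values
#' themselves (exactly 0.02 or 0.4) falling in the intermediate class.
#'
#' @param n_positive,n_total non-negative counts, `n_positive <= n_total`,
#'   `n_total > 0`.
#' @return list with `fraction` and `class`.
#' @export
ki67_index <- function(n_positive, n_total) {
  stopifnot(n_total > 0, n_positive >= 0, n_positive <= n_total)
  f <- n_positive / n_total
  cls <- if (f < 0.02) "senescent" else if (f > 0.4) "young" else "intermediate"
  list(fraction = f, class = cls)
}

#' Measure one nucleus stack
#'
#' Full per-nucleus quantification: segments the DAPI channel into the
#' nucleus mask (largest component, holes filled), optionally the lamin
#' shell, then measures each territory channel (despeckled, segmented,
#' minimum edge distance, volumes, lamina contact) and each probe channel
#' (centroid and lamina contact), plus the inter-locus distance when
#' exactly two probe channels are given.
#'
#' @param grid a [voxel_grid()].
#' @param dapi,lamin channel names (lamin optional).
#' @param territories,probes character vectors of channel names.
#' @param threshold segmentation method for the DAPI, lamin and territory
#'   channels, passed to [segment_mask()].
#' @param probe_threshold segmentation method for probe (spot) channels;
#'   defaults to `"halfmax"`, since point-like signals occupy far too small
#'   a voxel fraction for a histogram-based threshold.
#' @param threshold_value value for `"fixed"`/`"percentile"` methods.
#' @param mode distance mode for [territory_min_edge_distance()].
#' @param despeckle despeckle territory slices before segmentation.
#' @return list with `nuclear_volume_um3`, data.frames `territories` and
#'   `probes`, and `pair_distance_um` (NA unless two probes).
#' @export
measure_fish <- function(grid, dapi = "dapi", lamin = NULL,
                         territories = character(), probes = character(),
                         threshold = "otsu", probe_threshold = "halfmax",
                         threshold_value = NULL,
                         mode = "two-plane", despeckle = TRUE) {
  stopifnot(inherits(grid, "voxel_grid"))
  chans <- names(grid$channels)
  need <- c(dapi, lamin, territories, probes)
  miss <- setdiff(need, chans)
  if (length(miss)) stop("channel(s) not in grid: ", paste(miss, collapse = ", "))
  vs <- unname(grid$voxel_size)

  nuc <- segment_mask(grid$channels[[dapi]], method = threshold,
                      value = threshold_value, keep_largest = TRUE)
  lam <- if (!is.null(lamin)) {
    segment_mask(grid$channels[[lamin]], method = threshold,
                 value = threshold_value, fill_holes = FALSE)
  }
  vv <- prod(vs)

  terr_rows <- lapply(territories, function(ch) {
    m <- segment_mask(grid$channels[[ch]], method = threshold,
                      value = threshold_value, keep_largest = TRUE,
                      despeckle = despeckle)
    vol <- territory_volume(m, nuc, vs)
    data.frame(channel = ch,
               min_edge_um = territory_min_edge_distance(m, nuc, vs, mode),
               volume_um3 = vol$volume_um3,
               volume_ratio = vol$volume_ratio,
               contact = if (is.null(lam)) NA_integer_ else lamina_contact(m, lam),
               stringsAsFactors = FALSE)
  })
  probe_rows <- lapply(probes, function(ch) {
    m <- segment_mask(grid$channels[[ch]], method = probe_threshold,
                      value = threshold_value, keep_largest = TRUE,
                      fill_holes = FALSE)
    cen <- signal_centroid(grid$channels[[ch]], m, vs)
    data.frame(channel = ch, x = cen[["x"]], y = cen[["y"]], z = cen[["z"]],
               contact = if (is.null(lam)) NA_integer_ else lamina_contact(m, lam),
               stringsAsFactors = FALSE)
  })
  probes_df <- if (length(probe_rows)) do.call(rbind, probe_rows) else NULL
  pair <- NA_real_
  if (!is.null(probes_df) && nrow(probes_df) == 2L) {
    pair <- interlocus_distance(unlist(probes_df[1L, c("x", "y", "z")]),
                                unlist(probes_df[2L, c("x", "y", "z")]))
  }
  list(nuclear_volume_um3 = sum(nuc) * vv,
       territories = if (length(terr_rows)) do.call(rbind, terr_rows) else NULL,
       probes = probes_df,
       pair_distance_um = pair)
}
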