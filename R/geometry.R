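# Per-slab lumen geometry: rasterized cross-section, area, channel widths,
# integrated lumen volume and lipid capacity.
#
# The lumen of a slice is the 2-D region bounded by the wall atoms' projected
# disks and a "mouth closure" that closes the open side of the groove:
# by default the convex hull of the projected atom centres (closing the mouth
# with a chord), alternatively a morphological closing of the wall mask for
# strongly non-convex walls.

# Signed distance (positive inside) from each cell centre (cx, cy) to the
# boundary of the convex hull of pts (n x 2). Exact for interior points of a
# convex polygon: min over edges of the inward half-plane distance.
.hull_signed_dist <- function(cx, cy, pts) {
  # coincident projections (e.g. stacked lattice rings) give degenerate hull
  # edges whose direction is numerical noise; deduplicate first
  pts <- unique(round(pts, 9))
  h <- grDevices::chull(pts)
  if (length(h) < 3L) return(rep(-Inf, length(cx)))
  hx <- pts[h, 1]; hy <- pts[h, 2]
  keep <- sqrt((hx - c(hx[-1], hx[1]))^2 + (hy - c(hy[-1], hy[1]))^2) > 1e-9
  if (sum(keep) < 3L) return(rep(-Inf, length(cx)))
  hx <- hx[keep]; hy <- hy[keep]
  # shoelace orientation of the hull polygon
  orient <- sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)
  sgn <- if (orient >= 0) 1 else -1
  dmin <- rep(Inf, length(cx))
  nh <- length(hx)
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    len <- sqrt(ex^2 + ey^2)
    cross <- ex * (cy - hy[i]) - ey * (cx - hx[i])
    dmin <- pmin(dmin, sgn * cross / len)
  }
  dmin
}

.empty_section <- function(slab, grid_resolution, mouth_closure) {
  structure(list(slab_index = slab$index, s_lo = slab$s_lo, s_hi = slab$s_hi,
                 s_mid = (slab$s_lo + slab$s_hi) / 2,
                 n_atoms = length(slab$atom_idx),
                 area = 0, width_inscribed = 0, width_maxchord = 0,
                 centroid = c(NA_real_, NA_real_), is_empty = TRUE,
                 grid_resolution = grid_resolution,
                 mouth_closure = mouth_closure),
            class = "lumen_cross_section")
}

#' Lumen cross-section of one slab
#'
#' Rasterizes the slab plane at the given resolution over the projected
#' atoms' bounding box (padded by 5 Angstrom), marks wall cells (cells inside
#' any atom's projected disk of radius vdW + `probe_inflate`), closes the
#' groove mouth, and measures the lumen:
#' * `area` = lumen cell count x resolution^2 (Angstrom^2);
#' * `width_inscribed` = largest empty-circle diameter inside the lumen
#'   (from a Euclidean distance transform, half-cell bias corrected);
#' * `width_maxchord` = maximum pairwise distance between lumen boundary
#'   cells (rim-to-rim width).
#'
#' Slabs with fewer than 3 atoms (or a degenerate projection) give an empty
#' section with zero area and widths, not an error.
#'
#' @param slab One element of `partition_slabs()$slabs`.
#' @param vdw_radius Per-member atom radii (Angstrom), recycled if length 1.
#' @param grid_resolution Grid cell edge, Angstrom (default 0.5; fixtures
#'   converge at 0.25).
#' @param mouth_closure `"convex"` (hull-of-centres chord closure, default)
#'   or `"morphological"` (closing of the wall mask with a disc of radius
#'   `alpha`, then hole filling).
#' @param probe_inflate Added to every disk radius (Angstrom), for
#'   solvent-excluded-style walls. Default 0 (bare vdW).
#' @param alpha Disc radius for the morphological closure, Angstrom.
#' @return A `lumen_cross_section` (see fields above, plus `centroid` and
#'   `is_empty`).
#' @export
#' @examples
#' g <- make_groove(groove_spec(length = 20, inner_radius = 10,
#'                              lattice_spacing = 1, atom_radius = 0))
#' ax <- fit_channel_axis(g$model)
#' sl <- partition_slabs(g$model, ax)$slabs[[2]]
#' lumen_cross_section(sl, 0, grid_resolution = 0.5)$area  # ~ pi * 100 / 2
lumen_cross_section <- function(slab, vdw_radius,
                                grid_resolution = 0.5,
                                mouth_closure = c("convex", "morphological"),
                                probe_inflate = 0, alpha = 8) {
  mouth_closure <- match.arg(mouth_closure)
  if (!is.numeric(grid_resolution) || grid_resolution <= 0) {
    stop("grid_resolution must be > 0", call. = FALSE)
  }
  n <- length(slab$atom_idx)
  if (n < 3L) return(.empty_section(slab, grid_resolution, mouth_closure))
  pts <- slab$proj
  if (nrow(unique(round(pts, 6))) < 3L) {
    return(.empty_section(slab, grid_resolution, mouth_closure))
  }
  r_eff <- rep_len(vdw_radius, n) + probe_inflate

  # the morphological closing dilates the wall by alpha, which must not be
  # clipped by the grid boundary
  pad <- if (mouth_closure == "morphological") {
    max(5, alpha + max(r_eff, 0) + 2)
  } else 5
  res <- grid_resolution
  xs <- seq(min(pts[, 1]) - pad, max(pts[, 1]) + pad, by = res)
  ys <- seq(min(pts[, 2]) - pad, max(pts[, 2]) + pad, by = res)
  nx <- length(xs); ny <- length(ys)

  # dwall = signed penetration of each cell centre into the nearest wall
  # disk (positive inside a disk); -Inf far from any wall
  dwall <- matrix(-Inf, nx, ny)
  for (i in seq_len(n)) {
    ri <- r_eff[i]
    if (ri <= 0) next
    win <- ri + res  # cover the anti-aliasing band around the disk rim
    ix <- which(abs(xs - pts[i, 1]) <= win)
    iy <- which(abs(ys - pts[i, 2]) <= win)
    if (!length(ix) || !length(iy)) next
    dx2 <- (xs[ix] - pts[i, 1])^2
    dy2 <- (ys[iy] - pts[i, 2])^2
    dwall[ix, iy] <- pmax(dwall[ix, iy], ri - sqrt(outer(dx2, dy2, `+`)))
  }
  wall <- dwall >= 0

  if (mouth_closure == "convex") {
    cx <- rep(xs, times = ny)
    cy <- rep(ys, each = nx)
    dhull <- matrix(.hull_signed_dist(cx, cy, pts), nx, ny)
    inside <- dhull >= 0
    # anti-aliased area: fractional cell coverage from the signed distances,
    # so the estimate does not depend on how the grid aligns with the walls
    cov_in <- pmin(1, pmax(0, 0.5 + dhull / res))
    cov_wall <- pmin(1, pmax(0, 0.5 + dwall / res))
    area <- sum(cov_in * (1 - cov_wall)) * res^2
  } else {
    if (!any(wall)) return(.empty_section(slab, grid_resolution, mouth_closure))
    brush_d <- 2L * as.integer(ceiling(alpha / res)) + 1L
    closed <- EBImage::closing(wall * 1, EBImage::makeBrush(brush_d, "disc"))
    inside <- EBImage::fillHull(closed) > 0
    area <- sum(inside & !wall) * res^2
  }

  lumen <- inside & !wall
  if (!any(lumen)) return(.empty_section(slab, grid_resolution, mouth_closure))

  # distance from each lumen cell centre to the nearest non-lumen cell
  # centre; the boundary cell-centre offset (~ +res/2) and the quantization
  # of the optimal centre (~ -res/2) cancel, so the raw maximum is used
  dmap <- EBImage::distmap(lumen * 1)
  width_inscribed <- 2 * max(dmap) * res

  # boundary cells: lumen cells 4-adjacent to a non-lumen cell (or the edge)
  pad_l <- matrix(FALSE, nx + 2L, ny + 2L)
  pad_l[2:(nx + 1L), 2:(ny + 1L)] <- lumen
  core <- pad_l[2:(nx + 1L), 2:(ny + 1L)]
  nb <- pad_l[1:nx, 2:(ny + 1L)] & pad_l[3:(nx + 2L), 2:(ny + 1L)] &
        pad_l[2:(nx + 1L), 1:ny] & pad_l[2:(nx + 1L), 3:(ny + 2L)]
  boundary <- core & !nb
  bi <- which(boundary, arr.ind = TRUE)
  bpts <- cbind(xs[bi[, 1]], ys[bi[, 2]])
  width_maxchord <- if (nrow(bpts) >= 2L) {
    h <- grDevices::chull(bpts)
    hp <- bpts[h, , drop = FALSE]
    sqrt(max(as.numeric(stats::dist(hp))^2))
  } else 0

  # the inscribed diameter cannot exceed the region diameter; the distance
  # transform overstates it by up to a cell on degenerate (few-cell) lumens
  width_inscribed <- min(width_inscribed, max(width_maxchord, res))

  li <- which(lumen, arr.ind = TRUE)
  centroid <- c(mean(xs[li[, 1]]), mean(ys[li[, 2]]))

  structure(list(slab_index = slab$index, s_lo = slab$s_lo, s_hi = slab$s_hi,
                 s_mid = (slab$s_lo + slab$s_hi) / 2, n_atoms = n,
                 area = area, width_inscribed = width_inscribed,
                 width_maxchord = width_maxchord, centroid = centroid,
                 is_empty = FALSE, grid_resolution = res,
                 mouth_closure = mouth_closure),
            class = "lumen_cross_section")
}

#' Groove profile along the channel axis
#'
#' Computes the per-slab lumen cross-sections in axial order, the integrated
#' lumen volume (sum of area x slab thickness), the lipid-capacity estimate,
#' and trimmed summary widths. Summary min/max widths exclude slabs whose
#' atom count is below `trim_fraction` of the median slab (the tapering end
#' caps would otherwise dominate the minimum).
#'
#' @param model A `structure_model`.
#' @param sel Optional selection (object or string).
#' @param axis Optional `axis_frame`; fitted from the selection when NULL.
#' @param thickness Slab thickness, Angstrom (default 5).
#' @param grid_resolution,mouth_closure,probe_inflate,alpha Passed to
#'   [lumen_cross_section()].
#' @param per_lipid_volume Molecular volume per lipid for the capacity
#'   estimate, Angstrom^3 (default 1300, a typical glycerophospholipid).
#' @param trim_fraction End-slab trimming threshold for the summary widths
#'   (fraction of the median per-slab atom count, default 0.25).
#' @return An object of class `groove_profile`: list with `table` (one row
#'   per slab: slab_index, s_lo, s_hi, s_mid, n_atoms, area_A2,
#'   width_inscribed_A, width_maxchord_A), `sections`, `axis`,
#'   `lumen_volume` (Angstrom^3), `capacity` (list: capacity, n_lipids),
#'   `summary` (trimmed min/max of both width metrics and of area),
#'   `params`.
#' @export
#' @examples
#' g <- make_groove(groove_spec(length = 40, inner_radius = 10,
#'                              lattice_spacing = 1.5, atom_radius = 0.5))
#' p <- groove_profile(g$model)
#' p$summary$width_inscribed_max
groove_profile <- function(model, sel = NULL, axis = NULL, thickness = 5,
                           grid_resolution = 0.5,
                           mouth_closure = "convex",
                           probe_inflate = 0, alpha = 8,
                           per_lipid_volume = 1300, trim_fraction = 0.25) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.null(sel)) model <- apply_selection(model, sel)
  if (is.null(axis)) axis <- fit_channel_axis(model)
  slabs <- partition_slabs(model, axis, thickness)

  sections <- lapply(slabs$slabs, function(sl) {
    lumen_cross_section(sl, model$atoms$vdw_radius[sl$atom_idx],
                        grid_resolution = grid_resolution,
                        mouth_closure = mouth_closure,
                        probe_inflate = probe_inflate, alpha = alpha)
  })

  tab <- do.call(rbind, lapply(sections, function(cs) {
    data.frame(slab_index = cs$slab_index, s_lo = cs$s_lo, s_hi = cs$s_hi,
               s_mid = cs$s_mid, n_atoms = cs$n_atoms, area_A2 = cs$area,
               width_inscribed_A = cs$width_inscribed,
               width_maxchord_A = cs$width_maxchord)
  }))
  tab <- tab[order(tab$s_mid), , drop = FALSE]
  rownames(tab) <- NULL

  lumen_volume <- sum(tab$area_A2 * (tab$s_hi - tab$s_lo))
  capacity <- estimate_lipid_capacity(lumen_volume, per_lipid_volume)

  nonempty <- tab$n_atoms >= 3 & tab$area_A2 > 0
  used <- nonempty
  if (any(nonempty)) {
    med <- stats::median(tab$n_atoms[nonempty])
    used <- nonempty & tab$n_atoms >= trim_fraction * med
  }
  summ <- if (any(used)) {
    list(width_inscribed_min = min(tab$width_inscribed_A[used]),
         width_inscribed_max = max(tab$width_inscribed_A[used]),
         width_maxchord_min = min(tab$width_maxchord_A[used]),
         width_maxchord_max = max(tab$width_maxchord_A[used]),
         area_min = min(tab$area_A2[used]),
         area_max = max(tab$area_A2[used]),
         slabs_used = tab$slab_index[used])
  } else {
    list(width_inscribed_min = 0, width_inscribed_max = 0,
         width_maxchord_min = 0, width_maxchord_max = 0,
         area_min = 0, area_max = 0, slabs_used = integer(0))
  }

  structure(list(table = tab, sections = sections, axis = axis,
                 slabs = slabs, lumen_volume = lumen_volume,
                 capacity = capacity, summary = summ,
                 params = list(thickness = thickness,
                               grid_resolution = grid_resolution,
                               mouth_closure = mouth_closure,
                               probe_inflate = probe_inflate, alpha = alpha,
                               per_lipid_volume = per_lipid_volume,
                               trim_fraction = trim_fraction)),
            class = "groove_profile")
}

#' @export
print.groove_profile <- function(x, ...) {
  cat(sprintf(paste0("groove_profile: %d slabs over %.1f A; ",
                     "width (inscribed) %.1f-%.1f A; ",
                     "lumen volume %.0f A^3 (~%d lipids)\n"),
              nrow(x$table), x$axis$extent,
              x$summary$width_inscribed_min, x$summary$width_inscribed_max,
              x$lumen_volume, x$capacity$n_lipids))
  invisible(x)
}

#' Lipid capacity of a lumen volume
#'
#' Capacity = lumen volume / per-lipid molecular volume, reported unrounded
#' and as the nearest integer. The divisor is an explicit parameter (default
#' 1300 Angstrom^3, a typical glycerophospholipid volume).
#'
#' @param x A `groove_profile` or a lumen volume in Angstrom^3.
#' @param per_lipid_volume Molecular volume per lipid, Angstrom^3 (> 0).
#' @return List with `capacity` (unrounded) and `n_lipids` (nearest integer).
#' @export
#' @examples
#' estimate_lipid_capacity(156000, 1300)  # ~120 lipids
estimate_lipid_capacity <- function(x, per_lipid_volume = 1300) {
  if (!is.numeric(per_lipid_volume) || per_lipid_volume <= 0) {
    stop("per_lipid_volume must be > 0", call. = FALSE)
  }
  vol <- if (inherits(x, "groove_profile")) x$lumen_volume else as.numeric(x)
  if (vol < 0) stop("lumen volume must be >= 0", call. = FALSE)
  cap <- vol / per_lipid_volume
  list(capacity = cap, n_lipids = as.integer(round(cap)))
}
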