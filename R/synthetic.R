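# Synthetic structures with analytic ground truth: open cylindrical grooves
# ("taco shell" wall lattices) and sphere systems for SASA validation.

#' Specify a synthetic groove
#'
#' Describes an elongated open-groove wall lattice: pseudo-atoms placed on a
#' cylindrical lattice spanning the closed part of the circumference, with an
#' angular opening (the groove "mouth"), optional extra wall layers, and
#' seeded Gaussian positional jitter. Defaults emulate a pseudo-C-alpha wall:
#' 3.8 Angstrom lattice step, 1.70 Angstrom atom radius.
#'
#' @param length Groove length along the axis, Angstrom.
#' @param inner_radius Inner wall radius: a constant (Angstrom) or a function
#'   of the axial coordinate `s` returning Angstrom.
#' @param opening_angle Angular width of the missing arc in degrees;
#'   0 = closed tube, 180 = half-pipe. The opening is centred on the +x side
#'   of the local frame.
#' @param wall_layers Number of concentric wall layers (>= 1). Layers share
#'   azimuths so outer atoms sit radially behind inner ones.
#' @param layer_spacing Radial distance between layers, Angstrom.
#' @param lattice_spacing Arc and axial step between pseudo-atoms, Angstrom.
#' @param axis_direction Unit 3-vector of the groove axis.
#' @param axis_origin 3-vector, Angstrom; the axial coordinate 0 point.
#' @param inner_residue 3-letter residue code for the innermost layer.
#' @param outer_residue 3-letter code for all outer layers.
#' @param atom_radius Pseudo-atom van der Waals radius, Angstrom (>= 0;
#'   0 gives point atoms for analytic area fixtures).
#' @param seed Integer seed for the jitter RNG.
#' @param jitter_sd Isotropic Gaussian jitter standard deviation, Angstrom.
#' @return An object of class `groove_spec`.
#' @export
#' @examples
#' groove_spec(length = 100, inner_radius = 10, opening_angle = 180)
groove_spec <- function(length = 100, inner_radius = 10, opening_angle = 180,
                        wall_layers = 1L, layer_spacing = 4.5,
                        lattice_spacing = 3.8,
                        axis_direction = c(0, 0, 1),
                        axis_origin = c(0, 0, 0),
                        inner_residue = "LEU", outer_residue = "ASP",
                        atom_radius = 1.70, seed = 1L, jitter_sd = 0) {
  if (length <= 0) stop("groove length must be > 0", call. = FALSE)
  if (lattice_spacing <= 0) stop("lattice_spacing must be > 0", call. = FALSE)
  if (opening_angle < 0 || opening_angle >= 360) {
    stop("opening_angle must be in [0, 360)", call. = FALSE)
  }
  if (wall_layers < 1) stop("wall_layers must be >= 1", call. = FALSE)
  if (atom_radius < 0 || jitter_sd < 0) {
    stop("atom_radius and jitter_sd must be >= 0", call. = FALSE)
  }
  rfun <- if (is.function(inner_radius)) inner_radius else {
    r0 <- inner_radius
    function(s) rep(r0, length(s))
  }
  probe_s <- seq(0, length, length.out = 101)
  rr <- rfun(probe_s)
  if (any(!is.finite(rr)) || any(rr <= atom_radius)) {
    stop("inner radius must exceed atom_radius everywhere along the groove",
         call. = FALSE)
  }
  d <- axis_direction / sqrt(sum(axis_direction^2))
  structure(list(length = length, radius_fun = rfun,
                 inner_radius = inner_radius,
                 opening_angle = opening_angle,
                 wall_layers = as.integer(wall_layers),
                 layer_spacing = layer_spacing,
                 lattice_spacing = lattice_spacing,
                 axis_direction = d, axis_origin = axis_origin,
                 inner_residue = inner_residue, outer_residue = outer_residue,
                 atom_radius = atom_radius, seed = as.integer(seed),
                 jitter_sd = jitter_sd),
            class = "groove_spec")
}

# Deterministic in-plane orthonormal basis for a unit axis direction: e1 is
# the global axis least aligned with d, orthogonalised; e2 = d x e1.
.plane_basis <- function(d) {
  k <- which.min(abs(d))
  a <- c(0, 0, 0); a[k] <- 1
  e1 <- a - sum(a * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

#' Generate a synthetic groove with ground truth
#'
#' Places wall pseudo-atoms (one single-atom residue each, atom name `CA`,
#' element C) on the cylindrical lattice described by the spec, applies
#' seeded Gaussian jitter, and returns both the model and the generator's
#' ground truth (per-atom lining labels, true axis, radius and analytic
#' convex-closure lumen area per axial position). Identical spec and seed
#' give bitwise-identical coordinates.
#'
#' @param spec A [groove_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{model}{the `structure_model`;}
#'     \item{truth}{list with `atoms` (data frame: serial, label
#'       interior/exterior, layer, s, azimuth_deg, radius), `axis_origin`,
#'       `axis_direction`, `radius_fun`, and `lumen_area_fun(s)` giving the
#'       analytic area enclosed by the convex mouth closure of the ideal
#'       (point-atom, jitter-free) wall;}
#'     \item{spec}{the spec.}
#'   }
#' @export
#' @examples
#' g <- make_groove(groove_spec(length = 30, inner_radius = 10))
#' nrow(g$model$atoms)
make_groove <- function(spec) {
  stopifnot(inherits(spec, "groove_spec"))
  s_vals <- seq(0, spec$length, by = spec$lattice_spacing)
  open_rad <- spec$opening_angle * pi / 180
  wall_arc <- 2 * pi - open_rad

  rows <- vector("list", length(s_vals) * spec$wall_layers)
  k <- 0L
  for (s in s_vals) {
    R0 <- spec$radius_fun(s)
    # azimuths fixed by the innermost layer so layers stack radially
    if (spec$opening_angle == 0) {
      n_arc <- max(3L, round(2 * pi * R0 / spec$lattice_spacing))
      phi <- open_rad / 2 + (seq_len(n_arc) - 1L) * (2 * pi / n_arc)
    } else {
      n_arc <- max(2L, floor(wall_arc * R0 / spec$lattice_spacing) + 1L)
      phi <- seq(open_rad / 2, 2 * pi - open_rad / 2, length.out = n_arc)
    }
    for (layer in seq_len(spec$wall_layers)) {
      R <- R0 + (layer - 1L) * spec$layer_spacing
      k <- k + 1L
      rows[[k]] <- data.frame(
        s = s, phi = phi, radius = R, layer = layer,
        label = if (layer == 1L) "interior" else "exterior",
        stringsAsFactors = FALSE
      )
    }
  }
  grid <- do.call(rbind, rows[seq_len(k)])
  n <- nrow(grid)

  u <- grid$radius * cos(grid$phi)
  v <- grid$radius * sin(grid$phi)
  w <- grid$s
  if (spec$jitter_sd > 0) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$seed)
    u <- u + stats::rnorm(n, 0, spec$jitter_sd)
    v <- v + stats::rnorm(n, 0, spec$jitter_sd)
    w <- w + stats::rnorm(n, 0, spec$jitter_sd)
  }

  b <- .plane_basis(spec$axis_direction)
  xyz <- outer(u, b$e1) + outer(v, b$e2) + outer(w, spec$axis_direction)
  xyz <- sweep(xyz, 2, spec$axis_origin, `+`)

  resid <- ifelse(grid$layer == 1L, spec$inner_residue, spec$outer_residue)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", element = "C",
    resid = resid, chain = "A", resno = seq_len(n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, is_hetero = FALSE, vdw_radius = spec$atom_radius,
    stringsAsFactors = FALSE
  )
  model <- structure_model(atoms, source_id = "synthetic-groove",
                           title = sprintf("synthetic groove seed=%d",
                                           spec$seed))

  rfun <- spec$radius_fun
  area_fun <- function(s) {
    R <- rfun(s)
    if (wall_arc >= pi) {
      # convex hull = disc minus the circular segment cut off by the mouth
      pi * R^2 - (R^2 / 2) * (open_rad - sin(open_rad))
    } else {
      # wall shorter than a half-circle: hull is the arc's own segment
      (R^2 / 2) * (wall_arc - sin(wall_arc))
    }
  }
  truth <- list(
    atoms = data.frame(serial = atoms$serial, label = grid$label,
                       layer = grid$layer, s = grid$s,
                       azimuth_deg = grid$phi * 180 / pi,
                       radius = grid$radius, stringsAsFactors = FALSE),
    axis_origin = spec$axis_origin, axis_direction = spec$axis_direction,
    radius_fun = rfun, lumen_area_fun = area_fun
  )
  list(model = model, truth = truth, spec = spec)
}

#' Generate a sphere system
#'
#' One single-atom residue per sphere, with the given van der Waals radii and
#' chain set by group label. Used as an analytic fixture for surface-area
#' calculations (isolated spheres, spherical-cap overlaps).
#'
#' @param centers Numeric matrix (n x 3) or list of 3-vectors, Angstrom.
#' @param radii Numeric vector of sphere radii, Angstrom.
#' @param group_labels Optional character vector of chain labels (default all
#'   `"A"`).
#' @return A `structure_model`.
#' @export
#' @examples
#' make_sphere_system(rbind(c(0, 0, 0), c(3.1, 0, 0)), c(1.7, 1.7),
#'                    c("A", "B"))
make_sphere_system <- function(centers, radii, group_labels = NULL) {
  if (is.list(centers)) centers <- do.call(rbind, centers)
  centers <- matrix(as.numeric(centers), ncol = 3)
  n <- nrow(centers)
  if (length(radii) == 1L) radii <- rep(radii, n)
  if (length(radii) != n) {
    stop("lengths of centers and radii disagree", call. = FALSE)
  }
  if (is.null(group_labels)) group_labels <- rep("A", n)
  if (length(group_labels) != n) {
    stop("group_labels length must match number of spheres", call. = FALSE)
  }
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", element = "C", resid = "SPH",
    chain = as.character(group_labels), resno = seq_len(n),
    x = centers[, 1], y = centers[, 2], z = centers[, 3],
    occupancy = 1, is_hetero = FALSE, vdw_radius = radii,
    stringsAsFactors = FALSE
  )
  structure_model(atoms, source_id = "synthetic-spheres")
}

#' Write groove ground truth as a CSV sidecar
#'
#' @param groove Result of [make_groove()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(groove, path) {
  write.table(groove$truth$atoms, path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Recover the inner wall radius from a groove profile
#'
#' Validation estimator for generated grooves: the largest-inscribed-circle
#' radius understates the wall radius (it is limited by the most inward
#' jittered atom plus the atom radius) while the max-chord radius overstates
#' it (rim-to-rim through the most outward atoms); under symmetric jitter the
#' two extreme-value biases cancel, so their average is used:
#' `R = (width_inscribed / 2 + atom_radius + width_maxchord / 2) / 2`,
#' averaged over the selected interior slabs.
#'
#' @param profile A [groove_profile()] result.
#' @param atom_radius The generator's pseudo-atom radius, Angstrom.
#' @param slab_range Optional integer vector of slab indices to average over
#'   (default: the profile's trimmed `slabs_used`, minus the two outermost
#'   slabs at each end).
#' @return Estimated inner radius, Angstrom.
#' @export
recover_inner_radius <- function(profile, atom_radius, slab_range = NULL) {
  stopifnot(inherits(profile, "groove_profile"))
  tab <- profile$table
  if (is.null(slab_range)) {
    used <- profile$summary$slabs_used
    slab_range <- used[used > min(used) + 1 & used < max(used) - 1]
    if (!length(slab_range)) slab_range <- used
  }
  sel <- tab$slab_index %in% slab_range
  if (!any(sel)) stop("no slabs in the requested range", call. = FALSE)
  r_insc <- mean(tab$width_inscribed_A[sel]) / 2 + atom_radius
  r_chord <- mean(tab$width_maxchord_A[sel]) / 2
  (r_insc + r_chord) / 2
}
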