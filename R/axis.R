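# Channel-axis fitting (principal component of atom coordinates) and
# partition of atoms into fixed-thickness slabs perpendicular to the axis —
# the programmatic analogue of sweeping a clipping plane along the channel.

#' Fit the channel axis of an elongated selection
#'
#' The axis direction is the dominant principal component of the selected
#' atoms' centred coordinates. The sign is chosen so the atom with the lowest
#' residue number of the lowest-ordered chain sits at the small-`s` end
#' (N terminus at axial coordinate ~0). The origin is the point on the axis
#' where the minimum axial coordinate over selected atoms is 0, so every
#' selected atom has axial coordinate in `[0, extent]`.
#'
#' A fixed in-plane orthonormal basis (`e1`, `e2`) is attached to the frame
#' and shared by all slabs, so slices are mutually registered like the fixed
#' camera of a slice sweep.
#'
#' @param model A `structure_model`.
#' @param sel Optional `atom_selection` or selection string; default all
#'   atoms.
#' @return An object of class `axis_frame`: list with `origin`, `direction`
#'   (unit 3-vector), `extent` (Angstrom), `e1`, `e2`, `n_atoms`.
#' @export
#' @examples
#' g <- make_groove(groove_spec(length = 60, inner_radius = 10))
#' fit_channel_axis(g$model)
fit_channel_axis <- function(model, sel = NULL) {
  stopifnot(inherits(model, "structure_model"))
  if (!is.null(sel)) model <- apply_selection(model, sel)
  xyz <- coords(model)
  if (nrow(xyz) < 3L) {
    stop("degenerate axis: need at least 3 atoms, got ", nrow(xyz),
         call. = FALSE)
  }
  ctr <- colMeans(xyz)
  centred <- sweep(xyz, 2, ctr)
  sv <- svd(centred, nu = 0, nv = 3)
  if (sv$d[1] <= .Machine$double.eps * nrow(xyz)) {
    stop("degenerate axis: atoms are coincident", call. = FALSE)
  }
  d <- sv$v[, 1]
  if (sv$d[1] > 0 && (sv$d[1] - sv$d[2]) / sv$d[1] < 0.01) {
    warning("ambiguous axis: top two principal extents within 1%; ",
            "using deterministic lexicographic tie-break", call. = FALSE)
  }
  # deterministic base sign before the orientation rule
  nz <- which(abs(d) > 1e-12)[1]
  if (d[nz] < 0) d <- -d

  s <- as.numeric(centred %*% d)
  # orientation: N-terminal atom (lowest resno of lowest chain) at small s
  a <- model$atoms
  ch0 <- min(a$chain)
  i_n <- which(a$chain == ch0)
  i_n <- i_n[which.min(a$resno[i_n])]
  if (s[i_n] - min(s) > max(s) - s[i_n]) {
    d <- -d
    s <- -s
  }
  origin <- ctr + min(s) * d
  extent <- max(s) - min(s)
  if (extent <= 0) stop("degenerate axis: zero extent", call. = FALSE)
  b <- .plane_basis(d)
  structure(list(origin = origin, direction = d, extent = extent,
                 e1 = b$e1, e2 = b$e2, n_atoms = nrow(xyz)),
            class = "axis_frame")
}

#' @export
print.axis_frame <- function(x, ...) {
  cat(sprintf("axis_frame: direction (%.3f, %.3f, %.3f), extent %.1f A, %d atoms\n",
              x$direction[1], x$direction[2], x$direction[3], x$extent,
              x$n_atoms))
  invisible(x)
}

#' Axial coordinates of atoms in an axis frame
#'
#' @param model A `structure_model`.
#' @param axis An `axis_frame`.
#' @return Numeric vector of axial coordinates `s` (Angstrom).
#' @export
axial_coords <- function(model, axis) {
  stopifnot(inherits(axis, "axis_frame"))
  as.numeric(sweep(coords(model), 2, axis$origin) %*% axis$direction)
}

#' Partition atoms into perpendicular slabs
#'
#' Tiles `[0, extent]` with half-open intervals `[s_lo, s_hi)` of the given
#' thickness (the last slab is closed so atoms exactly at the extent belong
#' to it) and assigns every atom to exactly one slab by axial coordinate.
#' In-slab 2-D projections use the frame's shared `e1`/`e2` basis, so all
#' slices are mutually registered.
#'
#' @param model A `structure_model` (typically the same selection the axis
#'   was fitted on).
#' @param axis An `axis_frame` from [fit_channel_axis()].
#' @param thickness Slab thickness in Angstrom (default 5, the conventional
#'   slice increment).
#' @return An object of class `slice_slabs`: list with `slabs` (list of
#'   per-slab lists: `index` 0-based, `s_lo`, `s_hi`, `atom_idx` row indices
#'   into `model$atoms`, `proj` n x 2 matrix), `thickness`, `axis`,
#'   `n_atoms`.
#' @export
#' @examples
#' g <- make_groove(groove_spec(length = 40, inner_radius = 10))
#' ax <- fit_channel_axis(g$model)
#' length(partition_slabs(g$model, ax)$slabs)
partition_slabs <- function(model, axis, thickness = 5) {
  stopifnot(inherits(model, "structure_model"), inherits(axis, "axis_frame"))
  if (!is.numeric(thickness) || thickness <= 0) {
    stop("slab thickness must be > 0", call. = FALSE)
  }
  s <- axial_coords(model, axis)
  n_slab <- max(1L, as.integer(ceiling((axis$extent - 1e-9) / thickness)))
  idx <- pmin(pmax(floor(s / thickness), 0), n_slab - 1L)
  xyz <- sweep(coords(model), 2, axis$origin)
  u <- as.numeric(xyz %*% axis$e1)
  v <- as.numeric(xyz %*% axis$e2)
  slabs <- lapply(seq_len(n_slab) - 1L, function(i) {
    members <- which(idx == i)
    list(index = i,
         s_lo = i * thickness,
         s_hi = if (i == n_slab - 1L) axis$extent else (i + 1) * thickness,
         atom_idx = members,
         proj = cbind(u = u[members], v = v[members]))
  })
  structure(list(slabs = slabs, thickness = thickness, axis = axis,
                 n_atoms = nrow(model$atoms)),
            class = "slice_slabs")
}

#' @export
print.slice_slabs <- function(x, ...) {
  cat(sprintf("slice_slabs: %d slabs of %.1f A over extent %.1f A (%d atoms)\n",
              length(x$slabs), x$thickness, x$axis$extent, x$n_atoms))
  invisible(x)
}
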