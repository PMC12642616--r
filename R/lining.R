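# Channel-lining classification (line-of-sight from the lumen centroid) and
# residue-level hydropathy profiles of lining vs exterior residues.

#' Classify atoms as channel-lining or exterior
#'
#' Within each slab, an atom is "lining" if the 2-D segment from the slab's
#' lumen centroid to the atom's projected centre intersects no other atom's
#' projected disk (line-of-sight rule); otherwise it is "exterior". Atoms in
#' empty slabs (no lumen) are "unassigned". An atom whose projection
#' coincides with the centroid is lining by convention.
#'
#' @param model The `structure_model` the slabs were built from.
#' @param slabs A `slice_slabs` from [partition_slabs()].
#' @param sections List of `lumen_cross_section` objects, one per slab (e.g.
#'   `groove_profile()$sections`).
#' @return An object of class `lining_labels`: data frame with columns
#'   `atom_row`, `serial`, `chain`, `resno`, `resid`, `slab_index`, `label`
#'   (factor: lining / exterior / unassigned).
#' @export
#' @examples
#' g <- make_groove(groove_spec(length = 30, inner_radius = 10,
#'                              wall_layers = 2, layer_spacing = 3))
#' p <- groove_profile(g$model)
#' table(classify_lining(g$model, p$slabs, p$sections)$label)
classify_lining <- function(model, slabs, sections) {
  stopifnot(inherits(model, "structure_model"),
            inherits(slabs, "slice_slabs"))
  if (length(sections) != length(slabs$slabs)) {
    stop("sections must have one entry per slab", call. = FALSE)
  }
  a <- model$atoms
  lab <- rep("unassigned", nrow(a))
  slab_of <- rep(NA_integer_, nrow(a))

  for (k in seq_along(slabs$slabs)) {
    sl <- slabs$slabs[[k]]
    cs <- sections[[k]]
    idx <- sl$atom_idx
    if (!length(idx)) next
    slab_of[idx] <- sl$index
    if (cs$is_empty || anyNA(cs$centroid)) next
    P <- sweep(sl$proj, 2, cs$centroid)  # centroid at the origin
    r <- a$vdw_radius[idx]
    r[is.na(r)] <- 0
    n <- length(idx)
    L2 <- rowSums(P^2)
    Ln <- sqrt(L2)
    for (i in seq_len(n)) {
      if (L2[i] < 1e-12) { lab[idx[i]] <- "lining"; next }
      # distance from each other atom j to the segment origin -> P[i,];
      # a blocker must intersect the sight line AND be radially interposed
      # (closer to the centroid by at least its own radius), so overlapping
      # wall neighbours at the same depth do not shadow each other
      t <- pmin(1, pmax(0, (P[, 1] * P[i, 1] + P[, 2] * P[i, 2]) / L2[i]))
      qx <- t * P[i, 1] - P[, 1]
      qy <- t * P[i, 2] - P[, 2]
      blocked <- (qx * qx + qy * qy < (r - 1e-9)^2) & r > 0 &
        (Ln < Ln[i] - r)
      blocked[i] <- FALSE
      lab[idx[i]] <- if (any(blocked)) "exterior" else "lining"
    }
  }
  out <- data.frame(atom_row = seq_len(nrow(a)), serial = a$serial,
                    chain = a$chain, resno = a$resno, resid = a$resid,
                    slab_index = slab_of,
                    label = factor(lab, levels = c("lining", "exterior",
                                                   "unassigned")),
                    stringsAsFactors = FALSE)
  class(out) <- c("lining_labels", class(out))
  out
}

#' Per-slab hydropathy of lining and exterior residues
#'
#' For every slab, the mean hydropathy over lining residues and over exterior
#' residues. Each residue contributes once per slab regardless of atom count;
#' a residue's slab class is the majority label of its atoms in that slab
#' (ties count as lining). Residues absent from the hydropathy table are
#' excluded; a slab with no standard residues in a class yields `NA` for that
#' mean (missing, not zero).
#'
#' @param labels A `lining_labels` from [classify_lining()].
#' @param table Named hydropathy vector (default [hydropathy_table()]).
#' @return Data frame with columns `slab_index`, `lining_mean_hydropathy`,
#'   `exterior_mean_hydropathy`, `n_lining_res`, `n_exterior_res`.
#' @export
hydropathy_profile <- function(labels, table = hydropathy_table()) {
  stopifnot(inherits(labels, "lining_labels"))
  lab <- labels[!is.na(labels$slab_index), , drop = FALSE]
  slabs <- sort(unique(lab$slab_index))
  out <- lapply(slabs, function(k) {
    sl <- lab[lab$slab_index == k & lab$label != "unassigned", , drop = FALSE]
    res <- data.frame(slab_index = k,
                      lining_mean_hydropathy = NA_real_,
                      exterior_mean_hydropathy = NA_real_,
                      n_lining_res = 0L, n_exterior_res = 0L)
    if (!nrow(sl)) return(res)
    key <- paste(sl$chain, sl$resno, sep = "\r")
    per_res <- lapply(split(seq_len(nrow(sl)), key), function(ii) {
      n_lin <- sum(sl$label[ii] == "lining")
      list(resid = sl$resid[ii[1]],
           class = if (n_lin >= length(ii) - n_lin) "lining" else "exterior")
    })
    resid <- vapply(per_res, `[[`, "", "resid")
    cls <- vapply(per_res, `[[`, "", "class")
    h <- unname(table[resid])  # NA for non-standard residues
    for (cl in c("lining", "exterior")) {
      v <- h[cls == cl]
      v <- v[!is.na(v)]
      if (cl == "lining") {
        res$n_lining_res <- length(v)
        if (length(v)) res$lining_mean_hydropathy <- mean(v)
      } else {
        res$n_exterior_res <- length(v)
        if (length(v)) res$exterior_mean_hydropathy <- mean(v)
      }
    }
    res
  })
  do.call(rbind, out)
}
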