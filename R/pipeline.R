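# Orchestration: end-to-end runners behind the command-line interface.
# Every output file carries a header echoing the effective configuration, and
# identical configurations produce byte-identical outputs (no RNG anywhere in
# the analysis path; the only seeded randomness is the generator's jitter).

.config_header <- function(config) {
  keys <- sort(names(config))
  vals <- vapply(keys, function(k) {
    v <- config[[k]]
    if (is.numeric(v)) paste(format(v, trim = TRUE, scientific = FALSE),
                             collapse = ",")
    else paste(as.character(v), collapse = ",")
  }, "")
  c(sprintf("# bltpgeom %s", as.character(utils::packageVersion("bltpgeom"))),
    sprintf("# %s=%s", keys, vals))
}

# CSV with '#' config header; numerics fixed to 4 decimals for byte-stable
# output across runs
.write_csv <- function(df, path, config) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- ifelse(is.na(out[[j]]), "NA", sprintf("%.4f", out[[j]]))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.config_header(config), con)
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a profile/compare CSV written by this package
#'
#' Skips the `#` configuration header and parses the table.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_output_csv <- function(path) {
  utils::read.table(path, sep = ",", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Built-in synthetic presets
#'
#' * `halfpipe10` — 100 Angstrom half-pipe (opening 180 deg), inner radius
#'   10 Angstrom, 1 Angstrom point-atom lattice: the analytic area fixture.
#' * `tube10` — same but closed (opening 0): the full-disc fixture.
#' * `twolayer` — two-layer Leu/Asp half-pipe (layer spacing 3 Angstrom,
#'   lattice 2 Angstrom, atom radius 0.9 Angstrom): the lining fixture.
#' * `flare8to16` — half-pipe whose inner radius grows linearly from 8 to
#'   16 Angstrom: the monotone-area fixture.
#'
#' @param name Preset name.
#' @return A [groove_spec()].
#' @export
synth_preset <- function(name) {
  switch(name,
    halfpipe10 = groove_spec(length = 100, inner_radius = 10,
                             opening_angle = 180, lattice_spacing = 1,
                             atom_radius = 0, jitter_sd = 0),
    tube10 = groove_spec(length = 100, inner_radius = 10, opening_angle = 0,
                         lattice_spacing = 1, atom_radius = 0, jitter_sd = 0),
    twolayer = groove_spec(length = 100, inner_radius = 10,
                           opening_angle = 180, wall_layers = 2,
                           layer_spacing = 3, lattice_spacing = 2,
                           atom_radius = 0.9, inner_residue = "LEU",
                           outer_residue = "ASP", jitter_sd = 0),
    flare8to16 = groove_spec(length = 100,
                             inner_radius = function(s) 8 + 8 * s / 100,
                             opening_angle = 180, lattice_spacing = 1.5,
                             atom_radius = 0.5, jitter_sd = 0),
    stop("unknown preset '", name, "'; available: halfpipe10, tube10, ",
         "twolayer, flare8to16", call. = FALSE)
  )
}

#' Generate and write a synthetic fixture
#'
#' Writes `<prefix>.pdb` (with REMARK lines recording the spec and seed) and
#' `<prefix>_truth.csv` (per-atom lining label and axial position).
#'
#' @param spec A [groove_spec()] or a preset name (see [synth_preset()]).
#' @param out_prefix Output path prefix.
#' @return Invisibly, the [make_groove()] result plus file paths.
#' @export
run_synth <- function(spec, out_prefix) {
  if (is.character(spec)) spec <- synth_preset(spec)
  stopifnot(inherits(spec, "groove_spec"))
  g <- make_groove(spec)
  pdb_path <- paste0(out_prefix, ".pdb")
  truth_path <- paste0(out_prefix, "_truth.csv")
  remarks <- c(
    sprintf("bltpgeom synthetic groove seed=%d jitter_sd=%g", spec$seed,
            spec$jitter_sd),
    sprintf("length=%g opening_angle=%g wall_layers=%d layer_spacing=%g",
            spec$length, spec$opening_angle, spec$wall_layers,
            spec$layer_spacing),
    sprintf("lattice_spacing=%g atom_radius=%g inner=%s outer=%s",
            spec$lattice_spacing, spec$atom_radius, spec$inner_residue,
            spec$outer_residue)
  )
  write_structure(g$model, pdb_path, remarks = remarks)
  write_ground_truth(g, truth_path)
  invisible(c(g, list(pdb = pdb_path, truth_csv = truth_path)))
}

#' Run the full groove-profiling pipeline
#'
#' read -> select -> axis fit -> 5 Angstrom slabs -> lumen cross-sections ->
#' lining classification -> hydropathy. With `out_prefix` set, writes
#' `<prefix>_profile.csv` (columns: slab_index, s_mid_A, n_atoms, area_A2,
#' width_inscribed_A, width_maxchord_A, lining_mean_hydropathy,
#' exterior_mean_hydropathy) and `<prefix>_summary.json`; both carry the full
#' configuration in their header.
#'
#' @param input A `structure_model` or a path to a PDB/mmCIF file.
#' @param selection Selection string or `atom_selection` (default all atoms).
#' @param out_prefix Output path prefix, or NULL for no files.
#' @param thickness,grid_resolution,mouth_closure,probe_inflate,alpha
#'   Geometry parameters, see [groove_profile()].
#' @param per_lipid_volume,trim_fraction See [groove_profile()].
#' @param radii_set Radii table used when reading from file.
#' @param hydropathy_scale Hydropathy scale name (see [hydropathy_table()]).
#' @return Invisibly, a list: `profile` ([groove_profile()] result),
#'   `lining`, `hydropathy`, `table` (the merged per-slab table), `config`,
#'   and output paths when written.
#' @export
#' @examples
#' g <- make_groove(groove_spec(length = 30, inner_radius = 10))
#' res <- run_profile(g$model)
#' head(res$table)
run_profile <- function(input, selection = "*", out_prefix = NULL,
                        thickness = 5, grid_resolution = 0.5,
                        mouth_closure = "convex", probe_inflate = 0,
                        alpha = 8, per_lipid_volume = 1300,
                        trim_fraction = 0.25, radii_set = "bondi",
                        hydropathy_scale = "kd") {
  model <- if (inherits(input, "structure_model")) input
           else read_structure(input, radii_set = radii_set)
  sel_str <- if (is.character(selection)) selection
             else format_selection(selection)
  model <- apply_selection(model, selection)

  prof <- groove_profile(model, thickness = thickness,
                         grid_resolution = grid_resolution,
                         mouth_closure = mouth_closure,
                         probe_inflate = probe_inflate, alpha = alpha,
                         per_lipid_volume = per_lipid_volume,
                         trim_fraction = trim_fraction)
  lin <- classify_lining(model, prof$slabs, prof$sections)
  hyd <- hydropathy_profile(lin, hydropathy_table(hydropathy_scale))

  tab <- merge(prof$table, hyd, by = "slab_index", all.x = TRUE)
  tab <- tab[order(tab$slab_index),
             c("slab_index", "s_mid", "n_atoms", "area_A2",
               "width_inscribed_A", "width_maxchord_A",
               "lining_mean_hydropathy", "exterior_mean_hydropathy")]
  names(tab)[names(tab) == "s_mid"] <- "s_mid_A"
  rownames(tab) <- NULL

  config <- list(
    input = if (is.character(input)) input else model$source_id,
    selection = sel_str, slab_thickness_A = thickness,
    grid_resolution_A = grid_resolution, mouth_closure = mouth_closure,
    probe_inflate_A = probe_inflate, alpha_A = alpha,
    per_lipid_volume_A3 = per_lipid_volume, trim_fraction = trim_fraction,
    radii_set = radii_set, hydropathy_scale = hydropathy_scale
  )
  out <- list(profile = prof, lining = lin, hydropathy = hyd, table = tab,
              config = config)

  if (!is.null(out_prefix)) {
    csv_path <- paste0(out_prefix, "_profile.csv")
    json_path <- paste0(out_prefix, "_summary.json")
    .write_csv(tab, csv_path, config)
    summary_obj <- list(
      tool = paste("bltpgeom",
                   as.character(utils::packageVersion("bltpgeom"))),
      config = config,
      extent_A = prof$axis$extent,
      n_slabs = nrow(tab),
      width_inscribed_min_A = prof$summary$width_inscribed_min,
      width_inscribed_max_A = prof$summary$width_inscribed_max,
      width_maxchord_min_A = prof$summary$width_maxchord_min,
      width_maxchord_max_A = prof$summary$width_maxchord_max,
      lumen_volume_A3 = prof$lumen_volume,
      capacity = prof$capacity$capacity,
      n_lipids = prof$capacity$n_lipids
    )
    jsonlite::write_json(summary_obj, json_path, auto_unbox = TRUE,
                         digits = 6, pretty = TRUE)
    out$profile_csv <- csv_path
    out$summary_json <- json_path
  }
  invisible(out)
}

#' Compare groove profiles across structures
#'
#' Runs [run_profile()] for every manifest entry and combines the per-slab
#' tables into one long-format table keyed by label and by the normalized
#' axial coordinate `s_norm = s_mid / extent` (so channels of different
#' lengths are comparable position-by-position). Raw `s_mid_A` is kept too.
#'
#' @param manifest Data frame with columns `label`, `path`, `selection`
#'   (selection may be omitted; defaults to `"*"`), or a path to a CSV with
#'   those columns. Labels must be unique; paths resolve locally only (this
#'   tool never downloads).
#' @param out_prefix Output prefix: writes `<prefix>_<label>_profile.csv`
#'   per entry and `<prefix>_combined.csv`. NULL for no files.
#' @param skip_failures Skip entries whose run fails (with a warning) rather
#'   than aborting.
#' @param ... Shared parameters passed to [run_profile()].
#' @return Invisibly, list with `results` (per label), `combined` (long data
#'   frame), and output paths when written.
#' @export
run_compare <- function(manifest, out_prefix = NULL, skip_failures = FALSE,
                        ...) {
  if (is.character(manifest)) {
    manifest <- utils::read.table(manifest, sep = ",", header = TRUE,
                                  comment.char = "#",
                                  stringsAsFactors = FALSE)
  }
  if (!all(c("label", "path") %in% names(manifest))) {
    stop("manifest needs columns 'label' and 'path'", call. = FALSE)
  }
  if (anyDuplicated(manifest$label)) {
    stop("manifest labels must be unique; duplicated: ",
         paste(unique(manifest$label[duplicated(manifest$label)]),
               collapse = ", "), call. = FALSE)
  }
  if (is.null(manifest$selection)) manifest$selection <- "*"

  results <- list()
  combined <- list()
  for (i in seq_len(nrow(manifest))) {
    lab <- manifest$label[i]
    res <- tryCatch(
      run_profile(manifest$path[i], selection = manifest$selection[i],
                  out_prefix = if (is.null(out_prefix)) NULL
                               else paste0(out_prefix, "_", lab), ...),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (skip_failures) {
        warning("entry '", lab, "' failed: ", conditionMessage(res),
                call. = FALSE)
        next
      }
      stop("compare entry '", lab, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    results[[lab]] <- res
    tb <- res$table
    tb$label <- lab
    tb$s_norm <- tb$s_mid_A / res$profile$axis$extent
    combined[[lab]] <- tb[, c("label", "slab_index", "s_mid_A", "s_norm",
                              "n_atoms", "area_A2", "width_inscribed_A",
                              "width_maxchord_A")]
  }
  combined <- do.call(rbind, combined)
  rownames(combined) <- NULL
  out <- list(results = results, combined = combined)
  if (!is.null(out_prefix) && !is.null(combined)) {
    path <- paste0(out_prefix, "_combined.csv")
    .write_csv(combined, path,
               list(n_entries = length(results),
                    labels = paste(names(results), collapse = ";")))
    out$combined_csv <- path
  }
  invisible(out)
}

#' Run the interface (buried surface) pipeline
#'
#' Evaluates [interface_bsa()] between two selections of a model and, with
#' `out_prefix`, writes `<prefix>_interface.csv` (group_a, group_b,
#' sasa_a_A2, sasa_b_A2, sasa_ab_A2, bsa_A2, bsa_one_sided_A2) and
#' `<prefix>_interface_residues.csv` (per-residue SASA loss).
#'
#' @param input A `structure_model` or file path.
#' @param group_a,group_b Selection strings or objects (disjoint).
#' @param out_prefix Output prefix or NULL.
#' @param probe_radius,n_points See [shrake_rupley_sasa()].
#' @param radii_set Radii table used when reading from file.
#' @return Invisibly, the `interface_report` (plus paths when written).
#' @export
run_interface <- function(input, group_a, group_b, out_prefix = NULL,
                          probe_radius = 1.4, n_points = 960L,
                          radii_set = "bondi") {
  model <- if (inherits(input, "structure_model")) input
           else read_structure(input, radii_set = radii_set)
  rep <- interface_bsa(model, group_a, group_b, probe_radius, n_points)
  if (!is.null(out_prefix)) {
    config <- list(
      input = if (is.character(input)) input else model$source_id,
      group_a = if (is.character(group_a)) group_a
                else format_selection(group_a),
      group_b = if (is.character(group_b)) group_b
                else format_selection(group_b),
      probe_radius_A = probe_radius, n_points = n_points,
      radii_set = radii_set
    )
    tab <- data.frame(group_a = config$group_a, group_b = config$group_b,
                      sasa_a_A2 = rep$sasa_a_alone,
                      sasa_b_A2 = rep$sasa_b_alone,
                      sasa_ab_A2 = rep$sasa_ab_combined,
                      bsa_A2 = rep$bsa_total,
                      bsa_one_sided_A2 = rep$bsa_one_sided)
    .write_csv(tab, paste0(out_prefix, "_interface.csv"), config)
    .write_csv(rep$per_residue,
               paste0(out_prefix, "_interface_residues.csv"), config)
  }
  invisible(rep)
}
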