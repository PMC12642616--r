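# Structure input/output: PDB/mmCIF reading (via bio3d), atom selections,
# radius assignment. Atom records keep author residue numbering untouched.

#' Construct a structure model
#'
#' Low-level constructor for the atom container used throughout the package:
#' a data frame of atom records plus provenance. Most users will get one from
#' [read_structure()] or [make_groove()] rather than building it by hand.
#'
#' @param atoms Data frame with columns `serial` (integer), `name`,
#'   `element`, `resid` (3-letter residue name), `chain`, `resno` (author
#'   residue number), `x`, `y`, `z` (Angstrom), `occupancy`, `is_hetero`
#'   (logical) and optionally `vdw_radius` (Angstrom).
#' @param source_id File path or accession the model came from.
#' @param title Free-text title.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, source_id = "", title = "") {
  required <- c("serial", "name", "element", "resid", "chain", "resno",
                "x", "y", "z", "occupancy", "is_hetero")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atoms is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(atoms) < 1L) stop("empty model: no atoms", call. = FALSE)
  if (anyDuplicated(atoms$serial)) {
    stop("atom serial numbers are not unique", call. = FALSE)
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates", call. = FALSE)
  }
  if (!"vdw_radius" %in% names(atoms)) atoms$vdw_radius <- NA_real_
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, source_id = source_id, title = title),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)")
  if (nzchar(x$source_id)) cat(" [", x$source_id, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param model A `structure_model`.
#' @return Numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  as.matrix(model$atoms[, c("x", "y", "z")])
}

# Infer element symbol from a PDB atom name when the element column is blank.
# Digits/primes are stripped; a leading two-letter match against common
# two-character elements wins, else the first alphabetic character.
.infer_element <- function(name) {
  two_letter <- c("FE", "ZN", "MG", "MN", "CA", "NA", "CL", "CU", "NI", "SE",
                  "BR", "CO", "CD", "HG")
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  el <- substr(nm, 1, 1)
  # atom names like "CA " for C-alpha must stay carbon; only treat as a metal
  # when the raw name is exactly the element symbol (common for HETATM ions)
  hit <- nm %in% two_letter & nchar(gsub("\\s", "", name)) == nchar(nm)
  ifelse(nchar(nm) == 0, "C", ifelse(hit & nchar(nm) == 2, nm, el))
}

#' Read an atomic model from PDB or mmCIF
#'
#' Parses the first model block of a coordinate file into a
#' [structure_model()]. Element symbols are taken from the file when present
#' and inferred from atom names otherwise; van der Waals radii are assigned
#' from the shipped table. When alternate locations are present, only the
#' highest-occupancy altloc of each atom is kept (ties: first in file).
#'
#' @param path Path to the coordinate file.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by file extension;
#'   `.cif`/`.mmcif` read as mmCIF, anything else as PDB).
#' @param include_hetero Keep HETATM records (waters, ligands)? Default FALSE.
#' @param include_hydrogens Keep hydrogen/deuterium atoms? Default FALSE
#'   (deposited cryo-EM models typically lack them).
#' @param radii_set Name of the radii table for [assign_radii()].
#' @return A `structure_model` with radii assigned.
#' @export
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' write_structure(make_sphere_system(rbind(c(0, 0, 0)), 1.7), f)
#' read_structure(f)
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           include_hetero = FALSE,
                           include_hydrogens = FALSE,
                           radii_set = "bondi") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                         verbose = FALSE)
    else bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE),
    error = function(e) {
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("empty model: no atoms in '", path, "'", call. = FALSE)
  }

  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  elem <- toupper(trimws(ifelse(is.na(elem), "", elem)))
  blank <- !nzchar(elem)
  elem[blank] <- .infer_element(at$elety[blank])

  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = elem,
    resid = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | !nzchar(trimws(at$chain)),
                   " ", trimws(at$chain)),
    resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  alt <- trimws(ifelse(is.na(at$alt), "", at$alt))

  # altloc: keep the highest-occupancy conformer per (chain, resno, name)
  if (any(nzchar(alt))) {
    key <- paste(atoms$chain, atoms$resno, atoms$name, sep = "\r")
    keep <- rep(TRUE, nrow(atoms))
    for (idx in split(seq_len(nrow(atoms)), key)) {
      if (length(idx) > 1L) {
        best <- idx[which.max(atoms$occupancy[idx])]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    atoms <- atoms[keep, , drop = FALSE]
  }

  if (!include_hetero) atoms <- atoms[!atoms$is_hetero, , drop = FALSE]
  if (!include_hydrogens) {
    atoms <- atoms[!atoms$element %in% c("H", "D"), , drop = FALSE]
  }
  if (nrow(atoms) == 0L) {
    stop("empty model: no atoms left after filtering in '", path, "'",
         call. = FALSE)
  }
  model <- structure_model(atoms, source_id = path)
  assign_radii(model, radii_set)
}

#' Write a model as a PDB file
#'
#' Fixed-column PDB output (via bio3d), optionally preceded by REMARK header
#' lines. Coordinates are written at the format's 3-decimal precision.
#'
#' @param model A `structure_model`.
#' @param path Output file path.
#' @param remarks Optional character vector written as `REMARK 250` lines
#'   before the coordinates.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, remarks = NULL) {
  stopifnot(inherits(model, "structure_model"))
  a <- model$atoms
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  bio3d::write.pdb(
    file = tmp,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    type = ifelse(a$is_hetero, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resid, eleno = a$serial,
    elety = a$name, chain = a$chain, o = a$occupancy,
    b = rep(0, nrow(a)), elesy = a$element, verbose = FALSE
  )
  lines <- readLines(tmp)
  if (!is.null(remarks) && length(remarks)) {
    lines <- c(sprintf("REMARK 250 %s", remarks), lines)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Define an atom selection
#'
#' Selections address atoms by chain, inclusive author-numbered residue
#' ranges, and optionally atom names. An empty `ranges` list means all
#' residues of the chain; chain `"*"` matches every chain.
#'
#' @param chain Chain identifier or `"*"` for any chain.
#' @param ranges List of length-2 integer vectors `c(start, end)`, 1-based
#'   inclusive at both ends, in author numbering. `NULL` or `list()` selects
#'   all residues.
#' @param atom_names Optional character vector of atom names to keep (e.g.
#'   `"CA"`).
#' @return An object of class `atom_selection`.
#' @export
#' @examples
#' selection("A", list(c(2, 3753)))
selection <- function(chain = "*", ranges = NULL, atom_names = NULL) {
  if (is.null(ranges)) ranges <- list()
  if (is.numeric(ranges) && length(ranges) == 2L) ranges <- list(ranges)
  for (r in ranges) {
    if (length(r) != 2L || !is.numeric(r) || anyNA(r)) {
      stop("each residue range must be a numeric pair c(start, end)",
           call. = FALSE)
    }
    if (r[1] > r[2]) {
      stop("residue range start (", r[1], ") exceeds end (", r[2], ")",
           call. = FALSE)
    }
  }
  structure(list(chain = as.character(chain), ranges = ranges,
                 atom_names = atom_names),
            class = "atom_selection")
}

#' Parse a selection string
#'
#' Accepts the command-line form `"CHAIN:START-END[,START-END...]"`, a bare
#' chain (`"A"`), or `"*"` for everything. Residue numbers are author-numbered
#' and ranges are inclusive at both ends.
#'
#' @param text Selection string.
#' @return An `atom_selection`.
#' @export
#' @examples
#' parse_selection("A:2-3753")
#' parse_selection("*")
parse_selection <- function(text) {
  text <- trimws(text)
  if (!nzchar(text) || identical(text, "*")) return(selection("*"))
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (length(parts) > 2L) stop("bad selection string: '", text, "'",
                               call. = FALSE)
  chain <- parts[1]
  if (length(parts) == 1L || !nzchar(trimws(parts[2]))) {
    return(selection(chain))
  }
  ranges <- lapply(strsplit(parts[2], ",", fixed = TRUE)[[1]], function(tok) {
    m <- regmatches(tok, regexec("^\\s*(-?\\d+)\\s*-\\s*(-?\\d+)\\s*$", tok))[[1]]
    if (length(m) != 3L) {
      m1 <- regmatches(tok, regexec("^\\s*(-?\\d+)\\s*$", tok))[[1]]
      if (length(m1) == 2L) return(c(as.integer(m1[2]), as.integer(m1[2])))
      stop("bad residue range token: '", tok, "'", call. = FALSE)
    }
    c(as.integer(m[2]), as.integer(m[3]))
  })
  selection(chain, ranges)
}

#' Format a selection as a string
#' @param sel An `atom_selection`.
#' @return A selection string in the CLI form.
#' @export
format_selection <- function(sel) {
  stopifnot(inherits(sel, "atom_selection"))
  if (sel$chain == "*" && !length(sel$ranges)) return("*")
  if (!length(sel$ranges)) return(sel$chain)
  paste0(sel$chain, ":",
         paste(vapply(sel$ranges, function(r) paste0(r[1], "-", r[2]), ""),
               collapse = ","))
}

#' Apply a selection to a model
#'
#' Keeps atoms whose chain and author residue number fall within the
#' selection, preserving file order and numbering (no renumbering).
#'
#' @param model A `structure_model`.
#' @param sel An `atom_selection` or selection string (see
#'   [parse_selection()]).
#' @return The selected `structure_model`.
#' @export
#' @examples
#' g <- make_groove(groove_spec(length = 20, inner_radius = 8))
#' apply_selection(g$model, "A")
apply_selection <- function(model, sel) {
  stopifnot(inherits(model, "structure_model"))
  if (is.character(sel)) sel <- parse_selection(sel)
  stopifnot(inherits(sel, "atom_selection"))
  a <- model$atoms
  keep <- if (sel$chain == "*") rep(TRUE, nrow(a)) else a$chain == sel$chain
  if (length(sel$ranges)) {
    in_range <- rep(FALSE, nrow(a))
    for (r in sel$ranges) {
      in_range <- in_range | (a$resno >= r[1] & a$resno <= r[2])
    }
    keep <- keep & in_range
  }
  if (!is.null(sel$atom_names)) keep <- keep & a$name %in% sel$atom_names
  if (!any(keep)) {
    stop("empty selection: '", format_selection(sel),
         "' matches no atoms", call. = FALSE)
  }
  out <- model
  out$atoms <- a[keep, , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Assign van der Waals radii by element
#'
#' Sets every atom's `vdw_radius` from the named radii table. Elements absent
#' from the table get the table's default radius, with one warning listing
#' them. Re-assignment with the same table is idempotent.
#'
#' @param model A `structure_model`.
#' @param radii_set Radii table name (see [radii_table()]).
#' @return The model with `vdw_radius` filled in.
#' @export
assign_radii <- function(model, radii_set = "bondi") {
  stopifnot(inherits(model, "structure_model"))
  tab <- radii_table(radii_set)
  el <- model$atoms$element
  r <- unname(tab$radii[el])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ",
            paste(sort(unique(el[unknown])), collapse = ", "),
            ": using default radius ", tab$default, " A", call. = FALSE)
    r[unknown] <- tab$default
  }
  model$atoms$vdw_radius <- r
  attr(model, "radii_set") <- radii_set
  model
}
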