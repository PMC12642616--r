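# Shipped constant tables: van der Waals radii and hydropathy scales.

# Bondi-type van der Waals radii (Angstrom). Single shipped set; elements not
# listed fall back to `default` with a warning at assignment time.
.radii_sets <- list(
  bondi = list(
    radii = c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20),
    default = 1.70
  )
)

# Kyte-Doolittle hydropathy (dimensionless; higher = more hydrophobic).
.kyte_doolittle <- c(
  ILE =  4.5, VAL =  4.2, LEU =  3.8, PHE =  2.8, CYS =  2.5,
  MET =  1.9, ALA =  1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
  TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2, GLU = -3.5,
  GLN = -3.5, ASP = -3.5, ASN = -3.5, LYS = -3.9, ARG = -4.5
)

#' Van der Waals radii table
#'
#' Returns the named per-element radii table shipped with the package.
#' The default set (`"bondi"`) uses C 1.70, N 1.55, O 1.52, S 1.80, P 1.80,
#' H 1.20 Angstrom, with 1.70 Angstrom for any other element.
#'
#' @param set Name of the radii set. Only `"bondi"` is shipped.
#' @return A list with elements `radii` (named numeric vector, Angstrom) and
#'   `default` (fallback radius, Angstrom).
#' @export
#' @examples
#' radii_table()$radii[["C"]]
radii_table <- function(set = "bondi") {
  if (!set %in% names(.radii_sets)) {
    stop("unknown radii set '", set, "'; available: ",
         paste(names(.radii_sets), collapse = ", "), call. = FALSE)
  }
  .radii_sets[[set]]
}

#' Residue hydropathy table
#'
#' The Kyte-Doolittle hydropathy scale for the 20 standard residues, keyed by
#' 3-letter code. Residues absent from the table (non-standard, ligands) are
#' excluded from hydropathy means rather than contributing a value.
#'
#' @param scale Scale name; only `"kd"` (Kyte-Doolittle) is shipped.
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' hydropathy_table()[["LEU"]]  # 3.8
hydropathy_table <- function(scale = "kd") {
  if (!identical(scale, "kd")) {
    stop("unknown hydropathy scale '", scale, "'", call. = FALSE)
  }
  .kyte_doolittle
}
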