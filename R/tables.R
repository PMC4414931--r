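#' Load the bundled physico-chemical property tables
#'
#' Feature construction is driven by data, not code: residue-level features
#' (Kyte-Doolittle hydropathy plus five physico-chemical class indicators),
#' atom-level features (a one-hot pharmacophore type per heavy atom of each
#' standard residue plus a ligand-binding propensity column), and the
#' donor/acceptor typing used for point-level counts all come from CSV files
#' under `inst/extdata/`. Users can substitute their own tables with the same
#' columns; the `schema_version` checksum changes whenever any value changes,
#' and models refuse feature vectors built under a different schema.
#'
#' @param dir directory holding `residue_features.csv`, `atom_features.csv`,
#'   `plb_propensities.csv` and `vdw_radii.csv`. Defaults to the copies
#'   bundled with the package.
#' @return an object of class `property_tables`: a list with elements
#'   `residue_table`, `atom_table`, `plb`, `vdw`, `feature_names`,
#'   `schema_version`.
#' @export
#' @examples
#' tab <- property_tables()
#' tab$residue_table["ILE", "hydropathy"]   # 4.5
property_tables <- function(dir = system.file("extdata", package = "pocketrank")) {
  res <- read.csv(file.path(dir, "residue_features.csv"), stringsAsFactors = FALSE)
  atm <- read.csv(file.path(dir, "atom_features.csv"), stringsAsFactors = FALSE)
  plb <- read.csv(file.path(dir, "plb_propensities.csv"), stringsAsFactors = FALSE)
  vdw <- read.csv(file.path(dir, "vdw_radii.csv"), stringsAsFactors = FALSE)

  stopifnot(all(c("residue", "hydropathy") %in% names(res)),
            all(c("residue", "atom", "ptype", "propensity") %in% names(atm)),
            all(c("residue", "plb") %in% names(plb)),
            all(c("element", "radius") %in% names(vdw)))
  std20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
             "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
             "TYR", "VAL")
  missing <- setdiff(std20, res$residue)
  if (length(missing))
    stop("residue table is missing standard residues: ",
         paste(missing, collapse = ", "))

  residue_table <- as.matrix(res[, setdiff(names(res), "residue"), drop = FALSE])
  rownames(residue_table) <- res$residue

  # expand the categorical pharmacophore type into one-hot columns
  ptypes <- c("hydrophobic", "aromatic", "donor", "acceptor", "donor_acceptor",
              "positive", "negative", "none")
  bad <- setdiff(unique(atm$ptype), ptypes)
  if (length(bad)) stop("unknown pharmacophore types: ", paste(bad, collapse = ", "))
  onehot <- outer(atm$ptype, ptypes, `==`) * 1
  colnames(onehot) <- paste0("pt_", ptypes)
  atom_table <- cbind(onehot, propensity = atm$propensity)
  rownames(atom_table) <- paste(atm$residue, atm$atom, sep = ".")

  feature_names <- c(paste0("agg_", c(colnames(residue_table), colnames(atom_table))),
                     "donors", "acceptors", "mean_b", "protrusion")

  payload <- paste(
    paste(capture_table(res), collapse = "\n"),
    paste(capture_table(atm), collapse = "\n"),
    paste(capture_table(plb), collapse = "\n"), sep = "\n--\n")
  structure(list(
    residue_table  = residue_table,
    atom_table     = atom_table,
    atom_ptype     = setNames(atm$ptype, rownames(atom_table)),
    plb            = setNames(plb$plb, plb$residue),
    vdw            = setNames(vdw$radius, toupper(vdw$element)),
    feature_names  = feature_names,
    schema_version = paste0("pt-", fnv1a_hex(payload))
  ), class = "property_tables")
}

#' @export
print.property_tables <- function(x, ...) {
  cat("Property tables [schema ", x$schema_version, "]\n", sep = "")
  cat("  residues:", nrow(x$residue_table),
      " residue features:", ncol(x$residue_table), "\n")
  cat("  atom rows:", nrow(x$atom_table),
      " atom features:", ncol(x$atom_table), "\n")
  cat("  IFV length:", length(x$feature_names), "\n")
  invisible(x)
}

# canonical text rendering of a table for checksumming
capture_table <- function(df) {
  apply(df, 1L, paste, collapse = ",")
}

# FNV-1a 32-bit hash over UTF-8 bytes, kept in double arithmetic (< 2^53)
fnv1a_hex <- function(text) {
  bytes <- as.integer(charToRaw(paste(text, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", h)
}

# xor of a 32-bit value held in a double with a byte
bitwXor_dbl <- function(h, b) {
  lo <- h %% 2^31
  hi <- h %/% 2^31
  lo2 <- bitwXor(as.integer(lo), as.integer(b))
  hi * 2^31 + (lo2 %% 2^31) + (if (lo2 < 0) 2^31 else 0)
}

#' Van der Waals radius of a heavy element
#'
#' Unknown elements fall back to the carbon radius 1.70 Angstrom with a
#' warning (never an error).
#'
#' @param element character vector of element symbols.
#' @param tables a `property_tables` object.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element, tables = property_tables()) {
  el <- toupper(element)
  r <- unname(tables$vdw[el])
  if (anyNA(r)) {
    unknown <- unique(el[is.na(r)])
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            ": using default vdW radius 1.70 A")
    r[is.na(r)] <- 1.70
  }
  r
}
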