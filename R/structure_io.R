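#' Default HETATM groups ignored when reading structures
#'
#' Waters plus common ions, buffer components and cryoprotectants. These
#' never become ligands and their atoms are dropped entirely.
#'
#' @return character vector of 1-3 letter group codes.
#' @export
default_ignore_groups <- function() {
  c("HOH", "DOD", "WAT", "H2O",
    "NA", "K", "MG", "CA", "ZN", "MN", "FE", "CU", "NI", "CO", "CD", "HG",
    "CL", "BR", "IOD", "F",
    "SO4", "PO4", "NO3", "ACT", "FMT", "CO3",
    "GOL", "EDO", "PEG", "PG4", "MPD", "TRS", "EPE", "MES", "DMS", "BME")
}

#' Construct a protein structure object
#'
#' Low-level constructor used by the PDB reader and by the synthetic fixture
#' generator. `atoms` holds the heavy polymer atoms; hydrogens must already
#' have been removed.
#'
#' @param atoms data.frame with columns `serial`, `element`, `name`,
#'   `resname`, `chain`, `resno`, `inscode`, `b`, `x`, `y`, `z`.
#' @param ligands list of ligands as returned by [ligand_group()].
#' @param id structure identifier string.
#' @return object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, ligands = list(), id = "structure") {
  need <- c("serial", "element", "name", "resname", "chain", "resno",
            "inscode", "b", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1L) stop("empty structure: no polymer atoms")
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serials")
  if (any(toupper(atoms$element) %in% c("H", "D")))
    stop("hydrogen atoms are not allowed in a protein_structure")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms, ligands = ligands),
            class = "protein_structure")
}

#' Construct a ligand group
#'
#' @param atoms data.frame of heavy atoms (same columns as in
#'   [protein_structure()]).
#' @param group_name 3-letter HET group code.
#' @return object of class `ligand`; `center` is the centroid of the heavy
#'   atoms.
#' @export
ligand_group <- function(atoms, group_name) {
  if (nrow(atoms) < 1L) stop("ligand must have at least one heavy atom")
  structure(list(atoms = atoms, group_name = group_name,
                 center = colMeans(as.matrix(atoms[, c("x", "y", "z")]))),
            class = "ligand")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("Protein structure '", x$id, "': ", nrow(x$atoms),
      " heavy polymer atoms, ", length(x$ligands), " ligand(s)\n", sep = "")
  if (length(x$ligands))
    cat("  ligands:", paste(vapply(x$ligands, function(l)
      sprintf("%s (%d atoms)", l$group_name, nrow(l$atoms)), ""),
      collapse = ", "), "\n")
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Keeps heavy polymer atoms of model 1 only: hydrogens/deuteriums are
#' dropped, alternate locations are resolved to the highest-occupancy copy
#' (ties broken by file order), and HETATM groups on the ignore list are
#' discarded. Remaining HETATM groups with at least `min_ligand_atoms` heavy
#' atoms become ligands; smaller groups are dropped. The ligand filter
#' matters because the ligand-centric evaluation counts one case per
#' (protein, relevant ligand) pair.
#'
#' @param path PDB file.
#' @param ignore_groups HET group codes never treated as ligands (default
#'   [default_ignore_groups()]).
#' @param min_ligand_atoms minimum heavy-atom count for a HETATM group to be
#'   a relevant ligand (default 5).
#' @param id structure id; defaults to the file name without extension.
#' @return a `protein_structure`.
#' @export
read_structure <- function(path, ignore_groups = default_ignore_groups(),
                           min_ligand_atoms = 5L,
                           id = sub("\\.(pdb|ent)$", "", basename(path))) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom
  at$element <- toupper(trimws(at$elesy))
  no_elem <- is.na(at$element) | at$element == ""
  # fall back to the first letter of the atom name when the element column
  # is blank (common in hand-made files)
  at$element[no_elem] <- substr(gsub("[^A-Za-z].*$", "",
                                     trimws(at$elety[no_elem])), 1L, 1L)
  at <- at[!(at$element %in% c("H", "D")), , drop = FALSE]

  # altloc: keep the highest-occupancy copy per atom site, ties -> file order
  alt <- trimws(ifelse(is.na(at$alt), "", at$alt))
  if (any(alt != "")) {
    site <- paste(at$chain, at$resno, at$insert, at$resid, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    ord <- order(site, -occ, seq_len(nrow(at)))
    keep <- !duplicated(site[ord])
    at <- at[ord[keep], , drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }

  as_atoms <- function(d) data.frame(
    serial = d$eleno, element = d$element, name = trimws(d$elety),
    resname = trimws(d$resid), chain = ifelse(is.na(d$chain), "A", d$chain),
    resno = d$resno,
    inscode = ifelse(is.na(d$insert) | d$insert == "", "", d$insert),
    b = ifelse(is.na(d$b), 0, d$b),
    x = d$x, y = d$y, z = d$z, stringsAsFactors = FALSE)

  poly <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(poly) == 0L) stop("empty structure: no polymer atoms in ", path)

  het <- at[at$type == "HETATM" & !(trimws(at$resid) %in% ignore_groups), ,
            drop = FALSE]
  ligands <- list()
  if (nrow(het)) {
    key <- paste(het$chain, het$resno, het$insert, het$resid)
    for (k in unique(key)) {
      g <- het[key == k, , drop = FALSE]
      if (nrow(g) >= min_ligand_atoms)
        ligands[[length(ligands) + 1L]] <-
          ligand_group(as_atoms(g), trimws(g$resid[1L]))
    }
  }
  protein_structure(as_atoms(poly), ligands, id = id)
}

new_pocket <- function(pocket_id, original_rank, members, center,
                       original_score = NA_real_, volume = NA_real_) {
  if (length(members) < 1L) stop("pocket ", pocket_id, " has no member atoms")
  structure(list(pocket_id = as.character(pocket_id),
                 original_rank = as.integer(original_rank),
                 original_score = as.numeric(original_score),
                 members = sort(unique(as.integer(members))),
                 center = as.numeric(center),
                 volume = as.numeric(volume)),
            class = "pocket_prediction")
}

check_pocket_list <- function(pockets) {
  if (!length(pockets)) return(invisible(pockets))
  ids <- vapply(pockets, `[[`, "", "pocket_id")
  if (anyDuplicated(ids))
    stop("duplicate pocket_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rk <- vapply(pockets, `[[`, 1L, "original_rank")
  if (!setequal(rk, seq_along(pockets)))
    stop("pocket ranks are not a contiguous 1..K permutation: ",
         paste(sort(rk), collapse = ","))
  invisible(pockets)
}

resolve_members <- function(members, structure, where) {
  bad <- setdiff(members, structure$atoms$serial)
  if (length(bad))
    stop("pocket atoms not found in structure (", where, "): serial(s) ",
         paste(bad, collapse = ", "))
  invisible(members)
}

member_centroid <- function(members, structure) {
  m <- structure$atoms[match(members, structure$atoms$serial), c("x", "y", "z")]
  colMeans(as.matrix(m))
}

#' Read Fpocket-style pocket predictions
#'
#' Reads the version-1 Fpocket layout: a `pockets/` subdirectory with one
#' `pocketN_atm.pdb` per candidate, listing the member protein atoms and
#' carrying `Pocket Score` / `Volume` header records. The pocket index N is
#' the original rank. Pocket centers are the centroids of the member atoms
#' (coordinates taken from `structure`).
#'
#' @param dir Fpocket output directory (the one containing `pockets/`).
#' @param structure the matching `protein_structure`.
#' @return list of `pocket_prediction` objects ordered by rank.
#' @export
read_fpocket_pockets <- function(dir, structure) {
  pdir <- file.path(dir, "pockets")
  if (!dir.exists(pdir))
    stop("not an Fpocket output directory (no pockets/ subdirectory): ", dir)
  files <- list.files(pdir, pattern = "^pocket[0-9]+_atm\\.pdb$")
  if (!length(files)) stop("no pocketN_atm.pdb files under ", pdir)
  n <- as.integer(sub("^pocket([0-9]+)_atm\\.pdb$", "\\1", files))
  files <- files[order(n)]; n <- sort(n)
  pockets <- vector("list", length(files))
  for (i in seq_along(files)) {
    path <- file.path(pdir, files[i])
    lines <- readLines(path, warn = FALSE)
    hdr <- lines[startsWith(lines, "HEADER")]
    score <- header_value(hdr, "Pocket Score")
    volume <- header_value(hdr, "Volume")
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
      error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
    serials <- pdb$atom$eleno
    resolve_members(serials, structure, files[i])
    pockets[[i]] <- new_pocket(
      pocket_id = paste0("pocket", n[i]), original_rank = i,
      members = serials, center = member_centroid(serials, structure),
      original_score = score, volume = volume)
  }
  check_pocket_list(pockets)
}

header_value <- function(hdr, key) {
  hit <- grep(key, hdr, value = TRUE, fixed = TRUE)
  if (!length(hit)) return(NA_real_)
  suppressWarnings(as.numeric(sub("^.*:\\s*", "", hit[1L])))
}

#' Read pockets from the generic CSV format
#'
#' Columns: `pocket_id`, `rank`, `score`, `volume`, `atom_serials`
#' (semicolon-joined integers) and optionally `cx`,`cy`,`cz`. When a center
#' is supplied it is taken verbatim; otherwise the centroid of the member
#' atoms is used. Ranks must be a contiguous 1..K permutation and ids unique.
#'
#' @param path CSV file.
#' @param structure the matching `protein_structure`.
#' @return list of `pocket_prediction` objects ordered by rank.
#' @export
read_pocket_csv <- function(path, structure) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("pocket_id", "rank", "atom_serials")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("pocket CSV missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(d$pocket_id))
    stop("duplicate pocket_id in ", path)
  if (!setequal(d$rank, seq_len(nrow(d))))
    stop("pocket ranks are not contiguous 1..K in ", path)
  d <- d[order(d$rank), , drop = FALSE]
  has_center <- all(c("cx", "cy", "cz") %in% names(d))
  pockets <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    members <- as.integer(strsplit(d$atom_serials[i], ";", fixed = TRUE)[[1L]])
    resolve_members(members, structure, d$pocket_id[i])
    center <- if (has_center && all(is.finite(c(d$cx[i], d$cy[i], d$cz[i]))))
      c(d$cx[i], d$cy[i], d$cz[i]) else member_centroid(members, structure)
    pockets[[i]] <- new_pocket(
      d$pocket_id[i], d$rank[i], members, center,
      original_score = if ("score" %in% names(d)) d$score[i] else NA_real_,
      volume = if ("volume" %in% names(d)) d$volume[i] else NA_real_)
  }
  check_pocket_list(pockets)
}

#' Write pockets to the generic CSV format
#'
#' Inverse of [read_pocket_csv()]; centers are always written explicitly so
#' a write/read round trip reproduces the pocket values exactly.
#'
#' @param pockets list of `pocket_prediction` objects.
#' @param path output CSV file.
#' @export
write_pocket_csv <- function(pockets, path) {
  d <- data.frame(
    pocket_id = vapply(pockets, `[[`, "", "pocket_id"),
    rank = vapply(pockets, `[[`, 1L, "original_rank"),
    score = vapply(pockets, `[[`, 1, "original_score"),
    volume = vapply(pockets, `[[`, 1, "volume"),
    atom_serials = vapply(pockets, function(p) paste(p$members, collapse = ";"), ""),
    cx = vapply(pockets, function(p) p$center[1L], 1),
    cy = vapply(pockets, function(p) p$center[2L], 1),
    cz = vapply(pockets, function(p) p$center[3L], 1),
    stringsAsFactors = FALSE)
  write.csv(d[order(d$rank), , drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a re-ranked pocket list
#'
#' @param ranked a `ranked_pockets` data.frame from [rescore_pockets()] or
#'   [rank_pockets()].
#' @param path output CSV file.
#' @return `path`, invisibly. Rows are sorted by `new_rank`.
#' @export
write_rescored <- function(ranked, path) {
  cols <- c("pocket_id", "original_rank", "new_rank", "pscore", "n_points")
  d <- as.data.frame(ranked)[, cols, drop = FALSE]
  names(d)[names(d) == "n_points"] <- "n_inner_points"
  write.csv(d[order(d$new_rank), , drop = FALSE], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pocket_prediction <- function(x, ...) {
  cat(sprintf("Pocket %s (rank %d): %d atoms, center (%.2f, %.2f, %.2f)",
              x$pocket_id, x$original_rank, length(x$members),
              x$center[1], x$center[2], x$center[3]))
  if (is.finite(x$volume)) cat(sprintf(", volume %.1f A^3", x$volume))
  cat("\n")
  invisible(x)
}
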