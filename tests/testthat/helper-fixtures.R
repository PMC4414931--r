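# Shared fixture builders: everything is generated in code at test time.

# a bare atoms data.frame from coordinate rows
atoms_df <- function(xyz, element = "C", name = "CA", resname = "GLY",
                     b = 0, serial = NULL, resno = NULL) {
  xyz <- matrix(xyz, ncol = 3L)
  n <- nrow(xyz)
  data.frame(
    serial = if (is.null(serial)) seq_len(n) else serial,
    element = rep_len(element, n), name = rep_len(name, n),
    resname = rep_len(resname, n), chain = "A",
    resno = if (is.null(resno)) seq_len(n) else resno,
    inscode = "", b = rep_len(b, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
}

# structure with atoms scattered randomly in a box, one residue per atom,
# residues/atom names drawn from the bundled tables
random_structure <- function(n = 40, seed = 1, span = 15, tables = test_tables()) {
  set.seed(seed)
  keys <- rownames(tables$atom_table)
  pick <- sample(keys, n, replace = TRUE)
  parts <- strsplit(pick, ".", fixed = TRUE)
  at <- atoms_df(matrix(runif(3 * n, -span, span), ncol = 3L),
                 b = round(runif(n, 5, 60), 2))
  at$resname <- vapply(parts, `[[`, "", 1L)
  at$name <- vapply(parts, `[[`, "", 2L)
  at$element <- substr(at$name, 1L, 1L)
  protein_structure(at, id = paste0("rand", seed))
}

# a cached copy of the bundled tables (loading parses four CSVs)
test_tables <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- property_tables()
    tab
  }
})

# minimal PDB text on disk via bio3d, returning the path
write_test_pdb <- function(atoms, het_resnames = character(), dir = tempdir(),
                           name = "test") {
  path <- file.path(dir, paste0(name, ".pdb"))
  bio3d::write.pdb(
    file = path,
    type = ifelse(atoms$resname %in% het_resnames, "HETATM", "ATOM"),
    eleno = atoms$serial, elety = atoms$name, resid = atoms$resname,
    chain = atoms$chain, resno = atoms$resno,
    xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
    o = rep(1, nrow(atoms)), b = atoms$b, elesy = atoms$element)
  path
}

# an Fpocket-style output directory for a structure: one pocketN_atm.pdb per
# member-serial set, with score/volume header records
write_fpocket_dir <- function(structure, member_sets, scores, volumes,
                              dir = tempfile("fp")) {
  pdir <- file.path(dir, "pockets")
  dir.create(pdir, recursive = TRUE)
  for (i in seq_along(member_sets)) {
    at <- structure$atoms[match(member_sets[[i]], structure$atoms$serial), ]
    tmp <- write_test_pdb(at, dir = tempdir(), name = sprintf("fp_tmp%d", i))
    lines <- readLines(tmp)
    lines <- lines[startsWith(lines, "ATOM")]
    hdr <- c(sprintf("HEADER %d - Pocket Score : %.4f", i - 1L, scores[i]),
             sprintf("HEADER %d - Volume : %.2f", i - 1L, volumes[i]))
    writeLines(c(hdr, lines, "END"),
               file.path(pdir, sprintf("pocket%d_atm.pdb", i)))
  }
  dir
}

# small cached toy protein + pockets for pipeline tests
test_toy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(seed = 303, n_proteins = 1)
      toy <- make_toy_protein(spec, 1)
      pockets <- make_decoy_pockets(toy$structure, toy$true_pocket,
                                    n = 3, seed = 303)
      cache <<- list(toy = toy, pockets = pockets, spec = spec)
    }
    cache
  }
})

# small cached forest trained on two toy proteins
test_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- fixture_spec(seed = 404, n_proteins = 2)
      corpus <- lapply(1:2, function(i) {
        toy <- make_toy_protein(spec, i)
        list(structure = toy$structure,
             pockets = make_decoy_pockets(toy$structure, toy$true_pocket,
                                          n = 2, seed = i))
      })
      ds <- build_point_dataset(corpus, test_tables())
      cache <<- ligandability_forest(ds, num_trees = 60, seed = 404)
    }
    cache
  }
})

# build a pocket over given member serials with centroid center
new_pocket_for_test <- function(id, rank, members, structure,
                                score = NA_real_, volume = NA_real_) {
  pocketrank:::new_pocket(
    id, rank, members,
    pocketrank:::member_centroid(members, structure), score, volume)
}
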