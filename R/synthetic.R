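# Synthetic toy structures and point datasets. These emulate the study
# conditions at desk scale: small pseudo-globular proteins with one planted
# concave binding site holding a multi-atom ring ligand, plus convex decoy
# pockets. Signal is planted both geometrically (the concavity) and
# chemically (lining composition and a B-factor shift), because the
# classifier sees only local chemistry.

#' Specification of a synthetic fixture set
#'
#' @param seed master integer seed; every derived quantity is reproducible
#'   from it.
#' @param n_proteins number of toy proteins in a benchmark corpus.
#' @param n_decoys decoy pockets per protein (default 4, giving 5 candidate
#'   pockets per protein).
#' @param effect_size chemical signal strength: the planted lining atoms'
#'   B-factors are shifted down by `effect_size` standard deviations.
#' @param ligand_size heavy atoms in the ring ligand (default 6).
#' @param globule_radius radius of the pseudo-globular shell in Angstrom.
#' @param noise_sd coordinate jitter s.d. in Angstrom.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_proteins = 60L, n_decoys = 4L,
                         effect_size = 1.5, ligand_size = 6L,
                         globule_radius = 11, noise_sd = 0.3) {
  stopifnot(effect_size >= 0, n_decoys >= 0L, ligand_size >= 5L,
            globule_radius > 5)
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 n_decoys = as.integer(n_decoys), effect_size = effect_size,
                 ligand_size = as.integer(ligand_size),
                 globule_radius = globule_radius, noise_sd = noise_sd),
            class = "fixture_spec")
}

# deterministic sub-seed below 2^31
sub_seed <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) * 7919 + index * 104729 + salt) %% 2147483647)
}

# quasi-even directions on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# residue pools: (resname, representative atom, element)
shell_pool <- data.frame(
  resname = c("GLY", "SER", "ALA", "LYS", "GLU", "THR", "ASN", "VAL",
              "ASP", "LEU"),
  name = c("CA", "OG", "CB", "NZ", "OE1", "CG2", "ND2", "CG1", "OD1", "CD1"),
  element = c("C", "O", "C", "N", "O", "C", "N", "C", "O", "C"),
  stringsAsFactors = FALSE)

lining_pool <- data.frame(
  resname = c("TRP", "PHE", "TYR", "MET", "HIS", "ILE"),
  name = c("CZ2", "CZ", "OH", "SD", "NE2", "CD1"),
  element = c("C", "C", "O", "S", "N", "C"),
  stringsAsFactors = FALSE)

#' Generate one toy protein with a planted binding site
#'
#' Builds a jittered spherical shell of single-atom residues (one heavy atom
#' per residue, drawn from a mixed composition pool), carves a concave
#' crater around the +z pole whose lining atoms come from an aromatic-rich
#' "ligandable" pool with B-factors shifted down by
#' `effect_size * 10`, and places a planar ring ligand (HETATM group `LIG`)
#' inside the crater. Shell B-factors are N(30, 10); crater B-factors are
#' N(30 - 10 * effect_size, 10), both floored at 1.
#'
#' @param spec a `fixture_spec`.
#' @param index protein index within the corpus (drives the sub-seed).
#' @return list with `structure` (a `protein_structure` including the
#'   ligand), `true_pocket` (a `pocket_prediction` over the crater atoms,
#'   rank/volume unset), `ligand` and `pdb_lines` (the structure as PDB
#'   text, byte-identical for a fixed seed).
#' @export
make_toy_protein <- function(spec, index = 1L) {
  set.seed(sub_seed(spec$seed, index))
  R <- spec$globule_radius
  depth <- 4
  cap_angle <- 35 * pi / 180
  n_shell <- round(4 * pi * R^2 / 8)

  dirs <- fibonacci_sphere(n_shell)
  polar <- acos(pmin(1, pmax(-1, dirs[, 3])))
  in_cap <- polar <= cap_angle
  radius <- ifelse(in_cap, R - depth, R)
  xyz <- dirs * radius + matrix(rnorm(3 * n_shell, 0, spec$noise_sd),
                                ncol = 3L)

  pool_idx <- ifelse(in_cap,
                     sample.int(nrow(lining_pool), n_shell, replace = TRUE),
                     sample.int(nrow(shell_pool), n_shell, replace = TRUE))
  pool <- shell_pool[pool_idx, , drop = FALSE]
  pool[in_cap, ] <- lining_pool[pool_idx[in_cap], , drop = FALSE]
  b <- pmax(1, rnorm(n_shell, 30 - ifelse(in_cap, 10 * spec$effect_size, 0), 10))

  # filled core: buried carbon layers occlude the inward-facing hemisphere of
  # every shell atom, so only the outer (and crater) surface is exposed
  core <- do.call(rbind, lapply(c(3, R - 5.5), function(rc)
    fibonacci_sphere(max(6L, round(4 * pi * rc^2 / 8))) * rc))
  n_core <- nrow(core)
  in_cap <- c(in_cap, rep(FALSE, n_core))
  xyz <- rbind(xyz, core)
  pool <- rbind(pool, data.frame(resname = "GLY", name = "CA", element = "C",
                                 stringsAsFactors = FALSE)[rep(1L, n_core), ])
  b <- c(b, pmax(1, rnorm(n_core, 30, 10)))
  n_all <- n_shell + n_core

  atoms <- data.frame(
    serial = seq_len(n_all), element = pool$element, name = pool$name,
    resname = pool$resname, chain = "A", resno = seq_len(n_all),
    inscode = "", b = round(b, 2), x = round(xyz[, 1], 3),
    y = round(xyz[, 2], 3), z = round(xyz[, 3], 3),
    stringsAsFactors = FALSE)

  # ring ligand inside the crater, plane normal to the crater axis
  nl <- spec$ligand_size
  ring_r <- 1.5 / (2 * sin(pi / nl))
  ang <- 2 * pi * (seq_len(nl) - 1L) / nl
  lz <- R - depth + 2.5
  lig_atoms <- data.frame(
    serial = n_all + seq_len(nl), element = "C",
    name = paste0("C", seq_len(nl)), resname = "LIG", chain = "A",
    resno = n_all + 1L, inscode = "", b = 30,
    x = round(ring_r * cos(ang), 3), y = round(ring_r * sin(ang), 3),
    z = round(rep(lz, nl), 3), stringsAsFactors = FALSE)
  lig <- ligand_group(lig_atoms, "LIG")

  st <- protein_structure(atoms, list(lig),
                          id = sprintf("toy%03d", index))
  true_pocket <- new_pocket("true_site", 1L, atoms$serial[in_cap],
                            member_centroid(atoms$serial[in_cap], st))
  list(structure = st, true_pocket = true_pocket, ligand = lig,
       pdb_lines = structure_to_pdb(st))
}

# render a structure (polymer + ligands) as PDB text via bio3d
structure_to_pdb <- function(st) {
  all_at <- rbind(st$atoms,
                  do.call(rbind, lapply(st$ligands, `[[`, "atoms")))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  is_het <- all_at$resname %in% vapply(st$ligands, `[[`, "", "group_name")
  bio3d::write.pdb(
    file = tmp, type = ifelse(is_het, "HETATM", "ATOM"),
    eleno = all_at$serial, elety = all_at$name, resid = all_at$resname,
    chain = all_at$chain, resno = all_at$resno,
    xyz = as.numeric(t(as.matrix(all_at[, c("x", "y", "z")]))),
    o = rep(1, nrow(all_at)), b = all_at$b, elesy = all_at$element)
  readLines(tmp)
}

#' Add decoy pockets and assign candidate ranks
#'
#' Places `n` decoy pockets on random convex surface patches whose centroids
#' lie at least 10 Angstrom from every ligand atom (so no decoy can pass a
#' 4 Angstrom detection criterion), merges them with the true pocket, draws
#' a volume for every pocket from a common log-normal (so neither volume nor
#' the volume-descending original rank carries information about which
#' pocket is real), and assigns `original_rank` by decreasing volume.
#'
#' @param structure a `protein_structure` (with its ligand present).
#' @param true_pocket the planted `pocket_prediction`.
#' @param n number of decoys.
#' @param seed integer seed.
#' @return list of `pocket_prediction` with contiguous ranks 1..(n+1).
#' @export
make_decoy_pockets <- function(structure, true_pocket, n = 4L, seed = 1L) {
  set.seed(sub_seed(seed, n, salt = 17L))
  at <- structure$atoms
  L <- do.call(rbind, lapply(structure$ligands,
                             function(l) coords_matrix(l$atoms)))
  A <- coords_matrix(at)
  decoys <- list()
  taken <- matrix(numeric(), 0L, 3L)
  guard <- 0L
  while (length(decoys) < n) {
    guard <- guard + 1L
    if (guard > 500L) stop("could not place decoy pockets; structure too small")
    seed_atom <- sample.int(nrow(at), 1L)
    members <- at$serial[sqrt(rowSums(sweep(A, 2L, A[seed_atom, ], `-`)^2)) <= 5.5]
    ctr <- member_centroid(members, structure)
    if (!is.null(L) && sqrt(min(rowSums(sweep(L, 2L, ctr, `-`)^2))) < 10) next
    if (nrow(taken) && sqrt(min(rowSums(sweep(taken, 2L, ctr, `-`)^2))) < 6) next
    taken <- rbind(taken, ctr)
    decoys[[length(decoys) + 1L]] <-
      new_pocket(paste0("decoy", length(decoys) + 1L), 1L, members, ctr)
  }
  pockets <- c(list(true_pocket), decoys)
  vol <- round(exp(rnorm(length(pockets), log(300), 0.5)), 1)
  ord <- order(-vol)
  out <- vector("list", length(pockets))
  for (i in seq_along(ord)) {
    p <- pockets[[ord[i]]]
    p$original_rank <- i
    p$volume <- vol[ord[i]]
    out[[i]] <- p
  }
  check_pocket_list(out)
}

#' Simulate an abstract labeled point dataset
#'
#' Draws feature vectors from a unit-variance normal; positive rows are
#' shifted by `effect_size` on the first `shifted_features` features. The
#' given class imbalance is preserved exactly (default 15:1, the natural
#' ratio of pocket-point corpora). Rows are assigned round-robin to
#' `n_groups` pseudo-proteins for grouped cross-validation.
#'
#' @param n_pos,n_neg class sizes (defaults 125 / 1875: 2000 points at 15:1).
#' @param effect_size mean shift of the positive class in feature s.d. units.
#' @param n_features total feature count (default 19, the size of the
#'   default IFV schema).
#' @param shifted_features how many leading features carry the shift.
#' @param seed integer seed.
#' @param n_groups pseudo-protein count.
#' @return a `point_dataset` with `schema_version = "simulated"`.
#' @export
simulate_point_dataset <- function(n_pos = 125L, n_neg = 1875L,
                                   effect_size = 2, n_features = 19L,
                                   shifted_features = 5L, seed = 1L,
                                   n_groups = 10L) {
  stopifnot(n_pos >= 0L, n_neg >= 0L, shifted_features <= n_features)
  set.seed(sub_seed(seed, n_pos + n_neg, salt = 29L))
  n <- n_pos + n_neg
  X <- matrix(rnorm(n * n_features), n, n_features)
  label <- c(rep(1L, n_pos), rep(0L, n_neg))
  if (n_pos > 0L && shifted_features > 0L)
    X[label == 1L, seq_len(shifted_features)] <-
      X[label == 1L, seq_len(shifted_features)] + effect_size
  colnames(X) <- paste0("f", seq_len(n_features))
  perm <- sample.int(n)
  point_dataset(X[perm, , drop = FALSE], label[perm],
                protein_id = paste0("sim", rep_len(seq_len(n_groups), n)),
                schema_version = "simulated")
}

#' Generate a benchmark corpus on disk
#'
#' Writes `n_proteins` toy structures (PDB), their candidate pocket lists
#' (generic CSV, true pocket plus decoys) and a manifest CSV binding them
#' together. The manifest is consumable end-to-end by
#' [build_point_dataset()], [ligandability_forest()], [rescore_pockets()]
#' and [success_rates()].
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame (columns `protein_id`, `pdb`, `pockets`,
#'   `n_ligands`), invisibly also written to `manifest.csv` in `dir`.
#' @export
make_benchmark <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", spec$n_proteins)
  for (i in seq_len(spec$n_proteins)) {
    toy <- make_toy_protein(spec, i)
    pockets <- make_decoy_pockets(toy$structure, toy$true_pocket,
                                  n = spec$n_decoys,
                                  seed = sub_seed(spec$seed, i, salt = 3L))
    pdb_path <- file.path(dir, paste0(toy$structure$id, ".pdb"))
    writeLines(toy$pdb_lines, pdb_path)
    csv_path <- file.path(dir, paste0(toy$structure$id, "_pockets.csv"))
    write_pocket_csv(pockets, csv_path)
    rows[[i]] <- data.frame(
      protein_id = toy$structure$id, pdb = basename(pdb_path),
      pockets = basename(csv_path), n_ligands = 1L,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  manifest
}

#' Load a benchmark corpus from a manifest
#'
#' @param dir directory written by [make_benchmark()].
#' @param ids optional subset of protein ids.
#' @return list of entries `list(structure, pockets)` suitable for
#'   [build_point_dataset()] and evaluation.
#' @export
load_benchmark <- function(dir, ids = NULL) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  if (!is.null(ids)) manifest <- manifest[manifest$protein_id %in% ids, ]
  lapply(seq_len(nrow(manifest)), function(i) {
    st <- read_structure(file.path(dir, manifest$pdb[i]),
                         id = manifest$protein_id[i])
    list(structure = st,
         pockets = read_pocket_csv(file.path(dir, manifest$pockets[i]), st))
  })
}
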