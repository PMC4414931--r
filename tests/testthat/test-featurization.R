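test_that("the linear distance weight has exact endpoints and symmetry", {
  expect_identical(weight_linear(0), 1)
  expect_identical(weight_linear(8), 0)
  expect_identical(weight_linear(4), 0.5)
  a <- seq(0, 8, by = 0.25)
  expect_equal(weight_linear(a) + weight_linear(8 - a), rep(1, length(a)))
  expect_error(weight_linear(-0.1), "neighborhood")
  expect_error(weight_linear(8.1), "neighborhood")
})

test_that("the atomic neighborhood is inclusive at 8 A and excludes buried atoms", {
  at <- atoms_df(rbind(c(7.9, 0, 0), c(8.1, 0, 0), c(3, 0, 0)))
  st <- protein_structure(at)
  nb <- atomic_neighborhood(c(0, 0, 0), exposed = c(1L, 2L), st)
  expect_equal(nb$serial, 1L)           # 8.1 outside, serial 3 not exposed
  expect_equal(nb$distance, 7.9)
  nb8 <- atomic_neighborhood(c(0.1, 0, 0), exposed = 1:3, st)
  expect_true(all(c(1L, 3L) %in% nb8$serial))
})

test_that("AFVs inherit residue features and look up atomic features", {
  tab <- test_tables()
  ile_ca <- atoms_df(c(0, 0, 0), resname = "ILE", name = "CA")
  afv <- compute_afv(ile_ca, tab)
  expect_equal(unname(afv["agg_hydropathy"]), 4.5)     # Kyte-Doolittle ILE
  ile_cd1 <- atoms_df(c(1, 0, 0), resname = "ILE", name = "CD1")
  afv2 <- compute_afv(ile_cd1, tab)
  res_block <- paste0("agg_", colnames(tab$residue_table))
  expect_equal(afv[res_block], afv2[res_block])
  expect_false(all(afv == afv2))       # atomic block differs (CA vs CD1)
  # unknown residue warns for both the residue and the (residue, atom) row
  expect_warning(expect_warning(afv3 <- compute_afv(
    atoms_df(c(0, 0, 0), resname = "XYZ", name = "CA"), tab), "XYZ"))
  expect_true(all(afv3[res_block] == 0))
})

test_that("protrusion index matches a brute-force count and caps at 15", {
  st <- random_structure(50, seed = 21)
  empty <- protrusion_index(c(500, 500, 500), st)
  expect_equal(empty, 15)
  A <- as.matrix(st$atoms[, c("x", "y", "z")])
  for (p in list(c(0, 0, 0), c(5, -3, 2), c(12, 12, -12))) {
    n <- sum(sqrt(colSums((t(A) - p)^2)) <= 10)
    vs <- 4 / 3 * pi * 1000
    want <- if (n == 0) 15 else min(15, (vs - n * 20.1) / (n * 20.1))
    expect_equal(protrusion_index(p, st), want)
  }
  # denser neighborhood => strictly smaller index
  dense <- protein_structure(atoms_df(matrix(runif(90, -3, 3), ncol = 3)))
  sparse <- protein_structure(atoms_df(matrix(c(1, 1, 1, 4, 4, 4), ncol = 3,
                                              byrow = TRUE)))
  expect_lt(protrusion_index(c(0, 0, 0), dense),
            protrusion_index(c(0, 0, 0), sparse))
})

test_that("point features count donors/acceptors and average B-factors", {
  tab <- test_tables()
  st <- protein_structure(atoms_df(c(0, 0, 0)))
  empty <- compute_point_features(c(100, 100, 100), st,
                                  atomic_neighborhood(c(100, 100, 100), 1L, st),
                                  tab)
  expect_equal(unname(empty), c(0, 0, 0, 15))

  ser <- atoms_df(rbind(c(2, 0, 0), c(4, 0, 0)), resname = "SER",
                  name = c("OG", "CB"), element = c("O", "C"), b = c(10, 30))
  st2 <- protein_structure(ser)
  nb <- atomic_neighborhood(c(0, 0, 0), 1:2, st2)
  fv <- compute_point_features(c(0, 0, 0), st2, nb, tab)
  expect_equal(unname(fv["donors"]), 1)      # OG is donor and acceptor
  expect_equal(unname(fv["acceptors"]), 1)
  expect_equal(unname(fv["mean_b"]), 20)
})

test_that("IFV aggregation is the distance-weighted AFV sum", {
  tab <- test_tables()
  at <- atoms_df(c(0, 0, 0), resname = "TRP", name = "NE1", element = "N")
  st <- protein_structure(at)
  nb <- atomic_neighborhood(c(0, 0, 0), 1L, st)    # one neighbor at d = 0
  fv <- compute_point_features(c(0, 0, 0), st, nb, tab)
  ifv <- aggregate_ifv(nb, fv, tab)
  afv <- suppressWarnings(compute_afv(at, tab))
  n_agg <- length(afv)
  expect_equal(unname(ifv[seq_len(n_agg)]), unname(afv))

  # two identical atoms at d = 4 sum to exactly one AFV (2 * 0.5)
  at2 <- atoms_df(rbind(c(4, 0, 0), c(0, 4, 0)), resname = "TRP",
                  name = "NE1", element = "N")
  st2 <- protein_structure(at2)
  nb2 <- atomic_neighborhood(c(0, 0, 0), 1:2, st2)
  ifv2 <- aggregate_ifv(nb2, compute_point_features(c(0, 0, 0), st2, nb2, tab),
                        tab)
  expect_equal(unname(ifv2[seq_len(n_agg)]), unname(afv))

  # empty neighborhood: zero aggregate block, FV appended
  nb0 <- atomic_neighborhood(c(100, 0, 0), 1:2, st2)
  ifv0 <- aggregate_ifv(nb0, compute_point_features(c(100, 0, 0), st2, nb0, tab),
                        tab)
  expect_true(all(ifv0[seq_len(n_agg)] == 0))
})

test_that("vectorized featurization agrees with the per-point route to 1e-9", {
  tab <- test_tables()
  st <- random_structure(40, seed = 31)
  exposed <- solvent_exposed_atoms(st, tables = tab)
  set.seed(32)
  P <- matrix(runif(30, -12, 12), ncol = 3L)
  X <- pocketrank:::featurize_points(P, st, exposed, tab)
  for (i in seq_len(nrow(P))) {
    nb <- atomic_neighborhood(P[i, ], exposed, st)
    fv <- compute_point_features(P[i, ], st, nb, tab)
    expect_equal(unname(X[i, ]), unname(aggregate_ifv(nb, fv, tab)),
                 tolerance = 1e-9)
  }
})

test_that("features are local: atoms beyond the cutoffs cannot matter", {
  tab <- test_tables()
  st <- random_structure(35, seed = 41, span = 10)
  far <- atoms_df(c(40, 40, 40), serial = 999L, resno = 999L)
  st1 <- protein_structure(rbind(st$atoms, far), id = "a")
  far2 <- far; far2$x <- 60; far2$y <- 55
  st2 <- protein_structure(rbind(st$atoms, far2), id = "b")
  exposed1 <- solvent_exposed_atoms(st1, tables = tab)
  exposed2 <- solvent_exposed_atoms(st2, tables = tab)
  P <- matrix(c(0, 0, 0, 3, -2, 5), ncol = 3L, byrow = TRUE)
  expect_identical(pocketrank:::featurize_points(P, st1, exposed1, tab),
                   pocketrank:::featurize_points(P, st2, exposed2, tab))
})

test_that("dataset building is additive over pockets and deterministic", {
  tab <- test_tables()
  toy <- test_toy()
  st <- toy$toy$structure
  corpus <- list(list(structure = st, pockets = toy$pockets))
  ds <- build_point_dataset(corpus, tab)
  pts <- sample_sas_points(st, tables = tab)
  per_pocket <- vapply(toy$pockets, function(p)
    nrow(select_inner_points(pts, p, st)), 1L)
  expect_equal(nrow(ds$features), sum(per_pocket))
  expect_equal(as.vector(table(ds$pocket_id)[unique(ds$pocket_id)]),
               per_pocket[match(unique(ds$pocket_id),
                                vapply(toy$pockets, `[[`, "", "pocket_id"))])
  expect_identical(ds, build_point_dataset(corpus, tab))
  expect_equal(sum(ds$class_counts), nrow(ds$features))

  # a ligand-free protein yields all negatives
  st0 <- protein_structure(st$atoms, list(), id = "apo")
  ds0 <- build_point_dataset(list(list(structure = st0,
                                       pockets = toy$pockets)), tab)
  expect_true(all(ds0$label == 0L))
})

test_that("point datasets round-trip through CSV", {
  ds <- simulate_point_dataset(20, 80, effect_size = 1, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_point_csv(ds, path)
  back <- read_point_csv(path)
  expect_equal(back$schema_version, ds$schema_version)
  expect_equal(back$label, ds$label)
  expect_equal(back$features, ds$features, tolerance = 1e-12)
})
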