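# independent vertex-count oracle: subdivide every icosahedron face on its
# own, collect all triangle corners, deduplicate by rounded coordinates
brute_icosphere_count <- function(level) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- list(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
            c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
            c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
            c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  tris <- lapply(f, function(idx) list(v[idx[1], ], v[idx[2], ], v[idx[3], ]))
  for (l in seq_len(level)) {
    tris <- do.call(c, lapply(tris, function(tr) {
      m <- lapply(list(c(1, 2), c(2, 3), c(3, 1)), function(e) {
        p <- tr[[e[1]]] + tr[[e[2]]]
        p / sqrt(sum(p^2))
      })
      list(list(tr[[1]], m[[1]], m[[3]]), list(tr[[2]], m[[2]], m[[1]]),
           list(tr[[3]], m[[3]], m[[2]]), list(m[[1]], m[[2]], m[[3]]))
    }))
  }
  pts <- do.call(rbind, lapply(tris, function(tr) do.call(rbind, tr)))
  nrow(unique(round(pts, 9)))
}

test_that("icosphere vertex counts follow 10*4^k + 2", {
  for (k in 0:2) {
    v <- icosphere_vertices(k)
    expect_equal(nrow(v), 10 * 4^k + 2)
    expect_equal(nrow(v), brute_icosphere_count(k))
    expect_equal(sqrt(rowSums(v^2)), rep(1, nrow(v)), tolerance = 1e-12)
  }
})

test_that("a lone carbon atom yields 162 points on its expanded sphere", {
  st <- protein_structure(atoms_df(c(0, 0, 0)))
  pts <- sample_sas_points(st, probe = 1.6, tess_level = 2L,
                           tables = test_tables())
  expect_equal(nrow(pts), 162L)
  r <- sqrt(pts$x^2 + pts$y^2 + pts$z^2)
  expect_equal(r, rep(3.30, 162L), tolerance = 1e-6)
})

test_that("distant atoms contribute additively, close atoms occlude", {
  tab <- test_tables()
  far <- protein_structure(atoms_df(rbind(c(0, 0, 0), c(100, 0, 0))))
  expect_equal(nrow(sample_sas_points(far, tables = tab)), 324L)

  near <- protein_structure(atoms_df(rbind(c(0, 0, 0), c(1, 0, 0))))
  pts <- sample_sas_points(near, tables = tab)
  expect_lt(nrow(pts), 324L)
  d1 <- sqrt(pts$x^2 + pts$y^2 + pts$z^2)
  d2 <- sqrt((pts$x - 1)^2 + pts$y^2 + pts$z^2)
  expect_true(all(d1 >= 3.30 - 1e-6 & d2 >= 3.30 - 1e-6))

  # brute-force occlusion oracle over every candidate vertex
  v <- icosphere_vertices(2L) * 3.30
  cand <- rbind(v, sweep(v, 2L, c(1, 0, 0), `+`))
  keep <- apply(cand, 1L, function(p) {
    sqrt(sum(p^2)) >= 3.30 - 1e-6 & sqrt(sum((p - c(1, 0, 0))^2)) >= 3.30 - 1e-6
  })
  expect_equal(nrow(pts), sum(keep))
})

test_that("surface points never lie inside any expanded sphere", {
  st <- random_structure(30, seed = 11)
  tab <- test_tables()
  pts <- sample_sas_points(st, tables = tab)
  A <- as.matrix(st$atoms[, c("x", "y", "z")])
  r <- vdw_radius(st$atoms$element, tab) + 1.6
  P <- as.matrix(pts[, c("x", "y", "z")])
  D <- sqrt(outer(rowSums(P^2), rowSums(A^2), `+`) - 2 * P %*% t(A))
  expect_true(all(sweep(D, 2L, r, `-`) >= -1e-6))
})

test_that("an atom buried under a covering shell is not exposed", {
  shell <- icosphere_vertices(1L) * 3.0
  st <- protein_structure(atoms_df(rbind(c(0, 0, 0), shell)))
  exposed <- solvent_exposed_atoms(st, tables = test_tables())
  expect_false(1L %in% exposed)
  # outer shell atoms remain exposed
  expect_true(all(2:nrow(st$atoms) %in% exposed))
})

test_that("the inner-point belt is inclusive at exactly 4.0 A", {
  st <- protein_structure(atoms_df(c(0, 0, 0)))
  pocket <- new_pocket_for_test("p", 1L, 1L, st)
  pts <- data.frame(x = c(4.0, 4.000001, 0.5), y = 0, z = 0,
                    atom_serial = 1L)
  inner <- select_inner_points(pts, pocket, st, belt = 4.0)
  expect_equal(inner$x, c(4.0, 0.5))
  expect_true(all(inner$pocket_id == "p"))
})

test_that("labeling is inclusive at exactly 2.5 A and defaults to negative", {
  lig <- ligand_group(atoms_df(c(0, 0, 0), name = "C1", resname = "LIG"),
                      "LIG")
  pts <- data.frame(x = c(2.5, 2.6, 0.1), y = 0, z = 0, atom_serial = 1L,
                    pocket_id = "p", label = NA_character_)
  lab <- label_points(pts, list(lig))
  expect_equal(lab$label, c("positive", "negative", "positive"))
  expect_equal(label_points(pts, list())$label, rep("negative", 3L))
})

test_that("belt and label thresholds are monotone; labels match brute force", {
  toy <- test_toy()
  st <- toy$toy$structure
  pts <- sample_sas_points(st, tables = test_tables())
  pocket <- toy$pockets[[1]]
  sizes <- vapply(c(3, 4, 5), function(b)
    nrow(select_inner_points(pts, pocket, st, belt = b)), 1L)
  expect_true(all(diff(sizes) >= 0))

  inner <- select_inner_points(pts, pocket, st, belt = 4)
  lab1 <- label_points(inner, st$ligands, threshold = 2.5)
  lab2 <- label_points(inner, st$ligands, threshold = 3.5)
  expect_true(all(lab2$label[lab1$label == "positive"] == "positive"))

  # naive all-pairs double loop oracle
  L <- as.matrix(st$ligands[[1]]$atoms[, c("x", "y", "z")])
  for (i in seq_len(nrow(inner))) {
    dmin <- min(apply(L, 1L, function(a)
      sqrt(sum((a - c(inner$x[i], inner$y[i], inner$z[i]))^2))))
    expect_equal(lab1$label[i] == "positive", dmin <= 2.5)
  }
})

test_that("inner points are a coordinate-preserving subset of the input", {
  toy <- test_toy()
  st <- toy$toy$structure
  pts <- sample_sas_points(st, tables = test_tables())
  inner <- select_inner_points(pts, toy$pockets[[2]], st)
  key <- function(d) paste(round(d$x, 9), round(d$y, 9), round(d$z, 9))
  expect_true(all(key(inner) %in% key(pts)))
})
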