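make_ligand <- function(xyz) {
  xyz <- matrix(xyz, ncol = 3L)
  ligand_group(atoms_df(xyz, name = paste0("C", seq_len(nrow(xyz))),
                        resname = "LIG", resno = 1L), "LIG")
}

# a ranking table built directly (pocket centers known, ranks as given)
ranked_table <- function(centers, new_rank = seq_len(nrow(centers))) {
  d <- data.frame(pocket_id = paste0("p", seq_len(nrow(centers))),
                  original_rank = seq_len(nrow(centers)),
                  pscore = rev(seq_len(nrow(centers))),
                  n_points = 1L, cx = centers[, 1], cy = centers[, 2],
                  cz = centers[, 3], volume = NA_real_, new_rank = new_rank)
  class(d) <- c("ranked_pockets", "data.frame")
  d
}

test_that("detection distances match their definitions", {
  lig <- make_ligand(rbind(c(3, 0, 0), c(5, 0, 0)))
  expect_equal(dca(c(0, 0, 0), lig), 3.0)
  expect_equal(dcc(c(0, 0, 0), lig), 4.0)     # centroid at (4,0,0)
  expect_equal(dca(c(3, 0, 0), lig), 0.0)
  expect_equal(dcc(c(4, 0, 0), lig), 0.0)

  # ring ligand: center-to-centroid can be far below center-to-atom
  hexagon <- cbind(2 * cos(2 * pi * (0:5) / 6), 2 * sin(2 * pi * (0:5) / 6), 0)
  ring <- make_ligand(hexagon)
  expect_equal(dcc(c(0, 0, 0), ring), 0)
  expect_equal(dca(c(0, 0, 0), ring), 2)
  expect_lt(dcc(c(0, 0, 0), ring), dca(c(0, 0, 0), ring))
})

test_that("dca and dcc agree with naive all-pairs recomputation", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(1:8, 1)
    xyz <- matrix(runif(3 * n, -10, 10), ncol = 3L)
    lig <- make_ligand(xyz)
    ctr <- runif(3, -10, 10)
    d_naive <- min(apply(xyz, 1L, function(a) sqrt(sum((a - ctr)^2))))
    expect_equal(dca(ctr, lig), d_naive, tolerance = 1e-9)
    expect_equal(dcc(ctr, lig), sqrt(sum((colMeans(xyz) - ctr)^2)),
                 tolerance = 1e-9)
  }
  expect_error(dca(c(0, 0, 0), list(atoms = atoms_df(numeric(0)))))
})

test_that("the detection threshold is inclusive", {
  lig <- make_ligand(c(4, 0, 0))
  rk <- ranked_table(matrix(c(0, 0, 0), 1L))
  expect_true(ligand_identified(rk, lig, eval_criterion("dca", 4), 1))
  lig2 <- make_ligand(c(4.0001, 0, 0))
  expect_false(ligand_identified(rk, lig2, eval_criterion("dca", 4), 1))
})

test_that("rank cutoffs gate identification", {
  centers <- rbind(c(50, 0, 0), c(60, 0, 0), c(0, 0, 0))
  rk <- ranked_table(centers)                      # true site at rank 3
  lig <- make_ligand(c(1, 0, 0))
  expect_false(ligand_identified(rk, lig, cutoff = 1))
  expect_true(ligand_identified(rk, lig, cutoff = 3))
  expect_true(ligand_identified(rk, lig, cutoff = Inf))
  far <- make_ligand(c(200, 0, 0))
  expect_false(ligand_identified(rk, far, cutoff = Inf))
})

test_that("success rates use per-protein Top-n with n = ligand count", {
  # protein with 2 ligands: cutoffs are Top-2 / Top-4; ligand B sits at rank 3
  centers <- rbind(c(0, 0, 0), c(50, 0, 0), c(100, 0, 0), c(150, 0, 0))
  entry <- list(protein_id = "P1",
                ligands = list(make_ligand(c(1, 0, 0)),
                               make_ligand(c(101, 0, 0))),
                ranked = ranked_table(centers))
  rep <- success_rates(list(entry))
  expect_equal(unname(rep$rates["top_n"]), 0.5)          # only ligand A in top 2
  expect_equal(unname(rep$rates["top_n_plus_2"]), 1.0)   # both within top 4
  expect_equal(unname(rep$rates["all"]), 1.0)
  expect_equal(rep$outcomes$n_sites, c(2L, 2L))

  # 4 pairs, 3 identified at Top-n
  solo <- function(id, hit) list(
    protein_id = id, ligands = list(make_ligand(c(if (hit) 1 else 500, 0, 0))),
    ranked = ranked_table(matrix(c(0, 0, 0), 1L)))
  rep2 <- success_rates(list(solo("a", TRUE), solo("b", TRUE),
                             solo("c", TRUE), solo("d", FALSE)))
  expect_equal(unname(rep2$rates["top_n"]), 0.75)
  expect_error(success_rates(list()), "empty")
})

test_that("cutoff rates are nested for arbitrary rankings", {
  set.seed(62)
  for (i in 1:10) {
    entries <- lapply(1:6, function(j) {
      centers <- matrix(runif(15, -20, 20), ncol = 3L)
      list(protein_id = paste0("p", j),
           ligands = lapply(seq_len(sample(1:2, 1)), function(k)
             make_ligand(runif(3, -20, 20))),
           ranked = ranked_table(centers, new_rank = sample(5)))
    })
    r <- success_rates(entries, eval_criterion("dca", sample(3:10, 1)))$rates
    expect_lte(r["top_n"], r["top_n_plus_2"])
    expect_lte(r["top_n_plus_2"], r["all"])
  }
})

test_that("moving the passing pocket down flips Top-n but not All", {
  centers <- rbind(c(0, 0, 0), matrix(rep(c(90, 0, 0), 4), ncol = 3L,
                                      byrow = TRUE))
  lig <- list(make_ligand(c(1, 0, 0)))
  top <- list(protein_id = "x", ligands = lig,
              ranked = ranked_table(centers, new_rank = 1:5))
  bottom <- list(protein_id = "x", ligands = lig,
                 ranked = ranked_table(centers, new_rank = c(4L, 1L, 2L, 3L, 5L)))
  r_top <- success_rates(list(top))$rates
  r_bot <- success_rates(list(bottom))$rates
  expect_equal(unname(r_top), c(1, 1, 1))
  expect_equal(unname(r_bot["top_n"]), 0)          # n = 1, pocket at rank 4
  expect_equal(unname(r_bot["top_n_plus_2"]), 0)   # rank 4 > n + 2 = 3
  expect_equal(unname(r_bot["all"]), 1)

  sweep <- success_rate_sweep(list(top), thresholds = c(2, 4))
  expect_equal(nrow(sweep), 12L)
  expect_true(all(sweep$rate >= 0 & sweep$rate <= 1))
})
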