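---
title: "Rescoring candidate binding pockets with local ligandability"
author: "pocketrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescoring candidate binding pockets with local ligandability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pocket-detection programs (Fpocket, ConCavity, and relatives) take a protein
structure and return an ordered list of candidate pockets. Their native
scoring functions — volume, depth, simple descriptor combinations — often
place the true ligand-binding site well below the top of that list, and a
practitioner who only inspects the first two or three candidates misses it.
pocketrank is a post-processing re-ranker: it never adds, removes or
reshapes pockets, it only reorders the candidates so that true sites rise to
the top. The ceiling of what re-ranking can achieve is therefore the *total
coverage* of the upstream detector — the success rate when all candidates
are considered.

## The model

The pocket is represented by its **inner points**: solvent-accessible
surface dots within a 4 Å belt of the pocket's heavy atoms. Surface dots are
generated per atom as the vertices of a level-2 subdivided icosahedron
(162 directions per atom) scaled to `r_vdw + probe` with a probe radius of
1.6 Å; a vertex strictly inside any other atom's expanded sphere is
discarded. This is a single accessible dot layer, not a re-entrant
(probe-rolling) molecular surface: the method only needs evenly spaced
near-surface points, and the parametrization (probe radius, tessellation
level) is the tuned operating point.

Each inner point `P` gets a local feature vector

    IFV(P) = sum_i AFV(A_i) * w(dist(P, A_i))  ||  FV(P)

where the sum runs over the **atomic neighborhood** of `P` — heavy,
solvent-exposed polymer atoms within 8 Å — and the weight is linear,
`w(d) = 1 - d/8`. The atom feature vector `AFV` concatenates residue-level
features (Kyte–Doolittle hydropathy plus five physico-chemical class
indicators) with atom-level features (a one-hot pharmacophore type and a
ligand-binding propensity per heavy atom of each standard residue). `FV(P)`
holds four point-level features: H-bond donor and acceptor counts in the
neighborhood, the mean B-factor, and a protrusion index. All features are
strictly local: an atom farther than the cutoffs cannot change a point's
vector, which the tests assert bit-exactly.

A random forest classifies points as ligandable or not. Training data are
labeled geometrically: a point is positive iff it lies within 2.5 Å of any
heavy ligand atom. Both the 4 Å belt and the 2.5 Å label radius are closed
boundaries (a point at exactly the threshold is inside). Point corpora are
heavily imbalanced (roughly 15 negatives per positive) and are deliberately
left that way — resampling and class weighting degrade generalization for
this problem, so the forest trains on the raw class ratio.

The pocket score is cumulative:

    PScore = sum_i P1(V_i)^2

Squaring emphasizes points voted close to 1; not dividing by the point count
means an oversized pocket that contains a true site keeps its score, and
padding a pocket with zero-probability points changes nothing (an exact
invariant in the test suite). Pockets are re-ordered by decreasing PScore;
ties keep the original order (stable sort), and a pocket with no inner
points is retained with score 0 rather than dropped.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `probe` | 1.6 Å | probe radius for the accessible dot layer |
| `tess_level` | 2 | icosphere subdivision; 162 dots/atom, count grows 4× per level |
| `belt` | 4.0 Å | inner-point belt around pocket heavy atoms (inclusive) |
| `label_threshold` | 2.5 Å | positive-label distance to ligand atoms (inclusive) |
| `neighborhood_radius` | 8.0 Å | chemical neighborhood for IFV aggregation (inclusive) |
| `num_trees` | 100 | forest size; `mtry = floor(sqrt(p))`, fully grown trees |
| `min_ligand_atoms` | 5 | heavy-atom filter for a HETATM group to count as a relevant ligand |

The first five are the tuned operating point of the method; we treat them as
fixed defaults rather than free knobs. Forest hyperparameters are ordinary
random-forest defaults with an explicit seed — training and prediction run
single-threaded so results are bit-reproducible. The ligand-relevance filter
(non-ignored HETATM group with at least five heavy atoms) is a documented
choice, not a published rule; it matters because the ligand-centric
evaluation counts one case per (protein, relevant ligand) pair, so the
filter changes the denominator. The ignore list (waters, common ions,
buffers, cryoprotectants) and the filter size are both configurable.

Two concretizations were genuinely open and are resolved as follows. The
protrusion index is implemented as the classic empty-to-occupied volume
ratio `(V_sphere - N*v_atom) / (N*v_atom)` in a 10 Å sphere with
`v_atom = 20.1` Å³, capped at 15 so an empty neighborhood stays finite. The
PLB baseline is the mean residue propensity over the distinct residues
lining the pocket. The bundled atomic propensity and PLB tables are
documented stand-ins with the canonical aromatic-rich ordering (the original
statistical tables are external); they live in `inst/extdata/` as plain CSV
so users can substitute the originals, and every model records the table
checksum (`schema_version`) and refuses features built under a different
schema.

## Evaluation protocol

Evaluation is ligand-centric: every relevant ligand of every protein is one
case, and a case succeeds at a cutoff if at least one pocket within the top
ranks passes the detection criterion. Two criteria are provided: D_CA, the
minimal distance from the pocket center to any ligand atom, and D_CC, the
center-to-ligand-centroid distance; both use an inclusive threshold,
usually 4 Å. Cutoffs are Top-n and Top-(n+2), where n is the number of
relevant ligands of the protein owning the evaluated site, plus All (total
coverage). The nested-cutoff inequality Top-n ≤ Top-(n+2) ≤ All holds by
construction and is asserted on every evaluation. Volume-overlap criteria
are deliberately absent: re-ranking does not change pocket shapes, so such
criteria could not change the ordering comparison.

## What the synthetic generator emulates

Real benchmark corpora require external structure collections and upstream
detector runs, so the package ships a generator of self-contained toy
complexes. Each toy protein is a jittered spherical shell of single-atom
residues (radius 11 Å, one heavy atom per residue, mixed composition, a
filled carbon core so only the outer surface is solvent-exposed) with one
concave crater: shell atoms within 35° of a pole are pulled 4 Å inward and
drawn from an aromatic-rich "ligandable" residue pool with B-factors
shifted down by `effect_size` × 10 (shell B-factors are N(30, 10), floored
at 1). A planar ring of six carbon atoms (HETATM group `LIG`) sits inside
the crater. Candidate pockets are the crater plus `n_decoys` convex surface
patches whose centroids lie ≥ 10 Å from every ligand atom; volumes are
drawn from a common log-normal and original ranks follow volume, so the
original ranking and the volume baseline are uninformative by construction
while the planted site always satisfies D_CA ≤ 4 Å. Signal is planted both
geometrically (concavity, hence protrusion) and chemically (lining
composition, B-factor shift), because the classifier sees only local
chemistry.

What the fixtures do **not** emulate: real backbone connectivity and
side-chain geometry, multiple binding sites per protein, partial pocket
overlap, heterogeneous ligand chemistry, or the structural diversity of
curated benchmark sets. A green synthetic benchmark therefore demonstrates
that the pipeline is wired correctly and that the ranker recovers a planted
chemical/geometric signal at realistic imbalance — not that the bundled
stand-in feature tables reach published accuracy on real proteins.

## Numerical choices and degenerate inputs

* Occlusion uses a 1e-6 Å tolerance so coincident spheres resolve
  deterministically; unknown elements fall back to the 1.70 Å carbon radius
  with a warning, never an error.
* Alternate locations keep the highest-occupancy copy (ties: file order);
  only model 1 of multi-model files is read; hydrogens and ignore-listed
  groups are dropped on input.
* Zero-denominator metrics (precision, recall, MCC on degenerate folds)
  return 0 flagged with a `degenerate` attribute instead of erroring.
* Cross-validation folds are split by protein, never by point, so
  near-duplicate neighboring points cannot leak across the train/test
  boundary.
* Per-protein rescoring is pure and order-independent; the test suite
  checks that processing proteins in any order yields identical output,
  which is the contract a parallel runner would have to honor.
* Problem sizes in the tests and the acceptance script are chosen for a
  single-CPU desk run: simulated point sets of 2 000–5 000 rows, benchmark
  corpora of 60 toy proteins (train on 30, evaluate on 30), forests of
  40–100 trees. At these sizes the full suite runs in about a minute.

## A worked run

```{r, eval = FALSE}
library(pocketrank)

spec <- fixture_spec(seed = 1, n_proteins = 20)
dir <- tempfile()
make_benchmark(spec, dir)
corpus <- load_benchmark(dir)

tab <- property_tables()
ds <- build_point_dataset(corpus[1:10], tab)
model <- ligandability_forest(ds, seed = 11)

entry <- corpus[[11]]
rescore_pockets(entry$structure, entry$pockets, model, tab)
```

## Known limitations

The surface layer is accessible-dot only (no re-entrant patches), pocket
parsing supports the version-1 Fpocket layout and a generic CSV (other
tools bridge through the CSV), mmCIF is not read, and the bundled atomic
propensity, pharmacophore and PLB tables are structural stand-ins for the
original statistical tables. Sequence conservation and whole-pocket shape
descriptors are out of scope by design — every feature is local.
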