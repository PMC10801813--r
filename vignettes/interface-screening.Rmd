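---
title: "Scoring and ranking predicted protein-protein interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and ranking predicted protein-protein interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`afmscreen` turns the raw outputs of an AlphaFold-Multimer style
prediction run — multi-chain coordinate files with per-residue pLDDT in
the B-factor field, and a directional predicted-aligned-error (PAE)
matrix per model — into interface confidence scores and ranked candidate
tables for in silico protein–protein interaction screens. This vignette
explains the model behind each stage, the parameters that matter, the
numerical decisions taken where the design was genuinely open, and what
the synthetic test fixtures do and do not establish about real data.

## The contact model

All downstream statistics reduce to one primitive: the inter-chain
residue *contact*. A unique residue pair (i on one chain, j on another)
is a contact when all three of the following hold, each a strict
inequality:

| filter | default | units | meaning |
|---|---|---|---|
| pair-average pLDDT | > 50 | 0–100 | both residues are at least moderately confidently placed |
| minimum directional PAE | < 15 | Å | the relative placement of the two residues is trusted in at least one alignment direction |
| minimum heavy-atom distance | < 8 | Å | the residues are physically adjacent |

Three readings deserve justification because the informal definition
("2 non-hydrogen atoms closer than 8 Å", "average pLDDT", "minimum PAE")
admits alternatives:

- **Pair-average pLDDT** is the arithmetic mean of the two residues'
  pLDDT. This is the only reading consistent with a filter applied per
  residue pair rather than per interface.
- **Minimum PAE** is `min(PAE[i,j], PAE[j,i])`. PAE is directional (the
  expected error of residue j when the model is aligned on residue i),
  and taking the minimum credits the better direction; requiring both
  directions would be a stricter, different filter.
- **The distance filter** holds when at least one heavy-atom pair — one
  atom drawn from each residue — is closer than 8 Å, i.e. the minimum
  inter-residue heavy-atom distance is below the cutoff. "Two atoms"
  cannot mean two atoms of the same residue, since fewer than two atoms
  define no distance. All heavy atoms are used, not only Cβ: the package
  records this as its adopted reading. Hydrogens (which appear in
  relaxed models) are parsed and kept but flagged non-heavy, and tests
  assert they can never change a contact set.

Strictness matters only on exact boundaries (a pair at exactly 8.000 Å
or average pLDDT exactly 50 is *not* a contact), but those boundaries
are exercised deliberately by the test suite, and the synthetic
generator rounds its planted values to the precision the file formats
carry (0.01 for B-factors, 0.001 Å for coordinates) so file truth and
analytic truth agree exactly.

Contact search uses a cell list with bins of one cutoff width, falling
back to a vectorized all-pairs distance computation for small atom
counts; correctness is anchored to an independent brute-force double
loop over residue and atom pairs that the test suite runs on every
random fixture. Chain pairs are canonicalized by sorting the two chain
ids, so `find_contacts(pred, c("A","B"))` and `c("B","A")` are
identical, and contact keys are order-independent.

## Structure and PAE input

The residue indexing shared by every stage is the *concatenated index*:
chains in file order, residues in file order within each chain. The PAE
matrix is indexed the same way, matching how multimer pipelines write
it. Reading enforces: at least two chains; unique residue numbers per
chain (insertion codes become part of the residue identity); at least
one heavy atom per residue; B-factors present. All atoms of a residue
are expected to carry the same pLDDT (tolerance 0.01; otherwise a
warning and the first atom's value). Files with all B-factors at or
below 1 are treated as 0–1 scaled pLDDT and rescaled ×100 with a
warning, since both conventions occur in the wild and the 50 threshold
assumes the 0–100 scale. Alternate locations keep the highest-occupancy
conformer (first on ties) — predicted models have none, but relaxed or
hand-edited files may. HETATM records are skipped with a message. Only
the first MODEL block of a multi-model file is used; the models of one
pair are assumed residue-identical, and no sequence alignment between
them is attempted.

PAE JSON is accepted in the ColabFold dialect (top-level `"pae"`) and
the AFDB dialect (`"predicted_aligned_error"`, possibly wrapped in a
one-element list). The matrix must be square and non-negative and is
never symmetrized.

## Interface statistics and pDockQ

Per model and chain pair, the interface summary averages the
per-contact values: `avg_interface_pae` is the mean of the contacts'
minimum PAE, `avg_interface_plddt` the mean of their pair-average
pLDDT. An empty interface has `NA` averages.

pDockQ is the sigmoid

$$\mathrm{pDockQ} = \frac{L}{1 + e^{-k(x - x_0)}} + b, \qquad
x = \overline{\mathrm{pLDDT}}_{\mathrm{interface}} \cdot \ln n_{\mathrm{contacts}}$$

with the published calibration $L = 0.724$, $x_0 = 152.611$,
$k = 0.052$, $b = 0.018$ (overridable via `pdockq_params()`). Two open
points were resolved as follows:

- **Which contacts feed x.** The original pDockQ calibration defines
  interface contacts by a Cβ distance criterion. This package computes
  x from *its own* contact set — the same set all other statistics use —
  because the screen applies one contact definition throughout. The
  numeric consequence is small near the sigmoid's flat regions but can
  matter near the midpoint; users wanting the Cβ recipe can run
  `find_contacts()` with a custom threshold set against Cβ-only input
  or evaluate `pdockq_score()` on externally computed values, which
  exposes the formula directly.
- **Empty interfaces score 0, not b.** With no predicted contacts there
  is no interface to score; awarding the sigmoid floor b = 0.018 would
  rank "no interface" above nothing and interleave empty pairs with
  genuinely weak ones. 0 sorts them cleanly below every predicted
  interface.

The natural logarithm is used, per the published formula. The score is
strictly increasing in x, bounded by $(b, L + b)$ for any non-empty
interface, and the suite checks the midpoint value $L/2 + b = 0.380$
against a closed-form construction.

## Cross-model agreement

For the M models of one pair, every unique contact key is counted by
the number of models whose contact set includes it. `avg_n_models` is
the mean of these counts over unique contacts; `max_n_models` is their
maximum. Both are bounded by [1, M] whenever any contact exists, and
both are undefined (NA, sinking in ranks) when no model predicts any
contact. Models with empty interfaces still count toward M — the count
is "how many models predicted this contact", not a renormalized
fraction. Uniqueness is exact key equality; no clustering of
near-identical contacts is attempted.

For the one-row-per-pair screen table, a reduction over models is
needed for `pdockq` and `avg_interface_pae`. The package defaults to
the *best* model (max pDockQ, min PAE, max pLDDT, over models with at
least one contact), treating the most confident model as the pair's
representative; `pair_reduction = "mean"` averages over models with
contacts instead. Which reduction the original screen tables used is
not documented, so both are provided and the choice is recorded in the
output config. Ties in `best_of()` break to the lexicographically
lowest model id, keeping every output a deterministic function of the
inputs.

## Screen assembly and ranking

`filter_proteome()` drops sequences shorter than 15 or longer than 3034
residues (bounds chosen for GPU-feasible folding; both bounds
inclusive-keep, strict-drop) and exact duplicates after uppercasing,
keeping first occurrences. No similarity-based redundancy is attempted
— "redundant" is read as exact duplication, the only reading that needs
no extra threshold.

`rank_candidates()` sorts by `avg_n_models` (desc), `pdockq` (desc),
`avg_interface_pae` (asc) and assigns ranks 1..N. Two determinism
decisions: residual ties break by `partner_id`, making the ordering a
pure function of the row set (the suite checks all 24 permutations of a
4-row table collapse to one output); and absent metrics sink — NA
`avg_n_models`/`pdockq` sort as −∞ and NA PAE as +∞ — because a pair
with no predicted interface is the weakest possible evidence.
`rerank_with_annotation()` prepends a binary annotation flag (e.g.
STRING membership of the partner) as the primary sort key and re-ranks;
with an empty annotation set it is an ordering no-op, which is also
tested.

## The synthetic fixture generator

`fixture_spec()`/`generate_fixture()` lay each chain out on a lattice
(20 Å residue spacing, chains separated by `background_min_dist`,
default 20 Å) and realize each planted contact by translating one
designated residue to the target heavy-atom distance (< 8 Å) from its
partner, directly toward its own chain. Background residues keep pLDDT
40 (failing the average filter at the default threshold) and PAE 30 Å,
so the planted truth is unambiguous three ways: geometry, confidence
and error all separate planted from background. Residue placement is
verified after layout — every planted pair within 0.01 Å of target,
every background inter-chain pair beyond 8 Å — and an infeasible spec
(e.g. one residue in two planted contacts) errors before any file is
written. One CA per residue is the default; a 3-atom mode (N, CA, C at
±1.3 Å along the lattice axis) exercises the minimum-over-atoms rule,
and an optional hydrogen per residue exercises the heavy-atom flag.

`ensemble_spec()`/`generate_ensemble()` write M coordinate/PAE pairs in
which model m contains exactly the planted contacts whose membership
set includes m, so `avg_n_models` and `max_n_models` are the mean and
max of the membership sizes — computable by hand and asserted exactly
in the end-to-end recovery suite.

The random spec generators define the study conditions of the test and
acceptance suites, fixed once: `random_fixture_spec()` draws 4–12
residues per chain, 0–4 planted contacts at 3–7.9 Å, pLDDT uniform over
the full 0–100 range and PAE uniform on 0–30 Å (so planted contacts
fail filters at realistic rates, including empty interfaces);
`random_ensemble_spec()` draws 1–5 contacts that always pass the
default filters (pLDDT 55–95, PAE 1–14 Å, distance 3–7.5 Å) with
uniformly drawn non-empty model-membership subsets, because its purpose
is to test agreement accounting, not filtering. These sizes keep the
full suites — 100 oracle fixtures, 100 recovery ensembles, a
200-fixture pDockQ suite and 50 agreement ensembles — at desk scale
(well under two minutes end to end) while covering every filter
boundary and membership pattern.

What the fixtures deliberately do **not** emulate: realistic backbone
geometry, secondary structure, sequence-dependent packing, correlated
PAE structure (real PAE matrices have block structure tied to domains),
or pLDDT spatial autocorrelation. Passing the planted-truth suites
therefore shows the *accounting* — parsing, indexing, filtering,
counting, aggregation, ranking — is exact; it says nothing about
whether AlphaFold's confidence estimates themselves identify true
interactors. That calibration question belongs to the prediction
system, not to this pipeline.

## Numerical and formatting choices

- Distances are compared on squared coordinates with a guard against
  tiny negative values from floating-point cancellation.
- TSV outputs fix real metrics at 3 decimals and leave integers
  unpadded, so re-running any command on identical inputs is
  byte-identical; logging goes to standard error only.
- The fixture writers round to the field widths of their formats (PDB:
  0.001 Å coordinates, 0.01 B-factor), and the random generators round
  their draws to the same precision, eliminating any gap between
  manifest truth and file truth.
- Seeds: every random spec is a deterministic function of a single
  integer seed; identical seeds produce byte-identical files.

## Limitations

- Works per chain pair; interfaces involving three chains at once are
  scored pairwise only.
- No ipTM/pTM extraction from prediction metadata, and no true DockQ
  against a reference structure.
- The FASTA redundancy filter is exact-match only.
- mmCIF support covers the `_atom_site` loop as written by prediction
  pipelines and this package's own writer; exotic mmCIF features
  (multi-datablock files, quoted atom fields) are out of scope.
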