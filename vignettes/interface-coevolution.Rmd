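---
title: "Validating protein complex interfaces with genome-proximity co-evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating protein complex interfaces with genome-proximity co-evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Residues that form a protein–protein interface co-evolve: across a deep set
of homologous complexes, substitutions on one side of the interface are
statistically compensated on the other. `coevomap` exploits this to test
whether a proposed multi-chain structural model places two proteins in
contact where evolution says they touch.

The central objects are:

* a **paired MSA** — each row concatenates one homologue of protein A with
  one of protein B drawn from the same genomic neighbourhood. Columns
  `1..L_A` belong to A, `L_A+1..L_A+L_B` to B;
* an **inter-protein score matrix** `S` of dimension `L_A x L_B`, where
  `S[i, j]` measures the evidence that profile column `i` of A contacts
  column `j` of B;
* a **multi-chain Cα model** against which top-scoring pairs are measured.

The pairing step is the biological crux. Sampling homologue pairs at random
would mix non-interacting orthologues and destroy the signal; restricting
to pairs encoded on the same nucleotide record fewer than 20 coding genes
apart preferentially samples pairs from one operon, which tend to assemble
into the same machine. This assumption — genomic proximity implies joint
function — is what licenses row-wise concatenation of the two alignments.

## Scoring backends

**Distogram aggregation.** External residue–residue distance predictors
emit, per inter-protein pair, a probability distribution over discretised
distance bins. The contact probability is the summed mass of every bin
whose *upper* edge is at or below the 12 Å cutoff. Requiring the upper edge
to qualify guarantees "distance ≤ cutoff" semantics whatever the bin grid;
bin edges are always read from the file, never assumed. A trailing
no-contact bin never contributes. Scores are probabilities in `[0, 1]`.

**Mutual information with average-product correction.** As a transparent,
fully self-contained alternative, the package scores every column pair by
mutual information in bits,

$$\mathrm{MI}(i,j) = \sum_{a,b} p_{ij}(a,b)\,
  \log_2 \frac{p_{ij}(a,b)}{p_i(a)\,p_j(b)},$$

with joint frequencies estimated from a pseudocounted 20 × 20 contingency
table, followed by the average-product correction
`APC(i,j) = MI(i,j) − MI̅(i)·MI̅(j)/MI̅`, which removes the entropic and
phylogenetic background that inflates raw MI at variable columns. The APC
means are taken over the off-diagonal of the full `(L_A+L_B)²` matrix —
intra-block couplings inform the background estimate — and the corrected
matrix is then sliced into inter and intra blocks. MI is *not* a substitute
for a trained distance predictor in terms of accuracy; it is a controlled,
independently verifiable scorer that makes the whole ranking/selection/
mapping machinery testable at desk scale, and remains useful in its own
right on deep alignments.

Design choices in the MI path, made once:

* **Gaps** are excluded pairwise (a row gapped in either column is dropped
  from that pair's counts) rather than treated as a 21st state: a gap
  records alignment coverage, not a residue identity.
* **Pseudocount** defaults to 1 (Laplace) per joint cell; `0` gives the
  plug-in estimator used by the closed-form tests.
* **Sequence weighting** is deliberately omitted from the default path.
  The synthetic generator draws rows independently, so weighting would be
  untestable dead weight here; on real, phylogenetically clustered data the
  redundancy filter (≤ 90% identity) performs the coarse version of the
  same job.
* A column pair with fewer than two mutually ungapped rows scores 0 and is
  counted in one consolidated warning.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_coverage` | 0.60 | fraction | hit filter, strict `>` ("more than 60% of the query covered") |
| `max_evalue` | 1e-3 | — | hit filter, inclusive; final round of the upstream 6-round search schedule (1e-12 ×4, 1e-6, 1e-3), which is carried as provenance in the run log |
| `max_separation` | 20 | coding genes | pairing bound, strict `<` |
| `max_gap_ratio` | 0.25 | fraction | row filter, inclusive |
| `max_identity` | 0.90 | fraction | redundancy ceiling, inclusive |
| `distance_cutoff` | 12 | Å | distogram aggregation bound |
| `min_score` | 0.05 | score units | reporting floor before ranking |
| `selection` | threshold70 | — | keep pairs ≥ 70% of the top score |
| `contact_cutoff` | 12 | Å | "within the interface" Cα–Cα bound |

Boundary semantics (strict coverage and separation, inclusive gap/identity/
e-value) are asserted by dedicated boundary fixtures in the test suite.

The interface cutoff deliberately equals the aggregation cutoff: a pair is
*predicted* in contact when most distogram mass lies below 12 Å, and
*verified* in contact when some chain-copy combination realises ≤ 12 Å.

## Selection and mapping

Ranked pairs (descending score, ties broken by ascending `(i, j)`) are
selected by one of three rules: `threshold70` (all pairs at ≥ 70% of the
top score — typically a displayable handful), `top:N` (when the threshold
rule keeps too many), or `min_score:x`. Each selected pair is measured
against the structure as the **minimum** Cα–Cα distance over all chain-copy
combinations of the two families; for a single family, only distinct-chain
combinations count. Minimising over copies reflects that a coupling is
satisfied if *any* copy pair realises the contact in a symmetric oligomer.

Categories: pairs across families are *hetero-oligomeric*; within one
family a pair is *homo-oligomeric* when its minimal cross-chain distance is
smaller than its minimal within-chain distance, else *intra*. The
cross-versus-within rule is this package's own operationalisation of the
distinction — a structural criterion had to be fixed, and this one is
deterministic and invariant to chain relabelling (tested by exhaustive
relabelling sweeps).

**Interface precision** is the fraction of selected pairs with computable
distance at or below `contact_cutoff`; residues unresolved in every chain
copy are excluded from the denominator but always reported (`n_unresolved`),
never silently dropped.

The ranking scope defaults to inter-protein (hetero) pairs only, the set
relevant for interface validation; `scope = "all"` additionally ranks the
intra-block pairs the MI backend computes anyway.

Where the structure's author numbering differs from profile columns, a
per-family integer offset maps column `i` to residue number `i + offset`.

## The synthetic generator

The generator emulates the three inputs with planted, recoverable truth:

* **Genomes** (`sim_genome_hits`): each record carries, with probability
  0.8, a co-located pair of family hits (separation drawn in 1..19) whose
  coverage and e-value pass the default filters — these are the truth.
  The remaining records are decoys that exercise the pipeline: far-separated
  pairs, single-family records, or co-located pairs failing coverage or
  e-value. Truth records always pass the filters by construction, because
  the pairing stage is specified to recover 100% of planted pairs; filter
  failures are exercised on decoys only.
* **Coupled alignments** (`sim_coupled_msa`): background columns draw
  independently from per-column flat-Dirichlet profiles over the 20 amino
  acids. Each planted pair `(i, j)` is coupled through a fixed random
  one-to-one state mapping applied with probability ε (default 0.9); gaps
  are injected uniformly at 5%. At ε = 1 without gaps the planted pair's
  plug-in MI equals the column entropy exactly — the closed form the tests
  assert — and mean planted MI is monotone in ε over {0, .25, .5, .75, 1}.
* **Toy structures** (`sim_structure`): planted pairs are placed inside a
  shared ball of radius `contact_distance`/2 (8 Å default) so their
  distance is ≤ 8 Å by construction; all other residues occupy grid cells
  spaced `far_distance + 2·contact_distance` apart, making every
  non-planted inter-family distance ≥ 20 Å. Symmetric copies are generated
  by rotation about a common axis at a radius that keeps distinct copies at
  least `far_distance` apart. The constructive guarantee is re-verified by
  an exhaustive distance scan at generation time. Plantings in which a
  coupled residue group would contain a non-planted inter-family pair are
  rejected as geometrically infeasible (the pair would have to be
  simultaneously near and far).

The default bundle (`bundle_defaults()`): two 30-column families, 500
records at 80% co-location (≈ 400 alignment rows), 10 planted pairs,
ε = 0.9, 2+2 chain copies. These sizes were chosen as the smallest study at
which the MI statistics are comfortably stable: at ≈ 400 rows the raw-MI
background bias `(19·19)/(2N ln 2)` is ≈ 0.65 bits before APC and the
planted signal ≈ 0.9 bits after APC sits far above the post-APC background
(which falls below the 0.05 reporting floor).

What the generator does **not** emulate: phylogenetic correlation between
rows (an optional duplication-with-mutation stress mode is out of the
default path), realistic substitution processes, indel structure, paralogy
beyond simple decoys, or structural realism beyond the distance
constraints. Passing tests therefore demonstrate the correctness of the
statistical and geometric machinery, not the field performance of MI on
real alignments — on real data, the trained-predictor distogram route is
the accurate backend and MI is the transparent cross-check.

## Numerical choices and degenerate inputs

* Distogram probability vectors must sum to 1 within 1e-4 and are then
  renormalised exactly; larger deviations are rejected, not repaired.
* Identity between two rows is matches over mutually non-gap columns, 0
  when no such column exists; redundancy filtering is a greedy keep-first
  scan in row order — deterministic, idempotent, and verified post hoc by
  an exhaustive pairwise scan in the tests.
* The two MSA filters run gap-first: identity between heavily gapped rows
  is unstable, so rows are de-gapped before identity is trusted. Both
  orders are defensible; this one is fixed and documented.
* One pair per nucleotide record (smallest separation, then smallest
  combined e-value, then lexicographic `(gene_index_a, gene_index_b)`)
  prevents paralogue fans from duplicating rows; `pairing = "all"` is
  available when every combination is wanted.
* Empty selections, empty ranked lists in threshold mode, unknown config
  keys, and cutoffs outside the binned range fail fast with classed errors
  (`coevomap_validation_error` / `coevomap_data_error`; the CLI wrapper
  maps them to exit codes 2 and 3).
* All generators are driven by `withr::with_seed`; sub-seeds are derived
  through a fixed 32-bit LCG step so any user seed yields valid seeds.

## Problem sizes in the test suite

The MI oracle sweep checks 200 random alignments of up to 50 rows × 10
columns against a brute-force contingency-table oracle at 1e-10. Planted
recovery uses 1000 rows × (30+30) columns with 10 planted pairs at ε = 0.9.
The end-to-end validation mirror runs the full default bundle. Geometry
oracles enumerate all chain combinations on structures with up to 6
symmetric copies. These sizes keep the statistics stable while the whole
suite completes in well under a minute per property.

## Limitations

* MI/APC without sequence weighting under-performs modern coupling models
  (pseudo-likelihood Potts, trained networks) on shallow or phylogenetically
  skewed alignments; the package's claim is correctness, with the distogram
  route as the accuracy path.
* The operon-proximity heuristic fails for interacting proteins encoded far
  apart, and the closest-pair rule keeps one homologue pair per record even
  where several paralogous systems coexist on a genome.
* Interface precision is a Cα-distance criterion; it does not measure
  buried surface area or side-chain contacts.
* Stockholm I/O is a minimal single-block dialect (sufficient for
  round-tripping this package's own alignments), not a full-featured parser.
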