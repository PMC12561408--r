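---
title: "Screening designed GLP-1 receptor agonists: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening designed GLP-1 receptor agonists: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepfunnel)
```

## The problem

Deep-learning sequence design can emit thousands of candidate analogues of a
therapeutic peptide in minutes, far more than any laboratory can express and
assay. `pepfunnel` implements the computational triage that sits between the
generator and the bench for GLP-1 receptor agonist (GLP-1RA) design: an
ordered funnel of **stability**, **efficacy** and **diversity** gates that
reduces a pool on the order of 10,000 designs to a few dozen candidates worth
synthesizing, plus the small bookkeeping computations used once in-vitro data
come back (relative expression, expression-threshold filtering, label
tallies).

The design context is template-constrained: candidates are point-substitution
variants of the Semaglutide backbone, GLP-1(7--37) with
2-aminoisobutyric acid (Aib) at position 8 and Arg at 34, numbered 7--37 by
the GLP-1 convention. Thirteen positions (7H, 8Aib, 9E, 10G, 11T, 12F, 13T,
14S, 15D, 17S, 26K, 34R, 37G) are anchored — nine because they are highly
conserved across marketed agonists and drive receptor engagement, the others
because they are Semaglutide-specific modification sites — leaving 18
designable positions. `semaglutide_spec()` carries this template and
`build_design_mask()` derives the fixed/designable partition.

## Sequence model

Sequences are ordered vectors of residue tokens: the 20 canonical one-letter
codes plus registered extended tokens such as `Aib`, serialized in brackets
(`H[Aib]EGT...`). Every extended token names a canonical *surrogate* residue
(Ala for Aib) used by physicochemical scales and by the matching policy:
two tokens match iff their surrogates are equal. The policy matters for
**sequence recovery** — the fraction of the 31 template positions at which a
candidate matches the template, rounded half-up to two decimals. Designed
sequences are emitted with canonical residues and bacterially expressed
constructs carry Ala, not Aib, at position 8, yet they are scored against
the Aib-containing template; Aib ~ Ala matching makes the template score 1
against itself and keeps biosynthesized constructs comparable. The
denominator is always the template length (31), consistent with reported
two-decimal values such as 25/31 = 0.81.

Conservation analysis (`conservation_profile()`) scores alignment columns
either by majority fraction (default) or Shannon entropy; gaps are excluded
from column counts. The reference-agonist alignment is an *input* — only
pairwise global alignment is recomputed here, with a hand-rolled
Needleman--Wunsch over the token alphabet (standard aligners cannot carry
bracketed tokens), a linear gap penalty, and a deterministic
diagonal-up-left traceback tie-break so identity distances are reproducible.

## Stability gate

Neutral endopeptidase 24.11 cleaves GLP-1 at six dipeptide sites:
Asp15-Val16, Ser18-Tyr19, Tyr19-Leu20, Glu27-Phe28, Phe28-Ile29 and
Trp31-Leu32. The gate's one hard default is *zero tolerated cleavage
sites*. Two scan modes are provided because the site definitions are
template-numbered but a designed sequence can relocate a motif:
`position_anchored` (default; a hit requires the exact dipeptide at the
rule's template position) and `motif_scan` (stricter; any adjacent matching
pair anywhere).

The remaining descriptors are computed and reported but default to
non-rejecting bounds, because no numeric cutoffs accompany them in the
source screening protocol:

* **Net charge** at pH 7.4 (physiological), by the Henderson--Hasselbalch
  sum with the EMBOSS pKa set (N-terminus 8.6, C-terminus 3.6; D 3.9, E 4.1,
  C 8.5, Y 10.1, H 6.5, K 10.8, R 12.5). Any table of the same shape can be
  injected. Aib carries no side-chain charge.
* **Isoelectric point**, the bisection root of the charge curve on (0, 14)
  to 1e-3 pH; undefined (an error) without ionizable groups of both signs,
  e.g. a Lys/Arg-only peptide with an amidated C-terminus.
* **Hydropathy (GRAVY)**, the Kyte--Doolittle per-residue mean.
* **Helix propensity**, the per-residue mean of negated Pace--Scholtz helix
  free energies, so larger is more helical (Ala 0, Gly -1.0, Pro -3.16) and
  a minimum bound reads naturally as a helicity requirement.

Gate results carry a complete machine-readable list of violated bounds with
observed values, so any reported failure can be re-tested independently.

## Efficacy gate

Candidates are evaluated as predicted peptide--receptor complexes against
the native reference complex:

* **TM-score** with $d_0 = 1.24(L-15)^{1/3} - 1.8$ clamped at 0.5 (for
  $L = 31$, $d_0 \approx 1.32$, so the clamp is inactive). Because template
  numbering fixes a one-to-one residue correspondence, the superposition is
  optimized by *iterative Kabsch reweighting* — start from the all-pair
  superposition, repeatedly re-superpose on pairs with $d_i < d_0$ until
  the selected set is stable (cap 20 iterations), keep the best score —
  rather than a TM-align-style fragment search. This is a deliberate
  simplification appropriate to fixed-correspondence comparisons.
* **C-alpha RMSD** after Kabsch superposition (SVD route with reflection
  correction, proper rotation enforced); the suite cross-checks it against
  an independent quaternion-eigenvalue implementation at 1e-8.
* **Mean pLDDT** of the peptide chain, read from the B-factor column
  (the AF2 convention).
* **Interface pAE**, the per-entry mean over both inter-chain blocks of the
  predicted-aligned-error matrix (both the bare-object and list-wrapped
  JSON dialects are accepted).
* **SAP** (spatial aggregation propensity): per residue, the sum over
  side-chain atoms within a 5 A neighbourhood of (exposed fraction x
  residue hydrophobicity), with exposure from Shrake--Rupley SASA against
  Tien-style theoretical maxima and a Gly-centered Black--Mould
  hydrophobicity scale; the aggregate sums positive per-residue values.
  All three tables and the radius are injectable, since none is fixed by
  the protocol being reproduced.
* **External affinity** (e.g. MM/GBSA energies) is ingested from TSV, never
  computed: molecular dynamics is out of scope.

SASA uses a deterministic golden-spiral sphere point set (default 256
points, probe 1.4 A) so results are bit-reproducible; the suite checks the
closed-form sphere area within 2% and 256-vs-960-point convergence within
3% of each atom's sphere area. Van der Waals radii come from a fixed
element table with a 1.8 A warning fallback.

Thresholds are *derived from the reference complex itself*
(`derive_thresholds()`): minimum TM and pLDDT scale down by `1 - slack`,
maximum RMSD and interface pAE scale up by `1 + slack`, with a 0.5 A floor
on the RMSD bound so a self-scored reference still admits finite deviation.
The slack default is 0.1 and is always echoed in the report, since no
published slack exists for this step.

## Diversity gate

Diversity serves two goals: patent distance from the marketed drug, and
spread across sequence space so correlated failures are less likely. The
gate:

1. fails candidates whose global-alignment identity to the template is at
   or above the patent cap (default 0.90; the true patent threshold is not
   public, so the cap is configuration),
2. builds a neighbor-joining tree on $d = 1 -$ identity (optionally
   Jukes--Cantor-stretched), via `ape::nj` with negative branch lengths
   clamped to zero and the deficit moved to the sibling,
3. cuts the tree into $k$ clusters (default: the configured target count),
4. keeps one representative per cluster — highest recovery by default
   (consistent with the highest-recovery candidate being carried forward
   in practice), with medoid and lexicographic-first rules and
   lexicographic tie-breaks.

Neighbor-joining replaces maximum-likelihood tree building with bootstraps
here: the tree's only role in the funnel is clustering, NJ recovers
additive metrics exactly (a property the suite asserts at 1e-9), and it
runs in seconds at pool scale. A consequence is that published
ML-tree-derived path distances are not reproduced numerically.

Cluster cutting deserves a note. "Remove the $k-1$ longest internal edges"
cannot produce $n$ singleton clusters (two leaves of a cherry stay
connected through their parent), so the implementation uses greedy
divisive removal over *all* edges: visit edges longest-first (ties by
child-node order) and keep a removal only if it increases the number of
connected leaf components, stopping at $k$. This yields exactly $k$
clusters for every $1 \le k \le n$, makes clusterings nested in $k$, and
still splits the longest internal edges first.

## Funnel orchestration and bookkeeping

`run_funnel()` executes the configured stages in order (default: dedupe,
stability, efficacy, diversity — the screening narrative), maintaining the
count invariant *entering = passing + failing* at every stage, and emits
per-candidate scorecards plus per-stage summaries. Candidates without
structures at the efficacy stage are an error in strict mode (default) or
pass through tagged "not evaluated" in lenient mode. Reports serialize to
JSON (lossless) and TSV (scorecards; absent scores are empty cells, never
zeros), byte-identically across repeated runs.

In-vitro outcomes are *data*: the packaged assay table records, for the 60
designed candidates (plus the Semaglutide control), pulldown labels,
relative expression, SPR dissociation constants and labels, cAMP EC50 and
half-lives. `relative_expression()` is the plain band-density ratio;
`apply_expression_filter()` excludes pulldown successes with expression
*strictly below* the threshold — the boundary policy is deliberate, as a
candidate at exactly 0.70 proceeds under the 0.7 default while five fall
below (0.67, 0.65, 0.63, 0.55, 0.65) — and `count_labels()` performs exact
label tallies (31 pulldown successes, 29 failures).

## The synthetic-data generator

Grading every gate requires inputs no public archive holds, so the
`synthetic_data` module generates them:

* **Candidate pools** (`generate_candidates()`): template-constrained point
  substitutions at the 18 designable positions. Defaults mirror the
  emulated campaign — $n = 10{,}000$ and a duplicate fraction of 0.8557,
  chosen so the expected unique count is about 1,443, matching the
  redundancy observed when a constrained design space is sampled at low
  temperature. The substitution distribution is position-independent and
  uniform by default; it makes no attempt to mimic a learned sequence
  model, which is sufficient to exercise every gate but means pass rates
  through the physicochemical bounds are not predictions about real
  designed pools.
* **Structures** (`build_ideal_helix()`): sequential internal-coordinate
  (NeRF) construction of N, CA, C, O (and CB for non-Gly) at canonical
  helix geometry (phi -57, psi -47, omega 180; N-CA 1.458, CA-C 1.525,
  C-N 1.329 A), giving 3.80 A CA-CA steps and a 1.5 A/residue rise.
  `perturb_structure()` adds seeded isotropic Gaussian noise to create
  RMSD/TM test pairs with controllable difficulty.
* **Confidence files** (`mock_confidence()`): pLDDT around requested
  per-chain means and PAE matrices with separable intra-/inter-chain
  levels, plus seeded noise.

All randomness flows through explicit integer seeds; the global RNG state
is saved and restored, so library calls never perturb a user's session.

## Numerical choices and degenerate inputs

* Half-up rounding for reported recovery (two decimals), matching the
  reporting convention of the source data.
* Bisection tolerance 1e-3 pH for pI; the suite checks against a
  14,000-point grid oracle at 2e-3.
* Kabsch on fewer than 3 points is an error; collinear sets are flagged
  but still returned.
* NJ on two taxa returns a single split edge; on non-additive input,
  negative branches are clamped as described.
* Alignment of an empty sequence is pure gap cost; dedupe on an
  all-distinct pool is the identity.
* The funnel's diversity stage skips clustering when survivors already
  number at most the target count (the patent cap still applies).

## What the tests do and do not show

The suite (under a minute on one CPU) runs candidate pools of 30--500
sequences, 31-residue helices, and trees of 3--12 leaves; property checks
use 50--100 randomized replicates under fixed seeds. Passing shows the
operations are correct on their contracts — exact recovery arithmetic,
oracle-matched superposition, additive-metric tree recovery, conserved
funnel counts, bit-reproducible runs. It does not show that the gates'
default bounds reproduce any particular experimental hit rate: real
designed pools have learned, position-dependent sequence statistics, real
AF2 models have correlated errors that ideal-helix fixtures do not, and
the in-vitro outcomes in the assay table are measurements, not predictions.

## Known limitations

* No maximum-likelihood phylogenetics or bootstrap support; NJ only.
* No structure prediction, MD, or MM/GBSA — structures, confidence files
  and affinities are inputs.
* Fatty-acid conjugation chemistry is metadata (an annotation string), not
  modeled.
* The conservation module assumes a user-supplied alignment; no progressive
  multiple aligner is included beyond pairwise.
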