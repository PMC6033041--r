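---
title: "Comparing immunoglobulin variable-domain families: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing immunoglobulin variable-domain families: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific question

Camelid heavy-chain antibodies bind antigen through a single ~15 kDa
variable domain (VHH, the nanobody when expressed in isolation), while
conventional antibodies use a paired VH--VL unit with six
hypervariable loops. How a single domain with only three loops
generates a comparable diversity of binding specificities is a
question that can be addressed quantitatively by comparing families of
antigen-bound VHH and VH domain structures: do single-domain binders
diversify their framework, lengthen their loops, broaden the set of
positions they bind with, or vary loop geometry more?

`igcompare` implements the statistics needed for that comparison as a
tested pipeline: scheme-numbered alignment handling, per-column
conservation and logo matrices, pairwise Hamming diversity,
loop-length distributions with Kullback--Leibler divergence,
antigen-contact propensity with paratope extraction, and
region-restricted pairwise RMSD under Kabsch superposition. A
synthetic family generator with full ground truth makes every stage
testable end to end without external downloads.

## Alignment handling and region maps

Input domains arrive with a per-residue numbering table (CSV:
`scheme_position, insertion_code, residue`) mapping each residue, in
chain order, to a position of a fixed-length scheme such as AHo.
AHo-style schemes place loop residues symmetrically from the loop ends
toward the center, so central loop columns are occupied in few
sequences. Following standard practice, columns with **more than 85%
gaps** (strict `>`) are removed for position-level statistics; on a
typical VHH/VH dataset this reduction yields ~126 positions. The
comparison is strict because the rule is stated as "more than 85%";
[reduce_alignment()] is idempotent and records both direction maps
between reduced and full positions.

Named regions are defined over the reduced alignment. The default
[region_map()] uses loops H1 = 26--35, H2 = 50--59 and H3 = 98--116,
which leaves 87 framework positions out of 126 -- the framework C-alpha
set used for superposition. Both the spans and, for label-carrying
datasets (e.g. synthetic families), per-column labels are
configurable, since alternative loop definitions exist in the
literature.

Loop *lengths* and loop *Hamming* statistics deliberately run on the
**full, unreduced** alignment: the low-occupancy central columns are
exactly where long loops differ, and dropping them would truncate the
length distributions. Loop *RMSD* runs on the reduced positions, since
central columns rarely have a structurally meaningful pairing.

## Sequence statistics

**Conservation.** For each column we store `n_ungapped` (sequences
with a residue) and `n_modal` (sequences carrying the most frequent
residue; ties broken alphabetically and flagged). The *conservation
level* used for significance testing is `n_modal / n_ungapped` -- a
gap-insensitive choice, so that datasets with different gap structure
remain comparable. Both counts are retained so a gap-inclusive view is
derivable.

**Logos.** [logo_matrix()] exports per-column residue frequencies and,
in bits mode, the information content \(I = \log_2 20 - H\) with
\(H\) the column Shannon entropy, optionally with the small-sample
correction \((s-1)/(2 n \ln 2)\), clipped at zero. Frequency mode is
preferred for long loops, where information content hides residue
usage at sparsely occupied columns.

**Hamming diversity.** The normalized Hamming distance counts
differing positions over the compared columns, scaled to [0, 1]. Gap
handling must be fixed explicitly for unequal loop lengths; we
exclude gap--gap columns from numerator *and* denominator and count
gap-vs-residue as a difference. This makes a length-9 vs length-11
loop differ at least at the unmatched columns, which is the intended
reading of "fraction of sequence changes". Restricted to gap-free
rows the distance is a metric (tested by enumeration). Per-loop
summaries deduplicate identical loop sequences by default
(`unique_loops = TRUE`), since repeated loops otherwise deflate the
diversity estimate; the count of unique loops is reported alongside.

**Conservation significance.** To ask whether a position is more or
less conserved in dataset A than expected from dataset B, we draw
`n_draws = 6` subsets of `draw_size = 90` sequences from B, compute
each draw's conservation level per column, and flag positions where
A's level falls outside the draw mean ± 2 sd. Draws are *without*
replacement by default (the operation emulates repeated subsampling
of a large single-species pool); when the pool is no larger than the
draw size -- as when comparing two 90-member datasets directly --
[run_comparison()] switches to with-replacement resampling so the
spread remains defined. With six draws the sd estimate is coarse;
flags should be read as a screen, not a calibrated test. A zero-sd
column is flagged only on any difference and marked degenerate.

**Distribution divergence.** [kl_divergence()] computes
\(D(P\|Q)=\sum_x p(x)\log(p(x)/q(x))\) over the union support of two
integer length distributions, in nats by default (base 2 available).
A pseudocount added to every union-support bin (then renormalized)
handles lengths observed in only one dataset; with no pseudocount a
support violation is reported explicitly as infinite. The pipeline
default is a small pseudocount (1e-3 on probability scale): large
enough to keep the divergence finite, small enough not to flatten the
distributions. Empirical KL on ~90 samples is upward-biased and
sensitive to tail bins, so seed-to-seed variation of a few tenths of
a nat is expected; the statistic is best read comparatively.

**t tests.** Cross-dataset differences in pairwise-distance
distributions use the pooled-variance two-tailed Student's t
([t_test_unpaired()]; Welch variant by flag). Pairwise distances are
not independent observations, so these p values are descriptive, not
calibrated -- they are reported because this is the field's
conventional summary.

## Structure statistics

**Superposition.** [kabsch()] implements closed-form least-squares
rigid superposition via SVD, restricted to proper rotations
(determinant +1; reflections are excluded because mirror images of
chiral molecules are not physical). Degenerate geometry (collinear or
coincident points, second singular value ~0) yields a warning and a
best-effort result. Correctness is tested against a multi-start
numerical minimizer over rotation angles and translations (agreement
to 1e-3 Å on small point sets) and by rigid-motion invariance at
1e-6 Å.

**Pairwise RMSD.** For every structure pair, [pairwise_rmsd()] fits on
the *fit positions* where **both** structures have C-alpha
coordinates, then measures RMSD over the *measure positions* where
both have coordinates, under that transform. Missing coordinates are
the norm in crystal structures, so this both-present policy is applied
per pair; pairs with fewer than 3 common fit positions (a rigid fit is
underdetermined below 3) or no common measure position are excluded
from the summaries and logged. Summaries report mean, sd and max over
the off-diagonal pair values (the sd is the spread of the pair
distribution), plus the mean/sd of common-position counts per pair.

Two fit frames are first-class: measuring a loop under the
*framework* fit includes the loop's placement relative to the domain
(lever-arm effects included), while fitting on the *loop's own*
positions isolates internal loop geometry. Both are computed, since
both readings are scientifically meaningful; the self fit is always
the smaller number.

**Contacts and paratope.** A binder residue contacts the antigen iff
its minimum heavy-atom distance to any antigen heavy atom is
**strictly below 5 Å**. Hydrogens are excluded everywhere (crystal
structures at typical resolutions lack them, and including them would
make the cutoff model-dependent). Contact propensity per alignment
position is the fraction of bound structures whose residue there
contacts antigen, with the number of bound structures as the default
denominator ("in >10% of structures"); the ungapped-denominator
variant is reported alongside. The paratope is the set of positions
with propensity **strictly above 0.10**. Per-structure contact counts
are residue counts; residues absent from the numbering (e.g.
expression tags) are excluded from the positional profile but kept in
per-structure counts, with a log message.

**Structure input.** PDB and mmCIF files are read through `bio3d`.
Alternate conformers keep the highest-occupancy conformer, ties going
to conformer "A". Residues are keyed by sequential index in chain
order (author numbers kept as metadata), decoupling the pipeline from
PDB numbering gaps. Only the 20 standard residues map to one-letter
codes; modified or nonstandard residues (SEP, MSE, ...) become `X`
and count as mismatches in Hamming statistics.

## The synthetic family generator

[generate_family()] emits immunoglobulin-like families with complete
ground truth so that every statistic above can be checked against a
planted value. What it emulates:

* an 87-position framework scaffold shared by all structures, as a
  uniform helical C-alpha trace with consecutive distances of 3.8 Å,
  perturbed per structure by isotropic Gaussian noise with a
  framework-specific sigma;
* three loop spans with capacities (14, 14, 31 columns) exceeding the
  typical loop lengths; loop lengths are drawn per structure from a
  configurable distribution and residues fill each span symmetrically
  from the ends inward, reproducing the AHo-style central-gap
  structure; loop coordinates get their own (larger) noise sigmas;
* per-column sequences drawn as modal residue with probability
  `conservation`, remainder uniform over the other 19 letters;
* a missing-coordinate mask (default 2% of residues lose their
  C-alpha but keep a side-chain pseudo-atom, exercising the
  both-present RMSD policy and the presence mask);
* an antigen pseudo-chain: each designated paratope position is
  contacted in exactly `round(propensity * n)` structures. In-contact
  residues get a side-chain pseudo-atom 3 Å from the C-alpha with the
  antigen atom 4.0--4.8 Å beyond it along a direction searched so
  every non-contact residue stays > 5.5 Å clear of all antigen atoms;
  the realized geometry is verified at generation time, so designed
  and detected contact sets agree exactly, away from the 5 Å
  boundary. (Strict-boundary behavior at exactly 5.0 Å is tested
  separately with dedicated fixtures.)

For isotropic per-atom noise with standard deviation \(\sigma\), the
expected pairwise RMSD between two structures is
\(\sqrt{6}\,\sigma\) up to a \(O(1/n_{atoms})\) fit correction --
the quantitative anchor for parameter-recovery tests (10% tolerance
at 30 structures, 87 atoms).

[make_paper_like_pair()] fixes a contrast between an `nb_like` and an
`ab_like` family. Its parameters are the study conditions, set once
from the dataset-level statistics such a comparison is expected to
show and then left alone: noise sigmas are target RMSD divided by
\(\sqrt 6\) (framework 0.41/0.46 Å; H1 1.37/0.65; H2 0.76/0.73; H3
2.62/1.44), H3 length distributions are discretized normals
(15.19 ± 4.23 vs 12.09 ± 3.81, medians 15/12), per-column
conservation targets invert the expected per-loop Hamming means via
\(\Pr(\text{match}) = p^2 + (1-p)^2/19\) (e.g. H3 0.29/0.39 for
Hamming 0.89/0.83), framework conservation is 0.85 vs 0.60, and the
designated paratopes span 50 vs 35 positions with propensities
summing to 18.76 vs 16.01 contacts per structure.

What the generator does **not** emulate: real Ig fold geometry
(sheets, pairing, H3 packing against the former VL interface),
sequence--structure covariation, canonical loop classes,
crystallographic artifacts beyond missing coordinates, and epitope
structure on the antigen side. Passing tests therefore demonstrate
that the *statistics are computed correctly* and that planted effects
of realistic size are recovered -- not that the biological
conclusions transfer to any particular real dataset, which
additionally depends on numbering-tool behavior and dataset curation.

## Numerical and design choices

* Strict inequalities everywhere a threshold is stated as strict:
  gap filter (> 85%), contact cutoff (< 5 Å), paratope threshold
  (> 10%).
* Modal-residue ties break alphabetically and are flagged.
* Kabsch: proper rotations only; < 3 points is an error; degeneracy
  warns.
* Pairs lacking 3 common fit positions are excluded and logged, never
  imputed.
* Deduplication of identical binder sequences at dataset load is on
  by default (sequence-unique datasets), with removals logged.
* All randomness (generator, subsampling) flows through explicit
  seeds; `run_comparison()` is byte-identical across reruns for a
  fixed config seed.
* Problem sizes: the bundled study runs 90 structures per family
  (4005 pairs per RMSD matrix); unit tests use 3--30 structures and
  parameter-recovery checks use 20--90.

## Known limitations

* The AHo/IMGT/Kabat numbering algorithms are out of scope; numbering
  is ingested (or generated synthetically). Real-data use requires an
  external numbering tool, and numbering-tool version differences of
  a few positions propagate into all position-level statistics.
* The conservation-significance screen inherits the coarseness of a
  6-draw sd estimate, and in the two-dataset setting the "pool" is
  only as large as the dataset itself.
* Empirical KL divergence on ~90 loops is smoothing- and
  tail-sensitive; treat magnitudes comparatively.
* t tests on pairwise distances are descriptive (non-independent
  samples); no multiple-testing correction is applied.
* The synthetic scaffold is a geometric stand-in, not a physical
  model; all-atom statistics (side-chain contacts beyond one
  pseudo-atom, buried surface areas) are out of scope.
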