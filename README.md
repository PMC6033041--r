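# igcompare

Comparative sequence and structure analysis of immunoglobulin
variable-domain families in R.

Camelid heavy-chain antibodies bind antigen through a single VHH
domain (the nanobody), with three hypervariable loops instead of the
six available to a conventional VH–VL pair. Comparing a family of
antigen-bound VHH structures with a matched family of VH domains asks
how a single small domain generates diverse binding specificities: a
more variable framework? longer loops? a broader set of
antigen-contacting positions? more loop geometry variation?
`igcompare` implements that comparison as a reusable, tested pipeline,
together with a synthetic family generator (known ground truth) that
exercises every stage without external downloads.

## What it computes

For two families of scheme-numbered, antigen-bound variable domains:

* **Alignment reduction and regions** — columns with > 85% gaps are
  removed (AHo-style schemes leave central loop columns sparsely
  occupied); named regions over the reduced alignment default to
  H1 = 26–35, H2 = 50–59, H3 = 98–116, leaving 87 framework positions
  of 126.
* **Conservation and logos** — per column: ungapped count n, modal
  count n_wt, conservation level n_wt/n; logo matrices in bits,
  I = log2(20) − H, or frequencies.
* **Sequence diversity** — normalized pairwise Hamming distance
  d(a, b) = (# differing positions)/(# compared positions) in [0, 1],
  with gap–gap columns excluded and gap-vs-residue a mismatch;
  per-loop summaries over unique loop sequences.
* **Loop lengths** — counted on the full (unreduced) alignment;
  normalized length histograms and the Kullback–Leibler divergence
  D(P‖Q) = Σ p log(p/q) between them.
* **Paratope** — a residue contacts antigen iff its minimum
  heavy-atom distance to the antigen is < 5 Å; per-position contact
  propensity (fraction of structures) and the paratope as positions
  with propensity > 0.10; per-structure contact counts.
* **Structural variability** — Kabsch least-squares superposition
  (proper rotations only) and region-restricted pairwise RMSD: fit on
  the framework (or on a loop's own positions), measure over the
  positions where both structures have coordinates; mean ± sd over
  all N(N−1)/2 pairs.
* **Cross-family statistics** — per-position conservation
  significance (target level outside mean ± 2σ of 6 random 90-sequence
  subsets of the other family), two-tailed unpaired t tests on the
  pairwise-distance distributions, and a deterministic JSON/TSV
  report.

## Worked example

Generate a paired synthetic study — an `nb_like` family (tight
framework, long noisy H3, 50-position paratope) against an `ab_like`
family — and run the full comparison:

```r
library(igcompare)

pair   <- make_paper_like_pair("families", n = 20, seed = 7)
nb     <- family_dataset(pair$nb)
ab     <- family_dataset(pair$ab)
report <- run_comparison(nb, ab, comparison_config(seed = 7))
print(report)
#> comparison_report: nb_like vs ab_like
#>   framework RMSD: 0.99 +/- 0.04 vs 1.12 +/- 0.05 A
#>   H1 RMSD (self fit): 3.00 vs 1.33 A; KL(len) 0.174
#>   H2 RMSD (self fit): 1.60 vs 1.60 A; KL(len) 0.527
#>   H3 RMSD (self fit): 5.91 vs 3.20 A; KL(len) 1.633
#>   paratope breadth: 50 vs 35 positions
```

The framework RMSD line says the nb-like family superposes more
tightly over its 87 framework C-alphas (0.99 Å mean pairwise RMSD)
than the ab-like family (1.12 Å), while its loops — especially H3 —
are far more variable structurally (5.91 vs 3.20 Å). The paratope
line counts alignment positions contacting antigen in > 10% of
structures: the nb-like family draws its paratopes from 50 positions
against 35. (KL values at n = 20 are small-sample noisy; the
20-structure example is for speed.) Drill into any component:

```r
report$a$loops$H3$hamming$summary$mean   # nb H3 loop sequence diversity
#> 0.9360208
report$a$contacts$mean                   # contacts per structure
#> 18.75
write_report(report, "report_dir")       # JSON + TSV tables
```

The `analysis/` directory holds the same study as numbered scripts
(simulate → sequence statistics → RMSD → paratope → full report),
each writing its tables under `results/`:

```sh
Rscript analysis/01_simulate_families.R
Rscript analysis/02_sequence_statistics.R
...
```

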