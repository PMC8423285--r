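---
title: "Methods: quantitative phage characterization with phagekit"
author: "phagekit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative phage characterization with phagekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagekit)
```

phagekit implements the desk-side analyses of a lytic-phage
characterization study: how well a phage's codon usage is adapted to its
bacterial host, whether the phage carries tRNAs for the codons it
over-uses, how fast it replicates (one-step growth kinetics), how
efficiently it plates across candidate host strains, and whether it
significantly reduces host biofilms. This vignette records the models, the
tunable parameters and the design decisions behind each stage, and what
the synthetic-data generator does and does not emulate.

## Codon usage adaptation

For each organism, all annotated coding sequences are extracted
strand-aware from the genome, the start codon of every CDS is removed
(start-codon choice reflects initiation, not synonymous preference), and
codons are counted as non-overlapping triplets pooled over the whole
coding complement. The relative frequency of codon $i$ is

$$f_i = \frac{n_i}{\sum_{j=1}^{64} n_j},$$

and the adaptation statistic is the phage-to-host ratio

$$r_i = \frac{f_i^{\text{phage}}}{f_i^{\text{host}}}.$$

A codon is binned as **higher** (phage over-uses it) when $r_i \ge 1.1$,
**similar** when $0.9 \le r_i < 1.1$, and **lower** when $r_i < 0.9$.
The three verbal clauses "at least 1.1", "between 0.9 and 1.1" and
"below 0.9" only partition the line cleanly if the `similar` bin is
half-open, $[0.9, 1.1)$; we adopt that reading, so $r = 0.9$ is `similar`
and $r = 1.1$ is `higher`. Codons the host never uses ($f_i^{host} = 0$)
get an `undefined` ratio rather than an infinite one and are excluded from
rankings; stop codons stay in the counts (only start codons are removed),
with a flag to drop them.

Counting is pooled — one table per organism — rather than per-gene
averaged, because $f_i$ is defined against "all codons" of the coding
complement. Whether a subset of host genes (e.g. pseudogenes) should be
excluded is an upstream annotation question; the package counts every CDS
the annotation provides and the validation policy admits.

CDS validation defaults: features whose length is not a multiple of 3,
that contain ambiguity codes, or that contain an in-frame stop before the
final codon are dropped (and logged with a reason); GFF features with
non-zero phase (partial CDS) are excluded by default because their reading
frame offset would corrupt codon counts. All of these are policy flags on
`extract_cds()`.

## tRNA cross-referencing

The anticodon cognate to a codon is its reverse complement, reported
5'→3' in the DNA alphabet to match the output of common tRNA predictors
(whose reports the package parses; it does not predict tRNAs itself).
`match_overrepresented()` lists every codon with $r_i$ at or above a
threshold (default 1.1) and whether the phage's anticodon complement
contains a cognate. Matching is exact by default — the natural reading of
"the anticodon corresponding to this codon" — with an optional wobble mode
(G:U pairing and inosine-like reading of A34) for exploratory use; wobble
matches are by construction a superset of exact matches. For a phage with
no tRNA genes at all, every row reports `has_cognate_trna = FALSE`
whatever the convention, so the headline conclusion is insensitive to this
choice.

## One-step growth kinetics

A one-step growth curve is titer versus time after synchronized infection
at known multiplicity (`moi()`). No extraction rule is standard in the
literature — the classical numbers are read off the plotted curve — so the
package fixes an explicit, tunable rule and documents it:

* titers are handled in log10 space (plaque titers are log-distributed),
  so every mean of titers is geometric;
* **burst onset** is the first sample exceeding `rise_factor` (default 2,
  a doubling) times the running geometric mean of all earlier samples;
* **latent period** is the last sampled time before onset, reported at
  sampling resolution (default 10-min grid) without interpolation;
* **plateau** is the maximal suffix of samples whose pairwise log10 range
  is at most `plateau_tol` (default 0.1, i.e. within ~26%);
* **rise period** is first plateau time minus latent time;
* **burst size** is the plateau geometric mean over the baseline
  geometric mean.

Replicates are estimated independently; latent and rise are combined by
the median (which stays on the sampling grid), burst size by the
arithmetic mean with a standard error across replicates. A replicate in
which no burst or no stable plateau is detected is dropped with a warning;
the estimate fails only if every replicate fails. Degenerate inputs
produce explicit errors (`no burst detected`, `no plateau`).

At the default noise level used in the tests (multiplicative log10 noise
of 0.02), the onset margin is about 2.5 noise SDs, so single-replicate
latent estimates occasionally slip one sampling interval; the median over
triplicates makes that rare. This is why recovery tolerances are stated as
"within one sampling interval".

## Efficiency of plating

From a 10-fold spot dilution series, the titer is read from the **most
dilute countable spot** — counts within `[countable_min, countable_max]`,
default [3, 100] plaques per 10 µL spot — as
`count / spot_volume * 10^exponent` PFU/mL. The most-dilute rule minimizes
plaque-overlap bias; the countable range is a plate-reading convention,
not a published constant, and both bounds are parameters. Note the
selection effect this rule implies: a spot whose expected count is near
the lower countable bound is only countable when Poisson noise pushes it
up, so titer series should be designed so the working spot sits
comfortably inside the range.

EOP of strain $s$ is $100 \times t_s / \max_u t_u$: the reference strain
(the most permissive) is exactly 100% by construction, ties broken by
input order, and scaling all titers by a common factor changes nothing.
Summaries print 2 significant figures (the convention for reporting EOP
percentages); JSON output keeps full precision.

## Biofilm statistics

The gating rule mirrors how biofilm assay data are analysed in practice:
Shapiro–Wilk normality per group at $\alpha_{norm} = 0.05$ (the
conventional level; the underlying study reported only that "data were
normal"); a two-sided **paired t-test** when the design is paired and both
groups pass; otherwise a two-sided **Mann–Whitney U**. Unpaired data take
the Mann–Whitney route regardless of normality — matching the study
design, where the unpaired confocal counts were compared
non-parametrically. The U test is exact (full enumeration) when both
groups have $n \le 8$ and there are no ties, and otherwise uses the
tie-corrected normal approximation with continuity correction and
mid-ranks. All tests are two-sided (no sidedness was pre-registered) and
significance is declared at $p < 0.05$; printed summaries report
`p < 0.001` when the p-value underflows that reporting precision, with
full precision in the JSON report.

## The synthetic-data generator

Every pipeline stage has a generator producing inputs with known ground
truth, all pure functions of their parameters and one integer seed:

* **Genome pairs** (`generate_genome_pair()`): each gene is `ATG` + body
  codons + `TAA`, the body drawn per an amino-acid-uniform mixture times
  per-family synonymous weights; genes alternate strands with random
  30-bp spacers. Because both organisms share the same gene-structure
  model, the generating usage ratio of a codon equals the ratio of its
  synonymous weights, which is what `biased_codon_weights()` lets you set
  directly. Defaults (78 genes of 100–350 codons) mirror a typical phage
  genome's coding complement; host genomes in tests simply use more
  genes. The `kmi8_like_codon_bias()` preset encodes the usage structure
  observed for phage KMI8 against *K. michiganensis*: five codons
  over-used ≥ 2.5-fold with ACT the strongest at over 3-fold.
* **Growth curves** (`generate_growth_curves()`): piecewise log-linear
  template (baseline to `latent_min`, log-linear rise over `rise_min` to
  `baseline * burst`, then plateau), sampled every 10 min to 90 min with
  multiplicative log-normal noise. Defaults (20 min, 30 min, burst 12,
  noise 0.02, triplicates) are the study conditions the estimators are
  tested against.
* **Spot series** (`generate_spot_series()`): Poisson counts with mean
  `titer * volume * 10^-exponent`.
* **Biofilm data** (`generate_biofilm_data()`): control around a baseline
  mean with CV 10%; the `strong_reduction` preset shifts the treated mean
  down 60%, the scale of reduction a strongly lytic phage produces;
  noise either normal or right-skewed log-normal; default $n = 42$
  mirrors 14 counting fields × 3 replicate experiments.

What the generator does **not** emulate: real genome architecture
(operon structure, overlapping genes, GC skew, alternative start/stop
codons, amino-acid composition bias), adsorption kinetics or secondary
infection cycles in growth curves, plate-level artefacts in spot assays,
or well-position effects in biofilm plates. Passing recovery tests
therefore show the estimators invert the stated data model at realistic
noise — not that every real-data complication is handled.

## Numerical choices and test problem sizes

Tie-breaks are deterministic everywhere: codon rankings break ratio ties
alphabetically, the EOP reference breaks titer ties by input order.
Frequencies sum to 1 to within 1e-12; ratio reciprocity
($r_i^{AB} r_i^{BA} = 1$) holds to 1e-9. The test suite checks codon-
frequency recovery at ~1e5 generated codons (estimates within 3
multinomial standard errors of truth), growth-curve recovery over 200
seeds (≥ 90% within one sampling interval for latent/rise and 20% for
burst), Mann–Whitney exactness against brute-force enumeration for all
group sizes 3–6, and the gated procedure's type-I error over 2000 null
simulations (≈ 5%). These sizes make the full suite run in well under a
minute while leaving the stochastic checks comfortable margins.

## Known limitations

* Codon analysis uses the standard genetic code only, and treats the
  annotation as ground truth — no correction for annotation errors,
  pseudogenes or horizontally transferred atypical genes.
* The kinetics extractor assumes the curve starts in the baseline phase
  and contains a plateau; truncated experiments (sampling stopped mid-
  rise) are rejected rather than extrapolated, and adsorption-phase
  decline is not modelled.
* The Mann–Whitney normal approximation is the usual large-sample one;
  for tied small samples the exact-with-ties distribution is not
  enumerated (mid-ranks plus correction are used instead).
* tRNA matching consumes predictor output; it does not assess tRNA
  functionality or expression.
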