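# phagekit

Quantitative analyses for characterizing a lytic bacteriophage against its
bacterial host, written for phage biologists who have a genome, an
annotation and a bench's worth of assay tables — and want the numbers side
of a characterization study to be reproducible. The motivating system is
phage KMI8 (a siphovirus, accession MN101222) and its host *Klebsiella
michiganensis* KLEB011, but every analysis is generic.

The package covers five analyses:

1. **Codon usage adaptation.** For each of the 64 codons, the relative
   codon frequency over an organism's coding complement (start codons
   removed) is *f*ᵢ = *n*ᵢ / Σⱼ *n*ⱼ, and the phage-to-host usage ratio is
   *r*ᵢ = *f*ᵢ^phage / *f*ᵢ^host. Codons are binned as **higher** (*r*ᵢ ≥
   1.1), **similar** (0.9 ≤ *r*ᵢ < 1.1) or **lower** (*r*ᵢ < 0.9), and the
   10 highest/lowest ratios are ranked.
2. **tRNA cross-referencing.** Over-used codons (*r*ᵢ above a threshold)
   are checked against the phage's tRNA anticodon complement (anticodon =
   reverse complement of the codon; optional wobble rules).
3. **One-step growth kinetics.** Latent period, rise period and burst size
   are extracted from titer-versus-time curves with an explicit, tunable
   rule (geometric means in log10 space; burst onset at a titer doubling
   over the running baseline; plateau by log-range).
4. **Efficiency of plating (EOP).** Titers from 10-fold spot dilution
   series (most dilute countable spot), and per-strain EOP = 100 ×
   titer / max titer, so the most permissive strain is exactly 100%.
5. **Biofilm statistics.** Normality-gated two-group comparison:
   Shapiro–Wilk per group, then a paired t-test (paired + normal) or a
   two-sided Mann–Whitney U (exact for small tie-free samples).

A seeded synthetic-data generator produces coding genome pairs with
controlled codon bias, growth curves, dilution series and biofilm
datasets with known ground truth, so the whole pipeline runs and is
testable without any downloads.

## Worked example

Simulate a KMI8-like phage/host pair, run the codon pipeline file-to-file,
then the phenotype analyses:

```r
library(phagekit)

sim <- tempfile("sim")
pair <- generate_genome_pair(
  host_bias  = codon_bias_spec(n_genes = 600),
  phage_bias = codon_bias_spec(n_genes = 78, weights = kmi8_like_codon_bias()),
  seed = 42, out_dir = sim)

res <- run_codon_usage(
  phage_fasta = file.path(sim, "phage.fasta"), phage_gff = file.path(sim, "phage.gff3"),
  host_fasta  = file.path(sim, "host.fasta"),  host_gff  = file.path(sim, "host.gff3"),
  out_dir = file.path(sim, "report"),
  anticodons = character(0))   # a phage encoding no tRNAs

head(res$top_bottom$top, 5)
#>   codon amino_acid    ratio
#> 1   ACT          T 3.168030
#> 2   GGT          G 3.029063
#> 3   GTT          V 2.886513
#> 4   CCG          P 2.831650
#> 5   TCT          S 2.724186
```

The five codons the generator over-weighted come back at their generating
ratios (ACT's truth is 3.2): the phage over-uses ACT more than 3-fold
relative to the host. Cross-referencing against its (empty) tRNA set:

```r
subset(as.data.frame(res$adaptation), ratio >= 2.5)
#>   codon amino_acid    ratio has_cognate_trna matched_anticodons
#> 1   ACT          T 3.168030            FALSE
#> 2   GGT          G 3.029063            FALSE
#> 3   GTT          V 2.886513            FALSE
#> 4   CCG          P 2.831650            FALSE
#> 5   TCT          S 2.724186            FALSE
```

— the phage carries no cognate tRNA for any codon it over-uses. The
directory `file.path(sim, "report")` now holds `codon_usage.tsv`,
`top_bottom_codons.json`, `gc_summary.json`, `adaptation_report.tsv` and a
`provenance.json` recording inputs and parameters.

Growth kinetics, EOP and biofilm statistics:

```r
estimate_kinetics(generate_growth_curves(seed = 42))
#> <kinetics_estimate> latent 20 min, rise 30 min, burst size 11.8 ± 0.3 PFU/infected cell (3 replicates)

efficiency_of_plating(c(KLEB011 = 1.0e9, KLEB014 = 3.2e7, KLEB015 = 4.8e6))
#> <eop_table> reference strain: KLEB011
#>   strain_id   titer eop_percent
#> 1   KLEB011 1.0e+09      100.00
#> 2   KLEB014 3.2e+07        3.20
#> 3   KLEB015 4.8e+06        0.48

gated_compare(generate_biofilm_data(effect = "strong_reduction", seed = 42))
#> <gated_test_report> control vs phage_treated (n = 42, 42; independent)
#>   normality p: control = 0.414, phage_treated = 0.0301
#>   mann_whitney_u: statistic = 1764, p < 0.001 (significant at alpha = 0.05)
```

The simulated triplicate growth curves (20 min latent, 30 min rise, burst
12, log10 noise 0.02) are recovered on the 10-min sampling grid; the titer
pattern 1.0e9 / 3.2e7 / 4.8e6 gives EOPs of 100% / 3.2% / 0.48%; and a 60%
biofilm reduction at n = 42 per group is detected by the Mann–Whitney
route at p < 0.001.

A thin command-line wrapper with subcommands `codon-usage`, `growth`,
`eop`, `biofilm` and `simulate` ships in `inst/cli/phagekit.R`
(`Rscript $(Rscript -e 'cat(system.file("cli","phagekit.R",package="phagekit"))') simulate --out-dir sim`).

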