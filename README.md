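# sdrscan

Comparative analysis of sex-determining-region (SDR) haplotypes in
dioecious plants.

In wild grapes, flower sex is controlled by a ~200–300 kbp SDR with three
haplotype classes: male-associated (M), female-associated (F), and the
hermaphrodite haplotype (H) of domesticated vines, which arose from a
single recombination joining an F 5' segment to an M 3' segment. `sdrscan`
implements the full comparative analysis of a phased SDR haplotype panel:

* **Alignment & variant discovery** — seed-and-chain pairwise alignment of
  each haplotype against an H reference (unique 21-mer anchors, weighted
  LIS chaining, affine-gap base alignment of small gaps), calling SNPs,
  small INDELs (≤ 50 bp) and structural variants (> 50 bp: insertions,
  deletions, inversions, complex).
* **Strict sex-linkage** — a variant is M-linked iff present in *all* M
  haplotypes and absent from *all* F and H haplotypes (symmetrically for
  F); SV identity uses reciprocal overlap ≥ 0.8; uncovered sites are
  uncallable, never linked. Windowed density tracks and SV sharing tables
  summarise the landscape.
* **Coding consequences** — frameshift/premature-stop annotation with
  mutant-protein truncation lengths (the F-haplotype *INP1* 8 bp deletion
  is the motivating case), plus an in-silico PCR engine for
  allele-specific marker assays and F1 genotyping.
* **Phylogenies & breakpoint** — per-gene neighbor-joining trees
  (p / Poisson / TN93 distances, column bootstrap), an exclusive-clade
  sex-monophyly test, and changepoint localization of the H recombination
  breakpoint from the ordered per-gene verdicts.
* **Dating** — Nei–Gojobori (1986) dS with Jukes–Cantor correction over
  all M×F allele pairs, a normal 95% CI with a Shapiro–Wilk check, and the
  molecular-clock conversion `T = dS / (2µ) × generation time`.
* **Population statistics** — windowed median LD r² (dosage correlation,
  MAF > 0.05, 20 kbp windows), F1 segregation χ² (no continuity
  correction), and marker–phenotype cosegregation reports.
* **Expression & motifs** — median-of-ratios normalization, the
  one-vs-both-other-sexes expression-pattern rule (Welch t + BH stand-in,
  or any external DE table), z-score heatmaps, and strict sex-linked
  presence/absence of promoter motif hits (3 kbp promoters, JASPAR PFMs,
  relative-score PWM scanning).
* **Simulator** — `simulate_trio()` and companions generate SDR panels,
  F1 tables, genotype matrices and expression counts with exact planted
  ground truth (breakpoint, linked variants, frameshift, clade patterns,
  dS target), so the whole pipeline is validated end to end.

Everything is tidyverse-native: functions take and return tibbles, fitted
results have `tidy()`/`glance()` methods, and result types have
`autoplot()` methods.

## Worked example

```r
library(sdrscan)

# simulate a default panel (3 M / 12 F / 5 H, 200 kbp, dS target 0.0275)
# and run the whole pipeline against the first H haplotype
cfg <- pipeline_config(simulate = sim_config(seed = 1))
rep <- run_pipeline(cfg)
rep
#> <sdr_report>
#>   reference: H01 (20 haplotypes)
#>   linked SNPs: 441 M / 911 F; linked SVs: 1 M / 3 F
#>   breakpoint: gene04 | gene05 (mismatches 0.0)
#>   divergence: 16.7 Myr (dS 0.0279)
#>   report hash: 483e43745c5067baefdcec8e59037e39
```

The linked-SNP asymmetry (F ≫ M) is the geometric signature of the H
breakpoint sitting near the 5' end of the region; the breakpoint call
matches the planted interval; and the recovered dS reproduces the
simulated 0.0275 target, converting to ~16.5 Myr under a 2.5×10⁻⁹
substitution rate and 3-year generations. Individual stages are ordinary
functions if you want the pieces:

```r
sim  <- simulate_trio(sim_config(seed = 1))
ref  <- sim$haplotypes$H01
al   <- align_pair(ref, sim$haplotypes$M01)     # anchor-chain alignment
call_variants(al)                                # tibble of SNP/INDEL/SV calls
glance(divergence_time(0.0275, 0.0258, 0.0292))  # 16.5 Myr (15.5-17.5)
tidy(segregation_chi2(102, 100))                 # chi2 = 0.02, df 1
```

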