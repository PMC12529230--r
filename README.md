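# napbind

Characterization of genome-wide binding by non-sequence-specific
nucleoid-associated proteins (NAPs) from ChIP-seq peak tables, with
quantification of the matching in vitro readouts and a fully seeded
synthetic-data generator.

NAP occupancy does not produce sharp motif-centered ChIP-seq peaks: it
produces broad, kilobase-scale enrichment zones with fold enrichments of
roughly 1–5× whose placement tracks base composition — in particular
AT-rich intergenic neighbourhoods. `napbind` is for researchers who have
called peaks for such a protein and want the standard downstream
characterization:

* **Summit-window context classification** — the 60-bp region from 30 bp
  upstream through 30 bp downstream of each summit is classified
  *intergenic* when strictly more than 30 bp of it overlaps the intergenic
  complement of the merged gene set, otherwise *coding*.
* **Fold-enrichment categories** — *all*, *FE ≥ 2* (boundary included),
  *top-20*, *bottom-20*; per category: percent intergenic, mean width,
  mean summit-window AT.
* **AT-content enrichment** — summit-window AT versus intergenic and coding
  genomic backgrounds, two-sided unpaired *t* test (Welch default, Student
  selectable), significance at *p* < 0.001, plus a seeded permutation test
  with *p* = (1 + k)/(n<sub>perm</sub> + 1).
* **Zone structure** — subpeak merging into lettered parent regions, gene
  annotation by ≥ 1 bp overlap, Pearson correlation of fold enrichment
  with peak width.
* **In vitro quantification** — apparent K<sub>D</sub> from EMSA saturation
  titrations via least-squares fits of θ = [P]/(K<sub>D</sub> + [P])
  (Hill variant optional, multistart initials); AFM topograph
  segmentation (plane levelling, thresholding, 8-connected components)
  with maximum-height bins 0–2/2–4/4–6/>6 nm, a tall-complex percentage
  (>12 nm) and prominence-based foci counts.
* **Synthetic data** — seeded generators for genomes with contrasting
  coding/intergenic AT (53% vs 62%), AT-coupled occupancy tracks,
  replicated Poisson coverage, toy peak calls, titrations and topographs
  with ground truth.

Inputs use standard formats: FASTA genomes, GFF3 annotation, MACS-style
narrowPeak or tab-separated peak summaries, TSV lane intensities,
plain-matrix height maps. Containers are standard Bioconductor classes
(`DNAStringSet`, `GRanges`).

## Worked example

Simulate a 200-kb genome under the default study conditions, call toy
peaks on triplicate coverage, and characterize them:

```r
library(napbind)

sim   <- simulate_genome(genome_spec(seed = 42))
track <- occupancy_track(sim$genome, occupancy_spec(seed = 42))
cov   <- sample_coverage(track, seed = 42)
peaks <- call_toy_peaks(cov, sim$genome)
res   <- characterize_peaks(sim$genome, sim$genes, peaks, seed = 42)

res$categories[, c("category", "n", "percent_intergenic", "mean_width_bp", "mean_at")]
#>    category  n percent_intergenic mean_width_bp mean_at
#> 1       all 58                100           419   0.680
#> 2     FE>=2 37                100           475   0.694
#> 3    top-20 20                100           542   0.712
#> 4 bottom-20 20                100           314   0.657
```

All 58 called peaks sit on intergenic summit windows — the simulated
occupancy is purely AT-driven — and summit AT rises with enrichment
category. The pooled AT comparisons against both genomic backgrounds:

```r
ac <- res$at_comparisons
ac[ac$context %in% c("all-vs-intergenic", "all-vs-coding"),
   c("category", "context", "n_peaks", "mean_at_peaks", "mean_at_background", "p")]
#>   category           context n_peaks mean_at_peaks mean_at_background        p
#>        all all-vs-intergenic      58         0.680              0.636 8.12e-03
#>        all     all-vs-coding      58         0.680              0.529 2.90e-28
#>      FE>=2 all-vs-intergenic      37         0.694              0.636 4.49e-04
#>      FE>=2     all-vs-coding      37         0.694              0.529 1.24e-23
#>     top-20 all-vs-intergenic      20         0.712              0.636 2.52e-05
#>     top-20     all-vs-coding      20         0.712              0.529 2.46e-14
#>  bottom-20 all-vs-intergenic      20         0.657              0.636 3.01e-01
#>  bottom-20     all-vs-coding      20         0.657              0.529 6.40e-08
```

Strongly enriched categories (FE ≥ 2, top-20) are significantly more
AT-rich than both backgrounds at *p* < 0.001, while the weakly enriched
bottom-20 is indistinguishable from the intergenic background — the
signature of composition-driven nonspecific occupancy. Width and
enrichment correlate positively, and a noisy simulated titration recovers
its dissociation constant:

```r
res$correlation$r
#> [1] 0.4618  # n = 58, p = 2.5e-04

fit_kd(simulate_emsa(300, c(25, 50, 100, 200, 400, 800, 1600, 3200),
                     noise_sd = 0.03, seed = 42))$kd_apparent
#> [1] 271.8   # nM, converged
```

A file-based interface (`run_simulate()` writes a complete FASTA + GFF3 +
bedGraph + peak-table bundle with a ground-truth sidecar and checksum
manifest; `run_characterize()` reads the bundle and writes every
figure-equivalent table as TSV plus a JSON report) and a thin CLI
(`inst/scripts/napbind.R` with subcommands `simulate`, `characterize`,
`emsa-fit`, `afm-quant`) wrap the same functions.

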