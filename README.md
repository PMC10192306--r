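# lyscreen

Analysis of positive-selection pooled CRISPR knockout screens — the
design in which a genome-wide GeCKO-v2-style library (six sgRNAs per
gene, split across half-libraries A and B, screened as four independent
pools A-1, A-2, B-1, B-2) is exposed to a selective agent such as the
sphingomyelin-binding cytolysin lysenin, and surviving cells reveal the
genes whose loss confers resistance. The package covers the full
computational path from raw reads to candidate genes, a ground-truthed
screen simulator, and the quantitative-imaging statistics used to
characterize hits. It is aimed at screen analysts and cell biologists
who want the scoring rules to be explicit, deterministic and testable.

## The scoring model

For guide *g* in sample *s* with raw count *c₍gs₎*:

- **Normalization:** n₍gs₎ = c₍gs₎ / Σ₍g′₎ c₍g′s₎ × 10⁷ (each sample
  column sums to 10⁷).
- **Fold enrichment**, per pool: FE₍g₎ = n(treated) / n(untreated),
  with a zero untreated value reformatted to 1 so the ratio stays
  finite; a zero treated value gives FE = 0.
- **Calling:** a guide is reproducibly enriched when FE > 5 (strictly)
  in *both* replicate pools of its half-library; a gene is a
  **candidate** when it has enriched guides in *both* half-libraries,
  and **partial** when in exactly one.

Threshold, replicate mode and the per-half guide minimum are
parameters; the defaults are the rules above.

## Modules

| Stage | Key functions |
|---|---|
| Read processing | `count_screen()`, `demultiplex_reads()`, `extract_spacers()`, `count_guides()` |
| Scoring & calling | `run_screen()`, `normalize_counts()`, `fold_enrichment()`, `call_enriched_sgrnas()`, `call_candidate_genes()`, `export_heatmap_matrix()` |
| Simulation | `simulate_screen()`, `screen_sim_config()`, `emit_fastq()` |
| Imaging | `pearson_roi()`, `manders()`, `binarize_marker()`, `masked_mean_intensity()`, `line_profile()`, `synth_coloc_image()` |
| Shell interface | `exec/lyscreen` with subcommands `simulate`, `count`, `enrich`, `coloc` |

## Worked example

Simulate a 100-gene screen with 3 true resistance genes, then call
candidates from the count table:

```r
library(lyscreen)
cfg <- screen_sim_config(n_genes = 100, n_hit_genes = 3, depth = 2e5, seed = 42)
sim <- simulate_screen(cfg)
res <- run_screen(sim$counts, sim$samples, sim$library)
res$report
#> Screen candidate report: 3 candidate gene(s), 0 partial
#>   enriched sgRNAs: 17 of 600
#>   parameters: threshold > 5, replicate_mode = all, min_per_half = 1
#>   candidates: GENE0017, GENE0055, GENE0072
sim$truth$hit_genes
#> [1] "GENE0017" "GENE0055" "GENE0072"
```

All three simulated resistance genes are recovered, with no false
calls. The per-pool fold enrichments behind the first candidate show
the half-library structure (A guides are screened in the A pools, B
guides in the B pools):

```r
round(res$fe[res$report$supporting_guides[["GENE0017"]], ], 1)
#>               A-1  A-2  B-1  B-2
#> GENE0017_sg1 50.8 47.5  0.0  0.0
#> GENE0017_sg2 28.7 26.9  0.0  0.0
#> GENE0017_sg3 20.8 19.2  0.0  0.0
#> GENE0017_sg4  0.0  0.0 71.7 63.0
#> GENE0017_sg5  0.0  0.0 27.4 23.1
```

Every listed guide exceeds the fivefold threshold in both replicate
experiments of its half-library, which is exactly the calling rule.

On the imaging side, a synthetic two-channel image with a designed
colocalized fraction of 0.5 recovers that fraction as the Manders
coefficients:

```r
si <- synth_coloc_image(overlap_fraction = 0.5, seed = 1)
round(manders(si$ch1, si$ch2), 4)
#>  M1  M2
#> 0.5 0.5
```

The same stages are available from a shell:

```sh
exec/lyscreen simulate --out sim --n-genes 100 --n-hit-genes 3 --seed 42 --fastq
exec/lyscreen count  --fastq sim/reads.fastq.gz --library sim/library.tsv --samples sim/samples.tsv --out counts
exec/lyscreen enrich --counts counts/counts.tsv --samples sim/samples.tsv --library sim/library.tsv --out calls
```

Each run writes a `config.json` echoing the effective parameters, and
identical configurations reproduce byte-identical outputs.

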