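# ribodom

Quantifying nucleolar dominance from barcoded ITS amplicon sequencing.

## The problem

In interspecific hybrids such as *Festuca* × *Lolium* (Festulolium), the 45S
rDNA arrays inherited from the two parents compete: often only one parent's
rRNA genes are transcribed while the other's are silenced — *nucleolar
dominance*. Because the internal transcribed spacers ITS1 and ITS2 diverge
between the parental species, deep amplicon sequencing of these spacers from
genomic DNA (what the hybrid *carries*) and from cDNA (what it *expresses*)
measures both the genomic ratio of parental rDNA units and their expression
ratio. `ribodom` implements the complete computational pipeline for this
design, for researchers working on hybrid and allopolyploid rDNA biology:

1. **Reference database** (`load_references()`, `between_group_mean_distance()`,
   `derive_identity_thresholds()`) — species-labelled parental ITS alignments;
   between-species mean p-distance with pairwise deletion,

   d(g₁, g₂) = mean over cross-group pairs of (# differing sites) / (# sites
   where both sequences have an unambiguous base);

   the classification identity threshold per region is 1 − min d, rounded up
   to the nearest 0.5 percentage points (ITS1: 1 − 0.017 → 98.5 %;
   ITS2: 1 − 0.033 → 97 %).
2. **Preprocessing** (`merge_read_pairs()`, `demultiplex()`,
   `trim_barcodes_and_primers()`, `reference_filter()`, `dereplicate()`) —
   2×300 bp mates merged by best ungapped overlap with a quality-aware
   consensus, dual 12-nt barcode demultiplexing, primer trimming, a
   best-identity screen against the references (removes endophyte/unspecific
   contamination), and exact-string dereplication into a ribotype × sample
   count table.
3. **Classification** (`best_hit()`, `classify_ribotypes()`,
   `remove_global_singletons()`) — each ribotype is assigned the parental
   type of its best reference hit iff the alignment spans > 200 columns and
   identity strictly exceeds the region threshold; cross-type ties are
   ambiguous; ribotypes seen exactly once in the whole dataset are removed.
4. **Dominance** (`sample_proportions()`, `aggregate_proportions()`,
   `dominance_report()`) — per-sample parental proportions
   p(type) = reads of type / classified reads, means ± SD over genotypes,
   and the DNA→cDNA shift that expresses dominance.
5. **Diversity** (`choose_subsample_depth()`, `rarefy()`,
   `rarefied_diversity()`, `depth_bias_correlation()`, `anova_one_way()`) —
   ribotype diversity D = k/m at a common subsampling depth m (the
   second-lowest per-sample total), the depth-bias Pearson diagnostic before
   and after subsampling, and one-way ANOVA of D across generations.
6. **Synthetic data** (`default_scenario()`, `generate_dataset()`) — a fully
   specified generator (parental pools at the published divergences, genomic and
   near-total cDNA mixing fractions, sequencing error, chimeras,
   contaminants) with a per-read truth manifest, so the entire pipeline runs
   and validates itself without downloads.

## Worked example

```r
library(ribodom)
library(dplyr)

scenario <- default_scenario(generations = c("F1", "F2"),
                             genotypes_per_generation = 3,
                             include_parents = TRUE,
                             n_reads = 1000, seed = 42)
generate_dataset(scenario, "demo")
res <- run_pipeline(run_config(dir = "demo", outdir = "demo/out", seed = 42))

res$thresholds
#>   region min_cross_divergence identity_threshold rule_id
#> 1 ITS1                 0.0182              0.985 ceil(1-min_divergence, step)
#> 2 ITS2                 0.0333              0.97  ceil(1-min_divergence, step)

res$summary |>
  filter(parental_type == "Lolium-type", generation %in% c("F1", "F2")) |>
  select(generation, template, region, mean_p, sd_p, n_genotypes) |>
  arrange(region, generation, template)
#>   generation template region mean_p      sd_p n_genotypes
#> 1 F1         DNA      ITS1    0.626 0.0162              3
#> 2 F1         cDNA     ITS1    0.993 0.00178             3
#> 3 F2         DNA      ITS1    0.686 0.0141              3
#> 4 F2         cDNA     ITS1    0.990 0.00322             3
#> 5 F1         DNA      ITS2    0.649 0.0158              3
#> 6 F1         cDNA     ITS2    0.993 0.0000688           3
#> 7 F2         DNA      ITS2    0.680 0.0298              3
#> 8 F2         cDNA     ITS2    0.992 0.00194             3
```

Reading: the recomputed reference divergences put the classification
thresholds at 98.5 % (ITS1) and 97 % (ITS2). In the F1 hybrids roughly 63 %
of *genomic* rDNA units are Lolium-type, but ~99 % of the *expressed* (cDNA)
sequences are — nucleolar dominance by the Lolium parent, recovering the
generator's ground truth (DNA 0.627, cDNA 0.997):

```r
res$report |> distinct(generation, region, dominant_type, strength, label)
#>   generation region dominant_type strength label
#> 1 F1         ITS1   Lolium-type      0.993 dominant
#> 2 F1         ITS2   Lolium-type      0.993 dominant
#> 3 F2         ITS1   Lolium-type      0.990 partial_dominance
#> 4 F2         ITS2   Lolium-type      0.992 dominant
#> 5 P_Fp       ITS1   Festuca-type     1     dominant
#> ...

res$anova   # rarefied-diversity ANOVA across generations, per homeolog/region
#>   homeolog     region     F df_between df_within p_value
#> 1 Festuca-type ITS1   1.14           2        11  0.354
#> 2 Festuca-type ITS2   0.435          2        11  0.658
#> 3 Lolium-type  ITS1   3.48           2        10  0.0714
#> 4 Lolium-type  ITS2   0.792          2        10  0.480
```

No generation differs significantly in rarefied ribotype diversity — no
sign of rDNA homogenization over these generations. `autoplot(res$summary)`
and `autoplot(res$diversity)` draw the DNA-vs-cDNA proportion bars and the
per-homeolog diversity bars.

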