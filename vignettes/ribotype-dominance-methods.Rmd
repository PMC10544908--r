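---
title: "Measuring nucleolar dominance from ITS amplicons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring nucleolar dominance from ITS amplicons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribodom)
```

## The measurement model

A hybrid carries rDNA units from both parents; transcription may use both or
silence one (nucleolar dominance). Amplifying ITS1 and ITS2 separately from
genomic DNA and from cDNA, with sample-specific 12-nt dual barcodes, gives
two paired readouts per genotype: the genomic composition of the rDNA pool
and the composition of its transcripts. The analysis reduces every library
to a vector of parental-type proportions and a ribotype-diversity value, and
all downstream claims (dominance, its strength, homogenization over
generations) are statements about those two summaries.

The pipeline assumes: (i) the parental ITS sequences are divergent enough
that single reads can be assigned (between-species p-distances here are
0.017–0.111, an order of magnitude above the per-read residual error after
merging); (ii) PCR amplifies both parental templates with similar
efficiency within a region (any shared bias cancels in DNA-vs-cDNA
comparisons of the same region); and (iii) sequencing artefacts are either
rare variants (handled by singleton removal), low-identity sequences
(handled by the reference screen), or parental mosaics (handled by the
cross-type tie rule and by the width of the identity margin).

## Distances and classification thresholds

Between-species divergence is the mean p-distance over all cross-group pairs
of an aligned reference set, with *pairwise deletion*: a column is skipped
for a pair when either sequence has a gap or an ambiguity code (including
N). Within-group means are reported for audit but never drive thresholds.

The identity threshold for a region is derived from the most similar
species pair: `1 - min_divergence`, rounded **up** to the nearest multiple
of `margin_step` (default 0.005, i.e. half a percentage point); exact
multiples are left unchanged, and the downstream comparison is strict
(identity must *exceed* the threshold). This rule reproduces both published
operating points from the published minima (0.017 → 98.5 %, 0.033 → 97 %)
and is monotone: a more similar species pair can only tighten the
threshold. The `rule_id` is carried in the `threshold_set` so any table of
thresholds is self-describing.

```{r}
derive_identity_thresholds(
  tibble::tibble(region = c("ITS1", "ITS2"), group1 = "Fp", group2 = "Lm",
                 distance = c(0.017, 0.033)))
```

## Alignment identity and the best hit

`align_identity()` performs a global alignment with free end gaps
(match +1, mismatch −1, gap open 2, gap extend 1; Biostrings'
`pairwiseAlignment(type = "overlap")`). Identity is matches divided by the
alignment columns spanned by both sequences: end-gap columns are excluded,
internal gap columns count against identity, and `aln_length` is that
column count — the analogue of a BLAST hit length, which is what the
`> 200` column rule is applied to.

`best_hit()` ranks references by alignment *score* and reports the winner's
identity. Ranking by identity alone is ill-posed under free end gaps: a
12-column perfect end-overlap against an unrelated reference would carry
identity 1.0 and outrank a genuine full-length hit at 0.99. Score ranking is
the BLAST-like resolution; the test suite pins it to an independent
affine-gap dynamic program and to exhaustive Hamming scans. Ties at the top
score and identity are recorded; a tie across references of *different*
parental types makes the ribotype `AMBIGUOUS` (this is what catches evenly
split chimeras), while ties within a type are assigned — the parental type,
not the species, is the unit of inference. No k-mer prescreen is used: the
reference sets in this design are at most a few dozen sequences, and the
vectorised aligner scans all of them in one pass, so any top-k prescreen
would be a no-op at risk of losing hits.

## Preprocessing choices

**Merging.** Mates are merged at the ungapped overlap maximising the match
count (ties to the longer overlap), requiring ≥ 20 overlap columns and a
mismatch fraction ≤ 0.25. At disagreeing overlap columns the base with the
higher Phred quality wins if the difference is ≥ 6 (`delta_q`), else the
consensus is `N`; agreements keep the higher quality. These defaults mimic
the behaviour of the classical contig-assembly step in amplicon pipelines;
all three are exposed in the configuration. A practical consequence worth
knowing: in the double-covered overlap, an error on one mate (low quality)
is corrected by the other (high quality), so the residual per-base error
rate after merging is roughly the square of the raw rate, and most
error-containing reads collapse back onto their true ribotype.

**Demultiplexing** is exact by default (`max_bc_mismatch = 0`): the barcode
pairs are unique by design, and with 12-nt barcodes an exact match keeps the
assignment unambiguous. Contigs matching two samples at a nonzero tolerance
go to an `ambiguous` bin and are never double-counted.

**Primer trimming** locates each primer by a Hamming match (≤ 2
substitutions) at its expected offset and retries the reverse-complemented
contig before rejecting, so inverted contigs are recovered. ITS2 inserts
retain the 51 nt of 5.8S covered by the amplicon; the references must match
that extent.

**Reference screen.** An insert is kept iff its best identity to any
reference is ≥ 0.75 over an alignment covering ≥ 0.5 of the insert. This is
deliberately permissive — its job is to remove endophyte/unspecific
sequences (uniform-random sequences score far below 0.75), not to
classify; 50/50 parental chimeras pass here and are dealt with by the tie
rule at classification. Qualities are carried through but not used for
filtering: the design has no quality-trimming step, and the merge consensus
already consumes the quality information.

**Dereplication** is exact-string over the whole region dataset, DNA and
cDNA pooled, so a ribotype shared between templates is one row with two
count cells. Ribotype ids are assigned by decreasing total abundance, which
makes them deterministic for a given input multiset.

## Proportions and dominance

Proportions are sequence-weighted (read counts, not ribotype counts), and
the denominator excludes `AMBIGUOUS` and `TOO_SHORT` ribotypes; the excluded
counts are reported alongside so the exclusion is auditable. Singleton
removal happens *after* classification and proportions are computed after
removal, following the stated order of the original protocol. Third-party
types (e.g. Lolium-type reads in a *Festuca* × *Festuca* cross) are reported
as their own category rather than folded into the cross's parents.

Group summaries are means ± sample SD (n − 1) over genotypes — the
biological replicate. The dominance report declares a parental type
*dominant* when its cDNA group mean is ≥ 0.99 ("nearly 100 %"), *partial
dominance* at ≥ 0.60, *codominant* below; exact cDNA ties are flagged.
Both cutoffs are configurable; they are labels on a continuous quantity,
not part of the estimation.

## Rarefied diversity

The diversity statistic is deliberately the simplest one: D = k/m, distinct
ribotypes over sequences, at a common depth m. The depth is the
*second-lowest* per-sample total within each homeolog × region dataset, so
only the single shallowest sample is lost; samples below m are excluded and
listed. Subsampling is uniform without replacement (a multivariate
hypergeometric draw, checked against its closed-form moments and vegan's
`rrarefy`). The original design subsamples once; `n_draws = 1` with a
recorded seed is the default, and `n_draws > 1` reports the mean and SD of
D over draws for users who want the subsampling noise quantified.

Diversity is computed per homeolog class because the two parental rDNA
families have independent histories in the hybrid; the depth rule is applied
within each homeolog × region dataset. The depth-bias diagnostic reports
the Pearson correlation of the per-sample *original* total with both the
pre-subsampling ratio and the post-subsampling D (DNA and cDNA pooled), the
before/after comparison that motivates subsampling in the first place.
The ANOVA across generations (parents included as levels) uses
genotype-level D values as replicates and the classical fixed-effects
F = MS_between / MS_within. Degenerate inputs are detected on the sums of
squares at a relative 1e-12 tolerance: all-equal observations give F = 0,
p = 1; zero within-group variance with unequal means is flagged rather than
reported as an infinite F.

## What the synthetic generator emulates — and what it does not

`scenario_config()` fixes the simulated experiment's conditions: two parental pools per
region at the published divergences (ITS1 0.017, ITS2 0.033), five
ribotypes per species pool at intra-divergence 0.005 with geometric
abundances (ratio 0.5) — a dominant repeat with minor variants; genomic
Lolium fractions 0.627 (F1), 0.675 (F2), 0.70 (F3), 0.96 (BC1) and a cDNA
fraction of 0.997 everywhere (the near-total dominance regime); 5,000 read
pairs per sample; per-base substitution error 0.003; 1 % single-breakpoint
chimeras and 1 % uniform-random contaminants. The F1/F2 DNA fractions and
the cDNA fraction are published operating points; F3 and BC1 interpolate
the same regime toward the backcross parent, and the chimera/contaminant
rates are ordinary amplicon-library magnitudes chosen once. Substitutions
only (no indels) by default so the realised p-distance is exact,
`round(L·d)/L`; qualities are Q40 at correct bases and Q10 at injected
errors — crude, but exactly what the merge consensus rule needs to be
exercised. Every read carries a truth-manifest row, so stage-wise confusion
matrices and read-level classification accuracy are computable.

What passing tests on this generator shows: the pipeline recovers known
mixing fractions within binomial noise, classifies reads at ≥ 99 % accuracy
when divergence dominates error, rejects contaminants, flags even chimeras,
and is deterministic. What it does not show: robustness to indels and
homopolymer artefacts, to quality-by-cycle error structure, to primer-site
variation, or to uneven library depths — in particular, because every
synthetic sample gets the same read budget, the positive depth–richness
correlation seen in real libraries is not reproduced, so the depth-bias
diagnostic is exercised for correctness, not for its real-data sign or
magnitude. Claims about real data rest on the method, not on these
simulations.

## Reproducibility and problem sizes

One master seed drives everything; per-sample and per-region seeds are
derived deterministically from it, and reruns of the same configuration are
bit-identical (asserted in the tests). Output tables carry the package
version and a hash of the analysis parameters. The test suite runs the
recovery experiment at the full 5,000 reads per sample over ten seeds, the
ANOVA calibration at 10,000 null simulations, and rarefaction checks at
1,000 draws; the vignette and README examples use 1,000 reads per sample,
which is ample for the proportion estimates they illustrate (binomial SE
≈ 0.015 at p = 0.63).

## Known limitations

- Classification is reference-bounded: a ribotype from a species absent
  from the database is either discarded by the screen or absorbed by the
  nearest present species if it clears the identity threshold.
- The identity thresholds are derived from the reference alignment; a
  different reference set (more divergent accessions, different alignment)
  shifts the minima and thus the thresholds. The derivation is recomputed
  from whatever references are supplied, never hard-coded.
- Proportions are read proportions. Mapping them onto rDNA copy numbers or
  locus dosage requires external calibration (locus counts, copy-number
  assays) outside this package's scope.
- D = k/m is depth-sensitive by construction even after subsampling when
  abundance distributions differ strongly between samples; it is the
  study's statistic, not a general-purpose diversity index (no Shannon,
  Simpson or Chao estimators are provided by design).
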