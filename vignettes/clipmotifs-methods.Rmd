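---
title: "clipmotifs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{clipmotifs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clipmotifs)
```

# Scope

`clipmotifs` re-implements, as a tested reusable pipeline, the
computational core of an iCLIP study of an RNA-binding protein that
recognises purine-rich motifs: crosslink-site extraction from barcoded
reads, genomic region-class enrichment, splice-junction RNA maps,
pentamer Z-score motif discovery, control cassette-exon selection, and
multivalent trimer pair-motif enrichment with a bootstrap
false-discovery estimate.  Everything runs end-to-end on synthetic data
with planted signal; the synthetic-data generator is first-class,
tested code, not a fixture.

# The crosslink model

iCLIP reverse transcription truncates at the protein–RNA crosslink, so
the nucleotide immediately 5' of a read's genomic start (in the read's
strand orientation) is taken as the crosslink site.  Reads carry a
9-nt block at their 5' end: two degenerate bases, a 4-nt experiment
index, and three more degenerate bases.  The five degenerate bases form
the random barcode (UMI).  Reads truncating at the same genomic
nucleotide with the same barcode are PCR copies of one cDNA; the
unique-cDNA count of a site is the number of distinct barcodes in its
(chrom, strand, truncation position) group.

Numerical/convention choices:

* The crosslink site is `start - 1` on "+" and `end` on "-"
  (upstream-nucleotide convention, the iCLIP standard); a
  `convention = "start"` flag selects the first read nucleotide
  instead.
* Barcode comparison is exact; no Hamming collapsing of barcodes is
  attempted.
* All coordinates are 0-based half-open on disk and in site tables.

The bundled aligner is a naive exhaustive scanner for toy genomes: a
hit is reported only when exactly one locus (over both strands)
achieves the best mismatch count, with at most one mismatch.  It
implements the alignment *policy* of the original analysis (one
mismatch, unique hits); real-data users supply pre-aligned reads as a
barcoded BED and skip it.

# Region enrichment and RNA maps

Crosslink tags are assigned to ncRNA, ORF, 5'UTR, 3'UTR, intron or
intergenic classes.  Where annotations overlap, a nucleotide takes the
highest-precedence class, ncRNA > ORF > UTR5 > UTR3 > intron >
intergenic; the precedence rule is a package choice (no rule is forced
by the data model) and is applied consistently to both tag assignment
and class length computation, so a uniform random tag stream has unit
enrichment in every class.  Density is tags per nucleotide of
precedence-resolved class length; enrichment is density over the
genome-average density.

The RNA map accumulates crosslink counts at offsets within ±300 nt of
3' or 5' splice sites.  Offset 0 is the first exonic nucleotide at a
3'ss and the last exonic nucleotide at a 5'ss; positive offsets run
downstream in transcript orientation.  Each offset's count is divided
by the number of junctions whose transcript spans the absolute
coordinate at that offset, scaled by `1e9 / total crosslinks`, and
smoothed.  "Smoothed" is a centred running mean, default window 5 nt,
truncated at the profile ends (no kernel is dictated by the source
analysis; a boxcar is the simplest auditable choice and the tests hold
it to an independent convolution oracle).

# Pentamer Z-scores

For each site the oriented 61-nt window (−30..+30) is extracted; sites
closer than 30 nt to a contig end are dropped by default.  Randomized
site sets are drawn uniformly within the *same region instance* as each
true site — for CDS-resident sites this is randomization within the
same CDS; sites in other classes are randomized within their own
instance of that class (an extension, flagged in output); unannotated
sites are excluded and counted.  For each of the 1024 pentamers,

\[ z = \frac{\mathrm{obs} - \overline{\mathrm{rand}}}{\mathrm{sd}(\mathrm{rand})} \]

where the statistic is, by default, the number of windows *containing*
the pentamer (robust to within-window repeats); a
`count_mode = "occurrences"` alternative counts all occurrences, since
the original method's statistic is not fully specified.  The standard
deviation is floored at 1e-9 and such pentamers are flagged.  The
default number of randomizations is 100.  Replicate concordance is the
Pearson correlation of the 1024-dimensional z-vectors.

# Control-exon selection

Control cassette exons are selected by a funnel that is logged step by
step: MiDAS p > 0.95; at least 3,000 reads (3 replicates summed) in
*each* condition separately (the stricter reading of the
"per-condition" threshold); internal to a transcript (flanking introns
on both sides); at least 100 nt long (so the first-50 and last-50
windows never overlap); mutually non-overlapping — every member of an
overlapping cluster is dropped, since the source procedure does not say
which representative to keep; and free of ambiguous nucleotides.
Up/down regulated exons are called at MiDAS p < 0.05 with fold change
beyond ±2; fold changes may be signed ratios or log2 (declared by the
caller, converted internally).  A simple period-3 tandem-repeat filter
(default: 6 or more perfect unit copies) stands in for full repeat
masking, which is out of scope at toy scale.

# Trimer pair motifs

The target trimers are AGA, AAG and GAA.  Analysis regions are the
first/last 50 nt of the exon and the adjoining 50 nt of each flanking
intron.  A qualifying pair is an ordered pair of trimer occurrences
fully inside the region with the downstream start at least k = 3
positions after the upstream start, which exactly excludes overlap
artifacts such as AAGA.  An exon "has" a pair if at least one
qualifying pair exists (presence/absence — the 2×2 Fisher framing
forces a binary per-exon event).  The nine specific ordered pairs plus
three degenerate pairs (specific upstream, any target trimer
downstream) are tested one-sided for over-representation in the target
set; per-position single-trimer tests are two-sided since no direction
is asserted there.  Results rank by smallest p, then larger target
count, then pair name.

The bootstrap FDR draws, per trial, 109 exons without replacement from
a population of known exons (at full scale, 10,000 trials) and re-tests
every pair against the fixed control set; the FDR of a pair is the
fraction of trials with a p-value at or below the observed one, and a
zero count is reported as "< 1/n_trials".  Observed p-values above
5e-4 are marked not significant.  Note that this per-pair definition
deliberately applies no multiplicity correction across the 12 pairs:
when a null target set is drawn from the population itself, each
pair's FDR is approximately uniform, so the *minimum* FDR over the 12
partially correlated pairs falls below 0.05 in roughly 20% of runs
(measured by the acceptance suite).  A selection-corrected alternative
would compare the observed best p against the distribution of each
trial's minimum p; it is not implemented because the per-pair formula
is the stated contract.

The mutation designer ablates every target trimer by replacing each G
inside any AAG/AGA/GAA occurrence with C, re-scanning to a fixed
point.  A G→C substitution can never create a purine trimer, so the
scan converges and is idempotent.

# The synthetic world

`sim_config()` fixes the stated world; its defaults are the conditions
exercised by the test suite:

* Toy genome: 20 non-overlapping genes with 5'UTR, 3–5 ORF exons
  (120–300 nt), introns (200–600 nt) and 3'UTR; ~15% of genes are
  single-block ncRNAs; uniform A/C/G/T base composition.  Uniform
  composition is the neutral default; the conclusions the tests draw
  are insensitive to realistic (near-uniform) exonic compositions.
* Crosslinks: 1,000 unique cDNA events, half placed on planted GAAGA
  instances (two per ORF exon, in transcript orientation), half
  uniform over ORF exons.  The crosslink nucleotide within a motif is
  a *free parameter* (default: offset 1, the first A); nothing in the
  source data constrains it.
* PCR: each event yields `1 + Poisson(3)` identical reads sharing one
  barcode; sequencing error defaults to 0 so deduplication tests are
  exact.
* Exon sets: 100 exons per regulated class; "down" exons receive, with
  probability 0.6, a planted AGA followed (gap 3–10) by a random
  target trimer inside the last 50 nt; controls and the 2,000-exon
  population are background-only.

Ground truth records what is *recoverable*: the unique-cDNA count is
the number of distinct (chrom, strand, position, barcode) tuples, since
two events colliding in both position and barcode are indistinguishable
to any downstream observer.

What the generator does **not** emulate — and hence what a green test
does not establish: sequencing error and quality structure, spliced
reads, realistic gene-length and composition statistics, array probe
behaviour behind the differential-exon table, and transcriptome-scale
background motif frequencies.

Two consequences of the toy scale are worth spelling out because they
shaped the acceptance suite:

* **Replicate concordance needs depth.**  Deduplication collapses all
  crosslinks at a planted instance to a single site, so with 1,000
  events on a 20-gene genome the planted pentamer's z saturates near
  4–7 and the replicate correlation stays near 0.2 no matter how
  correct the code is.  The concordance test therefore runs in a
  proportionally deeper world (150 genes, 3,000 events per replicate),
  where the planted z reaches ~20 and r ≈ 0.6, emulating the
  deep-sequencing regime in which replicate correlations near 0.95 are
  reported; the null half of the test runs at shallow depth.
* **Degenerate pairs do not always out-rank specific ones.**  A
  planted upstream AGA also forms qualifying pairs with background
  trimers in the same 50-nt region, so the specific AGA→X pairs carry
  almost the same planted signal as AGA→Any (presence ~0.55 vs ~0.7)
  at a lower control baseline (~0.17 vs ~0.29); their Fisher p-values
  are statistically indistinguishable, and AGA→Any ranks first in only
  about 6 of 10 seeds.  The corresponding acceptance expectation is
  left failing rather than met by tuning the generator.

# Known limitations

* The naive mapper is O(genome × reads) and intended for genomes up to
  a few megabases; no indels, no spliced alignment.
* Randomization of non-CDS sites within their own region instance is
  an extension of the CDS rule, flagged in output.
* The period-3 repeat filter does not detect divergent repeats.
* The no-antibody control channel is processed identically and
  reported side by side; no subtraction is performed.

# A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- make_genome(cfg)
rr  <- plant_crosslink_reads(sim$genome, sim$annotation, cfg)
dm  <- demultiplex(rr$reads, c(AACC = "rep1"))
aln <- map_inserts(dm$samples$rep1, sim$genome)
sites <- deduplicate(aln)

classify_sites(sites, sim$annotation,
               setNames(Biostrings::width(sim$genome),
                        names(sim$genome)))$density
pentamer_scores(sites, sim$genome, sim$annotation, seed = 1)$scores[1:5, ]

es <- make_exon_sets(cfg)
ex <- es$exons
res <- pair_test_all(ex[ex$class_label == "down", ],
                     ex[ex$class_label == "control", ])
bootstrap_fdr(res, ex[ex$class_label == "population", ],
              ex[ex$class_label == "control", ],
              n_trials = 500, seed = 1)
```
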