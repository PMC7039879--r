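---
title: "RNA-chromatin interaction calling with radicl: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RNA-chromatin interaction calling with radicl: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radicl)
```

## The data and the construct

RADICL-seq captures RNA-chromatin contacts by ligating a bridge adapter
between an RNA molecule and a genomic DNA end held in proximity inside the
nucleus. After reverse transcription and second-strand synthesis the
chimera is digested with EcoP15I, a type III restriction enzyme that cuts
25-27 nt away from its CAGCAG recognition site; one site sits at each end
of the 50-nt adapter (`ecop15i_sites(radicl_oligos()$adapter_top)` returns
2), so every chimeric 150-nt read carries an RNA tag and a DNA tag of
near-uniform length flanking the adapter, followed by a sequencing linker
and a 6-nt multiplexing barcode.

The adapter is ligated to the RNA 3'-OH, so its orientation within the
read discriminates the two tags unambiguously: when the adapter top strand
appears in read orientation, the upstream flank is the RNA tag read in
transcript sense; when its reverse complement appears, the whole construct
was sequenced from the other side and the read is reverse-complemented
before splitting. This orientation rule is the single contract shared by
the simulator and the extractor. The byte-level placement of the barcode
within the 3' linker read-through is not fully specified by the protocol
description; the package adopts a documented stand-in layout (linker
upper strand followed immediately by the barcode) used consistently on
both sides.

## Read deconvolution

`extract_tags()` locates the adapter by exhaustive Hamming scan of the
top strand and its reverse complement (`max_adapter_mismatches = 2` by
default), keeping the unique best placement and rejecting ties as
`ambiguous_adapter`. A Hamming-only scan (no indels) was chosen
deliberately: substitution errors dominate the platform, and the decision
makes the extractor exactly testable against the simulator; it is a
simplification relative to HMM-based demultiplexers. The RNA tag is the
upstream flank (at least 25 nt; flanks of 28+ nt keep only the
adapter-proximal 27 bases, since DNase fragments may extend past the
EcoP15I read-through). The DNA tag length (25-27 nt) is resolved by
scoring the sequencing-linker stub at the three candidate offsets; the
barcode is then read at its fixed post-linker position and matched to the
whitelist within `max_barcode_mismatches = 1` (unique best match, else
`bad_barcode`).

rRNA contamination is screened on the RNA tag only, by exact k-mer
sharing (default k = 21, both strands) against an rDNA repeating unit;
with 25-27 nt tags a single shared 21-mer is, for practical purposes,
proof of origin, and the false-positive probability against a 5-kb
reference is about $5000 \times 2 \times 7 / 4^{21} \approx 10^{-8}$ per
tag. PCR duplicates are removed on the exact triple (RNA sequence, DNA
sequence, barcode), keeping the first occurrence.

## Mapping and pairing

On real data, tags are aligned externally and imported as a tab-separated
pairs table; both tags must map uniquely, encoded as BWA MAPQ 37. The
protocol text states the threshold both as "= 37" and as ">= 37"; the
package adopts the weaker `mapq_min >= 37` form and exposes it as a
parameter. For fixture genomes, `exact_map()` is a deterministic
stand-in for the aligner: a unique exact hit on either strand gets MAPQ
37, two or more hits MAPQ 0, no hit is unmapped. The RNA tag's strand is
the strand whose sense matches the tag, which is what preserves
sense/antisense transcript assignment downstream; DNA tag strand is
stored but ignored, as the method discards it.

Every fragment is reduced to the single base at its center,
`start + floor((length - 1) / 2)`; for even lengths the base left of the
midpoint is used (the protocol does not specify a convention; any fixed
rule works, and this one is documented for reproducibility). Distance
between tags is measured center-to-center. The underlying description
says only "linear genomic distance between RNA and DNA tags" without an
edge/center choice; center-to-center is consistent with the center-point
feature assignment and is applied everywhere, including the six distance
classes: local (<= 10 kb), short (> 10-100 kb), medium (> 100 kb-1 Mb),
long (> 1-10 Mb), extreme (> 10 Mb), and trans.

## The significance model

Contacts are aggregated per (RNA feature, 25-kb genomic bin). For RNA $r$
with genome-wide total $N(r)$ contacts over $U(r)$ distinct bins, the
count $k$ in a bin is scored with the one-sided cumulative binomial test

$$p = \sum_{i=k}^{N} \binom{N}{i} P^i (1-P)^{N-i}, \qquad P = 1/U(r),$$

computed through the survival function of the binomial distribution for
numerical stability (the test suite checks agreement with brute-force
log-space pmf summation to 1e-9 relative). $N$ and $U$ are genome-wide,
cis and trans alike. All observed (RNA, bin) p-values are adjusted
jointly by Benjamini-Hochberg — the description is silent on per-RNA
versus global correction, and a single adjustment over the full
interaction list is the most literal reading of one call to the
correction — and interactions with adjusted p < 0.05 are significant.
Blacklist filtering is applied after significance, matching the stated
order of operations; by default a call is removed when its DNA-bin
interval intersects a blacklist region, with a toggle to test the raw
tag centers instead.

Two model consequences worth knowing: an RNA observed in a single bin has
$P = 1$ and can never be significant, and the uniform-background
assumption makes the test anti-conservative for strictly proximal RNAs —
the null calibration property (an RNA with 10,000 contacts spread
uniformly over 1,000 bins yields under 1% significant bins) holds by
construction only under an exchangeable background.

## The synthetic-data generator

`sim_config()` / `build_fixture()` / `sample_contacts()` /
`synthesize_reads()` produce, deterministically under a seed, a small
genome with non-overlapping genes in four biotype groups, TADs, A/B
compartments, repeat annotation with a planted multi-copy identical
segment, a blacklist, a synthetic rRNA unit, ground-truth contacts, and
full 150-nt reads. Default study conditions: two 500-kb chromosomes, 40
genes with three exons each, biotype mix 55/20/15/10% across
protein_coding / long_ncRNA / ncRNA / other, log-normal expression
weights (meanlog 1, sdlog 1), cis decay $P(d) \propto (d + d_0)^{-\alpha}$
with $\alpha = 1.2$ and $d_0 = 1$ kb, 10% trans contacts, 15%
nascent-like contacts (< 1 kb, the proxy for RNA captured at its own
transcription locus), 10% PCR duplicates, 5% rRNA contaminants, and a
0.1% per-base substitution rate. These values were fixed once as
plausible for a chromatin-interaction library at fixture scale — the
decay exponent near 1, a visible but minority trans fraction, and
contamination/duplication rates in the range routinely reported for
proximity-ligation libraries — and are not tuned thereafter.

Enriched (RNA, bin) pairs are simulated by discretising the background
mixture onto the bin grid for that RNA, multiplying the target bin's mass
by the fold factor and renormalising, so a fold-$f$ bin among $B$
uniform bins is hit with probability $f/(B-1+f)$ — the closed form the
generator tests check. Cis distances are drawn by inverse-transform from
the truncated power law, then clipped to the feasible side of the RNA
position, and the distribution test accounts for that clipping exactly.

What the generator does not emulate: indel sequencing errors, quality
score structure, chromatin-state-dependent contact propensity, gene
nesting and isoform complexity, and realistic repeat families (the
planted repeat is a verbatim duplicated segment). Tests passing on this
fixture therefore validate the bookkeeping and the statistics, not
biological fidelity of any particular genome.

## Downstream summaries

* Reproducibility: pairwise Pearson correlation on counts of (RNA, bin)
  units observed in all replicates ("complete observations").
* Expression correlation: interaction counts per gene normalised to RPK,
  compared to TPM on log10 scale after a lower threshold of 1 on both,
  reported as $r^2$.
* Distance decay by expression quartile: distance from the DNA tag center
  to the nearest gene-span edge (0 inside the gene body), log-spaced
  bins, each quartile's curve normalised to sum to 1.
* TAD metaprofiles: each region extended by its own width on both sides
  and chopped into 300 bins, per-bin counts scaled to per-bp rates and
  averaged across regions, so the region proper occupies bins 101-200.
  The inside/outside split is computed TAD-by-TAD, because an RNA outside
  one TAD may originate inside a neighbouring one.
* Peak density: per-offset counts in a +/-5 kb window at 1-bp steps,
  divided by the mean over the window to align baselines. The phrase
  "mean of values of +/-5000 bp" is ambiguous between the window mean and
  the edge mean; the window mean is the default, with an edge-mean
  toggle.
* Repeat enrichment: percentage of significant interactions per RNA-DNA
  distance interval over the family's total RNA tag count
  (self-interactions removed first, "NR" = not repeat-mapped), compared
  between each family and NR by a two-sided equal-variance Student's t
  test on replicate-level proportions, as printed.
* Cross-condition comparisons: Jaccard distance between per-gene binary
  5-kb binding vectors; capture-rate difference as a percentage of the
  maximum in either condition (capture rate taken as CPM, the most
  natural reading of "normalized counts"); promoter (+/-2 kb around the
  TSS) log2 ratios of CPM with a pseudocount of 1 to handle zeros;
  shared interaction keys reported as a percentage of the union of the
  two sets (the printed percentage does not define its denominator; the
  union is the symmetric choice); top-K overlap with ties at the
  boundary broken by gene id.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script were chosen to make
every stochastic check statistically decisive at fixture scale: 50,000
reads for round trips, 10,000 contacts over 1,000 bins across 20 (null)
and 50 (power) seeds, 200 random triples for the binomial oracle, 100
vectors for the BH oracle. All coordinates are 0-based half-open
internally; BED is read and written natively and GTF converted on read,
which keeps a single convention and avoids off-by-one drift. Degenerate
inputs are handled explicitly: empty pair tables return empty objects
with a warning, regions whose extension leaves the chromosome are
dropped and counted, both-empty binding profiles give Jaccard distance
0, and zero-count promoters are covered by the pseudocount.

## Known limitations

The exact mapper is exhaustive-exact only (no mismatches), which is
appropriate for fixture genomes but not a replacement for a real aligner;
real data enters through the aligned-pairs table. The binomial background
is uniform over occupied bins, with no distance stratification or
matrix balancing — both are deliberate non-goals. Multi-mapping is
handled by exclusion (MAPQ filter), so repeat-dense interactomes are
under-represented exactly as in the original analysis; the tag-trimming
utility exists to quantify that effect, not to fix it.
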