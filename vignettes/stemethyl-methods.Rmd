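---
title: "Models and methods behind stemethyl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stemethyl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

stemethyl analyses plant whole-genome bisulfite sequencing (WGBS) methylomes
from the point where a bisulfite mapper has produced per-cytosine counts of
methylated and total reads. This vignette explains the statistical models the
package implements, the parameters that matter and their defaults, what the
synthetic-study generator does and does not emulate, and the design choices
made where the methodology was genuinely open.

## Sequence contexts

Plant cytosine methylation is analysed in three sequence contexts — CG, CHG
and CHH, with H one of A, T or C — because distinct maintenance pathways act
on each. `classify_contexts()` reads the context 5'→3' on the cytosine's own
strand: a `C` on the plus strand takes its two downstream reference bases; a
`G` on the plus strand is a cytosine on the minus strand and takes the
reverse complement of its two upstream bases. CG and CHG are symmetric
across strands, CHH is not. A cytosine whose context window runs off the
chromosome end or touches an `N` is emitted with an undefined context and
excluded from analysis rather than guessed; real assemblies contain enough
N runs that a guessing rule would contaminate per-context summaries.

## Conversion-rate calibration and site calling

Bisulfite treatment converts unmethylated C to U (sequenced as T); methylated
cytosines resist conversion. A small fraction of unmethylated cytosines also
escapes conversion, so apparent methylation at low levels is partly chemistry
noise. The unmethylated lambda phage spike-in measures this directly:
`estimate_conversion()` pools all lambda cytosines and returns
`conversion = sum(total - mc) / sum(total)`; typical plant libraries give
~99.5% conversion, i.e. a non-conversion rate around 0.005.

`call_sites()` tests each cytosine's pooled count against the null that all
its apparent methylation is non-conversion:
`p = P(X >= mc)`, `X ~ Binomial(total, non_conversion_rate)`. Choices made
here, since the upstream literature typically states only "binomial test
with FDR control":

- the test is one-sided upper-tail (only an excess of unconverted reads is
  evidence of methylation);
- replicates of a sample are pooled (counts summed per site) before
  testing, and the non-conversion rate is per sample, not global;
- multiple testing is controlled by Benjamini–Hochberg at q <= 0.05 — BH is
  transparent and easy to verify against an oracle, and the discreteness of
  small-count binomial p-values makes it conservative in practice;
- sites with fewer than 4 reads are excluded from testing entirely (the
  coverage floor used throughout the package).

## Sliding windows and DMR detection

Replicates are merged on a 200 bp sliding window advancing in 100 bp steps.
`build_windows()` pools counts per window by summation: per-site counts are
first summed across replicates, sites under the 4-read floor are dropped,
and the window level is `sum(mc) / sum(total)` over the context sites it
contains. Count pooling (rather than averaging per-site ratios) weights deep
sites more and makes window levels exact integer bookkeeping, which the test
suite checks as an identity. Windows are enumerated from position 0 of each
chromosome; a truncated tail window is emitted only when it covers bases no
earlier window covers, so a 1000 bp chromosome yields exactly nine windows.
CG and CHG counts from the two strands of a symmetric site both contribute
to their window — the strands measure the same methylation state and pooling
stabilises the counts — while CHH windows simply take every CHH site, as the
context is inherently strand-specific.

`call_dmrs()` compares a window between two samples with the 2x2 Pearson
chi-square test (no continuity correction) on pooled methylated /
unmethylated counts, then applies Benjamini–Hochberg across all tested
windows of the context. A window is a differentially methylated region (DMR)
when all three criteria hold:

| context | context sites in window | \|delta level\| | q |
|---------|------------------------|-----------------|------|
| CG, CHG | >= 5                   | >= 0.25         | <= 0.05 |
| CHH     | >= 15                  | >= 0.15         | <= 0.05 |
| all C   | >= 20                  | >= 0.20         | <= 0.05 |

The site-count floor is read as the number of covered context cytosine
positions in the window, not read counts. Windows with a degenerate margin
(no methylated or no unmethylated reads in either sample) have no defined
statistic and are skipped with a log line. Overlapping surviving windows of
the same direction are merged into one reported DMR spanning their union
(the merged delta re-pools the constituent windows' counts; the q-value is
the minimum). The direction convention is declared in all outputs: for a
comparison "A vs B", `hyper` means more methylated in B.

A DMR is associated with a gene — making it a differentially methylated gene
(DMG) — when it overlaps the gene body extended by 2 kb on both sides by
more than 1 nt; genes hit by both hyper- and hypomethylated DMRs are
labelled `mixed`.

## Profiles and summaries

All level aggregation in `feature_levels()`, `metaprofile()` and
`gene_methylation()` is count-pooled (`sum(mc)/sum(total)`), applied
uniformly so comparisons between features, bins and gene groups are
internally consistent; a feature set covering the whole genome reproduces
the genome-wide pooled level exactly. Sites inside overlapping features
count toward every feature they fall in, since an exon inside a TE is
legitimately both.

Metaprofiles scale each feature body to 20 bins and add 2 kb flanks in
100 bp bins (defaults; plot granularity is a presentation choice), orienting
minus-strand features 5'→3'. Body bin assignment uses the site's midpoint
offset `(d + 0.5)/width`, which makes the binning exactly mirror-symmetric
under strand reversal for even-width features; an odd-width feature has a
single self-mirroring central base that must land on one side or the other.

`level_histogram()` bins per-site levels into ten 10% bins with the final
bin closed (`[90,100%]`), so a fully methylated site is counted once.
`genome_summary()` reports covered and called-methylated site counts per
context; `context_proportions()` reports the share of called methylated
cytosines per context; `chromosome_density()` counts methylated sites per
100 kb bin (default) per chromosome, strand and context.

## Expression integration

Expression bins follow the conventional FPKM thresholds — None (<= 1),
Low (1,10], Moderate (10,100], High (> 100). Published descriptions of
these bins often overlap at exactly 100 ("<= 100" and ">= 100"); the package
makes the boundaries half-open and disjoint, assigning FPKM = 100 to
Moderate, so that binning is a partition. Methylation tertiles are computed
per genic region x context over genes with at least one covered site,
sorting by level with ties broken by gene id so the binning is reproducible;
genes with no covered site are `None`. The methylation–expression Spearman
correlation uses average ranks for ties and the large-sample p-value
approximation, is computed per region (promoter, gene body, 2 kb
downstream) x context, and refuses fewer than 10 genes. DEG calling is
deliberately an input contract, not a method: when no DEG table is given,
a documented fold-change rule (|log2 FC| >= 1 between condition means, both
means > 1 FPKM) generates lists for synthetic tests only.

## The synthetic-study generator

`simulate_study()` builds a complete two-condition study with known ground
truth. What it emulates, and the defaults (all in `synthetic_config()`):

- **Genome**: random sequence at GC fraction 0.34 (a typical broadleaf
  genome), split evenly across chromosomes. Genes (with exons, introns and
  UTRs) are placed without overlap in roughly the first half of each
  chromosome and TEs in the second half, giving the gene-rich
  hypomethylated versus TE-dense hypermethylated regional contrast plant
  methylomes show. Requested features that cannot be placed raise an
  explicit placement error — never silent truncation.
- **True methylation levels**: per context, a Beta mixture. Defaults place
  0.45 (CG), 0.65 (CHG) and 0.83 (CHH) of sites in an exactly-unmethylated
  point-mass component and 0.40 / 0.24 / 0.01 in a high component (means
  0.97 / 0.95 / 0.90), with a moderate middle component taking the rest —
  masses chosen to reproduce the familiar bimodal CG/CHG and low-CHH
  level histograms of stem methylomes. Published histograms constrain bin
  masses, not distributions; the Beta forms and their concentrations are a
  modeling choice, with concentrations set so each component's histogram
  mass matches its weight (the CHH middle component uses concentration 14
  so its spill below 10% stays within the tested tolerance).
- **TE effect**: an additive true-level boost (default +0.3, clamped to
  [0,1]) inside TE spans.
- **Planted DMRs**: intervals that shift condition B's true level by a
  configured delta (clamped). The shift is additive, so a planted delta is
  diluted wherever the base level is already high — visible in the toy
  pipeline, where a DMR planted on top of highly methylated CG sites can
  fall below the 0.25 delta criterion. Detection-side behaviour is tested
  with low-base-level mixtures where the realized delta equals the planted
  one.
- **Counts**: per replicate, depth ~ Poisson(30) per site — the simplest
  overdispersion-free model, standing in for unstated per-site depth
  structure — and methylated count ~ Binomial(depth, level*(1-nc) +
  (1-level)*nc) with non-conversion rate nc = 0.0049, mirroring ~99.5%
  conversion. The symmetric error term means pooled observed levels carry a
  small deterministic bias nc*(1-2*level) relative to true levels, largest
  (~0.0044) for the nearly-unmethylated CHH context and well inside the
  recovery tolerances the tests assert.
- **Lambda spike-in**: a 48,502 bp random sequence whose cytosines all have
  true level 0; methylated counts are pure non-conversion noise.
- **Expression**: a Gaussian copula on the ranks of true gene-body CG
  methylation. The latent normal correlation is set to `2*sin(pi*rho/6)` so
  the *population Spearman* correlation equals the configured rho exactly
  (at |rho| = 1 the copula degenerates to an exact monotone map, which is
  also why rho = ±1 is accepted rather than rejected). FPKM is log-normal
  (`10^(0.8 + 1.2 z)`), populating all four expression bins. A configured
  fraction of genes (default 10%) receives a condition-B log2 fold-change
  drawn from [1,3] with random sign; other contexts and regions inherit
  correlation only indirectly through genomic colocation.

What the generator does **not** emulate: read-level data (FASTQ, mapping
bias, PCR duplicates), sequencing error beyond non-conversion, replicate
overdispersion (depth is Poisson; biological replicates differ only by
counting noise), CpG-island-like local rate variation, or any mechanistic
link between methylation and expression beyond the copula. Tests passing on
this generator therefore demonstrate the correctness of the pipeline's
arithmetic and inference under its stated model — not robustness to the
full messiness of real libraries.

Determinism: every generator stage derives its RNG state from the config
seed plus a fixed stage offset, so identical configs give byte-identical
outputs, the two conditions share their base methylome (planted DMRs are
the only systematic difference), and any stage can be regenerated in
isolation.

## Numerical and interface choices

- Intervals are handled by IRanges/GenomicRanges (1-based inclusive)
  internally; window tables and BED exports use BED-style 0-based half-open
  starts. Call tables and GFF3 are 1-based inclusive at the boundary.
- The chi-square statistic is computed vectorised from the closed-form 2x2
  expression `N(ad-bc)^2/(r1 r2 c1 c2)`; tests cross-check it against
  `chisq.test(correct = FALSE)` to 1e-10 and against Fisher's exact test
  for rejection ordering.
- Degenerate inputs are explicit: empty lambda tables, zero-read sites,
  non-conversion rates outside (0,1), windows with no context sites,
  correlation with n < 10, and duplicate gene ids in DMG/DEG tables all
  raise errors or are emitted as explicitly-undefined rows rather than
  silently dropped.
- Problem sizes in the test suite (2 Mb genomes for recovery checks,
  n = 5000 genes for correlation recovery, a 200 kb toy study end-to-end)
  were chosen so each statistical property is measured with comfortable
  margin while the whole suite stays fast on a laptop.

## Known limitations

- The binomial caller ignores overdispersion; a beta-binomial would be more
  faithful for heterogeneous tissues and is out of scope by design.
- BH is used where the original methylKit-based workflow defaults to SLIM
  q-values; rankings are identical, thresholds differ slightly.
- Merged DMR deltas re-pool overlapping windows, so sites in the overlap of
  two constituent windows are counted twice in the merged summary (the
  per-window statistics are unaffected).
- The DEG fold-change rule is a fixture generator, not a differential
  expression method; use a dedicated DE tool for real data and pass its
  output as the DEG table.
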