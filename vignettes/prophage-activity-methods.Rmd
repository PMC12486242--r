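---
title: "Methods: quantifying prophage activity from packaging signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying prophage activity from packaging signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muflap)
```

This vignette is the package's own account of its models, the choices
behind them, and what the synthetic tests do and do not demonstrate.

## Coordinates, alphabet, topology

All intervals are 0-based and half-open throughout the API; conversion to
1-based happens only at file boundaries (GFF3 input is converted on read).
Sequences are restricted to `{A,C,G,T,N}`; IUPAC ambiguity codes other
than `N` are rejected at parse time because every downstream comparison —
flap mapping, junction k-mers, motif scanning — is defined on exact
nucleotides, and a silent wildcard interpretation would corrupt counts.
Circular chromosomes are stored linearly with a topology flag; any
operation that slides a k-length window (motif scan, k-mer indexing, flap
mapping) virtually extends the sequence by `k - 1` so origin-crossing
windows are first-class.

## The Mu-type flap model

A transposable prophage occupies `[left, right)` on its host chromosome
with the 5-bp duplicated target immediately outside both boundaries.
Storing the duplication outside the recorded interval (explicitly, in the
prophage record) gives one bookkeeping rule for both integration
chemistries: site-specific prophages analogously carry one copy of the
attachment core (`attP`) on each side. `reconstruct_attB_reference()`
deletes `[left, right + w)` per prophage (`w` = repeat width), collapsing
the duplicated flank to a single copy; on simulator output this inverts
integration bit-exactly, which the tests assert.

Flap extraction anchors an exact `anchor_len = 20` nt match to a prophage
terminus inside a read (after canonicalizing read orientation against the
prophage strand) and takes the outward 20 nt as the flap. Exact matching
mirrors the 100%-identity stance of the analysis the package implements;
sequencing errors therefore cost sensitivity (an error in the anchor or
flap drops the read) but not specificity (an erroneous 20-mer virtually
never re-occurs exactly elsewhere), a property the tests probe at a 5%
substitution rate.

Mapping requires a *unique* exact occurrence of the flap on the host
chromosome, either strand; multi-mapping flaps are `ambiguous` and
excluded from both `x` and `y` — conservative and symmetric. A flap is
*original* when it maps to the 20-nt window abutting the native prophage
boundary on its side; every other uniquely mapped flap is *new*. Because
the comparison windows sit immediately outside `[left, right)` (hence
immediately outside the duplication on the left, inside-edge on the
right), the native locus and true re-insertions are handled by the same
rule with no 5-nt off-by-one classes.

### Burst size

With each mature particle corresponding to one transposon copy, and a
cell's copies being one original plus `n` duplicates, burst
`= (x + y)/x = 1 + n`. Two counting modes are provided because the
identity and the particle proxy pull in different directions:

* `dedupe = TRUE` counts each distinct (end, flap sequence) once — a
  site-level count. At saturating coverage `x = 2` and `y = 2n`, so the
  estimator returns `1 + n` *exactly*; this is the mode used for the
  identity checks.
* `dedupe = FALSE` (default) counts every read occurrence, since read
  count is the particle proxy; the estimate is then a ratio of read
  counts with the usual ratio-estimator noise, and subsampled estimates
  agree with full-data estimates within delta-method error
  (`sigma = est * sqrt(1/x + 1/y)`), as tested.

## NYSRN scanning and TTP

The scanner is a vectorized per-slot membership test rather than a call
into a general IUPAC matcher, for one load-bearing reason: a genome `N`
(unknown/masked base) must match **nothing**, including the motif's `N`
slots, so that masked prophage regions contribute zero motifs. General
matchers treat pattern `N` as a wildcard over subject `N`. A brute-force
per-window oracle validates the scanner in the tests. NYSRN is its own
reverse-complement pattern, so single-strand scanning suffices; a
both-strand count would be exactly 2x everywhere and TTP ranks are
invariant to that factor. Overlapping occurrences are all counted (no
de-overlap rule is defensible a priori, and counting all is
deterministic). On uniform random DNA the per-window match probability is
`1 * 1/2 * 1/2 * 1/2 * 1 = 1/8`, used as a binomial sanity check.

Both the TTP numerator (new-flap 20-mers) and denominator (NYSRN 5-mers)
credit a gene only on **full containment** of the feature span — symmetric
crediting keeps the ratio interpretable at gene boundaries. Genes with
zero motifs cannot host NYSRN-targeted insertions; they are excluded from
scoring (0/0 is undefined) and reported in a sidecar attribute rather
than being assigned score 0, which would silently pull them into the
cold tail.

Ranking ties are broken by motif count (descending), then gene id, making
bins deterministic across runs; bins are contiguous rank blocks with
sizes as equal as possible, earlier bins taking the remainder.

### Hot/cold spot calling

Per (category, bin) cell the enrichment and depletion tails come from the
hypergeometric distribution at raw `alpha = 0.01` without multiplicity
correction (an optional BH flag exists, off by default, to keep the
default procedure faithful to the analysis it implements). The tails are
checked against exhaustive `choose()` enumeration for all populations up
to 25 at `1e-12`.

A hot spot must be enriched among top-ranking bins *and* depleted among
low-ranking bins (cold: mirrored). "Top" defaults to bins 1–2 and "low"
to bins 4–6, both configurable — the partition is a declared choice, not
an inference. The default assessment **pools** the top bins into one
hypergeometric test and the low bins into another. The reason is a hard
small-sample fact: a single bin's depletion p-value is floored at
`P[X = 0] = C(N-K, m)/C(N, m)`, which for, say, 40 genes in 6 bins
exceeds 0.01 unless the category covers nearly half the genome — a
per-bin depletion requirement can then never fire regardless of how
clean the signal is. Pooling preserves the logic (over-represented at the
top, missing from the bottom) while keeping the test attainable at desk
scale; `method = "per_bin"` retains the literal per-bin rule for large
gene sets.

## Induction signatures

For integrase-type prophages the excised-circle junction is modelled as
`last J nt of the genome + attP + first J nt` with `J = 20` (the
signature fragments are 20-mers, so 20 nt of terminal context on each
side is the minimal sufficient window). Signature k-mers must span the
full attP (when `attP <= 20`; longer attP falls back to covering the
junction midpoint, with a warning) **and** must not occur anywhere on the
lysogen chromosome, either strand. That uniqueness screen is essential:
k-mers that stop exactly at an attP boundary also occur at attL or attR
in every untouched lysogen and would count resident-prophage reads as
induction. Detection is then an exact substring count over reads in both
orientations, with `min_evidence = 1` read by default — any junction
molecule is evidence — configurable upward for noisy libraries.

Mu-type induction detection simply reruns the flap pipeline on cellular
reads: original flaps are expected from the resident locus and are not
evidence; the new-flap count `y` is. The two detectors are independent by
construction (Mu molecules contain no attP junction; excised circles
contain no Mu termini), which a mixture test asserts.

`detect_termini()` is deliberately a simplified stand-in for full
terminal-redundancy analysis: a position whose read 5'-start count
reaches `fold = 20` times the strand's median nonzero count is a
candidate terminus, and circularly adjacent opposite-strand peaks (within
`max_gap = 5`) are paired as cos ends. A cut at position `c` yields
forward starts at `c` and reverse 5' ends at `c - 1`, so the pairing rule
is exact on clean data. The pile-up itself only exists under a
fragmentation model in which fragments are bounded by molecule ends —
uniform read starts carry no terminus information — so the simulator
models per-molecule random breakpoints and reads off both fragment ends.

## Abundance and PtW inference

`RPKM = reads / (length/1e3) / (sample_bp/1e6)`, with the sample size
taken as total post-quality-filter base pairs (the recruitment
convention; the choice of post- over pre-filter is declared here since
either reading is possible). Retention thresholds are strict
inequalities: hosts `> 0.1`, prophages `> 0.01` RPKM. Pairing joins the
cellular-fraction host with the virion-fraction phage per station;
`VHR = phage/host` on those pairs.

The power-law exponent comes from OLS on log10–log10 data (the slope is
base-invariant). Classification uses the 95% CI rather than the point
estimate — the explicit, testable substitute for unspecified significance
stars: `sublinear` iff CI in (0, 1); `linear` iff CI contains 1 and
excludes 0; `superlinear` iff the lower bound exceeds 1; otherwise
`indeterminate`. With zero residual variance the CI degenerates to the
point estimate, so noise-free power laws classify exactly. Spearman
correlations use average ranks on ties; a zero-variance margin (constant
VHR under exact linearity) returns rho = 0, p = 1 by convention rather
than NA.

## What the generator emulates — and what it does not

`make_lysogen()` builds a uniform-random circular chromosome
(default 50 kb) with `n_genes = 40` non-overlapping 400-bp genes in five
categories: a designated hot category (default multiplier 10, emulating
co-resident-prophage/hypothetical genes favoured by Mu-type targeting), a
designated cold category (multiplier 0, emulating spared
respiration/protein-metabolism genes), and neutral/hypothetical baseline
(weight 1, shared with intergenic sites so the TTP denominator is
nontrivial genome-wide). A Mu-like prophage (5 kb) integrates at an
intergenic NYSRN site with the 5-bp duplication; a site-specific
prophage (5 kb) integrates at a distinct intergenic locus whose resident
sequence is taken as the attB = attP core (15 bp), i.e. attachment arms
beyond the core are not modelled; a cos sequence (the 19-nt P2-like cut
site by default) is planted at a recorded position. Insertions are
intergenic so genes stay contiguous; forward-orientation insertion only.

Transposition targets are drawn from NYSRN sites with gene-multiplier
weights and zero weight across the resident Mu span (transposition
immunity). **Without replacement** is the default so sites are distinct
and the burst identity `1 + n` is exact. For the TTP stress scenario
(5000 events on a 50-kb chromosome, scaling down tens of thousands of
events on a multi-Mb chromosome) the draw is **with replacement**: a
50-kb chromosome offers only ~6000 NYSRN sites, so a without-replacement
draw of 5000 saturates the pool and flattens every planted preference —
site reuse is precisely what the scaled-down regime implies. The
with-replacement draw keeps per-site rates proportional to the planted
multipliers, which is what the real-data regime looks like far from
saturation.

Packaged molecules carry `flank_capture = 150` nt of host context per end
(well above the 20-nt flap requirement). Reads are uniform-start,
substitution-only (`error_rate`, default 0), constant quality —
exact-match pipelines make indel modelling pure noise. Cellular-DNA
simulation emits chromosome reads at `cell_depth = 100` with a
`spi_rate` fraction of reads drawn from induction molecules; induced
Mu copies are given at least one read length of chromosomal flank
(they live in cellular DNA, so `flank_capture` does not clip them). The
depth default is chosen so that at `spi_rate = 0.01` both detectors
expect several junction-bearing reads per run (read length 300,
~20,000 reads), keeping detection a property of the method rather than
of a lucky draw. Metagenome tables emit real-valued mapped-read mass
consistent with the RPKM formula, so zero-noise tables reproduce the
planted exponent to machine precision; integer rounding would only blur
the algebra the module is meant to expose.

Problem sizes throughout the test suite (50-kb chromosomes, 5-kb
prophages, depths of 15–100, 60 metagenome stations, 20-seed controls)
are the package's chosen desk scale: large enough that every statistic
operates in its intended regime, small enough to iterate quickly.

What passing tests do **not** show about real data: no indels, chimeras,
adapter or quality artefacts; no repeat structure in the host beyond
chance 20-mer collisions; no asymmetric per-end packaging lengths; no
strand-biased or GC-biased coverage; single host, no strain mixture; and
the metagenome module consumes idealized count tables, not alignments —
the identity/coverage recruitment filters of a real pipeline live
upstream of this package's contract.

## Known limitations

* Flap mapping is in-memory exact matching; accession-scale data should
  be mapped externally and re-enter as tables.
* Site-specific attachment is modelled core-only; real attL/attR arms and
  imperfect cores would require a more general junction model.
* The cos detector is a pile-up heuristic, not a terminal-redundancy
  analysis; it requires end-bounded fragmentation to see anything.
* Whether identical flaps should be deduplicated before burst estimation
  is data-dependent (PCR duplicates vs true recurrence); both modes are
  exposed, and the default (no dedup) counts particles.
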