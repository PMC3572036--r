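---
title: "Tracing de novo gene origin: models, conventions and design choices"
author: "orfgenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing de novo gene origin: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfgenesis)
```

# The problem

A gene born *de novo* leaves a characteristic signature in a multiple
genome alignment: the orthologous locus is present and alignable in many
species, yet almost none of them could translate it into the focal
protein, because the reading frame is interrupted by lineage-specific
differences — a mutated start codon here, a frameshifting indel there, a
premature stop elsewhere. `orfgenesis` formalizes that reading of an
alignment. Its input is a reference-anchored alignment of a single-exon
CDS (`CdsAlignment`); its central outputs are per-species ORF integrity
reports and a parsimony placement of the disrupting events on the species
phylogeny.

This vignette records the models, the coordinate and rounding conventions,
the tunable parameters, and the design decisions that were genuinely open.

# Reference anchoring and alignability

`stitchCds()` extracts the columns of a MAF alignment that carry the
reference CDS interval. Coordinates are 1-based inclusive throughout the
user-facing API (alignment columns are an internal detail); minus-strand
intervals are reverse-complemented so position 1 is always the first
coding base. Insertion columns — reference gaps between retained reference
positions — are kept, because species-specific insertions are exactly what
the ORF tracer must see. Three conventions matter:

* Reference positions covered by no block become `N` in the reference row
  and gaps elsewhere; the alignment always has full reference length.
* When blocks overlap on a reference position, the block with more species
  rows wins (ties: first encountered); the conflict is reported.
* `alignableFraction()` counts non-gap, non-`N` bases: `N` is low-quality
  fill in MULTIZ alignments, while other IUPAC ambiguity codes are genuine
  (if uncertain) bases and count as aligned. An open alternative would be
  to count gap columns inside otherwise-aligned spans as aligned context;
  we deliberately count only bases, which makes the fraction a statement
  about sequence content rather than about span coverage.

Species absent from every block simply surface with fraction 0, matching
how a locus "virtually absent" from a clade is reported.

# ORF tracing

`scanSpeciesOrf()` walks the reference CDS left to right and reports
disruptions in reference coordinates:

* **Start**: the species bases aligned to reference positions 1–3 must be
  exactly `ATG`; otherwise a `start_loss` at position 0 (with an
  `unaligned` note when codon 1 is entirely gapped).
* **Indels**: each maximal gap run is an event of its own; a run whose
  length is not a multiple of 3 is a frameshift. Per-run (rather than
  net-offset) detection means two compensating indels are both reported —
  the first still truncates the protein, which is why homology is defined
  by the first event only.
* **Stops**: the species sequence is translated as the concatenation of
  its aligned bases, anchored at codon 1 — i.e. in the frame implied by
  the cumulative indel offset at each point. Stops readable only in other
  frames are ignored. The first in-frame stop strictly upstream of the
  reference stop codon is a `premature_stop`; if no in-frame stop exists
  through the aligned span at all, the species is `nonstop` at position
  `L + 1` (such transcripts are candidate non-stop-decay substrates and
  cannot yield a stable protein).

**Homology denominator.** The protein-homology fraction is
`(p_first − 1)/(L − 3)`: coding nucleotides before the event over the
coding length excluding the stop. For the canonical worked case — a 1-bp
deletion at nt 12 of a 135-codon CDS — this gives `11/405 = 2.7%`, which
rounds to 3%; a per-codon count (3/135) would give 2.2% and round to 2%,
so the nucleotide convention is the one that reproduces the reported
values. A `nonstop` event sits past the last coding position, so its
homology clamps to 1: the protein is intact *per se* but flagged as
unterminated.

# Event placement on the phylogeny

Events are matched across species by (kind, reference position, indel
length) and placed by a Dollo-style single-gain rule: the stem branch of
the maximal clade in which every *eligible* tip carries the event.
Identical indels arising twice independently are rare, so a
non-monophyletic carrier set is reported as ambiguous (with the maximal
carrier-only subclades listed) rather than resolved into multiple gains.

Two details are worth calling out:

* Tips whose alignable fraction is below a floor (default `0.10`) are
  excluded from matching: with almost no aligned sequence their ORF calls
  are noise, and a single such tip would otherwise break every placement.
* The reference species participates with its implicit identity report.
  Without it, a clade consisting of the reference plus the carriers would
  vacuously satisfy "all annotated tips carry the event" and placements
  would creep rootward through reference-only branches; the recovery suite
  caught exactly this.

`fitchAncestral()` provides the complementary state-based view. It is
implemented as a unit-cost Sankoff dynamic program (subtree costs down,
outside costs up), which yields, for every node, the full set of states
attainable in a most-parsimonious reconstruction — exactly for
multifurcations too, with no reliance on the classic two-pass set-update
rules. `cladeLowerBound()` is the simple observation that an ancestor must
have carried at least as much of the CDS as its best-preserved descendant:
the maximum tip fraction in the clade.

The package ships a 32-tip placental phylogeny (`placentalTree()`) in the
accepted topology used by the UCSC multiple alignments, with named clades
supplied as a tip-set mapping (`placentalClades()`) since UCSC newick
files carry no internal labels.

# Codon-usage bias

`codonUsageScore()` is the per-codon mean log-likelihood ratio of the
observed codons against a uniform 1/64 null. The per-codon mean (not the
raw sum) makes genes of different lengths comparable to a genome-wide
average; the natural log is the default and the base is configurable. Stop
codons are excluded from scoring, and table frequencies are renormalized
over the 61 sense codons by default — `renormalizeSense = FALSE` uses the
table exactly as given, which is the mode in which a literal uniform
table scores exactly 0. The shipped default table (`humanCodonFreqs()`)
is the standard GenBank-derived human nuclear codon usage.

`reshufflePvalue()` permutes *nucleotides* (preserving length and base
composition exactly), rescores each permutation in frame, and reports the
raw frequency of permutation scores at least as large as the observed one;
the smallest reportable p is `1/nReps`. Permutations containing in-frame
stops are scored like any other sequence (at their table frequencies) —
no rejection rule is applied, so the null is the full composition-
preserving permutation distribution. Results are bit-reproducible given
the seed.

# Ka/Ks

The synonymous/nonsynonymous analysis uses the classical NG86 counting
estimator: sites by per-position mutational-opportunity fractions
(averaged over the two sequences; changes to stops count as
nonsynonymous), differences by equal-weight averaging over all orderings
of multi-difference codons, Jukes–Cantor correction for multiple hits.
This is a documented approximation to more elaborate site-classification
estimators used by dedicated tools; agreement is therefore expected within
confidence-interval width, not to three decimals. Counts are pooled
(summed) across reference-vs-species pairs of a multiple alignment —
pooling was an open choice, so per-pair estimates are always reported
alongside. Gapped or ambiguous codon columns are dropped listwise.

The 95% CI is a parametric Monte Carlo: difference counts are redrawn
binomially at the estimated per-site proportions, re-estimated, and the
2.5/97.5 percentiles of the simulated ratios taken. On pairs simulated
with a true ratio of 1.0 at 405 sites, the interval covers the truth in
well over 90% of seeded replicates; with `Ks = 0` the ratio is undefined
and the CI omitted.

# Promoter and sequence features

TSS-relative coordinates follow promoter convention: the TSS base is +1,
the base upstream is −1, and there is no position 0 (this matches the
mixed +4/−53/−30 style in which core elements are conventionally
reported; the printed motif positions are reproduced as given, without
reinterpreting their anatomy). GC content is measured over the
`2×100+1`-base window centred on the TSS; the GC-poor/GC-rich boundary
defaults to 0.45 — between the GC-poor observation this analysis makes and
the CpG-island regime — and is recorded on every classification. Motif
scanning is exact IUPAC consensus matching on the given strand;
PWM scoring is out of scope. In-silico PCR is exact primer matching
(forward match, reverse-complemented reverse match downstream, product =
inclusive span), intended for predicting amplicon sizes from a reference
cDNA rather than modelling hybridization. Track summaries report the
arithmetic mean and the *population* (n-denominator) standard deviation —
the ± convention of the summarized tracks is unstated, so the choice is
recorded in the result's attributes.

# Expression association

`pearsonWithP()` uses the t-transform of r on n−2 degrees of freedom.
`correlationPercentile()` ranks the focal gene's correlation profile by
descending signed r — strong positive correlates land at low percentiles —
with no multiple-testing correction, matching how such screens are
conventionally reported. Group comparisons use Welch's unequal-variance
one-tailed t-test (safer than pooled variance for the unequal group sizes
of public datasets); the 2×2 factorial analysis uses type-II sums of
squares via `car::Anova`, appropriate for unbalanced designs and equal to
the classical decomposition when balanced.

# The synthetic-data generator

`simulateCdsEvolution()` evolves a root ORF down a tree: scripted events
first (deterministic, on their branches), then background substitutions
(transition:transversion 2:1) at `subsRate` per site per unit branch
length, then background indels at `indelRate` with geometric lengths of
mean 2 — so 1-bp frameshifts, the most informative event class, are the
most common. The *true* alignment is emitted directly from the simulation:
insertions open gap columns in every other lineage and deletions leave gap
characters, so there is no realignment step and ORF-tracing correctness is
tested in isolation from aligner error.

Defaults: `subsRate = 0.01`, `indelRate = 0` — a conservative,
primate-like divergence per branch with indels opted into explicitly. The
truth-recovery suites run with both rates at 0 and scripted events only;
that is a deliberate isolation of the tracing logic, not a statement that
real alignments are noise-free. What passing recovery shows is that every
scripted disruption class is detected at its exact position and placed on
its exact branch *when the generator's assumptions hold*: a correct
alignment, events that do not overprint each other, and monophyletic
carrier sets. It does not show robustness to alignment error, to
low-quality sequence, or to convergent identical events — those surface as
`N`-driven low alignability (excluded tips) or as `ambiguous` placements,
by design.

`simulateExpression()` plants partners at exact population correlation r
(`r·focal + sqrt(1−r²)·noise`) plus optional additive group effects on the
focal gene; `makePromoter()` draws background bases at a target GC and
writes motif texts at fixed TSS-relative positions. Both return their
ground truth beside the data, and all three generators are byte-identical
given spec and seed.

# Problem sizes and numerical choices

The test suite runs entirely on generated data: 135-codon CDSs (the focal
gene's size) for worked values, 60-codon CDSs on 10-tip random trees for
the 50-scenario recovery suite, 100 seeded replicates at 405 sites for CI
coverage, 200 draws for permutation rank-uniformity, and exhaustive
enumeration oracles (all internal labelings for parsimony on trees of ≤10
tips; all 720 permutations of 6-nt sequences for the exact permutation
p). These sizes were chosen to make the oracles exact and the statistics
stable while keeping the suite fast on one CPU.

Degenerate inputs are handled explicitly: zero-coverage stitching, unknown
species, invalid reference ORFs, zero-frequency codons (opt-in
pseudocount), Jukes–Cantor saturation (error when pooled, `NA` per pair),
`Ks = 0` (undefined ratio), empty factorial cells, and self-correlation
are all errors or flagged results rather than silent numbers.

# Known limitations

* Single-exon CDS only; no splicing, chaining or netting, and no aligner —
  the alignment is an input.
* Dollo placement reports convergent identical events as ambiguous rather
  than resolving multiple gains.
* NG86+JC is a deliberate approximation; use its CI, not its point
  estimate, when comparing against other estimators.
* The codon-usage permutation test conditions on base composition only,
  not on dinucleotide or amino-acid structure.
* The expression layer assumes pre-normalized matrices; no survival
  modelling or normalization is included.
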