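# orfgenesis

Comparative-genomics toolkit for tracing the *de novo* origin of a
protein-coding gene across a multiple genome alignment.

Most new protein-coding genes arise by duplication; a small class instead
emerges *de novo* from previously non-coding DNA through a handful of point
mutations and frameshifts that happen to open a reading frame. Establishing
such an origin requires showing, species by species, *where* along the
phylogeny the ORF-disrupting differences (lost start codons, frameshifting
indels, premature or missing stop codons) were gained or lost relative to
the focal genome. `orfgenesis` implements that analysis for a single-exon
CDS aligned against many genomes, plus the companion measurements such a
study reports: codon-usage bias with a permutation test, Ka/Ks with
Monte-Carlo confidence intervals, promoter GC/motif architecture, in-silico
PCR, conservation-track summaries, and expression-matrix association
screens. A synthetic-data generator evolves a CDS down a tree with scripted
disruptions, so every stage of the pipeline is testable offline with exact
ground truth.

## The core quantities

For a reference CDS of `L` coding nucleotides (stop codon included) aligned
to species *s*:

* **Alignable fraction** — the share of reference CDS positions where *s*
  contributes an aligned base (`N` and gaps do not count):
  `a_s = #{i : base_s(i) ∉ {-, N}} / L`.
* **Protein-homology fraction** — coding nucleotides strictly upstream of
  the first ORF disruption, over the coding length without the stop:
  `h = (p_first − 1) / (L − 3)`, with `h = 0` for a lost start and
  `h = 1` for an intact ORF. A 1-bp deletion at nt 12 of a 135-codon CDS
  gives `11/405 ≈ 3%`.
* **Event placement** — disruptions matched across species by (kind,
  position, indel length) are placed Dollo-style on the stem branch of the
  maximal clade whose reliably aligned members all carry them;
  non-monophyletic carrier sets are flagged ambiguous. Ancestral states can
  also be reconstructed by exact Fitch parsimony (`fitchAncestral`), and
  `cladeLowerBound` turns tip alignabilities into a lower bound on an
  ancestor's sequence content (the maximum over the clade's tips).
* **Codon-usage bias** — the Guigó-style per-codon mean log-likelihood
  ratio `s = (1/n) Σ ln(F(C_i)/(1/64))` against a uniform null, with
  significance from nucleotide reshuffling (composition-preserving
  permutations, raw frequency of equal-or-higher scores).
* **Ka/Ks** — NG86 counting (mutational-opportunity sites, equal-weight
  pathway averaging) with Jukes–Cantor correction, pooled across
  reference-vs-species pairs, and a parametric Monte-Carlo 95% CI.

## Worked example

Evolve a 135-codon CDS down the bundled 32-species placental phylogeny with
four scripted events — a start-codon loss in the Glires ancestor, a 1-bp
deletion in dog, a stop-codon loss in the common ancestor of the bats, and
a premature stop in rhesus — then scan every species and place the events:

```r
library(orfgenesis)
tr <- placentalTree()
cl <- placentalClades()
ev <- rbind(
  scriptedEvent(paste0("node", ape::getMRCA(tr, cl$Glires)), "start_loss"),
  scriptedEvent("Dog", "frameshift_deletion", 12, 1),
  scriptedEvent(paste0("node", ape::getMRCA(tr, c("Microbat", "Megabat"))),
                "stop_loss"),
  scriptedEvent("Rhesus", "premature_stop", 88))
sim <- simulateCdsEvolution(
  evolSpec(tr, randomOrf(135, seed = 2), refSpecies = "Human",
           subsRate = 0, events = ev), seed = 7)

scanSpeciesOrf(sim$aln, "Dog")
#> SpeciesOrfReport for Dog
#>   alignable fraction: 0.998
#>   protein homology:   0.027
#>   start codon intact: TRUE
#>   2 disruption(s):
#>     frameshift_deletion at ref nt 12 (1 nt)
#>     premature_stop at ref nt 47
```

The deletion removes one of 408 alignable positions (0.998) and truncates
protein homology at `11/405 ≈ 3%`; the premature stop at nt 47 is the
downstream consequence of the shifted frame. The rhesus stop at nt 88
leaves `87/405 ≈ 21%` homology. Placing all events on the tree:

```r
placeEvents(tr, scanAllSpecies(sim$aln))
#>                  kind refPos indelLen branch ambiguous nCarriers         carriers
#>            start_loss      0        0 node45     FALSE         7 GuineaPig,...,Squirrel
#>   frameshift_deletion     12        1    Dog     FALSE         1              Dog
#>        premature_stop     47        0    Dog     FALSE         1              Dog
#>        premature_stop     88        0 Rhesus     FALSE         1           Rhesus
#>               nonstop    409        0 node58     FALSE         2 Megabat,Microbat
```

Each scripted event is recovered on exactly the branch where it was
planted: the start loss on the Glires stem (`node45`), the stop loss as a
shared non-stop state on the bat stem (`node58`), and the private events on
their terminal branches.

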