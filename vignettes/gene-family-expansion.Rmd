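---
title: "Dating and dissecting a gene-family expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating and dissecting a gene-family expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogon)
library(dplyr)
```

## The problem

Plant secondary-metabolism genes often expand into local arrays of highly
similar copies: an ancestral gene is duplicated in tandem, whole blocks of
tens of kilobases are then reduplicated segmentally, transposable elements
invade the blocks, and the duplicate promoters degenerate in a complementary
fashion so that the copies partition the ancestral expression domain between
them (the duplication–degeneration–complementation, DDC, model). A classic
example is the flavonoid 3',5'-hydroxylase family of grapevine, where more
than a dozen copies sit in a single chromosome arm, most of them inside
near-identical duplicate blocks, with one copy formed by recombination
between two paralogues and the copies' transcription partitioned across
organs and ripening stages.

`paralogon` implements the analysis layer such a locus needs — duplicate
dating, block delimitation, recombinant detection, promoter comparison and
copy-specific qPCR statistics — together with a sequence-family evolution
simulator that provides exact ground truth for every stage, so the whole
pipeline is testable without any external data.

## Molecular dating with 4DTV

Divergence between duplicates is measured at four-fold degenerate
third-codon positions, counting only transversions (4DTV). A third-codon
column is eligible if, in **both** sequences, the codon belongs to a
four-fold degenerate family and the first two codon positions are
identical; any third-position change is then strictly synonymous in both
directions. With $p$ the observed transversion fraction at eligible sites,
multiple hits are corrected by

$$d = -\tfrac12 \log(1 - 2p),$$

the standard two-state (purine/pyrimidine) correction; $p \ge 0.5$ is
saturation and no finite distance is reported. Because transversions are a
two-state character, the corrected value estimates the expected number of
transversions per site: under a two-parameter substitution model with
transition/transversion ratio $\kappa$ and total branch length $t$, that is
$2t/(\kappa+2)$ ($t/2$ at the default $\kappa = 2$). Note that the
correction's excess over $p$ is quadratic — $d - p = p^2 + \tfrac43 p^3 +
\dots$ — so corrected and raw values agree to order $p^2$ at small
distances, with the excess slightly *above* $p^2$ for every positive $p$.

Pairwise alignment is protein-guided: proteins are aligned globally
(BLOSUM62, affine gaps) and the gaps are back-threaded onto codons, so
nucleotide gaps are always in frame. Estimates with fewer than 20 eligible
sites (`min_sites`) carry a low-information flag rather than failing;
full-length plant P450 genes (~500 codons) typically provide 150–300
eligible sites. Distance matrices feed a standard neighbor-joining tree
(taxa sorted lexicographically for deterministic ties; negative branch
lengths clamped to zero with a warning).

```{r fourdtv-example}
a <- withr::with_seed(1, random_cds(500))
b <- evolve_sequence(a, t = 0.1, kappa = 2, coding = TRUE, seed = 2)
fourdtv(a, b)
```

## The evolution simulator

`evolution_config()` + `simulate_family()` generate a locus with known
history: an ancestral block (promoter, CDS, intergenic filler) evolves
under a K80 model and is copied head-to-tail at each duplication event;
terminal branches then differentiate the copies; finally structural
mutations are applied — TE insertions whose two LTRs are identical at
insertion and then diverge by a stated post-insertion branch, copy-specific
promoter deletions, and optionally a chimeric extra copy spliced from two
parents at a stated breakpoint fraction.

Design choices worth knowing:

* **Substitution model.** K80 with user `kappa` (default 2) — the minimal
  model with a defined transversion fraction, which is exactly what 4DTV
  measures. The original study did not state a model for its dating, so the
  model here is a simulator knob, not an inference.
* **Clock.** Event `time` is measured in expected substitutions/site since
  the ancestor; the locus evolves by the inter-event increment between
  events. The expected distance between two copies is therefore
  $2(T - t_{\mathrm{split}})$ plus their terminal branches, which the truth
  tables record per pair.
* **No indels inside CDSs.** Frameshifted pseudogene copies exist in real
  arrays but are out of analytical scope here; coding evolution rejects
  internal stop codons and keeps the start codon.
* **One root seed.** Every stochastic step draws from a named substream of
  the root seed (`substream_seed()`), so adding a feature cannot silently
  reorder existing draws; identical configs are byte-identical.
* **Synthetic TEs.** Elements are random sequence with recognisable
  terminal repeats; no real TE libraries are bundled, and the simulator
  makes no attempt at TE phylogenies or codon-usage realism.

What passing tests on these families show — and what they do not: the
simulator reproduces the *statistical* structure the analyses assume
(known distances, exact block copies, identical-at-insertion LTRs, clean
deletions). Real assemblies add gaps, segmental rearrangement,
microsatellite churn and gene conversion, all absent here; block
boundaries on real data will be correspondingly fuzzier than the
simulator-calibrated ones.

## Duplicate blocks from self-comparison

`self_match()` computes all exact k-mer self-matches of the locus (the dot
plot; default `k = 16`, below which matches drown in noise), and
`chain_and_delimit()` chains co-diagonal matches with gaps up to
`max_gap = 2000` bp into diagonal segments (minimum 500 bp), then derives
block boundaries from the clustered segment *starts* projected on both
axes — segment ends are deliberately not used, because a projection of a
shorter partner block ends mid-block. Blocks under 10 kb are classified
tandem, larger ones segmental (a block of exactly 10 kb counts as
segmental). Forward-strand matches only by default: tandem arrays are
direct repeats. Runs of Ns (assembly gaps) never match because k-mers
containing N are dropped.

The defaults resolve the regime the method is aimed at — blocks of tens of
kilobases at 90–99% identity, where an exact 16-mer still occurs every few
tens of bases. At identities below ~85% the exact-match chain thins out and
`max_gap` would need to grow.

`block_identity()` scores a block pair by chaining exact anchors,
counting matches directly inside each gapless chained segment, aligning
short inter-segment gaps globally, and *excluding* columns opposite
unfilled gaps longer than `gap_cap` (private TE insertions) from the
denominator. `te_fraction_profile()` reports merged-TE coverage in tiling
windows (so the window-weighted mean equals the whole-locus fraction), and
`flank_conservation()` reports per-window identity around two gene copies
from the anchor chain at its local diagonal, plus the distance from the CDS
at which identity stays at or above 70% in 100-bp windows.

## LTR insertion dating

A retrotransposon's two LTRs are identical when it inserts; their
divergence clocks the insertion. `ltr_divergence()` reports both the raw
p-distance and the Jukes–Cantor correction $-\tfrac34\log(1-\tfrac43 p)$,
because published "substitution rates between LTRs" do not always say
which scale they are on. LTRs under 50 bp are flagged low-information.

## Detecting a recombinant paralogue

Given two tight parental groups (within-group corrected 4DTV at most
`within_ceiling`, default 0.01) and a candidate, `classify_sites()` labels
every eligible 4D site: assigned to group A or B where the group
consensuses differ by a transversion and the candidate matches one;
variable-within-group and transversion-to-both sites are reported
separately (the long and short ticks of the classic diagnostic plot).
`detect_chimera()` walks +1/−1 along the assigned sites and uses the
maximal absolute excursion as its asymmetry statistic; the breakpoint
estimate is the site at the extremum. Significance comes from permuting
the labels — exhaustively when $\binom{n}{n_A}$ is small (exact discrete
p-values), Monte Carlo otherwise. The statistic and permutation null are
this package's formalisation of what is usually argued qualitatively from
the tick plot; it is exact on small site counts and assumes a single
breakpoint.

How many informative sites to expect: groups at corrected 4DTV $d$ give
roughly $n_{4D} \cdot (1 - e^{-2d})/2$ diagnostic transversions, so two
groups ~0.05 apart on a 500-codon gene yield only a handful — enough to
display, not to test. The test requires at least 6 informative sites.

## Promoter segmentation and the DDC signature

`segment_promoters()` chains exact anchors of at least `min_anchor = 10`
bp (the classic minimum HSP length for promoter-scale alignment) between
two promoters (the 2,000 bp upstream of the translation start is the
conventional window). Gap interiors are bridged only if identity over a
100-bp window centred on the gap stays at or above 70% — so a substitution
cluster bridges, a structural deletion does not. Conserved segments tile
against copy-unique segments, and the complementarity score is the
fraction of the segment union private to exactly one copy: 0 for
identical promoters, approaching 1 for unrelated ones. With three
promoters, `triplet_polarity()` labels each segment by its presence
pattern; under parsimony a segment present in two copies and absent from
the third is a deletion in the third, and a deletion-only history makes
two-present segments outnumber one-present ones — the DDC signature.

Boundary precision is limited by the anchor width: a deletion boundary can
be placed up to ~`min_anchor` bp off when flanking bases happen to match
across the breakpoint.

`scan_motifs()` scans both strands with a bundled editable IUPAC consensus
library covering the motif classes relevant to anthocyanin-pathway
promoters (Myb-binding, light-responsive, drought MBS, ABRE,
CGTCA/TGACG MeJA, heat-shock elements, plus common core elements marked
"other"). It is a consensus matcher, not a PWM scorer, and it does not try
to reproduce any web service's hit list.

## Copy-specific qPCR analysis

* `design_copy_specific_primers()` enumerates primer pairs in which one
  primer's 3'-terminal base sits on a position discriminating the target
  from every paralogue; selectivity is validated pair-wise (perfect 3'
  match to target, 3' mismatch or absent site on every non-target).
  Identical paralogues return an explicit "indistinguishable" flag — in a
  real array only a subset of copies is assayable.
* `insilico_pcr()` applies the same 3'-terminal rule on a template (up to
  `max_mismatch` internal mismatches) and reports genomic and spliced
  product sizes when a gene model is supplied.
* `qpcr_efficiency()` fits Ct against $\log_{10}$ input; $E =
  10^{-1/\text{slope}}$, QC passes at 90–110% and, across genotypes, when
  the SD of percent efficiencies stays below 10 points.
* `relative_expression()` implements $2^{-\Delta\Delta C_t}$ with
  technical replicates averaged on the Ct scale after a 1-Ct repeatability
  check (flagged, never dropped). The calibrator sample is a required
  argument — there is no sensible default — and its relative expression is
  exactly 1 by construction.
* `anova_snk()` fits balanced fixed-effects ANOVA (1–3 factors, fully
  crossed; unbalanced multi-factor input is refused with a pointer to
  per-level one-way analysis) and separates means by the stepwise
  Student–Newman–Keuls procedure, with critical values from the
  studentized-range distribution (`qtukey`), never a hard-coded table, and
  the containment rule protecting sub-ranges of non-significant ranges.

`simulate_qpcr_ct()` closes the loop: it generates Ct tables from known
fold changes so the entire ddCt → profiles → ANOVA/SNK chain can be
checked against its own ground truth. Gaussian Ct noise with a per-bio-rep
shift is the only error model; pipetting series and inhibitor effects are
not modelled.

## An end-to-end run

```{r pipeline, eval = FALSE}
cfg <- evolution_config(
  seed = 5, ancestral_cds_length = 510,
  duplication_events = data.frame(type = "segmental",
                                  block_length = c(40000, 40000),
                                  time = c(0.06, 0.12)),
  branch_lengths = 0.004,
  te_insertions = data.frame(family = "Gypsy", copy = 2,
                             ltr_length = 300, post_branch = 0.02),
  promoter_deletions = data.frame(copy = c(2, 3), offset = c(300, 1200),
                                  length = c(200, 250)),
  chimera = list(parent_a = 1, parent_b = 2, breakpoint_fraction = 0.5))
run <- run_full_analysis(cfg, out_dir = "paralogon_demo")
```

All outputs are plain text (FASTA, GFF3, TSV, newick, JSON); a manifest
records the configuration and seed, and reruns with the same seed are
byte-identical.

## Numerical choices and problem sizes

The packaged tests run the simulator at deliberate desk scale: 10-kb CDS
pairs for dating recovery, twenty families of 3–9 blocks of 35–55 kb for
block recovery, 2-kb LTRs, 1,000-alignment oracle sweeps and 1,000-run
permutation-null calibrations. These sizes give standard errors small
enough for 3-SE checks while a full run of the suite stays in the minutes
range on one core. Degenerate inputs are contracts, not accidents: zero
eligible 4D sites, saturated distances, anchor-free promoter pairs,
all-zero expression series and zero residual variance all return flagged
results or informative errors rather than numbers.

## Known limitations

* Dating assumes no gene conversion between duplicates; conversion tracts
  would bias 4DTV downward pairwise and sideways in the tree.
* Block delimitation is tuned for direct repeats at 90–99% identity;
  inversions are only found with `both_strands = TRUE` and are not
  chained into blocks.
* The chimera test assumes exactly one breakpoint and equal-length,
  indel-free CDSs across candidate and groups.
* Promoter segmentation is anchor-based, not a full aligner: segments
  shorter than the anchor width are invisible, and boundary placement is
  accurate to about one anchor width.
* The qPCR module is fixed-effects only, matching balanced complete
  designs with few biological replicates; no mixed models, no absolute
  quantification, no melting-curve analytics.
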