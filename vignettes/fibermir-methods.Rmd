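---
title: "Methods: miRNA discovery and profiling from developmental small-RNA libraries"
author: "fibermir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA discovery and profiling from developmental small-RNA libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibermir)
```

# Scope

`fibermir` reimplements, as a tested R pipeline, the standard analysis
chain used to discover and profile plant microRNAs from a developmental
time course of small-RNA sequencing libraries — the motivating system is
elongating cotton fiber sampled at 5, 10, 15 and 20 days post-anthesis
(DPA).  The chain is: read cleaning and collapsing; contaminant
(rRNA/tRNA/snRNA/snoRNA/repeat) annotation; exact genome mapping;
assignment to known mature miRNAs; hairpin-based novel miRNA prediction;
reads-per-ten-million (RPTM) normalization with complete-linkage
clustering of temporal profiles; position-weighted miRNA–target
complementarity scanning; and the two classical validation analyses,
5′-RACE cleavage-site mapping and 2^-ΔΔCT qPCR quantification.

Because the original sequencing libraries are not redistributable, the
package ships a seeded synthetic-data generator that produces every input
the pipeline consumes, with full ground truth.  All statements below about
what the pipeline "recovers" are statements about that generator; what
that does and does not imply about real libraries is discussed at the end.

# The synthetic-data generator

`sim_config()` bundles every tunable.  The study-design defaults are four
libraries labelled 5/10/15/20 DPA, a 2 Mb genome at 42% G+C, 200,000 reads
per library, 30 known and 20 novel embedded loci, and an even class mix
over the four temporal archetypes.  Tests and the acceptance script run
the same generator at reduced sizes (typically a 60–100 kb genome, 6–8
loci per type, 6,000–10,000 reads per library) so the whole suite
completes in minutes on one CPU; nothing in the method depends on scale
beyond counting statistics.

**Genome and loci.**  Each precursor is constructed as
`mature (21 nt) + loop (15–60 nt) + star + 2-nt unpaired 3′ overhang`,
where the star is the reverse complement of the mature carrying 0–3
substitutions.  With zero substitutions the mature/star duplex is perfect,
which pins down the expected duplex statistics exactly (a property the
tests exploit).  Loci are placed on random strands in disjoint 600-nt
slots with 400-nt genome margins so every folding window fits.  Known loci
are emitted as a mature reference *and* a hairpin (precursor) reference
with family-structured identifiers (`miR156a`, `miR156b`, …) drawn from a
pool of common plant families.

**Libraries.**  Reads per library are an exact mixture: miRNA-locus reads
(12%), contaminant fragments (5%), unmappable junk (3%), and random genome
fragments (the remainder, which also acts as the conservation buffer so
each library totals exactly `reads_per_library`).  Locus reads follow the
locus's class archetype across libraries with negative-binomial noise
(variance = μ + 0.1 μ²; Poisson at dispersion 0); within a locus, reads
are 80% exact mature, 8% 3′+1 templated, 4% 3′−1, and 8% star.  Background
fragment lengths are drawn from a distribution peaked at 24 nt so that,
after cleaning, 20–24-nt reads exceed 90% of the analysis set with a 24-nt
mode — the size profile typical of plant libraries where 24-nt
heterochromatic siRNAs dominate.  Every read is ligated to the 3′ adaptor
and given a constant high-quality string; quality filtering is therefore
modelled as a threshold these always pass.

**The four archetypes** (rows of `archetype_weights()`) are the package's
operational definition of the expression classes:

* A — monotone decreasing (0.40, 0.30, 0.20, 0.10);
* B — peak in the second library (0.15, 0.45, 0.25, 0.15);
* C — peak in the third (0.10, 0.20, 0.45, 0.25);
* D — monotone increasing (0.10, 0.20, 0.30, 0.40).

C and D were deliberately kept close (they differ only in the last two
libraries): distinguishing a mid-course peak from a late rise is exactly
the hard case in four-point time courses.

**Validation data.**  For a selection of loci the generator emits a
transcript embedding a near-complementary site (one substitution by
default), RACE clones whose 5′ ends fall opposite miRNA position 10 with
probability `p_canonical = 0.7` and scatter uniformly otherwise, and a Ct
table (3 biological × 3 technical replicates) whose latent target
expression is anti-correlated with the miRNA archetype
(`e_s = −strength · log2(w_s / mean(w))`, strength 0.9, with configurable
Ct noise).  Setting the noise to zero makes 2^-ΔΔCT recovery exact, which
the tests assert to 1e-9.

# Preprocessing

`clean_reads()` applies the conventional cascade — minimum per-base Phred
score, no ambiguous bases, 3′ adaptor located and trimmed, insert length
bounds — and collapses survivors to unique sequences with counts.  The
adaptor is found by the leftmost occurrence of a ≥8-nt adaptor prefix with
at most one substitution (an exact-seed fast path with a per-read rescue
scan); reads without an adaptor are treated as un-ligated and discarded,
and trimming is idempotent on already-trimmed input.  Since the literature
quotes both an 18–44-nt cleaning window and an 18–28-nt analysis window,
both are exposed: the pipeline cleans at 18–44 and then restricts with
`subset_lengths(18, 28)`.  Internally all sequences use the DNA alphabet
(T, not U); report writers emit U where miRNA convention expects it.

# Annotation and mapping

Contaminant classification labels a read with the first class, in priority
order rRNA > tRNA > snRNA > snoRNA > repeat, containing it as an exact
sense-strand subsequence (mismatch-tolerant matching is available).  The
priority order is a configuration choice; it only matters for reads
matching several classes.  Genome mapping records *every* occurrence of
each unique read on both strands (Biostrings `PDict` per width at zero
mismatches, per-read `matchPattern` otherwise).  Reads with more than 20
hits are flagged multi-mappers: still genome-matched for the class table,
but barred from seeding novel loci.  The mapper's contract is exact
hit-set equality with a naive all-positions string search, asserted on a
100-kb genome with 1,000 reads.

The class-distribution table partitions clean reads — contaminant classes
first, then genome-matched, then unannotated — and computes percentages as
`count / clean_reads × 100` with half-up rounding to two decimals
(`class_percent()`).  Published tables of this kind occasionally contain
percentage cells inconsistent with their own counts; the report always
recomputes from counts.

# Known miRNAs

`assign_known()` compares each read against every reference mature of
equal length and assigns it to the reference(s) with the fewest
substitutions, up to two (no indels).  Equal-best ties split the read
count evenly, so totals are conserved exactly.  Reads 1–2 nt shorter or
longer whose 5′-anchored overlap fits the same budget are attached to the
call as flagged 3′ length variants (isomiRs) rather than as separate
miRNAs.  Reads occurring anywhere inside a known hairpin — star or loop
fragments — are excluded from novel-locus seeding via the hairpin
reference, mirroring practice of mapping against both matures and
precursors.  Lowering the mismatch budget can only remove calls, a
monotonicity the tests check.

# Novel miRNA prediction

**Seeding.**  Alignments of eligible reads (not contaminant, not assigned,
not multi-mapping, not inside known hairpins) are clustered per chromosome
and strand with a 10-nt merge gap; clusters with a summed count below 5
are dropped.  Only reads seen at least twice take part in clustering
(`min_read_count = 2`): on deeply covered genomes, singleton background
fragments otherwise chain distinct loci into one genome-wide cluster.
Singletons still count toward the dominance denominator.  Each cluster's
modal read becomes the prospective mature, and two windows are emitted —
far flank on the left, and far flank on the right — so the mature may sit
on either hairpin arm.

**Folding.**  `fold_rna()` is a pluggable adapter.  The preferred backend
is ViennaRNA's `RNAfold` (thermodynamic nearest-neighbour model, called in
batch); a built-in base-pair-maximization folder with simple stacking
weights (G:C = 3, A:U = 2, G:U = 1, minimum loop 3, deterministic
traceback) exists for dependency-free testing and is labelled `bpmax` in
the output metadata.  Windows are folded twice: the full window locates
the star arm, the window is trimmed to the mature/star duplex plus 10-nt
padding, and the trimmed precursor is refolded and evaluated.  Trimming
gives realistic precursor lengths (~60–120 nt), energies and MFEI values;
scoring the whole 270-nt window would dilute all three.

**Criteria.**  From the pair table of the dot-bracket structure,
`duplex_features()` walks the mature/star duplex: maximal unpaired runs
with an equal number of unpaired bases on the opposite strand are
symmetric internal loops and contribute their length to
`duplex_mismatches`; runs with unequal contributions (including
strand-exclusive bulges) count once each as `asymmetric_bulges`; terminal
unpaired mature bases count as mismatches of unknown pairing, never as
bulges.  The star span is inferred from the partners of the mature with a
2-nt 3′ overhang.  The verdict requires: mature on a single arm with at
most 4 unpaired bases; duplex mismatches ≤ 4; asymmetric bulges ≤ 2;
dominance (reads on the mature/star ± 2 nt footprint over all
precursor-overlapping reads) ≥ 0.8; MFE ≤ −18 kcal/mol.  The MFEI,
`100·|MFE| / (length · GC%)` with GC as a percentage, is computed and
flagged against 0.85 but is *not* a hard filter — genuine plant miRNAs
below 0.85 are routinely retained, so it is reported as evidence.  The
mismatch, dominance and energy ceilings are not published constants; they
follow community gold criteria and are all configuration-exposed.
Clusters passing on both windows keep the lower-MFE precursor, and calls
whose precursors overlap on opposite strands (a hairpin's star arm maps
both ways) are collapsed the same way.

**False-discovery behaviour.**  Two null experiments characterize the
caller.  Running discovery against a dinucleotide-shuffled genome (same
composition, hairpins destroyed) reports essentially nothing, because true
read stacks no longer map — this is the pipeline-level false-discovery
control and is asserted at ≤ 5% of the embedded locus count.  A harsher
structural null plants random read stacks directly on the shuffled genome,
granting every random 21-mer perfect expression support so only the
structural criteria can reject it; 3–7% of such stacks pass, almost always
with MFEI well below 0.85.  That rate is the honest structural
false-positive cost of keeping MFEI advisory; the acceptance script
reports it separately (`null_stack_hairpin_pass_rate_pct`) so the
trade-off stays visible.

# Expression profiling

RPTM is `count / library_total × scale`, with the scale configurable
because the unit's name (per ten million, 1e7) and its printed defining
formula (×1e6) disagree in the source literature; the default is 1e7 and
no result here depends on the choice, since selection and clustering are
scale-free given the threshold.  Rows with a maximum above 100 RPTM in at
least one library (strict inequality) form the "strongly expressed" set.
Profiles are transformed to `log2((rptm + 1) / (rowmean + 1))` — the
pseudocount of 1 RPTM tames zeros — and clustered by complete-linkage
agglomeration on Euclidean distance (Pearson distance available), with the
tree cut at k = 4.  Clusters are labelled from their centroids: strictly
decreasing → A, strictly increasing → D, peak at library 2 → B (first such
cluster by row order), peak at library 2 or 3 → C, anything else
unclassified.

At log-normal multiplicative noise of σ = 0.1 this labelling recovers at
least 90% of true classes on a 40-row, 10-per-archetype matrix across all
of 100 random seeds (minimum observed accuracy 0.93).  Beyond σ ≈ 0.15 the
C and D archetypes begin to overlap genuinely — complete linkage then
merges late-rising C rows into the D cluster — so the tests state the
property at σ = 0.1 and make no claim in the overlap regime.

# Target prediction

`score_duplex()` aligns the miRNA 5′→3′ antiparallel against a site:
position 1 pairs the site's 3′-most base.  Per-position penalties are
match 0, G:U wobble 0.5, mismatch 1, gap 2, all doubled inside the seed
(miRNA positions 2–13), summed into an "expectation"; every parameter
lives in `duplex_scheme()` so alternative schemes are declarative.  G:U
detection is orientation-aware (miRNA G with site U, or miRNA U with site
G).  `scan_transcripts()` runs a small dynamic program (in C++) over every
transcript anchor allowing at most one gap, reports hits at or below the
cutoff (default 3.0), and deduplicates overlapping hits keeping the lowest
expectation.  With gaps disabled the scanner equals an exhaustive
per-window rescoring, asserted on a 5-kb transcript; a planted site with
one seed mismatch scores exactly 2.0, is recovered at cutoff 3.0 and
missed at 1.5.  Only cleavage-mode scoring is implemented; target-site
accessibility energies and translational-inhibition calls are out of
scope.  `target_summary()` divides non-redundant miRNA–transcript pairs by
the number of miRNAs with at least one hit, reported to one decimal with
half-up rounding.

# Validation analyses

**RACE.**  `map_cleavage()` converts each clone's 5′-end transcript
coordinate to a miRNA-relative position — position *p* means the clone end
is the target base paired to miRNA base *p* — so canonical cleavage
between bases 10 and 11 concentrates clones at position 10, and the
reported `canonical_fraction` sums positions 9–11 to honour the
"9–11th position" convention.  Clones outside the site ± 20 nt are tallied
as unmapped; fractions are over mapped clones and always sum to 1.

**qPCR.**  `ddct()` averages technical replicates within each biological
replicate, forms ΔCt against the reference gene per replicate, subtracts
the calibrator sample's mean ΔCt, and reports `2^-ΔΔCT` as mean ± SD over
biological replicates only — so uncertainty reflects biology, not
pipetting.  The estimate is invariant to adding a constant to all Ct
values.  `correlate_profiles()` reports Pearson (or Spearman) r and an
anti-correlation verdict; with four time points no p-value is attached, by
design — r is descriptive.

# Numerical and formatting choices

Coordinates are 0-based half-open internally and 1-based closed in GFF3
and reports.  Reported percentages use half-up rounding (two decimals for
class tables, one for 5′-nucleotide percentages and targets-per-miRNA);
fractions print to three decimals and MFEI to two.  All tabular outputs
are TSV with fixed column orders, so a rerun under the same seed is
byte-identical — the pipeline test asserts this file-by-file.  Degenerate
inputs fail loudly: empty libraries, zero library totals, zero-variance
correlation profiles, malformed structures, clones beyond the transcript,
and unknown configuration keys are all errors, not warnings.

# Limitations

The generator emulates the statistical skeleton of a small-RNA experiment,
not its biology: contaminant references are random sequences (matching is
by subsequence identity, so realism is unnecessary), there is no
sequencing-error or UMI model, expression archetypes are exact mixtures
rather than empirical profiles, and precursors always fold cleanly because
they are built that way.  Passing recovery tests therefore demonstrates
that the implementation is faithful to its stated criteria and consistent
end to end — not that those criteria would achieve the same recall or
specificity on real libraries, where isomiR complexity, repeat-derived
siRNA stacks and imperfect hairpins are the norm.  Dataset-level counts
from any particular study (how many miRNAs, how many differentially
expressed) depend on its unreleased libraries and are not reproducible at
desk scale; what is reproducible — and what the acceptance script
recomputes — is the arithmetic those counts feed (class-table percentages,
cross-tabulations, targets-per-miRNA means) plus the behavioural
properties above.
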