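---
title: "Methods: small RNA and degradome analysis for drought-responsive miRNA discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA and degradome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnapipe)
```

srnapipe implements, as a tested and reusable pipeline, the standard
analysis for discovering drought-responsive microRNAs in a plant such as
foxtail millet from paired small RNA-seq libraries (a well-watered control,
CL, and a drought-stressed treatment, DT) together with degradome (PARE)
sequencing for target validation. This vignette explains the models and procedures the package
implements, the choices made where the method description left the design
open, and what the synthetic validation data do and do not establish.

## The analysis at a glance

1. **Cleaning and collapsing.** Raw reads are adapter-trimmed (longest
   prefix of the 3' adapter found as a read suffix), filtered to 16-30 nt,
   and collapsed to unique sequences with counts. Libraries are compared by
   shared/specific sequence overlap and by read-length distribution (plant
   libraries peak at 24 nt).
2. **Annotation.** Each unique sequence is mapped to the genome by perfect
   match on both strands and assigned one category by a fixed precedence:
   rRNA > tRNA > snRNA > snoRNA > known miRNA > repeat > exon (sense, then
   antisense) > intron (sense, then antisense) > others. Reference-first
   precedence mirrors the practice of removing Rfam ncRNA classes before
   miRNA analysis; a multi-locus read is classified once, by its
   highest-precedence annotation, and contributes its whole count once.
3. **miRNA identification.** Known miRNAs are library sequences matching a
   reference mature set with equal length and at most 2 substitutions.
   Novel candidates come from clustering the remaining unannotated mapped
   reads into loci (same strand, gap <= 200 nt, >= 5 reads) and taking each
   locus's most abundant read as the mature candidate. Every candidate must
   satisfy the identification criteria below on its best-scoring precursor
   window.
4. **Differential expression.** Counts are normalised to tags per million
   (TPM = count / library total x 10^6) and tested with the Audic-Claverie
   exact test (primary), Fisher's exact test and a Pearson chi-square on
   the 2x2 table. A miRNA is called differentially expressed when
   |log2 FC (DT/CL)| >= 1 and the primary p-value is <= 0.01, after
   excluding miRNAs with sequencing frequency < 10 in both libraries.
5. **Degradome target validation.** Degradome tags (5'-anchored 20-nt
   signatures of uncapped ends) are mapped to transcripts to build
   T-plots. Binding sites are scored with an Allen-style complementarity
   penalty; a site is validated when tags fall within 1 nt of the position
   opposite miRNA nucleotide 10, and classified into categories 0-4 by the
   dominance of its tag pile.

## The folding engine

Precursor structures are computed by a Nussinov-style dynamic programme
that minimises the sum of per-pair energies, e(G:C) = -3.0, e(A:U) = -2.0,
e(G:U) = -1.0 kcal/mol, with a minimum hairpin loop of 3 nt and no loop
penalties. Ties are broken toward fewer pairs, then by a fixed
deterministic traceback (the left end pairs its largest admissible partner
first), which keeps equal-energy stems contiguous and makes folding
reproducible. The engine is exact for its model: tests compare it against
an oracle that enumerates every nested structure of short sequences.

This is deliberately not a nearest-neighbour (Turner) thermodynamic model:
it has no stacking context, no loop penalties and no temperature
dependence, and its energies will not numerically reproduce RNAfold's. The
hairpin acceptance threshold of -18 kcal/mol is therefore applied *under
this model*, and the published precursor MFE values (which came from
RNAfold's Turner model) are not comparison targets for it. Because the
model rewards any admissible pair, arbitrary sequences fold with many
pairs; the stem-quality rule below compensates.

## Identification criteria

A candidate passes when all of the following hold:

1. **Marked stem-loop.** The precursor folds into a structure with exactly
   one terminal loop, a stem of >= 15 base pairs, and at most 15% unpaired
   bases within the stem span (terminal loop excluded). The unpaired-
   fraction bound operationalises "marked": under a maximum-pairing energy
   model nearly every sequence folds into *some* single-loop shape once the
   enclosing stem is trimmed out of its window, but clean pre-miRNA stems
   sit near 0% unpaired while dinucleotide-shuffled or random sequence sits
   near 25-35%. The 15% default separates these two regimes with a wide
   margin on both sides and is calibrated to this package's energy model,
   not to Turner-model folds.
2. **Duplex mismatches <= 4** between the mature and its star.
3. **Asymmetric bulges <= 2 nt** in the duplex.
4. **Precursor MFE <= -18.0 kcal/mol** (boundary inclusive: "maximum free
   energy allowed" is read as an inclusive bound).

plus two siRNA exclusions: at most 24 perfect genomic loci for the mature
(more loci indicate repeat-derived siRNA), and no siRNA duplex signature at
the locus (two abundant opposite-strand reads whose duplex carries a 2-nt
3' overhang on each strand).

When the star is expressed, criteria 2-3 are evaluated on the most
abundant library sequence on the opposite arm whose duplex with the mature
shows the canonical 2-nt 3' overhang geometry (within 1 nt). Otherwise the
duplex is evaluated against the structure-implied star: the region paired
with the mature, shifted 2 nt 3'-ward. A star is not required for a novel
call (most published novel plant miRNAs lack an observed star), but
`require_star = TRUE` enables the stricter mode.

### Precursor windows and hairpin trimming

The method description does not state how precursor sequences are obtained
around a mature locus. The package extracts three windows,
`[start - f, end + g]` for `(f, g)` in `{(250, 20), (20, 250), (125,
125)}`, clipped to the scaffold. A window necessarily carries flanking
genomic sequence that folds into side branches, so whole-window structures
are never single hairpins. The package therefore trims each folded window
to the maximal unbranched stem enclosing the mature's arm (walking outward
from the terminal loop nearest the mature until the first branch point),
refolds the trimmed interval, and evaluates the criteria on that precursor
— the same role sub-hairpin extraction plays in the established novel-miRNA
predictors. Among windows, the passing precursor with the lowest MFE wins.

## Count statistics

With library totals N1 (CL) and N2 (DT) and counts x, y for one miRNA, the
Audic-Claverie conditional distribution is

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!}
  \left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)},$$

a negative-binomial law computed in log space; the two-sided p-value is
`min(1, 2 min(P(K <= y), P(K >= y)))`. Tests verify it against an
independent direct-summation oracle to 10^-10 relative error and check its
size under a Poisson null (at most 2% of null replicates at p <= 0.01 —
the discrete test is conservative). One caution surfaced by those tests:
the two-sided p-value is *not* symmetric under swapping the libraries,
even at equal depths, because the conditioning variable changes; only the
conditional density is symmetric at N1 = N2.

Design choices here: the Audic-Claverie p is primary for DE calls (it is
the headline two-library tag-count test of the IDEG6 battery the study
used), with Fisher and chi-square reported alongside; the frequency-10
filter excludes a miRNA only when *both* libraries are below 10 reads,
since the strict both-must-pass reading would discard strongly induced
miRNAs absent from one library (a flag restores the strict mode); zero
counts enter the fold-change as a 0.5-read pseudo-TPM to keep log ratios
finite and symmetric; and no multiple-testing correction is applied to the
calls (the study applied none) — a Benjamini-Hochberg column is emitted
for information only.

## Degradome analysis

The complementarity score follows the Allen penalty: aligned ungapped
against the reverse complement of the site, each mismatch costs 1, each
G:U wobble 0.5, doubled at miRNA positions 2-13; the cutoff is 4.5 for
degradome-validated calls and 3.0 for pure in-silico prediction. Published
degradome target tables of this kind print alignment scores in half-point
steps from 0 to 4.5, the value range this scheme produces, which is why it
is the adopted interpretation where the scoring rule is otherwise
unstated. The expected cleavage position is the
transcript base paired to miRNA nucleotide 10, with a +/- 1 nt acceptance
window (whether the original analysis allowed a window is unstated).

Cleavage sites are classified by the cascade: a site whose tag pile is a
single raw read is category 4 (tested first, so a transcript whose only
tag sits at the site yields 4, not 0); the unique maximum on the
transcript is 0; a tied maximum is 1; above the median of occupied
positions is 2; otherwise 3. The median is computed over positions with at
least one tag, so zero positions cannot dilute it.

## The synthetic study

`sim_config()` / `sim_genome()` / `sim_srna_libraries()` /
`sim_degradome()` generate a complete input set with known truth,
emulating the study conditions: two libraries at 2 x 10^6 reads each, 20
planted miRNA hairpin loci on 5 x 20 kb scaffolds, precursors 61-222 nt,
25% of miRNAs differentially expressed at log2 FC = 2 (applied to the DT
mean), negative-binomial counts with dispersion 0.02, a 24-nt-dominated
background containing rRNA/tRNA/snRNA/snoRNA decoys, repeats, gene-derived
reads and unmappable sequence, one dinucleotide-shuffled decoy locus per
precursor, siRNA duplex loci, and a degradome of 5 x 10^4 tags in which
90% of a target transcript's tags start exactly at the planted cleavage
site. Planted hairpins carry fully complementary mature:star duplexes with
the canonical 2-nt 3' overhangs; extra precursor length goes into the stem
extension rather than the terminal loop, because long-stem short-loop is
what real pre-miRNAs look like and what survives window folding. Mature
expression is drawn log-uniformly from 800-5000 expected reads per 2
million (scaled with depth), the range of a well-expressed plant miRNA;
planted loci are spaced >= 420 nt apart so read clusters stay distinct
under the 200 nt clustering gap.

All randomness derives from a single integer seed, and identical
configurations produce byte-identical outputs. The generator is itself
first-class, tested code: containment of every planted sequence, the
degenerate zero-dispersion limit (counts equal rounded means), empirical
recovery of planted fold-changes, and the tag-pile geometry are all
asserted.

What passing on this fixture shows: the pipeline's stages are internally
consistent and recover a planted truth of the kind the method assumes,
with shuffled decoys rejected. What it does not show: performance on real
libraries, where expression is burstier, backgrounds are vastly more
diverse (millions of unique sequences), precursors deviate from perfect
complementarity, sequencing error is non-uniform, and the reference sets
are incomplete. Genome-scale inventories of this kind (tens of known
miRNA families, dozens of novel candidates) depend on full-size read
archives, a complete reference genome and current miRBase/Rfam releases,
none of which are desk-scale; the package instead reproduces the report
arithmetic exactly (TPM conversions, overlap and annotation percentages)
and validates the method's behaviour on planted truth.

Problem sizes used by the shipped validation: module tests run the fixture
at 2 x 10^5 reads per library; the end-to-end acceptance checks run the
full 2 x 10^6-read configuration. Folding oracles enumerate structures up
to 18 nt; the count-test oracle grid spans counts up to 200 at depths
10^5 and 10^7.

## Numerical conventions

* Percentages in report tables are rounded half away from zero to 2
  decimals, TPM to 1 decimal, the conventions such report
  tables use (`round_half_up()`).
* Coordinates are 1-based inclusive in memory and in TSV reports; BED
  files are written/read through rtracklayer, which handles the 0-based
  half-open conversion.
* Genome and reads are stored as DNA (T); folding and duplex analysis
  transliterate to RNA (U). G:U wobbles count as pairs in duplex analysis
  and are penalised 0.5 in target scoring.
* Degenerate inputs: empty libraries collapse to empty tables rather than
  errors downstream; a zero-expectation chi-square table returns p = 1
  with a degenerate flag; `categorize_site()` refuses a position with no
  signal.

## Known limitations

* The energy model is a teaching-grade Nussinov variant; use the plug-in
  point (fold any precursor with an external engine and pass the structure
  into `duplex_stats()` / `apply_criteria()`) where Turner-model parity
  matters.
* Perfect-match-only mapping: no mismatch tolerance at the genome level,
  consistent with perfect-match practice but unforgiving of sequencing
  error.
* One category per called site: dual or fractional categories that appear
  in published tables (e.g. "0/2") arise from multiple tag piles and are
  not reproduced; their definition is unstated in the source material.
* The in-silico target predictor is a complementarity scan, a deliberate
  simplification standing in for an external prediction service.
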