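---
title: "Methods: two-library small RNA analysis of divergent chicken muscle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-library small RNA analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mirgallus` compares the skeletal-muscle miRNA transcriptomes of two
chicken lines — broilers (meat-type, fast muscle growth) and layers
(egg-type) — from two deep sequencing libraries, and assembles a
miRNA–target interaction network from the differentially expressed miRNAs.
This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the design decisions taken
where the methodology left genuine freedom.

## Counting rule and annotation cascade

All sequences are held internally in the DNA alphabet (U is converted to T
on ingest and re-emitted as RNA only in human-readable reports), and all
genomic coordinates are 0-based half-open internally and in BED output;
1-based closed coordinates appear only inside folded-sequence windows.

Small RNA reads carry untemplated 3' additions, so exact full-length
matching undercounts miRNAs. The counting rule is therefore: a tag of
20–25 nt is a copy of a reference miRNA iff its 5' 19 nt equal the
reference's 5' 19 nt; everything 3' of position 19 is ignored. The same
rule serves the miRNA\* and metazoan-homolog classes. The remaining classes
(snoRNA, snRNA, rRNA, tRNA, mRNA, repeats) are interval classes: a tag
must have a genomic locus fully contained in a feature interval on the
feature's strand — "perfect match" read as containment.

Annotation is a priority cascade in a fixed, total order: chicken miRNA,
chicken miRNA\*, metazoan miRNA homolog, metazoan miRNA\* homolog, snoRNA,
snRNA, rRNA, tRNA, mRNA, repeats. Each step sees only tags left
unannotated by earlier steps, so category read totals plus the unannotated
remainder always partition the library.

Two conventions where the methodology is silent:

* A tag whose 19-nt prefix matches several catalog miRNAs is credited to
  *every* matching id in the expression table (the ambiguity is logged);
  the category is still assigned once.
* B/L ratios print with two decimals below 10 and three significant digits
  (one decimal) at 10 and above, ties rounded half away from zero — the
  convention the published abundance table itself follows (0.59, 2.67,
  6.39, 11.4). The unrounded ratio is kept alongside.
* The "similar levels" flag in the arm comparison uses a pooled-count
  ratio of at most 4 between mature and star arms; no cutoff was published
  and 4 reproduces the qualitative calls for the miR-199/miR-1329-type
  loci while excluding ~26-fold-skewed loci like miR-181a.

isomiR stacks align every tag occurring exactly within a hairpin and
report 5'/3' offsets against the catalog mature. The most abundant row is
chosen by total count with ties broken by smaller |5' offset|, then
smaller |3' offset|, then lexicographic sequence; a stack is flagged when
that row is not the reference isoform. A tag occurring twice in one
hairpin is assigned its leftmost occurrence (logged).

## The two-library likelihood-ratio test

Counts $x_A, x_B$ from libraries of sizes $N_A, N_B$ are modelled as
independent Poissons with rates per sequenced read, $x_i \sim
\mathrm{Poisson}(N_i\lambda_i)$. The likelihood-ratio statistic for
$H_0: \lambda_A = \lambda_B$ has the closed form

$$ 2\left[x_A \log\frac{x_A}{N_A\hat\lambda_0}
        + x_B \log\frac{x_B}{N_B\hat\lambda_0}\right],
\qquad \hat\lambda_0 = \frac{x_A + x_B}{N_A + N_B}, $$

with $0\log 0 := 0$, referred to $\chi^2_1$. A zero statistic always maps
to $p = 1$. The published cutoff is a raw $p < 10^{-4}$ with no
multiple-testing correction; a Benjamini–Hochberg option exists but is off
by default to reproduce that rule. Direction is the sign of
$x_B/N_B - x_A/N_A$.

Two unstated choices, both configurable with defaults logged at run time:

* **Library size**: $N_i$ defaults to the genome-mapped read total, since
  the comparison is about the expression of mapped tags; raw totals can be
  selected.
* **Microarray t-test**: two-sample, equal-variance, two-sided. With both
  groups constant and equal, $p := 1$; constant but different, $p := 0$
  (the noiseless limit of the simulation).

The microarray gene filter is conjunctive: mean-intensity ratio strictly
above 1.5 (or below 1/1.5) *and* $t$-test $p < 0.05$, per embryonic time
point (E10–E18); the union list is deduplicated. Intensities are assumed
pre-normalized on the linear scale, which the synthetic generator
guarantees. Type-I error of the LRT is checked empirically in the
acceptance suite on 50,000 null pairs at expected counts ≥ 50.

## Secondary structure: base-pair maximization

Hairpin checks use a deterministic base-pair-maximization fold (Nussinov
dynamic programming) over {AU, UA, GC, CG, GU, UG} with a minimum hairpin
loop of 3 unpaired bases. Traceback prefers pairing the 5'-most open base
over leaving it unpaired and takes the smallest admissible partner first.
The pair count is validated against exhaustive enumeration of all nested
structures for sequences up to 14 nt. Externally computed dot-bracket
structures (e.g. thermodynamic folds) can be supplied through
`fold_from_dotbracket()` wherever a fold result is consumed.

A count-maximizing fold has no notion of stability, and its optima are
highly degenerate: on windows with random flanking sequence it can
scatter a stem's partners across equally scoring alternatives. Two
consequences are handled explicitly:

* **Precursor trimming.** Homolog acceptance and candidate calling first
  fold the wide excised window (hit ± 70 nt); when the stem rule fails
  there, precursor-sized windows (flanks of 33–45 nt: loop + a
  mature-length star + slack) are folded as well, because trimming removes
  the distracting flank pairings. Enumerating several loop lengths
  reflects the variation of real precursors.
* **Star-side inference.** The star region implied by a fold is the hull
  of the mature's outside partners *on one side* of it (5' or 3'); a stem
  pairs arm against arm, so per-side hulls stay disjoint from the mature
  where a global hull would not.

## Conservation rules

A mature sequence is scanned against each target genome by ungapped
sliding comparison on both strands. The covered region is always a prefix
of the mature (the seed side must anchor) and ends at a match; it is
accepted iff it spans strictly more than 80% of the mature and holds at
most one mismatch — "fewer than two mismatches" read as ≤ 1, both
thresholds strict. Accepted hits must additionally sit in an excised
precursor whose fold pairs strictly more than 70% of the hit region into
the star region. Lineage classification is hierarchical: any accepted
homolog in a non-avian vertebrate genome ⇒ vertebrate-conserved; else
zebra finch ⇒ avian-specific; else chicken-specific.

## Novel candidates and the permutation control

Tags mapping to more than 5 genomic positions or overlapping a repeat are
discarded (exonic positions are deliberately allowed). Remaining loci are
clustered (overlapping same-strand loci merge); each cluster is anchored
at its highest-count tag locus and excised twice — once per arm
orientation — with a 70 nt flank. A window is called iff

1. **stem**: > 70% of the modal tag footprint pairs into one star window
   of footprint width + 10 nt (with the precursor-trimming fallback
   above);
2. **arm consistency**: ≥ 90% of the stack's reads (count-weighted) lie on
   the mature or star arm (± 4 nt isomiR slack);
3. **5' homogeneity**: ≥ 80% of mature-arm reads share one 5' start.

The external predictor's probabilistic log-odds score is deliberately not
re-implemented; this rule triple is a documented simplification, so
candidate lists will differ from the original publication's. Overlapping
passing windows (the two arm views of one precursor) are merged into one
candidate locus before counting.

The permutation control shuffles each tag's sequence preserving
mononucleotide composition (counts untouched; a dinucleotide-preserving
swap shuffle is available) and reruns mapping, excision and calling. The
published permutation unit was unstated; per-tag shuffling is the
documented choice. At synthetic scale almost no shuffled 16–30 nt tag
re-maps exactly to a 100 kb genome, so the permuted dataset typically
yields zero windows and the signal-to-noise denominator is guarded
(`max(n_permuted, 1)`, flagged degenerate). Against a 1 Gb real genome,
shuffled tags re-map readily and the ratio is informative — the guard
changes nothing there.

## Network construction

Seed sites follow the canonical classes against miRNA positions 1–8:
7mer-m8 (exact reverse complement of positions 2–8), 7mer-1A (reverse
complement of 2–7 followed by an A in the UTR), 8mer (both). Overlapping
sites report once at the strongest type. Context scores, conserved-branch
weighting and ortholog mapping of the cited prediction tool are out of
scope — seed matching only.

A predicted miRNA→target edge survives iff the target is in the microarray
DE union and its breed direction opposes the miRNA's sequencing-based
direction at ≥ 1 time point where the target was itself called DE — the
published pooling of E10–E18 calls does not state a per-time-point rule,
so agreement at one embryonic stage is required. Target–target edges come
from the PPI list, kept iff both endpoints have expression profiles and
|PCC| ≥ 0.3 across all 54 arrays (per-array profiles, not time-point
means; the boundary is inclusive since 0.3 is "used as a cutoff"). The
correlation p-value uses the $t$ transform with $n-2$ df. Assembly drops
target–target edges whose endpoint is not a retained target, and exports
(SIF, GraphML, TSV, JSON summary) are emitted in sorted order so reruns
are byte-stable.

## The synthetic study

The generator's defaults *are* the study conditions, at 1/100 sequencing
depth: two libraries of 27,000 and 25,766 reads (layer, broiler), 30
hairpin loci in a 100 kb genome, 10 differentially expressed miRNAs with
true folds drawn from [4, 8] balanced between directions, a 10% star-arm
fraction with one star-dominant locus (mature arm silent, mirroring the
miR-140-like pattern), 5' offset probabilities (0.01, 0.03, 0.92, 0.03,
0.01) over −2..+2 and 3' probabilities (0.01, 0.04, 0.15, 0.55, 0.15,
0.07, 0.03) over −3..+3 (3' ends are the heterogeneous ones, and the
dominant insert length stays 22 nt), 35% contaminant reads split over
rRNA/tRNA/snoRNA/snRNA/mRNA/repeat features (the published per-category
proportions are graphical only, so these weights are chosen, not derived),
a 9-stage × 2-breed × 3-replicate expression panel (54 arrays) with
log2-scale noise sd 0.2, twofold planted breed effects at the embryonic
stages, 60 PPI edges (half genuinely co-expressed), 30 planted
miRNA–target pairs with 8mer sites, and decoy sets (DE genes without
sites; genes with sites but no DE) that the filters must reject.

Sampling is multinomial from the library-size total, so emitted totals are
exact; null miRNAs have identical expected rates per mapped read in both
libraries (the DE mass is capped at planning time so the broiler-side
folds never exhaust the contaminant budget — otherwise renormalization
would leak composition effects into the null). isomiR offsets act on
hairpin coordinates and are resampled if they leave the hairpin or the
16–30 nt insert range. Contaminant reads are exact substrings of their
source features. UTRs are rejection-sampled so that negatives verifiably
contain no site for any catalog miRNA.

Planted precursors are constructed, not merely sampled: the star arm is
the reverse complement of the mature with 3 substituted positions (real
passenger strands are imperfect complements; a perfect inverted repeat
would also let star reads map the mature locus on the opposite strand,
which real data does not show), the loop is drawn from {A, C} so it cannot
self-pair, and a candidate is rejected unless the assembled hairpin passes
the package's own fold + pairing check, its mature arm is essentially
unstructured (< 4 self-pairs), and it carries no homopolymer run of 5 or
more (such runs blur the arm/loop boundary and misfold in genomic
context). Species genomes for conservation testing carry each conserved
miRNA's full hairpin verbatim at random positions.

What the generator does **not** emulate: sequencing errors and quality
scores, adapter dimers, expression-dependent ligation biases, isomiR
templated/untemplated distinctions, overdispersion between biological
replicates of the sequencing libraries (each breed is one library, as in
the study), imperfect homologs (conserved loci are planted verbatim), and
genome-scale repeat structure. Passing tests therefore demonstrate the
pipeline's internal correctness and its statistical behaviour under the
stated model — not robustness to real-data artifacts outside it.

## Numerical and boundary conventions

* Strict inequalities: coverage > 0.8, pairing > 0.7, microarray fold
  > 1.5; inclusive bounds: |PCC| ≥ 0.3, tag lengths 20–25 and insert
  lengths 16–30, ≤ 5 genomic loci.
* The LRT statistic is clamped at 0 against floating-point negatives at
  the null; `statistic == 0` forces `p = 1`.
* Concordance rates round half away from zero to one decimal;
  signal-to-noise rounds to the nearest integer with a guarded
  denominator.
* All generator randomness flows through one seeded stream per stage,
  derived deterministically from the master seed; identical configuration
  and seed give byte-identical artifacts.
* Problem sizes in the test and acceptance runs (tiny 40 kb/12-locus
  bundles for unit tests, the default 100 kb/30-locus bundle for
  end-to-end checks, 50,000 null pairs for calibration) were chosen so the
  full suite completes in minutes on one core while keeping every planted
  signal comfortably above sampling noise.

## Known limitations

* The base-pair-maximization fold is a stand-in for thermodynamic folding;
  its degenerate optima occasionally fail a genuine hairpin even with
  precursor trimming (observed at isolated planted loci under some seeds),
  and its hairpin rule has no energy notion at all.
* The candidate rule triple is not the external predictor's probabilistic
  score; absolute candidate lists are not comparable to the original
  publication's, only the control logic (permutation, signal-to-noise) is.
* The Poisson two-library test has no overdispersion; with biological
  replicates a negative-binomial model would be required.
* Homolog scanning is ungapped; a real indel-containing homolog would be
  missed.
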