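---
title: "Methods: PAM discovery, editing quantification and allele-specific design for Cas12a"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAM discovery, editing quantification and allele-specific design for Cas12a}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cas12atk)
```

## The reporter model

cas12atk implements the computational side of a GFP-activation screen for
Cas12a nucleases with degenerate, pyrimidine-rich PAMs. The reporter
carries a 29-nt insert — a 5-nt randomized PAM region followed by a 24-bp
protospacer (`GGATATGTTGAAGAACACCATGAC`) — between two 20-nt homology arms
(`AAGCCTTGTTTGCCACCATG` upstream, `GTGAGCAAGGGCGAGGAGCT` downstream),
immediately after the GFP start codon. Because 29 mod 3 = 2, the unedited
insert knocks GFP out of frame. A nuclease that recognises the PAM cuts
the protospacer; error-prone repair leaves an indel with net length change
$\Delta$, and the cell turns green iff $(29 + \Delta) \bmod 3 = 0$.
GFP-positive cells are sorted, the insert is amplicon-sequenced, and the
5-mers observed among in-frame-mutated reads reveal the PAM preference.

```{r reporter}
reporter_construct()
```

The frame rule is deliberately frame-only: net $\Delta \equiv 1 \bmod 3$
restores GFP regardless of the inserted bases. Stop codons created inside
the insert are ignored, since the selection readout being modelled is
in-frame restoration; this slightly overstates the green fraction relative
to a real sorter but affects ref and alt 5-mers alike, so PAM inference is
unbiased.

## The synthetic-data generator

Every input the pipeline consumes can be generated with known ground
truth:

* `make_library(n, seed)` draws uniform random 5-mers onto the shared
  reporter template.
* `simulate_editing()` cuts each construct with probability
  `edit_prob * activity(PAM)`. Activity is a per-position product of base
  factors in $[0,1]$ (`pam_activity_model()`); all-or-none models come
  from IUPAC strings, e.g. `pam_model_from_iupac("NTTTV")` for a
  TTTV-preferring enzyme or `"NNYYN"` for a degenerate YYN recogniser.
  `edit_prob` defaults to 0.8 — a high-efficiency transfection; the exact
  value only scales the selected pool size, not the recovered PAM
  composition.
* The staggered cut: the nontarget strand is cut after protospacer
  position 18 and the target strand after position 23, leaving the 5-nt
  5′ overhang characteristic of Cas12a. Only the 5-nt stagger is treated
  as fixed biology; the absolute offsets are a configurable convention,
  since repair is modelled at the nontarget-strand cut only.
* Repair outcome: deletion with probability 0.7, insertion 0.3 (the
  remainder, zero by default, is perfect re-ligation, which leaves no
  scar and is therefore not an edit). Deletion lengths are geometric
  (p = 0.3) truncated at 20 nt, insertions geometric (p = 0.6) truncated
  at 10 nt, centred on the cut. These defaults produce a realistic mix of
  in-frame and frameshift alleles; any single-parameter family with
  support on both $\Delta \equiv 1$ and $\Delta \not\equiv 1 \bmod 3$
  would serve the tests equally.
* `simulate_gfp_pool()` applies the frame rule exactly, with an optional
  `leak_rate` for sorting impurity (default 0).
* `simulate_allele_amplicons()` generates biallelic amplicon reads with
  per-allele editing rates and a uniform substitution error rate. The
  container also carries a `cut_site` (default: centre of the reference)
  and an `indel_model`, so simulated indels land where the quantifier
  looks; a spec without a cut position could not place indels at all.
* `simulate_gel(f)` builds lane intensities obeying
  $(b+c)/(a+b+c) = 1-(1-f)^2$ exactly, so the cleavage formula inverts to
  $100f$ to machine precision.

Reads are full-length, single-end amplicons with no quality model beyond
the substitution rate: the downstream analysis consumes indel content, not
read-level artefacts. Consequently, green tests demonstrate correctness of
the *quantification machinery* under clean and lightly noised reads — they
do not certify behaviour on real libraries with PCR chimeras, adapter
read-through or quality dropoff.

## PAM discovery

`extract_random_region()` fixes the 5-mer between the literal anchors
`TTGTTTGCCACCATG` (upstream) and `GGA` (the protospacer start): exact
matching by default, with an optional single anchor mismatch. Rejections
are tagged outcomes (`no_upstream_anchor`, `downstream_mismatch`,
`non_acgt_base`, `truncated`), never errors, and `build_pam_counts()`
records how many reads each filter removed.

`classify_frame()` aligns each read globally to the reporter rendered with
that read's own 5-mer and sums indels intersecting the insert;
substitution-only reads are unedited. The in-frame class is exactly
$\Delta \ne 0 \wedge (29+\Delta) \bmod 3 = 0$, and only in-frame reads
enter the count table — out-of-frame reads survive sorting only as leak
and carry no PAM signal.

`compute_profile()` produces the position frequency matrix and the logo
information content $IC(j) = 2 + \sum_b p_{bj}\log_2 p_{bj}$ bits.
Choices worth stating:

* Logo positions are $-5..-1$ with $-1$ adjacent to the protospacer, the
  standard orientation for a 5′ PAM.
* Weighting is per-read (each sequenced molecule counts once), recorded in
  the output metadata; per-distinct-5-mer weighting would discard depth
  information.
* No baseline normalisation by the unselected library is applied by
  default (raw logos from selected reads); a `baseline` argument divides
  by input-library frequencies when library bias is a concern.
* The small-sample correction $e(n) = 3/(2\ln 2\, n)$ is off by default,
  matching common logo-tool behaviour, and floored at zero bits.

`compute_wheel()` builds the hierarchical (Krona-style) wheel: wedge
angles are proportional to joint path frequencies, siblings are ordered
alphabetically (a deterministic tie-break), and the default ring order
puts $-1$ innermost; the orientation is configurable because nothing in
the chart's definition fixes it. Exports are JSON (lossless), TSV and a
hand-rendered SVG, so no graphics device is required.

## Amplicon indel quantification

Alignment is Needleman–Wunsch with affine gaps via
`Biostrings::pairwiseAlignment` (match +5, mismatch −4, gap open −10, gap
extend −1): standard amplicon-calling parameters. Reads are
orientation-detected against the reference; alignments are deterministic,
with gap placement in ambiguous runs following the aligner's fixed
tie-break (class and net $\Delta$ are invariant to that placement, which
is what the oracle tests pin down). Reads under 80% identity over aligned,
non-gap columns are `unalignable` and leave the denominator — chimeric or
contaminant reads should not deflate rates.

`call_indels()` classifies by the indels intersecting a window of ±10 nt
around the cut site (`deletion`, `insertion`, `complex`, else
`unedited`); indels wholly outside the window are ignored and
substitutions never count. The window half-width is configurable; ±10
covers the indel spread produced by a distal staggered cut while excluding
unrelated polymorphisms on long amplicons.

Allele assignment reads the base aligned to the SNV column: alt base →
`alt`, ref base → `ref`; a spanning deletion, a third base or N →
`unassigned` (excluded from per-allele denominators). Off-target
efficiencies are normalised as `off/on`; ratios above 1 are flagged, not
clipped.

A quirk of periodic references is worth knowing: in a reference like
`ACGTACGT…` a deletion whose length matches the repeat period can be
placed anywhere in the repeat, including outside the quantification
window. This is an alignment-theoretic ambiguity, not a defect; the
package's tests therefore use random references, and real amplicons are
rarely periodic over 20 nt.

## Gel cleavage quantitation

For a substrate cut independently on both strands with probability $f$,
the cut fraction is $1-(1-f)^2$, giving
$$\mathrm{cleavage}(\%) = 100\left(1 - \sqrt{1 - \frac{b+c}{a+b+c}}\right)$$
with $a$ the undigested band and $b, c$ the product bands. The formula
uses only $b+c$; both bands are still recorded for provenance.
Intensities are taken as background-subtracted numbers — densitometry is
out of scope. The statistic is scale-invariant, bounded in $[0,100]$, and
strictly increasing in $b+c$ at fixed total.

## Allele-specific guide design

`scan_candidates()` scans both strands of a variant-centred window
(30-nt flanks, 61 nt total) for PAM-pattern matches (default `YYN`)
immediately 5′ of a full-length spacer (default 23 nt) such that the SNV
falls at a mismatch-sensitive spacer position — positions 1–2, 4–5, 7, 10
and 13–18 counted from the PAM-proximal end. Design decisions:

* Spacer length defaults to 23 nt (recorded in output metadata and
  configurable); the reporter's protospacer is 24 bp but crRNA spacers are
  typically processed shorter, and the mismatch window only reaches
  position 18 either way.
* Candidates whose PAM would overlap the SNV are excluded: the design
  strategy is allele discrimination through a spacer mismatch;
  PAM-destroying designs are a different strategy with different rules.
* The default targeted allele is the alternate (disrupt the pathogenic
  allele); `alleles = c("ref", "alt")` also emits reference-targeting
  guides.
* The full PAM + spacer must fit inside the extracted window; windows
  truncated at contig ends are flagged.
* Coordinates: VCF positions are 1-based; `pam_start` is 0-based on the
  scanned strand (plus-strand window for `+`, its reverse complement for
  `-`); spacer position 1 is PAM-proximal.

The scanner is validated against an unexported brute-force reference
implementation (explicit per-offset loops, its own IUPAC table, no shared
code) on thousands of random windows for both YYN and TTTV patterns, plus
strand-symmetry and window-monotonicity properties.

`design_batch()` accepts a VCF (via vcfR) or a plain variant table plus a
FASTA/named-vector genome, splits multi-allelic records, skips and counts
non-SNVs, and reports per-variant targetability. It deliberately does not
reproduce genome-scale ClinVar/dbSNP counts, which depend on database
versions.

## Problem sizes and numerical tolerances

The shipped tests run the PAM-recovery pipeline on 50,000 simulated
constructs, frame-classification truth-matching on 20,000 reads,
indel-rate recovery at rates 0.05/0.25/0.5 with 10,000 reads each (20,000
for the allele-resolved case), and 1,000 random design windows per PAM
pattern — sizes at which binomial 3-SD bounds are tight enough to catch
real defects while the whole suite stays inside a few minutes on one
core. Statistical recoveries are asserted within three binomial standard
deviations under fixed seeds; exact identities (gel round trip, wheel
angle nesting, JSON round trip) are asserted at 1e−9 or tighter.

## Known limitations

* The editing simulator models one cut and one local repair event; large
  rearrangements, microhomology-biased deletion spectra and multi-cut
  outcomes are absent.
* Frame classification assumes the sequenced amplicon spans the whole
  insert; fragmented or merged-pair inputs are out of scope.
* The PAM activity model is multiplicative across positions; epistatic
  PAM preferences would need a full 1024-parameter model, which the
  container admits but no constructor builds.
* The designer scores placement only; it does not rank guides by
  predicted activity or genome-wide off-target risk.
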