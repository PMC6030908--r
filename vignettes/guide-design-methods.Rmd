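---
title: "Methods: guide scanning, off-target scoring and reagent design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guide scanning, off-target scoring and reagent design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidecraft)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## Guide discovery

An input sequence (plain text or single-record FASTA; whitespace and line
numbers are stripped so numbered dumps paste cleanly) is scanned on both
strands for the nuclease's PAM. A candidate is emitted wherever the PAM
matches and the full protospacer fits inside the input. Case is preserved
as an annotation layer (`case_mask`): users mark regions of interest with
lowercase. `N` bases mark known variant positions; IUPAC ambiguity codes
are conservatively mapped to N. A sequence N matches *no* IUPAC class
during PAM matching — a variant under a PAM kills the PAM call, and a guide
whose protospacer or PAM touches an N is flagged `OVERLAPS_N` and dropped
from default output, because the variant may abolish binding.

Guide identifiers are `"<pos><forw|rev>"` where `<pos>` is the 1-based
plus-strand coordinate of the *leftmost* PAM base. For minus-strand guides
"first PAM base" is orientation-dependent; the leftmost-coordinate
convention was chosen so an id maps to a unique sequence position
regardless of strand. The id later names primers (`33forw_F`,
`33forw_ot2_R`) and pool oligos.

Built-in nuclease profiles: SpCas9 (NGG, 3' PAM, 20-nt guide, blunt cut
3 bp 5' of the PAM, i.e. between protospacer positions 17/18), SaCas9
(NNGRRT, otherwise as SpCas9), Cpf1 (TTTV, 5' PAM, 23-nt guide, staggered
PAM-distal cut; the protospacer-strand nick after position 18 serves as
the reference cut for primers and microhomology). Cut offsets are data in
the profile, not code. Cpf1 guide length is genuinely ambiguous in
practice (20 vs 23); 23 was chosen as the default processed spacer length
and is configurable in the profile.

Warning flags: `HIGH_GC` / `LOW_GC` when protospacer GC% is strictly above
75 / below 25 (common-practice bounds for "very high/low"; both
configurable), and `TTTT` when the Pol III terminator appears in the
protospacer. Prefix filters (`G-`, `GG-`, `A-`) support U6/T7/U3
promoters. Restriction screening reports enzymes whose recognition site
(either strand) spans the predicted cut *and* occurs exactly once in the
50 bp context, so site loss reports editing; the shipped table holds 16
common 6–8-cutters and is user-replaceable.

## Off-target search

The contract: every site on either strand whose PAM matches the canonical
pattern — or, for SpCas9 with `alt_pams = TRUE` (default), NAG/NGA — and
whose protospacer is within Hamming distance `max_mm` (default 4,
range 0–5) of the guide. Sites containing N are never reported.

Two independent implementations share this contract:

* the fast path anchors on PAM occurrences (every reportable hit must
  carry one) and verifies the adjacent protospacer with vectorised
  per-position comparisons. PAM anchoring is *complete* — unlike an exact
  protospacer seed, it cannot miss a hit whose mismatches cluster in any
  particular window, which is why a seed-and-verify shortcut was rejected;
* `brute_force_offtargets()` extracts every window as a string, tests the
  PAM with an anchored IUPAC regex, and counts mismatches on character
  matrices, scanning the minus strand on the reverse-complemented contig.

The test suite asserts exact tibble equality between the two on 100 seeded
random (20-nt guide, 50 kb genome) pairs across all budgets 0–4, plus
planted-site fixtures for SaCas9 and Cpf1; these sizes are the package's
chosen verification scale and run in well under two minutes.

The on-target site appears in the output and is flagged when locatable
(submitted locus given, or a unique perfect canonical-PAM match); it is
excluded from specificity aggregation and the mismatch histogram, while
*duplicate* perfect sites deliberately count as off-targets — a guide with
two perfect genomic matches is not specific.

## Scores

**MIT hit score.** For mismatch positions \(P\) (1 = PAM-distal) with
weights \(W\):
\[ 100 \prod_{p\in P}(1-W_p)\cdot
   \frac{1}{((19-\bar d)/19)\cdot 4+1}\cdot\frac{1}{m^2}, \]
with \(m=|P|\), \(\bar d\) the mean pairwise distance between mismatch
positions; the distance and \(1/m^2\) terms apply only for \(m\ge 2\), and
the empty product gives 100. The shipped weight vector is the standard
published 20-vector. It contains zeros at tolerated PAM-distal positions,
so a single mismatch there scores exactly 100 — the "maximum iff perfect
match" law holds only for strictly positive weights, which is how the
uniform test tables are built; with the shipped vector the tests assert
the forward direction and range laws. For guides longer than 20 nt the
weight vector is aligned at the PAM-proximal end and extended with zeros
distally (distal mismatches are the well-tolerated ones).

**Specificity.** \(100\cdot 100/(100+\sum \text{hit scores})\): 100 with
no off-targets, strictly decreasing in every added hit,
permutation-invariant. Colour classes: green \(\ge 50\), red \(<30\),
yellow between (a score exactly at the red boundary is yellow). The
cutoffs are display conventions, configurable per run.

**CFD.** Product of per-(position, guide base, off base) penalties and a
PAM-class penalty, all in \([0,1]\). The package is table-driven; the
*shipped tables are synthetic*: penalty
\(= \min(0.98, \text{tol}\cdot(1-0.85\,(p-1)/19))\) with tol 1.0 for
transitions and 0.7 for transversions, floored at 0.02, plus PAM penalties
NGG 1, NAG 0.26, NGA 0.07. The 0.98 cap keeps a perfect canonical site the
unique CFD maximum. These reproduce the qualitative structure of
experimentally derived tables (PAM-proximal mismatches and non-canonical
PAMs hurt most) but not their exact values; `read_score_tables()` loads a
published table from the same three-file TSV dialect.

**Efficiency** is a registry of models. The default `pam_proximal_gc`
(`100·(0.2 + 0.6·GC₁₀/10 + 0.2·[terminal base is G])`, range 20–100) was
chosen because it is fully specified, needs no trained coefficients, and
encodes two robust sequence preferences. For 5'-PAM nucleases the
PAM-proximal ten bases are the *first* ten, handled by the auto-selected
`pam_proximal_gc_5p` variant. Trained linear one-hot models load from TSV
(`register_linear_model()`; intercept row `position 0, base *`; raw sums
clamp to \([0,100]\)). A guide whose model needs unavailable context gets
`NA` — reported as unavailable, never as 0.

**Out-of-frame score.** Microhomology pairs are identical substrings
(length ≥ 2) with the left copy ending at or before the cut and the right
copy starting at or after it, within 30 bp on each side (window truncated
at the context bounds; both constants configurable — 30 bp covers the
deletion sizes that dominate microhomology-mediated end joining).
Sub-patterns contained in a longer pattern with the same deletion length
are suppressed, and identical (sequence, deletion) pairs at shifted
offsets collapse to the leftmost. Each pattern weighs
\(100\cdot\mathrm{round}(e^{-\Delta/20},3)\cdot(2\,GC+AT)\); the score is
100 times the weight fraction with \(\Delta\bmod 3\neq 0\). No patterns at
all → `NA` (unavailable). The guide-level score uses the 50 bp plus-strand
context centred on the cut, so guides within 25 bp of the input edge have
no score; the search itself is reverse-complement symmetric (tested).

## Primers, oligos, pools

**Tm** is a nearest-neighbor enthalpy/entropy sum over dinucleotide steps
plus terminal initiation terms (unified parameter set, shipped as TSV;
dH kcal/mol, dS cal/(K·mol)):
\(T_m = 1000\,\Delta H/(\Delta S + R\ln(C/4)) - 273.15 +
16.6\log_{10}[\mathrm{Na}^+]\), defaults C = 50 nM, [Na⁺] = 50 mM.

**Primer picking** is a deliberately transparent deterministic greedy: all
candidates of length 18–27 in the flanks; discard homopolymer runs of four,
non-G/C 3' ends, and Tm outside target ± tolerance (default 60 ± 3 °C);
among pairs whose product covers the site within the length range, pick
the minimal summed |Tm − target|, ties broken by smaller product, then
leftmost coordinates — identical inputs give identical pairs. Defaults:
600–1000 bp products for Sanger validation, 200–280 bp for amplicon
sequencing (short enough for paired-end overlap). A locus where the narrow
amplicon window admits no compliant pair is reported as a skip with the
binding constraint, never an exception in batch mode; batch output always
conserves hits (pairs + skips). The CRISPResso manifest writes one
`name / amplicon_seq / guide_seq` row per amplicon, where `guide_seq` is
the protospacer the amplicon actually contains (the genomic site sequence
for off-target amplicons) — validated by substring check before writing.

**Cloning oligos**: forward = 4-base vector overhang + insert, reverse =
reverse overhang + reverse complement of the insert. Prefix rules:
`add_G_if_absent` (U6) prepends a G only when needed, avoiding a
mismatching base otherwise; `require_GG` (T7) prepends up to two Gs. The
`bbsI_U6` profile uses the standard ACCG/AAAC BbsI overhangs; the
`t7_invitro` overhangs are generic placeholders for a vector the user
names — both are ordinary registry entries.

**Pools**: each selected guide becomes
`fwd_barcode + left_adapter + insert + right_adapter + revcomp(rev_barcode)`.
The reverse barcode is stored as the reverse complement of the subpool's
reverse PCR primer so each subpool amplifies with its own primer pair. One
fixed, documented layout was preferred over a configurable one because it
makes decoding (`decode_pool()`) a total inverse — tested as a round trip
from sequence alone. Barcodes must be pairwise distinct and ≥ 6 bases;
mixed-length inserts within a subpool (G-prepended vs not) produce a
validation warning listing the offenders rather than silent padding.
Saturating selection keeps guides with specificity and efficiency at or
above the thresholds and no variant overlap, and reports the maximum gap
between adjacent retained cut sites as a coverage diagnostic.

## The synthetic-genome fixture generator

`generate_toy_genome()` emulates the one property the search contract
needs: a genome with a *known, exhaustive* list of sites within the
mismatch budget. Background is i.i.d. uniform A/C/G/T; each plan entry
plants the guide mutated at exactly `m` positions beside a concrete
canonical PAM on the requested strand, non-overlapping with a 5 bp margin.
After planting, the brute-force scanner verifies the genome contains
exactly the planted sites (checked with alternative PAMs on, so fixtures
are clean under default search settings); on collision the background is
regenerated, up to 20 times, then the generator fails loudly. The result
is a pure function of its arguments including the seed.

What this does *not* emulate: real genomes' repeat structure, GC skew,
homopolymers and segmental duplications, which produce far more near-miss
sites per guide than uniform sequence. Passing tests therefore demonstrate
the correctness of the search/score/design machinery, not off-target
burdens representative of any real organism. Default fixture sizes
(2–3 kb contigs for planted tests, 50 kb for oracle equivalence) are the
package's verification scale, chosen to exercise all code paths quickly.

## Degenerate inputs and numerical conventions

Coordinates are 0-based half-open everywhere internally; 1-based columns
in human-facing TSVs carry a `1` suffix (`start1`). Scores are computed at
full precision and rounded to integers only in the guide TSV. Guide tables
sort by specificity descending with ties broken by position then strand
(+ first), which together with fixed rounding makes reruns byte-identical;
`run.json` serialises every parameter so any output directory reproduces
from its config alone. Zero-guide inputs are not errors: the design run
writes a header-only table and returns status 3. Empty hit lists score
specificity 100. Off-target TSVs cap at the 1000 highest-CFD rows per
guide while `mmCounts` keeps full counts.

## Known limitations

- Input sequences are located in the genome by exact plus-strand match
  (Ns wildcarded); an input from the minus strand or spanning an assembly
  gap is treated as not locatable (guides still score, but on-target
  exclusion and validation primers are skipped).
- No bulge/indel off-targets, no population-variant-aware search.
- Shipped CFD tables are synthetic (above); efficiency defaults are a
  simple closed-form model, not a trained predictor.
- MIT hit scores for non-20-nt guides rely on the PAM-proximal alignment
  convention described above.
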