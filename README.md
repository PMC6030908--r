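# guidecraft

CRISPR guide selection, off-target scoring and assay design in R — for
anyone planning a genome-editing experiment who needs to pick guide RNAs
from a target sequence, judge how specific and active each one is likely to
be, and walk out with orderable reagents: cloning oligos, validation and
off-target PCR primers, amplicon-sequencing manifests, and barcoded oligo
pools for saturating-mutagenesis screens.

`guidecraft` supports SpCas9 (NGG), SaCas9 (NNGRRT) and Cpf1 (TTTV, 5' PAM)
and works on any genome you can supply as FASTA — it was built with
non-model organisms in mind, so nothing depends on hosted annotation.
Everything is a plain R function returning a tibble, so results pipe
straight into dplyr/ggplot2 workflows; a thin command-line wrapper
(`inst/cli/guidecraft`) covers shell use.

## The scores

For a guide *g* and a genomic site *s* differing at mismatch positions
*P* (numbered 1 = PAM-distal … 20 = PAM-proximal), with position weights
*W*:

- **MIT hit score** (per off-target, 0–100):
  `100 · Π_{p∈P}(1−W_p) · 1/(((19−d̄)/19)·4+1) · 1/m²`,
  where `m = |P|` and `d̄` is the mean pairwise distance between mismatch
  positions (the last two factors apply for `m ≥ 2`). Clustered,
  PAM-proximal mismatches are penalised least — such sites are unlikely to
  be cut.
- **Specificity score** (per guide, 0–100):
  `100·100 / (100 + Σ hits)` over all off-target hit scores, excluding the
  on-target site. 100 = no off-targets; guides are classed green (≥ 50),
  yellow, red (< 30).
- **CFD score** (per off-target, 0–1): product of per-position,
  per-substitution mismatch penalties times a PAM-class penalty
  (NGG canonical; NAG/NGA tolerated weakly). Exactly 1 only for a perfect
  match with canonical PAM. The shipped penalty tables are *synthetic*
  defaults (documented positional decay × transition/transversion factor);
  drop in experimentally derived tables via `read_score_tables()` to
  reproduce published values.
- **Out-of-frame score** (per guide, 0–100): from microhomology pairs
  flanking the cut, each weighted `100·round(e^(−Δ/20),3)·(2·GC+AT)` for
  deletion length Δ; the score is the weight fraction with `Δ mod 3 ≠ 0`,
  i.e. the predicted share of frame-shifting microhomology-mediated
  deletions.
- **Efficiency score** (per guide, 0–100): pluggable registry; the default
  `pam_proximal_gc` model is `100·(0.2 + 0.6·GC₁₀/10 + 0.2·[terminal G])`
  over the ten PAM-proximal protospacer bases. Linear one-hot coefficient
  models load from TSV via `register_linear_model()`.

Off-target search finds every site on either strand within a Hamming
distance of 4 (configurable 0–5) of the guide next to a canonical or
alternative PAM, via a PAM-anchored vectorised scan; a brute-force
window-by-window oracle (`brute_force_offtargets()`) implements the same
contract independently and backs every search result in the test suite.

## Worked example

Plant a guide and two decoy off-targets (2 and 4 mismatches) in a synthetic
two-contig genome, then design against it:

```r
library(guidecraft)

fx <- generate_toy_genome("GACGTAGCTAGCTAGGATCC",
        plan = data.frame(mismatches = c(0, 2, 4), strand = c("+", "-", "+")),
        n_contigs = 2, contig_len = 3000, seed = 7)
on <- fx$sites[fx$sites$mismatches == 0, ]
input <- substr(unclass(fx$genome)[[on$contig]], on$start - 99, on$start + 120)

design <- design_guides(input, fx$genome)
glance(design)
#> # A tibble: 1 × 7
#>   n_guides n_green n_yellow n_red n_offtargets median_spec median_eff
#>      <int>   <int>    <int> <int>        <int>       <dbl>      <dbl>
#> 1       25      25        0     0            2         100         50
```

25 candidate guides were found in the 220 bp input; all are green
(specificity ≥ 50) because this small random genome offers few similar
sites, and the two planted decoys belong to the planted guide. Per guide:

```r
head(tidy(design)[, c("guide_id", "protospacer", "strand", "spec_score",
                      "eff_score", "oof_score", "color")], 3)
#>   guide_id          protospacer strand spec_score eff_score oof_score color
#> 1    14rev TCTGAGATACCAGCGTGACC      -        100        62        NA green
#> 2    15rev GTCTGAGATACCAGCGTGAC      -        100        62        NA green
#> 3   25forw AGCTTGGGTCCCGGTCACGC      +        100        68        NA green
```

(`guide_id` encodes the PAM position and strand; `oof_score` is NA for
guides whose cut sits too close to the input edge for a 50 bp context.)
The planted guide's off-target list shows the decoys with their mismatch
counts and scores:

```r
find_offtargets("GACGTAGCTAGCTAGGATCC", fx$genome)[,
  c("contig", "start", "strand", "mismatches", "mit_hit", "cfd", "is_on_target")]
#>   contig start strand mismatches     mit_hit        cfd is_on_target
#> 1     c1   591      +          0 100.0000000 1.00000000         TRUE
#> 2     c1  2256      -          2   1.4253132 0.19659600        FALSE
#> 3     c1   486      +          4   0.1195104 0.03349283        FALSE
```

The MIT hit scores of the two decoys sum to 1.54, giving the planted guide
a specificity of `100·100/101.54 ≈ 98.5`. From here,
`design_flanking_primers()` / `run_offtarget_primers()` produce validation
and amplicon-sequencing primers with nearest-neighbor Tm plus a CRISPResso
manifest, `cloning_oligos()` emits annealing oligo pairs (U6/BbsI or T7
rules), and `run_satmut()` + `assemble_pool()` build a barcoded
saturating-mutagenesis oligo pool that `decode_pool()` can invert from
sequence alone.

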