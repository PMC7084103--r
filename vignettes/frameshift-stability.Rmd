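---
title: "Methods: quantifying frameshift robustness of protein properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying frameshift robustness of protein properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

A ±1 shift of the translational reading frame replaces essentially every
residue of a protein, and the resulting sequence typically shares only a few
percent of positions with the wild type. Yet amino acids encoded by
overlapping codons are not physicochemically independent: the architecture
of the standard genetic code makes certain properties — hydrophobicity above
all — surprisingly robust to frameshifting. `frameshiftr` implements the
machinery to quantify this robustness at two levels:

1. **the genetic code itself** — how well a property scale survives the
   codon → shifted-codon map, and
2. **whole proteomes** — how similar windowed property *profiles* of
   wild-type proteins are to those of their +1/−1 frameshifted variants.

## Frameshift pairs and the code-level statistic

Every codon plus one flanking base defines a frameshift context: for a +1
shift the new codon reads bases 2–3 of the original plus the downstream
base; for −1, the upstream base plus bases 1–2. Of the 64 × 4 = 256
contexts, 24 involve a stop codon on one side or the other and are
excluded, leaving **232 amino-acid pairs** in either direction
(`enumerate_frameshift_pairs()`). Contexts are enumerated uniformly — each
counted once — which is what the 64 × 4 accounting implies; a flanking-base
weight vector is accepted for sensitivity analyses but defaults to uniform.

For a scale $s$ (one real value per amino acid), the code-level statistic
is the Pearson correlation

$$R(s) = \mathrm{cor}\big(s(a_i),\, s(b_i)\big), \qquad i = 1, \dots, 232$$

over the pair multiset $(a_i, b_i)$ (`ugc_correlation()`). $R$ is invariant
under positive affine maps of $s$ and unchanged by full inversion, so
hydrophobicity and hydrophilicity readings of the same scale score
identically.

## The random-scale null

Significance is judged against scales whose 20 values are i.i.d. standard
normal (`sample_null()`). Normal draws are the natural rotation-invariant
choice, and since Pearson R is location/scale-free any i.i.d. continuous
choice with finite variance behaves the same. The null distribution of $R$
is fitted with a Gaussian; p-values default to the **upper tail** because
the scientific claim is directional (high $R$ = stability) and inversion
cannot flip $R$'s sign. A two-sided option and an empirical tail with
add-one smoothing, $p = (k+1)/(n+1)$, are available.

Two numerical caveats worth knowing:

* The null is *approximately* centered at zero. At very large draw counts
  a small structural bias becomes resolvable (about $-1.2 \times 10^{-3}$
  for the 232-pair set; Pearson R over a finite structured multiset is not
  exactly mean-zero). The calibration checks in the test suite therefore
  run at $10^4$ draws, where the bias is well below the Monte-Carlo
  resolution; at full production size ($10^6$ draws at the code level,
  $10^5$ at the proteome level) p-values in the relevant tail are
  unaffected to the precision reported.
* The Gaussian fit is accurate through the body and the moderate tail
  (Gaussian and empirical p agree within a few percent for $p \ge 10^{-3}$);
  far-tail p-values are smooth extrapolations, which is exactly what a
  Gaussian background is for.

Category enrichment among significant scales uses the two-sided Fisher
exact test on the 2×2 table (in/out of category × below/above the p
cutoff), via `category_enrichment()`. "Enriched" means odds ratio above 1
*and* Fisher p below the cutoff; categories can also be significantly
depleted, which is not enrichment.

### Randomized-code controls

`randomize_code()` / `code_randomization_correlations()` invert the
question: fix the scale, randomize the code. Two modes are implemented:

* `block_preserving` — synonymous-codon blocks stay intact, the 20 amino
  acids are permuted across the 20 sense blocks, stops fixed. This is the
  conservative control; its $R$ distribution for a fixed scale is
  statistically indistinguishable from the random-scale null (two-sample
  KS distance ≈ 0.01 at $10^4$ codes), so either background gives the
  same p-values.
* `unconstrained` — the 61 sense codons are reassigned independently,
  every amino acid keeping at least one codon, stops fixed. Published
  descriptions of "less conservative" randomizations are not detailed
  enough to reproduce a specific scheme, so this mode is our own
  reasonable reading and is documented as such.

Stops being fixed in both modes is what keeps the excluded-context set
constant (always the same 24), which both matches the pair-count
conservation property and enables a vectorized implementation.

## Optimally frameshift-stable scales

`optimize_scale()` maximizes $R(s)$ over all of $\mathbb{R}^{20}$ by
multi-start local optimization: BFGS with an analytic gradient, starts
drawn standard normal, and a polishing second BFGS run from each found
point (the objective is extremely flat along its optimal manifold, and the
restart pulls near-converged solutions tightly onto it). For the standard
code and +1 pairs the optimum is $R \approx 0.558$, and nearly every start
reaches it; the best experimentally derived scales reach about 0.4.
Optimization defaults to the +1 direction; the −1 pair set can be passed
instead.

Because $R$ is affine-invariant, each solution is reported normalized
(zero mean, unit Euclidean norm) rather than constrained during
optimization. The solution set is a continuum: `collect_optimal_set()`
retains all solutions within 0.01 of the best $R$ and, by default, closes
the set under sign inversion (if $s$ is optimal so is $-s$), which centers
it exactly at the origin. PCA of the set (`fit_pca()`) shows the first two
components carry essentially all variance — the normalized optimal scales
lie on a circle in the (PC1, PC2) plane. `project_scale()` places any
scale into this space after normalization; optimal-set members land on the
unit circle, frameshift-stable experimental scales cluster near it, and
inversion maps a projection to its antipode (exactly, because the
symmetrized set has zero mean).

## Sequence-level profiles

Frameshifted protein variants are generated from the wild-type coding
sequence by removing its first **four** bases (+1 shift) or first **two**
bases (−1 shift) and translating in the new frame
(`frameshift_translate()`). Internal stop codons are read through and
marked with the sentinel `*`; the terminal stop is stripped.

`build_profile()` converts a sequence into a numerical profile: each
residue is replaced by its scale value and smoothed with a centered
21-residue moving average. Two conventions matter:

* **Edges**: windows truncate at the termini rather than dropping edge
  positions, so the profile length equals the sequence length and profiles
  of different frames stay index-aligned. A 21-residue window is the
  classic choice for hydrophobicity-style profiles — long enough to smooth
  residue-level noise, short enough to resolve structural elements such as
  transmembrane helices.
* **Stop exclusion**: `*` positions contribute nothing to any window they
  fall in (the effective window shrinks by their number) and carry no
  profile value themselves. Disorder profiles are the exception: they are
  supplied externally per residue and no masking is applied to them.

**Alignment registration.** Both frameshift variants drop the bases
spanning the first wild-type codon, so shifted residue $i$ is compared
with wild-type residue $i+1$ (`frameshift_offset()`). This registration
maximizes per-position nucleotide overlap. The exact registration used in
prior work is not stated at this level of detail; the convention is a
documented default and every comparison function accepts an explicit
`offset`.

`profile_correlation()` then gives the per-protein stability: Pearson R
over aligned, mutually unmasked positions. mRNA purine-density profiles
(`purine_density_profile()`) are computed **per codon** (window 21 codons
= 63 nt) so they align one-to-one with protein profiles; per-codon is the
only convention that puts both on a shared position axis, and it makes the
mRNA-side profile bit-identical across wt/+1/−1 comparisons of the same
gene. Charge uses an integer convention (D, E = −1; K, R = +1; H = 0 —
half-protonated histidine is a pH-dependent refinement users can supply as
a custom scale).

## Proteome scans

`scan_proteome()` applies the profile comparison to every coding sequence
and reports per-protein R values, the median, and per-reason skip counts
(proteins shorter than 21 residues, insufficient aligned overlap, or
undefined correlations are skipped, never imputed — silent imputation
would bias the medians). Windowed profile values are linear in the 20
scale values, so the scan precomputes per-protein weight matrices once and
evaluates any number of scales by matrix products; `proteome_scale_pvalues()`
exploits this to score a whole library *and* a random-scale proteome null
(median R of random scales over the same proteome, Gaussian-fitted) in
seconds. Ranking ties are broken lexicographically by id so exports are
deterministic.

## The synthetic-data generator

`generate_proteome()` emulates just enough of a real proteome to exercise
every stage: gene count, a log-normal protein length distribution with
median 375 residues (a typical proteome-like scale), optional GC-content
targeting by exponential tilting of the codon-usage table, and uniform
codon usage by default with no internal stops. `generate_scale_library()`
emulates a property-scale library's cluster structure: categories of
equicorrelated scales (within-category correlation ρ = 0.5 by default)
plus a planted frameshift-stable category built as the optimized scale
plus Gaussian noise (sd 0.1 against a value RMS of $1/\sqrt{20} \approx
0.22$), placing its code-level R between the optimum and zero.
`generate_disorder_profiles()` provides bounded, autocorrelated stand-ins
for external disorder predictions.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: organism-specific codon usage and amino-acid
composition, length–composition covariation, homology structure, and any
sequence-dependence of disorder. Two visible consequences: the net-charge
relation between wild-type and +1 variants is composition-dependent (real
human data show charge anticorrelation; a uniform-usage synthetic proteome
need not), and synthetic disorder profiles of wild-type and shifted
sequences are independent draws, so their expected correlation is zero.
Real-proteome headline numbers (median R ≈ 0.55/0.45 for the human
consensus hydrophobicity scale, ortholog stability R = 0.74, and the like)
require UniProt/ENA/AAindex downloads; `analysis/06_real_proteome_template.R`
runs the identical pipeline on such inputs when the user supplies them.

## Problem sizes and reproducibility

All randomness is seeded: generators take explicit seeds, and
`sample_null()`, `randomize_code()` and the optimizers accept one. The
bundled analysis scripts and test suite run at desk scale by choice:
$10^4$–$10^5$ random scales for code-level nulls, 200 random scales for
proteome nulls, a 500-gene proteome, 100-scale libraries, 100 optimizer
starts, $10^4$ randomized codes. Production-scale defaults ($10^6$ and
$10^5$ null draws) are documented on the respective functions and change
only tail resolution, not the statistics' definitions.

## Known limitations

* Only the standard nuclear genetic code ships built-in (custom 64-codon
  tables can be constructed and are fully supported downstream).
* Positional identity and profile alignment are gap-free by design; gapped
  alignment similarity is a different question answered by substitution
  matrices, not by this package.
* The unconstrained code randomization is one reading of "abolishing the
  block structure", not a reproduction of a specific published scheme.
* Computing intrinsic disorder is out of scope; the package consumes
  per-residue values produced elsewhere.
* GO-term enrichment of stable proteins is out of scope; the package
  exports ranked id lists for external tools.
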