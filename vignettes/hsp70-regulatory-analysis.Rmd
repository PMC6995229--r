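---
title: "Methods: regulatory-region differentiation and basal hsp70 expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulatory-region differentiation and basal hsp70 expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hspreg)
```

`hspreg` asks one biological question in three statistical layers: do the
cold-climate (O~ST~) and warm-climate (O~3+4+7~) arrangements of the
*D. subobscura* O chromosome differ in (i) the *cis*-regulatory architecture
of their two *hsp70* copies, (ii) the sequence composition of those
regulatory regions, and (iii) basal *hsp70* mRNA output? This vignette is
the package's own account of the methods, their assumptions, and the design
choices that were genuinely open.

## 1. Element annotation

**HSE model.** A heat-shock element is modelled as a maximal run of
contiguous 5-bp units whose central triplet alternates `GAA`/`TTC`, either
phase first, with `min_units = 3` by default — the minimal HSF trimer
footprint. Only positions 2–4 of each pentamer are constrained; positions 1
and 5 are wildcards, because in these promoters polymorphisms concentrate in
the first and fifth pentamer positions, which HSF binding constrains least.
Runs are maximal (not extendable by a valid unit on either side) and
reported greedily left-to-right without overlap. An exploratory
`max_core_mismatch` budget exists but defaults to 0: the unit counts of
interest (3/4/4/3 across the four promoter HSEs) are perfectly conserved at
exact matching, and loosening the core would only blur the maximal-run
boundaries. There is no explicit rule for how large a spacer separates two
HSEs rather than splitting one: the maximal-run definition makes adjacent
elements distinct whenever a single non-matching unit interrupts the
alternation, which reproduces the observed four-element promoter layout.

**Fixed motifs.** GAGA sites (`GAGAG`/`CTCTC`), AREs (`ATTTA`, i.e. mRNA
`AUUUA` on the DNA sense strand — inputs are genomic) and the TATA box
(IUPAC `TATAWAWR`; a consensus stand-in for promoter-prediction software,
used for diagrams only) are literal scans. Overlapping hits are all
reported; collapsing is left to consumers because it loses information
irreversibly.

**Coordinates.** Internally scans run on the de-gapped sequence, 1-based
inclusive in every user-facing table (BED export shifts to 0-based
half-open). TSS-relative coordinates skip zero (−1 abuts +1); the mapping
`tss_relative()`/`tss_absolute()` is a bijection, which the suite checks.
The TSS column is a user input: alignments do not carry it.

**In-silico PCR** requires exact primer matches (the printed primers were
designed against exact targets); degenerate template codes match via IUPAC
expansion. Zero products or more than one distinct product are errors, not
silent choices, because a qPCR assay is only interpretable for a unique
amplicon.

## 2. Differentiation statistics

All statistics operate after **complete deletion**: restriction to the
compared sequences, then removal of every column holding a gap or `N` in a
retained sequence. Columns gapped only in excluded sequences survive, which
maximises analysed sites per comparison; passing all ids gives the stricter
whole-alignment mode. Site classes (monomorphic / fixed difference / shared
/ exclusive polymorphism) partition the analysed columns by
within-population variability only, so multi-allelic columns need no special
rule.

D~xy~ is the mean cross-population Hamming distance per analysed site.
Hudson's F~st~ = 1 − H~w~/H~b~ uses the **unweighted** mean of the two
within-population diversities by default: the study design is balanced (6
lines per arrangement), where weighting is moot; a pair-count-weighted
option exists for unbalanced use. S~nn~ counts, for each sequence, the
fraction of its minimal-distance neighbours belonging to its own population,
all ties included in the denominator — the tie rule matters in short
regulatory regions where identical haplotypes are common (an all-identical
alignment returns the own-population share, not an error). Significance
comes from uniformly random label permutations preserving group sizes, with
the +1/+1 rule `p = (#{S*ₙₙ ≥ Sₙₙ} + 1)/(B + 1)`, so `p > 0` always and
`B = 1000` replicates yield the customary resolution of 0.001. Ties with
the observed statistic count toward the tail (conservative). With few
sequences the permutation space is small — 6 distinct assignments for 2 + 2
— and p-values are correspondingly coarse; the suite's calibration checks
therefore use 6 + 6 samples of long sequences, where distance ties are rare
and the null p is uniform to Kolmogorov–Smirnov precision.

**Combined rows.** A per-region combined row joins the two gene copies.
Two schemes are defensible and both are implemented: `"concatenate"`
(default) joins each line's A and B sequences end-to-end before gap
deletion, keeping 6 haplotypes per arrangement and matching the
line-as-replicate logic of the study design; `"pool"` treats A and B as
separate haplotypes (12 per arrangement). On concatenated data every count
column is exactly the sum of the per-copy rows, which published combined
counts need not equal (they exceed per-copy sums in the real data for
reasons the source tables do not resolve); the package documents the scheme
it used rather than guessing the other tool's.

## 3. Expression analysis

Ct technical replicates are averaged per gene within a biological
replicate; ΔC~T~ = mean(target) − mean(reference) and relative expression
is 2^−ΔC~T~ (comparative C~T~ method). The ANOVA response is **2^−ΔC~T~**,
not ΔC~T~ — the scale on which the biological statements ("equal mRNA
amounts") are made — and that choice is exactly why a permutation check
matters: normal noise in cycles becomes log-normal in expression, so the
parametric F assumptions are approximations.

The model is `y = μ + A + L(A) + S + A:S + ε` with line random and nested
in arrangement. Sums of squares are Type III under sum-to-zero contrasts,
computed as RSS differences between the full and single-term-deleted
design matrices; on balanced data this coincides with the sequential
decomposition (asserted to 1e-10 against a closed-form oracle). The design
it targets — 67 of 72 planned observations — is mildly unbalanced, where SS
types differ in the third significant figure; Type III is the convention of
the commercial packages this analysis style comes from. F denominators
follow the mixed-model expectations: arrangement over the line mean square
(10 df), everything else over error. Degenerate inputs (zero response
variance, zero error MS, a single arrangement, < 2 lines per arrangement)
are errors, not NaNs.

**Four-stage restricted permutation test.** Each term's F is recalibrated
under its own exchangeability structure: (1) line — observations permuted
among lines *within* arrangement; (2) arrangement — whole lines, with all
their observations, reassigned to arrangements preserving the 6/6 split
(the line, not the fly, is the replicate for the arrangement contrast);
(3) sex — labels exchanged within line by default, preserving the nuisance
line structure (a global variant exists since the exchange unit is a
genuine modelling choice); (4) interaction — observations shuffled across
the four arrangement × sex cells (a Freedman–Lane residual-permutation
variant is available). P-values use the same +1/+1 tail rule; 9999
allocations plus the observed value give 10 000 F values per term and a
minimum attainable p of 10⁻⁴. One sub-seed is drawn per stage from the
user's seed, so stages are independently reproducible. Implementation
note: stages with a fixed design are evaluated as batched orthogonal
projections, and stage 2 collapses to weighted line × sex cell means
(every design column is cell-constant), with caching over the at most
`choose(12, 6) = 924` distinct assignments — this keeps 9999 allocations
in a few seconds without approximating anything.

The reference-gene check is a one-way ANOVA on raw Ct across the four
sex × arrangement groups plus Levene's test, reporting both the
median-centred (Brown–Forsythe) and mean-centred variants via `car`.

## 4. What the synthetic data do and do not emulate

`simulate_haplotypes()` plants exact numbers of fixed differences,
exclusive and shared polymorphisms, and gap columns on a motif-free uniform
background (backgrounds are rejection-sampled to exclude spontaneous
alternating GAA/TTC runs, `GAGAG`/`CTCTC`/`ATTTA` literals and TATA
consensus matches, so planted truth is unambiguous).
`simulate_promoter()` synthesises elements from their definitions — the
default layout is the observed promoter architecture: HSEs of 3/4/4/3
units, three GAGA sites, one TATA box upstream of a TSS at +291 of a
550-bp region — and re-scans the assembly, resampling until recovery
equals truth so splice junctions cannot create or destroy elements.
`simulate_ct_data()` simulates the nested model on the ΔC~T~ scale (line
effects normal with `sd_line = 0.15`, residuals `sd_error = 0.3`,
technical noise `sd_tech = 0.1` cycles — values in the range qPCR
replication typically shows), emits raw technical-replicate Ct rows for
both genes, and deletes `n_missing = 5` biological replicates completely
at random to reproduce the 67-of-72 analysed design; a
`effect_scale = "rel_expr"` mode generates normal, homoscedastic
expression directly for tests that need the parametric assumptions to hold
exactly. `grand_mean_dct = 12.5` puts relative expression at the order
10⁻⁴, the magnitude basal *hsp70*/*rp49* contrasts show.

These generators emulate the *statistical* structure the methods assume —
independent lines, a single shared background per alignment, MCAR missing
replicates. They do not emulate linkage or recombination along real
haplotypes, gene conversion between paralogs, indel mutation processes,
sequencing error, or amplification-efficiency differences. Green tests
therefore demonstrate correctness of the statistics and scanners, and
calibration of the permutation procedures, under the model's assumptions —
not robustness to every feature of real fly data.

## 5. Calibration results and problem sizes

The suite verifies, among others: exact equality of D~xy~/F~st~/S~nn~ with
brute-force loop oracles over 200 random small alignments (n ≤ 6, L ≤ 30);
exact site-class recovery over 100 seeded generator runs; planted-motif
recovery with precision = recall = 1 over 100 promoters; empirical size of
the four-stage permutation ANOVA within the binomial 95% CI of α = 0.05
over 500 null datasets of the study size (999 allocations each); and power
> 0.9 for a 1-cycle sex effect at `sd_error = 0.3` over 200 datasets.
These sizes keep each property estimable with useful precision while the
whole suite runs in minutes; `scripts/acceptance.R` recomputes the same
quantities at slightly smaller Monte-Carlo sizes under a user-supplied
seed.

## 6. Known limitations

* The HSE spacer question (when do two nearby runs merge?) is resolved by
  the maximal-run rule, not by HSF binding energetics; promoters with
  unusual spacing may be segmented differently than an expert would draw
  them.
* S~nn~ p-values are conservative under heavy distance ties (short or
  near-monomorphic regions).
* The ANOVA treats line as random but estimates no variance components;
  REML-based mixed modelling is out of scope.
* `in_silico_pcr` does not model mismatched or degenerate-primer annealing.
* Efficiency-corrected ΔΔC~T~ (Pfaffl-style) quantification is out of
  scope; primer efficiencies near 100% are assumed.
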