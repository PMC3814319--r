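---
title: "Methods: population immunogenetics of KIR and HLA class I co-evolution"
author: "kirhla"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population immunogenetics of KIR and HLA class I co-evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirhla)
```

## The scientific problem

Killer-cell immunoglobulin-like receptors (KIR, chromosome 19) and their HLA
class I ligands (chromosome 6) form one of the most polymorphic
receptor-ligand systems in the human genome. KIR haplotypes vary in gene
content as well as allele sequence; HLA class I alleles partition into four
mutually exclusive KIR-relevant epitopes (A3/11, Bw4, C1, C2). Population
cohorts of mother-child pairs allow allele-level haplotypes of both loci to be
deduced by segregation, and the resulting frequency spectra carry the
signature of natural selection: balancing selection flattens spectra
(Tajima's D > 0, negative normalized Ewens-Watterson deviates), directional
selection sharpens them.

`kirhla` re-implements this analysis chain as a tested pipeline: pedigree
phasing, epitope and receptor-ligand pair accounting, motif-restricted
selection statistics with simulation-based significance, haplotype-structure
diagnostics, and an iterative Mantel-test scan for co-evolving receptor and
ligand residue groups. Because the cohorts such studies rest on are typically
not deposited, the package also contains a first-class synthetic-cohort
generator so that every stage can be validated end-to-end against known
truth.

## Data model

A **locus model** fixes gene order, framework status (genes present on every
haplotype), per-gene alignment lengths, and leader-peptide lengths. The
shipped KIR model has seven gene slots (KIR3DL3, KIR2DL2, KIR2DL3, KIR2DL1 |
KIR2DL4, KIR3DL1, KIR3DL2; the bar marks the centromeric/telomeric boundary)
with KIR2DL2 and KIR2DL3 mutually exclusive, reproducing their behaviour as
alternatives at one locus. Gene absence is the reserved allele `ABSENT` and
participates everywhere as an ordinary allele state; in gapped concatenated
alignments an absent gene is a run of gaps.

Residue numbering is mature-protein, 1-based; nucleotide numbering starts at
ATG = 1. Proteins are derived deterministically from the aligned CDS by codon
translation followed by removal of the configured leader (24 residues for HLA
class I, 21 for KIR). An *allele* is a unique coding sequence; an *allotype*
is a unique protein (synonymous digits collapse: `KIR3DL1*01501` and
`*01502` are one allotype, `KIR3DL1*015`).

## Phasing

Mother-child pairs are phased by segregation: all splits of the child's
genotype into two gene-wise consistent haplotypes are enumerated, and a split
survives if at least one side could have been transmitted by the mother
(gene-wise containment in her genotype). A child with exactly one surviving
split is segregation-resolved; the mother's second haplotype follows as the
gene-wise complement of the transmitted one. Ambiguous children and unrelated
individuals fall through to a standard multi-locus haplotype-frequency EM in
which the segregation-deduced haplotype counts enter every M-step as
pseudo-counts (weight configurable, default 1, i.e. observed counts at face
value). A coalescent-informed Bayesian phaser (PHASE-style) is the traditional
tool for unrelated samples; this package uses the plain EM because at the
heterozygosity levels of such cohorts phase ambiguity is rare, recovery of
known truth is what the validation suite measures, and the EM is transparent
and fast. Maximum-posterior assignment breaks ties to the
lexicographically smallest haplotype pair, so output is deterministic.

The haplotype census counts two haplotypes per "child" (every individual who
is nobody's mother): 131 children give 2N = 262. Adding each mother's
non-transmitted haplotype gives the extended set (2N = 366 with 104 pairs).

## Epitopes and functional pairs

Epitope assignment reads the protein sequence: Bw4 requires the residue 77-83
window to match a configured pattern with arginine 83 mandatory; HLA-C
carries C1 with asparagine 80 and C2 with lysine 80 (config-overridable,
including the B*46:01/B*73:01 C1 exceptions); A3/11 is assigned by allele
name because the KIR3DL2-binding determinant of HLA-A is unknown. The
interaction table is data, not code: gene-level rules (KIR2DL2/3 with C1,
KIR2DL1 and KIR2DS1 with C2, KIR3DL1 with Bw4, KIR3DL2 with A3/11) plus
explicit allotype exceptions (KIR2DL2 cross-reacts with C*04:01 among
others) and expression-null lists (KIR3DL1*004 by default). Pair counting is
over the set of distinct (KIR allotype, HLA allotype) pairs both carried and
expressed — phase, homozygous duplication, and slot order never change a
count, and adding a rule can only increase it.

## Selection statistics

**Tajima's D** is computed from the standard 1989 constants with
D = (pi − S/a1) / sqrt(e1 S + e2 S (S − 1)). On gapped alignments, sites
containing any gap are excluded from S while pi uses pairwise deletion. The
undefined case S = 0 is flagged rather than raised. Significance is
empirical: the observed D is ranked in a coalescent null distribution, two
tails, add-one correction, capped at 1.

The **coalescent simulator** is a Hudson-style neutral coalescent with
piecewise-constant population size and infinite-sites mutation. Time is in
units of 2N generations; k lineages coalesce at rate k(k−1)/2 scaled by the
inverse relative size of the current epoch, and mutations are Poisson with
rate theta/2 per unit branch length, so E[pi] = theta for n = 2 and
E[S] = theta · a1. Demographic models are config entries; the shipped set
(constant; 10x ancient expansion at 0.5 coalescent units; bottleneck-
expansion; repeated bottlenecks) covers the standard alternatives used when
asking whether a selection signal survives demographic explanations, and no
validation check depends on their exact parameters.

**Ewens-Watterson / Slatkin.** F = sum of squared sample frequencies. The
null conditional on (k, n) is sampled from the Ewens sampling formula by a
Chinese-restaurant construction with theta solved so E[k] = k, rejecting
draws with the wrong realised k; this is exact (the conditional distribution
is theta-free) and is verified in the tests against exhaustive partition
enumeration for n ≤ 8, k ≤ 4. The reported p is Pr(F_sim ≤ F_obs) with
add-one correction, and the normalized deviate is
F_nd = (F_obs − mean F_sim)/sd F_sim, the PyPop convention: negative F_nd
means a flatter-than-neutral spectrum,
balancing selection. Monomorphic motifs (k = 1) are flagged "(-)" rather
than tested. Default n_sim is 10,000.

**Motif restriction.** Binding-site configurations list named residue sets
per gene (peptide B/F pockets, TCR, KIR, LILR, CD8 contacts); the derived
*exclusive* sets (residues in exactly one named site) are what the
motif-restricted statistics use, so overlapping motifs do not share signal.
`motif_project()` collapses allotypes by the identity of their residue-set
substring and sums counts; it is idempotent by construction.

## Diversity structure

Nei's unbiased heterozygosity is n/(n−1)(1 − sum p²); `he_ssf()` is the
plug-in 1 − SSF, identically 1 − F. Mismatch distributions use p-distances
with pairwise deletion; pairs with no comparable sites are excluded with a
warning. Sliding-window MAF profiles average per-marker minor allele
frequencies over fully contained windows (default 15 markers, step 1), with
gene-presence pseudo-markers entering the series as biallelic markers next to
sequence sites; the empirical percentile of a window mean is its rank in a
user-supplied reference distribution.

Haplotype networks use Hamming distances on the gapped concatenation, where
gap-versus-base counts as a difference (gene absence is a mutational step)
and gap-versus-gap as a match. Primary links form a minimum spanning tree
built by Prim's algorithm with deterministic tie-breaking in node label
order; alternative links are non-tree pairs whose distance exactly equals the
largest primary-link weight on the tree path between them (a zero-tolerance
rule). The parsimony
probability attached to nodes is derived from a Bayes comparison of "j
mutations at j distinct sites" against the leading non-parsimonious
alternative (one coincident, non-reverting pair among j + 1 uniformly placed
mutations on m sites with b states), which gives the closed form
P = 1 / (1 + j(j+1)(b−2) / (2m(b−1))): 1 at j = 0, monotone decreasing in j,
increasing in m.

## The co-evolution scan

Individuals are represented by their two phased residue strings concatenated
in canonical (lexicographic) order — this makes every distance independent of
how the phase happened to be stored — and compared by p-distance with
pairwise deletion. The Mantel statistic is z = sum over unordered pairs of
A_ij B_ij with the null obtained by jointly permuting rows and columns of one
matrix; p is one-tailed upper with add-one correction (so p is never zero
and the smallest attainable value at 10,000 permutations is about 0.0001).

The scan proceeds in stages: (1) every polymorphic HLA residue
against each whole-gene KIR matrix; (2) significant HLA residues against
single KIR residues; (3) significant residues merged into LD groups at
r² ≥ 1 by default ("perfect LD"; relaxable); (4) group-versus-group tests,
iterated with fresh permutations until the ranking is stable (capped at 10
rounds). Two design points deserve mention. First, the gate between stages
uses raw alpha; Bonferroni-adjusted
p-values are reported alongside, and stage-1 results are retained in the
output for null-calibration checks. Second, the output ranking uses the
permutation-standardized deviate (z − mean z_perm)/sd z_perm rather than raw
z: the raw statistic scales with the magnitude of the distance matrices being
compared, so an uncorrelated pair of large-distance matrices can exceed a
genuinely coupled pair; the standardized deviate is the scale-free form of
the same statistic and makes rankings comparable across matrix pairs. LD
between sites uses multiallelic r² and D′ as allele-frequency-weighted
averages of per-allele-pair normalised disequilibria.

## The synthetic-cohort generator

The generator emulates the study design the analysis assumes: haplotype pools
per locus with configurable frequency spectra, mothers drawn as two
independent pool haplotypes, children receiving one maternal haplotype
(optionally crossed over at the centromeric/telomeric boundary) and one
paternal haplotype drawn fresh from the pool (fathers are latent, as only
mothers and children are sampled), and the two loci segregating
independently. Spectrum modes: `balanced` (symmetric Dirichlet, concentration
100), `directional` (one class at 0.86-0.95), and `neutral_coalescent`
(an Ewens-conditional configuration — the coalescent infinite-alleles
spectrum — rather than a literal tree simulation).

Planted coupling biases the joint sampling of the two loci by rejection at
the individual level: the focal class on each side is the most frequent
residue-set state in the pool, an individual "matches" when its focal-class
dosages (0/1/2) agree on both sides, and non-matching individuals are
rejected with probability equal to the coupling strength. Strength 0
reproduces independence exactly; marginal frequencies are essentially
preserved because pools are untouched. `coupling_study_config()` constructs
the canonical validation design: HLA-B segregating two classes at residues
77/83 (perfect LD, independent of a third HLA-B residue) coupled to KIR3DL1
classes at residues 31/44/86, with all other residues segregating
independently — so the scan's correct answer is a unique, known group pair.

What the generator does **not** emulate: allele-frequency evolution under
explicit selection (spectra are imposed, not evolved), within-gene
recombination, genotyping error, and copy-number expansions beyond simple
absence. Passing tests therefore demonstrate correctness of the statistical
machinery under the stated sampling model, not robustness to artefacts of
real genotyping.

## Problem sizes and numerical choices

The validation suite runs at the sizes the statistics need, chosen as a
scientist would for a desk-scale calibration: coalescent closed-form checks
at 20,000 replicates (3 Monte-Carlo SEs); Tajima calibration at 1,000
neutral replicates of n = 50, theta = 5; Ewens-conditional exactness by full
enumeration for n ≤ 8, k ≤ 4 plus 1,000 null spectra for the F_nd centring;
Mantel type-I error over 500 independent-matrix trials at 1,000 permutations;
phasing truth-recovery on a cohort of 104 mother-child pairs plus 27
unrelated individuals drawn from 20-haplotype pools at heterozygosity above
0.9; scan power over replicate cohorts of 200 individuals at coupling
strength 0.5. The acceptance script (`scripts/acceptance.R`) recomputes the
same quantities from scratch under a caller-supplied seed.

Tolerances and tie-breaks that matter: EM stops when the log-likelihood gain
drops below 1e-8 (cap 500 iterations) and is asserted non-decreasing;
"perfect LD" allows 1e-9 slack on r² = 1; MST and maximum-posterior ties
break by label order; permutation p-values always carry the add-one
correction so p = 0 is impossible; undefined Tajima replicates (S = 0) are
dropped with a logged count rather than imputed.

## Known limitations

- Segregation phasing treats haplotypes as transmitted intact; a
  recombinant transmission (supported by the generator) shows up as an
  EM-phased or, rarely, Mendelian-inconsistent pair, not as a detected
  crossover.
- The EM phaser is not a substitute for coalescent-informed phasing at low
  heterozygosity or with many rare haplotypes; its accuracy claims are tied
  to the cohort structure above.
- Copy-number duplications are representable in genotypes (more than two
  entries per gene) but not phased.
- The scan's stage gating is at raw alpha; the Bonferroni columns are
  reported for users who prefer a family-wise guarantee.
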