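# kirhla

Population immunogenetics of KIR and HLA class I co-evolution, as a tested R
package.

Natural killer cells read the state of a cell through killer-cell
immunoglobulin-like receptors (KIR) binding HLA class I molecules. The two
gene families sit on different chromosomes, both are exceptionally
polymorphic — KIR haplotypes vary even in gene content — and HLA class I
allotypes partition into four mutually exclusive KIR epitopes (A3/11, Bw4,
C1, C2). Cohorts of mother-child pairs let allele-level haplotypes of both
loci be deduced from segregation, and the resulting frequency spectra and
receptor-ligand genotype correlations carry the footprint of selection.
`kirhla` is for population immunogeneticists who want that analysis chain as
reusable, validated functions rather than a one-off collection of tools.

What it implements:

- **Nomenclature and IO** — KIR allele names (`KIR3DL1*01502`: gene,
  3-digit allotype, 2-digit synonymous field), haplotype gene-content motifs
  (`cA01`, `tB04`, `cB01:001:002`), HLA colon-delimited names; genotype TSV +
  gapped registry FASTA with full validation.
- **Phasing** — segregation analysis in mother-child pairs with an EM phaser
  (segregation counts as pseudo-count priors) for unrelated individuals;
  haplotype censuses at allele and allotype resolution, with or without
  maternal non-transmitted haplotypes (131 children: 2N = 262; plus 104
  mothers: 2N = 366).
- **Ligand-receptor accounting** — sequence-based epitope assignment (Bw4
  needs Arg83; HLA-C is C1 with Asn80, C2 with Lys80), a JSON interaction
  table with expression-null filtering, and per-individual counts of distinct
  viable (KIR allotype, HLA allotype) pairs.
- **Selection statistics** — Tajima's D (pairwise deletion on gapped
  alignments) with empirical two-tail p from a built-in Hudson-style
  coalescent under piecewise-constant demography; Ewens-Watterson
  homozygosity F with the Slatkin exact test conditional on (k, n) and its
  normalized deviate F_nd = (F − E[F]) / SD[F]; projection of allotype
  spectra onto binding-site residue motifs (exclusive sets only).
- **Diversity structure** — Nei's unbiased heterozygosity, mismatch
  distributions, sliding-window MAF profiles with percentile ranking,
  Hamming haplotype networks (MST plus alternative links, parsimony node
  probabilities), cumulative haplotype-frequency curves.
- **Co-evolution scan** — individual-by-individual p-distance matrices from
  phased residue genotypes, a C++-backed Mantel permutation test, multiallelic
  r²/D′, and the iterative residue → residue-group scan between HLA and KIR.
- **Synthetic cohorts** — haplotype pools with balanced, directional or
  neutral-coalescent spectra, Mendelian mother-child transmission with
  optional cen/tel crossover, plantable receptor-ligand coupling, and truth
  files for every downstream stage.

## The statistics at the core

For a sample of n haplotypes with k variants at frequencies p_i:

- F = Σ p_i², H_e = 1 − F, Nei's unbiased H = n/(n−1) (1 − Σ p_i²).
- Tajima's D = (π − S/a₁) / √(e₁S + e₂S(S−1)) with the standard a₁, a₂, b₁,
  b₂, c₁, c₂, e₁, e₂ constants in n; D > 0 indicates balancing selection,
  D < 0 directional selection or expansion.
- F_nd = (F_obs − mean F_null) / sd F_null, with the null drawn from the
  Ewens sampling formula conditional on (k, n); p = Pr(F_null ≤ F_obs).
- Mantel z = Σ_{i<j} A_ij B_ij, permutation p = (1 + #{z_perm ≥ z_obs}) /
  (1 + n_perm); rankings use the standardized deviate
  (z − mean z_perm)/sd z_perm.

## A worked example

The classic boundary case is an individual homozygous for common haplotypes
on both chromosomes — HLA A\*23:01, B\*44:03, C\*04:01 with KIR2DL2\*001, no
KIR2DL1/S1/S2, and the expression-null KIR3DL1\*004 — whose entire NK
repertoire rests on a single receptor-ligand interaction:

```r
library(kirhla)
co  <- worked_example_cohort()
epi <- assign_epitopes_registry(co$registry)
count_functional_pairs(co$genotypes[["GA001"]], co$registry, epi)
#> <functional pairs> count = 1
#>          kir     hla
#>  KIR2DL2*001 C*04:01
```

Bw4 is present (A\*23:01 and B\*44:03 both carry Arg83) but its receptor
KIR3DL1\*004 is not expressed; C\*04:01 carries C2, not C1, and pairs with
KIR2DL2\*001 only through the table's explicit cross-reactivity — one
interaction.

A full synthetic study, end to end:

```r
models <- default_locus_models()
reg <- synthetic_allele_registry(models, k_default = 5, seed = 11)
cfg <- sim_config(seed = 42, n_pairs = 104, n_unrelated = 27,
                  kir_pool = synthetic_haplotype_pool(reg, models$KIR, 20, seed = 2),
                  hla_pool = synthetic_haplotype_pool(reg, models$HLA, 20, seed = 3),
                  registry = reg, models = models)
sim <- simulate_cohort(cfg)
ph  <- phase_cohort(sim$cohort)
haplotype_census(ph, "KIR")
#> <haplotype census> KIR (allele resolution): 2N = 262, k = 20
```

Two haplotypes per child give 2N = 262; with
`include_maternal_nontransmitted = TRUE` the census grows to 2N = 366. The
same objects feed `cohort_pair_distribution()`, `tajimas_d()` on
`census_gene_sequences()`, `slatkin_fnd()` on `census_gene_spectrum()`,
`hamming_network()` / `mismatch_distribution()` on
`haplotype_concat_sequences()`, and `coevolution_scan()` on the phased
cohort. `run_pipeline()` (or `inst/scripts/run_pipeline.R`) chains all of it
into a run directory with a JSON manifest.

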