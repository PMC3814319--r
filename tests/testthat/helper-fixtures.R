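# shared fixtures, built in code at test time

# three-gene toy locus for phasing unit tests (no registry needed)
toy_model <- function(genes = c("A", "B", "C")) {
  kirhla:::new_locus_model(list(
    id = "TOY", genes = genes,
    framework = rep(TRUE, length(genes)),
    aln_len = rep(3L, length(genes)),
    leader_aa = rep(0L, length(genes)),
    name_prefix = genes))
}

# the standard study-shaped simulation: 20-haplotype pools with high
# heterozygosity, 100 mother-child pairs + 27 unrelated, no recombination
study_sim <- function(seed = 42, n_pairs = 100L, n_unrelated = 27L,
                      recomb_rate = 0) {
  models <- default_locus_models()
  reg <- synthetic_allele_registry(models, k_default = 5L, seed = seed)
  kp <- synthetic_haplotype_pool(reg, models$KIR, n_haplotypes = 20L,
                                 seed = seed + 1L)
  hp <- synthetic_haplotype_pool(reg, models$HLA, n_haplotypes = 20L,
                                 seed = seed + 2L)
  cfg <- sim_config(seed = seed, n_pairs = n_pairs, n_unrelated = n_unrelated,
                    kir_pool = kp, hla_pool = hp, registry = reg,
                    models = models, recomb_rate = recomb_rate)
  simulate_cohort(cfg)
}

hap_pair_keys <- function(h1, h2) {
  sort(c(kirhla:::hap_key(h1), kirhla:::hap_key(h2)))
}

# does the phased result for `id` match the simulation truth at `locus`?
phase_matches_truth <- function(sim, phased, id, locus) {
  r <- phased$phased[[locus]][[id]]
  tr <- sim$truth$individuals[[id]]$haplotypes[[locus]]
  identical(hap_pair_keys(r$h1, r$h2), hap_pair_keys(tr[[1]], tr[[2]]))
}

# independent verifier: re-derive the unphased genotype from truth haplotypes
# and compare with the emitted genotype table
truth_consistent <- function(sim) {
  for (id in sim$cohort$individuals$id) {
    tr <- sim$truth$individuals[[id]]$haplotypes
    for (locus in names(tr)) {
      for (g in sim$cohort$models[[locus]]$genes) {
        expected <- sort(c(tr[[locus]][[1]][[g]], tr[[locus]][[2]][[g]]))
        if (!identical(expected, sort(sim$cohort$genotypes[[id]][[g]])))
          return(FALSE)
      }
    }
  }
  TRUE
}

# random valid KIR allele names for round-trip fuzzing
random_kir_names <- function(n, seed = 1) {
  set.seed(seed)
  genes <- c("KIR3DL3", "KIR2DL1", "KIR2DL4", "KIR3DL1", "KIR2DS3", "KIR3DP1")
  vapply(seq_len(n), function(i) {
    g <- sample(genes, 1)
    digits <- if (runif(1) < 0.5) sprintf("%03d", sample(0:999, 1))
              else sprintf("%03d%02d", sample(0:999, 1), sample(0:99, 1))
    paste0(g, "*", digits)
  }, character(1))
}
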