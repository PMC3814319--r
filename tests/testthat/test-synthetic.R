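test_that("a single-haplotype pool gives a fully homozygous, zero-diversity cohort", {
  models <- default_locus_models()
  reg <- synthetic_allele_registry(models, k_default = 2L, seed = 9)
  kp <- synthetic_haplotype_pool(reg, models$KIR, n_haplotypes = 1L, seed = 1)
  hp <- synthetic_haplotype_pool(reg, models$HLA, n_haplotypes = 1L, seed = 2)
  cfg <- sim_config(seed = 1, n_pairs = 2L, n_unrelated = 3L, kir_pool = kp,
                    hla_pool = hp, registry = reg, models = models)
  sim <- simulate_cohort(cfg)
  for (id in sim$cohort$individuals$id) {
    for (g in names(sim$cohort$genotypes[[id]])) {
      pair <- sim$cohort$genotypes[[id]][[g]]
      expect_equal(pair[1], pair[2])
    }
  }
  ph <- phased_from_truth(sim)
  cc <- haplotype_census(ph, "KIR")
  expect_equal(nrow(cc), 1L)
  expect_equal(cumulative_haplotype_curve(cc), 1.0)
})

test_that("child haplotype frequencies match a two-haplotype pool at (0.7, 0.3)", {
  models <- default_locus_models()
  reg <- synthetic_allele_registry(models, k_default = 2L, seed = 9)
  kp <- synthetic_haplotype_pool(reg, models$KIR, n_haplotypes = 2L, seed = 3)
  kp$freqs <- c(0.7, 0.3)
  hp <- synthetic_haplotype_pool(reg, models$HLA, n_haplotypes = 1L, seed = 4)
  cfg <- sim_config(seed = 11, n_pairs = 2500L, n_unrelated = 0L, kir_pool = kp,
                    hla_pool = hp, registry = reg, models = models)
  sim <- simulate_cohort(cfg)
  key1 <- kirhla:::hap_key(kp$haplotypes[[1]])
  children <- grep("^C", sim$cohort$individuals$id, value = TRUE)
  n_hap <- 2L * length(children)
  count1 <- 0L
  for (id in children) {
    tr <- sim$truth$individuals[[id]]$haplotypes$KIR
    count1 <- count1 + sum(vapply(tr, kirhla:::hap_key, character(1)) == key1)
  }
  se <- sqrt(0.7 * 0.3 / n_hap)
  expect_lt(abs(count1 / n_hap - 0.7), 3 * se)
})

test_that("with recomb_rate = 0 every child shares a whole haplotype with its mother", {
  sim <- study_sim(seed = 13, n_pairs = 50L, n_unrelated = 0L, recomb_rate = 0)
  for (p in 1:50) {
    cid <- sprintf("C%03d", p); mid <- sprintf("M%03d", p)
    for (locus in c("KIR", "HLA")) {
      ch <- sim$truth$individuals[[cid]]$haplotypes[[locus]]
      mh <- sim$truth$individuals[[mid]]$haplotypes[[locus]]
      ck <- vapply(ch, kirhla:::hap_key, character(1))
      mk <- vapply(mh, kirhla:::hap_key, character(1))
      expect_true(any(ck %in% mk))
    }
  }
})

test_that("identical SimConfig yields byte-identical outputs", {
  s1 <- study_sim(seed = 21, n_pairs = 5L, n_unrelated = 5L)
  s2 <- study_sim(seed = 21, n_pairs = 5L, n_unrelated = 5L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulated_cohort(s1, d1); write_simulated_cohort(s2, d2)
  for (f in c("genotypes.tsv", "alleles.fasta", "truth_haplotypes.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("truth haplotypes re-derive the emitted genotypes exactly", {
  sim <- study_sim(seed = 23, n_pairs = 10L, n_unrelated = 5L, recomb_rate = 0.3)
  expect_true(truth_consistent(sim))
})

test_that("haplotype-level genotype frequencies satisfy Hardy-Weinberg", {
  models <- default_locus_models()
  reg <- synthetic_allele_registry(models, k_default = 2L, seed = 9)
  kp <- synthetic_haplotype_pool(reg, models$KIR, n_haplotypes = 3L, seed = 5)
  kp$freqs <- c(0.5, 0.3, 0.2)
  hp <- synthetic_haplotype_pool(reg, models$HLA, n_haplotypes = 1L, seed = 6)
  cfg <- sim_config(seed = 31, n_pairs = 0L, n_unrelated = 3000L, kir_pool = kp,
                    hla_pool = hp, registry = reg, models = models)
  sim <- simulate_cohort(cfg)
  keys <- vapply(kp$haplotypes, kirhla:::hap_key, character(1))
  geno_count <- table(vapply(sim$cohort$individuals$id, function(id) {
    tr <- sim$truth$individuals[[id]]$haplotypes$KIR
    paste(sort(match(vapply(tr, kirhla:::hap_key, character(1)), keys)),
          collapse = "/")
  }, character(1)))
  p <- kp$freqs
  combos <- c("1/1", "1/2", "1/3", "2/2", "2/3", "3/3")
  expected <- c(p[1]^2, 2 * p[1] * p[2], 2 * p[1] * p[3], p[2]^2,
                2 * p[2] * p[3], p[3]^2) * 3000
  observed <- as.numeric(geno_count[combos])
  observed[is.na(observed)] <- 0
  chi <- suppressWarnings(chisq.test(observed, p = expected / sum(expected)))
  expect_gt(chi$p.value, 0.001)
})

test_that("sample_spectrum modes have the promised shapes", {
  # balanced with concentration 100, k = 4: Dirichlet(100) quantiles put every
  # frequency inside (0.15, 0.35) with overwhelming probability
  for (s in 1:20) {
    f <- sample_spectrum("balanced", k = 4, seed = s)
    expect_equal(sum(f), 1)
    expect_true(all(f > 0.15 & f < 0.35))
  }
  for (s in 1:20) {
    f <- sample_spectrum("directional", k = 4, seed = s)
    expect_gt(max(f), 0.85)
    expect_equal(sum(f), 1)
  }
  f <- sample_spectrum("neutral_coalescent", k = 5, n = 50, seed = 2)
  expect_equal(length(f), 5L)
  expect_equal(sum(f), 1)
  for (mode in c("balanced", "directional", "neutral_coalescent")) {
    expect_equal(sample_spectrum(mode, k = 1, seed = 1), 1.0)
  }
  expect_error(sample_spectrum("balanced", k = 0), "k")
})

test_that("coupling at strength zero leaves the loci independent", {
  cfg <- coupling_study_config(seed = 51, n_unrelated = 400, strength = 0)
  expect_null(cfg$coupling)
  sim <- simulate_cohort(cfg)
  # association between HLA-B Bw4-class dosage and KIR3DL1 class dosage
  reg <- sim$cohort$registry
  dos <- function(id, gene, residues, focal) {
    tr <- sim$truth$individuals[[id]]$haplotypes[[
      if (grepl("HLA", gene)) "HLA" else "KIR"]]
    sum(vapply(tr, function(h)
      kirhla:::hap_residue_state(h, gene, residues, reg) == focal, logical(1)))
  }
  ids <- sim$cohort$individuals$id
  x <- vapply(ids, dos, numeric(1), gene = "HLA-B", residues = c(77, 83),
              focal = "NR")
  y <- vapply(ids, dos, numeric(1), gene = "KIR3DL1", residues = c(31, 44, 86),
              focal = "IRS")
  expect_gt(suppressWarnings(chisq.test(table(x, y))$p.value), 0.001)
})

test_that("coupling requires polymorphic residue sets", {
  cfg <- coupling_study_config(seed = 52, n_unrelated = 10, strength = NULL)
  # residue 10 of KIR2DL4 is monomorphic in this registry
  expect_error(plant_coupling(cfg, "HLA-B", c(77, 83), "KIR2DL4", 10, 0.5),
               "monomorphic")
  expect_error(plant_coupling(cfg, "HLA-B", c(77, 83), "KIR3DL1",
                              c(31, 44, 86), 1.5), "strength")
})
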