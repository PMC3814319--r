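toy_geno <- function(...) {
  g <- list(...)
  lapply(g, function(v) sort(v))
}

test_that("a fully homozygous mother forces the child's phase", {
  m <- toy_model()
  mother <- toy_geno(A = c("A1", "A1"), B = c("B1", "B1"), C = c("C1", "C1"))
  child <- toy_geno(A = c("A1", "A2"), B = c("B1", "B2"), C = c("C1", "C2"))
  r <- segregation_phase(mother, child, m)
  expect_equal(r$resolution, "segregation")
  maternal <- r[[c("h1", "h2")[r$maternal]]]
  expect_equal(unname(maternal), c("A1", "B1", "C1"))
})

test_that("a fully homozygous child is trivially phased", {
  m <- toy_model()
  mother <- toy_geno(A = c("A1", "A2"), B = c("B1", "B2"), C = c("C1", "C2"))
  child <- toy_geno(A = c("A1", "A1"), B = c("B1", "B1"), C = c("C1", "C1"))
  r <- segregation_phase(mother, child, m)
  expect_equal(r$resolution, "segregation")
  expect_identical(r$h1, r$h2)
})

test_that("segregation matches the exhaustive split-enumeration oracle on the 3-gene toy", {
  m <- toy_model()
  mother <- toy_geno(A = c("A1", "A2"), B = c("B1", "B1"), C = c("C1", "C2"))
  child <- toy_geno(A = c("A1", "A3"), B = c("B1", "B2"), C = c("C1", "C3"))
  # oracle: enumerate all 2^3 ordered allocations by brute force
  survivors <- list()
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    h1 <- c(A = child$A[a], B = child$B[b], C = child$C[cc])
    h2 <- c(A = child$A[3 - a], B = child$B[3 - b], C = child$C[3 - cc])
    contain <- function(h) all(h["A"] %in% mother$A, h["B"] %in% mother$B,
                               h["C"] %in% mother$C)
    if (contain(h1) || contain(h2)) {
      key <- paste(sort(c(paste(h1, collapse = "|"), paste(h2, collapse = "|"))),
                   collapse = " ")
      survivors[[key]] <- list(h1, h2)
    }
  }
  expect_equal(length(survivors), 1L)
  r <- segregation_phase(mother, child, m)
  expect_equal(r$resolution, "segregation")
  maternal <- r[[c("h1", "h2")[r$maternal]]]
  paternal <- r[[c("h1", "h2")[3 - r$maternal]]]
  expect_equal(unname(maternal), c("A1", "B1", "C1"))
  expect_equal(unname(paternal), c("A3", "B2", "C3"))
})

test_that("Mendelian inconsistency is reported with the offending gene", {
  m <- toy_model()
  mother <- toy_geno(A = c("A1", "A1"), B = c("B1", "B1"), C = c("C1", "C1"))
  child <- toy_geno(A = c("A2", "A3"), B = c("B1", "B1"), C = c("C1", "C1"))
  expect_error(segregation_phase(mother, child, m), "gene A")
})

test_that("ABSENT participates in segregation like an ordinary allele", {
  m <- toy_model()
  mother <- toy_geno(A = c("ABSENT", "ABSENT"), B = c("B1", "B1"),
                     C = c("C1", "C2"))
  child <- toy_geno(A = c("ABSENT", "A1"), B = c("B1", "B2"), C = c("C1", "C3"))
  r <- segregation_phase(mother, child, m)
  expect_equal(r$resolution, "segregation")
  maternal <- r[[c("h1", "h2")[r$maternal]]]
  expect_equal(unname(maternal), c("ABSENT", "B1", "C1"))
})

test_that("EM reproduces the two-haplotype analytic fixed point and obeys priors", {
  m <- toy_model(c("S1", "S2"))
  # all individuals homozygous: exact phases in one iteration
  genos <- list(i1 = toy_geno(S1 = c("a", "a"), S2 = c("b", "b")))
  r <- em_phase(genos, m)
  expect_equal(length(attr(r, "loglik")), 2L)
  expect_equal(unname(r$i1$h1), c("a", "b"))
  # classic double heterozygote: priors favouring the coupling phase win
  genos <- list(i1 = toy_geno(S1 = c("a", "A"), S2 = c("b", "B")))
  priors <- c("A|B" = 10, "a|b" = 10, "A|b" = 1, "a|B" = 1)
  r <- em_phase(genos, m, priors = priors)
  keys <- hap_pair_keys(r$i1$h1, r$i1$h2)
  expect_equal(keys, c("A|B", "a|b"))
  # and repulsion priors give the repulsion phase
  priors <- c("A|b" = 10, "a|B" = 10)
  r <- em_phase(genos, m, priors = priors)
  expect_equal(hap_pair_keys(r$i1$h1, r$i1$h2), c("A|b", "a|B"))
})

test_that("EM log-likelihood is non-decreasing and frequencies sum to one", {
  sim <- study_sim(seed = 61, n_pairs = 0L, n_unrelated = 40L)
  genos <- lapply(setNames(nm = sim$cohort$individuals$id), function(id)
    kirhla:::locus_genotype(sim$cohort, id, "KIR"))
  r <- em_phase(genos, sim$cohort$models$KIR)
  ll <- attr(r, "loglik")
  expect_true(all(diff(ll) >= -1e-9))
  expect_equal(sum(attr(r, "freqs")), 1)
})

test_that("census arithmetic: 131 children give 2N = 262, plus 104 maternal gives 366", {
  sim <- study_sim(seed = 42, n_pairs = 104L, n_unrelated = 27L)
  ph <- phase_cohort(sim$cohort)
  for (locus in c("KIR", "HLA")) {
    cc <- haplotype_census(ph, locus)
    expect_equal(attr(cc, "n2"), 262L)
    expect_equal(sum(cc$freq), 1)
    cc2 <- haplotype_census(ph, locus, include_maternal_nontransmitted = TRUE)
    expect_equal(attr(cc2, "n2"), 366L)
    expect_equal(sum(cc2$count), 366L)
    # allotype-level k never exceeds allele-level k
    cca <- haplotype_census(ph, locus, resolution = "allotype")
    expect_lte(nrow(cca), nrow(cc))
  }
})

test_that("phased haplotype pairs reproduce the unphased genotype", {
  sim <- study_sim(seed = 71, n_pairs = 10L, n_unrelated = 5L)
  ph <- phase_cohort(sim$cohort)
  for (id in sim$cohort$individuals$id) {
    for (locus in c("KIR", "HLA")) {
      r <- ph$phased[[locus]][[id]]
      for (g in names(r$h1)) {
        expect_identical(sort(c(r$h1[[g]], r$h2[[g]])),
                         sort(sim$cohort$genotypes[[id]][[g]]))
      }
    }
  }
})

test_that("segregation-resolved phases never contradict truth when recomb_rate is 0", {
  sim <- study_sim(seed = 81, n_pairs = 40L, n_unrelated = 10L, recomb_rate = 0)
  ph <- phase_cohort(sim$cohort)
  for (locus in c("KIR", "HLA")) {
    for (id in kirhla:::cohort_children(sim$cohort)) {
      r <- ph$phased[[locus]][[id]]
      if (r$resolution == "segregation") {
        expect_true(phase_matches_truth(sim, ph, id, locus))
      }
    }
  }
})
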