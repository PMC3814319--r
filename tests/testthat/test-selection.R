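test_that("frequency spectra carry exact F and He", {
  sp <- freq_spectrum(c(5, 3, 2))
  expect_equal(sp$n, 10L)
  expect_equal(sp$k, 3L)
  expect_equal(sp$F, 0.38)
  expect_equal(sp$He, 0.62)
  expect_equal(sp$F + sp$He, 1)
  expect_equal(ewens_watterson_f(freq_spectrum(rep(2, 5))), 1 / 5)
  expect_equal(ewens_watterson_f(freq_spectrum(7)), 1)
  expect_error(freq_spectrum(c(3, 0)))
})

test_that("Tajima's D matches the hand-evaluated toy alignment", {
  seqs <- c("ACGTA", "ACGTT", "ACGAA", "CCGTA")
  td <- tajimas_d(seqs)
  expect_equal(td$S, 3L)
  expect_equal(td$pi, 1.5)
  # independent evaluation written out from the 1989 constants
  n <- 4
  a1 <- 1 + 1/2 + 1/3; a2 <- 1 + 1/4 + 1/9
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  d_oracle <- (1.5 - 3 / a1) / sqrt(e1 * 3 + e2 * 3 * 2)
  expect_equal(td$D, d_oracle, tolerance = 1e-12)
  expect_equal(td$D, -0.754451, tolerance = 1e-5)
})

test_that("invariant alignments flag D as undefined rather than erroring", {
  td <- tajimas_d(rep("ACGTACGT", 5))
  expect_equal(td$S, 0L)
  expect_equal(td$pi, 0)
  expect_true(is.na(td$D))
})

test_that("gapped sites are excluded from S and pairwise-deleted in pi", {
  seqs <- c("AC-TA", "ACGTT", "ACGAA", "CCGTA")
  td <- tajimas_d(seqs)
  expect_equal(td$S, 3L)  # gapped site 3 never segregates; sites 1, 4, 5 do
  # pi by manual pairwise deletion
  manual <- mean(c(1, 1, 1, 2, 2, 2))
  expect_equal(td$pi, manual)
})

test_that("coalescent simulator matches closed forms at modest replicate counts", {
  m <- demographic_model("const", data.frame(time = 0, size = 1), theta = 4)
  sims <- coalescent_simulate(m, n = 2, reps = 4000, seed = 5)
  se <- sd(sims$pi) / sqrt(nrow(sims))
  expect_lt(abs(mean(sims$pi) - 4), 3 * se)
  m5 <- demographic_model("const", data.frame(time = 0, size = 1), theta = 5)
  sims10 <- coalescent_simulate(m5, n = 10, reps = 4000, seed = 6)
  a1 <- sum(1 / (1:9))
  se <- sd(sims10$S) / sqrt(nrow(sims10))
  expect_lt(abs(mean(sims10$S) - 5 * a1), 3 * se)
})

test_that("recent expansion drives Tajima's D negative", {
  growth <- demographic_model("expansion",
                              data.frame(time = c(0, 0.25), size = c(1, 0.1)),
                              theta = 5)
  sims <- coalescent_simulate(growth, n = 30, reps = 500, seed = 7)
  expect_lt(mean(sims$D, na.rm = TRUE), 0)
})

test_that("empirical two-tail p follows rank arithmetic with add-one correction", {
  sims <- seq(-2, 2, length.out = 9999)
  expect_equal(tajima_significance(3, sims), 2 / 10000)
  expect_equal(tajima_significance(-3, sims), 2 / 10000)
  expect_equal(tajima_significance(0, sims), 1)
  # invariant under permutation of the replicate order
  set.seed(1)
  expect_equal(tajima_significance(1.3, sims),
               tajima_significance(1.3, sample(sims)))
  # undefined replicates are dropped with a message
  expect_message(p <- tajima_significance(0, c(sims, NA, NA)), "dropping 2")
  expect_equal(p, 1)
})

test_that("the conditional-on-k null matches exhaustive Ewens enumeration (n <= 8, k <= 4)", {
  n_sim <- 4000
  for (n in 4:8) {
    for (k in 2:min(4, n - 1)) {
      parts <- partitions_nk(n, k)
      probs <- vapply(parts, ewens_cond_prob, numeric(1), n = n, k = k)
      expect_equal(sum(probs), 1, tolerance = 1e-12)
      f_vals <- vapply(parts, function(p) sum((p / n)^2), numeric(1))
      expect_equal(anyDuplicated(round(f_vals, 12)), 0L)
      set.seed(n * 100 + k)
      theta <- kirhla:::ewens_theta_for_k(n, k)
      f_sim <- kirhla:::.ewens_f_cpp(n, k, theta, n_sim, 1e7)
      for (i in seq_along(parts)) {
        p_hat <- mean(abs(f_sim - f_vals[i]) < 1e-9)
        se <- sqrt(probs[i] * (1 - probs[i]) / n_sim)
        expect_lt(abs(p_hat - probs[i]), 4 * se + 1e-6)
      }
    }
  }
})

test_that("F_nd is near zero on null spectra and negative for even spectra", {
  # self-consistency: spectra drawn from the same conditional null
  set.seed(99)
  n <- 40; k <- 5
  theta <- kirhla:::ewens_theta_for_k(n, k)
  vals <- replicate(200, {
    cfg <- kirhla:::ewens_config(n, k)
    slatkin_fnd(freq_spectrum(cfg), n_sim = 500)$F_nd
  })
  expect_lt(abs(mean(vals)), 0.2)
  # maximally even observed spectrum: balancing-selection signature
  ew <- slatkin_fnd(freq_spectrum(rep(8, 5)), n_sim = 2000, seed = 1)
  expect_lt(ew$F_nd, 0)
  expect_lt(ew$p_slatkin, 0.5)
  # monomorphic flag
  mono <- slatkin_fnd(freq_spectrum(10))
  expect_true(mono$monomorphic)
  expect_true(is.na(mono$F_nd))
})

test_that("motif projection collapses allotypes by residue-set identity", {
  at <- data.frame(name = c("X*01", "X*02", "X*03"),
                   protein = c("ARND", "ARNE", "AKND"),
                   count = c(4L, 3L, 3L))
  # full-length projection: identity
  sp <- motif_project(at, 1:4)
  expect_equal(sp$k, 3L)
  expect_equal(sp$F, sum((c(4, 3, 3) / 10)^2))
  # residues 1-2: X*01 and X*02 merge
  sp2 <- motif_project(at, 1:2)
  expect_equal(sp2$k, 2L)
  expect_equal(sort(sp2$counts), c(3L, 7L))
  # monomorphic set flagged
  sp1 <- motif_project(at, 1)
  expect_equal(sp1$k, 1L)
  expect_true(attr(sp1, "monomorphic"))
  # idempotence: projecting a projection changes nothing
  classes <- attr(sp2, "classes")
  re <- motif_project(data.frame(name = classes, protein = classes,
                                 count = sp2$counts), 1:2)
  expect_equal(sort(re$counts), sort(sp2$counts))
  expect_error(motif_project(at, 9), "outside")
})

test_that("binding-site exclusive sets are disjoint and cover the scan defaults", {
  sites <- read_binding_sites()
  need <- list("HLA-B" = c(24, 45, 77:83, 114, 194),
               "HLA-C" = c(14, 49, 194, 261, 273, 311, 313, 332, 345),
               "KIR3DL1" = c(31, 44, 86),
               "KIR2DL1" = c(154, 163, 182, 216, 245))
  for (g in names(need)) {
    expect_true(all(need[[g]] %in% unlist(sites[[g]]$sites)), label = g)
    ex <- sites[[g]]$exclusive
    all_ex <- unlist(ex)
    expect_equal(anyDuplicated(all_ex), 0L, label = g)
  }
})
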