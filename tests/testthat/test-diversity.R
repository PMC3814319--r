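test_that("heterozygosity estimators follow their formulas", {
  expect_equal(nei_heterozygosity(freq_spectrum(c(5, 5))), 10 / 9 * 0.5)
  expect_equal(nei_heterozygosity(freq_spectrum(4)), 0)
  expect_error(nei_heterozygosity(freq_spectrum(1)), "n >= 2")
  expect_equal(he_ssf(c(0.5, 0.5)), 0.5)
  expect_equal(he_ssf(1), 0)
  # finite-sample correction never shrinks
  for (counts in list(c(3, 2), c(9, 1), c(4, 3, 2, 1))) {
    sp <- freq_spectrum(counts)
    expect_gte(nei_heterozygosity(sp), sp$He)
    # definitional identity He = 1 - F
    expect_equal(he_ssf(counts / sum(counts)), 1 - ewens_watterson_f(sp))
  }
})

test_that("mismatch distribution uses pairwise deletion and counts all pairs", {
  mm <- mismatch_distribution(rep("ACGT", 4))
  expect_true(all(mm$distances == 0))
  expect_equal(length(mm$distances), 6L)
  # gapped toy pair: compared over the 2 gap-free shared sites
  mm2 <- mismatch_distribution(c("ACT-", "AC-G"))
  expect_equal(mm2$distances, 0)
  mm3 <- mismatch_distribution(c("TCT-", "AC-G"))
  expect_equal(mm3$distances, 0.5)
  # no comparable sites: excluded with a warning
  expect_warning(mm4 <- mismatch_distribution(c("A--", "-CC", "ACC")),
                 "no comparable sites")
  expect_equal(length(mm4$distances), 2L)
})

test_that("two divergent clades give a bimodal mismatch distribution, a star does not", {
  clade1 <- c("AAAAAAAAAAAA", "AAAAAAAAAAAT", "AAAAAAAAAACA", "AAAAAAAAATAA")
  clade2 <- c("TTTTTTTTTTTT", "TTTTTTTTTTTA", "TTTTTTTTTTAT", "TTTTTTTTATTT")
  mm <- mismatch_distribution(c(clade1, clade2), binwidth = 1 / 12)
  nz <- which(mm$counts > 0)
  # a gap of empty bins separates within-clade from between-clade distances
  expect_true(any(diff(nz) > 1))
  star <- c("AAAAAAAAAAAA", "TAAAAAAAAAAA", "ATAAAAAAAAAA", "AATAAAAAAAAA",
            "AAATAAAAAAAA")
  mm_star <- mismatch_distribution(star, binwidth = 1 / 12)
  nz_star <- which(mm_star$counts > 0)
  expect_true(all(diff(nz_star) == 1))
})

test_that("sliding-window MAF profiles have the right geometry", {
  expect_equal(sliding_window_maf(rep(0.3, 20), window = 15)$mean_maf,
               rep(0.3, 6))
  expect_equal(nrow(sliding_window_maf(runif(20, 0, 0.5), window = 15)), 6L)
  expect_error(sliding_window_maf(runif(10), window = 15), "fewer markers")
  # percentile rank arithmetic
  ref <- seq(0.1, 1, by = 0.1)
  expect_equal(percentile_of_interval(0.05, ref), 0)
  expect_lt(percentile_of_interval(0.05, ref), 100 / length(ref))
  expect_equal(percentile_of_interval(0.55, ref), 50)
  expect_equal(percentile_of_interval(2, ref), 100)
})

test_that("marker series mixes presence pseudo-markers with sequence sites", {
  sim <- study_sim(seed = 33, n_pairs = 10L, n_unrelated = 5L)
  ph <- phase_cohort(sim$cohort)
  cc <- haplotype_census(ph, "KIR")
  ms <- marker_series(cc, sim$cohort$registry, sim$cohort$models$KIR)
  expect_true(all(ms$type %in% c("presence", "site")))
  expect_true(any(ms$type == "presence"))
  expect_true(all(ms$maf > 0 & ms$maf <= 0.5 + 1e-9))
})

test_that("hamming networks: chain topology and exhaustive MST oracle", {
  net <- hamming_network(c(H1 = "AAA", H2 = "AAT"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$steps, 1L)
  net3 <- hamming_network(c(A = "AAA", B = "AAT", C = "ATT"))
  prim <- net3$edges[net3$edges$type == "primary", ]
  expect_equal(sort(prim$steps), c(1L, 1L))
  expect_false(any(prim$from == "A" & prim$to == "C"))

  # gap handling: gap-base is a step, gap-gap a match
  netg <- hamming_network(c(X = "A-A", Y = "A-T", Z = "AT-"))
  expect_equal(netg$dist["X", "Y"], 1L)
  expect_equal(netg$dist["X", "Z"], 2L)

  # brute-force minimum spanning tree oracle for <= 6 haplotypes
  set.seed(17)
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(1:6, function(i)
    paste(sample(bases, 8, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- paste0("H", 1:6)
  seqs <- seqs[!duplicated(seqs)]
  n <- length(seqs)
  net6 <- hamming_network(seqs)
  mst_weight <- sum(net6$edges$steps[net6$edges$type == "primary"])
  d <- net6$dist
  pairs <- t(combn(n, 2))
  best <- Inf
  for (sel in combn(nrow(pairs), n - 1, simplify = FALSE)) {
    es <- pairs[sel, , drop = FALSE]
    # connectivity check by union-find
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in seq_len(nrow(es))) {
      a <- find(es[e, 1]); b <- find(es[e, 2])
      if (a == b) { ok <- FALSE; break }
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(d[es]))
  }
  expect_equal(mst_weight, best)
})

test_that("alternative links match a displaced primary-link weight", {
  # square: A-B=1, B-C=1, C-D=1, D-A=1, diagonals 2
  seqs <- c(A = "AA", B = "AT", C = "TT", D = "TA")
  net <- hamming_network(seqs)
  prim <- net$edges[net$edges$type == "primary", ]
  alt <- net$edges[net$edges$type == "alternative", ]
  expect_equal(nrow(prim), 3L)
  expect_true(nrow(alt) >= 1L)
  expect_true(all(alt$steps == 1L))
})

test_that("parsimony node probability is 1 at zero steps and monotone", {
  expect_equal(templeton_node_probability(0, 100), 1)
  for (m in c(10, 100, 1000)) {
    p <- vapply(0:m, templeton_node_probability, numeric(1), m = m)
    expect_true(all(diff(p) <= 0))
    expect_true(all(p > 0 & p <= 1))
  }
  expect_error(templeton_node_probability(11, 10), "exceed")
  # reference evaluation of the closed form on a grid
  for (j in c(1, 3, 7)) {
    for (m in c(50, 500)) {
      expect_equal(templeton_node_probability(j, m),
                   1 / (1 + j * (j + 1) * 2 / (2 * m * 3)))
    }
  }
})

test_that("cumulative haplotype curves are monotone and end at 1", {
  expect_equal(cumulative_haplotype_curve(c(1)), 1)
  expect_equal(cumulative_haplotype_curve(rep(0.25, 4)),
               c(0.25, 0.5, 0.75, 1))
  sim <- study_sim(seed = 35, n_pairs = 10L, n_unrelated = 5L)
  ph <- phase_cohort(sim$cohort)
  for (resn in c("allele", "allotype")) {
    cv <- cumulative_haplotype_curve(haplotype_census(ph, "KIR",
                                                      resolution = resn))
    expect_true(all(diff(cv) >= 0))
    expect_equal(cv[length(cv)], 1)
  }
})
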