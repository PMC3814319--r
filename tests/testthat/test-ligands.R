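test_that("the doubly homozygous worked example forms exactly one pair", {
  co <- worked_example_cohort()
  epi <- assign_epitopes_registry(co$registry)
  pc <- count_functional_pairs(co$genotypes[["GA001"]], co$registry, epi)
  expect_equal(pc$count, 1L)
  expect_equal(pc$pairs$kir, "KIR2DL2*001")
  expect_equal(pc$pairs$hla, "C*04:01")
})

test_that("epitope assignment follows sequence rules", {
  co <- worked_example_cohort()
  epi <- assign_epitopes_registry(co$registry)
  # B*53:01 and B*35:01 differ only across the Bw4 window
  expect_equal(epi[["B*53:01"]], "Bw4")
  expect_equal(epi[["B*35:01"]], character(0))
  b53 <- co$registry[co$registry$name == "B*53:01", ]
  b35 <- co$registry[co$registry$name == "B*35:01", ]
  diffs <- which(strsplit(b53$protein, "")[[1]] != strsplit(b35$protein, "")[[1]])
  expect_true(all(diffs >= 77 & diffs <= 83))
  # C alleles: Lys80 -> C2, Asn80 -> C1; never both
  expect_equal(epi[["C*04:01"]], "C2")
  expect_equal(epi[["C*07:01"]], "C1")
  for (e in epi) expect_false(all(c("C1", "C2") %in% e))
  # an HLA-C allotype with neither determinant is an error
  rules <- read_epitope_rules()
  expect_error(assign_epitopes("HLA-C", "C*99:99",
                               strrep("A", 345), rules), "neither")
  # a gap in the epitope window is an untyped region
  gappy <- paste0(strrep("A", 76), "---", strrep("A", 270))
  expect_error(assign_epitopes("HLA-B", "B*99:99", gappy, rules), "untyped")
})

test_that("expression filtering: null KIR means no pairs", {
  co <- worked_example_cohort()
  epi <- assign_epitopes_registry(co$registry)
  tab <- read_interaction_table()
  geno <- co$genotypes[["GA001"]]
  # KIR2DL2*001 also on the null list -> only receptor left is null 3DL1*004
  tab2 <- tab
  tab2$kir_expression_null <- c(tab$kir_expression_null, "KIR2DL2*001")
  expect_equal(count_functional_pairs(geno, co$registry, epi, tab2)$count, 0L)
})

test_that("expressed KIR3DL1 with Bw4-positive and -negative HLA-B gives one pair", {
  co <- worked_example_cohort()
  epi <- assign_epitopes_registry(co$registry)
  geno <- list(
    "HLA-A" = c("A*23:01", "A*23:01"),
    "HLA-B" = c("B*53:01", "B*35:01"),
    "HLA-C" = c("C*07:01", "C*07:01"),
    "KIR3DL3" = c("ABSENT", "ABSENT"),
    "KIR2DL2" = c("ABSENT", "ABSENT"),
    "KIR2DL3" = c("ABSENT", "ABSENT"),
    "KIR2DL1" = c("ABSENT", "ABSENT"),
    "KIR2DL4" = c("ABSENT", "ABSENT"),
    "KIR3DL1" = c("KIR3DL1*001", "KIR3DL1*001"),
    "KIR3DL2" = c("ABSENT", "ABSENT"))
  pc <- count_functional_pairs(geno, co$registry, epi)
  # A*23:01 carries Bw4 too, so 3DL1 sees two ligands: B*53:01 and A*23:01
  expect_setequal(pc$pairs$hla, c("B*53:01", "A*23:01"))
  expect_true(!"B*35:01" %in% pc$pairs$hla)
  # restricted to HLA-B only: exactly the single Bw4 pair remains
  geno$`HLA-A` <- c("ABSENT", "ABSENT")
  pc <- count_functional_pairs(geno, co$registry, epi)
  expect_equal(pc$count, 1L)
  expect_equal(pc$pairs$hla, "B*53:01")
})

test_that("counting has set semantics and is phase and homozygosity invariant", {
  co <- worked_example_cohort()
  epi <- assign_epitopes_registry(co$registry)
  geno <- co$genotypes[["GA001"]]
  het <- geno
  het$`HLA-C` <- c("C*04:01", "C*07:01")
  base <- count_functional_pairs(het, co$registry, epi)$count
  # swapping slot order (phase representation) changes nothing
  flipped <- lapply(het, rev)
  expect_equal(count_functional_pairs(flipped, co$registry, epi)$count, base)
  # homozygous duplication of a ligand counts once
  expect_equal(count_functional_pairs(geno, co$registry, epi)$count, 1L)
})

test_that("adding a rule never decreases any individual's count", {
  co <- worked_example_cohort()
  epi <- assign_epitopes_registry(co$registry)
  tab <- read_interaction_table()
  geno <- co$genotypes[["GA001"]]
  before <- count_functional_pairs(geno, co$registry, epi, tab)$count
  tab$rules <- c(tab$rules, list(list(kir_gene = "KIR3DL2",
                                      epitopes = character(0),
                                      hla_exceptions = "A*23:01")))
  after <- count_functional_pairs(geno, co$registry, epi, tab)$count
  expect_gte(after, before)
  expect_equal(after, 2L)
})

test_that("an empty interaction table gives all-zero counts", {
  co <- worked_example_cohort()
  epi <- assign_epitopes_registry(co$registry)
  tab <- read_interaction_table()
  tab$rules <- list()
  dist <- cohort_pair_distribution(co, epitopes = epi, table = tab)
  expect_true(all(dist$counts == 0))
})

test_that("a cohort of clones has mean 1 and degenerate interval", {
  co <- worked_example_cohort()
  ids <- paste0("CL", 1:5)
  clones <- kirhla:::new_cohort(
    ids, setNames(rep(NA_character_, 5), ids),
    setNames(rep(list(co$genotypes[["GA001"]]), 5), ids),
    co$registry, co$models)
  dist <- cohort_pair_distribution(clones)
  expect_equal(dist$mean, 1)
  expect_equal(unname(dist$interval), c(1, 1))
})
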