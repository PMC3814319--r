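#' Epitope assignment rules
#'
#' Reads the configuration mapping HLA class I protein sequence to the four
#' mutually exclusive KIR-relevant epitopes: Bw4 (HLA-A/B residues 77-83, with
#' arginine 83 required), C1 (HLA-C asparagine 80, plus configured HLA-B
#' exceptions such as B*46:01 and B*73:01), C2 (HLA-C lysine 80), and A3/11
#' (HLA-A allele groups A*03 and A*11, assigned by name because the KIR3DL2
#' binding determinant is unknown).
#'
#' @param path JSON rules path (default: shipped rules).
#' @return List of class `epitope_rules`.
#' @export
read_epitope_rules <- function(path = system.file("extdata", "epitope_rules.json",
                                                  package = "kirhla")) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(r, class = "epitope_rules")
}

#' Interaction table: which KIR see which HLA epitopes
#'
#' Rules act at the KIR gene level, each listing accepted epitopes plus
#' explicit HLA allotype exceptions (cross-reactivities outside the epitope
#' system, e.g. KIR2DL2 with C*04:01). Allotypes on the expression-null lists
#' never form pairs.
#'
#' @param path JSON table path (default: shipped table).
#' @return List of class `interaction_table` with `rules`,
#'   `kir_expression_null`, `hla_expression_null`.
#' @export
read_interaction_table <- function(path = system.file("extdata", "interaction_table.json",
                                                      package = "kirhla")) {
  t <- jsonlite::read_json(path, simplifyVector = TRUE)
  t$rules <- lapply(seq_len(nrow(t$rules)), function(i) {
    list(kir_gene = t$rules$kir_gene[i],
         epitopes = unlist(t$rules$epitopes[i]),
         hla_exceptions = unlist(t$rules$hla_exceptions[i]))
  })
  structure(t, class = "interaction_table")
}

#' Assign KIR-relevant epitopes to an HLA allotype
#'
#' @param gene HLA gene (`"HLA-A"`, `"HLA-B"`, `"HLA-C"`).
#' @param name Allotype name (e.g. `"B*53:01"`).
#' @param protein Mature-numbered protein sequence.
#' @param rules An `epitope_rules` object.
#' @return Character vector, subset of `c("A3/11", "Bw4", "C1", "C2")`.
#' @export
assign_epitopes <- function(gene, name, protein, rules = read_epitope_rules()) {
  ep <- character(0)
  if (gene %in% c("HLA-A", "HLA-B")) {
    win <- substr(protein, rules$bw4$window_start, rules$bw4$window_end)
    if (grepl("-", win) || grepl("X", win))
      stop("untyped epitope region (gap in residues ", rules$bw4$window_start,
           "-", rules$bw4$window_end, ") for ", name)
    if (any(vapply(rules$bw4$patterns, function(p) grepl(p, win), logical(1))))
      ep <- c(ep, "Bw4")
    if (gene == "HLA-B" && name %in% rules$hla_b_c1_exceptions)
      ep <- c(ep, "C1")
    if (gene == "HLA-A") {
      grp <- sub(":.*$", "", name)
      if (grp %in% rules$a3_11_allele_groups) ep <- c(ep, "A3/11")
    }
  } else if (gene == "HLA-C") {
    aa80 <- substr(protein, rules$c1_c2_residue, rules$c1_c2_residue)
    if (aa80 %in% c("-", "X", ""))
      stop("untyped epitope region (residue ", rules$c1_c2_residue, ") for ", name)
    if (aa80 == rules$c1_aa) ep <- c(ep, "C1")
    else if (aa80 == rules$c2_aa) ep <- c(ep, "C2")
    else stop("HLA-C allotype ", name, " carries neither the C1 nor the C2 ",
              "determinant at residue ", rules$c1_c2_residue)
  } else stop("not an HLA class I gene: ", gene)
  ep
}

#' Epitope assignment for every HLA allotype of a registry
#'
#' @param registry An `allele_registry`.
#' @param rules An `epitope_rules` object.
#' @return Named list: allotype name -> epitope subset.
#' @export
assign_epitopes_registry <- function(registry, rules = read_epitope_rules()) {
  hla <- registry[grepl("^HLA-", registry$gene), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(hla))) {
    at <- allotype_name(hla$name[i])
    if (!is.null(out[[at]])) next
    out[[at]] <- assign_epitopes(hla$gene[i], at, hla$protein[i], rules)
  }
  out
}

# carried expressed allotypes of an individual's genotype, for one gene family
carried_allotypes <- function(genotype, genes, registry, null_list) {
  out <- character(0)
  for (g in intersect(genes, names(genotype))) {
    alleles <- setdiff(unique(genotype[[g]]), ABSENT)
    if (!length(alleles)) next
    rows <- registry_rows(registry, alleles)
    expressed <- rows$name[rows$expressed]
    ats <- unique(allotype_name(expressed))
    out <- c(out, setdiff(ats, null_list))
  }
  unique(out)
}

#' Count distinct viable receptor-ligand allotype pairs for one individual
#'
#' A pair (KIR allotype, HLA allotype) is viable when both are carried and
#' surface-expressed and the interaction table deems them compatible (epitope
#' match or explicit exception). Counting is at allotype resolution, on the
#' set of distinct pairs: homozygosity and phase never change the count.
#'
#' @param genotype Named list gene -> allele vector (phased or unphased).
#' @param registry An `allele_registry`.
#' @param epitopes Named list from [assign_epitopes_registry()].
#' @param table An `interaction_table`.
#' @return List of class `pair_count`: `pairs` (data frame `kir`, `hla`),
#'   `count`.
#' @export
count_functional_pairs <- function(genotype, registry, epitopes,
                                   table = read_interaction_table()) {
  kir_genes <- unique(registry$gene[grepl("^KIR", registry$gene)])
  hla_genes <- unique(registry$gene[grepl("^HLA-", registry$gene)])
  kir <- carried_allotypes(genotype, kir_genes, registry, table$kir_expression_null)
  hla <- carried_allotypes(genotype, hla_genes, registry, table$hla_expression_null)
  missing <- setdiff(hla, names(epitopes))
  if (length(missing))
    stop("allotype(s) missing from epitope configuration: ",
         paste(missing, collapse = ", "))
  pairs <- data.frame(kir = character(0), hla = character(0))
  for (rule in table$rules) {
    k_here <- kir[sub("\\*.*$", "", kir) == rule$kir_gene]
    if (!length(k_here)) next
    for (h in hla) {
      viable <- length(intersect(epitopes[[h]], rule$epitopes)) > 0 ||
        h %in% rule$hla_exceptions
      if (viable) pairs <- rbind(pairs, expand.grid(kir = k_here, hla = h,
                                                    stringsAsFactors = FALSE))
    }
  }
  pairs <- unique(pairs)
  structure(list(pairs = pairs, count = nrow(pairs)), class = "pair_count")
}

#' @export
print.pair_count <- function(x, ...) {
  cat("<functional pairs> count =", x$count, "\n")
  if (x$count) print.data.frame(x$pairs, row.names = FALSE)
  invisible(x)
}

#' Distribution of functional pair counts over a cohort
#'
#' Per-individual distinct viable receptor-ligand pair counts, with mean,
#' 95% empirical interval and histogram. Counting is phase-independent, so
#' the cohort may be phased or unphased.
#'
#' @param cohort A `kir_cohort`.
#' @param epitopes Named epitope list (default: derived from the cohort's
#'   registry with the shipped rules).
#' @param table An `interaction_table`.
#' @return Object of class `pair_distribution`: `counts` (named per
#'   individual), `mean`, `interval` (2.5% and 97.5% empirical quantiles),
#'   `histogram`.
#' @export
cohort_pair_distribution <- function(cohort,
                                     epitopes = assign_epitopes_registry(cohort$registry),
                                     table = read_interaction_table()) {
  ids <- cohort$individuals$id
  counts <- vapply(ids, function(id)
    count_functional_pairs(cohort$genotypes[[id]], cohort$registry, epitopes,
                           table)$count, numeric(1))
  structure(list(counts = counts, mean = mean(counts),
                 interval = unname(quantile(counts, c(0.025, 0.975), type = 1)),
                 histogram = table(factor(counts, levels = 0:max(counts, 1)))),
            class = "pair_distribution")
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("<pair distribution> n = %d individuals, mean = %.2f, 95%% interval [%d, %d]\n",
              length(x$counts), x$mean, x$interval[1], x$interval[2]))
  print(x$histogram)
  invisible(x)
}
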