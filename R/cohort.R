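#' Cohort genotype tables
#'
#' A cohort holds per-individual, per-gene unphased allele multisets (with the
#' reserved `ABSENT` state for missing genes), optional mother links for
#' mother-child pairs, the allele sequence registry, and the locus models.
#'
#' `load_cohort()` reads the on-disk representation: a genotype TSV with header
#' `individual_id  mother_id  gene  allele_1  allele_2[  allele_3 ...]`
#' (mother_id `"."` for none) plus the registry FASTA. Every referenced allele
#' must exist in the registry; mother ids must resolve within the cohort.
#'
#' @param genotype_table Path to the genotype TSV.
#' @param alleles Path to the allele registry FASTA.
#' @param models Named list of `locus_model`s (default [default_locus_models()]).
#' @param quiet Suppress the load summary message.
#' @return An object of class `kir_cohort`.
#' @export
load_cohort <- function(genotype_table, alleles, models = default_locus_models(),
                        quiet = FALSE) {
  registry <- read_allele_registry(alleles, models)
  tab <- read.delim(genotype_table, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("individual_id", "mother_id", "gene", "allele_1", "allele_2")
  if (!all(need %in% names(tab)))
    stop("genotype table must have columns: ", paste(need, collapse = ", "))
  allele_cols <- grep("^allele_", names(tab), value = TRUE)

  ids <- unique(tab$individual_id)
  genotypes <- vector("list", length(ids)); names(genotypes) <- ids
  mothers <- setNames(rep(NA_character_, length(ids)), ids)
  for (id in ids) {
    rows <- tab[tab$individual_id == id, , drop = FALSE]
    if (anyDuplicated(rows$gene))
      stop("duplicated individual id/gene rows for '", id, "'")
    mid <- unique(rows$mother_id)
    if (length(mid) != 1L)
      stop("individual '", id, "': conflicting mother_id entries")
    mothers[[id]] <- if (mid == ".") NA_character_ else mid
    g <- lapply(seq_len(nrow(rows)), function(i) {
      v <- unlist(rows[i, allele_cols], use.names = FALSE)
      v <- v[!is.na(v) & nzchar(v)]
      v
    })
    names(g) <- rows$gene
    genotypes[[id]] <- g
  }
  new_cohort(ids, mothers, genotypes, registry, models,
             provenance = list(genotype_table = genotype_table, alleles = alleles),
             quiet = quiet)
}

new_cohort <- function(ids, mothers, genotypes, registry, models,
                       provenance = list(), quiet = TRUE) {
  cohort <- structure(
    list(individuals = data.frame(id = ids, mother_id = unname(mothers[ids]),
                                  stringsAsFactors = FALSE),
         genotypes = genotypes[ids],
         registry = registry,
         models = models,
         provenance = provenance),
    class = "kir_cohort")
  validate_cohort(cohort)
  if (!quiet) {
    n_pairs <- sum(!is.na(cohort$individuals$mother_id))
    message("cohort: ", length(ids), " individuals (", n_pairs, " with sampled mother); ",
            nrow(registry), " registry alleles")
  }
  cohort
}

validate_cohort <- function(cohort) {
  ind <- cohort$individuals
  if (anyDuplicated(ind$id)) stop("duplicated individual id: ",
                                  ind$id[duplicated(ind$id)][1])
  known_mothers <- ind$mother_id[!is.na(ind$mother_id)]
  missing <- setdiff(known_mothers, ind$id)
  if (length(missing)) stop("mother id(s) not in cohort: ", paste(missing, collapse = ", "))
  all_genes <- unlist(lapply(cohort$models, `[[`, "genes"))
  for (id in ind$id) {
    g <- cohort$genotypes[[id]]
    bad <- setdiff(names(g), all_genes)
    if (length(bad)) stop("individual '", id, "': unknown gene(s) ",
                          paste(bad, collapse = ", "))
    for (gene in names(g)) {
      alleles <- setdiff(g[[gene]], ABSENT)
      if (length(g[[gene]]) < 2L)
        stop("individual '", id, "', gene ", gene, ": fewer than 2 allele slots")
      unknown <- setdiff(alleles, cohort$registry$name[cohort$registry$gene == gene])
      if (length(unknown)) stop("unknown allele '", unknown[1], "' for gene ", gene,
                                " (individual '", id, "')")
    }
  }
  invisible(cohort)
}

#' Write a cohort's genotype table and registry to disk
#'
#' Inverse of [load_cohort()]; `load_cohort()` of the written files reproduces
#' the cohort field-for-field.
#'
#' @param cohort A `kir_cohort`.
#' @param genotype_table,alleles Output paths (TSV, FASTA).
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, genotype_table, alleles) {
  rows <- list()
  for (id in cohort$individuals$id) {
    mid <- cohort$individuals$mother_id[cohort$individuals$id == id]
    g <- cohort$genotypes[[id]]
    for (gene in names(g)) {
      v <- g[[gene]]
      row <- c(individual_id = id, mother_id = if (is.na(mid)) "." else mid, gene = gene,
               setNames(v, paste0("allele_", seq_along(v))))
      rows[[length(rows) + 1L]] <- row
    }
  }
  ncol_max <- max(vapply(rows, length, integer(1)))
  mat <- t(vapply(rows, function(r) c(r, rep(NA_character_, ncol_max - length(r))),
                  character(ncol_max)))
  colnames(mat) <- c("individual_id", "mother_id", "gene",
                     paste0("allele_", seq_len(ncol_max - 3L)))
  write.table(mat, genotype_table, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  write_allele_registry(cohort$registry, alleles)
  invisible(c(genotype_table = genotype_table, alleles = alleles))
}

#' @export
print.kir_cohort <- function(x, ...) {
  n_pairs <- sum(!is.na(x$individuals$mother_id))
  cat("<cohort> ", nrow(x$individuals), " individuals; ", n_pairs,
      " mother-child pairs; ", nrow(x$registry), " registry alleles\n", sep = "")
  invisible(x)
}

#' @export
summary.kir_cohort <- function(object, ...) {
  per_gene <- table(object$registry$gene)
  cat("Cohort of", nrow(object$individuals), "individuals\n")
  cat("  mother-child pairs:", sum(!is.na(object$individuals$mother_id)), "\n")
  cat("  alleles per gene:\n")
  for (g in names(per_gene)) cat("    ", g, ": ", per_gene[[g]], "\n", sep = "")
  invisible(object)
}

# individuals that are nobody's mother ("children" + unrelated); the census
# default set
cohort_children <- function(cohort) {
  setdiff(cohort$individuals$id, cohort$individuals$mother_id)
}

# genes of one locus in model order, for an individual's genotype
locus_genotype <- function(cohort, id, locus) {
  genes <- cohort$models[[locus]]$genes
  g <- cohort$genotypes[[id]]
  g[intersect(genes, names(g))]
}
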