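#' Allele sequence registries
#'
#' A registry holds one row per allele: gene, nomenclature name, aligned coding
#' sequence (IUPAC plus `-` gaps, in the gene's alignment frame, ATG = 1), the
#' surface-expression flag, and the derived mature-protein sequence. Proteins
#' are derived deterministically from the CDS by codon translation followed by
#' removal of the gene's leader peptide, so residue numbers are mature-protein,
#' 1-based.
#'
#' @param path Path to a gapped multi-FASTA with headers
#'   `>GENE*NAME expressed=0|1`.
#' @param models Named list of `locus_model` objects (see
#'   [default_locus_models()]).
#' @return A data frame of class `allele_registry` with columns `gene`, `name`,
#'   `expressed`, `cds`, `protein`.
#' @export
read_allele_registry <- function(path, models) {
  seqs <- Biostrings::readBStringSet(path)
  hdr <- names(seqs)
  name <- sub("\\s.*$", "", hdr)
  expr_field <- regmatches(hdr, regexpr("expressed=[01]", hdr))
  if (length(expr_field) != length(hdr))
    stop("registry FASTA: every header needs an 'expressed=0|1' field")
  expressed <- expr_field == "expressed=1"
  gene <- vapply(name, allele_gene, character(1), models = models, USE.NAMES = FALSE)
  new_allele_registry(data.frame(gene = gene, name = name, expressed = expressed,
                                 cds = as.character(seqs), stringsAsFactors = FALSE),
                      models)
}

new_allele_registry <- function(df, models) {
  stopifnot(all(c("gene", "name", "expressed", "cds") %in% names(df)))
  for (i in seq_len(nrow(df))) {
    g <- df$gene[i]
    m <- models[[gene_locus(g, models)]]
    if (nchar(df$cds[i]) != m$aln_len[[g]])
      stop("allele ", df$name[i], ": cds length ", nchar(df$cds[i]),
           " != alignment length ", m$aln_len[[g]], " for gene ", g)
  }
  # equal cds within a gene must mean equal name (an allele IS its sequence)
  for (g in unique(df$gene)) {
    sub <- df[df$gene == g, ]
    by_cds <- split(sub$name, sub$cds)
    clash <- by_cds[vapply(by_cds, function(v) length(unique(v)) > 1L, logical(1))]
    if (length(clash))
      stop("gene ", g, ": identical cds under different allele names (",
           paste(unlist(clash), collapse = ", "), ")")
  }
  df$protein <- vapply(seq_len(nrow(df)), function(i) {
    g <- df$gene[i]
    m <- models[[gene_locus(g, models)]]
    translate_cds(df$cds[i], m$leader_aa[[g]])
  }, character(1))
  structure(df, class = c("allele_registry", "data.frame"), models = models)
}

#' Write an allele registry as gapped multi-FASTA
#'
#' @param registry An `allele_registry`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_allele_registry <- function(registry, path) {
  seqs <- Biostrings::BStringSet(setNames(
    registry$cds, paste0(registry$name, " expressed=", as.integer(registry$expressed))))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

# translate a gapped CDS to the mature protein (leader residues removed).
# Codons that are all-gap translate to '-' (gene-absence / indel frame);
# codons mixing gaps and bases, or containing ambiguity codes, give 'X'.
translate_cds <- function(cds, leader_aa) {
  n <- nchar(cds)
  stopifnot(n %% 3L == 0L)
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  code <- Biostrings::GENETIC_CODE
  aa <- vapply(codons, function(cd) {
    cdu <- toupper(cd)
    if (cdu == "---") return("-")
    if (grepl("-", cdu)) return("X")
    v <- code[cdu]
    if (is.na(v)) "X" else unname(v)
  }, character(1), USE.NAMES = FALSE)
  paste(aa[-seq_len(leader_aa)], collapse = "")
}

#' @export
print.allele_registry <- function(x, ...) {
  cat("<allele registry> ", nrow(x), " alleles over ",
      length(unique(x$gene)), " genes\n", sep = "")
  tab <- table(x$gene)
  cat(paste0("  ", names(tab), ": k=", as.integer(tab)), sep = "\n")
  invisible(x)
}

# look up registry rows for a character vector of allele names (no ABSENT)
registry_rows <- function(registry, names) {
  idx <- match(names, registry$name)
  if (anyNA(idx))
    stop("unknown allele name(s): ", paste(names[is.na(idx)], collapse = ", "))
  registry[idx, , drop = FALSE]
}
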