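#' Gapped concatenated coding sequences of census haplotypes
#'
#' Concatenates each haplotype's per-gene aligned coding sequences in locus
#' order; absent genes contribute all-gap segments, so gene content enters the
#' alignment as runs of gaps (the convention used for haplotype networks and
#' mismatch analysis).
#'
#' @param census A `haplotype_census`.
#' @param registry The `allele_registry`.
#' @param model The matching `locus_model`.
#' @param expand With `expand = TRUE` each haplotype appears once per census
#'   count (a 2N-row alignment); otherwise one sequence per distinct haplotype.
#' @return Named character vector of aligned sequences.
#' @export
haplotype_concat_sequences <- function(census, registry, model, expand = FALSE) {
  haps <- attr(census, "haplotypes")
  seq_of <- function(h) {
    paste(vapply(model$genes, function(g) {
      if (h[[g]] == ABSENT) strrep("-", model$aln_len[[g]])
      else registry$cds[match(h[[g]], registry$name)]
    }, character(1)), collapse = "")
  }
  seqs <- vapply(haps, seq_of, character(1))
  names(seqs) <- census$haplotype
  if (expand) seqs <- rep(seqs, census$count)
  seqs
}

#' Per-gene aligned allele sequences of the census haplotype set
#'
#' One sequence per haplotype copy carrying the gene (absent copies dropped),
#' for per-gene selection statistics such as Tajima's D.
#'
#' @inheritParams haplotype_concat_sequences
#' @param gene Gene name.
#' @return Character vector of aligned sequences (possibly empty).
#' @export
census_gene_sequences <- function(census, registry, model, gene) {
  haps <- attr(census, "haplotypes")
  alleles <- rep(vapply(haps, function(h) h[[gene]], character(1)), census$count)
  alleles <- alleles[alleles != ABSENT]
  registry$cds[match(alleles, registry$name)]
}

#' Per-gene allele (or allotype) frequency spectrum from a census
#'
#' Counts allele copies at one gene over the census haplotype set; the ABSENT
#' state can be included as a class of its own or dropped.
#'
#' @inheritParams census_gene_sequences
#' @param resolution `"allele"` or `"allotype"`.
#' @param include_absent Count ABSENT as a class.
#' @return A `freq_spectrum` (NULL when the gene is absent from every copy).
#' @export
census_gene_spectrum <- function(census, gene, resolution = c("allele", "allotype"),
                                 include_absent = FALSE) {
  resolution <- match.arg(resolution)
  haps <- attr(census, "haplotypes")
  alleles <- rep(vapply(haps, function(h) h[[gene]], character(1)), census$count)
  if (!include_absent) alleles <- alleles[alleles != ABSENT]
  if (!length(alleles)) return(NULL)
  if (resolution == "allotype") alleles <- allotype_name(alleles)
  tab <- sort(table(alleles), decreasing = TRUE)
  sp <- freq_spectrum(as.integer(tab), label = paste0(gene, " (", resolution, ")"))
  names(sp$counts) <- names(tab)
  sp
}

#' Allotype table (name, protein, count) at one gene of a census
#'
#' The input [motif_project()] expects: distinct allotypes of the gene with
#' their census counts and protein sequences.
#'
#' @inheritParams census_gene_sequences
#' @return Data frame with `name`, `protein`, `count` (NULL if gene absent
#'   everywhere).
#' @export
census_gene_allotypes <- function(census, registry, model, gene) {
  sp <- census_gene_spectrum(census, gene, resolution = "allotype")
  if (is.null(sp)) return(NULL)
  names_at <- names(sp$counts)
  # representative protein per allotype: first registry allele collapsing to it
  prot <- vapply(names_at, function(at) {
    cand <- registry[registry$gene == gene, ]
    hit <- cand$protein[allotype_name(cand$name) == at]
    hit[1]
  }, character(1))
  data.frame(name = names_at, protein = unname(prot),
             count = as.integer(sp$counts), stringsAsFactors = FALSE)
}
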