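#' Locus models
#'
#' A locus model fixes the gene order of a locus, which genes are framework
#' (present on every haplotype), each gene's alignment length, the
#' leader-peptide length used to convert coding sequence to mature-protein
#' numbering, and the allele-name prefix that maps names to genes. For the KIR
#' locus it also records the centromeric/telomeric boundary used by the
#' transmission model.
#'
#' @param path Path to a locus-model JSON file.
#' @return An object of class `locus_model`.
#' @seealso [default_locus_models()]
#' @export
read_locus_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_locus_model(x)
}

new_locus_model <- function(x) {
  stopifnot(!is.null(x$id), !is.null(x$genes))
  m <- structure(
    list(id = x$id,
         genes = as.character(x$genes),
         framework = setNames(as.logical(x$framework), x$genes),
         aln_len = setNames(as.integer(x$aln_len), x$genes),
         leader_aa = setNames(as.integer(x$leader_aa), x$genes),
         name_prefix = setNames(as.character(x$name_prefix), x$genes),
         cen_tel_boundary_after = x$cen_tel_boundary_after %||% NA_character_),
    class = "locus_model")
  validate_locus_model(m)
}

validate_locus_model <- function(m) {
  if (anyDuplicated(m$genes)) stop("locus model '", m$id, "': duplicated gene ids")
  if (anyDuplicated(m$name_prefix)) stop("locus model '", m$id, "': duplicated name prefixes")
  if (any(m$aln_len %% 3L != 0L))
    stop("locus model '", m$id, "': alignment lengths must be codon multiples")
  m
}

#' @export
print.locus_model <- function(x, ...) {
  cat("<locus model> ", x$id, ": ", length(x$genes), " genes (",
      sum(x$framework), " framework)\n  ", paste(x$genes, collapse = " - "), "\n", sep = "")
  invisible(x)
}

#' Built-in KIR-like and HLA class I locus models
#'
#' The KIR model carries seven gene slots in map order with framework genes
#' KIR3DL3, KIR2DL4 and KIR3DL2 and the cen/tel boundary after KIR2DL1;
#' KIR2DL2 and KIR2DL3 occupy mutually exclusive slots (a haplotype carries
#' one, the other is ABSENT), reproducing their behaviour as alternatives at a
#' single locus. The HLA model carries HLA-A, -B and -C, all framework.
#'
#' @return Named list of two `locus_model` objects, `KIR` and `HLA`.
#' @export
default_locus_models <- function() {
  kir <- read_locus_model(system.file("extdata", "kir_locus.json", package = "kirhla"))
  hla <- read_locus_model(system.file("extdata", "hla_locus.json", package = "kirhla"))
  list(KIR = kir, HLA = hla)
}

# map an allele name to its gene via the locus models' name prefixes
allele_gene <- function(name, models) {
  prefix <- sub("\\*.*$", "", name)
  for (m in models) {
    hit <- names(m$name_prefix)[m$name_prefix == prefix]
    if (length(hit) == 1L) return(hit)
  }
  stop("allele name '", name, "' matches no gene in the locus models")
}

# which locus model owns a gene
gene_locus <- function(gene, models) {
  for (nm in names(models)) if (gene %in% models[[nm]]$genes) return(nm)
  stop("gene '", gene, "' not in any locus model")
}
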