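#' Parse a KIR allele name
#'
#' KIR alleles are written `<gene>*<digits>`: the first three digits identify
#' the allotype (unique protein), and an optional further two digits identify
#' synonymous variants of that allotype. `KIR3DL1*01501` and `KIR3DL1*01502`
#' are synonymous variants of the `KIR3DL1*015` allotype.
#'
#' @param s Character scalar, e.g. `"KIR3DL1*01502"` or `"KIR2DL4*013"`.
#' @return An object of class `kir_allele_name`: a list with `gene`,
#'   `allotype_digits` (3-character string) and `synonymous_digits`
#'   (2-character string or `NA`).
#' @examples
#' parse_kir_allele_name("KIR3DL1*01502")
#' format(parse_kir_allele_name("KIR2DL4*013"))
#' @export
parse_kir_allele_name <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  m <- regmatches(s, regexec("^(KIR[0-9]D[LSP][0-9][A-B]?)\\*([0-9]+)$", s))[[1]]
  if (length(m) == 0L) {
    if (!grepl("\\*", s))
      stop("malformed KIR allele name '", s, "': missing '*' separator", call. = FALSE)
    if (!grepl("^KIR[0-9]D[LSP][0-9][A-B]?\\*", s))
      stop("malformed KIR allele name '", s, "': unrecognised gene field", call. = FALSE)
    stop("malformed KIR allele name '", s, "': digit field must be numeric", call. = FALSE)
  }
  digits <- m[3]
  if (!nchar(digits) %in% c(3L, 5L))
    stop("malformed KIR allele name '", s,
         "': digit field must have 3 (allotype) or 5 (allotype+synonymous) digits",
         call. = FALSE)
  structure(
    list(gene = m[2],
         allotype_digits = substr(digits, 1L, 3L),
         synonymous_digits = if (nchar(digits) == 5L) substr(digits, 4L, 5L) else NA_character_),
    class = "kir_allele_name")
}

#' @method format kir_allele_name
#' @export
format.kir_allele_name <- function(x, ...) {
  syn <- if (is.na(x$synonymous_digits)) "" else x$synonymous_digits
  paste0(x$gene, "*", x$allotype_digits, syn)
}

#' @export
print.kir_allele_name <- function(x, ...) {
  cat("<KIR allele> ", format(x), "  [allotype ", x$gene, "*", x$allotype_digits, "]\n",
      sep = "")
  invisible(x)
}

#' Parse a KIR haplotype gene-content motif name
#'
#' KIR haplotypes divide into centromeric (`c`) and telomeric (`t`) segments of
#' group `A` or `B`. Two digits identify the gene-content motif (`cA01`,
#' `tB04`, ...); two optional colon-separated 3-digit fields distinguish motifs
#' of identical gene content differing by non-synonymous, respectively only
#' synonymous/non-coding, variation.
#'
#' @param s Character scalar, e.g. `"cA01"` or `"cB01:001:002"`.
#' @return An object of class `kir_motif_name` with fields `region`
#'   (`"centromeric"`/`"telomeric"`), `group` (`"A"`/`"B"`), `content_digits`,
#'   `nonsyn_digits`, `syn_digits` (the latter two `NA` when absent).
#' @examples
#' parse_motif_name("tB04")
#' format(parse_motif_name("cB01:001:002"))
#' @export
parse_motif_name <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  m <- regmatches(s, regexec("^([ct])([AB])([0-9]{2})(:([0-9]{3})(:([0-9]{3}))?)?$", s))[[1]]
  if (length(m) == 0L)
    stop("malformed motif name '", s,
         "': expected [ct][AB]<2 digits>[:<3 digits>[:<3 digits>]]", call. = FALSE)
  structure(
    list(region = if (m[2] == "c") "centromeric" else "telomeric",
         group = m[3],
         content_digits = m[4],
         nonsyn_digits = if (nzchar(m[6])) m[6] else NA_character_,
         syn_digits = if (nzchar(m[8])) m[8] else NA_character_),
    class = "kir_motif_name")
}

#' @method format kir_motif_name
#' @export
format.kir_motif_name <- function(x, ...) {
  out <- paste0(if (x$region == "centromeric") "c" else "t", x$group, x$content_digits)
  if (!is.na(x$nonsyn_digits)) {
    out <- paste0(out, ":", x$nonsyn_digits)
    if (!is.na(x$syn_digits)) out <- paste0(out, ":", x$syn_digits)
  }
  out
}

#' @export
print.kir_motif_name <- function(x, ...) {
  cat("<KIR motif> ", format(x), " (", x$region, ", group ", x$group, ")\n", sep = "")
  invisible(x)
}

#' Parse an HLA allele name (modern colon-delimited convention)
#'
#' Only the first two fields (allele group : specific protein) are required;
#' two-field names already identify the allotype.
#'
#' @param s Character scalar, e.g. `"B*53:01"`.
#' @return List with `gene` (e.g. `"HLA-B"`), `field1`, `field2`.
#' @export
parse_hla_allele_name <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  m <- regmatches(s, regexec("^(HLA-)?([A-C])\\*([0-9]{2,3}):([0-9]{2,3})$", s))[[1]]
  if (length(m) == 0L)
    stop("malformed HLA allele name '", s, "': expected <locus>*<2-3 digits>:<2-3 digits>",
         call. = FALSE)
  list(gene = paste0("HLA-", m[3]), field1 = m[4], field2 = m[5])
}

#' Collapse an allele name to its allotype name
#'
#' KIR alleles drop the synonymous (4th-5th) digits; HLA two-field names are
#' already at allotype resolution; the reserved `ABSENT` state passes through.
#'
#' @param name Character vector of allele names.
#' @return Character vector of allotype names.
#' @examples
#' allotype_name(c("KIR3DL1*01502", "B*53:01", "ABSENT"))
#' @export
allotype_name <- function(name) {
  vapply(name, function(s) {
    if (s == ABSENT) return(s)
    if (grepl("^KIR", s)) {
      p <- parse_kir_allele_name(s)
      return(paste0(p$gene, "*", p$allotype_digits))
    }
    s
  }, character(1), USE.NAMES = FALSE)
}
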