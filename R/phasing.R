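# A haplotype over one locus is a named character vector (one allele per gene,
# in model order, ABSENT allowed). The key string is its canonical identity.
hap_key <- function(h) paste(h, collapse = "|")

hap_from_key <- function(key, model) {
  setNames(strsplit(key, "|", fixed = TRUE)[[1]], model$genes)
}

# order the genotype's allele slots into model order; every gene must have
# exactly two slots for phasing
normalize_genotype <- function(geno, model) {
  g <- lapply(model$genes, function(gene) {
    v <- geno[[gene]]
    if (is.null(v)) stop("genotype missing gene ", gene)
    if (length(v) != 2L)
      stop("gene ", gene, ": phasing requires exactly 2 allele slots, got ", length(v))
    sort(v)
  })
  names(g) <- model$genes
  g
}

# all unordered splits of a genotype into two haplotypes; each split is a list
# of two named vectors, canonicalised so hap1 key <= hap2 key
enumerate_splits <- function(geno, model) {
  geno <- normalize_genotype(geno, model)
  het <- vapply(geno, function(v) v[1] != v[2], logical(1))
  n_het <- sum(het)
  if (n_het > 20L) stop("too many heterozygous genes to enumerate (", n_het, ")")
  n_comb <- if (n_het == 0L) 1L else 2L^(n_het - 1L)  # fix first het gene to kill mirror
  splits <- vector("list", n_comb)
  het_genes <- names(geno)[het]
  for (s in seq_len(n_comb)) {
    bits <- if (n_het > 1L) as.integer(intToBits(s - 1L))[seq_len(n_het - 1L)] else integer(0)
    pick <- c(0L, bits)  # first het gene always takes slot 1 on hap1
    h1 <- vapply(model$genes, function(g) {
      if (!het[[g]]) geno[[g]][1] else geno[[g]][1 + pick[match(g, het_genes)]]
    }, character(1))
    h2 <- vapply(model$genes, function(g) {
      if (!het[[g]]) geno[[g]][2] else geno[[g]][2 - pick[match(g, het_genes)]]
    }, character(1))
    if (hap_key(h2) < hap_key(h1)) { tmp <- h1; h1 <- h2; h2 <- tmp }
    splits[[s]] <- list(h1 = h1, h2 = h2)
  }
  splits
}

# is haplotype h drawable from (contained gene-wise in) genotype geno?
hap_contained <- function(h, geno) {
  all(vapply(names(h), function(g) h[[g]] %in% geno[[g]], logical(1)))
}

#' Segregation phasing of one mother-child pair
#'
#' Enumerates all splits of the child's genotype into two gene-wise-consistent
#' haplotypes and keeps those where at least one side could have been
#' transmitted by the mother (is gene-wise contained in the mother's
#' genotype). If exactly one split survives the child is segregation-resolved.
#' The ABSENT state participates as an ordinary allele. Ambiguous children
#' (several surviving splits) are left for the EM phaser.
#'
#' @param mother,child Genotypes: named lists (gene -> 2 alleles) over the
#'   locus model's genes.
#' @param model A `locus_model`.
#' @return List with `resolution` (`"segregation"` or `"unresolved"`),
#'   `h1`, `h2` (canonical order), `maternal` (1 or 2, which haplotype is
#'   maternal; NA if ambiguous), and `splits` (surviving splits when
#'   unresolved).
#' @export
segregation_phase <- function(mother, child, model) {
  mother <- normalize_genotype(mother, model)
  splits <- enumerate_splits(child, model)
  surv <- list()
  for (sp in splits) {
    c1 <- hap_contained(sp$h1, mother)
    c2 <- hap_contained(sp$h2, mother)
    if (c1 || c2) surv[[length(surv) + 1L]] <- c(sp, list(m1 = c1, m2 = c2))
  }
  if (!length(surv)) {
    child_n <- normalize_genotype(child, model)
    bad <- model$genes[vapply(model$genes, function(g)
      !any(child_n[[g]] %in% mother[[g]]), logical(1))]
    stop("Mendelian inconsistency between mother and child at gene ",
         paste(bad, collapse = ", "))
  }
  if (length(surv) == 1L) {
    sp <- surv[[1L]]
    maternal <- if (sp$m1 && sp$m2) NA_integer_ else if (sp$m1) 1L else 2L
    list(resolution = "segregation", h1 = sp$h1, h2 = sp$h2, maternal = maternal)
  } else {
    list(resolution = "unresolved", h1 = NULL, h2 = NULL, maternal = NA_integer_,
         splits = surv)
  }
}

#' EM haplotype-frequency phasing
#'
#' Standard multi-locus haplotype-frequency EM over the set of haplotypes
#' consistent with the sample, with prior counts (typically the
#' segregation-deduced haplotype census) entering every M-step as
#' pseudo-counts. Each individual is then assigned its maximum-posterior
#' phase; ties break to the lexicographically smallest haplotype pair. The
#' log-likelihood is non-decreasing across iterations.
#'
#' @param genotypes Named list (individual id -> genotype) of unphased
#'   genotypes over one locus.
#' @param model A `locus_model`.
#' @param priors Optional named numeric vector of prior haplotype counts
#'   (names are haplotype keys), or a `haplotype_census`.
#' @param prior_weight Multiplier on the prior counts (default 1: observed
#'   segregation counts enter at face value).
#' @param max_iter,tol EM stopping controls.
#' @return List per individual: `h1`, `h2`, `resolution = "em"`, plus
#'   attributes `freqs` (final haplotype frequencies) and `loglik` (trace).
#' @export
em_phase <- function(genotypes, model, priors = NULL, prior_weight = 1,
                     max_iter = 500L, tol = 1e-8) {
  if (inherits(priors, "haplotype_census"))
    priors <- setNames(priors$count, priors$haplotype)
  splits <- lapply(genotypes, enumerate_splits, model = model)
  keys <- unique(c(unlist(lapply(splits, function(ss)
    unlist(lapply(ss, function(sp) c(hap_key(sp$h1), hap_key(sp$h2)))))),
    names(priors)))
  if (!length(keys)) stop("no haplotypes consistent with the sample")
  prior_counts <- setNames(numeric(length(keys)), keys)
  if (!is.null(priors)) prior_counts[names(priors)] <- priors * prior_weight
  # split index structures
  idx <- lapply(splits, function(ss) {
    t(vapply(ss, function(sp) c(match(hap_key(sp$h1), keys),
                                match(hap_key(sp$h2), keys)), integer(2)))
  })
  n_ind <- length(genotypes)
  freqs <- setNames(rep(1 / length(keys), length(keys)), keys)
  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    exp_counts <- setNames(numeric(length(keys)), keys)
    ll <- 0
    for (i in seq_len(n_ind)) {
      m <- idx[[i]]
      w <- freqs[m[, 1L]] * freqs[m[, 2L]] * ifelse(m[, 1L] == m[, 2L], 1, 2)
      tw <- sum(w)
      if (tw <= 0) {
        # fallback: uniform over this individual's splits
        w <- rep(1, nrow(m)); tw <- nrow(m)
      }
      ll <- ll + log(tw)
      w <- w / tw
      for (s in seq_len(nrow(m))) {
        exp_counts[m[s, 1L]] <- exp_counts[m[s, 1L]] + w[s]
        exp_counts[m[s, 2L]] <- exp_counts[m[s, 2L]] + w[s]
      }
    }
    loglik <- c(loglik, ll)
    new_freqs <- (exp_counts + prior_counts) / sum(exp_counts + prior_counts)
    done <- it > 1L && (loglik[it] - loglik[it - 1L]) < tol
    freqs <- new_freqs
    if (done) break
  }
  out <- vector("list", n_ind)
  names(out) <- names(genotypes)
  for (i in seq_len(n_ind)) {
    m <- idx[[i]]
    w <- freqs[m[, 1L]] * freqs[m[, 2L]] * ifelse(m[, 1L] == m[, 2L], 1, 2)
    pair_keys <- paste(keys[m[, 1L]], keys[m[, 2L]], sep = " / ")
    best <- which(w == max(w))
    if (length(best) > 1L) best <- best[order(pair_keys[best])][1L]
    sp <- splits[[i]][[best]]
    out[[i]] <- list(h1 = sp$h1, h2 = sp$h2, resolution = "em",
                     maternal = NA_integer_)
  }
  attr(out, "freqs") <- freqs
  attr(out, "loglik") <- loglik
  out
}

#' Phase a cohort: segregation in mother-child pairs, EM for the rest
#'
#' Children with a sampled mother are phased by segregation; mothers are then
#' phased from the transmitted haplotype (their second haplotype is the
#' gene-wise complement of the transmitted one). Individuals left ambiguous by
#' segregation, and unrelated individuals, are phased by EM using the
#' segregation-deduced haplotype counts as prior pseudo-counts.
#'
#' @param cohort A `kir_cohort`.
#' @param loci Character vector of locus names (default: all models).
#' @param prior_weight Passed to [em_phase()].
#' @return Object of class `phased_cohort`: the cohort plus `$phased`, a list
#'   `locus -> individual id -> (h1, h2, resolution, maternal)`.
#' @export
phase_cohort <- function(cohort, loci = names(cohort$models), prior_weight = 1) {
  phased <- list()
  for (locus in loci) {
    model <- cohort$models[[locus]]
    ids <- cohort$individuals$id
    mothers <- setNames(cohort$individuals$mother_id, ids)
    res <- vector("list", length(ids)); names(res) <- ids
    seg_counts <- list()
    # pass 1: segregation for children with sampled mothers
    for (id in ids) {
      mid <- mothers[[id]]
      if (is.na(mid)) next
      sp <- segregation_phase(locus_genotype(cohort, mid, locus),
                              locus_genotype(cohort, id, locus), model)
      if (sp$resolution == "segregation") {
        res[[id]] <- sp
        for (k in c(hap_key(sp$h1), hap_key(sp$h2)))
          seg_counts[[k]] <- (seg_counts[[k]] %||% 0) + 1
      }
    }
    # pass 2: EM for everything unresolved that is not a mother
    need_em <- ids[vapply(ids, function(id)
      is.null(res[[id]]) && !(id %in% mothers), logical(1))]
    if (length(need_em)) {
      genos <- lapply(need_em, function(id) locus_genotype(cohort, id, locus))
      names(genos) <- need_em
      em <- em_phase(genos, model, priors = unlist(seg_counts),
                     prior_weight = prior_weight)
      for (id in need_em) res[[id]] <- em[[id]]
    }
    # pass 3: mothers from the transmitted haplotype
    for (id in ids) {
      mid <- mothers[[id]]
      if (is.na(mid) || !is.null(res[[mid]])) next
      child <- res[[id]]
      if (is.null(child)) next
      mgeno <- normalize_genotype(locus_genotype(cohort, mid, locus), model)
      mat_idx <- child$maternal
      if (is.na(mat_idx)) {
        cand <- Filter(function(k) hap_contained(child[[k]], mgeno), c("h1", "h2"))
        mat_idx <- if (length(cand)) match(cand[[1L]], c("h1", "h2")) else NA_integer_
      }
      if (is.na(mat_idx)) next  # child EM phase inconsistent with mother; leave to EM
      transmitted <- child[[c("h1", "h2")[mat_idx]]]
      other <- vapply(model$genes, function(g) {
        pair <- mgeno[[g]]
        if (pair[1] == transmitted[[g]]) pair[2] else pair[1]
      }, character(1))
      h1 <- transmitted; h2 <- other
      if (hap_key(h2) < hap_key(h1)) { tmp <- h1; h1 <- h2; h2 <- tmp }
      res[[mid]] <- list(resolution = "segregation", h1 = h1, h2 = h2,
                         maternal = NA_integer_,
                         transmitted_key = hap_key(transmitted))
    }
    # pass 4: any mother still unresolved (child ambiguous + EM couldn't anchor)
    leftover <- ids[vapply(ids, function(id) is.null(res[[id]]), logical(1))]
    if (length(leftover)) {
      genos <- lapply(leftover, function(id) locus_genotype(cohort, id, locus))
      names(genos) <- leftover
      em <- em_phase(genos, model, priors = unlist(seg_counts),
                     prior_weight = prior_weight)
      for (id in leftover) res[[id]] <- em[[id]]
    }
    phased[[locus]] <- res
  }
  out <- cohort
  out$phased <- phased
  class(out) <- c("phased_cohort", class(cohort))
  out
}

#' Haplotype census of a phased cohort
#'
#' The default haplotype set takes the two haplotypes of every "child"
#' (every individual that is nobody's mother), giving 2N = 2 * n_children
#' independently segregating haplotypes. With
#' `include_maternal_nontransmitted = TRUE` each sampled mother additionally
#' contributes her non-transmitted haplotype (2N = 2 * n_children + n_pairs).
#' Counts can be taken at allele resolution or collapsed to allotype
#' resolution (synonymous variation removed).
#'
#' @param phased A `phased_cohort`.
#' @param locus Locus name.
#' @param include_maternal_nontransmitted Logical flag.
#' @param resolution `"allele"` or `"allotype"`.
#' @return Object of class `haplotype_census`: data frame `haplotype`, `count`,
#'   `freq`, with attributes `n2` (total haplotypes), `haplotypes` (named
#'   vectors), `resolution`, `locus`.
#' @export
haplotype_census <- function(phased, locus,
                             include_maternal_nontransmitted = FALSE,
                             resolution = c("allele", "allotype")) {
  resolution <- match.arg(resolution)
  stopifnot(inherits(phased, "phased_cohort"))
  model <- phased$models[[locus]]
  res <- phased$phased[[locus]]
  children <- cohort_children(phased)
  if (!length(children)) stop("empty phased set")
  haps <- list()
  for (id in children) haps <- c(haps, list(res[[id]]$h1, res[[id]]$h2))
  if (include_maternal_nontransmitted) {
    mothers <- unique(phased$individuals$mother_id)
    mothers <- mothers[!is.na(mothers)]
    for (mid in mothers) {
      r <- res[[mid]]
      if (is.null(r)) next
      tk <- r$transmitted_key
      nt <- if (!is.null(tk) && hap_key(r$h1) == tk) r$h2 else r$h1
      haps <- c(haps, list(nt))
    }
  }
  if (resolution == "allotype")
    haps <- lapply(haps, function(h) setNames(allotype_name(h), names(h)))
  keys <- vapply(haps, hap_key, character(1))
  tab <- sort(table(keys), decreasing = TRUE)
  df <- data.frame(haplotype = names(tab), count = as.integer(tab),
                   freq = as.integer(tab) / length(keys), stringsAsFactors = FALSE)
  structure(df, class = c("haplotype_census", "data.frame"),
            n2 = length(keys),
            haplotypes = lapply(df$haplotype, hap_from_key, model = model),
            resolution = resolution, locus = locus)
}

#' @export
print.haplotype_census <- function(x, ...) {
  cat("<haplotype census> ", attr(x, "locus"), " (", attr(x, "resolution"),
      " resolution): 2N = ", attr(x, "n2"), ", k = ", nrow(x), "\n", sep = "")
  print.data.frame(head(x, 10))
  if (nrow(x) > 10) cat("  ... ", nrow(x) - 10, " more\n")
  invisible(x)
}
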