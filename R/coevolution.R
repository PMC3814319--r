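# per-individual phased residue strings for a set of (gene, residue) columns.
# Returns an n x 2L character matrix: each individual's two phased strings
# concatenated in canonical (lexicographic) order, so results are independent
# of the phase representation.
phased_residue_strings <- function(phased, locus, genes, residues = NULL) {
  stopifnot(inherits(phased, "phased_cohort"))
  registry <- phased$registry
  ids <- phased$individuals$id
  res <- phased$phased[[locus]]
  cols <- list()
  for (g in genes) {
    rr <- if (is.list(residues)) residues[[g]] else residues
    if (is.null(rr)) {
      # ALL: every residue of the gene's mature protein
      model <- phased$models[[locus]]
      rr <- seq_len(model$aln_len[[g]] / 3L - model$leader_aa[[g]])
    }
    cols[[g]] <- as.integer(rr)
  }
  # per-gene lookup: allele name -> residue substring (ABSENT -> gaps)
  lut <- lapply(genes, function(g) allele_residue_lut(registry, g, cols[[g]]))
  names(lut) <- genes
  one_string <- function(h) {
    paste(vapply(genes, function(g) lut[[g]][[h[[g]]]], character(1)),
          collapse = "")
  }
  strings <- t(vapply(ids, function(id) {
    r <- res[[id]]
    sort(c(one_string(r$h1), one_string(r$h2)))
  }, character(2)))
  rownames(strings) <- ids
  strings
}

# residue substring lookup table for every allele of a gene (plus ABSENT)
allele_residue_lut <- function(registry, gene, residues) {
  rows <- which(registry$gene == gene)
  out <- vapply(rows, function(i) {
    p <- registry$protein[i]
    paste(vapply(residues, function(r) substr(p, r, r), character(1)),
          collapse = "")
  }, character(1))
  names(out) <- registry$name[rows]
  out[[ABSENT]] <- strrep("-", length(residues))
  out
}

#' Individual-by-individual p-distance matrix from phased residue genotypes
#'
#' Each individual is represented by its two phased residue strings
#' concatenated in canonical (lexicographic) order; the distance between two
#' individuals is the number of differing positions divided by the number of
#' compared positions, with pairwise deletion of positions gapped (absent
#' gene) in either individual.
#'
#' @param phased A `phased_cohort`.
#' @param locus Locus name (`"HLA"` or `"KIR"`).
#' @param genes Gene name(s) within the locus.
#' @param residues `NULL` for all residues, an integer vector applied to every
#'   gene, or a named list per gene.
#' @return Labeled symmetric numeric matrix (zero diagonal, entries in \[0,1\]).
#' @export
residue_distance_matrix <- function(phased, locus, genes, residues = NULL) {
  strings <- phased_residue_strings(phased, locus, genes, residues)
  full <- paste0(strings[, 1], strings[, 2])
  if (length(unique(full)) < 2L)
    stop("no variation in the selected residues")
  n <- length(full)
  mat <- matrix(unlist(strsplit(full, "")), nrow = n, byrow = TRUE)
  gap <- mat == "-"
  d <- matrix(0, n, n, dimnames = list(rownames(strings), rownames(strings)))
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    ok <- !gap[rest, , drop = FALSE] & matrix(!gap[i, ], length(rest),
                                              ncol(mat), byrow = TRUE)
    diff <- (mat[rest, , drop = FALSE] !=
               matrix(mat[i, ], length(rest), ncol(mat), byrow = TRUE)) & ok
    nc <- rowSums(ok)
    dv <- ifelse(nc > 0, rowSums(diff) / nc, 0)
    d[i, rest] <- dv
    d[rest, i] <- dv
  }
  d
}

#' Mantel permutation test
#'
#' z = sum over unordered pairs of A_ij * B_ij; the null distribution permutes
#' the labels of B simultaneously over rows and columns. The one-tailed upper
#' p-value uses the add-one convention: p = (1 + #\{z_perm >= z_obs\}) /
#' (1 + n_perm).
#'
#' @param A,B Labeled symmetric distance matrices over the same individuals in
#'   the same order.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return Object of class `mantel_result` with `z`, `z_std` (the
#'   permutation-standardized deviate (z - mean(z_perm)) / sd(z_perm), a
#'   scale-free measure of association), `p`, `n_perm`, `labels`.
#' @export
mantel_test <- function(A, B, n_perm = 10000L, seed = NULL) {
  if (!identical(dim(A), dim(B))) stop("matrix dimension mismatch")
  la <- rownames(A); lb <- rownames(B)
  if (!is.null(la) && !is.null(lb) && !identical(la, lb))
    stop("matrix label mismatch")
  if (!is.null(seed)) set.seed(seed)
  z <- .mantel_perm_cpp(A, B, as.integer(n_perm))
  s <- sd(z[-1])
  structure(list(z = z[1],
                 z_std = if (s > 0) (z[1] - mean(z[-1])) / s else 0,
                 p = (1 + sum(z[-1] >= z[1])) / (1 + n_perm),
                 n_perm = as.integer(n_perm), labels = la),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<Mantel> z = %.4f, p = %.4g (%d permutations)\n",
              x$z, x$p, x$n_perm))
  invisible(x)
}

#' Multiallelic linkage disequilibrium between two sites
#'
#' r-squared and D-prime as allele-frequency-weighted averages of the
#' per-allele-pair normalised disequilibria: for alleles a at site x and b at
#' site y with D_ab = p_ab - p_a p_b,
#' r2 = sum_ab p_a p_b D_ab^2 / (p_a(1-p_a) p_b(1-p_b)) and
#' D' = sum_ab p_a p_b |D_ab| / D_max(a,b). Both reduce to the classical
#' biallelic statistics.
#'
#' @param x,y State vectors over the same phased haplotypes.
#' @return List with `r2` and `dprime`.
#' @export
ld_stats <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- x != "-" & y != "-"
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("monomorphic site")
  n <- length(x)
  pa <- table(x) / n; pb <- table(y) / n
  r2 <- 0; dp <- 0
  for (a in names(pa)) {
    for (b in names(pb)) {
      pab <- sum(x == a & y == b) / n
      D <- pab - pa[[a]] * pb[[b]]
      r2 <- r2 + pa[[a]] * pb[[b]] *
        D^2 / (pa[[a]] * (1 - pa[[a]]) * pb[[b]] * (1 - pb[[b]]))
      dmax <- if (D < 0) min(pa[[a]] * pb[[b]], (1 - pa[[a]]) * (1 - pb[[b]]))
              else min(pa[[a]] * (1 - pb[[b]]), (1 - pa[[a]]) * pb[[b]])
      dp <- dp + pa[[a]] * pb[[b]] * if (dmax > 0) abs(D) / dmax else 0
    }
  }
  list(r2 = unname(r2), dprime = unname(dp))
}

# phased haplotype residue-state matrix for one gene: 2n rows (haplotypes),
# one column per residue
phased_hap_states <- function(phased, locus, gene, residues) {
  res <- phased$phased[[locus]]
  ids <- phased$individuals$id
  lut <- allele_residue_lut(phased$registry, gene, residues)
  strings <- character(2L * length(ids))
  for (i in seq_along(ids)) {
    r <- res[[ids[i]]]
    strings[2L * i - 1L] <- lut[[r$h1[[gene]]]]
    strings[2L * i] <- lut[[r$h2[[gene]]]]
  }
  states <- matrix(unlist(strsplit(strings, "")), ncol = length(residues),
                   byrow = TRUE)
  colnames(states) <- as.character(residues)
  states
}

# polymorphic mature-protein residues of a gene across the cohort's phased
# haplotypes (>= 2 non-gap states among carried alleles)
polymorphic_residues <- function(phased, locus, gene) {
  model <- phased$models[[locus]]
  all_res <- seq_len(model$aln_len[[gene]] / 3L - model$leader_aa[[gene]])
  res <- phased$phased[[locus]]
  carried <- unique(unlist(lapply(res, function(r)
    c(r$h1[[gene]], r$h2[[gene]]))))
  carried <- setdiff(carried, ABSENT)
  if (length(carried) < 2L) return(integer(0))
  prot <- matrix(unlist(strsplit(
    phased$registry$protein[match(carried, phased$registry$name)], "")),
    nrow = length(carried), byrow = TRUE)
  keep <- vapply(all_res, function(j) {
    s <- prot[, j]
    length(unique(s[s != "-"])) >= 2L
  }, logical(1))
  all_res[keep]
}

# merge residues into LD groups: connected components of the graph joining
# residue pairs with r2 >= threshold; returns list of groups with min r2
ld_groups <- function(states, residues, threshold = 1) {
  k <- length(residues)
  if (k == 1L)
    return(list(list(residues = residues, min_r2 = NA_real_, class = "single")))
  r2 <- matrix(0, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      r2[i, j] <- r2[j, i] <- ld_stats(states[, i], states[, j])$r2
    }
  }
  linked <- r2 >= threshold - 1e-9
  comp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (linked[i, j] && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(unique(comp), function(cc) {
    idx <- which(comp == cc)
    min_r2 <- if (length(idx) == 1L) NA_real_ else
      min(r2[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))])
    list(residues = residues[idx], min_r2 = min_r2,
         class = if (length(idx) == 1L) "single"
                 else if (min_r2 >= 1 - 1e-9) "perfect LD" else "LD group")
  })
}

#' Iterative Mantel scan for co-evolving HLA and KIR residue groups
#'
#' Stage 1 tests every polymorphic HLA residue's distance matrix against each
#' whole-gene KIR matrix; stage 2 tests the significant HLA residues against
#' single KIR residues; stage 3 merges the significant residues on each side
#' into linkage-disequilibrium groups (r2 at or above `r2_threshold`; the
#' default 1 groups only residues in perfect LD); stage 4 re-tests group
#' against group and iterates with fresh permutations until the ranking of
#' group pairs by the standardized Mantel deviate is stable (capped at
#' `max_rounds`). Ranking uses the permutation-standardized z (scale-free)
#' rather than the raw z, whose magnitude depends on the distance scales of
#' the matrices being compared; the raw z is reported alongside. The significance gate
#' between stages uses raw `alpha`; the output also carries
#' Bonferroni-adjusted p-values.
#'
#' @param phased A `phased_cohort`.
#' @param hla_genes,kir_genes Genes to scan on each side.
#' @param alpha Stage gate significance level (raw p).
#' @param n_perm Permutations per Mantel test.
#' @param seed Integer seed (the whole scan is deterministic given it).
#' @param r2_threshold LD-group merge threshold (default 1 = perfect LD).
#' @param max_rounds Stability iteration cap.
#' @return Object of class `coevolution_scan`: `results` (data frame ranked
#'   by `z_std`, with hla_gene, hla_residues, hla_r2_class, kir_gene,
#'   kir_residues, kir_r2_class, z, z_std, p, p_bonferroni), `stage1` (all
#'   stage-1 tests), `converged`, `rounds`.
#' @export
coevolution_scan <- function(phased, hla_genes, kir_genes, alpha = 0.05,
                             n_perm = 1000L, seed = NULL, r2_threshold = 1,
                             max_rounds = 10L) {
  if (!is.null(seed)) set.seed(seed)
  # stage 1: single HLA residues vs whole-gene KIR matrices
  kir_full <- list()
  for (kg in kir_genes) {
    pk <- polymorphic_residues(phased, "KIR", kg)
    if (length(pk) < 1L) next
    kir_full[[kg]] <- residue_distance_matrix(phased, "KIR", kg, pk)
  }
  stage1 <- list()
  sig_hla <- list()  # gene -> residues
  for (hg in hla_genes) {
    ph <- polymorphic_residues(phased, "HLA", hg)
    for (r in ph) {
      A <- tryCatch(residue_distance_matrix(phased, "HLA", hg, r),
                    error = function(e) NULL)
      if (is.null(A)) next
      for (kg in names(kir_full)) {
        mt <- mantel_test(A, kir_full[[kg]], n_perm = n_perm)
        stage1[[length(stage1) + 1L]] <- data.frame(
          hla_gene = hg, hla_residue = r, kir_gene = kg,
          z = mt$z, p = mt$p, stringsAsFactors = FALSE)
        if (mt$p <= alpha)
          sig_hla[[hg]] <- sort(unique(c(sig_hla[[hg]], r)))
      }
    }
  }
  stage1 <- if (length(stage1)) do.call(rbind, stage1) else
    data.frame(hla_gene = character(0), hla_residue = integer(0),
               kir_gene = character(0), z = numeric(0), p = numeric(0))
  empty <- structure(list(results = data.frame(), stage1 = stage1,
                          converged = TRUE, rounds = 0L),
                     class = "coevolution_scan")
  if (!length(sig_hla)) {
    message("co-evolution scan: no significant HLA residues at stage 1")
    return(empty)
  }
  # stage 2: significant HLA residues vs single KIR residues
  sig_kir <- list()
  for (hg in names(sig_hla)) {
    for (r in sig_hla[[hg]]) {
      A <- residue_distance_matrix(phased, "HLA", hg, r)
      for (kg in names(kir_full)) {
        for (kr in polymorphic_residues(phased, "KIR", kg)) {
          B <- tryCatch(residue_distance_matrix(phased, "KIR", kg, kr),
                        error = function(e) NULL)
          if (is.null(B)) next
          mt <- mantel_test(A, B, n_perm = n_perm)
          if (mt$p <= alpha)
            sig_kir[[kg]] <- sort(unique(c(sig_kir[[kg]], kr)))
        }
      }
    }
  }
  if (!length(sig_kir)) {
    message("co-evolution scan: no significant KIR residues at stage 2")
    return(empty)
  }
  # stage 3: LD groups within each side
  groups_of <- function(locus, gene_residues) {
    out <- list()
    for (g in names(gene_residues)) {
      states <- phased_hap_states(phased, locus, g, gene_residues[[g]])
      for (grp in ld_groups(states, gene_residues[[g]], r2_threshold))
        out[[length(out) + 1L]] <- c(list(gene = g), grp)
    }
    out
  }
  hla_groups <- groups_of("HLA", sig_hla)
  kir_groups <- groups_of("KIR", sig_kir)
  # stage 4: group-vs-group, iterate until ranking stable
  pair_tests <- function() {
    rows <- list()
    for (hgp in hla_groups) {
      A <- residue_distance_matrix(phased, "HLA", hgp$gene, hgp$residues)
      for (kgp in kir_groups) {
        B <- residue_distance_matrix(phased, "KIR", kgp$gene, kgp$residues)
        mt <- mantel_test(A, B, n_perm = n_perm)
        rows[[length(rows) + 1L]] <- data.frame(
          hla_gene = hgp$gene,
          hla_residues = paste(hgp$residues, collapse = ","),
          hla_r2_class = hgp$class,
          kir_gene = kgp$gene,
          kir_residues = paste(kgp$residues, collapse = ","),
          kir_r2_class = kgp$class,
          z = mt$z, z_std = mt$z_std, p = mt$p, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }
  prev_rank <- NULL
  converged <- FALSE
  rounds <- 0L
  res <- NULL
  while (rounds < max_rounds) {
    rounds <- rounds + 1L
    res <- pair_tests()
    rank_now <- order(-res$z_std)
    if (!is.null(prev_rank) && identical(rank_now, prev_rank)) {
      converged <- TRUE
      break
    }
    prev_rank <- rank_now
  }
  res <- res[order(-res$z_std), , drop = FALSE]
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  rownames(res) <- NULL
  structure(list(results = res, stage1 = stage1, converged = converged,
                 rounds = rounds),
            class = "coevolution_scan")
}

#' @export
print.coevolution_scan <- function(x, ...) {
  cat("<co-evolution scan> ", nrow(x$results), " group pairs (",
      if (x$converged) "ranking stable" else "ranking NOT stable",
      " after ", x$rounds, " round(s))\n", sep = "")
  if (nrow(x$results)) print.data.frame(head(x$results, 10), row.names = FALSE)
  invisible(x)
}
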