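#' Allele-frequency spectra
#'
#' A frequency spectrum holds the counts of distinct variants in a sample of
#' size n, with the Ewens-Watterson expected homozygosity F = sum(p_i^2) and
#' heterozygosity H_e = 1 - F.
#'
#' @param counts Integer vector of per-variant counts (names optional).
#' @param label Optional label for reporting.
#' @return Object of class `freq_spectrum` with fields `counts`, `n`, `k`,
#'   `F`, `He`, `label`.
#' @examples
#' freq_spectrum(c(5, 3, 2))
#' @export
freq_spectrum <- function(counts, label = NULL) {
  counts <- as.integer(counts)
  if (length(counts) < 1L || any(counts <= 0L)) stop("counts must be positive")
  n <- sum(counts)
  p <- counts / n
  structure(list(label = label, counts = counts, n = n, k = length(counts),
                 F = sum(p^2), He = 1 - sum(p^2)),
            class = "freq_spectrum")
}

#' @export
print.freq_spectrum <- function(x, ...) {
  cat("<frequency spectrum>", if (!is.null(x$label)) x$label else "", "\n")
  cat(sprintf("  n = %d, k = %d, F = %.4f, He = %.4f\n", x$n, x$k, x$F, x$He))
  invisible(x)
}

#' Ewens-Watterson expected homozygosity F
#'
#' F = sum((count_i / n)^2), the proportion of homozygotes expected under
#' Hardy-Weinberg equilibrium for the sample's allele frequencies.
#'
#' @param spectrum A `freq_spectrum` (or raw counts).
#' @return Numeric scalar F.
#' @export
ewens_watterson_f <- function(spectrum) {
  if (!inherits(spectrum, "freq_spectrum")) spectrum <- freq_spectrum(spectrum)
  sum((spectrum$counts / spectrum$n)^2)
}

# Tajima (1989) constants in n
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from a gapped alignment
#'
#' D contrasts the mean number of pairwise differences (pi) with the
#' segregating-site estimate S/a1 of theta. D < 0 indicates an excess of rare
#' variants (directional selection or expansion), D > 0 an excess of
#' intermediate-frequency variants (balancing selection). Sites containing a
#' gap in any sequence are excluded from S; pi uses pairwise deletion (a pair's
#' comparison skips sites gapped in either sequence).
#'
#' @param sequences Character vector of aligned sequences (equal length,
#'   IUPAC + `-`), or a character matrix (rows = sequences).
#' @return Object of class `tajima_result` with `S`, `pi`, `D` (NA when S = 0),
#'   `n`, `p_two_tail` (NA until [tajima_significance()] is applied).
#' @export
tajimas_d <- function(sequences) {
  mat <- as_seq_matrix(sequences)
  n <- nrow(mat)
  if (n < 4L) stop("Tajima's D needs at least 4 sequences")
  gap <- mat == "-"
  gap_free <- colSums(gap) == 0L
  S <- sum(apply(mat[, gap_free, drop = FALSE], 2L, function(col) length(unique(col)) > 1L))
  # pi: mean pairwise differences, pairwise deletion
  total <- 0
  pairs <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      total <- total + sum(mat[i, ok] != mat[j, ok])
      pairs <- pairs + 1L
    }
  }
  pi <- total / pairs
  D <- if (S == 0L) NA_real_ else {
    k <- tajima_constants(n)
    (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  }
  structure(list(S = S, pi = pi, D = D, n = n, p_two_tail = NA_real_),
            class = "tajima_result")
}

#' @export
print.tajima_result <- function(x, ...) {
  cat(sprintf("<Tajima> n = %d, S = %d, pi = %.3f, D = %s",
              x$n, x$S, x$pi, if (is.na(x$D)) "undefined (S = 0)" else sprintf("%.4f", x$D)))
  if (!is.na(x$p_two_tail)) cat(sprintf(", two-tail p = %.4g", x$p_two_tail))
  cat("\n")
  invisible(x)
}

as_seq_matrix <- function(sequences) {
  if (is.matrix(sequences)) return(sequences)
  stopifnot(is.character(sequences))
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must be aligned (equal length)")
  matrix(unlist(strsplit(toupper(sequences), "")), nrow = length(sequences),
         byrow = TRUE, dimnames = list(names(sequences), NULL))
}

#' Read demographic models for coalescent simulation
#'
#' Models are piecewise-constant population-size histories: `epochs` is a list
#' of (time, size) with times in coalescent units of 2N generations, increasing
#' backwards from the present (time 0), and sizes relative to the present.
#'
#' @param path JSON config path; default is the set shipped with the package
#'   (constant, ancient expansion, bottleneck-expansion, repeated bottlenecks).
#' @return Named list of `demographic_model` objects.
#' @export
read_demographic_models <- function(path = system.file("extdata", "demographic_models.json",
                                                       package = "kirhla")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) demographic_model(x$label, x$epochs, x$theta))
}

#' @rdname read_demographic_models
#' @param label Model label.
#' @param epochs Data frame with columns `time` and `size`.
#' @param theta Scaled mutation rate 4Nu for the simulated segment.
#' @export
demographic_model <- function(label, epochs, theta) {
  epochs <- as.data.frame(epochs)
  stopifnot(all(c("time", "size") %in% names(epochs)))
  if (epochs$time[1] != 0 || is.unsorted(epochs$time, strictly = TRUE))
    stop("epoch times must strictly increase from 0")
  if (any(epochs$size <= 0)) stop("epoch sizes must be positive")
  structure(list(label = label, epochs = epochs, theta = theta),
            class = "demographic_model")
}

#' Coalescent simulation of frequency-spectrum statistics
#'
#' Hudson-style neutral coalescent with piecewise-constant population size and
#' infinite-sites mutation. Time is measured in units of 2N generations; k
#' active lineages coalesce at rate k(k-1)/2 scaled by the inverse of the
#' current relative size, and mutations fall on branches as a Poisson process
#' with rate theta/2 per unit branch length. Each replicate yields the number
#' of segregating sites S, the mean pairwise difference pi, and Tajima's D.
#'
#' @param model A `demographic_model`.
#' @param n Sample size (number of sequences).
#' @param reps Number of replicates.
#' @param seed Integer seed (controls all randomness).
#' @param theta Optional override of `model$theta`.
#' @return Data frame with columns `S`, `pi`, `D` (one row per replicate).
#' @export
coalescent_simulate <- function(model, n, reps, seed = NULL, theta = NULL) {
  stopifnot(inherits(model, "demographic_model"), n >= 2L, reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  theta <- theta %||% model$theta
  ep_t <- model$epochs$time
  ep_s <- model$epochs$size
  const <- if (n >= 4L) tajima_constants(n) else NULL
  out <- matrix(NA_real_, reps, 3L, dimnames = list(NULL, c("S", "pi", "D")))
  for (r in seq_len(reps)) {
    desc <- rep(1L, n)          # descendant counts of active lineages
    birth <- rep(0, n)          # time each active lineage began
    t <- 0
    branch_desc <- integer(2L * (n - 1L))
    branch_len <- numeric(2L * (n - 1L))
    nb <- 0L
    k <- n
    while (k > 1L) {
      rate0 <- k * (k - 1L) / 2
      # advance through epochs with memoryless redraws at boundaries
      repeat {
        cur <- findInterval(t, ep_t)
        lambda <- ep_s[cur]
        w <- rexp(1L, rate = rate0 / lambda)
        nxt <- if (cur < length(ep_t)) ep_t[cur + 1L] else Inf
        if (t + w <= nxt) { t <- t + w; break }
        t <- nxt
      }
      pair <- sample.int(k, 2L)
      for (x in pair) {
        nb <- nb + 1L
        branch_desc[nb] <- desc[x]
        branch_len[nb] <- t - birth[x]
      }
      merged <- desc[pair[1L]] + desc[pair[2L]]
      keep <- setdiff(seq_len(k), pair)
      desc <- c(desc[keep], merged)
      birth <- c(birth[keep], t)
      k <- k - 1L
    }
    muts <- rpois(nb, theta / 2 * branch_len[seq_len(nb)])
    S <- sum(muts)
    freqs <- rep.int(branch_desc[seq_len(nb)], muts)
    pi <- if (S == 0L) 0 else sum(freqs * (n - freqs)) / (n * (n - 1) / 2)
    D <- if (S == 0L || is.null(const)) NA_real_ else
      (pi - S / const$a1) / sqrt(const$e1 * S + const$e2 * S * (S - 1))
    out[r, ] <- c(S, pi, D)
  }
  as.data.frame(out)
}

#' Empirical two-tail significance of an observed Tajima's D
#'
#' Ranks the observed D within a simulated null distribution:
#' p = 2 * min(lower tail, upper tail) / (reps + 1) with add-one correction,
#' capped at 1. Replicates with undefined D (S = 0) are dropped with a message.
#'
#' @param observed A `tajima_result` or numeric D value.
#' @param sims Numeric vector of simulated D values, or the data frame from
#'   [coalescent_simulate()].
#' @return The observed `tajima_result` with `p_two_tail` filled in (or the
#'   p-value itself when `observed` is numeric).
#' @export
tajima_significance <- function(observed, sims) {
  d_obs <- if (inherits(observed, "tajima_result")) observed$D else observed
  if (is.na(d_obs)) stop("observed D is undefined (S = 0)")
  d_sim <- if (is.data.frame(sims)) sims$D else sims
  n_drop <- sum(is.na(d_sim))
  if (n_drop > 0L) message("dropping ", n_drop, " replicates with undefined D")
  d_sim <- d_sim[!is.na(d_sim)]
  if (!length(d_sim)) stop("no usable replicates")
  reps <- length(d_sim)
  lo <- sum(d_sim <= d_obs) + 1L
  hi <- sum(d_sim >= d_obs) + 1L
  p <- min(1, 2 * min(lo, hi) / (reps + 1L))
  if (inherits(observed, "tajima_result")) {
    observed$p_two_tail <- p
    observed
  } else p
}

# solve theta so that the Ewens expectation of k matches the observed k
ewens_theta_for_k <- function(n, k) {
  if (k <= 1L) return(0)
  if (k >= n) return(Inf)
  f <- function(log_th) sum(exp(log_th) / (exp(log_th) + 0:(n - 1))) - k
  exp(uniroot(f, c(-20, 20), extendInt = "yes")$root)
}

#' Slatkin exact test and normalized deviate of Ewens-Watterson F
#'
#' Simulates the neutral null distribution of F conditional on the observed
#' number of alleles k and sample size n: allele configurations are drawn from
#' the Ewens sampling formula (Chinese-restaurant construction with theta
#' solved so E\[k\] = k), rejecting draws whose realised allele count differs
#' from k. The reported p is Pr(F_sim <= F_obs) with add-one correction, and
#' F_nd = (F_obs - mean(F_sim)) / sd(F_sim). Significantly negative F_nd
#' indicates balancing selection; positive, directional selection.
#'
#' @param spectrum A `freq_spectrum`.
#' @param n_sim Number of accepted null configurations (default 10000).
#' @param seed Integer seed.
#' @return Object of class `ew_result` with `F_obs`, `k`, `n`, `p_slatkin`,
#'   `F_nd`, `n_sim`, `monomorphic`. For k = 1 the test is undefined and the
#'   result is flagged monomorphic (p and F_nd are NA).
#' @export
slatkin_fnd <- function(spectrum, n_sim = 10000L, seed = NULL) {
  stopifnot(inherits(spectrum, "freq_spectrum"))
  if (spectrum$k < 2L) {
    return(structure(list(F_obs = spectrum$F, k = spectrum$k, n = spectrum$n,
                          p_slatkin = NA_real_, F_nd = NA_real_, n_sim = 0L,
                          monomorphic = TRUE),
                     class = "ew_result"))
  }
  if (!is.null(seed)) set.seed(seed)
  theta <- ewens_theta_for_k(spectrum$n, spectrum$k)
  if (!is.finite(theta)) {
    # k = n: the only configuration is all singletons; F is degenerate
    f_sim <- rep(1 / spectrum$n, n_sim)
  } else {
    f_sim <- .ewens_f_cpp(spectrum$n, spectrum$k, theta, as.integer(n_sim),
                          max_tries = n_sim / 1e-4)
  }
  mu <- mean(f_sim); sdv <- sd(f_sim)
  structure(list(F_obs = spectrum$F, k = spectrum$k, n = spectrum$n,
                 p_slatkin = (1 + sum(f_sim <= spectrum$F)) / (1 + n_sim),
                 F_nd = if (sdv > 0) (spectrum$F - mu) / sdv else NA_real_,
                 n_sim = as.integer(n_sim), monomorphic = FALSE),
            class = "ew_result")
}

#' @export
print.ew_result <- function(x, ...) {
  if (x$monomorphic) {
    cat(sprintf("<Ewens-Watterson> n = %d, k = 1: monomorphic (-)\n", x$n))
  } else {
    cat(sprintf("<Ewens-Watterson> n = %d, k = %d, F = %.4f, F_nd = %.3f, p(Slatkin) = %.4g\n",
                x$n, x$k, x$F_obs, x$F_nd, x$p_slatkin))
  }
  invisible(x)
}

#' Project allotypes onto a binding-motif residue set
#'
#' Collapses allotypes by the identity of their protein substring at a set of
#' mature-numbering residues, summing counts, and returns the motif-restricted
#' frequency spectrum. Motifs with a single residue-set class are flagged
#' monomorphic (reported "(-)" in selection tables).
#'
#' @param allotypes Data frame with columns `name`, `protein`, `count`.
#' @param residues Integer vector of mature-protein positions (1-based).
#' @param label Optional spectrum label.
#' @return A `freq_spectrum` with attributes `classes` (the residue strings)
#'   and `monomorphic`.
#' @export
motif_project <- function(allotypes, residues, label = NULL) {
  stopifnot(all(c("name", "protein", "count") %in% names(allotypes)))
  residues <- sort(unique(as.integer(residues)))
  plen <- min(nchar(allotypes$protein))
  if (max(residues) > plen || min(residues) < 1L)
    stop("residue outside protein length (", plen, ")")
  key <- vapply(allotypes$protein, function(p)
    paste(vapply(residues, function(r) substr(p, r, r), character(1)), collapse = ""),
    character(1), USE.NAMES = FALSE)
  agg <- tapply(allotypes$count, key, sum)
  sp <- freq_spectrum(as.integer(agg), label = label)
  attr(sp, "classes") <- names(agg)
  attr(sp, "monomorphic") <- sp$k == 1L
  sp
}

#' Binding-site residue definitions with derived exclusive sets
#'
#' Reads the named residue sets per gene (peptide pockets, TCR, KIR, LILR,
#' CD8, ...) and derives for each gene the exclusive sets: residues belonging
#' to exactly one named site. Motif-restricted selection statistics use the
#' exclusive sets so overlapping motifs do not share signal.
#'
#' @param path JSON config path (default: shipped definitions).
#' @return Named list per gene: list of `sites` (as configured) and
#'   `exclusive` (same names, overlap removed).
#' @export
read_binding_sites <- function(path = system.file("extdata", "binding_sites.json",
                                                  package = "kirhla")) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(sets) {
    sets <- lapply(sets, as.integer)
    all_res <- unlist(sets, use.names = FALSE)
    shared <- unique(all_res[duplicated(all_res)])
    exclusive <- lapply(sets, function(v) setdiff(v, shared))
    list(sites = sets, exclusive = exclusive)
  })
}
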