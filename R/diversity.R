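#' Nei's unbiased heterozygosity estimator
#'
#' H = n/(n-1) * (1 - sum(p_i^2)); the finite-sample correction makes H at
#' least as large as the plug-in heterozygosity.
#'
#' @param spectrum A `freq_spectrum` (or raw counts).
#' @return Numeric scalar H.
#' @export
nei_heterozygosity <- function(spectrum) {
  if (!inherits(spectrum, "freq_spectrum")) spectrum <- freq_spectrum(spectrum)
  if (spectrum$n < 2L) stop("Nei's estimator needs n >= 2")
  spectrum$n / (spectrum$n - 1) * (1 - sum((spectrum$counts / spectrum$n)^2))
}

#' Heterozygosity as one minus the sum of squared frequencies
#'
#' H_e = 1 - SSF, the definitional complement of the Ewens-Watterson F.
#'
#' @param frequencies Numeric frequencies summing to 1.
#' @return Numeric scalar H_e.
#' @export
he_ssf <- function(frequencies) {
  if (abs(sum(frequencies) - 1) > 1e-6) stop("frequencies must sum to 1")
  1 - sum(frequencies^2)
}

#' Mismatch distribution of pairwise p-distances
#'
#' For each unordered pair of haplotype sequences the p-distance is the number
#' of differing sites divided by the number of compared sites, with pairwise
#' deletion (sites gapped in either sequence are skipped). Pairs with no
#' comparable sites are excluded with a warning. Under population expansion
#' the histogram is unimodal; divergent balanced lineages give multimodality.
#'
#' @param sequences Aligned character vector or matrix (gapped concatenated
#'   haplotypes).
#' @param binwidth Histogram bin width on the p-distance scale.
#' @return Object of class `mismatch_distribution`: `distances` (per pair),
#'   `breaks`, `counts`, `n_excluded`.
#' @export
mismatch_distribution <- function(sequences, binwidth = 0.01) {
  mat <- as_seq_matrix(sequences)
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 haplotypes")
  gap <- mat == "-"
  d <- numeric(0)
  n_excl <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      m <- sum(ok)
      if (m == 0L) { n_excl <- n_excl + 1L; next }
      d <- c(d, sum(mat[i, ok] != mat[j, ok]) / m)
    }
  }
  if (n_excl > 0L) warning(n_excl, " pair(s) with no comparable sites excluded")
  breaks <- seq(0, max(ceiling(max(d, 0) / binwidth), 1) * binwidth, by = binwidth)
  counts <- hist(d, breaks = breaks, plot = FALSE)$counts
  structure(list(distances = d, breaks = breaks, counts = counts,
                 n_excluded = n_excl),
            class = "mismatch_distribution")
}

#' @export
print.mismatch_distribution <- function(x, ...) {
  cat("<mismatch distribution> ", length(x$distances), " pairs; mean p-distance ",
      sprintf("%.4f", mean(x$distances)), "\n", sep = "")
  invisible(x)
}

#' @export
plot.mismatch_distribution <- function(x, ...) {
  mids <- head(x$breaks, -1) + diff(x$breaks) / 2
  graphics::barplot(x$counts, names.arg = signif(mids, 2), xlab = "p-distance",
                    ylab = "pairs", ...)
  invisible(x)
}

#' Marker series over a haplotype set
#'
#' Builds the ordered marker table used for sliding-window MAF profiling: for
#' each gene of the locus model, a gene-presence pseudo-marker (biallelic
#' present/absent, included when gene content varies) followed by the
#' polymorphic alignment columns of the gene. Minor allele frequency at a
#' marker is the frequency of the second most common state; sites are
#' evaluated on the haplotype copies of the census (absent genes contribute
#' no state to the gene's sequence markers).
#'
#' @param census A `haplotype_census`.
#' @param registry The cohort's `allele_registry`.
#' @param model The `locus_model` the census was built over.
#' @return Object of class `marker_series`: data frame with columns
#'   `marker_id`, `gene`, `type` (`presence`/`site`), `maf`.
#' @export
marker_series <- function(census, registry, model) {
  haps <- attr(census, "haplotypes")
  counts <- census$count
  rows <- list()
  for (g in model$genes) {
    alleles <- vapply(haps, function(h) h[[g]], character(1))
    present <- alleles != ABSENT
    w <- counts
    # gene-presence pseudo-marker when content varies
    pres_freqs <- c(sum(w[present]), sum(w[!present])) / sum(w)
    if (all(pres_freqs > 0)) {
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = paste0(g, ":presence"), gene = g, type = "presence",
        maf = min(pres_freqs), stringsAsFactors = FALSE)
    }
    if (!any(present)) next
    seqs <- registry$cds[match(alleles[present], registry$name)]
    mat <- as_seq_matrix(seqs)
    wp <- w[present]
    for (col in seq_len(ncol(mat))) {
      tab <- tapply(wp, mat[, col], sum)
      if (length(tab) < 2L) next
      tab <- sort(tab / sum(tab), decreasing = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        marker_id = paste0(g, ":", col), gene = g, type = "site",
        maf = unname(tab[2L]), stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("marker_series", "data.frame"))
}

#' Sliding-window mean-MAF profile
#'
#' Mean per-marker minor allele frequency over fully contained windows
#' (`markers - window + 1` windows at step 1).
#'
#' @param series A `marker_series` or numeric MAF vector.
#' @param window Window size in markers (default 15).
#' @param step Step in markers (default 1).
#' @return Data frame with `start`, `end`, `mean_maf`.
#' @export
sliding_window_maf <- function(series, window = 15L, step = 1L) {
  maf <- if (is.numeric(series)) series else series$maf
  n <- length(maf)
  if (n < window) stop("fewer markers (", n, ") than window (", window, ")")
  starts <- seq(1L, n - window + 1L, by = step)
  data.frame(start = starts, end = starts + window - 1L,
             mean_maf = vapply(starts, function(s) mean(maf[s:(s + window - 1L)]),
                               numeric(1)))
}

#' Empirical percentile of a value within a reference distribution
#'
#' Percentile = 100 * (number of reference values <= value) / length(reference).
#' Used to rank a locus window's mean MAF within a genome-wide reference set.
#'
#' @param value Numeric scalar (e.g. a window or segment mean).
#' @param reference Numeric reference distribution.
#' @return Percentile in \[0, 100\].
#' @export
percentile_of_interval <- function(value, reference) {
  stopifnot(length(reference) >= 1L)
  100 * sum(reference <= value) / length(reference)
}

#' Haplotype network under the Hamming distance model
#'
#' Pairwise Hamming distances are computed on the gapped concatenated
#' haplotype sequences; a gap compared against a base counts as a difference
#' (gene absence is a mutational step) and gap against gap as a match. Primary
#' links form the minimum spanning tree (Prim's algorithm with deterministic
#' tie-breaking by node label order); alternative links are non-tree pairs
#' whose distance equals the largest primary-link weight on the tree path
#' between them. Each node carries the parsimony probability of its shortest
#' primary link (see [templeton_node_probability()]).
#'
#' @param sequences Aligned character vector (named by haplotype label) or
#'   matrix of distinct haplotype sequences.
#' @param frequencies Optional per-haplotype frequencies (for node sizes).
#' @return Object of class `haplotype_network` with `nodes` (label, frequency,
#'   node_prob), `edges` (from, to, steps, type = primary/alternative), and the
#'   distance matrix.
#' @export
hamming_network <- function(sequences, frequencies = NULL) {
  mat <- as_seq_matrix(sequences)
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 distinct haplotypes")
  labels <- rownames(mat) %||% paste0("H", seq_len(n))
  if (is.null(rownames(mat))) rownames(mat) <- labels
  m_sites <- ncol(mat)
  d <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) d[i, j] <- d[j, i] <- sum(mat[i, ] != mat[j, ])
  }
  # Prim MST from node 1; ties broken by smallest (to, from) label order
  in_tree <- c(TRUE, rep(FALSE, n - 1L))
  edges <- data.frame(from = character(0), to = character(0), steps = integer(0))
  while (!all(in_tree)) {
    best <- NULL
    for (j in which(!in_tree)) {
      for (i in which(in_tree)) {
        cand <- c(i, j, d[i, j])
        if (is.null(best) || cand[3] < best[3] ||
            (cand[3] == best[3] && (cand[2] < best[2] ||
                                    (cand[2] == best[2] && cand[1] < best[1]))))
          best <- cand
      }
    }
    edges <- rbind(edges, data.frame(from = labels[best[1]], to = labels[best[2]],
                                     steps = as.integer(best[3])))
    in_tree[best[2]] <- TRUE
  }
  edges$type <- "primary"
  # alternative links: non-tree pairs whose distance equals the max primary
  # weight on the tree path between them
  adj <- lapply(seq_len(n), function(i) integer(0))
  wts <- lapply(seq_len(n), function(i) integer(0))
  for (e in seq_len(nrow(edges))) {
    i <- match(edges$from[e], labels); j <- match(edges$to[e], labels)
    adj[[i]] <- c(adj[[i]], j); wts[[i]] <- c(wts[[i]], edges$steps[e])
    adj[[j]] <- c(adj[[j]], i); wts[[j]] <- c(wts[[j]], edges$steps[e])
  }
  path_max <- function(a, b) {
    # DFS from a to b tracking max edge weight
    seen <- rep(FALSE, n); seen[a] <- TRUE
    stack <- list(list(node = a, mx = 0L))
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (cur$node == b) return(cur$mx)
      for (idx in seq_along(adj[[cur$node]])) {
        nb <- adj[[cur$node]][idx]
        if (!seen[nb]) {
          seen[nb] <- TRUE
          stack[[length(stack) + 1L]] <- list(node = nb, mx = max(cur$mx, wts[[cur$node]][idx]))
        }
      }
    }
    stop("tree path not found")  # cannot happen on a spanning tree
  }
  tree_pairs <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  alt <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      key <- paste(pmin(labels[i], labels[j]), pmax(labels[i], labels[j]))
      if (key %in% tree_pairs) next
      if (d[i, j] == path_max(i, j))
        alt[[length(alt) + 1L]] <- data.frame(from = labels[i], to = labels[j],
                                              steps = d[i, j], type = "alternative")
    }
  }
  if (length(alt)) edges <- rbind(edges, do.call(rbind, alt))
  min_link <- vapply(labels, function(l) {
    e <- edges[edges$type == "primary" & (edges$from == l | edges$to == l), ]
    min(e$steps)
  }, numeric(1))
  nodes <- data.frame(label = labels,
                      frequency = if (is.null(frequencies)) NA_real_ else frequencies,
                      node_prob = vapply(min_link, templeton_node_probability,
                                         numeric(1), m = m_sites),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, dist = d),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("<haplotype network> ", nrow(x$nodes), " nodes; ",
      sum(x$edges$type == "primary"), " primary + ",
      sum(x$edges$type == "alternative"), " alternative links\n", sep = "")
  invisible(x)
}

#' Parsimony probability of a network link
#'
#' Probability that two haplotypes separated by `j` observed differences over
#' `m` compared sites are connected parsimoniously, i.e. that no additional
#' superimposed mutations occurred. Computed by comparing the likelihood that
#' exactly `j` uniformly placed mutations produced `j` visible differences
#' against the leading non-parsimonious alternative (one coincident pair among
#' `j + 1` mutations), for a `b`-state character; the closed form is
#' `1 / (1 + j(j+1)(b-2) / (2m(b-1)))`. Equal to 1 at j = 0 and monotone
#' non-increasing in j.
#'
#' @param j Number of observed differences (steps), `0 <= j <= m`.
#' @param m Number of compared sites.
#' @param b Number of character states per site (default 4, nucleotides).
#' @return Probability in (0, 1\].
#' @export
templeton_node_probability <- function(j, m, b = 4) {
  stopifnot(j >= 0, m >= 1, b >= 2)
  if (j > m) stop("j (steps) cannot exceed m (sites)")
  1 / (1 + j * (j + 1) * (b - 2) / (2 * m * (b - 1)))
}

#' Cumulative haplotype-frequency curve
#'
#' Haplotype frequencies added in order of decreasing frequency; the curve is
#' monotone non-decreasing and terminates at 1.
#'
#' @param census A `haplotype_census` (or numeric frequency vector).
#' @return Numeric cumulative frequency series.
#' @export
cumulative_haplotype_curve <- function(census) {
  f <- if (is.numeric(census)) census else census$freq
  if (!length(f)) stop("empty census")
  cumsum(sort(f, decreasing = TRUE)) / sum(f)
}
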