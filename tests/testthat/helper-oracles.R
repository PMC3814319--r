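# unsigned Stirling numbers of the first kind, by recurrence
stirling1 <- function(n, k) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1
  for (i in 1:n) for (j in 1:i) {
    s[i + 1, j + 1] <- s[i, j] + (i - 1) * s[i, j + 1]
  }
  s[n + 1, k + 1]
}

# all partitions of n into exactly k positive parts (decreasing)
partitions_nk <- function(n, k, max_part = n) {
  if (k == 1) {
    if (n <= max_part) return(list(n)) else return(list())
  }
  out <- list()
  for (first in min(n - k + 1, max_part):1) {
    for (rest in partitions_nk(n - first, k - 1, first)) {
      out[[length(out) + 1]] <- c(first, rest)
    }
  }
  out
}

# Ewens conditional-on-k probability of an allele configuration
ewens_cond_prob <- function(parts, n, k) {
  a <- table(parts)
  factorial(n) / (stirling1(n, k) * prod(as.numeric(names(a))^as.numeric(a)) *
                    prod(factorial(as.numeric(a))))
}

# all permutations of 1..n (tiny n), as integer vectors
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) {
    for (pos in 1:n) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1)
    }
  }
  out
}
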