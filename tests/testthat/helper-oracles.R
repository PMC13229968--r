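# Independent metric oracles, kept deliberately naive:
#  - LCS by exhaustive subsequence enumeration (lengths <= 8),
#  - optimal transport by brute-force assignment over permutations,
#  - WD1 as the integrated absolute ECDF difference over breakpoints.

lcs_bruteforce <- function(a, b) {
  best <- 0L
  n <- length(a)
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    sub <- a[idx]
    if (length(sub) <= best) next
    j <- 1L
    for (x in b) {
      if (j <= length(sub) && x == sub[j]) j <- j + 1L
    }
    if (j == length(sub) + 1L) best <- length(sub)
  }
  best
}

wd_assignment_bruteforce <- function(a, b) {
  stopifnot(length(a) == length(b))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  min(vapply(perms(b), function(p) mean(abs(a - p)), numeric(1)))
}

wd_cdf_integral <- function(a, b) {
  x <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(x); fb <- stats::ecdf(b)(x)
  sum(abs(fa - fb)[-length(x)] * diff(x))
}
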