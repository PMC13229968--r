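# Sequence- and distribution-level evaluation metrics.

.as_id_list <- function(x) {
  if (is.list(x)) lapply(x, function(s) as.integer(unclass(s)))
  else list(as.integer(unclass(x)))
}

#' Teacher-forcing token accuracy
#'
#' Fraction of aligned positions where the predicted token equals the
#' reference token. Both sequences must have equal length (teacher-forcing
#' alignment).
#'
#' @param pred,ref Token sequences (integer vectors) of equal length.
#' @return Fraction in `[0, 1]`.
#' @export
token_accuracy <- function(pred, ref) {
  pred <- as.integer(unclass(pred)); ref <- as.integer(unclass(ref))
  if (length(pred) != length(ref))
    stop("alignment error: sequences must have equal length", call. = FALSE)
  mean(pred == ref)
}

#' Per-token evaluation report for aligned sequences
#'
#' Computes per-token-ID precision, recall and F1 (one-vs-rest over the
#' aligned positions) with reference supports, plus overall accuracy and the
#' support-weighted F1
#' `sum_k n_k F1_k / sum_k n_k` over token IDs `k = 0..227`. Classes absent
#' from the reference carry zero weight.
#'
#' @param pred,ref Token sequences of equal length.
#' @return List with `accuracy`, `weighted_f1` and a `per_token` data.frame
#'   (`id`, `n`, `precision`, `recall`, `f1`).
#' @export
sequence_eval <- function(pred, ref) {
  pred <- as.integer(unclass(pred)); ref <- as.integer(unclass(ref))
  if (length(pred) != length(ref))
    stop("alignment error: sequences must have equal length", call. = FALSE)
  classes <- sort(unique(c(pred, ref)))
  tab <- lapply(classes, function(k) {
    tp <- sum(pred == k & ref == k)
    fp <- sum(pred == k & ref != k)
    fn <- sum(ref == k & pred != k)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
    data.frame(id = k, n = sum(ref == k), precision = precision,
               recall = recall, f1 = f1)
  })
  per_token <- do.call(rbind, tab)
  list(accuracy = mean(pred == ref),
       weighted_f1 = sum(per_token$n * per_token$f1) / sum(per_token$n),
       per_token = per_token)
}

#' Support-weighted F1 of aligned token sequences
#'
#' @inheritParams token_accuracy
#' @return Weighted F1 in `[0, 1]`.
#' @export
weighted_f1 <- function(pred, ref) sequence_eval(pred, ref)$weighted_f1

.ngram_keys <- function(ids, n) {
  len <- length(ids)
  if (len < n) return(character(0))
  if (n == 1) return(as.character(ids))
  vapply(seq_len(len - n + 1L), function(i)
    paste(ids[i:(i + n - 1L)], collapse = " "), character(1))
}

#' Corpus BLEU-4 score
#'
#' Precision-based n-gram overlap between generated and reference token
#' sequences, as the geometric mean of the clipped 1- to 4-gram precisions
#' multiplied by the brevity penalty
#' `min(1, exp(1 - sum(l_ref) / sum(l_gen)))`. Counts and lengths are pooled
#' over all sequence pairs (corpus-level). A zero n-gram precision yields a
#' score of 0 (no smoothing). Returned in percent.
#'
#' @param gen,ref A token sequence or a list of token sequences; when lists,
#'   pair `i` of `gen` is scored against pair `i` of `ref`.
#' @return BLEU-4 in percent (0--100).
#' @export
bleu4 <- function(gen, ref) {
  gen <- .as_id_list(gen); ref <- .as_id_list(ref)
  if (length(gen) != length(ref))
    stop("gen and ref must contain the same number of sequences", call. = FALSE)
  if (any(vapply(gen, length, integer(1)) == 0) ||
      any(vapply(ref, length, integer(1)) == 0))
    stop("sequences must be non-empty", call. = FALSE)
  precisions <- numeric(4)
  for (n in 1:4) {
    matched <- 0; total <- 0
    for (i in seq_along(gen)) {
      g <- .ngram_keys(gen[[i]], n)
      r <- .ngram_keys(ref[[i]], n)
      total <- total + length(g)
      if (length(g) == 0) next
      gt <- table(g); rt <- table(r)
      common <- intersect(names(gt), names(rt))
      matched <- matched + sum(pmin(gt[common], rt[common]))
    }
    precisions[n] <- if (total > 0) matched / total else 0
  }
  l_ref <- sum(vapply(ref, length, integer(1)))
  l_gen <- sum(vapply(gen, length, integer(1)))
  bp <- min(1, exp(1 - l_ref / l_gen))
  if (any(precisions == 0)) return(0)
  100 * bp * prod(precisions)^(1 / 4)
}

#' Longest common subsequence length
#'
#' Dynamic-programming LCS over two integer token vectors.
#'
#' @param a,b Integer vectors.
#' @return Length of the longest common subsequence.
#' @export
lcs_length <- function(a, b) {
  a <- as.integer(unclass(a)); b <- as.integer(unclass(b))
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    match_i <- a[i] == b
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (match_i[j]) prev[j] + 1L else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' ROUGE-L score
#'
#' LCS-based F-score, averaged over sequence pairs. The default follows this
#' package's reference orientation with `R = LCS / len(gen)`,
#' `P = LCS / len(ref)`, `beta = P / R` and
#' `F = (1 + beta^2) R P / (R + beta P)`; identical sequences score exactly
#' 1 and disjoint sequences 0. Set `standard = TRUE` for the conventional
#' ROUGE-L orientation (`R = LCS / len(ref)`, `P = LCS / len(gen)`,
#' `F = (1 + beta^2) R P / (R + beta^2 P)`).
#'
#' @param gen,ref A token sequence or a list of token sequences (paired).
#' @param standard Use the conventional ROUGE-L formula instead of the
#'   package's reference orientation.
#' @return Mean F-score in `[0, 1]`.
#' @export
rouge_l <- function(gen, ref, standard = FALSE) {
  gen <- .as_id_list(gen); ref <- .as_id_list(ref)
  if (length(gen) != length(ref))
    stop("gen and ref must contain the same number of sequences", call. = FALSE)
  scores <- vapply(seq_along(gen), function(i) {
    g <- gen[[i]]; r <- ref[[i]]
    if (length(g) == 0 || length(r) == 0)
      stop("sequences must be non-empty", call. = FALSE)
    l <- lcs_length(g, r)
    if (l == 0) return(0)
    if (standard) {
      rec <- l / length(r); prec <- l / length(g)
      beta <- prec / rec
      (1 + beta^2) * rec * prec / (rec + beta^2 * prec)
    } else {
      rec <- l / length(g); prec <- l / length(r)
      beta <- prec / rec
      (1 + beta^2) * rec * prec / (rec + beta * prec)
    }
  }, numeric(1))
  mean(scores)
}

#' One-dimensional Wasserstein distance between samples
#'
#' Empirical p-Wasserstein distance on the line via the quantile-function
#' formulation (for `p = 1` this is the earth mover's distance, equal to the
#' integrated absolute CDF difference). The normalized variant divides by the
#' range of the reference sample `b`; a degenerate (zero-range) reference
#' yields 0 when the raw distance is 0 and `Inf` otherwise.
#'
#' @param a,b Non-empty numeric sample vectors; `b` is the reference for
#'   normalization.
#' @param p Order of the distance (default 1).
#' @param normalize Divide by `max(b) - min(b)`.
#' @return Non-negative distance.
#' @export
wasserstein_1d <- function(a, b, p = 1, normalize = FALSE) {
  if (length(a) == 0 || length(b) == 0)
    stop("sample sets must be non-empty", call. = FALSE)
  a <- sort(a); b <- sort(b)
  na <- length(a); nb <- length(b)
  u <- sort(unique(c(seq_len(na) / na, seq_len(nb) / nb)))
  du <- diff(c(0, u))
  mid <- u - du / 2
  qa <- a[pmin(na, ceiling(mid * na))]
  qb <- b[pmin(nb, ceiling(mid * nb))]
  wd <- sum(du * abs(qa - qb)^p)^(1 / p)
  if (!normalize) return(wd)
  rng <- b[nb] - b[1]
  if (rng <= .Machine$double.eps)
    return(if (wd <= .Machine$double.eps) 0 else Inf)
  wd / rng
}

#' Regression error summaries
#'
#' Coefficient of determination, root-mean-squared error and mean absolute
#' percentage error between predicted and true series. Positions with a true
#' value of 0 are excluded from MAPE with a warning-carrying count.
#'
#' @param pred,truth Numeric vectors of equal length.
#' @return List with `r2`, `rmse`, `mape_percent`, `n_mape_excluded`.
#' @export
regression_metrics <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length", call. = FALSE)
  resid <- truth - pred
  ss_res <- sum(resid^2)
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  rmse <- sqrt(mean(resid^2))
  nonzero <- truth != 0
  n_excl <- sum(!nonzero)
  if (n_excl > 0)
    warning(sprintf("%d zero true value(s) excluded from MAPE", n_excl),
            call. = FALSE)
  mape <- if (any(nonzero))
    100 * mean(abs(resid[nonzero] / truth[nonzero])) else NA_real_
  list(r2 = r2, rmse = rmse, mape_percent = mape, n_mape_excluded = n_excl)
}

#' Compare decoded parameter distributions of two token populations
#'
#' Detokenizes two populations of token sequences and, for every stored
#' architectural parameter (by parameter name and unifoliate/trifoliate
#' context), computes the p = 1 Wasserstein distance between the two decoded
#' value distributions, normalized by the reference (`b`) population's range.
#'
#' @param seqs_a,seqs_b Lists of token sequences; `seqs_b` is the reference.
#' @param vocab A [build_vocabulary()] object.
#' @return data.frame with columns `parameter`, `context`, `n_a`, `n_b`,
#'   `wd`, `normalized_wd`.
#' @export
distribution_eval <- function(seqs_a, seqs_b, vocab = build_vocabulary()) {
  decode_all <- function(seqs)
    .collect_parameters(lapply(seqs, function(s) detokenize(s, vocab)$plant))
  pa <- decode_all(seqs_a)
  pb <- decode_all(seqs_b)
  keys <- intersect(names(pa), names(pb))
  rows <- lapply(keys, function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    x <- pa[[key]]; y <- pb[[key]]
    data.frame(parameter = parts[1], context = parts[2],
               n_a = length(x), n_b = length(y),
               wd = wasserstein_1d(x, y),
               normalized_wd = wasserstein_1d(x, y, normalize = TRUE))
  })
  out <- do.call(rbind, rows)
  out[order(out$parameter, out$context), , drop = FALSE]
}
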