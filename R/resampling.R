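## Shared inference machinery: permutation nulls, Holm sequential
## correction, and distribution-equating stratified subsampling.

#' Generic permutation test
#'
#' @param observed_fn function(data) -> scalar statistic
#' @param shuffle_fn function(data, i) -> shuffled data for iteration i
#'   (must draw from the declared null; receives the iteration index so
#'   callers can derive per-iteration seeds)
#' @param data the dataset passed to both functions
#' @param n_perm number of permutations
#' @param sidedness `"greater"`, `"less"`, or `"two_sided"`
#' @param seed integer seed
#' @return a `permutation_result`: `observed`, `null_values`, `p`
#'   (with the +1 correction, so the floor is `1/(n_perm+1)`), `n_perm`,
#'   `sidedness`
#' @export
permutation_null <- function(observed_fn, shuffle_fn, data, n_perm = 1500,
                             sidedness = c("two_sided", "greater", "less"),
                             seed = 1L) {
  sidedness <- match.arg(sidedness)
  if (n_perm < 100) warning("fewer than 100 permutations")
  set.seed(seed)
  obs <- observed_fn(data)
  null_values <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    v <- observed_fn(shuffle_fn(data, i))
    if (!is.finite(v)) stop2("non-finite statistic at permutation ", i)
    null_values[i] <- v
  }
  p <- perm_pvalue(obs, null_values, sidedness)
  structure(list(observed = obs, null_values = null_values, p = p,
                 n_perm = n_perm, sidedness = sidedness),
            class = "permutation_result")
}

#' Permutation p-value with the +1 correction
#' @param observed scalar
#' @param null_values numeric vector
#' @param sidedness tail(s) counted as as-or-more-extreme
#' @export
perm_pvalue <- function(observed, null_values,
                        sidedness = c("two_sided", "greater", "less")) {
  sidedness <- match.arg(sidedness)
  n <- length(null_values)
  k <- switch(sidedness,
    greater = sum(null_values >= observed),
    less = sum(null_values <= observed),
    two_sided = {
      mu <- mean(null_values)
      sum(abs(null_values - mu) >= abs(observed - mu))
    })
  (1 + k) / (n + 1)
}

#' Holm sequential (step-down Bonferroni) correction
#'
#' @param pvalues numeric vector in [0, 1]
#' @param alpha family-wise error level
#' @return logical rejection flags in the original order
#' @export
holm_correct <- function(pvalues, alpha = 0.05) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "holm") <= alpha
}

#' Distribution-equating stratified subsample
#'
#' Builds a common histogram over the pooled range of a nuisance variable
#' (e.g., alpha/low-beta power) and, within every bin, subsamples both
#' groups without replacement to the smaller count, so the two retained
#' groups have identical per-bin counts (hence matched distributions) and
#' equal sizes.
#'
#' @param values_a,values_b nuisance-variable values per trial in each group
#' @param n_bins number of histogram bins (20 by default)
#' @param seed integer seed
#' @return a `stratified_sample`: `kept_a`, `kept_b` (indices into the
#'   input vectors)
#' @export
stratify <- function(values_a, values_b, n_bins = 20, seed = 1L) {
  stopifnot(length(values_a) > 0, length(values_b) > 0)
  set.seed(seed)
  rng <- range(c(values_a, values_b))
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin_a <- findInterval(values_a, brk, rightmost.closed = TRUE,
                        all.inside = TRUE)
  bin_b <- findInterval(values_b, brk, rightmost.closed = TRUE,
                        all.inside = TRUE)
  kept_a <- integer(0); kept_b <- integer(0)
  for (b in seq_len(n_bins)) {
    ia <- which(bin_a == b); ib <- which(bin_b == b)
    m <- min(length(ia), length(ib))
    if (m == 0) next
    kept_a <- c(kept_a, if (length(ia) > m) sample(ia, m) else ia)
    kept_b <- c(kept_b, if (length(ib) > m) sample(ib, m) else ib)
  }
  if (length(kept_a) == 0)
    stop2("no overlap between the two distributions; nothing to equate")
  structure(list(kept_a = sort(kept_a), kept_b = sort(kept_b),
                 n_bins = n_bins), class = "stratified_sample")
}
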