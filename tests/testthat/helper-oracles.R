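# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the code paths they check.

# BH step-up, spelled out from the definition
bh_step_up_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  running_min <- 1
  for (i in n:1) {
    running_min <- min(running_min, p[ord[i]] * n / i)
    adj[ord[i]] <- running_min
  }
  adj
}

# upper-tail hypergeometric via explicit binomial coefficients
hyper_tail_oracle <- function(k, K, n, N) {
  if (k <= 0) return(1)
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# min-over-prefixes ranked hypergeometric, naive loop
ranked_hyper_oracle <- function(query, term, background) {
  query <- query[query %in% background]
  term <- unique(term[term %in% background])
  N <- length(background); K <- length(term)
  best_p <- 1; best_d <- 0L
  if (length(query) && K > 0) {
    for (d in seq_along(query)) {
      k <- sum(query[1:d] %in% term)
      p <- hyper_tail_oracle(k, K, d, N)
      if (p < best_p - 1e-15) { best_p <- p; best_d <- d }
    }
    if (best_d == 0L) best_d <- 1L  # all-ones case: smallest depth wins ties
  }
  list(pvalue = best_p, depth = best_d)
}

# chi-square statistic of independence for a contingency table
chisq_stat_oracle <- function(M) {
  E <- outer(rowSums(M), colSums(M)) / sum(M)
  sum((M - E)^2 / E)
}

# small synthetic compendium shared across tests (built once per run)
tiny_compendium <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_compendium(seed = 42)
    cache
  }
})
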