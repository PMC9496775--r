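# Independent oracles and small utilities shared across tests.

# Adjusted Rand index between two hard labelings (noise label included as
# its own class).
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# Exact collapsed posterior over all k^N topic-assignment configurations of
# a single document (token word ids `words`, vocabulary size V), by direct
# enumeration of the collapsed joint
#   p(z, w) prop. prod_t Gamma(n_t^doc + alpha) *
#           prod_t [prod_w Gamma(n_tw + eta)] / Gamma(n_t + V eta).
enumerate_lda_posterior <- function(words, V, k, alpha, eta) {
  N <- length(words)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), N)))
  logp <- apply(grid, 1L, function(z) {
    lp <- 0
    for (t in seq_len(k)) {
      n_dt <- sum(z == t)
      lp <- lp + lgamma(n_dt + alpha) - lgamma(alpha)
      n_tw <- tabulate(words[z == t], nbins = V)
      lp <- lp + sum(lgamma(n_tw + eta) - lgamma(eta))
      lp <- lp - (lgamma(n_dt + V * eta) - lgamma(V * eta))
    }
    lp
  })
  p <- exp(logp - max(logp))
  list(configs = grid, prob = p / sum(p))
}

# Minimum spanning tree weight of a complete graph by brute force over all
# n^(n-2) Pruefer sequences (exact for small n).
brute_force_mst_weight <- function(w) {
  n <- nrow(w)
  if (n == 2L) return(w[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    prufer <- seqs[i, ]
    degree <- rep(1L, n)
    for (v in prufer) degree[v] <- degree[v] + 1L
    wt <- 0
    for (v in prufer) {
      leaf <- which.max(degree == 1L)  # smallest-index leaf
      wt <- wt + w[leaf, v]
      degree[leaf] <- 0L
      degree[v] <- degree[v] - 1L
    }
    rest <- which(degree == 1L)
    wt <- wt + w[rest[1L], rest[2L]]
    if (wt < best) best <- wt
  }
  best
}

# Small labeled corpus used across I/O and evaluation tests.
toy_corpus <- function() {
  corpus(
    texts = c("ho avuto febbre e spossatezza per mesi",
              "i miei colleghi in terapia intensiva",
              "una riflessione generale sulla pandemia"),
    labels = c("PASC", "non-PASC", "non-PASC"))
}

# Tiny synthetic configuration for fast pipeline tests.
small_synth_config <- function(seed = 1L) {
  synthetic_config(n_pasc = 25L, n_non_pasc = 35L,
                   mean_length_pasc = 60, mean_length_non_pasc = 90,
                   seed = seed)
}
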