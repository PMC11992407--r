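# Independent oracles the implementation is checked against.

# O(n^2) pair enumeration: TP/TN/pair counts straight from the definitions.
pair_counts_oracle <- function(a, b) {
  n <- length(a)
  tp <- 0L; tn <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
      if (same_a && same_b) tp <- tp + 1L
      if (!same_a && !same_b) tn <- tn + 1L
    }
  }
  list(tp = tp, tn = tn, n_pairs = n * (n - 1) / 2)
}

rand_index_oracle <- function(a, b) {
  pc <- pair_counts_oracle(a, b)
  (pc$tp + pc$tn) / pc$n_pairs
}

# ARI from pair enumeration plus the permutation-model adjustment computed
# from marginal pair sums (no contingency-table shortcut for the index).
ari_oracle <- function(a, b) {
  pc <- pair_counts_oracle(a, b)
  sum_a <- sum(choose(table(a), 2))
  sum_b <- sum(choose(table(b), 2))
  expected <- sum_a * sum_b / pc$n_pairs
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (pc$tp - expected) / (maximum - expected)
}

# direct entropies via the chain rule H(C|K) = H(C,K) - H(K)
entropy_oracle <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

homogeneity_oracle <- function(truth, pred) {
  hc <- entropy_oracle(truth)
  if (hc == 0) return(1)
  h_joint <- entropy_oracle(paste(truth, pred, sep = "\r"))
  1 - (h_joint - entropy_oracle(pred)) / hc
}

completeness_oracle <- function(truth, pred) homogeneity_oracle(pred, truth)

v_measure_oracle <- function(truth, pred, beta = 1) {
  h <- homogeneity_oracle(truth, pred)
  cm <- completeness_oracle(truth, pred)
  if (beta * h + cm == 0) return(0)
  (1 + beta) * h * cm / (beta * h + cm)
}

# small labelled blob generator for clustering checks (not the count model)
make_blobs <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), mean = rep(centers[i, ], each = n_per),
                 sd = sd), nrow = n_per)
  }))
  rownames(x) <- sprintf("c%03d", seq_len(nrow(x)))
  list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
}

small_sim <- function(n = 120, g = 200, design = "separate3", seed = 42, ...) {
  simulate_baseline(simulation_params(n, g, tree = preset_tree(design),
                                      seed = seed, ...))
}
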