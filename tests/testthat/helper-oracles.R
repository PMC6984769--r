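# Independent brute-force oracles, deliberately written without the
# package's vectorised index arithmetic.

oracle_groups7 <- local({
  groups <- c(A = 1, G = 1, V = 1, I = 2, L = 2, F = 2, P = 2,
              Y = 3, M = 3, T = 3, S = 3, H = 4, N = 4, Q = 4, W = 4,
              R = 5, K = 5, D = 6, E = 6, C = 7)
  function(x) unname(groups[x])
})

# classify every length-3 window one at a time
oracle_triad_counts <- function(seq) {
  r <- oracle_groups7(strsplit(seq, "")[[1]])
  counts <- numeric(343)
  for (i in seq_len(length(r) - 2)) {
    g <- r[i:(i + 2)]
    j <- 49 * (g[1] - 1) + 7 * (g[2] - 1) + g[3]
    counts[j] <- counts[j] + 1
  }
  counts
}

# tally 4-mer strings against the full lexicographic list
oracle_fourmer_counts <- function(seq) {
  kmers <- substring(seq, 1:(nchar(seq) - 3), 4:nchar(seq))
  all4 <- apply(expand.grid(rpiforest:::RNA4, rpiforest:::RNA4,
                            rpiforest:::RNA4, rpiforest:::RNA4)[, 4:1],
                1, paste, collapse = "")
  as.numeric(table(factor(kmers, levels = all4)))
}

# scalar per-point segment classifiers
oracle_classify24 <- function(p) {
  ang <- atan2(p[2], p[1])
  if (ang < 0) ang <- ang + 2 * pi
  sector <- min(floor(ang / (pi / 6)) + 1, 12)
  band <- if (sqrt(sum(p^2)) >= 0.5) 1 else 0
  2 * (sector - 1) + band + 1
}

oracle_classify16 <- function(p) {
  cc <- min(floor(4 * p[1]), 3)
  rr <- min(floor(4 * p[2]), 3)
  4 * rr + cc + 1
}

# Mann-Whitney AUC by explicit pair counting, ties counted half
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
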