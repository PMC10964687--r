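# Independent oracles and fixture builders used across the suite.

ALPH <- c("A", "C", "G", "T")

random_seqs <- function(n, t, seed, alphabet = ALPH) {
  set.seed(seed)
  vapply(seq_len(n), function(i)
    paste0(sample(alphabet, t, replace = TRUE), collapse = ""), character(1))
}

random_dataset <- function(n, t, seed) {
  seq_dataset(sprintf("s%d", seq_len(n)), random_seqs(n, t, seed))
}

# Dictionary (hash-map) k-mer counting oracle: counts every N-free window.
dict_count_oracle <- function(seqs, k) {
  counts <- list()
  for (s in seqs) {
    t <- nchar(s)
    if (t < k) next
    wins <- substring(s, 1:(t - k + 1), k:t)
    wins <- wins[!grepl("N", wins, fixed = TRUE)]
    for (w in wins) counts[[w]] <- (counts[[w]] %||% 0L) + 1L
  }
  unlist(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Brute-force Hamming-ball oracle: stored k-mers within distance d of query.
hamming_ball_oracle <- function(stored_kmers, query, d) {
  dist <- vapply(stored_kmers, hamming, 1L, b = query)
  sort(stored_kmers[dist <= d])
}

# Per-position background probability computed directly from the transition
# tables (no sliding sums): the naive counterpart of the fast decomposition.
naive_position_logp <- function(sequence, bg) {
  t <- nchar(sequence)
  chars <- strsplit(sequence, "")[[1]]
  r <- bg$order
  vapply(seq_len(t), function(j) {
    L <- min(j - 1, r)
    ctx <- if (L > 0) substr(sequence, j - L, j - 1) else ""
    tab <- bg$trans[[L + 1]]
    log(tab[match(ctx, rownames(tab)), match(chars[j], ALPH)])
  }, numeric(1))
}

# Naive three-product per-offset log marginal: background product up to the
# window, PWM product over the window, background product after it.
naive_log_marginal <- function(sequence, pwm_mat, bg) {
  k <- nrow(pwm_mat)
  t <- nchar(sequence)
  lp <- naive_position_logp(sequence, bg)
  chars <- strsplit(sequence, "")[[1]]
  bidx <- match(chars, ALPH)
  vapply(seq_len(t - k + 1), function(u) {
    pre <- if (u > 1) sum(lp[1:(u - 1)]) else 0
    win <- sum(log(pwm_mat[cbind(1:k, bidx[u:(u + k - 1)])]))
    post <- if (u + k <= t) sum(lp[(u + k):t]) else 0
    pre + win + post
  }, numeric(1))
}

random_pwm <- function(k, seed) {
  set.seed(seed)
  m <- matrix(runif(4 * k, 0.05, 1), nrow = k)
  pwm(m / rowSums(m))
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fa")
  writeLines(lines, path)
  path
}

# k-let count table of a sequence (brute force).
klet_counts <- function(s, klet) {
  t <- nchar(s)
  table(substring(s, 1:(t - klet + 1), klet:t))
}
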