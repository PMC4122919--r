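# Independent brute-force oracles. Each is written from the definition of
# the quantity, not from the package's implementation path.

# log P(obs) by exhaustive summation over all K^T hidden state paths
enum_forward <- function(obs, trans, emis, init) {
  K <- nrow(trans); T_ <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    p <- init[s[1]] * emis[s[1], obs[1]]
    if (T_ > 1) for (t in 2:T_) p <- p * trans[s[t - 1], s[t]] * emis[s[t], obs[t]]
    total <- total + p
  }
  log(total)
}

# max-path log probability by exhaustive enumeration
enum_viterbi <- function(obs, trans, emis, init) {
  K <- nrow(trans); T_ <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    lp <- log(init[s[1]]) + log(emis[s[1], obs[1]])
    if (T_ > 1) for (t in 2:T_) lp <- lp + log(trans[s[t - 1], s[t]]) + log(emis[s[t], obs[t]])
    if (lp > best) best <- lp
  }
  best
}

random_hmm <- function(K = 2, M = 4) {
  tr <- matrix(rgamma(K * K, 1), K); tr <- tr / rowSums(tr)
  em <- matrix(rgamma(K * M, 1), K); em <- em / rowSums(em)
  init <- rgamma(K, 1); init <- init / sum(init)
  list(trans = tr, emis = em, init = init)
}

# midrank Spearman from first principles: counting-based average ranks and
# the explicit Pearson product-moment formula
naive_spearman <- function(x, y) {
  midrank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) {
      less <- sum(v < v[i])
      eq <- sum(v == v[i])
      r[i] <- less + (eq + 1) / 2
    }
    r
  }
  a <- midrank(x); b <- midrank(y)
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  num / den
}

# affine-gap global alignment score by memoized enumeration of move
# sequences (match/gap-in-source/gap-in-target with the previous move
# tracked for gap opening). Gap of length k costs open + k * ext.
align_score_oracle <- function(s, t, match = 1, mismatch = -2,
                               gap_open = -5, gap_ext = -1) {
  s <- strsplit(s, "")[[1]]; t <- strsplit(t, "")[[1]]
  memo <- new.env(hash = TRUE)
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > length(s) && j > length(t)) return(0)
    best <- -Inf
    if (i <= length(s) && j <= length(t)) {
      sub <- if (s[i] == t[j] && s[i] != "N") match else mismatch
      best <- max(best, sub + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(s))   # source base unmatched: gap in target
      best <- max(best, (if (prev == "D") 0 else gap_open) + gap_ext +
                    rec(i + 1, j, "D"))
    if (j <= length(t))   # target base unmatched: gap in source
      best <- max(best, (if (prev == "I") 0 else gap_open) + gap_ext +
                    rec(i, j + 1, "I"))
    memo[[key]] <- best
    best
  }
  rec(1, 1, "start")
}

# discrete-time replication fork walk counting single-stranded steps
fork_sim_dssh <- function(L, origin_h, origin_l, direction = 1) {
  lead_arrival <- integer(L)
  pos <- origin_h
  for (t in 0:(L - 1)) {
    lead_arrival[pos + 1] <- t
    pos <- (pos + direction) %% L
  }
  D <- lead_arrival[origin_l + 1]
  lag_arrival <- integer(L)
  pos <- origin_l
  for (t in D:(D + L - 1)) {
    lag_arrival[pos + 1] <- t
    pos <- (pos - direction) %% L
  }
  pmax(lag_arrival - lead_arrival, 0)
}

# per-base boolean bitmap intersection
bitmap_overlap <- function(a, b) {
  L <- attr(a, "genome_length")
  va <- logical(L); vb <- logical(L)
  for (i in seq_len(nrow(a))) va[(a$start[i] + 1):a$end[i]] <- TRUE
  for (i in seq_len(nrow(b))) vb[(b$start[i] + 1):b$end[i]] <- TRUE
  sum(va & vb)
}

random_element_set <- function(L, n, max_len = 50) {
  starts <- sort(sample(0:(L - 1), n))
  ends <- pmin(starts + sample(1:max_len, n, replace = TRUE), L)
  keep <- logical(n); last_end <- -1L
  for (i in seq_len(n)) {
    if (starts[i] > last_end) { keep[i] <- TRUE; last_end <- ends[i] }
  }
  element_set(starts[keep], ends[keep], L)
}
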