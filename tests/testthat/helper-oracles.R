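# Independent oracles, deliberately implemented with none of the package's
# machinery: plain-R dynamic programming and closed-form statistics.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

mutate_subs <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  for (p in sample(length(ch), k)) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# Optimal overlap (free-end-gap) alignment SCORE by affine-gap DP:
# match +1, mismatch -1, gap of length L costs open + L * extend.
# Score-only, O(nm), three-state recurrence.
oracle_overlap_score <- function(a, b, match = 1, mismatch = -1,
                                 open = 2, extend = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # x[i] aligned to y[j]
  X <- matrix(NEG, n + 1, m + 1)   # gap in y (x[i] unmatched)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in x
  M[1, ] <- 0; M[, 1] <- 0         # free leading end gaps
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  # free trailing end gaps: best over last row/column, all states
  max(M[n + 1, ], M[, m + 1], X[n + 1, ], X[, m + 1],
      Y[n + 1, ], Y[, m + 1])
}

# Identity for equal-length, substitution-only comparisons (the unique
# optimal ungapped overlap alignment).
oracle_hamming_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  stopifnot(length(x) == length(y))
  sum(x == y) / length(x)
}

# Mean Hamming p-distance over all cross pairs of two gap-free groups.
oracle_between_group <- function(ga, gb) {
  tot <- 0; np <- 0
  for (a in ga) for (b in gb) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    tot <- tot + sum(x != y) / length(x)
    np <- np + 1
  }
  tot / np
}

# Textbook one-way fixed-effects ANOVA from sums of squares.
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  gbar <- tapply(values, groups, mean)
  ng <- tapply(values, groups, length)
  gm <- mean(values)
  ssb <- sum(ng * (gbar - gm)^2)
  ssw <- sum((values - gbar[groups])^2)
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, df_between = dfb, df_within = dfw,
       p = pf(f, dfb, dfw, lower.tail = FALSE))
}

# Hypergeometric moments for the count of one ribotype after drawing m of
# total sequences when the ribotype has count K.
hyper_mean <- function(m, K, total) m * K / total
hyper_var <- function(m, K, total) {
  m * (K / total) * (1 - K / total) * (total - m) / (total - 1)
}
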