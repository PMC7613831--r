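# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# BH step-up adjustment, literal definition: sort p ascending, q_i = p_i*m/i,
# enforce monotonicity from the largest rank down, clip at 1.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# hypergeometric upper tail by explicit pmf summation
bruteHyperTail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# AUC by all-pairs comparison, ties counted half
bruteAUC <- function(labels, scores) {
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# row-max localization by explicit scan
bruteLocalize <- function(atlas) {
  out <- character(nrow(atlas))
  for (i in seq_len(nrow(atlas))) {
    best <- 1
    for (j in seq_len(ncol(atlas)))
      if (atlas[i, j] > atlas[i, best]) best <- j
    out[i] <- colnames(atlas)[best]
  }
  out
}

# Venn region counts by per-element pattern tabulation
bruteVenn <- function(sets) {
  u <- unique(unlist(sets))
  pats <- vapply(u, function(e)
    paste(names(sets)[vapply(sets, function(s) e %in% s, logical(1))],
          collapse = "&"), "")
  table(pats)
}

# Pearson correlation from the covariance/SD definition
brutePearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# median-of-ratios size factors, loop form
bruteSizeFactors <- function(k) {
  geo <- apply(k, 1, function(r) prod(r)^(1 / length(r)))
  keep <- geo > 0
  vapply(seq_len(ncol(k)), function(j)
    median(k[keep, j] / geo[keep]), numeric(1))
}
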