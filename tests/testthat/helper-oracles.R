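# Independent oracles used to cross-check the package's own implementations.
# These deliberately use different algorithms from the code paths they verify.

# NIPALS PLS1: iterative first-component weight for a single response.
nipals_pls1_weight <- function(X, y, tol = 1e-12, max_iter = 500) {
  u <- y - mean(y)
  Xc <- scale(X, scale = FALSE)
  w <- rep(1 / sqrt(ncol(X)), ncol(X))
  for (i in seq_len(max_iter)) {
    w_new <- drop(crossprod(Xc, u))
    w_new <- w_new / sqrt(sum(w_new^2))
    t_scores <- drop(Xc %*% w_new)
    u <- y - mean(y)   # single response: u stays the centred y
    if (sqrt(sum((w_new - w)^2)) < tol) return(w_new)
    w <- w_new
  }
  w
}

# Brute-force Benjamini-Hochberg step-up: find the largest i with
# p_(i) <= i q / m and reject everything at or below it.
bh_bruteforce <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  pass <- which(ps <= seq_len(m) * q / m)
  rej <- rep(FALSE, m)
  if (length(pass)) rej[o[seq_len(max(pass))]] <- TRUE
  rej
}

# Pairwise-counting AUROC: P(score_pos > score_neg) + 0.5 P(tie).
auroc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive threshold scan over every observed score plus sentinels.
threshold_bruteforce <- function(scores, labels) {
  cand <- sort(unique(c(scores - 1e-9, scores + 1e-9,
                        min(scores) - 1, max(scores) + 1)))
  errs <- sapply(cand, function(th) {
    pred <- as.integer(scores >= th)
    sum(pred != labels)
  })
  min(errs)
}

# Pooled-variance two-sample t statistic, straight from the formula.
t_bruteforce <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}
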