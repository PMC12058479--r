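# Independent oracles used to validate the package implementations.

# Two-sided Fisher p by direct enumeration with binomial-coefficient
# ratios (no shared code with the package's log-space dhyper route).
fisher_enum_p <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- a + c
  n <- a + b + c + d
  lo <- max(0, m1 + m2 - n)
  hi <- min(m1, m2)
  ks <- lo:hi
  probs <- vapply(ks, function(k) {
    choose(m2, k) * choose(n - m2, m1 - k) / choose(n, m1)
  }, numeric(1))
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Damped-Newton maximum-likelihood logistic regression: an implementation
# independent of IRLS, with step halving on the log-likelihood.
newton_logistic <- function(x, y, tol = 1e-12, max_iter = 200) {
  x <- cbind(1, as.matrix(x))
  beta <- rep(0, ncol(x))
  loglik <- function(b) {
    eta <- as.vector(x %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll <- loglik(beta)
  for (i in seq_len(max_iter)) {
    p <- plogis(as.vector(x %*% beta))
    g <- as.vector(crossprod(x, y - p))
    h <- crossprod(x * (p * (1 - p)), x)
    step <- solve(h, g)
    lambda <- 1
    repeat {
      cand <- beta + lambda * step
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (max(abs(cand - beta)) < tol) {
      beta <- cand
      break
    }
    beta <- cand
    ll <- ll_new
  }
  beta
}

# O(n^2) pairwise-concordance AUC with half-credit for ties.
auc_pairwise <- function(score, y) {
  s1 <- score[y == 1]
  s0 <- score[y == 0]
  cmp <- outer(s1, s0, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}
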