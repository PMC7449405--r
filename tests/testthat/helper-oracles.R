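# Independent oracles used to cross-check package implementations. These are
# deliberately written as literal, naive transcriptions of the definitions and
# share no code with the package internals.

# Breadth-first flood fill labeling, queue-based, written independently of the
# package's union/stack implementation.
oracle_label_flood <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        r <- p[1] + o[1]; c <- p[2] + o[2]
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] != 0 && lab[r, c] == 0) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Literal step-by-step transcription of the DerSimonian-Laird formulas.
oracle_dl_meta <- function(beta, se) {
  k <- length(beta)
  w <- 1 / se^2
  beta_fe <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - beta_fe)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - (k - 1)) / C)
  w_star <- 1 / (se^2 + tau2)
  beta_re <- sum(w_star * beta) / sum(w_star)
  se_re <- sqrt(1 / sum(w_star))
  list(beta = beta_re, se = se_re, tau2 = tau2, q = Q,
       p = 2 * pnorm(-abs(beta_re / se_re)))
}

# Brute-force enumeration of the exact Hardy-Weinberg conditional
# distribution over heterozygote counts.
oracle_hwe_enum <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  nA <- 2 * n_hom_ref + n_het
  nB <- 2 * n_hom_alt + n_het
  hs <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  logp <- vapply(hs, function(h) {
    a <- (nA - h) / 2; b <- (nB - h) / 2
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(b + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

# Oracle distribution for one (n, nA) cell: exact p for every compatible
# heterozygote count at once (used by the exhaustive agreement tests).
oracle_hwe_all_hets <- function(n, nA) {
  nB <- 2 * n - nA
  hs <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  logp <- lgamma(n + 1) - lgamma((nA - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((nB - hs) / 2 + 1) + hs * log(2) +
    lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p <- vapply(seq_along(hs), function(i)
    min(1, sum(pr[pr <= pr[i] * (1 + 1e-9)])), numeric(1))
  list(het = hs, p = p)
}
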