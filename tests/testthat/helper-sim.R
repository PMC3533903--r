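# Shared fixtures and independent oracles, built in code.

# five polytomous items, 4 categories (m = 3)
bank4 <- function() {
  item_bank(list(v = c(-1.3, -0.2, 0.9), w = c(-0.9, 0.1, 1.2),
                 x = c(-0.5, 0.4, 1.4), y = c(-1.6, -0.6, 0.5),
                 z = c(-0.2, 0.7, 1.6)))
}

# five 5-category items (m = 4), GH-like
bank5 <- function() {
  item_bank(list(a = c(-1.7, -0.6, 0.2, 1.1), b = c(-1.2, -0.4, 0.6, 1.3),
                 c = c(-1, -0.1, 0.9, 1.6), d = c(-0.6, 0.1, 0.8, 1.7),
                 e = c(-1.5, -0.3, 0.4, 1.2)))
}

# draw a response matrix from a bank at given traits
draw_matrix <- function(theta, bank) {
  vapply(bank$delta, function(d) pcm_draw(theta, d), numeric(length(theta)))
}

# center a bank's thresholds to the PCE sum-zero identification
center_bank <- function(bank) {
  dv <- unlist(bank$delta)
  shift <- mean(dv)
  item_bank(lapply(bank$delta, function(d) d - shift))
}

# Independent oracle: PCM category probabilities by direct evaluation of
# the unnormalised terms (no shared code with pcm_prob).
oracle_pcm_prob <- function(theta, delta) {
  cd <- c(0, cumsum(delta))
  u <- exp((0:length(delta)) * theta - cd)
  u / sum(u)
}

# Independent oracle: log pairwise conditional likelihood by brute-force
# enumeration of all response pairs compatible with each observed sum.
oracle_pce_loglik <- function(delta, responses) {
  ids <- names(delta)
  ll <- 0
  for (j in seq_along(ids)[-length(ids)]) for (k in (j + 1L):length(ids)) {
    dj <- delta[[j]]; dk <- delta[[k]]
    cdj <- c(0, cumsum(dj)); cdk <- c(0, cumsum(dk))
    for (n in seq_len(nrow(responses))) {
      a <- responses[n, ids[j]]; b <- responses[n, ids[k]]
      if (is.na(a) || is.na(b)) next
      s <- a + b
      num <- exp(-cdj[a + 1] - cdk[b + 1])
      den <- 0
      for (aa in 0:length(dj)) for (bb in 0:length(dk))
        if (aa + bb == s) den <- den + exp(-cdj[aa + 1] - cdk[bb + 1])
      ll <- ll + log(num / den)
    }
  }
  ll
}

# Independent oracle: H_jk from explicit enumeration of the joint and
# comonotone-coupled tables.
oracle_hjk <- function(yj, yk) {
  n <- length(yj)
  ml_cov <- function(a, b) mean(a * b) - mean(a) * mean(b)
  ml_cov(yj, yk) / ml_cov(sort(yj), sort(yk))
}
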