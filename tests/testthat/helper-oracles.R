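# Independent oracles used across the suite. These deliberately avoid the
# package's own density/transition code paths.

# bivariate normal log density via explicit inverse and determinant
oracle_dmvnorm2 <- function(r, cov) {
  r <- as.numeric(r)
  inv <- solve(cov)
  -log(2 * pi) - 0.5 * determinant(cov, logarithm = TRUE)$modulus[1] -
    0.5 * drop(t(r) %*% inv %*% r)
}

# exact per-time state marginals by brute-force enumeration of all 2^T
# state sequences for a fixed path x and fixed parameters
oracle_state_marginals <- function(x, params) {
  T_ <- nrow(x)
  A <- rbind(c(params$alpha[1], 1 - params$alpha[1]),
             c(params$alpha[2], 1 - params$alpha[2]))
  s1 <- A[1, 2]; s2 <- A[2, 1]
  pi0 <- c(s2, s1) / (s1 + s2)
  # per-time, per-state process emission (log), times 1..2 flat
  em <- matrix(0, T_, 2)
  for (t in 3:T_) for (k in 1:2) {
    g <- params$gamma[k]; th <- params$theta[k]
    R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
    mu <- g * R %*% (x[t - 1, ] - x[t - 2, ])
    em[t, k] <- oracle_dmvnorm2((x[t, ] - x[t - 1, ]) - mu, params$sigma)
  }
  seqs <- as.matrix(expand.grid(rep(list(1:2), T_)))
  lp <- apply(seqs, 1, function(b) {
    v <- log(pi0[b[1]])
    for (t in 2:T_) v <- v + log(A[b[t - 1], b[t]])
    v + sum(em[cbind(seq_len(T_), b)])
  })
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  # P(b_t = 2) per time
  colSums(w * (seqs == 2))
}

# small deterministic toy path with visible state contrast
toy_path <- function(T_ = 6, seed = 99) {
  set.seed(seed)
  params <- process_params(gamma = c(0.9, 0.1), theta = c(0, pi),
                           sigma = diag(2), alpha = c(0.8, 0.2))
  p <- simulate_path(T_, params)
  list(x = p$x, b = p$b, params = params)
}

table1_params <- function(delta = "large") {
  process_params(gamma = c(if (delta == "large") 0.95 else 0.65, 0.10),
                 theta = c(0, pi), sigma = diag(2) * 25,
                 alpha = c(0.90, 0.10))
}
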