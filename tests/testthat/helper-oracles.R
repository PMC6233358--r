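# Independent oracles used across the suite.

# Dense joint-Gaussian moments of a dlm_spec: stacked theta_{0:K} and eta_{1:K}.
# Brute-force assembly, independent of the filter recursions.
dense_dlm_moments <- function(spec) {
  K <- spec$K
  p <- length(spec$m0)
  q <- ncol(spec$V_seq[[1L]])
  mean_th <- vector("list", K + 1L)
  mean_th[[1L]] <- spec$m0
  Cth <- array(NA_real_, c(K + 1L, K + 1L, p, p))
  Cth[1L, 1L, , ] <- as.matrix(spec$C0)
  for (k in seq_len(K)) {
    G <- spec$G_seq[[k]]
    mean_th[[k + 1L]] <- drop(G %*% mean_th[[k]])
    Cth[k + 1L, k + 1L, , ] <- G %*% Cth[k, k, , ] %*% t(G) + spec$W_seq[[k]]
    for (l in seq_len(k)) {
      Cth[k + 1L, l, , ] <- G %*% matrix(Cth[k, l, , ], p, p)
      Cth[l, k + 1L, , ] <- t(matrix(Cth[k + 1L, l, , ], p, p))
    }
  }
  mean_eta <- vector("list", K)
  Ceta <- array(NA_real_, c(K, K, q, q))
  Cthe <- array(NA_real_, c(K + 1L, K, p, q))   # Cov(theta_{k-1}, eta_l)
  for (k in seq_len(K)) {
    Fk <- spec$F_seq[[k]]
    mean_eta[[k]] <- drop(t(Fk) %*% mean_th[[k + 1L]])
    for (l in seq_len(K)) {
      Fl <- spec$F_seq[[l]]
      Ceta[k, l, , ] <- t(Fk) %*% matrix(Cth[k + 1L, l + 1L, , ], p, p) %*% Fl +
        if (k == l) spec$V_seq[[k]] else matrix(0, q, q)
    }
    for (j in seq_len(K + 1L)) {
      Cthe[j, k, , ] <- matrix(Cth[j, k + 1L, , ], p, p) %*% Fk
    }
  }
  list(mean_theta = mean_th, cov_theta = Cth,
       mean_eta = mean_eta, cov_eta = Ceta, cov_theta_eta = Cthe)
}

# log density of the observed (non-missing) eta rows under the dense joint
dense_dlm_loglik <- function(spec, eta, missing = rep(FALSE, spec$K)) {
  mom <- dense_dlm_moments(spec)
  obs <- which(!missing)
  q <- ncol(spec$V_seq[[1L]])
  n <- length(obs) * q
  mu <- unlist(mom$mean_eta[obs])
  Sig <- matrix(NA_real_, n, n)
  for (a in seq_along(obs)) for (b in seq_along(obs)) {
    Sig[(a - 1L) * q + seq_len(q), (b - 1L) * q + seq_len(q)] <-
      matrix(mom$cov_eta[obs[a], obs[b], , ], q, q)
  }
  x <- as.numeric(t(eta[obs, , drop = FALSE]))
  L <- chol((Sig + t(Sig)) / 2)
  z <- backsolve(L, x - mu, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# conditional moments of each theta_k given observed eta, from the dense joint
dense_dlm_smoother <- function(spec, eta, missing = rep(FALSE, spec$K)) {
  mom <- dense_dlm_moments(spec)
  obs <- which(!missing)
  p <- length(spec$m0)
  q <- ncol(spec$V_seq[[1L]])
  n <- length(obs) * q
  mu <- unlist(mom$mean_eta[obs])
  Sig <- matrix(NA_real_, n, n)
  for (a in seq_along(obs)) for (b in seq_along(obs)) {
    Sig[(a - 1L) * q + seq_len(q), (b - 1L) * q + seq_len(q)] <-
      matrix(mom$cov_eta[obs[a], obs[b], , ], q, q)
  }
  Sig_inv <- solve((Sig + t(Sig)) / 2)
  x <- as.numeric(t(eta[obs, , drop = FALSE]))
  s <- S <- vector("list", spec$K + 1L)
  for (j in seq_len(spec$K + 1L)) {
    Cxe <- matrix(NA_real_, p, n)
    for (a in seq_along(obs)) {
      Cxe[, (a - 1L) * q + seq_len(q)] <- matrix(mom$cov_theta_eta[j, obs[a], , ], p, q)
    }
    s[[j]] <- drop(mom$mean_theta[[j]] + Cxe %*% Sig_inv %*% (x - mu))
    S[[j]] <- matrix(mom$cov_theta[j, j, , ], p, p) - Cxe %*% Sig_inv %*% t(Cxe)
  }
  list(s = s, S = S)
}

# random small dlm_spec generator for property suites
random_dlm_spec <- function(K, p, q, seed) {
  set.seed(seed)
  rspd <- function(d, scale = 1) {
    A <- matrix(rnorm(d * d), d)
    scale * (A %*% t(A) / d + diag(0.2, d))
  }
  dlm_spec(
    F_seq = lapply(seq_len(K), function(k) matrix(rnorm(p * q), p, q)),
    G_seq = lapply(seq_len(K), function(k) {
      G <- matrix(rnorm(p * p, sd = 0.5), p); diag(G) <- 1; G
    }),
    W_seq = lapply(seq_len(K), function(k) rspd(p, 0.5)),
    V_seq = lapply(seq_len(K), function(k) rspd(q, 0.3)),
    m0 = rnorm(p), C0 = rspd(p, 2))
}

# deterministic small count fixture
toy_counts_fixture <- function(n = 8, D = 4, seed = 7) {
  set.seed(seed)
  m <- matrix(rpois(n * D, 30), n, D)
  count_table(m, paste0("t", seq_len(D)), paste0("s", seq_len(n)))
}
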