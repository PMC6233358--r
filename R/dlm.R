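#' Dynamic linear model specification
#'
#' Describes a Gaussian linear state-space model over `K` steps:
#' `eta_k = t(F_k) theta_k + v_k`, `v_k ~ N(0, V_k)`;
#' `theta_k = G_k theta_{k-1} + w_k`, `w_k ~ N(0, W_k)`;
#' `theta_0 ~ N(m0, C0)`.  All sequence arguments may be a single matrix
#' (recycled over steps) or a list of length `K`.
#'
#' @param F_seq `p x q` design matrix or list of them (`q` = observation dim).
#' @param G_seq `p x p` evolution matrix or list.
#' @param W_seq `p x p` evolution covariance or list (PSD; exactly zero is
#'   allowed and encodes no evolution, e.g. between technical replicates).
#' @param V_seq `q x q` observation covariance or list (positive definite).
#' @param m0 prior state mean (`p`-vector).
#' @param C0 prior state covariance (`p x p`, PSD).
#' @param K number of steps (required when all sequences are single matrices).
#' @return object of class `dlm_spec`.
#' @export
dlm_spec <- function(F_seq, G_seq, W_seq, V_seq, m0, C0, K = NULL) {
  as_seq <- function(x, K) {
    if (is.list(x)) x else rep(list(as.matrix(x)), K)
  }
  if (is.null(K)) {
    lens <- vapply(list(F_seq, G_seq, W_seq, V_seq), function(x)
      if (is.list(x)) length(x) else NA_integer_, integer(1))
    K <- stats::na.omit(lens)[1]
    if (is.na(K)) stop("K must be given when no argument is a list")
  }
  spec <- list(F_seq = as_seq(F_seq, K), G_seq = as_seq(G_seq, K),
               W_seq = as_seq(W_seq, K), V_seq = as_seq(V_seq, K),
               m0 = as.numeric(m0), C0 = as.matrix(C0), K = as.integer(K))
  lens <- vapply(spec[c("F_seq", "G_seq", "W_seq", "V_seq")], length, integer(1))
  if (!all(lens == K)) stop("sequence lengths must all equal K", call. = FALSE)
  for (nm in c("W_seq", "V_seq")) {
    for (k in seq_len(K)) .check_psd(spec[[nm]][[k]], paste0(nm, "[", k, "]"))
  }
  .check_psd(spec$C0, "C0")
  class(spec) <- "dlm_spec"
  spec
}

.check_psd <- function(S, name, tol = 1e-8) {
  S <- as.matrix(S)
  if (max(abs(S - t(S))) > tol * max(1, max(abs(S)))) {
    stop(name, " is not symmetric", call. = FALSE)
  }
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(1, max(abs(ev)))) {
    stop(name, " is not positive semi-definite", call. = FALSE)
  }
  invisible(S)
}

.sym <- function(S) (S + t(S)) / 2

# Cholesky with logged ridge fallback (policy: no silent jitter)
.chol_safe <- function(S, name = "covariance") {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(out)) {
    warning("Cholesky of ", name, " failed; adding 1e-10 ridge", call. = FALSE)
    out <- chol(S + diag(1e-10, nrow(S)))
  }
  out
}

.lmvn <- function(x, mean, cov) {
  # log N(x; mean, cov) via Cholesky
  L <- .chol_safe(.sym(cov), "one-step predictive covariance")
  z <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

#' Kalman filter with per-step missingness
#'
#' Runs the forward filtering recursion for a [dlm_spec], accumulating the
#' log marginal likelihood as the sum of one-step-ahead predictive log
#' densities over the observed steps.  A step flagged missing contributes
#' nothing to the likelihood: the moments are propagated through the
#' evolution equation only, which is identical to marginalizing that
#' observation out of the joint Gaussian.
#'
#' @param spec a [dlm_spec].
#' @param eta `K x q` matrix of observations (rows; ignored where missing).
#' @param missing logical vector of length `K`; `TRUE` marks a fully missing
#'   step.
#' @return object of class `dlm_filter`: lists `a`, `R` (predicted state
#'   moments), `m`, `C` (filtered), `f`, `Q` (one-step observation moments,
#'   `NULL` at missing steps), and scalar `log_marginal`.
#' @export
kalman_filter <- function(spec, eta, missing = rep(FALSE, spec$K)) {
  stopifnot(inherits(spec, "dlm_spec"))
  eta <- rbind(eta)
  K <- spec$K
  if (nrow(eta) != K) stop("eta must have one row per step", call. = FALSE)
  if (length(missing) != K) stop("missing flags must have length K", call. = FALSE)
  if (any(!is.finite(eta[!missing, , drop = FALSE]))) {
    stop("observed eta values must be finite", call. = FALSE)
  }
  m <- spec$m0
  C <- .sym(spec$C0)
  a <- R <- mm <- CC <- f <- Q <- vector("list", K)
  ll <- 0
  for (k in seq_len(K)) {
    G <- spec$G_seq[[k]]
    a[[k]] <- drop(G %*% m)
    R[[k]] <- .sym(G %*% C %*% t(G) + spec$W_seq[[k]])
    if (missing[k]) {
      m <- a[[k]]
      C <- R[[k]]
    } else {
      Fk <- spec$F_seq[[k]]
      f[[k]] <- drop(t(Fk) %*% a[[k]])
      Q[[k]] <- .sym(t(Fk) %*% R[[k]] %*% Fk + spec$V_seq[[k]])
      ll <- ll + .lmvn(eta[k, ], f[[k]], Q[[k]])
      Kg <- R[[k]] %*% Fk %*% solve(Q[[k]])
      m <- a[[k]] + drop(Kg %*% (eta[k, ] - f[[k]]))
      C <- .sym(R[[k]] - Kg %*% Q[[k]] %*% t(Kg))
    }
    mm[[k]] <- m
    CC[[k]] <- C
  }
  structure(list(a = a, R = R, m = mm, C = CC, f = f, Q = Q,
                 missing = missing, log_marginal = ll, spec = spec),
            class = "dlm_filter")
}

#' Kalman (RTS) smoother
#'
#' Backward recursion returning the margins of `p(theta_k | eta_{1:K})` for
#' `k = 0, ..., K` (index 0 is the prior state one step before the first
#' observation), together with the lag-one smoothed cross covariances
#' `Cov(theta_{k-1}, theta_k | eta)` used by EM-style score identities.
#'
#' @param spec the [dlm_spec] used for filtering.
#' @param filt the matching [kalman_filter] result.
#' @return list with `s` (list of smoothed means, index `k+1` holds step `k`,
#'   starting at step 0), `S` (smoothed covariances), and `lag1`
#'   (`lag1[[k]] = Cov(theta_{k-1}, theta_k | eta)` for `k = 1..K`).
#' @export
kalman_smoother <- function(spec, filt) {
  stopifnot(inherits(filt, "dlm_filter"))
  K <- spec$K
  if (filt$spec$K != K) stop("filter does not match spec length", call. = FALSE)
  s <- S <- vector("list", K + 1L)
  lag1 <- vector("list", K)
  s[[K + 1L]] <- filt$m[[K]]
  S[[K + 1L]] <- filt$C[[K]]
  m_all <- c(list(spec$m0), filt$m)     # filtered mean at step k-1 = m_all[[k]]
  C_all <- c(list(.sym(spec$C0)), filt$C)
  for (k in K:1) {
    G <- spec$G_seq[[k]]
    Rk <- filt$R[[k]]
    J <- C_all[[k]] %*% t(G) %*% solve(Rk)
    s[[k]] <- drop(m_all[[k]] + J %*% (s[[k + 1L]] - filt$a[[k]]))
    S[[k]] <- .sym(C_all[[k]] + J %*% (S[[k + 1L]] - Rk) %*% t(J))
    lag1[[k]] <- J %*% S[[k + 1L]]
  }
  list(s = s, S = S, lag1 = lag1)
}

#' Backward (FFBS) sampling of the state path
#'
#' Draws one exact joint sample of `theta_{0:K}` from
#' `p(theta | eta, V, W, F, G, m0, C0)` by sampling `theta_K` from its
#' filtered distribution and recursing backwards.
#'
#' @param spec the [dlm_spec].
#' @param filt the matching [kalman_filter] result.
#' @param n_draws number of independent joint draws.
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return array `n_draws x (K+1) x p`; index 1 of the second dimension is
#'   step 0.
#' @export
backward_sample <- function(spec, filt, n_draws = 1L, seed = NULL) {
  stopifnot(inherits(filt, "dlm_filter"))
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  K <- spec$K
  p <- length(spec$m0)
  out <- array(NA_real_, c(n_draws, K + 1L, p))
  m_all <- c(list(spec$m0), filt$m)
  C_all <- c(list(.sym(spec$C0)), filt$C)
  rmvn1 <- function(mean, cov) {
    ev <- eigen(.sym(cov), symmetric = TRUE)
    lam <- pmax(ev$values, 0)
    drop(mean + ev$vectors %*% (sqrt(lam) * stats::rnorm(length(mean))))
  }
  for (d in seq_len(n_draws)) {
    th <- rmvn1(filt$m[[K]], filt$C[[K]])
    out[d, K + 1L, ] <- th
    for (k in K:1) {
      G <- spec$G_seq[[k]]
      Rk <- filt$R[[k]]
      J <- C_all[[k]] %*% t(G) %*% solve(Rk)
      mean_k <- drop(m_all[[k]] + J %*% (th - filt$a[[k]]))
      cov_k <- .sym(C_all[[k]] - J %*% Rk %*% t(J))
      th <- rmvn1(mean_k, cov_k)
      out[d, k, ] <- th
    }
  }
  out
}
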