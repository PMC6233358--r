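#' Fit configuration
#'
#' Sampler settings for [mallard_fit()].  Defaults mirror the study setup
#' (4 chains, 1000 warmup / 1000 sampling iterations, convergence declared
#' at split-Rhat below 1.01, pseudo-count 0.65 initialization); scaled-down
#' runs override `n_warmup` / `n_samples`.
#'
#' @param n_chains number of chains (>= 1; >= 2 needed for split-Rhat).
#' @param n_warmup,n_samples warmup and retained iterations per chain.
#' @param rng_seed integer seed; chain `c` uses `rng_seed + 7919 * (c - 1)`.
#' @param rhat_threshold flag the fit non-converged if any split-Rhat is at
#'   or above this.
#' @param init_pseudocount pseudo-count added to counts for the eta
#'   initialization.
#' @param max_treedepth,adapt_delta No-U-Turn sampler controls.
#' @param block_sweeps number of Metropolis refreshment sweeps applied to
#'   the covariance-parameter block after every NUTS iteration (0 disables);
#'   the sweeps use the cheap value-only marginal density and substantially
#'   raise the effective sample size of the scale and correlation
#'   parameters.
#' @param divergence_warn warn if the post-warmup divergence fraction
#'   exceeds this.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(n_chains = 4L, n_warmup = 1000L, n_samples = 1000L,
                       rng_seed = 1L, rhat_threshold = 1.01,
                       init_pseudocount = 0.65, max_treedepth = 10L,
                       adapt_delta = 0.9, block_sweeps = 15L,
                       divergence_warn = 0.01) {
  stopifnot(n_chains >= 1L, n_warmup >= 1L, n_samples >= 1L,
            rhat_threshold > 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples),
                 rng_seed = as.integer(rng_seed),
                 rhat_threshold = rhat_threshold,
                 init_pseudocount = init_pseudocount,
                 max_treedepth = as.integer(max_treedepth),
                 adapt_delta = adapt_delta,
                 block_sweeps = as.integer(block_sweeps),
                 divergence_warn = divergence_warn),
            class = "fit_config")
}

# ---------------------------------------------------------------------------
# unconstrained parameterization
#
# upar = [vec(eta) | log sigma_V | z_V | log sigma_W | z_W]
# z are tanh canonical partial correlations feeding the Cholesky-factor
# construction of the correlation matrices.

.n_z <- function(p) p * (p - 1L) / 2L

.unpack_upar <- function(upar, K, p) {
  nz <- .n_z(p)
  ofs <- K * p
  list(eta = matrix(upar[seq_len(ofs)], K, p),
       lsV = upar[ofs + seq_len(p)],
       zV = if (nz > 0) upar[ofs + p + seq_len(nz)] else numeric(0),
       lsW = upar[ofs + p + nz + seq_len(p)],
       zW = if (nz > 0) upar[ofs + 2L * p + nz + seq_len(nz)] else numeric(0))
}

.pack_upar <- function(eta, lsV, zV, lsW, zW) {
  c(as.numeric(eta), lsV, zV, lsW, zW)
}

# Cholesky factor of a correlation matrix from unconstrained z.
# Row i of L: L[i,j] = w[i,j] * sqrt(q_j), q_j = prod_{m<j} (1 - w[i,m]^2),
# L[i,i] = sqrt(q_i), with w = tanh(z) laid out row-wise (i = 2..p, j < i).
.corr_chol <- function(z, p) {
  L <- diag(p)
  w <- tanh(z)
  idx <- 0L
  for (i in seq_len(p)[-1L]) {
    q <- 1
    for (j in seq_len(i - 1L)) {
      idx <- idx + 1L
      L[i, j] <- w[idx] * sqrt(q)
      q <- q * (1 - w[idx]^2)
    }
    L[i, i] <- sqrt(q)
  }
  list(L = L, w = w, corr = L %*% t(L))
}

# Value of the LKJ (Cholesky form) log density plus the z -> L log Jacobian,
# and the gradient in z of that value plus a model score backpropagated
# through the transform.  gL is d(model loglik)/dL (lower triangle + diag).
.corr_chol_vjp <- function(ch, gL, zeta, p) {
  w <- ch$w
  L <- ch$L
  nz <- length(w)
  val <- 0
  grad_z <- numeric(nz)
  idx <- 0L
  for (i in seq_len(p)[-1L]) {
    c_i <- p - i + 2 * zeta - 2
    for (jj in seq_len(i - 1L)) {
      m <- idx + jj
      # a_im: coefficient of log(1 - w^2) in the target
      a_im <- 0.5 * c_i + 0.5 * (i - 1L - jj) + 1
      val <- val + a_im * log(1 - w[m]^2)
      # model score: dL[i,j]/dw[i,m] terms
      q_m <- if (jj == 1L) 1 else prod(1 - w[idx + seq_len(jj - 1L)]^2)
      later <- 0
      if (jj < i - 1L) {
        for (j2 in (jj + 1L):(i - 1L)) {
          later <- later + gL[i, j2] * L[i, j2]
        }
      }
      later <- later + gL[i, i] * L[i, i]
      g_w <- gL[i, jj] * sqrt(q_m) - w[m] / (1 - w[m]^2) * later
      grad_z[m] <- g_w * (1 - w[m]^2) - 2 * a_im * w[m]
    }
    idx <- idx + i - 1L
  }
  list(value = val, grad_z = grad_z)
}

# ---------------------------------------------------------------------------
# marginalized log posterior and gradient in unconstrained space

.model_internals <- function(model) {
  obs <- which(model$schedule$steps$observed)
  Y <- model$counts$counts[model$count_row[obs], , drop = FALSE]
  list(obs = obs, Y = Y, n = rowSums(Y), psi = .psi(model$basis),
       K = model$schedule$n_steps, p = model$p,
       vessel_steps = model$vessel_steps,
       gaps = lapply(model$vessel_steps,
                     function(idx) model$schedule$steps$gap[idx]),
       m0 = model$m0, c0 = model$priors$C0_scale, priors = model$priors)
}

.lp_grad <- function(upar, mi) {
  p <- mi$p
  K <- mi$K
  reject <- list(lp = -Inf, grad = numeric(length(upar)))
  if (any(!is.finite(upar))) return(reject)
  u <- .unpack_upar(upar, K, p)
  sV <- exp(u$lsV)
  sW <- exp(u$lsW)
  chV <- .corr_chol(u$zV, p)
  chW <- .corr_chol(u$zW, p)
  V <- sV * t(sV * chV$corr)
  W <- sW * t(sW * chW$corr)
  if (any(!is.finite(V)) || any(!is.finite(W))) return(reject)

  # multinomial term and gradient at observed steps
  eta_obs <- u$eta[mi$obs, , drop = FALSE]
  clr_coord <- eta_obs %*% mi$psi
  mx <- apply(clr_coord, 1L, max)
  ez <- exp(clr_coord - mx)
  pr_mat <- ez / rowSums(ez)
  lp <- sum(mi$Y * (clr_coord - mx - log(rowSums(ez))))
  grad_eta <- matrix(0, K, p)
  grad_eta[mi$obs, ] <- (mi$Y - mi$n * pr_mat) %*% t(mi$psi)

  # marginal Gaussian term per vessel (Kalman filter + smoother gradients)
  SV <- matrix(0, p, p)
  SW <- matrix(0, p, p)
  for (vi in seq_along(mi$vessel_steps)) {
    idx <- mi$vessel_steps[[vi]]
    res <- .dlm_rw_lp_grad_cpp(t(u$eta[idx, , drop = FALSE]), mi$gaps[[vi]],
                               mi$m0, mi$c0, V, W)
    if (!is.finite(res$loglik)) return(reject)
    lp <- lp + res$loglik
    grad_eta[idx, ] <- grad_eta[idx, ] + t(res$grad_eta)
    SV <- SV + res$score_V
    SW <- SW + res$score_W
  }

  pr <- mi$priors
  # log-normal scale priors expressed in log sigma (Jacobian absorbed)
  lp <- lp + sum(stats::dnorm(u$lsV, pr$xi_V, pr$tau_V, log = TRUE)) +
    sum(stats::dnorm(u$lsW, pr$xi_W, pr$tau_W, log = TRUE))
  g_lsV <- -(u$lsV - pr$xi_V) / pr$tau_V^2
  g_lsW <- -(u$lsW - pr$xi_W) / pr$tau_W^2

  # chain rule: covariance scores -> scales and correlation parameters
  # d ll / d log sigma_i = 2 sigma_i (S diag(sigma) Lambda)_{ii}
  g_lsV <- g_lsV + 2 * sV * diag(t(t(SV) * sV) %*% chV$corr)
  g_lsW <- g_lsW + 2 * sW * diag(t(t(SW) * sW) %*% chW$corr)
  # S_Lambda = diag(sigma) S diag(sigma); dll/dL = 2 S_Lambda L
  gLV <- 2 * (outer(sV, sV) * SV) %*% chV$L
  gLW <- 2 * (outer(sW, sW) * SW) %*% chW$L
  vjV <- .corr_chol_vjp(chV, gLV, pr$zeta_V, p)
  vjW <- .corr_chol_vjp(chW, gLW, pr$zeta_W, p)
  lp <- lp + vjV$value + vjW$value

  list(lp = lp,
       grad = .pack_upar(grad_eta, g_lsV, vjV$grad_z, g_lsW, vjW$grad_z))
}

# value-only target evaluation (for Metropolis block refreshment)
.lp_value <- function(upar, mi) {
  p <- mi$p
  K <- mi$K
  if (any(!is.finite(upar))) return(-Inf)
  u <- .unpack_upar(upar, K, p)
  sV <- exp(u$lsV)
  sW <- exp(u$lsW)
  chV <- .corr_chol(u$zV, p)
  chW <- .corr_chol(u$zW, p)
  V <- sV * t(sV * chV$corr)
  W <- sW * t(sW * chW$corr)
  if (any(!is.finite(V)) || any(!is.finite(W))) return(-Inf)
  eta_obs <- u$eta[mi$obs, , drop = FALSE]
  clr_coord <- eta_obs %*% mi$psi
  mx <- apply(clr_coord, 1L, max)
  ez <- exp(clr_coord - mx)
  lp <- sum(mi$Y * (clr_coord - mx - log(rowSums(ez))))
  for (vi in seq_along(mi$vessel_steps)) {
    idx <- mi$vessel_steps[[vi]]
    ll <- .dlm_rw_loglik_cpp(t(u$eta[idx, , drop = FALSE]), mi$gaps[[vi]],
                             mi$m0, mi$c0, V, W)
    if (!is.finite(ll)) return(-Inf)
    lp <- lp + ll
  }
  pr <- mi$priors
  lp <- lp + sum(stats::dnorm(u$lsV, pr$xi_V, pr$tau_V, log = TRUE)) +
    sum(stats::dnorm(u$lsW, pr$xi_W, pr$tau_W, log = TRUE))
  zg <- matrix(0, p, p)
  lp + .corr_chol_vjp(chV, zg, pr$zeta_V, p)$value +
    .corr_chol_vjp(chW, zg, pr$zeta_W, p)$value
}

# ---------------------------------------------------------------------------
# No-U-Turn sampler with dual-averaging step size and diagonal metric,
# optionally composed with random-walk Metropolis refreshment sweeps on a
# slow-mixing parameter block (both kernels leave the target invariant)

.find_epsilon <- function(lp_grad_fn, theta, invM) {
  eps <- 0.1
  r <- stats::rnorm(length(theta)) / sqrt(invM)
  cur <- lp_grad_fn(theta)
  joint0 <- cur$lp - 0.5 * sum(r^2 * invM)
  step <- function(eps) {
    r1 <- r + 0.5 * eps * cur$grad
    th1 <- theta + eps * invM * r1
    nxt <- lp_grad_fn(th1)
    r1 <- r1 + 0.5 * eps * nxt$grad
    nxt$lp - 0.5 * sum(r1^2 * invM)
  }
  j1 <- step(eps)
  if (!is.finite(j1)) j1 <- -Inf
  a <- if (j1 - joint0 > log(0.5)) 1 else -1
  for (it in seq_len(50L)) {
    eps <- eps * 2^a
    j1 <- step(eps)
    if (!is.finite(j1)) j1 <- -Inf
    if (a * (j1 - joint0) <= a * log(0.5)) break
  }
  eps
}

.nuts_chain <- function(lp_grad_fn, init, n_warmup, n_samples, seed,
                        max_treedepth = 10L, adapt_delta = 0.8,
                        lp_value_fn = NULL, block_idx = NULL,
                        n_block_sweeps = 0L) {
  set.seed(seed)
  nb <- length(block_idx)
  bs_log_scale <- log(0.3)
  bs_adapt_n <- 0L
  bs_chol <- if (nb > 0L) diag(1, nb) else NULL
  n_par <- length(init)
  theta <- init
  invM <- rep(1, n_par)
  n_iter <- n_warmup + n_samples
  draws <- matrix(NA_real_, n_samples, n_par)
  lp_keep <- numeric(n_samples)
  divergent <- logical(n_samples)
  treedepth <- integer(n_samples)

  # adaptation schedule (Stan-style buffers, scaled to the warmup length)
  init_buf <- max(20L, as.integer(0.15 * n_warmup))
  term_buf <- max(10L, as.integer(0.10 * n_warmup))
  win_start <- init_buf + 1L
  win_size <- max(25L, as.integer(0.08 * n_warmup))
  win_ends <- integer(0)
  s <- win_start
  repeat {
    e <- s + win_size - 1L
    if (e + term_buf >= n_warmup || e + win_size + term_buf > n_warmup) {
      e <- n_warmup - term_buf
      win_ends <- c(win_ends, e)
      break
    }
    win_ends <- c(win_ends, e)
    s <- e + 1L
    win_size <- win_size * 2L
  }
  win_ends <- win_ends[win_ends > win_start]
  acc <- NULL  # accumulator for metric adaptation

  eps <- .find_epsilon(lp_grad_fn, theta, invM)
  mu <- log(10 * eps)
  log_eps_bar <- 0
  Hbar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  adapt_iter <- 0L

  cur <- lp_grad_fn(theta)
  env <- new.env()  # divergence flag for the current transition

  build_tree <- function(theta, r, grad, logu, v, j, joint0) {
    if (j == 0L) {
      r1 <- r + 0.5 * v * eps * grad
      th1 <- theta + v * eps * invM * r1
      nxt <- lp_grad_fn(th1)
      r1 <- r1 + 0.5 * v * eps * nxt$grad
      joint <- nxt$lp - 0.5 * sum(r1^2 * invM)
      if (!is.finite(joint)) joint <- -Inf
      n1 <- as.integer(logu <= joint)
      s1 <- logu < joint + 1000
      if (!s1) env$divergent <- TRUE
      alpha <- min(1, exp(joint - joint0))
      list(theta_minus = th1, r_minus = r1, grad_minus = nxt$grad,
           theta_plus = th1, r_plus = r1, grad_plus = nxt$grad,
           theta_prime = th1, lp_prime = nxt$lp, grad_prime = nxt$grad,
           n = n1, s = s1, alpha = alpha, n_alpha = 1L)
    } else {
      t1 <- build_tree(theta, r, grad, logu, v, j - 1L, joint0)
      if (!t1$s) return(t1)
      if (v == -1L) {
        t2 <- build_tree(t1$theta_minus, t1$r_minus, t1$grad_minus,
                         logu, v, j - 1L, joint0)
        t1$theta_minus <- t2$theta_minus
        t1$r_minus <- t2$r_minus
        t1$grad_minus <- t2$grad_minus
      } else {
        t2 <- build_tree(t1$theta_plus, t1$r_plus, t1$grad_plus,
                         logu, v, j - 1L, joint0)
        t1$theta_plus <- t2$theta_plus
        t1$r_plus <- t2$r_plus
        t1$grad_plus <- t2$grad_plus
      }
      ntot <- t1$n + t2$n
      if (t2$n > 0L && stats::runif(1) < t2$n / max(ntot, 1L)) {
        t1$theta_prime <- t2$theta_prime
        t1$lp_prime <- t2$lp_prime
        t1$grad_prime <- t2$grad_prime
      }
      dth <- t1$theta_plus - t1$theta_minus
      t1$s <- t2$s &&
        sum(dth * (invM * t1$r_minus)) >= 0 &&
        sum(dth * (invM * t1$r_plus)) >= 0
      t1$n <- ntot
      t1$alpha <- t1$alpha + t2$alpha
      t1$n_alpha <- t1$n_alpha + t2$n_alpha
      t1
    }
  }

  for (iter in seq_len(n_iter)) {
    r0 <- stats::rnorm(n_par) / sqrt(invM)
    joint0 <- cur$lp - 0.5 * sum(r0^2 * invM)
    logu <- joint0 - stats::rexp(1)
    env$divergent <- FALSE
    tm <- tp <- theta
    rm_ <- rp <- r0
    gm <- gp <- cur$grad
    j <- 0L
    n <- 1L
    s_flag <- TRUE
    prop <- list(theta = theta, lp = cur$lp, grad = cur$grad)
    alpha_sum <- 0; n_alpha <- 0L
    while (s_flag && j < max_treedepth) {
      v <- sample(c(-1L, 1L), 1L)
      if (v == -1L) {
        tr <- build_tree(tm, rm_, gm, logu, v, j, joint0)
        tm <- tr$theta_minus; rm_ <- tr$r_minus; gm <- tr$grad_minus
      } else {
        tr <- build_tree(tp, rp, gp, logu, v, j, joint0)
        tp <- tr$theta_plus; rp <- tr$r_plus; gp <- tr$grad_plus
      }
      if (tr$s && stats::runif(1) < tr$n / n) {
        prop <- list(theta = tr$theta_prime, lp = tr$lp_prime,
                     grad = tr$grad_prime)
      }
      n <- n + tr$n
      dth <- tp - tm
      s_flag <- tr$s &&
        sum(dth * (invM * rm_)) >= 0 && sum(dth * (invM * rp)) >= 0
      alpha_sum <- tr$alpha; n_alpha <- tr$n_alpha
      j <- j + 1L
    }
    theta <- prop$theta
    cur <- list(lp = prop$lp, grad = prop$grad)

    # Metropolis refreshment of the slow block (e.g. covariance parameters)
    if (!is.null(block_idx) && n_block_sweeps > 0L) {
      lp_cur <- cur$lp
      changed <- FALSE
      for (sweep in seq_len(n_block_sweeps)) {
        th_p <- theta
        th_p[block_idx] <- th_p[block_idx] +
          exp(bs_log_scale) * drop(stats::rnorm(nb) %*% bs_chol)
        lp_p <- lp_value_fn(th_p)
        acc_mh <- is.finite(lp_p) && log(stats::runif(1)) < lp_p - lp_cur
        if (acc_mh) {
          theta <- th_p
          lp_cur <- lp_p
          changed <- TRUE
        }
        if (iter <= n_warmup) {
          bs_adapt_n <- bs_adapt_n + 1L
          bs_log_scale <- bs_log_scale +
            (as.numeric(acc_mh) - 0.35) / sqrt(bs_adapt_n)
        }
      }
      if (changed) cur <- lp_grad_fn(theta)
    }

    if (iter <= n_warmup) {
      adapt_iter <- adapt_iter + 1L
      a_stat <- if (n_alpha > 0L) alpha_sum / n_alpha else 0
      Hbar <- (1 - 1 / (adapt_iter + t0)) * Hbar +
        (adapt_delta - a_stat) / (adapt_iter + t0)
      log_eps <- mu - sqrt(adapt_iter) / gamma * Hbar
      wt <- adapt_iter^(-kappa)
      log_eps_bar <- wt * log_eps + (1 - wt) * log_eps_bar
      eps <- exp(log_eps)
      if (iter > init_buf && iter <= n_warmup - term_buf) {
        acc <- rbind(acc, theta)
        if (iter %in% win_ends) {
          nobs <- nrow(acc)
          if (nobs >= 10L) {
            v_est <- apply(acc, 2L, stats::var)
            invM <- v_est * nobs / (nobs + 5) + 1e-3 * (5 / (nobs + 5))
            if (!is.null(block_idx) && nobs > nb + 5L) {
              # full-covariance Metropolis proposal for the slow block
              bc <- stats::cov(acc[, block_idx, drop = FALSE])
              bc <- bc * nobs / (nobs + 5) + diag(1e-6, nb)
              bs_chol <- chol(bc)
              bs_log_scale <- log(2.4 / sqrt(nb))
              bs_adapt_n <- 0L
            }
            acc <- NULL
            # restart step-size adaptation around the current step size
            eps <- .find_epsilon(lp_grad_fn, theta, invM)
            mu <- log(10 * eps)
            Hbar <- 0
            adapt_iter <- 0L
            log_eps_bar <- log(eps)
          }
        }
      }
      if (iter == n_warmup) eps <- exp(log_eps_bar)
    } else {
      i_keep <- iter - n_warmup
      draws[i_keep, ] <- theta
      lp_keep[i_keep] <- cur$lp
      divergent[i_keep] <- env$divergent
      treedepth[i_keep] <- j
    }
  }
  list(draws = draws, lp = lp_keep, divergent = divergent,
       treedepth = treedepth, eps = eps, invM = invM)
}

# ---------------------------------------------------------------------------
# initialization, fitting, diagnostics

#' Deterministic initialization of sampler parameters
#'
#' eta starts from the ILR of counts regularized by a pseudo-count (rows of
#' all zeros become uniform compositions); imputed steps carry the previous
#' observed value forward within their vessel; both correlation matrices
#' start at the identity (`z = 0`); log scales are drawn from their priors
#' under the chain seed.
#'
#' @param model a [mallard_model].
#' @param config a [fit_config].
#' @param chain chain number (1-based); sets the scale-draw seed.
#' @return unconstrained parameter vector.
#' @export
mallard_init <- function(model, config = fit_config(), chain = 1L) {
  mi <- .model_internals(model)
  eta <- matrix(0, mi$K, mi$p)
  Yp <- model$counts$counts + config$init_pseudocount
  props <- Yp / rowSums(Yp)
  eta_obs <- ilr(props, model$basis)
  eta[mi$obs, ] <- eta_obs[model$count_row[mi$obs], , drop = FALSE]
  for (idx in model$vessel_steps) {
    last <- NULL
    for (k in idx) {
      if (model$schedule$steps$observed[k]) {
        last <- eta[k, ]
      } else if (!is.null(last)) {
        eta[k, ] <- last
      }
    }
    # leading imputed steps: carry the first observed value backwards
    first_obs <- idx[which(model$schedule$steps$observed[idx])[1L]]
    for (k in idx) {
      if (k == first_obs) break
      eta[k, ] <- eta[first_obs, ]
    }
  }
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(config$rng_seed + 7919L * (chain - 1L))
  pr <- model$priors
  lsV <- stats::rnorm(mi$p, pr$xi_V, pr$tau_V)
  lsW <- stats::rnorm(mi$p, pr$xi_W, pr$tau_W)
  nz <- .n_z(mi$p)
  .pack_upar(eta, lsV, numeric(nz), lsW, numeric(nz))
}

#' Sample the marginal posterior of a MALLARD model
#'
#' Runs the in-package No-U-Turn sampler on the Kalman-marginalized
#' unnormalized log posterior `p(eta, V, W | Y)`; the latent states `theta`
#' are never MCMC parameters (draw them afterwards with [sample_theta()]).
#' Scales are sampled on the log scale and correlations through a
#' Cholesky-factor transform, with analytic gradients throughout.
#'
#' @param model a [mallard_model].
#' @param config a [fit_config].
#' @return object of class `mallard_fit` carrying per-chain draws of `eta`,
#'   `sigma_V`, `corr_V`, `sigma_W`, `corr_W`, derived `V` and `W`,
#'   diagnostics (`lp`, divergences, tree depths), and the split-Rhat table.
#' @export
mallard_fit <- function(model, config = fit_config()) {
  stopifnot(inherits(model, "mallard_model"), inherits(config, "fit_config"))
  mi <- .model_internals(model)
  lp_grad_fn <- function(th) .lp_grad(th, mi)
  lp_value_fn <- function(th) .lp_value(th, mi)
  K <- mi$K; p <- mi$p; nz <- .n_z(p)
  block_idx <- K * p + seq_len(2L * p + 2L * nz)
  nc <- config$n_chains; ns <- config$n_samples
  eta <- array(NA_real_, c(nc, ns, K, p))
  sigma_V <- sigma_W <- array(NA_real_, c(nc, ns, p))
  zdraw_V <- zdraw_W <- array(NA_real_, c(nc, ns, max(nz, 1L)))
  corr_V <- corr_W <- Vd <- Wd <- array(NA_real_, c(nc, ns, p, p))
  lp <- matrix(NA_real_, nc, ns)
  divergent <- matrix(FALSE, nc, ns)
  treedepth <- matrix(NA_integer_, nc, ns)
  eps <- numeric(nc)
  for (ch in seq_len(nc)) {
    init <- mallard_init(model, config, chain = ch)
    res <- .nuts_chain(lp_grad_fn, init, config$n_warmup, config$n_samples,
                       seed = config$rng_seed + 7919L * (ch - 1L),
                       max_treedepth = config$max_treedepth,
                       adapt_delta = config$adapt_delta,
                       lp_value_fn = lp_value_fn, block_idx = block_idx,
                       n_block_sweeps = config$block_sweeps)
    for (i in seq_len(ns)) {
      u <- .unpack_upar(res$draws[i, ], K, p)
      eta[ch, i, , ] <- u$eta
      sigma_V[ch, i, ] <- exp(u$lsV)
      sigma_W[ch, i, ] <- exp(u$lsW)
      if (nz > 0) {
        zdraw_V[ch, i, ] <- u$zV
        zdraw_W[ch, i, ] <- u$zW
      }
      cV <- .corr_chol(u$zV, p)$corr
      cW <- .corr_chol(u$zW, p)$corr
      corr_V[ch, i, , ] <- cV
      corr_W[ch, i, , ] <- cW
      Vd[ch, i, , ] <- exp(u$lsV) * t(exp(u$lsV) * cV)
      Wd[ch, i, , ] <- exp(u$lsW) * t(exp(u$lsW) * cW)
    }
    lp[ch, ] <- res$lp
    divergent[ch, ] <- res$divergent
    treedepth[ch, ] <- res$treedepth
    eps[ch] <- res$eps
  }
  fit <- structure(list(eta = eta, sigma_V = sigma_V, sigma_W = sigma_W,
                        z_V = zdraw_V, z_W = zdraw_W,
                        corr_V = corr_V, corr_W = corr_W, V = Vd, W = Wd,
                        lp = lp, divergent = divergent, treedepth = treedepth,
                        eps = eps, n_chains = nc, n_samples = ns,
                        K = K, p = p, config = config,
                        basis = model$basis, schedule = model$schedule),
                   class = "mallard_fit")
  fit$rhat <- split_rhat(fit)
  fit$converged <- all(is.finite(fit$rhat)) &&
    max(fit$rhat, na.rm = TRUE) < config$rhat_threshold
  div_frac <- mean(divergent)
  if (div_frac > config$divergence_warn) {
    warning(sprintf("%.1f%% divergent transitions post warmup; ",
                    100 * div_frac),
            "results may be biased (consider raising adapt_delta)",
            call. = FALSE)
  }
  if (!fit$converged && nc >= 2L) {
    warning(sprintf("max split-Rhat = %.4f >= %.3f: fit flagged non-converged",
                    max(fit$rhat, na.rm = TRUE), config$rhat_threshold),
            call. = FALSE)
  }
  mallard_log("fit", seed = config$rng_seed, config = config,
              max_rhat = sprintf("%.4f", suppressWarnings(
                max(fit$rhat, na.rm = TRUE))),
              divergence_fraction = sprintf("%.4f", div_frac))
  fit
}

#' @export
print.mallard_fit <- function(x, ...) {
  cat("mallard_fit:", x$n_chains, "chains x", x$n_samples, "samples;",
      x$K, "samples x", x$p, "ILR coordinates\n")
  cat(sprintf("max split-Rhat %.4f; %.2f%% divergent\n",
              suppressWarnings(max(x$rhat, na.rm = TRUE)),
              100 * mean(x$divergent)))
  invisible(x)
}

#' Split-chain potential scale reduction
#'
#' For a matrix of draws (iterations x chains), each chain is split in half
#' and the standard potential-scale-reduction factor is computed over the
#' resulting half-chains.  Zero-variance parameters give `NaN`.  For a
#' `mallard_fit`, the statistic is computed for every sampled scalar (each
#' eta coordinate, log scales, correlation transforms) and returned as a
#' named vector.
#'
#' @param x draw matrix (iterations x chains) or a `mallard_fit`.
#' @return scalar, or named vector for a fit.
#' @export
split_rhat <- function(x) {
  if (inherits(x, "mallard_fit")) return(.split_rhat_fit(x))
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("split_rhat needs at least 2 chains", call. = FALSE)
  if (nrow(x) < 4L) stop("split_rhat needs at least 4 iterations", call. = FALSE)
  n_half <- floor(nrow(x) / 2L)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(j)
    cbind(x[seq_len(n_half), j],
          x[(nrow(x) - n_half + 1L):nrow(x), j])))
  m <- ncol(halves)
  n <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2L, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(NaN)
  sqrt(((n - 1) / n * W + B / n) / W)
}

.split_rhat_fit <- function(fit) {
  nc <- fit$n_chains
  if (nc < 2L) {
    warning("split-Rhat undefined with a single chain", call. = FALSE)
    return(stats::setNames(NaN, "lp"))
  }
  ns <- fit$n_samples
  p <- fit$p
  nz <- .n_z(p)
  grab <- function(arr, name) {
    d <- dim(arr)
    n_slot <- prod(d[-(1:2)])
    v <- numeric(n_slot)
    for (j in seq_len(n_slot)) {
      slot_idx <- arrayInd(j, d[-(1:2)])
      dm <- matrix(NA_real_, ns, nc)
      for (ch in seq_len(nc)) {
        idx_list <- c(list(ch, seq_len(ns)), as.list(slot_idx))
        dm[, ch] <- do.call(`[`, c(list(arr), idx_list))
      }
      v[j] <- split_rhat(dm)
    }
    stats::setNames(v, paste0(name, "[", seq_len(n_slot), "]"))
  }
  out <- c(grab(fit$eta, "eta"),
           grab(log(fit$sigma_V), "log_sigma_V"),
           grab(log(fit$sigma_W), "log_sigma_W"))
  if (nz > 0) {
    out <- c(out, grab(fit$z_V, "z_V"), grab(fit$z_W, "z_W"))
  }
  out
}

#' Draw latent state paths conditional on posterior draws
#'
#' For each retained posterior draw, runs one forward-filtering
#' backward-sampling pass per vessel conditioned on that draw's `eta`, `V`
#' and `W`, returning exact joint draws of `theta` on the full padded time
#' grid (marginalized time points included; technical replicates share their
#' time's state).
#'
#' @param fit a [mallard_fit].
#' @param model the [mallard_model] that produced it.
#' @param seed integer seed.
#' @return the fit with an added `theta` array
#'   (`chains x samples x T x vessels x p`) and `theta_times` (the padded
#'   time grid).
#' @export
sample_theta <- function(fit, model, seed = 1L) {
  stopifnot(inherits(fit, "mallard_fit"), inherits(model, "mallard_model"))
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  sch <- model$schedule
  grid <- seq(min(sch$all_times), max(sch$all_times))
  Tn <- length(grid)
  R <- length(sch$vessels)
  p <- fit$p
  # per-vessel expanded structure, computed once
  ex_list <- lapply(sch$vessels, function(v) {
    ex <- expand_schedule(sch, v)
    step_idx <- which(sch$steps$vessel == v)
    # map expanded rows with an eta parameter to rows of the step table
    eta_row <- rep(NA_integer_, nrow(ex))
    eta_row[ex$status != "marginalized"] <- step_idx
    list(ex = ex, eta_row = eta_row,
         last_at_time = vapply(grid, function(tt)
           max(which(ex$time == tt)), integer(1)))
  })
  theta <- array(NA_real_, c(fit$n_chains, fit$n_samples, Tn, R, p))
  for (ch in seq_len(fit$n_chains)) {
    for (i in seq_len(fit$n_samples)) {
      V <- matrix(fit$V[ch, i, , ], p, p)
      W <- matrix(fit$W[ch, i, , ], p, p)
      for (vi in seq_len(R)) {
        exl <- ex_list[[vi]]
        eta_v <- matrix(NA_real_, nrow(exl$ex), p)
        okk <- !is.na(exl$eta_row)
        eta_v[okk, ] <- fit$eta[ch, i, exl$eta_row[okk], ]
        th <- .rw_ffbs(eta_v, missing = !okk, gaps = exl$ex$gap,
                       V = V, W = W, m0 = model$m0,
                       c0 = model$priors$C0_scale)
        theta[ch, i, , vi, ] <- th[exl$last_at_time + 1L, , drop = FALSE]
      }
    }
  }
  fit$theta <- theta
  fit$theta_times <- grid
  fit
}

# FFBS for the random-walk model over an expanded unit-gap sequence.
# eta: steps x p (NA rows where missing); gaps: 0 (replicate) or 1.
# Returns (steps + 1) x p; row 1 is theta_0.
.rw_ffbs <- function(eta, missing, gaps, V, W, m0, c0) {
  Ks <- nrow(eta)
  p <- ncol(eta)
  m <- matrix(NA_real_, Ks + 1L, p)
  Cl <- vector("list", Ks + 1L)
  Rl <- vector("list", Ks)
  m[1L, ] <- m0
  Cl[[1L]] <- diag(c0, p)
  for (k in seq_len(Ks)) {
    R <- Cl[[k]] + gaps[k] * W
    if (missing[k]) {
      m[k + 1L, ] <- m[k, ]
      Cl[[k + 1L]] <- R
    } else {
      Q <- R + V
      Kg <- R %*% solve(Q)
      m[k + 1L, ] <- m[k, ] + drop(Kg %*% (eta[k, ] - m[k, ]))
      Cl[[k + 1L]] <- .sym(R - Kg %*% R)
    }
    Rl[[k]] <- .sym(R)
  }
  rmvn1 <- function(mean, cov) {
    ev <- eigen(.sym(cov), symmetric = TRUE)
    drop(mean + ev$vectors %*% (sqrt(pmax(ev$values, 0)) *
                                  stats::rnorm(length(mean))))
  }
  th <- matrix(NA_real_, Ks + 1L, p)
  th[Ks + 1L, ] <- rmvn1(m[Ks + 1L, ], Cl[[Ks + 1L]])
  for (k in Ks:1L) {
    R <- Rl[[k]]
    if (all(R == 0)) {   # zero-gap replicate step: state carried over exactly
      th[k, ] <- th[k + 1L, ]
      next
    }
    J <- Cl[[k]] %*% solve(R)
    mean_k <- drop(m[k, ] + J %*% (th[k + 1L, ] - m[k, ]))
    cov_k <- .sym(Cl[[k]] - J %*% R %*% t(J))
    th[k, ] <- rmvn1(mean_k, cov_k)
  }
  th
}

#' Write and read a draw store
#'
#' Serializes a fit to a directory of plain CSV files (scalar parameters
#' with chain and iteration indices; eta in long format) plus a JSON file of
#' run metadata.
#'
#' @param fit a [mallard_fit].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_draws <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nc <- fit$n_chains; ns <- fit$n_samples; p <- fit$p
  idx <- expand.grid(iteration = seq_len(ns), chain = seq_len(nc))
  scalars <- data.frame(chain = idx$chain, iteration = idx$iteration)
  for (nm in c("sigma_V", "sigma_W")) {
    for (j in seq_len(p)) {
      scalars[[paste0(nm, ".", j)]] <- as.numeric(t(fit[[nm]][, , j]))
    }
  }
  for (nm in c("V", "W")) {
    for (a in seq_len(p)) for (b in a:p) {
      scalars[[paste0(nm, ".", a, ".", b)]] <- as.numeric(t(fit[[nm]][, , a, b]))
    }
  }
  scalars$lp <- as.numeric(t(fit$lp))
  scalars$divergent <- as.integer(t(fit$divergent))
  utils::write.csv(scalars, file.path(dir, "scalars.csv"), row.names = FALSE)
  rows <- vector("list", nc * ns)
  ri <- 0L
  for (ch in seq_len(nc)) for (i in seq_len(ns)) {
    ri <- ri + 1L
    rows[[ri]] <- data.frame(chain = ch, iteration = i,
                             step = rep(seq_len(fit$K), p),
                             coord = rep(seq_len(p), each = fit$K),
                             value = as.numeric(fit$eta[ch, i, , ]))
  }
  eta_long <- do.call(rbind, rows)
  utils::write.csv(eta_long, file.path(dir, "eta.csv"), row.names = FALSE)
  meta <- list(n_chains = nc, n_samples = ns, K = fit$K, p = fit$p,
               eps = fit$eps, rhat_max = suppressWarnings(
                 max(fit$rhat, na.rm = TRUE)),
               config = unclass(fit$config))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_draws
#' @export
read_draws <- function(dir) {
  scalars <- utils::read.csv(file.path(dir, "scalars.csv"))
  eta_long <- utils::read.csv(file.path(dir, "eta.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  nc <- meta$n_chains; ns <- meta$n_samples; K <- meta$K; p <- meta$p
  eta <- array(NA_real_, c(nc, ns, K, p))
  for (r in seq_len(nrow(eta_long))) {
    eta[eta_long$chain[r], eta_long$iteration[r],
        eta_long$step[r], eta_long$coord[r]] <- eta_long$value[r]
  }
  Vd <- Wd <- array(NA_real_, c(nc, ns, p, p))
  sigma_V <- sigma_W <- array(NA_real_, c(nc, ns, p))
  for (ch in seq_len(nc)) for (i in seq_len(ns)) {
    row <- which(scalars$chain == ch & scalars$iteration == i)
    for (j in seq_len(p)) {
      sigma_V[ch, i, j] <- scalars[row, paste0("sigma_V.", j)]
      sigma_W[ch, i, j] <- scalars[row, paste0("sigma_W.", j)]
    }
    for (a in seq_len(p)) for (b in seq_len(p)) {
      aa <- min(a, b); bb <- max(a, b)
      Vd[ch, i, a, b] <- scalars[row, paste0("V.", aa, ".", bb)]
      Wd[ch, i, a, b] <- scalars[row, paste0("W.", aa, ".", bb)]
    }
  }
  structure(list(eta = eta, sigma_V = sigma_V, sigma_W = sigma_W,
                 V = Vd, W = Wd,
                 lp = matrix(scalars$lp, nc, ns, byrow = TRUE),
                 divergent = matrix(as.logical(scalars$divergent), nc, ns,
                                    byrow = TRUE),
                 n_chains = nc, n_samples = ns, K = K, p = p),
            class = "mallard_fit")
}
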