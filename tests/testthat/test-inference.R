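make_tiny_model <- function(seed = 1, K = 4, D = 3, depth = 40) {
  set.seed(seed)
  basis <- contrast_from_partition(random_sbp(D, seed = seed + 50))
  ids <- paste0("s", seq_len(K))
  sch <- sample_schedule(ids, rep("v1", K), seq_len(K))
  Y <- t(sapply(seq_len(K), function(k)
    rmultinom(1, depth, clr_inv(rnorm(D)))[, 1]))
  cnt <- count_table(Y, basis$taxa_names, ids)
  mallard_model(cnt, sch, basis)
}

test_that("initialization applies the pseudo-count and is deterministic", {
  basis <- contrast_from_partition(sbp(rbind(c(1, -1, -1), c(0, 1, -1))))
  ids <- c("s1", "s2")
  cnt <- count_table(rbind(c(1, 0, 3), c(0, 0, 0)), basis$taxa_names, ids)
  mod <- mallard_model(cnt, sample_schedule(ids, c("v1", "v1"), 1:2), basis)
  cfg <- fit_config(rng_seed = 3)
  up <- mallard_init(mod, cfg)
  u <- mallard:::.unpack_upar(up, 2, 2)
  # row (1, 0, 3) with pseudo-count 0.65: (1.65, 0.65, 3.65) / 5.95
  expect_equal(ilr_inv(u$eta[1, ], basis),
               c(1.65, 0.65, 3.65) / 5.95, tolerance = 1e-10,
               ignore_attr = TRUE)
  # all-zero row becomes the uniform composition
  expect_equal(ilr_inv(u$eta[2, ], basis), rep(1 / 3, 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_identical(mallard_init(mod, cfg), up)
  # chains differ only in their random scale draws
  up2 <- mallard_init(mod, cfg, chain = 2)
  expect_identical(up2[1:4], up[1:4])
  expect_false(identical(up2[5:6], up[5:6]))
})

test_that("analytic gradients match central finite differences", {
  mod <- make_tiny_model(seed = 2, K = 5, D = 4)
  mi <- mallard:::.model_internals(mod)
  n_par <- mi$K * mi$p + 2 * mi$p + 2 * mallard:::.n_z(mi$p)
  set.seed(3)
  upar <- rnorm(n_par, 0, 0.6)
  res <- mallard:::.lp_grad(upar, mi)
  h <- 1e-6
  for (i in sample(n_par, 12)) {
    up <- upar; up[i] <- up[i] + h
    dn <- upar; dn[i] <- dn[i] - h
    g_fd <- (mallard:::.lp_grad(up, mi)$lp -
               mallard:::.lp_grad(dn, mi)$lp) / (2 * h)
    expect_equal(res$grad[i], g_fd, tolerance = 1e-5)
  }
})

test_that("the sampled target differs from log_posterior only by transform terms", {
  mod <- make_tiny_model(seed = 4)
  mi <- mallard:::.model_internals(mod)
  p <- mi$p
  nz <- mallard:::.n_z(p)
  set.seed(5)
  z_fix <- rnorm(2 * nz, 0, 0.4)
  gap_at <- function(eta_v, ls_v) {
    upar <- mallard:::.pack_upar(eta_v, ls_v[1:p], z_fix[1:nz],
                                 ls_v[p + 1:p], z_fix[nz + 1:nz])
    u <- mallard:::.unpack_upar(upar, mi$K, p)
    chV <- mallard:::.corr_chol(u$zV, p)
    chW <- mallard:::.corr_chol(u$zW, p)
    lp_z <- mallard:::.lp_grad(upar, mi)$lp
    lp_pub <- log_posterior(u$eta, exp(u$lsV), chV$corr, exp(u$lsW),
                            chW$corr, mod)
    # remove the log-sigma Jacobian so the remainder depends on z only
    lp_z - lp_pub - sum(u$lsV) - sum(u$lsW)
  }
  g1 <- gap_at(matrix(rnorm(mi$K * p), mi$K, p), rnorm(2 * p))
  g2 <- gap_at(matrix(rnorm(mi$K * p), mi$K, p), rnorm(2 * p))
  expect_equal(g1, g2, tolerance = 1e-9)
})

test_that("split rhat calibrates on known chain configurations", {
  set.seed(6)
  same <- matrix(rnorm(4000), 2000, 2)
  expect_lt(split_rhat(same), 1.01)
  expect_gte(split_rhat(same), sqrt(1 - 1 / 1000))  # attainable minimum
  apart <- cbind(rnorm(500), rnorm(500) + 5)
  expect_gt(split_rhat(apart), 1.5)
  expect_true(is.nan(split_rhat(matrix(1, 100, 2))))
  expect_error(split_rhat(matrix(rnorm(10), 10, 1)), "2 chains")
})

test_that("a degenerate one-sample model runs and returns finite draws", {
  basis <- contrast_from_partition(sbp(matrix(c(1, -1), 1)))
  cnt <- count_table(matrix(c(7, 3), 1, 2), basis$taxa_names, "s1")
  mod <- mallard_model(cnt, sample_schedule("s1", "v1", 1), basis)
  cfg <- fit_config(n_chains = 2, n_warmup = 80, n_samples = 60,
                    rng_seed = 5)
  fit <- suppressWarnings(mallard_fit(mod, cfg))
  expect_true(all(is.finite(fit$eta)))
  expect_true(all(is.finite(fit$V)))
  expect_true(all(fit$sigma_V > 0))
})

test_that("fits are reproducible given the seed", {
  mod <- make_tiny_model(seed = 7)
  cfg <- fit_config(n_chains = 2, n_warmup = 60, n_samples = 40,
                    rng_seed = 9)
  f1 <- suppressWarnings(mallard_fit(mod, cfg))
  f2 <- suppressWarnings(mallard_fit(mod, cfg))
  expect_identical(f1$eta, f2$eta)
  expect_identical(f1$V, f2$V)
})

test_that("marginalized sampling matches a theta-augmented brute-force MCMC", {
  mod <- make_tiny_model(seed = 10, K = 4, D = 3, depth = 60)
  mi <- mallard:::.model_internals(mod)
  K <- mi$K; p <- mi$p
  cfg <- fit_config(n_chains = 2, n_warmup = 500, n_samples = 1500,
                    rng_seed = 21)
  fit <- suppressWarnings(mallard_fit(mod, cfg))
  eta_mean_marg <- apply(fit$eta, c(3, 4), mean)

  # brute force: random-walk Metropolis on (eta, theta, log sigma, z) with
  # the complete-data density -- no Kalman marginalization anywhere
  pri <- mod$priors
  Y <- mi$Y
  psi <- mi$psi
  nz <- mallard:::.n_z(p)
  logdens <- function(par) {
    eta <- matrix(par[1:(K * p)], K, p)
    theta <- matrix(par[K * p + 1:((K + 1) * p)], K + 1, p)
    ofs <- K * p + (K + 1) * p
    lsV <- par[ofs + 1:p]; zV <- par[ofs + p + 1:nz]
    lsW <- par[ofs + p + nz + 1:p]; zW <- par[ofs + 2 * p + nz + 1:nz]
    chV <- mallard:::.corr_chol(zV, p); chW <- mallard:::.corr_chol(zW, p)
    V <- exp(lsV) * t(exp(lsV) * chV$corr)
    W <- exp(lsW) * t(exp(lsW) * chW$corr)
    Vi <- solve(V); Wi <- solve(W)
    ldV <- determinant(V)$modulus[1]; ldW <- determinant(W)$modulus[1]
    clr_coord <- eta %*% psi
    lp <- sum(Y * (clr_coord - log(rowSums(exp(clr_coord)))))
    dv <- eta - theta[-1, , drop = FALSE]
    lp <- lp - 0.5 * K * ldV - 0.5 * sum((dv %*% Vi) * dv)
    dw <- theta[-1, , drop = FALSE] - theta[-(K + 1), , drop = FALSE]
    lp <- lp - 0.5 * K * ldW - 0.5 * sum((dw %*% Wi) * dw)
    lp <- lp - 0.5 * sum(theta[1, ]^2) / pri$C0_scale
    lp <- lp + sum(dnorm(lsV, pri$xi_V, pri$tau_V, log = TRUE)) +
      sum(dnorm(lsW, pri$xi_W, pri$tau_W, log = TRUE))
    # same LKJ-on-Cholesky + Jacobian terms as the marginalized target
    lp + mallard:::.corr_chol_vjp(chV, matrix(0, p, p), pri$zeta_V, p)$value +
      mallard:::.corr_chol_vjp(chW, matrix(0, p, p), pri$zeta_W, p)$value
  }
  set.seed(31)
  n_par <- K * p + (K + 1) * p + 2 * p + 2 * nz
  par <- rnorm(n_par, 0, 0.3)
  cur <- logdens(par)
  n_iter <- 120000
  keep_every <- 20
  eta_sum <- matrix(0, K, p)
  kept <- 0
  sd_prop <- 0.12
  for (it in seq_len(n_iter)) {
    prop <- par + rnorm(n_par, 0, sd_prop)
    lp_prop <- logdens(prop)
    if (is.finite(lp_prop) && log(runif(1)) < lp_prop - cur) {
      par <- prop
      cur <- lp_prop
    }
    if (it > 20000 && it %% keep_every == 0) {
      eta_sum <- eta_sum + matrix(par[1:(K * p)], K, p)
      kept <- kept + 1
    }
  }
  eta_mean_brute <- eta_sum / kept
  expect_lt(max(abs(eta_mean_marg - eta_mean_brute)), 0.12)
})

test_that("conditional state draws behave like the smoother says", {
  p <- 2
  V <- diag(0.3, p)
  m0 <- c(0, 0)
  set.seed(12)
  eta <- matrix(rnorm(10), 5, p)
  # zero evolution noise: the path is constant over time
  th0 <- mallard:::.rw_ffbs(eta, missing = rep(FALSE, 5), gaps = rep(1, 5),
                            V = V, W = diag(1e-12, p), m0 = m0, c0 = 25)
  expect_lt(max(abs(sweep(th0, 2, th0[1, ]))), 1e-4)
  # replicate pooling: the state at a 5-fold replicated time has less spread
  ids <- paste0("s", 1:9)
  times <- c(1, 2, 3, 4, rep(5, 5))
  sch <- sample_schedule(ids, rep("v1", 9), times)
  basis <- contrast_from_partition(random_sbp(3, seed = 13))
  set.seed(14)
  cnt <- count_table(matrix(rpois(9 * 3, 50), 9, 3), basis$taxa_names, ids)
  mod <- mallard_model(cnt, sch, basis)
  cfg <- fit_config(n_chains = 2, n_warmup = 150, n_samples = 150,
                    rng_seed = 15)
  fit <- suppressWarnings(mallard_fit(mod, cfg))
  fit <- sample_theta(fit, mod, seed = 16)
  expect_equal(dim(fit$theta), c(2, 150, 5, 1, 2))
  expect_true(all(is.finite(fit$theta)))
  spread <- apply(fit$theta[, , , 1, ], 3, function(x) mean(apply(
    matrix(x, ncol = 2), 2, var)))
  expect_lt(spread[5], min(spread[1:4]))
})

test_that("parameter recovery: credible intervals cover simulated truth", {
  # scaled-down replicate study of the recovery experiment
  n_rep <- 6
  hits_W <- hits_V <- 0
  for (rep_i in seq_len(n_rep)) {
    W <- matrix(c(0.05, 0.01, 0.01, 0.05), 2)
    V <- matrix(c(0.2, -0.1, -0.1, 0.2), 2)
    basis <- contrast_from_partition(random_sbp(3, seed = 100 + rep_i))
    ids <- sprintf("s%03d", 1:110)
    times <- c(1:100, rep(100, 10))
    sch <- sample_schedule(ids, rep("v1", 110), times)
    set.seed(200 + rep_i)
    depths <- round(exp(runif(110, log(100), log(5000))))
    sim <- simulate_series(W, V, c(1, -2), basis, sch, depths,
                           seed = 300 + rep_i)
    mod <- mallard_model(sim$counts, sch, basis)
    cfg <- fit_config(n_chains = 2, n_warmup = 200, n_samples = 200,
                      rng_seed = 400 + rep_i)
    fit <- suppressWarnings(mallard_fit(mod, cfg))
    tr_W <- apply(fit$W, c(1, 2), function(m) sum(diag(matrix(m, 2, 2))))
    tr_V <- apply(fit$V, c(1, 2), function(m) sum(diag(matrix(m, 2, 2))))
    ci_W <- quantile(tr_W, c(0.025, 0.975))
    ci_V <- quantile(tr_V, c(0.025, 0.975))
    if (ci_W[1] <= 0.1 && 0.1 <= ci_W[2]) hits_W <- hits_W + 1
    if (ci_V[1] <= 0.4 && 0.4 <= ci_V[2]) hits_V <- hits_V + 1
  }
  expect_gte(hits_W, n_rep - 2)
  expect_gte(hits_V, n_rep - 2)
})

test_that("draw stores round-trip through CSV", {
  mod <- make_tiny_model(seed = 20)
  cfg <- fit_config(n_chains = 2, n_warmup = 50, n_samples = 20,
                    rng_seed = 30)
  fit <- suppressWarnings(mallard_fit(mod, cfg))
  d <- tempfile()
  write_draws(fit, d)
  fit2 <- read_draws(d)
  expect_equal(fit2$eta, fit$eta, tolerance = 1e-12)
  expect_equal(fit2$V, fit$V, tolerance = 1e-12)
  expect_equal(fit2$lp, fit$lp, ignore_attr = TRUE, tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
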