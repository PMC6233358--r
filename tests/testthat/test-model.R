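test_that("schedules classify replicates, gaps and marginalized times", {
  sch <- sample_schedule(paste0("s", 1:6), rep("v1", 6),
                         c(1, 2, 2, 5, 5, 5))
  expect_equal(sch$steps$gap, c(1, 1, 0, 3, 0, 0))
  expect_equal(sum(is_replicate(sch)), 3)
  expect_equal(sch$marginalized_times, c(3, 4))
  expect_error(sample_schedule("a", "v", 0), "positive")
  expect_error(sample_schedule(c("a", "a"), c("v", "v"), c(1, 2)),
               "duplicate")
  expect_error(sample_schedule(character(0), character(0), integer(0)),
               "empty")
})

test_that("evolution covariances follow the replicate and padding rules", {
  W <- matrix(c(2, 1, 1, 2), 2)
  # all distinct times: every step gets W
  sch1 <- sample_schedule(paste0("s", 1:4), rep("v1", 4), 1:4)
  Ws <- build_evolution_covariances(sch1, W)[["v1"]]
  expect_true(all(vapply(Ws, function(m) identical(m, W), logical(1))))
  # 20 samples at the final time point: 19 consecutive zero matrices
  sch2 <- sample_schedule(paste0("s", 1:24), rep("v1", 24),
                          c(1:5, rep(5, 19)))
  Ws2 <- build_evolution_covariances(sch2, W)[["v1"]]
  zeros <- vapply(Ws2, function(m) all(m == 0), logical(1))
  expect_equal(sum(zeros), 19)
  expect_true(all(zeros[(length(zeros) - 18):length(zeros)]))
  # a time observed nowhere contributes one W step with no observation
  sch3 <- sample_schedule(paste0("s", 1:3), rep("v1", 3), c(1, 2, 4))
  ex3 <- expand_schedule(sch3, "v1")
  expect_equal(nrow(ex3), 4)
  expect_equal(ex3$status[ex3$time == 3], "marginalized")
  Ws3 <- build_evolution_covariances(sch3, W)[["v1"]]
  expect_equal(length(Ws3), 4)
  expect_true(all(vapply(Ws3, function(m) identical(m, W), logical(1))))
})

test_that("vessel-specific missing times are imputed, shared gaps marginalized", {
  sch <- sample_schedule(c("a1", "a2", "a3", "b1", "b3"),
                         c("v1", "v1", "v1", "v2", "v2"),
                         c(1, 2, 3, 1, 3))
  st <- sch$steps
  # v2 lacks time 2, which v1 observes: imputed step for v2
  imp <- st[!st$observed, ]
  expect_equal(nrow(imp), 1)
  expect_equal(imp$vessel, "v2")
  expect_equal(imp$time, 2)
  expect_equal(sch$marginalized_times, integer(0))
})

test_that("covariance decompositions reconstruct exactly", {
  expect_equal(decomposition_to_cov(c(1, 1), diag(2)), diag(2))
  expect_equal(decomposition_to_cov(c(2, 3), matrix(c(1, 0.5, 0.5, 1), 2)),
               matrix(c(4, 3, 3, 9), 2))
  set.seed(1)
  for (i in 1:10) {
    A <- matrix(rnorm(9), 3)
    Sig <- A %*% t(A) + diag(0.1, 3)
    d <- cov_to_decomposition(Sig)
    expect_equal(decomposition_to_cov(d$sigma, d$corr), Sig,
                 tolerance = 1e-10)
    expect_equal(diag(d$corr), rep(1, 3))
  }
  expect_error(decomposition_to_cov(c(1, 1), matrix(c(2, 0, 0, 1), 2)),
               "unit diagonal")
})

test_that("log_posterior equals the dense Gaussian + multinomial oracle", {
  set.seed(11)
  D <- 3
  basis <- contrast_from_partition(random_sbp(D, seed = 2))
  ids <- paste0("s", 1:5)
  sch <- sample_schedule(ids, rep("v1", 5), c(1, 2, 2, 4, 5))
  cnt <- count_table(matrix(rpois(5 * D, 25), 5, D,
                            dimnames = list(ids, basis$taxa_names)))
  pri <- mallard_priors()
  mod <- mallard_model(cnt, sch, basis, pri)
  p <- D - 1
  eta <- matrix(rnorm(sch$n_steps * p), sch$n_steps, p)
  sV <- c(0.7, 1.2); sW <- c(0.5, 0.9)
  cV <- matrix(c(1, -0.3, -0.3, 1), 2)
  cW <- matrix(c(1, 0.4, 0.4, 1), 2)
  lp <- log_posterior(eta, sV, cV, sW, cW, mod)
  # oracle: dense joint Gaussian via general dlm spec with explicit steps
  V <- decomposition_to_cov(sV, cV)
  W <- decomposition_to_cov(sW, cW)
  gaps <- sch$steps$gap
  spec <- dlm_spec(F_seq = rep(list(diag(p)), 5),
                   G_seq = rep(list(diag(p)), 5),
                   W_seq = lapply(gaps, function(g) g * W),
                   V_seq = rep(list(V), 5),
                   m0 = rep(0, p), C0 = diag(25, p))
  gauss <- dense_dlm_loglik(spec, eta)
  multi <- sum(vapply(1:5, function(k)
    dmultinom(cnt$counts[k, ], prob = ilr_inv(eta[k, ], basis), log = TRUE),
    numeric(1)))
  prior_term <- sum(dlnorm(sV, pri$xi_V, pri$tau_V, log = TRUE)) +
    sum(dlnorm(sW, pri$xi_W, pri$tau_W, log = TRUE)) +
    (pri$zeta_V - 1) * determinant(cV)$modulus[1] +
    (pri$zeta_W - 1) * determinant(cW)$modulus[1]
  expect_equal(lp, gauss + multi + prior_term, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("a zero-depth sample adds nothing to the count term", {
  D <- 3
  basis <- contrast_from_partition(random_sbp(D, seed = 3))
  ids <- c("s1", "s2")
  sch <- sample_schedule(ids, c("v1", "v1"), c(1, 2))
  set.seed(4)
  cnt1 <- count_table(rbind(rpois(D, 20), rep(0, D)), basis$taxa_names, ids)
  eta <- matrix(rnorm(2 * (D - 1)), 2)
  mod1 <- mallard_model(cnt1, sch, basis)
  # changing eta at the zero-depth sample only shifts the Gaussian term
  lp_a <- log_posterior(eta, c(1, 1), diag(2), c(1, 1), diag(2), mod1)
  eta2 <- eta
  eta2[2, ] <- eta[2, ] + 0.5
  lp_b <- log_posterior(eta2, c(1, 1), diag(2), c(1, 1), diag(2), mod1)
  gaps <- sch$steps$gap
  V <- W <- diag(2)
  spec <- dlm_spec(F_seq = rep(list(diag(2)), 2), G_seq = rep(list(diag(2)), 2),
                   W_seq = lapply(gaps, function(g) g * W),
                   V_seq = rep(list(V), 2), m0 = c(0, 0), C0 = diag(25, 2))
  expect_equal(lp_b - lp_a,
               dense_dlm_loglik(spec, eta2) - dense_dlm_loglik(spec, eta),
               tolerance = 1e-8)
})

test_that("identical vessels double the filter term", {
  D <- 3
  basis <- contrast_from_partition(random_sbp(D, seed = 5))
  set.seed(6)
  Y <- matrix(rpois(4 * D, 30), 4, D)
  eta1 <- matrix(rnorm(4 * (D - 1)), 4)
  sch1 <- sample_schedule(paste0("s", 1:4), rep("v1", 4), 1:4)
  cnt1 <- count_table(Y, basis$taxa_names, paste0("s", 1:4))
  mod1 <- mallard_model(cnt1, sch1, basis)
  sch2 <- sample_schedule(paste0("s", 1:8), rep(c("v1", "v2"), each = 4),
                          rep(1:4, 2))
  cnt2 <- count_table(rbind(Y, Y), basis$taxa_names, paste0("s", 1:8))
  mod2 <- mallard_model(cnt2, sch2, basis)
  eta2 <- rbind(eta1, eta1)
  args <- list(c(0.8, 1.1), matrix(c(1, 0.2, 0.2, 1), 2),
               c(0.6, 0.9), matrix(c(1, -0.1, -0.1, 1), 2))
  lp1 <- do.call(log_posterior, c(list(eta1), args, list(mod1)))
  lp2 <- do.call(log_posterior, c(list(eta2), args, list(mod2)))
  # data + filter terms double; the shared prior term is counted once
  pri <- mod1$priors
  prior_term <- sum(dlnorm(args[[1]], pri$xi_V, pri$tau_V, log = TRUE)) +
    sum(dlnorm(args[[3]], pri$xi_W, pri$tau_W, log = TRUE))
  expect_equal(lp2 - lp1, lp1 - prior_term, tolerance = 1e-8)
})

test_that("log_posterior is invariant to reordering technical replicates", {
  D <- 3
  basis <- contrast_from_partition(random_sbp(D, seed = 7))
  set.seed(8)
  ids <- paste0("s", 1:5)
  times <- c(1, 2, 2, 2, 3)
  Y <- matrix(rpois(5 * D, 25), 5, D, dimnames = list(ids, basis$taxa_names))
  eta <- matrix(rnorm(5 * (D - 1)), 5)
  perm <- c(1, 4, 3, 2, 5)   # swap two replicates at time 2
  mod_a <- mallard_model(count_table(Y), sample_schedule(ids, rep("v1", 5), times), basis)
  mod_b <- mallard_model(count_table(Y[perm, ]),
                         sample_schedule(ids[perm], rep("v1", 5), times),
                         basis)
  args <- list(c(1, 1), diag(2), c(0.5, 0.5), diag(2))
  lp_a <- do.call(log_posterior, c(list(eta), args, list(mod_a)))
  # schedule orders by time, so permuted rows land in permuted step order
  lp_b2 <- do.call(log_posterior, c(list(eta[perm, ]), args, list(mod_b)))
  expect_equal(lp_b2, lp_a, tolerance = 1e-8)
})

test_that("the count term does not depend on the ILR basis", {
  D <- 4
  b1 <- contrast_from_partition(random_sbp(D, seed = 9))
  b2 <- contrast_from_partition(random_sbp(D, seed = 10))
  set.seed(11)
  x <- clr_inv(rnorm(D))
  Y <- rmultinom(1, 500, x)[, 1]
  ll1 <- mallard:::.multinom_loglik(rbind(ilr(x, b1)), rbind(Y), .psi(b1))
  ll2 <- mallard:::.multinom_loglik(rbind(ilr(x, b2)), rbind(Y), .psi(b2))
  expect_equal(ll1, ll2, tolerance = 1e-10)
  expect_equal(ll1, dmultinom(Y, prob = x, log = TRUE), tolerance = 1e-10)
})

test_that("prior draws respect their construction", {
  pri <- mallard_priors()
  ps <- prior_sample(pri, p = 2, n_draws = 4000, seed = 42)
  # LKJ(1) off-diagonal is uniform on (-1, 1) at p = 2
  off <- ps$corr_V[, 1, 2]
  ks <- suppressWarnings(ks.test(off, punif, -1, 1))
  expect_gt(ks$p.value, 0.001)
  # log sigma_W has the prior location and scale
  lw <- log(ps$sigma_W)
  expect_lt(abs(mean(lw) - 0), 3 * 2 / sqrt(length(lw)))
  expect_lt(abs(sd(lw) - 2), 0.05)
  # decomposition invariants hold draw by draw
  for (i in 1:50) {
    expect_equal(diag(ps$corr_W[i, , ]), rep(1, 2))
    expect_gte(min(eigen(ps$corr_W[i, , ])$values), -1e-12)
  }
  # deterministic given the seed
  ps2 <- prior_sample(pri, p = 2, n_draws = 10, seed = 7)
  ps3 <- prior_sample(pri, p = 2, n_draws = 10, seed = 7)
  expect_identical(ps2, ps3)
})

test_that("the default state prior bounds single-taxon enrichment near 200", {
  bound <- prior_theta0_ratio_bound(mallard_priors(), D = 10)
  expect_equal(bound, exp(sqrt(25 * 10 / 9)), tolerance = 1e-12)
  # Monte-Carlo oracle for the same standard deviation
  set.seed(13)
  basis <- contrast_from_partition(random_sbp(10, seed = 14))
  th <- matrix(rnorm(2e5 * 9, 0, 5), ncol = 9)
  clr_draws <- th %*% .psi(basis)
  ratio_log <- (10 / 9) * clr_draws[, 1]
  expect_equal(sd(ratio_log), log(bound), tolerance = 0.01)
  expect_lt(abs(bound - 200) / 200, 0.05)
})

test_that("LKJ sampler matches the known Beta marginal for larger p", {
  set.seed(15)
  draws <- rlkj_corr(2000, 3, zeta = 2)
  # at p = 3, zeta = 2: marginal of any off-diagonal is 2*Beta(2.5, 2.5)-1
  off <- draws[, 1, 2]
  ks <- suppressWarnings(ks.test((off + 1) / 2, pbeta, 2.5, 2.5))
  expect_gt(ks$p.value, 0.001)
})

test_that("the implied technical:biological ratio prior is as measured", {
  # the log-normal scale priors put the MEDIAN total-variation ratio near
  # e^2 (~7.4, i.e. 'approximately 10'); the probability of the ratio lying
  # in [1e-2, 1e2] is well below 95% (measured ~0.78 at p = 9)
  pr <- prior_variation_ratio_probability(p = 9, n_draws = 5e4, seed = 4)
  expect_gt(pr, 0.74)
  expect_lt(pr, 0.82)
  set.seed(5)
  sv <- matrix(rlnorm(5e4 * 9, 1, 2), ncol = 9)
  sw <- matrix(rlnorm(5e4 * 9, 0, 2), ncol = 9)
  med_ratio <- median(rowSums(sv^2) / rowSums(sw^2))
  expect_equal(log(med_ratio), 2, tolerance = 0.1)
})
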