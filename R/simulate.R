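#' Simulate counts from the generative state-space model
#'
#' Runs the model forwards: per vessel, the latent state `theta` performs a
#' Gaussian random walk over the schedule (one innovation of covariance `W`
#' per base-interval step, none between technical replicates), technical
#' noise `v ~ N(0, V)` perturbs each sample's `eta = theta + v`
#' independently (replicates share `theta` but not `v`), and counts are
#' multinomial with probabilities `ilr_inv(eta)` at the sample's depth.
#'
#' @param W,V `(D-1) x (D-1)` biological and technical covariances (PSD).
#' @param theta0 initial state: `(D-1)`-vector shared by all vessels, or a
#'   `vessels x (D-1)` matrix.
#' @param basis a [contrast_matrix] (defines D).
#' @param schedule a [sample_schedule]; counts are generated at its observed
#'   steps.
#' @param depths sequencing depth per observed step (recycled), in the order
#'   of `schedule$steps[schedule$steps$observed, ]`.
#' @param seed integer seed.
#' @return list with `counts` (a [count_table]) and `truth` (class
#'   `sim_truth`: `theta_true`, `eta_true` per schedule step, `W`, `V`,
#'   `theta0`, `basis`, `depths`, `seed`).
#' @export
simulate_series <- function(W, V, theta0, basis, schedule, depths,
                            seed = 1L) {
  stopifnot(inherits(schedule, "sample_schedule"))
  psi <- .psi(basis)
  p <- nrow(psi)
  W <- as.matrix(W); V <- as.matrix(V)
  .check_psd(W, "W"); .check_psd(V, "V")
  if (!all(dim(W) == p) || !all(dim(V) == p)) {
    stop("W and V must be (D-1) x (D-1) for the basis", call. = FALSE)
  }
  R <- length(schedule$vessels)
  theta0 <- if (is.matrix(theta0)) theta0 else
    matrix(theta0, R, p, byrow = TRUE)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  cW <- .msqrt(W)
  cV <- .msqrt(V)
  st <- schedule$steps
  n_obs <- sum(st$observed)
  depths <- rep_len(depths, n_obs)
  theta_true <- eta_true <- matrix(NA_real_, nrow(st), p)
  counts <- matrix(0L, n_obs, ncol(psi))
  oi <- 0L
  for (vi in seq_len(R)) {
    idx <- which(st$vessel == schedule$vessels[vi])
    th <- theta0[vi, ]
    for (k in idx) {
      g <- st$gap[k]
      # g accumulated base-interval innovations have covariance g * W
      if (g > 0L) th <- th + sqrt(g) * drop(cW %*% stats::rnorm(p))
      theta_true[k, ] <- th
      eta <- th + drop(cV %*% stats::rnorm(p))
      eta_true[k, ] <- eta
      if (st$observed[k]) {
        oi <- oi + 1L
        pi_k <- ilr_inv(eta, psi)
        counts[oi, ] <- stats::rmultinom(1L, depths[oi], pi_k)
      }
    }
  }
  obs_ids <- st$sample_id[st$observed]
  tab <- count_table(counts, colnames(psi), obs_ids)
  truth <- structure(list(theta_true = theta_true, eta_true = eta_true,
                          W = W, V = V, theta0 = theta0, basis = basis,
                          depths = depths, seed = seed, schedule = schedule),
                     class = "sim_truth")
  list(counts = tab, truth = truth)
}

.msqrt <- function(S) {
  ev <- eigen(.sym(S), symmetric = TRUE)
  ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
}

#' Three-taxon toy simulation
#'
#' A single vessel followed over 200 time points with 25 extra technical
#' replicates at the final time point; samples at times 15, 16 and 20 are
#' deleted after simulation (they remain in the model as marginalized
#' evolution steps).  True parameters: `W` with diagonal 0.05 and
#' off-diagonal 0.01, `V` with diagonal 0.2 and off-diagonal -0.1,
#' `theta0 = (1, -3)`, expressed in a random ILR basis.  Sequencing depths
#' are drawn log-uniformly from `depth_range`, which with the default
#' `[50, 5000]` produces data rich in zero and low counts.
#'
#' @param seed integer seed for states, noise, depths and counts.
#' @param depth_range range of the log-uniform depth distribution.
#' @param basis_seed seed of the random basis (fixed by default so the basis
#'   is reproducible independently of `seed`).
#' @return list with `counts`, `truth` (see [simulate_series()]), `schedule`
#'   (the post-deletion [sample_schedule]) and `basis`.
#' @export
simulate_toy <- function(seed = 1L, depth_range = c(50, 5000),
                         basis_seed = 4711L) {
  W <- matrix(c(0.05, 0.01, 0.01, 0.05), 2L)
  V <- matrix(c(0.2, -0.1, -0.1, 0.2), 2L)
  theta0 <- c(1, -3)
  part <- random_sbp(3L, seed = basis_seed)
  basis <- contrast_from_partition(part)
  times <- c(1:200, rep(200L, 25L))
  ids <- sprintf("s%03d", seq_along(times))
  full_sched <- sample_schedule(ids, rep("v1", length(times)), times)
  st <- full_sched$steps
  n_obs <- sum(st$observed)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  depths <- round(exp(stats::runif(n_obs, log(depth_range[1L]),
                                   log(depth_range[2L]))))
  sim <- simulate_series(W, V, theta0, basis, full_sched, depths,
                         seed = seed + 1L)
  drop_times <- c(15L, 16L, 20L)
  keep_ids <- st$sample_id[st$observed & !(st$time %in% drop_times)]
  counts <- count_table(sim$counts$counts[keep_ids, , drop = FALSE],
                        sim$counts$taxa_names, keep_ids)
  keep_rows <- st$observed & !(st$time %in% drop_times)
  schedule <- sample_schedule(st$sample_id[keep_rows],
                              st$vessel[keep_rows], st$time[keep_rows])
  list(counts = counts, truth = sim$truth, schedule = schedule,
       basis = basis, partition = part)
}

#' Multi-vessel artificial-gut-style simulation
#'
#' Emulates a bioreactor sampling design: `n_vessels` independent vessels
#' sharing `W` and `V`, sampled daily over `n_days` (with some days
#' missing), then hourly for `hourly_days` days, with `n_replicates` extra
#' technical replicates at the final time point of each vessel.  Daily-only
#' periods are represented on the hourly base interval, so the skipped hours
#' become marginalized evolution steps.
#'
#' @param n_vessels number of vessels.
#' @param schedule_spec list with `n_days`, `missing_days` (day indices with
#'   no sample anywhere), `hourly_days`, `n_replicates`.
#' @param W,V covariance matrices; defaults extend the toy magnitudes to
#'   four taxa (biological diagonal 0.05, off-diagonal 0.01; technical
#'   diagonal 0.2, off-diagonal -0.05).
#' @param theta0 initial state vector or `n_vessels x (D-1)` matrix.
#' @param depth_range log-uniform depth range.
#' @param seed integer seed.
#' @param basis a [contrast_matrix]; default is a random basis from
#'   `basis_seed`.
#' @param basis_seed seed of the default random basis.
#' @return list with `counts`, `truth`, `schedule`, `basis`.
#' @export
simulate_gut_study <- function(n_vessels = 4L,
                               schedule_spec = list(n_days = 28L,
                                                    missing_days = c(10L, 15L, 21L),
                                                    hourly_days = 5L,
                                                    n_replicates = 20L),
                               W = NULL, V = NULL, theta0 = NULL,
                               depth_range = c(5000, 50000), seed = 1L,
                               basis = NULL, basis_seed = 2718L) {
  if (is.null(basis)) {
    basis <- contrast_from_partition(random_sbp(4L, seed = basis_seed))
  }
  p <- nrow(.psi(basis))
  if (is.null(W)) W <- diag(0.05 - 0.01, p) + matrix(0.01, p, p)
  if (is.null(V)) V <- diag(0.2 + 0.05, p) + matrix(-0.05, p, p)
  if (is.null(theta0)) theta0 <- rep(0, p)
  sp <- schedule_spec
  daily_days <- setdiff(seq_len(sp$n_days), sp$missing_days)
  daily_hours <- (daily_days - 1L) * 24L + 1L
  hourly_hours <- sp$n_days * 24L + seq_len(sp$hourly_days * 24L)
  final_hour <- max(hourly_hours)
  times_one <- c(daily_hours, hourly_hours, rep(final_hour, sp$n_replicates))
  vessel <- rep(paste0("v", seq_len(n_vessels)), each = length(times_one))
  times <- rep(times_one, n_vessels)
  ids <- sprintf("%s_s%03d", vessel, rep(seq_along(times_one), n_vessels))
  schedule <- sample_schedule(ids, vessel, times)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  n_obs <- sum(schedule$steps$observed)
  depths <- round(exp(stats::runif(n_obs, log(depth_range[1L]),
                                   log(depth_range[2L]))))
  sim <- simulate_series(W, V, theta0, basis, schedule, depths,
                         seed = seed + 1L)
  list(counts = sim$counts, truth = sim$truth, schedule = schedule,
       basis = basis)
}

#' Write a simulation to disk
#'
#' Emits the count TSV, the manifest TSV, the basis sign-matrix TSV (when
#' the basis came from a partition) and a JSON file of the true parameters
#' and seed.
#'
#' @param sim result of [simulate_toy()], [simulate_gut_study()] or a
#'   `simulate_series` pair plus schedule.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(sim$counts, file.path(dir, "counts.tsv"))
  sched <- if (!is.null(sim$schedule)) sim$schedule else sim$truth$schedule
  write_manifest(sched, file.path(dir, "manifest.tsv"))
  if (!is.null(sim$partition)) {
    write_sbp_tsv(sim$partition, file.path(dir, "basis.tsv"))
  }
  truth <- sim$truth
  jsonlite::write_json(
    list(W = truth$W, V = truth$V, theta0 = truth$theta0,
         depths = truth$depths, seed = truth$seed,
         psi = .psi(truth$basis)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    matrix = "rowmajor")
  invisible(dir)
}
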