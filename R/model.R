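#' Sample schedule for replicated, gappy longitudinal designs
#'
#' Maps each sample to a time index on a declared base interval (e.g. hourly)
#' and to a series (vessel).  Duplicate (vessel, time) pairs are technical
#' replicates.  Time points observed in at least one vessel but missing from
#' another are flagged for imputation in the vessels lacking them (an eta
#' parameter with no count likelihood); time points observed in no vessel are
#' marginalized by the Kalman filter through widened evolution steps.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param vessel vessel / series label per sample.
#' @param time positive integer time index per sample on the base interval.
#' @return object of class `sample_schedule` with a `steps` data frame (one
#'   row per model step: `vessel`, `time`, `gap`, `observed`, `sample_id`),
#'   the observed time grid `all_times`, `marginalized_times`, and `n_steps`.
#' @export
sample_schedule <- function(sample_id, vessel, time) {
  if (length(sample_id) == 0L) stop("empty schedule", call. = FALSE)
  if (anyDuplicated(sample_id)) stop("duplicate sample ids", call. = FALSE)
  time <- as.integer(time)
  if (any(is.na(time)) || any(time < 1L)) {
    stop("time indices must be positive integers on the base interval",
         call. = FALSE)
  }
  vessel <- as.character(vessel)
  all_times <- sort(unique(time))
  t0 <- min(all_times) - 1L
  full_grid <- seq(min(all_times), max(all_times))
  marginalized <- setdiff(full_grid, all_times)
  vessels <- unique(vessel)
  steps <- vector("list", length(vessels))
  for (vi in seq_along(vessels)) {
    v <- vessels[vi]
    rows <- which(vessel == v)
    rows <- rows[order(time[rows], rows)]
    v_steps <- data.frame(vessel = character(0), time = integer(0),
                          observed = logical(0), sample_id = character(0))
    for (tt in all_times) {
      here <- rows[time[rows] == tt]
      if (length(here) == 0L) {
        v_steps <- rbind(v_steps, data.frame(
          vessel = v, time = tt, observed = FALSE, sample_id = NA_character_))
      } else {
        v_steps <- rbind(v_steps, data.frame(
          vessel = v, time = tt, observed = TRUE, sample_id = sample_id[here]))
      }
    }
    prev <- c(t0, v_steps$time[-nrow(v_steps)])
    v_steps$gap <- v_steps$time - prev
    steps[[vi]] <- v_steps
  }
  steps <- do.call(rbind, steps)
  rownames(steps) <- NULL
  structure(list(steps = steps, vessels = vessels, all_times = all_times,
                 marginalized_times = marginalized,
                 n_steps = nrow(steps), base_time = t0),
            class = "sample_schedule")
}

#' @rdname sample_schedule
#' @param x object to test / print.
#' @export
is_replicate <- function(x) {
  stopifnot(inherits(x, "sample_schedule"))
  x$steps$observed & x$steps$gap == 0L
}

#' Per-step evolution covariances
#'
#' Expands a shared biological covariance `W` into the per-step sequence of
#' the model: one `W` step for every advance of the time index (including
#' time points marginalized in all vessels, which contribute an evolution
#' step with no observation) and the zero matrix between technical
#' replicates that share a time index.
#'
#' @param schedule a [sample_schedule].
#' @param W `(D-1) x (D-1)` biological covariance.
#' @return named list per vessel; each element is a list of per-step
#'   covariance matrices aligned with [expand_schedule] for that vessel.
#' @export
build_evolution_covariances <- function(schedule, W) {
  W <- as.matrix(W)
  zero <- matrix(0, nrow(W), ncol(W))
  out <- lapply(schedule$vessels, function(v) {
    ex <- expand_schedule(schedule, v)
    lapply(seq_len(nrow(ex)), function(i) if (ex$gap[i] > 0L) W else zero)
  })
  names(out) <- schedule$vessels
  out
}

#' Expanded per-vessel step sequence
#'
#' Returns one row per base-interval step for a vessel, including time
#' points marginalized in all vessels (`status = "marginalized"`), time
#' points imputed for this vessel (`"imputed"`), observed samples
#' (`"observed"`), and zero-gap technical replicates.
#'
#' @param schedule a [sample_schedule].
#' @param vessel one of `schedule$vessels`.
#' @return data frame with columns `time`, `gap`, `status`, `sample_id`.
#' @export
expand_schedule <- function(schedule, vessel) {
  st <- schedule$steps[schedule$steps$vessel == vessel, , drop = FALSE]
  rows <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    g <- st$gap[i]
    pad <- if (g > 1L) {
      data.frame(time = (st$time[i] - g + 1L):(st$time[i] - 1L), gap = 1L,
                 status = "marginalized", sample_id = NA_character_)
    } else NULL
    status <- if (!st$observed[i]) "imputed" else "observed"
    rows[[i]] <- rbind(pad, data.frame(
      time = st$time[i], gap = min(g, 1L), status = status,
      sample_id = st$sample_id[i]))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prior settings for the hierarchical covariance model
#'
#' Defaults follow the artificial-gut analysis: a diffuse state prior
#' (`m0 = 0`, `C0 = 25 I`, under which a single taxon is within about
#' 200-fold of the geometric mean of the rest at one standard deviation),
#' uniform LKJ priors on the technical and biological correlation matrices
#' (`zeta = 1`), and log-normal priors on the scale components with
#' `log sigma_V ~ N(1, 2^2)` and `log sigma_W ~ N(0, 2^2)`.
#'
#' @param m0 prior state mean; scalar is recycled to length `D - 1` at model
#'   build time.
#' @param C0_scale scalar `c` in `C0 = c I`; must be positive.
#' @param zeta_V,zeta_W LKJ shape parameters (>= 1 treated as valid).
#' @param xi_V,tau_V,xi_W,tau_W location and standard deviation of
#'   `log sigma` for the technical and biological scales.
#' @return object of class `mallard_priors`.
#' @export
mallard_priors <- function(m0 = 0, C0_scale = 25, zeta_V = 1, zeta_W = 1,
                           xi_V = 1, tau_V = 2, xi_W = 0, tau_W = 2) {
  if (C0_scale <= 0) stop("C0_scale must be positive", call. = FALSE)
  if (tau_V <= 0 || tau_W <= 0) stop("tau must be positive", call. = FALSE)
  if (zeta_V < 1 || zeta_W < 1) stop("zeta must be >= 1", call. = FALSE)
  structure(list(m0 = m0, C0_scale = C0_scale, zeta_V = zeta_V,
                 zeta_W = zeta_W, xi_V = xi_V, tau_V = tau_V,
                 xi_W = xi_W, tau_W = tau_W),
            class = "mallard_priors")
}

#' Covariance decomposition into scales and correlation
#'
#' `decomposition_to_cov` rebuilds `Sigma = diag(sigma) corr diag(sigma)`;
#' `cov_to_decomposition` extracts the positive scales and correlation.
#'
#' @param sigma positive scale vector.
#' @param corr correlation matrix (symmetric, unit diagonal, PSD).
#' @return covariance matrix / list with `sigma` and `corr`.
#' @export
decomposition_to_cov <- function(sigma, corr) {
  corr <- as.matrix(corr)
  if (max(abs(diag(corr) - 1)) > 1e-8) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  if (any(sigma <= 0)) stop("scales must be positive", call. = FALSE)
  sigma * t(sigma * corr)   # diag(sigma) %*% corr %*% diag(sigma)
}

#' @rdname decomposition_to_cov
#' @param Sigma covariance matrix.
#' @export
cov_to_decomposition <- function(Sigma) {
  Sigma <- as.matrix(Sigma)
  sigma <- sqrt(diag(Sigma))
  corr <- t(Sigma / sigma) / sigma
  diag(corr) <- 1
  list(sigma = sigma, corr = corr)
}

#' Assemble a MALLARD model
#'
#' Binds a count table, a sample schedule, an ILR basis and priors into the
#' model object used by [log_posterior()] and [mallard_fit()].  Vessels are
#' conditionally independent given shared `V` and `W`, so the Gaussian term
#' factors into one `(D-1)`-dimensional Kalman filter per vessel (the
#' Kronecker-structured expanded state gives the identical density).
#'
#' @param counts a [count_table].
#' @param schedule a [sample_schedule]; every schedule sample id must be a
#'   row of `counts`.
#' @param basis a [contrast_matrix] matching the taxa of `counts`; default is
#'   the basis of the sequential binary partition obtained by always
#'   splitting the first taxon off (used only if none supplied).
#' @param priors a [mallard_priors].
#' @return object of class `mallard_model`.
#' @export
mallard_model <- function(counts, schedule, basis = NULL,
                          priors = mallard_priors()) {
  stopifnot(inherits(counts, "count_table"),
            inherits(schedule, "sample_schedule"),
            inherits(priors, "mallard_priors"))
  D <- ncol(counts$counts)
  if (is.null(basis)) {
    basis <- contrast_from_partition(default_sbp(counts$taxa_names))
  }
  if (ncol(.psi(basis)) != D) {
    stop("basis dimension does not match the number of taxa", call. = FALSE)
  }
  obs_ids <- schedule$steps$sample_id[schedule$steps$observed]
  missing_ids <- setdiff(obs_ids, counts$sample_ids)
  if (length(missing_ids) > 0L) {
    stop("schedule sample ids absent from count table: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "), call. = FALSE)
  }
  p <- D - 1L
  m0 <- rep_len(priors$m0, p)
  # per-vessel step bookkeeping for the filters
  vessel_steps <- lapply(schedule$vessels, function(v)
    which(schedule$steps$vessel == v))
  names(vessel_steps) <- schedule$vessels
  count_row <- match(schedule$steps$sample_id, counts$sample_ids)
  structure(list(counts = counts, schedule = schedule, basis = basis,
                 priors = priors, D = D, p = p, m0 = m0,
                 vessel_steps = vessel_steps, count_row = count_row),
            class = "mallard_model")
}

#' Default sequential binary partition
#'
#' A deterministic fallback basis: split the first taxon from the rest, then
#' recurse on the rest.
#'
#' @param taxa_names taxa labels.
#' @return an [sbp].
#' @export
default_sbp <- function(taxa_names) {
  D <- length(taxa_names)
  signs <- matrix(0, D - 1L, D, dimnames = list(NULL, taxa_names))
  for (i in seq_len(D - 1L)) {
    signs[i, i] <- 1
    signs[i, (i + 1L):D] <- -1
  }
  sbp(signs)
}

# log multinomial pmf summed over rows of Y given ILR coordinates eta
.multinom_loglik <- function(eta, Y, psi) {
  clr_coord <- eta %*% psi
  m <- apply(clr_coord, 1L, max)
  logz <- m + log(rowSums(exp(clr_coord - m)))
  logp <- clr_coord - logz
  n <- rowSums(Y)
  sum(lgamma(n + 1)) - sum(lgamma(Y + 1)) + sum(Y * logp)
}

# unnormalized LKJ log density on a correlation matrix
.lkj_logdens <- function(corr, zeta) {
  (zeta - 1) * determinant(corr, logarithm = TRUE)$modulus[1]
}

#' Marginal unnormalized log posterior density
#'
#' Evaluates `log p(eta, V, W | Y, priors)` up to a constant: the multinomial
#' count likelihood at the observed steps, the Kalman-filter marginal
#' Gaussian density of `eta` per vessel (states `theta` marginalized out),
#' the LKJ log densities of the correlation factors, and the log-normal log
#' densities of the scale components.
#'
#' @param eta `n_steps x (D-1)` matrix of logistic-normal parameters, rows
#'   aligned with `model$schedule$steps` (imputed steps included).
#' @param sigma_V,sigma_W positive scale vectors of length `D-1`.
#' @param corr_V,corr_W correlation matrices.
#' @param model a [mallard_model].
#' @return scalar unnormalized log density.
#' @export
log_posterior <- function(eta, sigma_V, corr_V, sigma_W, corr_W, model) {
  stopifnot(inherits(model, "mallard_model"))
  eta <- rbind(eta)
  if (nrow(eta) != model$schedule$n_steps || ncol(eta) != model$p) {
    stop("eta must be n_steps x (D-1), aligned with the schedule",
         call. = FALSE)
  }
  V <- decomposition_to_cov(sigma_V, corr_V)
  W <- decomposition_to_cov(sigma_W, corr_W)
  obs <- which(model$schedule$steps$observed)
  Y <- model$counts$counts[model$count_row[obs], , drop = FALSE]
  lp <- .multinom_loglik(eta[obs, , drop = FALSE], Y, .psi(model$basis))
  for (idx in model$vessel_steps) {
    gaps <- model$schedule$steps$gap[idx]
    lp <- lp + .dlm_rw_loglik_cpp(t(eta[idx, , drop = FALSE]), gaps,
                                  model$m0, model$priors$C0_scale, V, W)
  }
  pr <- model$priors
  lp + .lkj_logdens(corr_V, pr$zeta_V) + .lkj_logdens(corr_W, pr$zeta_W) +
    sum(stats::dlnorm(sigma_V, pr$xi_V, pr$tau_V, log = TRUE)) +
    sum(stats::dlnorm(sigma_W, pr$xi_W, pr$tau_W, log = TRUE))
}

#' Draw LKJ-distributed correlation matrices
#'
#' C-vine construction: canonical partial correlations are Beta-distributed
#' on (-1, 1) and converted to full correlations, giving draws from
#' `LKJ(zeta)`.
#'
#' @param n number of draws.
#' @param p matrix dimension.
#' @param zeta LKJ shape; `zeta = 1` is uniform over correlation matrices.
#' @return `n x p x p` array (or `p x p` matrix when `n = 1`).
#' @export
rlkj_corr <- function(n, p, zeta = 1) {
  out <- array(NA_real_, c(n, p, p))
  for (d in seq_len(n)) {
    P <- matrix(0, p, p)
    S <- diag(p)
    for (k in seq_len(p - 1L)) {
      beta_par <- zeta + (p - 1L - k) / 2
      for (i in (k + 1L):p) {
        P[k, i] <- 2 * stats::rbeta(1L, beta_par, beta_par) - 1
        r <- P[k, i]
        if (k > 1L) {
          for (l in (k - 1L):1L) {
            r <- r * sqrt((1 - P[l, i]^2) * (1 - P[l, k]^2)) + P[l, i] * P[l, k]
          }
        }
        S[k, i] <- S[i, k] <- r
      }
    }
    out[d, , ] <- S
  }
  if (n == 1L) out[1L, , ] else out
}

#' Sample covariance components and initial states from the prior
#'
#' Used for prior-predictive checks and random initialization of scale
#' components.
#'
#' @param priors a [mallard_priors].
#' @param p ILR dimension `D - 1`.
#' @param n_draws number of draws.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return list with `sigma_V`, `sigma_W` (`n x p` matrices), `corr_V`,
#'   `corr_W` (`n x p x p` arrays), and `theta0` (`n x p`).
#' @export
prior_sample <- function(priors, p, n_draws = 1L, seed = NULL) {
  stopifnot(inherits(priors, "mallard_priors"), n_draws >= 1L)
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  draw_arr <- function(x) if (n_draws == 1L) array(x, c(1L, p, p)) else x
  list(
    sigma_V = matrix(stats::rlnorm(n_draws * p, priors$xi_V, priors$tau_V),
                     n_draws, p),
    sigma_W = matrix(stats::rlnorm(n_draws * p, priors$xi_W, priors$tau_W),
                     n_draws, p),
    corr_V = draw_arr(rlkj_corr(n_draws, p, priors$zeta_V)),
    corr_W = draw_arr(rlkj_corr(n_draws, p, priors$zeta_W)),
    theta0 = matrix(stats::rnorm(n_draws * p, rep_len(priors$m0, p),
                                 sqrt(priors$C0_scale)),
                    n_draws, p, byrow = TRUE)
  )
}

#' One-standard-deviation prior bound on single-taxon enrichment
#'
#' Under `theta_0 ~ N(0, c I)` in any orthonormal ILR basis of `D` taxa, the
#' log ratio of one taxon to the geometric mean of the remaining taxa is
#' `(D/(D-1)) * clr_i`, with standard deviation `sqrt(c D / (D - 1))`.  The
#' returned value is `exp` of that: the fold ratio covered at one standard
#' deviation.  With the default `c = 25` and `D = 10` this is about 194,
#' i.e. roughly 200-fold.
#'
#' @param priors a [mallard_priors] (uses `C0_scale`).
#' @param D number of taxa.
#' @return fold-ratio bound (scalar).
#' @export
prior_theta0_ratio_bound <- function(priors = mallard_priors(), D = 10) {
  exp(sqrt(priors$C0_scale * D / (D - 1)))
}

#' Monte-Carlo prior probability of the technical:biological variation ratio
#'
#' Estimates `P(lo <= sum(sigma_V^2) / sum(sigma_W^2) <= hi)` under the
#' log-normal scale priors, the calibration statement attached to the
#' default priors.
#'
#' @param priors a [mallard_priors].
#' @param p ILR dimension.
#' @param lo,hi ratio interval bounds.
#' @param n_draws Monte-Carlo size.
#' @param seed integer seed.
#' @return estimated probability.
#' @export
prior_variation_ratio_probability <- function(priors = mallard_priors(),
                                              p = 9, lo = 1e-2, hi = 1e2,
                                              n_draws = 1e5, seed = 1) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  sv <- matrix(stats::rlnorm(n_draws * p, priors$xi_V, priors$tau_V), n_draws, p)
  sw <- matrix(stats::rlnorm(n_draws * p, priors$xi_W, priors$tau_W), n_draws, p)
  ratio <- rowSums(sv^2) / rowSums(sw^2)
  mean(ratio >= lo & ratio <= hi)
}
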