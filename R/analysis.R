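#' Technical versus biological variance decomposition
#'
#' For each posterior draw, total biological variation is `Tr(W)`, total
#' technical variation `Tr(V)`, the biological fraction
#' `Tr(W) / (Tr(V) + Tr(W))`, and the crossover sampling interval
#' `L* = Tr(V) / Tr(W)`: biological variation accrues linearly with the
#' sampling interval `L` as `L Tr(W)` while technical variation is constant,
#' so at intervals beyond `L*` biological signal exceeds technical noise.
#' Traces are invariant to the ILR basis choice.
#'
#' @param fit a [mallard_fit] (or a list with `W` and `V` draw arrays shaped
#'   `chains x samples x p x p`).
#' @return object of class `variance_decomposition`: per-draw data frame
#'   `draws` (`tr_W`, `tr_V`, `biological_fraction`, `crossover`) and a
#'   `summary` data frame (posterior median and central 95% interval).
#' @export
variance_decomposition <- function(fit) {
  tr <- function(arr) {
    d <- dim(arr)
    apply(arr, c(1, 2), function(m) sum(diag(matrix(m, d[3], d[4]))))
  }
  tr_W <- as.numeric(tr(fit$W))
  tr_V <- as.numeric(tr(fit$V))
  draws <- data.frame(tr_W = tr_W, tr_V = tr_V,
                      biological_fraction = tr_W / (tr_V + tr_W),
                      crossover = tr_V / tr_W)
  qs <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  summary <- do.call(rbind, lapply(names(draws), function(nm) {
    q <- qs(draws[[nm]])
    data.frame(quantity = nm, median = q[1], lower95 = q[2], upper95 = q[3])
  }))
  structure(list(draws = draws, summary = summary),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Riemannian distance between covariance matrices
#'
#' The affine-invariant metric on symmetric positive-definite matrices:
#' the Frobenius norm of `logm(S1^{-1/2} S2 S1^{-1/2})`, computed by
#' eigendecomposition; eigenvalues of the similarity transform below 1e-12
#' are floored with a warning.
#'
#' @param S1,S2 symmetric positive-definite matrices of equal dimension.
#' @return non-negative scalar; symmetric in its arguments.
#' @export
riemannian_cov_distance <- function(S1, S2) {
  S1 <- as.matrix(S1); S2 <- as.matrix(S2)
  if (!all(dim(S1) == dim(S2))) stop("dimension mismatch", call. = FALSE)
  e1 <- eigen(.sym(S1), symmetric = TRUE)
  if (min(e1$values) <= 0) {
    stop(sprintf("S1 is singular (condition number %.3g)",
                 max(e1$values) / max(min(e1$values), .Machine$double.xmin)),
         call. = FALSE)
  }
  inv_sqrt <- e1$vectors %*% (1 / sqrt(e1$values) * t(e1$vectors))
  M <- .sym(inv_sqrt %*% S2 %*% inv_sqrt)
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) <= 0) {
    stop(sprintf("S2 is singular relative to S1 (condition number %.3g)",
                 max(lam) / max(min(lam), .Machine$double.xmin)),
         call. = FALSE)
  }
  if (min(lam) < 1e-12) {
    warning("eigenvalues floored at 1e-12 in matrix logarithm", call. = FALSE)
    lam <- pmax(lam, 1e-12)
  }
  sqrt(sum(log(lam)^2))
}

# coerce draws given as chains x samples x p x p array, n x p x p array or
# list of matrices into a list of matrices
.as_matrix_list <- function(draws) {
  if (is.list(draws) && !is.array(draws)) return(lapply(draws, as.matrix))
  d <- dim(draws)
  if (length(d) == 4L) {
    out <- vector("list", d[1] * d[2])
    k <- 0L
    for (ch in seq_len(d[1])) for (i in seq_len(d[2])) {
      k <- k + 1L
      out[[k]] <- matrix(draws[ch, i, , ], d[3], d[4])
    }
    out
  } else if (length(d) == 3L) {
    lapply(seq_len(d[1]), function(i) matrix(draws[i, , ], d[2], d[3]))
  } else {
    stop("cannot interpret draws", call. = FALSE)
  }
}

#' Permutation test for distinct correlation structures
#'
#' Tests whether two groups of correlation-matrix draws (e.g. posterior
#' draws of the technical and biological correlation matrices) come from the
#' same distribution.  The statistic `delta` is the ratio of summed
#' within-group Riemannian distances to twice the summed between-group
#' distances; small `delta` means the groups are far apart relative to
#' their spread, so the test is one-sided toward small values.  The p-value
#' uses the `(b + 1) / (m + 1)` estimator.
#'
#' @param draws_A,draws_B equal-sized groups of correlation matrices
#'   (list of matrices, or `n x p x p` / `chains x samples x p x p` arrays).
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer seed.
#' @return object of class `permutation_test`: `delta_observed`,
#'   `delta_perm`, `p_value`, `n_permutations`.
#' @export
correlation_structure_test <- function(draws_A, draws_B, n_perm = 1000L,
                                       seed = 1L) {
  A <- .as_matrix_list(draws_A)
  B <- .as_matrix_list(draws_B)
  if (length(A) != length(B)) {
    stop("the two groups must contain equal numbers of draws", call. = FALSE)
  }
  if (n_perm < 100L) stop("use at least 100 permutations", call. = FALSE)
  mats <- c(A, B)
  for (m in mats) .check_psd(m, "correlation draw")
  n <- length(mats)
  labels <- rep(c(1L, 2L), each = length(A))
  Dm <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      Dm[i, j] <- Dm[j, i] <- riemannian_cov_distance(mats[[i]], mats[[j]])
    }
  }
  Dm[Dm < 1e-12] <- 0   # distances at numerical zero are exact ties
  delta_stat <- function(lab) {
    within <- sum(Dm[lab == 1L, lab == 1L]) + sum(Dm[lab == 2L, lab == 2L])
    between <- sum(Dm[lab == 1L, lab == 2L])
    if (within == 0) return(0)
    if (between == 0) return(Inf)
    within / (2 * between)
  }
  delta_obs <- delta_stat(labels)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  delta_perm <- vapply(seq_len(n_perm), function(b)
    delta_stat(sample(labels)), numeric(1))
  p <- (1 + sum(delta_perm <= delta_obs)) / (n_perm + 1)
  structure(list(delta_observed = delta_obs, delta_perm = delta_perm,
                 p_value = p, n_permutations = n_perm),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("delta = %.4f, p = %.4g (%d permutations)\n",
              x$delta_observed, x$p_value, x$n_permutations))
  invisible(x)
}

# sequential binary partition from a Ward dendrogram: splits ordered by
# merge height, root (largest) first
.hclust_to_sbp <- function(hc, taxa_names) {
  D <- length(hc$order)
  members <- vector("list", D - 1L)
  for (i in seq_len(D - 1L)) {
    kids <- hc$merge[i, ]
    members[[i]] <- unlist(lapply(kids, function(k)
      if (k < 0) -k else members[[k]]))
  }
  ord <- order(hc$height, decreasing = TRUE)
  signs <- matrix(0, D - 1L, D, dimnames = list(NULL, taxa_names))
  for (r in seq_along(ord)) {
    i <- ord[r]
    kids <- hc$merge[i, ]
    left <- if (kids[1] < 0) -kids[1] else members[[kids[1]]]
    right <- if (kids[2] < 0) -kids[2] else members[[kids[2]]]
    signs[r, left] <- 1
    signs[r, right] <- -1
  }
  sbp(signs)
}

# variance of the balance with contrast row psi_row, from a variation array:
# Var(psi' clr) = -0.5 * psi' T psi for zero-sum psi
.balance_var_from_T <- function(psi_row, T_mat) {
  -0.5 * drop(psi_row %*% T_mat %*% psi_row)
}

#' Principal balances by Ward clustering of variation arrays
#'
#' The variation array computed from the biological covariance is
#' proportional to squared Aitchison distances between taxa, so classical
#' Ward clustering on it (entries treated as squared dissimilarities,
#' `hclust` method `"ward.D"`) approximates the sequence of orthonormal
#' balances that successively maximize explained variance.  Each posterior
#' draw yields one dendrogram / sequential binary partition; draws are
#' summarized by the majority-rule consensus tree and the posterior
#' frequency of each consensus bipartition.
#'
#' @param variation_draws draws of `D x D` variation arrays (list, or
#'   `n x D x D` / `chains x samples x D x D` array).
#' @param taxa_names optional taxa labels.
#' @return list: `consensus_tree` (`phylo`), `consensus_sbp` ([sbp] or
#'   `NULL` when the consensus has polytopes), `bipartition_freq` (data
#'   frame: clade members, posterior frequency), `variance_explained`
#'   (mean fraction of total variation carried by the balance at each
#'   root-to-tip rank), `partitions` (per-draw [sbp] list).
#' @export
ward_principal_balances <- function(variation_draws, taxa_names = NULL) {
  Ts <- .as_matrix_list(variation_draws)
  if (length(Ts) < 1L) stop("need at least one draw", call. = FALSE)
  D <- nrow(Ts[[1L]])
  if (D < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (is.null(taxa_names)) {
    taxa_names <- colnames(Ts[[1L]])
    if (is.null(taxa_names)) taxa_names <- paste0("t", seq_len(D))
  }
  for (T_mat in Ts) {
    if (max(abs(T_mat - t(T_mat))) > 1e-8) {
      stop("variation arrays must be symmetric", call. = FALSE)
    }
  }
  parts <- vector("list", length(Ts))
  trees <- vector("list", length(Ts))
  var_frac <- matrix(NA_real_, length(Ts), D - 1L)
  for (i in seq_along(Ts)) {
    T_mat <- Ts[[i]]
    dimnames(T_mat) <- list(taxa_names, taxa_names)
    hc <- stats::hclust(stats::as.dist(T_mat), method = "ward.D")
    parts[[i]] <- .hclust_to_sbp(hc, taxa_names)
    trees[[i]] <- ape::as.phylo(hc)
    psi <- contrast_from_partition(parts[[i]])$psi
    v <- vapply(seq_len(D - 1L), function(r)
      .balance_var_from_T(psi[r, ], T_mat), numeric(1))
    var_frac[i, ] <- v / sum(v)
  }
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5, rooted = TRUE)
  pp <- ape::prop.part(trees)
  freq <- data.frame(
    clade = vapply(pp, function(cl)
      paste(sort(attr(pp, "labels")[cl]), collapse = ","), character(1)),
    frequency = attr(pp, "number") / length(trees))
  freq <- freq[order(-freq$frequency), ]
  rownames(freq) <- NULL
  cons_sbp <- tryCatch(sbp_from_phylo(cons), error = function(e) NULL)
  list(consensus_tree = cons, consensus_sbp = cons_sbp,
       bipartition_freq = freq,
       variance_explained = colMeans(var_frac),
       partitions = parts)
}

#' Per-taxon shares of biological variation
#'
#' For each draw of the biological covariance, the diagonal of its CLR
#' representation is normalized to sum to one, giving the share of total
#' biological variation attributable to each taxon (shares over a subset of
#' taxa sum to that subset's variance fraction).
#'
#' @param W_draws draws of `(D-1) x (D-1)` ILR covariances.
#' @param basis the [contrast_matrix] the draws are expressed in.
#' @return list: `shares` (draws x D matrix) and `summary` (median and 95%
#'   interval per taxon).
#' @export
family_variation_shares <- function(W_draws, basis) {
  Ws <- .as_matrix_list(W_draws)
  psi <- .psi(basis)
  D <- ncol(psi)
  shares <- matrix(NA_real_, length(Ws), D,
                   dimnames = list(NULL, colnames(psi)))
  for (i in seq_along(Ws)) {
    dv <- diag(cov_to_clr(Ws[[i]], basis))
    shares[i, ] <- dv / sum(dv)
  }
  summary <- data.frame(
    taxon = colnames(shares),
    median = apply(shares, 2L, stats::median),
    lower95 = apply(shares, 2L, stats::quantile, 0.025),
    upper95 = apply(shares, 2L, stats::quantile, 0.975))
  rownames(summary) <- NULL
  list(shares = shares, summary = summary)
}

#' Regression of relative biological variation on starting abundance
#'
#' Per posterior draw, the CLR-transformed starting community (cross-vessel
#' mean of the first observed state) is the predictor and the CLR transform
#' of the normalized CLR variances of the biological covariance is the
#' response; ordinary least squares gives one slope draw per posterior
#' draw.  A permutation null is built by permuting the taxon labels of the
#' predictor and recomputing the posterior-mean slope.
#'
#' @param theta1_draws draws of the first-time state: `n_draws x R x p` (per
#'   vessel, averaged internally) or `n_draws x p`, in ILR coordinates.
#' @param W_draws matching draws of the biological covariance.
#' @param basis the [contrast_matrix].
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return list: `beta` (slope draws), `beta_mean`, `beta_interval` (95%),
#'   `perm_beta`, `p_value`.
#' @export
abundance_variation_regression <- function(theta1_draws, W_draws, basis,
                                           n_perm = 1000L, seed = 1L) {
  psi <- .psi(basis)
  D <- ncol(psi)
  if (D < 3L) stop("regression needs at least 3 taxa", call. = FALSE)
  Ws <- .as_matrix_list(W_draws)
  th <- theta1_draws
  if (length(dim(th)) == 3L) th <- apply(th, c(1, 3), mean)  # average vessels
  n_draws <- nrow(th)
  if (length(Ws) != n_draws) stop("draw counts differ", call. = FALSE)
  X <- th %*% psi                       # CLR starting composition, draws x D
  Om <- matrix(NA_real_, n_draws, D)
  for (i in seq_len(n_draws)) {
    dv <- diag(cov_to_clr(Ws[[i]], basis))
    Om[i, ] <- clr(dv / sum(dv))
  }
  slope <- function(Xm) {
    xc <- Xm - rowMeans(Xm)
    yc <- Om - rowMeans(Om)
    rowSums(xc * yc) / rowSums(xc^2)
  }
  beta <- slope(X)
  beta_mean <- mean(beta)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old))
  set.seed(seed)
  perm_beta <- vapply(seq_len(n_perm), function(b)
    mean(slope(X[, sample(D), drop = FALSE])), numeric(1))
  p <- if (beta_mean <= stats::median(perm_beta)) {
    (1 + sum(perm_beta <= beta_mean)) / (n_perm + 1)
  } else {
    (1 + sum(perm_beta >= beta_mean)) / (n_perm + 1)
  }
  list(beta = beta, beta_mean = beta_mean,
       beta_interval = stats::quantile(beta, c(0.025, 0.975), names = FALSE),
       perm_beta = perm_beta, p_value = p)
}

#' Prior-sensitivity sweep
#'
#' Re-fits the model under a list of single-field prior perturbations and
#' reports, per fit, the posterior median and 95% interval of the
#' biological variance fraction and (optionally, when states are sampled)
#' the abundance-variation regression slope.
#'
#' @param model a [mallard_model].
#' @param base_config a [fit_config].
#' @param perturbations list of `list(field = <prior field>, value = <new>)`.
#' @param compute_beta also compute the regression slope (requires D >= 3;
#'   runs [sample_theta()] per fit).
#' @return data frame with one row per fit (base fit first).
#' @export
sensitivity_harness <- function(model, base_config = fit_config(),
                                perturbations = list(),
                                compute_beta = FALSE) {
  run_one <- function(label, priors) {
    m <- mallard_model(model$counts, model$schedule, model$basis, priors)
    fit <- mallard_fit(m, base_config)
    vd <- variance_decomposition(fit)
    row <- data.frame(
      fit = label,
      bio_fraction_median = stats::median(vd$draws$biological_fraction),
      bio_fraction_lower95 = stats::quantile(vd$draws$biological_fraction,
                                             0.025, names = FALSE),
      bio_fraction_upper95 = stats::quantile(vd$draws$biological_fraction,
                                             0.975, names = FALSE),
      max_rhat = suppressWarnings(max(fit$rhat, na.rm = TRUE)))
    if (compute_beta && model$D >= 3L) {
      fit <- sample_theta(fit, m, seed = base_config$rng_seed)
      first_t <- 1L
      nd <- fit$n_chains * fit$n_samples
      R <- dim(fit$theta)[4L]
      th1 <- array(NA_real_, c(nd, R, fit$p))
      k <- 0L
      for (ch in seq_len(fit$n_chains)) for (i in seq_len(fit$n_samples)) {
        k <- k + 1L
        th1[k, , ] <- fit$theta[ch, i, first_t, , ]
      }
      reg <- abundance_variation_regression(
        th1, fit$W, model$basis, n_perm = 200L,
        seed = base_config$rng_seed)
      row$beta_mean <- reg$beta_mean
      row$beta_lower95 <- reg$beta_interval[1L]
      row$beta_upper95 <- reg$beta_interval[2L]
    }
    row
  }
  pr0 <- model$priors
  for (pt in perturbations) {
    if (!pt$field %in% names(unclass(pr0))) {
      stop("unknown prior field: ", pt$field, call. = FALSE)
    }
  }
  out <- run_one("base", pr0)
  for (pt in perturbations) {
    pr <- unclass(pr0)
    pr[[pt$field]] <- pt$value
    pr <- do.call(mallard_priors, pr)
    out <- rbind(out, run_one(paste0(pt$field, "=", pt$value), pr))
  }
  rownames(out) <- NULL
  out
}

#' Tidy TSV + JSON export of analysis results
#'
#' @param results named list of data frames (written as TSV) and scalar
#'   summaries (written into one JSON file).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      utils::write.table(x, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    } else {
      scalars[[nm]] <- x
    }
  }
  if (length(scalars) > 0L) {
    jsonlite::write_json(scalars, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
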