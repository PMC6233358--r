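#' Centered log-ratio transform
#'
#' Maps strictly positive compositions (or any positive vectors; the CLR is
#' scale invariant) to centered log coordinates, `log x - mean(log x)`.
#'
#' @param x numeric vector of strictly positive parts, or a matrix with one
#'   composition per row.
#' @return vector or matrix of CLR coordinates (rows sum to zero).
#' @seealso [ilr()], [clr_inv()]
#' @export
clr <- function(x) {
  if (is.matrix(x)) {
    .check_positive(x)
    lx <- log(x)
    lx - rowMeans(lx)
  } else {
    .check_positive(x)
    lx <- log(x)
    lx - mean(lx)
  }
}

#' Inverse centered log-ratio transform
#'
#' @param z numeric vector of CLR coordinates, or matrix with one vector per
#'   row.  Coordinates need not sum to zero; the result is normalized.
#' @return composition(s) on the unit simplex.
#' @export
clr_inv <- function(z) {
  if (is.matrix(z)) {
    e <- exp(z - apply(z, 1L, max))
    e / rowSums(e)
  } else {
    e <- exp(z - max(z))
    e / sum(e)
  }
}

.check_positive <- function(x) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("compositions must be strictly positive and finite; ",
         "zeros are handled by the count model upstream, not by the transform",
         call. = FALSE)
  }
  invisible(x)
}

#' Sequential binary partition
#'
#' A recursive bipartition of `D` taxa into `D - 1` nested splits, encoded as
#' a sign matrix with one row per split: `+1` marks the numerator group, `-1`
#' the denominator group, `0` taxa not involved at that split.  Rows are
#' ordered root to tip, and every row's nonzero support must lie entirely
#' inside the `+1` set, the `-1` set, or the `0` set of each earlier row.
#'
#' @param signs numeric `(D-1) x D` matrix with entries in `{-1, 0, 1}`.
#'   Column names (or `taxa_names`) label the taxa; row names (or
#'   `node_names`) label the internal splits.
#' @param taxa_names,node_names optional labels overriding dimnames.
#' @return an object of class `sbp`.
#' @export
sbp <- function(signs, taxa_names = colnames(signs), node_names = rownames(signs)) {
  signs <- as.matrix(signs)
  D <- ncol(signs)
  if (is.null(taxa_names)) taxa_names <- paste0("t", seq_len(D))
  if (is.null(node_names)) node_names <- paste0("n", seq_len(nrow(signs)))
  dimnames(signs) <- list(node_names, taxa_names)
  obj <- structure(list(signs = signs, taxa_names = taxa_names,
                        node_names = node_names), class = "sbp")
  validate_sbp(obj)
  obj
}

#' Validate a sequential binary partition
#'
#' @param x an `sbp` object.
#' @return `x`, invisibly; errors name the first offending row.
#' @export
validate_sbp <- function(x) {
  signs <- x$signs
  D <- ncol(signs)
  if (nrow(signs) != D - 1L) {
    stop("a sequential binary partition of ", D, " taxa needs ", D - 1L,
         " rows, got ", nrow(signs), call. = FALSE)
  }
  if (!all(signs %in% c(-1, 0, 1))) {
    stop("partition entries must be -1, 0 or +1", call. = FALSE)
  }
  for (i in seq_len(nrow(signs))) {
    r <- signs[i, ]
    if (!any(r > 0) || !any(r < 0)) {
      stop("partition row ", rownames(signs)[i],
           " must have at least one +1 and one -1 entry", call. = FALSE)
    }
    supp <- which(r != 0)
    for (j in seq_len(i - 1L)) {
      groups <- split(supp, signs[j, supp])
      if (length(groups) > 1L) {
        stop("partition row ", rownames(signs)[i],
             " straddles the split defined by earlier row ",
             rownames(signs)[j], ": not a recursive bipartition",
             call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' Orthonormal contrast matrix from a sequential binary partition
#'
#' Builds the `(D-1) x D` isometric log-ratio contrast matrix whose row `i`
#' carries `+sqrt(s/(r(r+s)))` on the `r` numerator taxa and
#' `-sqrt(r/(s(r+s)))` on the `s` denominator taxa of split `i`.  Rows are
#' orthonormal and sum to zero, so `psi %*% t(psi) = I`.
#'
#' @param partition an [sbp] object (or a bare sign matrix).
#' @return an object of class `contrast_matrix` with elements `psi` and
#'   `taxa_names`.
#' @examples
#' p <- sbp(rbind(c(1, -1, -1), c(0, 1, -1)))
#' contrast_from_partition(p)$psi
#' @export
contrast_from_partition <- function(partition) {
  if (!inherits(partition, "sbp")) partition <- sbp(partition)
  signs <- partition$signs
  psi <- matrix(0, nrow(signs), ncol(signs), dimnames = dimnames(signs))
  for (i in seq_len(nrow(signs))) {
    r <- sum(signs[i, ] > 0)
    s <- sum(signs[i, ] < 0)
    psi[i, signs[i, ] > 0] <- sqrt(s / (r * (r + s)))
    psi[i, signs[i, ] < 0] <- -sqrt(r / (s * (r + s)))
  }
  contrast_matrix(psi, partition$taxa_names)
}

#' Contrast matrix constructor
#'
#' @param psi `(D-1) x D` matrix with orthonormal, zero-sum rows.
#' @param taxa_names optional taxon labels.
#' @return `contrast_matrix` object.
#' @export
contrast_matrix <- function(psi, taxa_names = colnames(psi)) {
  psi <- as.matrix(psi)
  if (is.null(taxa_names)) taxa_names <- paste0("t", seq_len(ncol(psi)))
  colnames(psi) <- taxa_names
  gram <- psi %*% t(psi)
  if (max(abs(gram - diag(nrow(psi)))) > 1e-10) {
    stop("contrast matrix rows are not orthonormal", call. = FALSE)
  }
  if (max(abs(rowSums(psi))) > 1e-10) {
    stop("contrast matrix rows must sum to zero", call. = FALSE)
  }
  structure(list(psi = psi, taxa_names = taxa_names), class = "contrast_matrix")
}

.psi <- function(basis) {
  if (inherits(basis, "contrast_matrix")) basis$psi else as.matrix(basis)
}

#' Isometric log-ratio transform
#'
#' `ilr(x, basis)` maps compositions to the orthonormal log-ratio coordinates
#' `psi %*% clr(x)`; `ilr_inv` maps back to the simplex.
#'
#' @param x strictly positive composition (vector) or matrix of compositions
#'   (rows).
#' @param basis a [contrast_matrix] (or bare `(D-1) x D` matrix).
#' @return `(D-1)`-vector of balances, or matrix with one row per input row.
#' @export
ilr <- function(x, basis) {
  psi <- .psi(basis)
  z <- clr(x)
  if (is.matrix(z)) {
    if (ncol(z) != ncol(psi)) stop("dimension mismatch between x and basis")
    z %*% t(psi)
  } else {
    if (length(z) != ncol(psi)) stop("dimension mismatch between x and basis")
    drop(psi %*% z)
  }
}

#' @rdname ilr
#' @param y ILR coordinates (vector or matrix of row vectors).
#' @export
ilr_inv <- function(y, basis) {
  psi <- .psi(basis)
  if (is.matrix(y)) {
    clr_inv(y %*% psi)
  } else {
    clr_inv(drop(t(psi) %*% y))
  }
}

#' Change of basis for log-ratio covariance matrices
#'
#' `cov_to_clr` maps a covariance expressed in an orthonormal ILR basis to its
#' `D x D` CLR representation `t(psi) %*% sigma %*% psi`; `cov_from_clr`
#' inverts the map; `cov_change_basis` composes the two for two ILR bases.
#' The trace (total variation) is preserved by any of these maps.
#'
#' @param sigma `(D-1) x (D-1)` symmetric covariance (ILR) or `D x D` (CLR).
#' @param basis,from_basis,to_basis contrast matrices.
#' @return the transformed covariance matrix.
#' @export
cov_to_clr <- function(sigma, basis) {
  psi <- .psi(basis)
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == nrow(psi))) {
    stop("covariance dimension does not match the basis", call. = FALSE)
  }
  out <- t(psi) %*% sigma %*% psi
  dimnames(out) <- list(colnames(psi), colnames(psi))
  out
}

#' @rdname cov_to_clr
#' @export
cov_from_clr <- function(sigma, basis) {
  psi <- .psi(basis)
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == ncol(psi))) {
    stop("covariance dimension does not match the basis", call. = FALSE)
  }
  psi %*% sigma %*% t(psi)
}

#' @rdname cov_to_clr
#' @export
cov_change_basis <- function(sigma, from_basis, to_basis) {
  cov_from_clr(cov_to_clr(sigma, from_basis), to_basis)
}

#' Variation array of a CLR covariance
#'
#' Converts a `D x D` CLR covariance into the matrix of pairwise log-ratio
#' variances `t_ij = rho_ii + rho_jj - 2 rho_ij` (Aitchison's variation
#' array).  Near-proportional pairs of taxa have entries near zero.
#'
#' @param sigma_clr symmetric `D x D` CLR covariance.
#' @return `D x D` matrix with zero diagonal, class `variation_array`.
#' @export
variation_array <- function(sigma_clr) {
  sigma_clr <- as.matrix(sigma_clr)
  if (nrow(sigma_clr) != ncol(sigma_clr)) {
    stop("variation_array needs a square covariance", call. = FALSE)
  }
  if (max(abs(sigma_clr - t(sigma_clr))) > 1e-8) {
    stop("variation_array needs a symmetric covariance", call. = FALSE)
  }
  v <- diag(sigma_clr)
  t_mat <- outer(v, v, "+") - 2 * sigma_clr
  diag(t_mat) <- 0
  if (min(t_mat) < -1e-12) {
    stop("variation array has a negative entry beyond numerical slack; ",
         "input covariance is not PSD", call. = FALSE)
  }
  t_mat[t_mat < 0] <- 0
  dimnames(t_mat) <- dimnames(sigma_clr)
  structure(t_mat, class = c("variation_array", "matrix", "array"))
}

#' Balances: scaled log-ratios of geometric means
#'
#' A balance contrasts a set of `r` "plus" taxa against a disjoint set of `s`
#' "minus" taxa.  Its value on a composition,
#' `sqrt(rs/(r+s)) * log(g(x+)/g(x-))` (natural log), is measured in units of
#' evidence information (e.i.).
#'
#' @param plus_set,minus_set disjoint, non-empty integer (or name) index sets.
#' @return object of class `balance` with elements `plus_set`, `minus_set`,
#'   `r`, `s`.
#' @export
balance <- function(plus_set, minus_set) {
  if (length(plus_set) < 1L || length(minus_set) < 1L) {
    stop("both sides of a balance must be non-empty", call. = FALSE)
  }
  if (length(intersect(plus_set, minus_set)) > 0L) {
    stop("plus and minus sets must be disjoint", call. = FALSE)
  }
  structure(list(plus_set = plus_set, minus_set = minus_set,
                 r = length(plus_set), s = length(minus_set)),
            class = "balance")
}

#' @rdname balance
#' @param x strictly positive composition.
#' @param b a [balance].
#' @return `balance_value`: the balance in e.i. units.
#' @export
balance_value <- function(x, b) {
  .check_positive(x)
  gp <- exp(mean(log(x[b$plus_set])))
  gm <- exp(mean(log(x[b$minus_set])))
  sqrt(b$r * b$s / (b$r + b$s)) * log(gp / gm)
}

#' Fold change equivalent to a balance (e.i.) value
#'
#' Converts a balance value `y` in evidence-information units back to the
#' ratio of geometric means of the two groups: `exp(y / sqrt(rs/(r+s)))`.
#' For a one-vs-one balance, 1 e.i. corresponds to `exp(sqrt(2))`, roughly a
#' 4-fold change, and 2 e.i. to `exp(2*sqrt(2))`, roughly 17-fold.
#'
#' @param y balance value in e.i.
#' @param r,s sizes of the plus and minus groups.
#' @return fold change `g(x+)/g(x-)`.
#' @export
fold_change_from_balance <- function(y, r, s) {
  if (r < 1 || s < 1) stop("group sizes must be at least 1", call. = FALSE)
  exp(y / sqrt(r * s / (r + s)))
}

#' Aitchison distance between two compositions
#'
#' Euclidean norm of the difference of CLR coordinates; identical to the
#' Euclidean distance of ILR coordinates in any orthonormal basis.
#'
#' @param x1,x2 strictly positive compositions of equal length.
#' @return non-negative scalar.
#' @export
aitchison_distance <- function(x1, x2) {
  if (length(x1) != length(x2)) {
    stop("compositions have different lengths", call. = FALSE)
  }
  sqrt(sum((clr(x1) - clr(x2))^2))
}

#' Sequential binary partitions from trees and files
#'
#' `sbp_from_phylo` converts a rooted, strictly binary `phylo` topology into
#' a sequential binary partition: internal nodes are visited in preorder
#' (root first) and within each split the `+1` side is the first-listed child
#' clade; tip labels become taxa names.  `sbp_from_newick` reads a Newick
#' file or string first.  `sbp_from_tsv` reads a sign matrix (rows = splits,
#' columns = taxa, entries +1/-1/0).
#'
#' @param tree an `ape::phylo` object.
#' @return an [sbp] object.
#' @export
sbp_from_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("need a phylo object", call. = FALSE)
  if (!ape::is.binary(tree)) {
    stop("the tree must be strictly binary to define a sequential binary ",
         "partition", call. = FALSE)
  }
  if (!ape::is.rooted(tree)) stop("the tree must be rooted", call. = FALSE)
  ntip <- length(tree$tip.label)
  signs <- matrix(0, ntip - 1L, ntip,
                  dimnames = list(NULL, tree$tip.label))
  node_names <- character(ntip - 1L)
  # preorder over internal nodes; tie-break on taxa names is inherited from
  # the tree's own child ordering, which read.tree keeps deterministic
  tree <- ape::reorder.phylo(tree, "cladewise")
  internal <- unique(tree$edge[, 1L])
  tips_below <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    unlist(lapply(kids, tips_below))
  }
  for (i in seq_along(internal)) {
    node <- internal[i]
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    signs[i, tips_below(kids[1L])] <- 1
    signs[i, tips_below(kids[2L])] <- -1
    node_names[i] <- if (!is.null(tree$node.label) &&
                         nzchar(tree$node.label[node - ntip])) {
      tree$node.label[node - ntip]
    } else {
      paste0("n", i)
    }
  }
  rownames(signs) <- node_names
  sbp(signs)
}

#' @rdname sbp_from_phylo
#' @param newick path to a Newick file, or a Newick string.
#' @export
sbp_from_newick <- function(newick) {
  tree <- if (file.exists(newick)) ape::read.tree(newick)
          else ape::read.tree(text = newick)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  sbp_from_phylo(tree)
}

#' @rdname sbp_from_phylo
#' @param path TSV file path for `sbp_from_tsv` / `write_sbp_tsv`.
#' @export
sbp_from_tsv <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                         check.names = FALSE)
  sbp(as.matrix(m))
}

#' @rdname sbp_from_phylo
#' @param x an `sbp` to write.
#' @export
write_sbp_tsv <- function(x, path) {
  stopifnot(inherits(x, "sbp"))
  utils::write.table(x$signs, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Random sequential binary partition
#'
#' Draws a uniform random recursive bipartition over the given taxa: each
#' group is split by assigning every taxon independently to one of two sides,
#' redrawing until both sides are non-empty.  Used to build random ILR bases
#' for simulations.
#'
#' @param taxa_names character vector of taxa (or an integer `D`).
#' @param seed optional integer seed for reproducibility.
#' @return an [sbp] object.
#' @export
random_sbp <- function(taxa_names, seed = NULL) {
  if (length(taxa_names) == 1L && is.numeric(taxa_names)) {
    taxa_names <- paste0("t", seq_len(taxa_names))
  }
  D <- length(taxa_names)
  if (D < 2L) stop("need at least two taxa", call. = FALSE)
  if (!is.null(seed)) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old))
    set.seed(seed)
  }
  rows <- vector("list", D - 1L)
  row_i <- 0L
  recurse <- function(idx) {
    if (length(idx) < 2L) return(invisible(NULL))
    repeat {
      side <- sample(c(-1, 1), length(idx), replace = TRUE)
      if (any(side > 0) && any(side < 0)) break
    }
    row <- numeric(D)
    row[idx] <- side
    row_i <<- row_i + 1L
    rows[[row_i]] <<- row
    recurse(idx[side > 0])
    recurse(idx[side < 0])
  }
  recurse(seq_len(D))
  signs <- do.call(rbind, rows)
  colnames(signs) <- taxa_names
  rownames(signs) <- paste0("n", seq_len(D - 1L))
  sbp(signs)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
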