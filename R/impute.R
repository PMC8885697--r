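#' Impute missing property measurements
#'
#' Single imputation by linear interpolation following orthogonal regression on
#' rank-transformed data, using alternating-least-squares (ALS) PCA for the
#' low-rank completion. The procedure is:
#'
#' 1. each property column is rank-transformed over its observed values;
#' 2. the rank matrix is completed at rank `n_components` by ALS PCA
#'    (iterated truncated SVD on the column-centred matrix, refilling only the
#'    missing cells each sweep until the largest change falls below `tol`);
#' 3. completed ranks are mapped back to measurement units by piecewise-linear
#'    interpolation against the observed (rank, value) pairs of each column,
#'    clamped to the observed range.
#'
#' Observed cells are returned bit-identical; only missing cells are filled.
#'
#' @param tbl A `property_table` (possibly with missing cells).
#' @param n_components Rank of the completion (default 2, the number of
#'   factors retained downstream).
#' @param tol Convergence threshold on the largest absolute change of an
#'   imputed rank between sweeps.
#' @param max_iter Maximum ALS sweeps.
#' @return A complete `property_table`.
#' @export
impute_missing <- function(tbl, n_components = 2, tol = 1e-6, max_iter = 5000) {
  stopifnot(inherits(tbl, "property_table"))
  cols <- property_cols()
  if (n_components >= length(cols)) {
    abort("n_components must be smaller than the number of properties")
  }
  X <- as.matrix(tbl[, cols])
  miss <- is.na(X)
  if (!any(miss)) return(tbl)
  n_obs_col <- colSums(!miss)
  if (any(n_obs_col == 0)) {
    abort(paste0("column '", cols[which(n_obs_col == 0)[1]],
                 "' has no observed values; cannot impute"))
  }

  # rank-transform each column over observed entries
  R <- matrix(NA_real_, nrow(X), ncol(X))
  for (j in seq_len(ncol(X))) {
    obs <- !miss[, j]
    R[obs, j] <- rank(X[obs, j])
  }

  # ALS PCA completion of the rank matrix
  Rc <- R
  for (j in seq_len(ncol(Rc))) {
    Rc[miss[, j], j] <- mean(R[!miss[, j], j])
  }
  rng <- apply(R, 2, range, na.rm = TRUE)
  converged <- FALSE
  delta <- Inf
  for (it in seq_len(max_iter)) {
    mu <- colMeans(Rc)
    Z <- sweep(Rc, 2, mu)
    sv <- svd(Z, nu = n_components, nv = n_components)
    Zhat <- sv$u %*% (diag(sv$d[seq_len(n_components)], n_components) %*%
                        t(sv$v))
    fill <- sweep(Zhat, 2, mu, "+")
    # keep completed ranks inside the observed support (also stabilises the
    # fixed point when trailing singular values are nearly degenerate)
    for (j in seq_len(ncol(fill))) {
      fill[, j] <- pmin(pmax(fill[, j], rng[1, j]), rng[2, j])
    }
    delta <- max(abs(fill[miss] - Rc[miss]))
    Rc[miss] <- fill[miss]
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(paste0("ALS imputation did not converge in ", max_iter,
                 " iterations (last max change ", signif(delta, 3), ")"))
  }

  # map completed ranks back to measurement units per column
  out <- X
  for (j in seq_len(ncol(X))) {
    obs <- !miss[, j]
    if (!any(miss[, j])) next
    xr <- R[obs, j]
    yv <- X[obs, j]
    if (sum(obs) == 1) {
      out[miss[, j], j] <- yv
    } else {
      out[miss[, j], j] <- approx(xr, yv, xout = Rc[miss[, j], j],
                                  rule = 2, ties = mean)$y
    }
  }

  res <- tbl
  for (j in seq_along(cols)) res[[cols[j]]] <- out[, j]
  as_property_table(res)
}
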