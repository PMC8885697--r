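#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' KMO = sum of squared off-diagonal correlations divided by that sum plus the
#' sum of squared off-diagonal anti-image partial correlations, where the
#' partial correlations come from the inverse correlation matrix:
#' `u_ij = -S_ij / sqrt(S_ii S_jj)` with `S = solve(cor(X))`. Values above 0.5
#' are conventionally taken as adequate for factor analysis.
#'
#' @param tbl A `log_ratio_table`, or any data frame whose numeric columns are
#'   the variables (the `mutation` column, if present, is dropped).
#' @return KMO statistic in \[0, 1\].
#' @export
kmo_statistic <- function(tbl) {
  X <- as.matrix(tbl[, setdiff(names(tbl), "mutation")])
  if (nrow(X) < 3) abort("need at least 3 rows")
  R <- cor(X)
  if (anyNA(R)) abort("correlation matrix undefined (constant column?)")
  Ri <- tryCatch(solve(R), error = function(e) {
    abort("correlation matrix is singular; KMO undefined")
  })
  U <- -Ri / sqrt(outer(diag(Ri), diag(Ri)))
  off <- upper.tri(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(U[off]^2))
}

#' Factor model of variant functional effects
#'
#' Principal component analysis of the standardized log-ratio table
#' (eigendecomposition of the correlation matrix), retaining `n_components`
#' components, rotating the retained loadings (varimax by default, promax for
#' an oblique solution), and computing rotated component scores by the
#' regression method. The WT reference row, which is identically zero, is
#' excluded from the fit.
#'
#' @param tbl A complete `log_ratio_table` (see [normalize_log()]).
#' @param n_components Number of components to retain (default 2).
#' @param rotation `"varimax"` (orthogonal, default) or `"promax"` (oblique).
#' @return A `factor_model` object with elements `loadings` (unrotated, p x m),
#'   `pattern` (rotated pattern matrix), `rotmat`, `scores` (tibble:
#'   `mutation`, `factor1`, `factor2`, ...), `variance_fraction`, `eigenvalues`,
#'   `kmo`, and `rotation`.
#' @export
fit_factors <- function(tbl, n_components = 2,
                        rotation = c("varimax", "promax")) {
  rotation <- match.arg(rotation)
  stopifnot(inherits(tbl, "log_ratio_table") || is.data.frame(tbl))
  cols <- setdiff(names(tbl), "mutation")
  keep <- if ("mutation" %in% names(tbl)) tbl$mutation != "WT" else
    rep(TRUE, nrow(tbl))
  X <- as.matrix(tbl[keep, cols])
  if (anyNA(X)) abort("table must be complete before factor analysis")
  p <- ncol(X)
  if (n_components > p) abort("n_components exceeds the number of properties")
  Z <- scale(X)
  R <- cor(X)
  eg <- eigen(R, symmetric = TRUE)
  if (n_components > sum(eg$values > 1e-12)) {
    abort("n_components exceeds the rank of the correlation matrix")
  }
  varfrac <- eg$values[seq_len(n_components)] / sum(eg$values)
  A <- eg$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(n_components)]), n_components)
  dimnames(A) <- list(cols, paste0("factor", seq_len(n_components)))

  if (n_components > 1) {
    rot <- if (rotation == "varimax") varimax(A) else promax(A)
    pattern <- unclass(rot$loadings)
    rotmat <- rot$rotmat
  } else {
    pattern <- A
    rotmat <- diag(1)
  }
  dimnames(pattern) <- dimnames(A)

  # sign convention: each factor's dominant loading is positive
  for (j in seq_len(ncol(pattern))) {
    if (pattern[which.max(abs(pattern[, j])), j] < 0) {
      pattern[, j] <- -pattern[, j]
      rotmat[, j] <- -rotmat[, j]
    }
  }

  # scores by per-factor least-squares projection of the standardized data
  # through the rotated pattern columns. Joint (multivariate) regression
  # scoring under an orthogonal rotation returns exactly uncorrelated scores
  # whatever the data, which would make any score-association annotation
  # vacuous; per-column projection preserves the oblique geometry instead.
  phi <- if (rotation == "promax" && n_components > 1) {
    solve(t(rotmat) %*% rotmat)
  } else {
    diag(n_components)
  }
  B <- sweep(pattern, 2, colSums(pattern^2), "/")
  scores <- Z %*% B
  colnames(scores) <- colnames(pattern)

  sc <- tibble::tibble(mutation = if ("mutation" %in% names(tbl))
    tbl$mutation[keep] else paste0("row", seq_len(nrow(scores))))
  for (j in seq_len(ncol(scores))) sc[[colnames(scores)[j]]] <- scores[, j]

  structure(list(
    loadings = A, pattern = pattern, rotmat = rotmat, phi = phi,
    scores = sc, variance_fraction = varfrac, eigenvalues = eg$values,
    kmo = tryCatch(kmo_statistic(as.data.frame(X)),
                   error = function(e) NA_real_),
    rotation = rotation, n = nrow(X)
  ), class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("Factor model (", x$rotation, " rotation), n = ", x$n, "\n", sep = "")
  cat("Variance fractions:",
      paste(sprintf("%.1f%%", 100 * x$variance_fraction), collapse = ", "),
      "\n")
  cat("KMO:", sprintf("%.3f", x$kmo), "\n\nPattern matrix:\n")
  print(round(x$pattern, 3))
  invisible(x)
}

#' Tidy a factor model's pattern matrix
#'
#' @param x A `factor_model`.
#' @param ... Unused.
#' @return Tibble with one row per (property, factor): columns `property`,
#'   `factor`, `loading`.
#' @export
tidy.factor_model <- function(x, ...) {
  p <- x$pattern
  tibble::tibble(
    property = rep(rownames(p), ncol(p)),
    factor = rep(colnames(p), each = nrow(p)),
    loading = as.vector(p)
  )
}

#' One-row summary of a factor model
#'
#' @param x A `factor_model`.
#' @param ... Unused.
#' @return Tibble with `n`, `n_components`, per-component variance fractions,
#'   their total and the KMO statistic.
#' @export
glance.factor_model <- function(x, ...) {
  out <- tibble::tibble(n = x$n, n_components = length(x$variance_fraction),
                        kmo = x$kmo,
                        total_variance = sum(x$variance_fraction))
  for (j in seq_along(x$variance_fraction)) {
    out[[paste0("var_frac", j)]] <- x$variance_fraction[j]
  }
  out
}

#' Rotated factor scores with cluster annotation
#'
#' @param x A `factor_model`.
#' @param clusters Optional `cluster_assignment` from [kmeans_cluster()].
#' @param ... Unused.
#' @return The score tibble, with a `cluster` column when supplied.
#' @export
augment.factor_model <- function(x, clusters = NULL, ...) {
  sc <- x$scores
  if (!is.null(clusters)) sc$cluster <- clusters$labels
  sc
}

#' Plot factor scores
#'
#' Scatter plot of the first two rotated factor scores, optionally coloured by
#' cluster, mirroring the usual variant-classification figure.
#'
#' @param object A `factor_model`.
#' @param clusters Optional `cluster_assignment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.factor_model <- function(object, clusters = NULL, ...) {
  sc <- augment.factor_model(object, clusters)
  p <- ggplot2::ggplot(sc, ggplot2::aes(.data$factor1, .data$factor2))
  if (!is.null(clusters)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$cluster)),
                                 size = 2) +
      ggplot2::labs(colour = "cluster")
  } else {
    p <- p + ggplot2::geom_point(size = 2)
  }
  p + ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::labs(x = "Factor 1 score", y = "Factor 2 score") +
    ggplot2::theme_minimal()
}
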