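#' K-means clustering of factor scores
#'
#' Runs `stats::kmeans` with `n_init` independently seeded single starts and
#' keeps the solution with the lowest total within-cluster sum of squares.
#' Ties between restarts are broken by the lowest seed index, so the result is
#' deterministic for a given `seed`.
#'
#' @param scores Numeric matrix or score tibble (a `mutation` column, if
#'   present, is kept for labelling).
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param n_init Number of restarts (default 100).
#' @return A `cluster_assignment`: list with `labels` (integer vector),
#'   `centroids` (k x d), `tot_withinss`, `k`.
#' @export
kmeans_cluster <- function(scores, k, seed = 1, n_init = 100) {
  X <- score_matrix(scores)
  if (k > nrow(X)) abort("k exceeds the number of points")
  if (k == nrow(X)) {
    return(structure(list(labels = seq_len(nrow(X)), centroids = X,
                          tot_withinss = 0, k = k),
                     class = "cluster_assignment"))
  }
  best <- NULL
  for (i in seq_len(n_init)) {
    set.seed(seed + i - 1)
    km <- suppressWarnings(kmeans(X, centers = k, nstart = 1,
                                  iter.max = 100))
    if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12) {
      best <- km
    }
  }
  structure(list(labels = as.integer(best$cluster),
                 centroids = best$centers,
                 tot_withinss = best$tot.withinss, k = k),
            class = "cluster_assignment")
}

score_matrix <- function(scores) {
  if (is.data.frame(scores)) {
    as.matrix(scores[, setdiff(names(scores), c("mutation", "cluster"))])
  } else {
    as.matrix(scores)
  }
}

#' Within-cluster sum of squares over a range of k
#'
#' @inheritParams kmeans_cluster
#' @param k_max Largest k to evaluate.
#' @return Tibble with columns `k` and `withinss` (non-increasing in `k`).
#' @export
withinss_curve <- function(scores, k_max, seed = 1, n_init = 25) {
  X <- score_matrix(scores)
  k_max <- min(k_max, nrow(X))
  wss <- vapply(seq_len(k_max), function(k) {
    if (k == 1) {
      sum(scale(X, scale = FALSE)^2)
    } else {
      kmeans_cluster(X, k, seed = seed, n_init = n_init)$tot_withinss
    }
  }, numeric(1))
  # enforce monotonicity against rare restart noise
  wss <- cummin(wss)
  tibble::tibble(k = seq_len(k_max), withinss = wss)
}

#' Elbow of a within-SS curve
#'
#' Automates reading the elbow off a sum-of-squares versus k plot: the chosen
#' k maximises the discrete second difference of `log(withinSS)`, i.e. the
#' point where the proportional drop per added cluster slows most abruptly
#' (the raw second difference systematically favours k = 2 on geometrically
#' decaying curves). A curve with no kink larger than `min_kink` log units --
#' e.g. a single featureless blob -- is treated as degenerate and `k_min` is
#' returned.
#'
#' @param wss Numeric vector of within-SS for k = 1..k_max (or the tibble from
#'   [withinss_curve()]).
#' @param k_min Floor for the returned k (default 1).
#' @param min_kink Minimum log-scale second difference for a kink to count as
#'   real structure (default 0.25, a ~28% change in the drop ratio).
#' @return Selected k.
#' @export
elbow_k <- function(wss, k_min = 1, min_kink = 0.25) {
  if (is.data.frame(wss)) wss <- wss$withinss
  n <- length(wss)
  if (n < 3) return(as.integer(max(k_min, 1)))
  lw <- log(pmax(wss, max(wss) * 1e-12))
  d2 <- lw[1:(n - 2)] - 2 * lw[2:(n - 1)] + lw[3:n]
  k_star <- which.max(d2) + 1L
  if (d2[k_star - 1L] < min_kink) return(as.integer(k_min))
  as.integer(max(k_star, k_min))
}

#' Select the number of clusters by the elbow rule
#'
#' @inheritParams kmeans_cluster
#' @param k_max Largest k to consider (must be < number of points).
#' @param k_min Floor for the returned k.
#' @return Selected k, with the within-SS curve attached as attribute
#'   `"withinss"`.
#' @export
select_k_elbow <- function(scores, k_max = 8, seed = 1, k_min = 1) {
  X <- score_matrix(scores)
  if (k_max >= nrow(X)) k_max <- nrow(X) - 1
  curve <- withinss_curve(X, k_max, seed = seed)
  k <- elbow_k(curve$withinss, k_min = k_min)
  attr(k, "withinss") <- curve
  k
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("k-means assignment, k =", x$k, " total within-SS =",
      signif(x$tot_withinss, 4), "\n")
  print(table(cluster = x$labels))
  invisible(x)
}
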