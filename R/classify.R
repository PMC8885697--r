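#' Classify variants from a property table
#'
#' The full functional-classification pipeline: impute missing measurements
#' ([impute_missing()]), normalise to WT log10 ratios ([normalize_log()]),
#' check sampling adequacy ([kmo_statistic()]), fit and rotate a
#' two-component factor model ([fit_factors()]), choose k by the elbow rule
#' and cluster the rotated scores ([select_k_elbow()], [kmeans_cluster()]),
#' and annotate the inter-factor score association with a
#' double-bootstrap-calibrated tau-b confidence interval.
#'
#' @param tbl A `property_table` (see [read_property_table()]).
#' @param n_components Retained components (default 2).
#' @param rotation `"varimax"` or `"promax"`.
#' @param k Number of clusters; `NULL` (default) selects it by the elbow rule.
#' @param k_max Largest k considered by the elbow search (default 8).
#' @param seed Seed for clustering and the bootstrap.
#' @param n_outer,n_inner Bootstrap resample counts (defaults 20000/200; use
#'   smaller values for quick looks).
#' @return A `variant_classification` list: `model` (the `factor_model`),
#'   `clusters`, `scores` (tibble with `mutation`, factors, `cluster`), `kmo`,
#'   `k`, `correlation` (tau-b with CI), and the imputed `table`.
#' @export
classify_variants <- function(tbl, n_components = 2,
                              rotation = c("varimax", "promax"), k = NULL,
                              k_max = 8, seed = 1, n_outer = 20000,
                              n_inner = 200) {
  rotation <- match.arg(rotation)
  filled <- impute_missing(tbl, n_components = n_components)
  lr <- normalize_log(filled)
  model <- fit_factors(lr, n_components = n_components, rotation = rotation)
  if (is.null(k)) k <- as.integer(select_k_elbow(model$scores, k_max = k_max,
                                                 seed = seed))
  clusters <- kmeans_cluster(model$scores, k = k, seed = seed)
  scores <- augment(model, clusters)
  corr <- correlate_scores(scores$factor1, scores$factor2,
                           n_outer = n_outer, n_inner = n_inner, seed = seed)
  structure(list(model = model, clusters = clusters, scores = scores,
                 kmo = model$kmo, k = k, correlation = corr, table = filled),
            class = "variant_classification")
}

#' @export
print.variant_classification <- function(x, ...) {
  cat("Variant classification:", nrow(x$scores), "mutations, k =", x$k, "\n")
  cat(sprintf("KMO %.3f | variance %s | tau-b %.3f [%.3f, %.3f]\n",
              x$kmo,
              paste(sprintf("%.0f%%", 100 * x$model$variance_fraction),
                    collapse = " + "),
              x$correlation$estimate, x$correlation$ci_low,
              x$correlation$ci_high))
  print(x$scores, n = 10)
  invisible(x)
}

#' Write classification outputs
#'
#' Writes the scores CSV (`mutation,factor1,factor2,cluster`) and a model JSON
#' (loadings, rotation, variance fractions, KMO, tau-b with CI).
#'
#' @param x A `variant_classification`.
#' @param dir Output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
write_classification <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scores_path <- file.path(dir, "scores.csv")
  write.csv(x$scores, scores_path, row.names = FALSE)
  model_path <- file.path(dir, "model.json")
  jsonlite::write_json(list(
    loadings = as.data.frame(x$model$loadings),
    pattern = as.data.frame(x$model$pattern),
    rotation = x$model$rotation,
    rotmat = unclass(x$model$rotmat),
    variance_fraction = x$model$variance_fraction,
    kmo = x$kmo, k = x$k,
    tau_b = as.list(x$correlation)
  ), model_path, auto_unbox = TRUE, digits = NA)
  invisible(c(scores_path, model_path))
}
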