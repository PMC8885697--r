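#' Run a reproducible pipeline stage
#'
#' Single programmatic entry point tying the stages together, mirrored by the
#' `inst/cli/grinsyn.R` command-line front-end. Every stochastic stage
#' receives an explicit seed, outputs go to `out_dir` together with a manifest
#' (inputs, seed, checksums), and on error any partial outputs are removed.
#'
#' Stages:
#' * `"synth_mutations"` -- write a synthetic mutation table + truth JSON;
#' * `"classify"` -- run [classify_variants()] on `table` (a CSV path);
#' * `"epsc"` -- generate-and-process or process a synthetic pair
#'   ([gen_epsc_pair()], [process_pair()]);
#' * `"simulate"` -- run [run_experiment_grid()] and write the summary CSV.
#'
#' @param stage One of `"synth_mutations"`, `"classify"`, `"epsc"`,
#'   `"simulate"`.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param table For `"classify"`: path to a property CSV.
#' @param params Named list of stage-specific overrides passed to the
#'   underlying functions.
#' @return Tibble manifest of the files written (also saved as
#'   `manifest.json`).
#' @export
run_workflow <- function(stage = c("synth_mutations", "classify", "epsc",
                                   "simulate"),
                         out_dir, seed = 1, table = NULL, params = list()) {
  stage <- match.arg(stage)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
  }
  tryCatch({
    if (stage == "synth_mutations") {
      gen <- do.call(gen_mutation_table, c(list(seed = seed), params))
      tab <- gen$table
      out <- tibble::tibble(
        mutation = tab$mutation,
        glu_ec50_uM = 1 / tab$glu_potency, gly_ec50_uM = 1 / tab$gly_potency,
        deact_tau_ms = tab$deact_tau,
        current_density_pA_pF = tab$current_density,
        open_prob = tab$open_prob, surface_rel = tab$surface_level)
      p1 <- file.path(out_dir, "mutations.csv")
      write.csv(out, p1, row.names = FALSE, na = "")
      p2 <- file.path(out_dir, "truth.json")
      jsonlite::write_json(gen$truth, p2, auto_unbox = TRUE, digits = NA)
      written <- c(p1, p2)
    } else if (stage == "classify") {
      if (is.null(table) || !file.exists(table)) {
        abort("classify requires an existing property CSV via `table`")
      }
      tbl <- read_property_table(table)
      args <- c(list(tbl = tbl, seed = seed), params)
      if (is.null(args$n_outer)) args$n_outer <- 2000
      if (is.null(args$n_inner)) args$n_inner <- 50
      cls <- do.call(classify_variants, args)
      written <- write_classification(cls, out_dir)
    } else if (stage == "epsc") {
      pair <- do.call(gen_epsc_pair, c(list(seed = seed), params))
      measures <- process_pair(pair)
      p1 <- file.path(out_dir, "measures.csv")
      write.csv(measures, p1, row.names = FALSE)
      nm <- measures[measures$component == "nmda", ]
      ratios <- dplyr::bind_rows(lapply(c("peak", "charge", "tau_w"),
        function(f) response_ratio(nm[nm$cell == "transfected", ],
                                   nm[nm$cell == "untransfected", ],
                                   field = f)))
      p2 <- file.path(out_dir, "ratios.csv")
      write.csv(ratios, p2, row.names = FALSE)
      written <- c(p1, p2)
    } else if (stage == "simulate") {
      grid <- do.call(run_experiment_grid,
                      c(list(seeds = seed + 0:9), params))
      p1 <- file.path(out_dir, "simulation_summary.csv")
      write.csv(grid, p1, row.names = FALSE)
      written <- p1
    }
    manifest <- tibble::tibble(
      file = basename(written),
      md5 = unname(tools::md5sum(written)),
      stage = stage, seed = seed)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest
  }, error = on_fail)
}
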