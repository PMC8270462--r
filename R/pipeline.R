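# End-to-end pipeline stages behind the command-line entry point
# (inst/cli/sparsesigs.R). Each stage writes its artifacts plus a JSON
# configuration echo sufficient to reproduce the run.

#' Count stage: variant files to a filtered count matrix
#'
#' Reads one or more variant files, builds the 96-category count matrix
#' against the reference genome, applies the minimum-mutation filter,
#' and writes the matrix and a JSON report (samples kept and removed,
#' records skipped) to `output_dir`.
#'
#' @param variant_files Character vector of VCF/MAF/TSV paths.
#' @param reference Indexed reference FASTA path.
#' @param output_dir Directory for `counts.tsv` and `count_report.json`.
#' @param min_mutations Filter threshold (default 1000).
#' @param strict Error on reference mismatches (default) or skip them.
#' @return The filtered count matrix, invisibly.
#' @export
run_count <- function(variant_files, reference, output_dir,
                      min_mutations = 1000, strict = TRUE) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  variants <- do.call(rbind, lapply(variant_files, read_variants))
  counts <- build_count_matrix(variants, reference, strict = strict)
  skipped <- attr(counts, "skipped")
  filtered <- filter_samples(counts, min_mutations)
  write_count_matrix(filtered, file.path(output_dir, "counts.tsv"))
  jsonlite::write_json(
    list(stage = "count", variant_files = variant_files,
         reference = reference, min_mutations = min_mutations,
         strict = strict, records_skipped = skipped,
         samples_kept = rownames(filtered),
         samples_removed = attr(filtered, "removed_samples")),
    file.path(output_dir, "count_report.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(filtered)
}

#' Full stage: cross-validate, fit, and evaluate a count matrix
#'
#' Runs repeated bi-cross-validation over the given grids, selects
#' (K, lambda), refits on the complete matrix, and writes the CV table,
#' final signatures and exposures, diagnostics, and a config echo under
#' `output_dir`. Reruns with the same seed produce identical artifacts.
#'
#' @param counts Count matrix, or path to a counts TSV.
#' @param output_dir Output directory.
#' @param background Background signature (`NULL` for none).
#' @param k_grid,lambda_grid,repetitions,holdout_fraction,rounds,iterations,restarts
#'   Passed to [cross_validate()].
#' @param rule Model selection rule (see [select_model()]).
#' @param seed Integer seed for the whole run.
#' @param verbose Report per-stage progress.
#' @return List with the `cv` object, the final `fit`, and the
#'   `diagnostics`, invisibly.
#' @export
run_full <- function(counts, output_dir,
                     background = load_background_preset("germline"),
                     k_grid = 2:10,
                     lambda_grid = c(0.01, 0.025, 0.05, 0.075, 0.1),
                     repetitions = 10, holdout_fraction = 0.01,
                     rounds = 5, iterations = 20, restarts = 10,
                     rule = c("modal", "median"), seed = 1,
                     verbose = FALSE) {
  rule <- match.arg(rule)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(counts)) counts <- read_count_matrix(counts)
  M <- .check_count_matrix(counts)

  cv <- cross_validate(M, background, k_grid = k_grid,
                       lambda_grid = lambda_grid, repetitions = repetitions,
                       holdout_fraction = holdout_fraction, rounds = rounds,
                       iterations = iterations, restarts = restarts,
                       seed = seed, verbose = verbose)
  sel <- select_model(cv, rule = rule)
  write_cv_result(cv, file.path(output_dir, "cv.tsv"), rule = rule)

  fit <- fit_signatures(M, background, K = sel$K,
                        lambda_fraction = sel$lambda,
                        iterations = iterations, restarts = restarts,
                        seed = .derive_seed(seed, 999L))
  write_signature_matrix(fit$signatures, file.path(output_dir, "signatures.tsv"),
                         background = fit$background)
  write_exposures(fit$exposures, file.path(output_dir, "exposures.tsv"),
                  alpha0 = fit$alpha0)
  write_exposures(fit$exposures, file.path(output_dir, "exposures_fraction.tsv"),
                  alpha0 = fit$alpha0, fraction = TRUE)

  diag <- fit_diagnostics(M, fit)
  jsonlite::write_json(
    list(stage = "full", selected = sel,
         diagnostics = diag[c("mse", "explained_variance", "sparsity",
                              "cross_signature_similarity",
                              "background_contamination",
                              "median_per_patient_correlation")],
         config = list(k_grid = k_grid, lambda_grid = lambda_grid,
                       repetitions = repetitions,
                       holdout_fraction = holdout_fraction, rounds = rounds,
                       iterations = iterations, restarts = restarts,
                       rule = rule, seed = seed,
                       background = !is.null(background)),
         conventions = list(
           categories = "96 pyrimidine-centered trinucleotide contexts, type-major order",
           K = "non-background signature count; total adds 1 when a background is fixed")),
    file.path(output_dir, "run.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(cv = cv, fit = fit, diagnostics = diag))
}
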