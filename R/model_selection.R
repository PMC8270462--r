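# Repeated bi-cross-validation over a (K, lambda) grid: random matrix
# cells are held out, zeroed, and iteratively imputed from the fitted
# model; the prediction MSE on the held-out cells scores each grid point.

#' Sample a set of held-out matrix cells
#'
#' Draws `ceiling(fraction * N * 96)` distinct cells uniformly without
#' replacement. A mask that would remove every nonzero cell of some
#' sample row is resampled (bounded retries), since such a row would
#' carry no signal for the fit.
#'
#' @param counts N x 96 count matrix.
#' @param fraction Fraction of cells to hold out, in (0, 1); default
#'   0.01 (1% of the dataset).
#' @param seed Integer seed; the same seed gives the same mask.
#' @return Two-column integer matrix of (row, col) indices.
#' @export
holdout_mask <- function(counts, fraction = 0.01, seed = NULL) {
  M <- .check_count_matrix(counts)
  if (fraction <= 0 || fraction >= 1) {
    stop("holdout fraction must be in (0, 1)", call. = FALSE)
  }
  n_cells <- nrow(M) * 96L
  n_mask <- as.integer(ceiling(fraction * n_cells))
  .with_seed(seed, {
    for (try in seq_len(100L)) {
      cells <- sample.int(n_cells, n_mask)
      rows <- ((cells - 1L) %% nrow(M)) + 1L
      cols <- ((cells - 1L) %/% nrow(M)) + 1L
      mask <- cbind(row = rows, col = cols)
      Mz <- M
      Mz[mask] <- 0
      if (all(rowSums(Mz) > 0 | rowSums(M) == 0)) return(mask)
    }
    stop("could not draw a holdout mask leaving signal in every sample; ",
         "reduce the holdout fraction", call. = FALSE)
  })
}

#' Held-out prediction error for one (K, lambda) pair
#'
#' Zeroes the masked cells, fits the model on the remaining data, then
#' replaces the masked cells with the model's predictions and refits;
#' this imputation loop is repeated `rounds` times (default 5), after
#' which the mean squared error between the final predictions and the
#' true held-out values is returned. Predictions stabilize over rounds
#' as the imputed values converge. Unmasked cells are never modified.
#'
#' Rounds after the first warm-start from the previous round's
#' signatures, which speeds convergence without changing the fixed
#' point.
#'
#' @inheritParams fit_signatures
#' @param mask Two-column (row, col) matrix from [holdout_mask()].
#' @param rounds Number of imputation rounds (default 5).
#' @return Scalar mean squared prediction error on the held-out cells.
#' @export
cv_error <- function(counts, mask, background, K, lambda_fraction,
                     beta_init = NULL, rounds = 5, iterations = 20,
                     restarts = 10, seed = NULL) {
  M <- .check_count_matrix(counts)
  if (!is.matrix(mask) || ncol(mask) != 2L || nrow(mask) == 0L) {
    stop("mask must be a two-column (row, col) matrix", call. = FALSE)
  }
  if (any(mask[, 1L] < 1L | mask[, 1L] > nrow(M) |
          mask[, 2L] < 1L | mask[, 2L] > 96L)) {
    stop("mask references a cell outside the matrix", call. = FALSE)
  }
  truth <- M[mask]
  if (is.null(beta_init) && K > 0) {
    beta_init <- initialize_signatures(M, K, restarts = restarts, seed = seed,
                                       background = background)
  }
  Mwork <- M
  Mwork[mask] <- 0
  beta <- beta_init
  pred <- NULL
  for (round in seq_len(rounds)) {
    f <- fit_signatures(Mwork, background, K, lambda_fraction,
                        iterations = iterations, beta_init = beta,
                        seed = seed)
    pred <- fitted(f)
    Mwork[mask] <- pred[mask]
    if (K > 0) beta <- f$signatures_raw
  }
  mean((pred[mask] - truth)^2)
}

#' Repeated bi-cross-validation over a (K, lambda) grid
#'
#' For each repetition a fresh holdout mask is drawn and every grid pair
#' is scored with [cv_error()] on that same mask, so grid points are
#' compared on identical held-out data. Initial signatures for each K
#' are computed once from the full matrix and shared across the grid.
#'
#' `K` counts non-background signatures throughout; when a background is
#' fixed, the total number of signatures in the model is `K + 1`.
#'
#' @inheritParams fit_signatures
#' @param k_grid Integer vector of K values to test (default `2:18`).
#' @param lambda_grid Numeric vector of penalty fractions (default
#'   `c(0.01, 0.025, 0.05, 0.075, 0.1)`).
#' @param repetitions Number of cross-validation repetitions (default
#'   10).
#' @param holdout_fraction Fraction of cells held out per repetition
#'   (default 0.01).
#' @param rounds Imputation rounds per fit (default 5).
#' @param seed Integer seed driving masks and initializations; the same
#'   seed and configuration give an identical result.
#' @param verbose Print per-repetition progress.
#' @return Object of class `sparsesigs_cv`: list with `mse` (3-d array
#'   K x lambda x repetition), `masks`, `selected` (from
#'   [select_model()] with the default rule) and the configuration.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(simulation_preset("sim1"), seed = 1)
#' cv <- cross_validate(sim$counts, load_background_preset("germline"),
#'                      k_grid = 2:5, lambda_grid = c(0.01, 0.05),
#'                      repetitions = 3, seed = 1)
#' select_model(cv)
#' }
#' @export
cross_validate <- function(counts, background = load_background_preset("germline"),
                           k_grid = 2:18,
                           lambda_grid = c(0.01, 0.025, 0.05, 0.075, 0.1),
                           repetitions = 10, holdout_fraction = 0.01,
                           rounds = 5, iterations = 20, restarts = 10,
                           seed = NULL, verbose = FALSE) {
  M <- .check_count_matrix(counts)
  if (length(k_grid) == 0L || length(lambda_grid) == 0L) {
    stop("k_grid and lambda_grid must be non-empty", call. = FALSE)
  }
  if (any(k_grid > min(nrow(M), 96L))) {
    stop("k_grid contains K values exceeding min(samples, categories)",
         call. = FALSE)
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  lambda_grid <- sort(unique(as.numeric(lambda_grid)))

  inits <- lapply(k_grid, function(K) {
    if (K == 0L) NULL else
      initialize_signatures(M, K, restarts = restarts,
                            background = background,
                            seed = if (is.null(seed)) NULL
                                   else .derive_seed(seed, K))
  })
  names(inits) <- as.character(k_grid)

  mse <- array(NA_real_,
               dim = c(length(k_grid), length(lambda_grid), repetitions),
               dimnames = list(K = as.character(k_grid),
                               lambda = format(lambda_grid, trim = TRUE),
                               repetition = as.character(seq_len(repetitions))))
  masks <- vector("list", repetitions)
  for (rep in seq_len(repetitions)) {
    mask_seed <- if (is.null(seed)) NULL else .derive_seed(seed, 1000L + rep)
    masks[[rep]] <- holdout_mask(M, holdout_fraction, seed = mask_seed)
    for (ki in seq_along(k_grid)) {
      for (li in seq_along(lambda_grid)) {
        mse[ki, li, rep] <- cv_error(
          M, masks[[rep]], background, k_grid[ki], lambda_grid[li],
          beta_init = inits[[ki]], rounds = rounds, iterations = iterations
        )
      }
    }
    if (verbose) {
      message(sprintf("repetition %d/%d done", rep, repetitions))
    }
  }
  out <- list(mse = mse, masks = masks, k_grid = k_grid,
              lambda_grid = lambda_grid, repetitions = repetitions,
              holdout_fraction = holdout_fraction, rounds = rounds,
              iterations = iterations, seed = seed,
              has_background = !is.null(background))
  out$selected <- select_model(out)
  class(out) <- "sparsesigs_cv"
  out
}

#' Choose (K, lambda) from cross-validation results
#'
#' Two selection rules:
#'
#' * `"modal"` (default) — within each repetition, find the grid pair
#'   with the lowest held-out MSE; return the pair that wins the most
#'   repetitions. Ties are broken by lower median MSE across
#'   repetitions, then smaller K, then larger lambda.
#' * `"median"` — return the pair minimizing the median MSE across
#'   repetitions (the summary reported in tabulated form by some
#'   analyses), with the same K/lambda tie-breaks.
#'
#' @param result A `sparsesigs_cv` object (or a compatible list with
#'   `mse`, `k_grid`, `lambda_grid`).
#' @param rule `"modal"` or `"median"`.
#' @return List with `K` (non-background count), `lambda`, `total_signatures`
#'   (`K + 1` when a background was fixed, else `K`), and the rule used.
#' @export
select_model <- function(result, rule = c("modal", "median")) {
  rule <- match.arg(rule)
  mse <- result$mse
  if (is.null(mse) || length(mse) == 0L) {
    stop("empty cross-validation result", call. = FALSE)
  }
  k_grid <- result$k_grid
  lambda_grid <- result$lambda_grid
  nk <- length(k_grid); nl <- length(lambda_grid)
  med <- apply(mse, c(1L, 2L), stats::median)

  # candidate ranking used for every tie-break ladder: lower median MSE,
  # then smaller K, then larger lambda
  rank_order <- order(as.vector(med),
                      rep(k_grid, times = nl),
                      -rep(lambda_grid, each = nk))

  pick <- if (rule == "median") {
    rank_order[1L]
  } else {
    reps <- dim(mse)[3L]
    wins <- integer(nk * nl)
    for (r in seq_len(reps)) {
      flat <- as.vector(mse[, , r])
      best <- which(flat == min(flat))
      # within-repetition ties: smaller K, then larger lambda
      best <- best[order(rep(k_grid, times = nl)[best],
                         -rep(lambda_grid, each = nk)[best])][1L]
      wins[best] <- wins[best] + 1L
    }
    top <- which(wins == max(wins))
    top[order(match(top, rank_order))][1L]
  }
  ki <- ((pick - 1L) %% nk) + 1L
  li <- ((pick - 1L) %/% nk) + 1L
  K <- k_grid[ki]
  list(K = K, lambda = lambda_grid[li],
       total_signatures = K + as.integer(isTRUE(result$has_background)),
       rule = rule)
}

#' @export
print.sparsesigs_cv <- function(x, ...) {
  cat("Bi-cross-validation result\n")
  cat(sprintf("  grid: K in {%s} x lambda in {%s}, %d repetitions\n",
              paste(x$k_grid, collapse = ", "),
              paste(format(x$lambda_grid), collapse = ", "),
              x$repetitions))
  s <- x$selected
  cat(sprintf("  selected: K = %d, lambda = %g (%s rule)%s\n",
              s$K, s$lambda, s$rule,
              if (x$has_background)
                sprintf(" -> %d signatures incl. background",
                        s$total_signatures) else ""))
  invisible(x)
}

#' Serialize cross-validation results
#'
#' Writes the per-cell errors as a long-format TSV with columns `K`,
#' `lambda`, `repetition`, `mse`, plus a JSON sidecar (`<path>.json`)
#' recording the selected pair and the rule used.
#'
#' @param result A `sparsesigs_cv`.
#' @param path Output TSV path.
#' @param rule Selection rule echoed into the JSON summary.
#' @export
write_cv_result <- function(result, path, rule = c("modal", "median")) {
  rule <- match.arg(rule)
  long <- expand.grid(K = result$k_grid, lambda = result$lambda_grid,
                      repetition = seq_len(result$repetitions))
  long$mse <- as.vector(result$mse)
  con <- file(path, "w")
  writeLines("# K counts non-background signatures; add 1 for the total when a background is fixed", con)
  utils::write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  sel <- select_model(result, rule = rule)
  jsonlite::write_json(
    list(selected = sel, k_grid = result$k_grid,
         lambda_grid = result$lambda_grid,
         repetitions = result$repetitions,
         holdout_fraction = result$holdout_fraction,
         has_background = result$has_background),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
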