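# Core alternating solver for
#   min || M - (alpha0 beta0 + alpha beta) ||_F^2 + lambda ||beta||_1
#   s.t. alpha0, alpha, beta >= 0,   beta0 fixed.
# Exposures are refit per sample by active-set NNLS; signatures by
# cyclic coordinate descent on the non-negative LASSO (src/solvers.cpp).

.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# deterministic sub-stream seeds, kept inside 32-bit integer range
.derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 7919) %% 2147483629 + 1)
}

#' Initial signatures from repeated NMF
#'
#' Runs plain multiplicative-update NMF (squared-error loss) from
#' several random starts and keeps the factorization with the lowest
#' reconstruction error. The resulting signature rows, normalized to sum
#' 1, seed the alternating sparse solver; the final discovered
#' signatures are typically quite different from this starting point.
#'
#' @param counts N x 96 count matrix.
#' @param K Number of signatures to initialize (`1 <= K <= min(N, 96)`).
#' @param restarts Number of random restarts (default 10).
#' @param seed Integer seed; the same seed gives bitwise-identical
#'   output.
#' @param background Optional fixed background signature. When supplied,
#'   the NMF is run on the non-negative part of the background-residual
#'   matrix `M - alpha0 beta0` (with `alpha0` from the background-only
#'   NNLS fit) rather than on `M` itself, so that no initial component
#'   is spent re-learning the fixed background. This markedly improves
#'   the basin of attraction of the alternating solver.
#' @param max_iter,tol Multiplicative-update iteration cap and relative
#'   convergence tolerance.
#' @return K x 96 matrix, rows named `Signature_1..K`, each summing
#'   to 1.
#' @export
initialize_signatures <- function(counts, K, restarts = 10, seed = NULL,
                                  background = NULL, max_iter = 200,
                                  tol = 1e-8) {
  M <- .check_count_matrix(counts)
  if (!is.null(background)) {
    e0 <- update_exposures(M, background, NULL)
    M <- pmax(M - outer(as.numeric(e0$alpha0), as.numeric(background)), 0)
    if (all(M == 0)) {
      stop("background alone explains the matrix exactly; nothing left ",
           "to initialize", call. = FALSE)
    }
  }
  n <- nrow(M)
  if (K < 1) stop("K must be at least 1", call. = FALSE)
  if (K > min(n, 96L)) {
    stop("K = ", K, " exceeds min(samples, categories) = ", min(n, 96L),
         call. = FALSE)
  }
  if (all(M == 0)) stop("count matrix is all zero", call. = FALSE)
  if (sum(rowSums(M) > 0) < K) {
    stop("need at least K samples with nonzero counts", call. = FALSE)
  }
  if (restarts < 1) stop("restarts must be at least 1", call. = FALSE)

  .with_seed(seed, {
    best <- NULL
    best_rss <- Inf
    scale0 <- sqrt(mean(M) / K) + 1e-12
    eps <- 1e-12
    for (r in seq_len(restarts)) {
      W <- matrix(stats::runif(n * K, min = eps, max = scale0), n, K)
      H <- matrix(stats::runif(K * 96L, min = eps, max = scale0), K, 96L)
      rss_prev <- Inf
      for (it in seq_len(max_iter)) {
        H <- H * (crossprod(W, M) / (crossprod(W) %*% H + eps))
        W <- W * (M %*% t(H) / (W %*% tcrossprod(H) + eps))
        if (it %% 10L == 0L) {
          rss <- sum((M - W %*% H)^2)
          if (is.finite(rss_prev) &&
              abs(rss_prev - rss) <= tol * max(1, rss_prev)) break
          rss_prev <- rss
        }
      }
      rss <- sum((M - W %*% H)^2)
      if (rss < best_rss) {
        best_rss <- rss
        best <- H
      }
    }
    rs <- rowSums(best)
    rs[rs == 0] <- 1
    beta <- best / rs
    dimnames(beta) <- list(paste0("Signature_", seq_len(K)),
                           mutation_categories())
    beta
  })
}

#' Refit exposures with signatures held fixed
#'
#' Solves, independently for each sample, the non-negative least-squares
#' problem of attributing its 96-category spectrum to the fixed
#' background plus the current signatures. This is one half-step of the
#' alternating algorithm and is also the exact background-only fit when
#' `beta` has zero rows.
#'
#' @param counts N x 96 matrix (counts, or partially imputed values
#'   during cross-validation).
#' @param background 96-vector background signature, or `NULL` for none.
#' @param beta K x 96 non-negative signature matrix (may have `K = 0`
#'   rows if a background is supplied).
#' @return List with `alpha0` (length-N background exposures, or `NULL`
#'   when no background is used) and `alpha` (N x K matrix, columns
#'   named after the rows of `beta`).
#' @export
update_exposures <- function(counts, background, beta) {
  M <- .check_count_matrix(counts)
  K <- if (is.null(beta)) 0L else nrow(beta)
  if (K > 0 && ncol(beta) != 96L) {
    stop("beta must have 96 columns", call. = FALSE)
  }
  if (is.null(background) && K == 0L) {
    stop("nothing to fit: no background and no signatures", call. = FALSE)
  }
  if (K > 0 && any(rowSums(abs(beta)) == 0) && is.null(background) && K == 1L) {
    stop("signature rows must not all be zero", call. = FALSE)
  }
  B <- rbind(if (!is.null(background)) matrix(as.numeric(background), 1L, 96L),
             if (K > 0) unname(beta))
  A <- cpp_update_exposures(M, B)
  has_bg <- !is.null(background)
  alpha0 <- if (has_bg) A[, 1L] else NULL
  alpha <- if (K > 0) {
    a <- A[, (has_bg + 1L):(has_bg + K), drop = FALSE]
    dimnames(a) <- list(rownames(M), rownames(beta))
    a
  } else {
    matrix(0, nrow(M), 0L, dimnames = list(rownames(M), NULL))
  }
  if (has_bg) names(alpha0) <- rownames(M)
  list(alpha0 = alpha0, alpha = alpha)
}

#' Maximal LASSO penalty
#'
#' The smallest penalty weight at which the signature subproblem's
#' minimizer is the zero matrix. From the stationarity condition of the
#' non-negative LASSO with squared-Frobenius loss (no 1/2 factor), this
#' is twice the largest positive entry of `t(alpha) %*% R`, where
#' `R = M - alpha0 beta0` is the residual after removing the background
#' contribution. The user-facing penalty is expressed as a fraction of
#' this value, making it comparable across datasets and values of K.
#'
#' @inheritParams update_exposures
#' @param exposures Current exposures, as returned by
#'   [update_exposures()].
#' @return Non-negative scalar; 0 (with a warning) when all exposures
#'   are zero.
#' @export
lambda_max <- function(counts, background, exposures) {
  M <- .check_count_matrix(counts)
  R <- .background_residual(M, background, exposures$alpha0)
  alpha <- exposures$alpha
  if (is.null(alpha) || ncol(alpha) == 0L) return(0)
  if (all(alpha == 0)) {
    warning("all exposures are zero; lambda_max is 0", call. = FALSE)
    return(0)
  }
  C <- crossprod(alpha, R)
  max(0, max(C)) * 2
}

.background_residual <- function(M, background, alpha0) {
  if (is.null(background)) return(M)
  M - outer(as.numeric(alpha0), as.numeric(background))
}

#' Refit signatures with exposures held fixed
#'
#' Solves the non-negative LASSO subproblem for the signature matrix by
#' cyclic coordinate descent, with the background signature excluded
#' from both the penalty and the update. The effective penalty is
#' `lambda_fraction * lambda_max`; at fraction 0 this is exactly the
#' non-negative least-squares solution, and at fractions >= 1 the whole
#' matrix is shrunk to zero.
#'
#' @inheritParams lambda_max
#' @param beta_init Warm-start K x 96 matrix (row names are preserved).
#' @param lambda_fraction Penalty as a fraction of [lambda_max()], in
#'   `[0, 1)` for useful fits.
#' @param lambda_max Precomputed maximal penalty; when `NULL` it is
#'   recomputed from `exposures`.
#' @param tol Relative objective-change tolerance of the coordinate
#'   descent (default 1e-8).
#' @param max_sweeps Iteration cap; exceeding it raises an error of
#'   class `sparsesigs_no_convergence` carrying the partial estimate in
#'   its `partial` field.
#' @return K x 96 non-negative matrix on the raw (unnormalized) scale.
#' @export
update_signatures <- function(counts, background, exposures, beta_init,
                              lambda_fraction, lambda_max = NULL,
                              tol = 1e-8, max_sweeps = 10000L) {
  M <- .check_count_matrix(counts)
  if (lambda_fraction < 0) stop("lambda_fraction must be >= 0", call. = FALSE)
  alpha <- exposures$alpha
  if (is.null(alpha) || ncol(alpha) == 0L) {
    stop("no non-background signatures to update", call. = FALSE)
  }
  if (nrow(beta_init) != ncol(alpha)) {
    stop("beta_init rows must match exposure columns", call. = FALSE)
  }
  R <- .background_residual(M, background, exposures$alpha0)
  if (is.null(lambda_max)) {
    lambda_max <- lambda_max(counts, background, exposures)
  }
  lambda <- lambda_fraction * lambda_max
  G <- crossprod(alpha)
  C <- crossprod(alpha, R)
  res <- cpp_nnlasso(G, C, unname(beta_init), lambda, sum(R^2), tol,
                     as.integer(max_sweeps))
  if (!res$converged) {
    cond <- structure(
      class = c("sparsesigs_no_convergence", "error", "condition"),
      list(message = sprintf(
             "signature update did not converge within %d sweeps", max_sweeps),
           call = sys.call(-1), partial = res$beta)
    )
    stop(cond)
  }
  beta <- res$beta
  dimnames(beta) <- dimnames(beta_init)
  beta
}

.penalized_objective <- function(M, background, exposures, beta, lambda) {
  pred <- if (is.null(background)) 0 else
    outer(as.numeric(exposures$alpha0), as.numeric(background))
  if (!is.null(beta) && nrow(beta) > 0) {
    pred <- pred + exposures$alpha %*% beta
  }
  sum((M - pred)^2) + lambda * sum(beta)
}

#' Fit sparse signatures at a fixed model size and penalty
#'
#' Alternates exposure refitting ([update_exposures()]) and penalized
#' signature refitting ([update_signatures()]) for a fixed number of
#' iterations, starting from repeated-NMF initial signatures. The
#' penalty weight is `lambda_fraction` times the maximal penalty
#' computed once from the initial exposures, so the effective
#' regularization is constant across the whole fit. Both subproblems are
#' solved exactly, so the penalized objective is non-increasing across
#' half-steps.
#'
#' On output, signature rows are renormalized to sum 1 and the exposure
#' columns rescaled so the product is unchanged; rows driven entirely to
#' zero by the penalty are kept as structural zeros and reflected in
#' `effective_k`.
#'
#' @param counts N x 96 count matrix (filtered; see [filter_samples()]).
#' @param background 96-vector fixed background signature (e.g. from
#'   [load_background_preset()]), or `NULL` for none.
#' @param K Number of non-background signatures (`K = 0` gives the
#'   background-only NNLS fit).
#' @param lambda_fraction LASSO penalty as a fraction of the maximal
#'   penalty, in `[0, 1)`; 0 disables regularization.
#' @param iterations Number of alternating iterations (default 20,
#'   sufficient for convergence in practice).
#' @param restarts,seed Passed to [initialize_signatures()].
#' @param beta_init Optional K x 96 starting signatures, bypassing the
#'   NMF initialization (used for warm starts during cross-validation).
#' @param tol Coordinate-descent tolerance.
#' @return Object of class `sparsesigs_fit`: a list with elements
#'   `signatures` (K x 96, rows summing to 1 or structurally zero),
#'   `signatures_raw`, `exposures` (N x K, count scale), `alpha0`,
#'   `background`, `lambda_fraction`, `lambda` (absolute penalty),
#'   `lambda_max`, `objective_trace` (after every half-step), `mse`
#'   (mean squared reconstruction error per cell), and `effective_k`.
#' @examples
#' sim <- simulate_dataset(simulation_preset("sim1"), seed = 1)
#' fit <- fit_signatures(sim$counts, load_background_preset("germline"),
#'                       K = 3, lambda_fraction = 0.05, seed = 1)
#' fit
#' @export
fit_signatures <- function(counts, background = load_background_preset("germline"),
                           K, lambda_fraction = 0.05, iterations = 20,
                           restarts = 10, seed = NULL, beta_init = NULL,
                           tol = 1e-8) {
  M <- .check_count_matrix(counts)
  if (K == 0) {
    if (is.null(background)) {
      stop("K = 0 requires a background signature", call. = FALSE)
    }
    exposures <- update_exposures(M, background, NULL)
    pred <- outer(as.numeric(exposures$alpha0), as.numeric(background))
    out <- list(
      signatures = matrix(0, 0L, 96L, dimnames = list(NULL, mutation_categories())),
      signatures_raw = matrix(0, 0L, 96L),
      exposures = exposures$alpha,
      alpha0 = exposures$alpha0,
      background = background,
      K = 0L, effective_k = 0L,
      lambda_fraction = lambda_fraction, lambda = 0, lambda_max = 0,
      objective_trace = sum((M - pred)^2),
      mse = mean((M - pred)^2)
    )
    class(out) <- "sparsesigs_fit"
    return(out)
  }

  if (is.null(beta_init)) {
    beta_init <- initialize_signatures(M, K, restarts = restarts, seed = seed,
                                       background = background)
  }
  if (nrow(beta_init) != K || ncol(beta_init) != 96L) {
    stop("beta_init must be K x 96", call. = FALSE)
  }
  if (is.null(rownames(beta_init))) {
    rownames(beta_init) <- paste0("Signature_", seq_len(K))
  }

  beta <- beta_init
  lam_max <- NULL
  lambda <- NA_real_
  trace <- numeric(0)
  exposures <- NULL
  for (it in seq_len(iterations)) {
    exposures <- update_exposures(M, background, beta)
    if (is.null(lam_max)) {
      lam_max <- lambda_max(M, background, exposures)
      lambda <- lambda_fraction * lam_max
    }
    trace <- c(trace, .penalized_objective(M, background, exposures, beta, lambda))
    beta <- update_signatures(M, background, exposures, beta,
                              lambda_fraction, lambda_max = lam_max,
                              tol = tol)
    trace <- c(trace, .penalized_objective(M, background, exposures, beta, lambda))
  }
  # final exposures consistent with the final beta
  exposures <- update_exposures(M, background, beta)
  trace <- c(trace, .penalized_objective(M, background, exposures, beta, lambda))

  rs <- rowSums(beta)
  keep_scale <- ifelse(rs > 0, rs, 1)
  signatures <- beta / keep_scale
  alpha <- sweep(exposures$alpha, 2L, rs, `*`)
  dimnames(signatures) <- list(rownames(beta), mutation_categories())
  colnames(alpha) <- rownames(beta)

  pred <- (if (is.null(background)) 0 else
             outer(as.numeric(exposures$alpha0), as.numeric(background))) +
    exposures$alpha %*% beta

  out <- list(
    signatures = signatures,
    signatures_raw = beta,
    exposures = alpha,
    alpha0 = exposures$alpha0,
    background = background,
    K = as.integer(K),
    effective_k = sum(rs > 0),
    lambda_fraction = lambda_fraction,
    lambda = lambda,
    lambda_max = lam_max,
    objective_trace = trace,
    mse = mean((M - pred)^2)
  )
  class(out) <- "sparsesigs_fit"
  out
}

#' @export
print.sparsesigs_fit <- function(x, ...) {
  cat("Sparse signature fit\n")
  cat(sprintf("  samples: %d   K (non-background): %d (effective %d)%s\n",
              if (is.null(x$alpha0)) nrow(x$exposures) else length(x$alpha0),
              x$K, x$effective_k,
              if (is.null(x$background)) "   background: none"
              else "   background: fixed"))
  cat(sprintf("  lambda: %.4g (fraction %.3g of lambda_max %.4g)\n",
              x$lambda, x$lambda_fraction, x$lambda_max))
  cat(sprintf("  reconstruction MSE per cell: %.6g\n", x$mse))
  invisible(x)
}

#' Reconstructed mutation spectra
#'
#' The fitted matrix `alpha0 beta0 + alpha beta` on the count scale.
#'
#' @param object A `sparsesigs_fit`.
#' @param ... Unused.
#' @return N x 96 numeric matrix.
#' @export
fitted.sparsesigs_fit <- function(object, ...) {
  pred <- if (is.null(object$background)) 0 else
    outer(as.numeric(object$alpha0), as.numeric(object$background))
  if (object$K > 0) pred <- pred + object$exposures %*% object$signatures
  pred
}
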