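# Metrics for scoring signature and exposure recovery on benchmark
# data, and diagnostics for fits on real cohorts.

#' Cosine similarity between spectra
#'
#' `dot(u, v) / (|u| |v|)`; scale-invariant, and in `[0, 1]` for
#' non-negative vectors.
#'
#' @param u,v Non-negative numeric vectors of equal length, not all
#'   zero.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine similarity undefined for a zero vector", call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

.cosine_matrix <- function(A, B) {
  # rows of A vs rows of B
  An <- A / sqrt(rowSums(A^2))
  Bn <- B / sqrt(rowSums(B^2))
  tcrossprod(An, Bn)
}

#' Match true signatures to estimated signatures
#'
#' Two matching semantics:
#'
#' * `"per_true_best"` (default, the benchmark convention) — each true
#'   signature is paired with the estimated signature of highest cosine
#'   similarity; one estimate may absorb several true signatures.
#' * `"one_to_one"` — the assignment maximizing total cosine similarity,
#'   with distinct estimates per true signature (exact bitmask dynamic
#'   program; estimated count capped at 20).
#'
#' Background rows are excluded by the caller, matching the convention
#' that background recovery is not scored.
#'
#' @param true_beta T x 96 matrix of generating signatures.
#' @param est_beta E x 96 matrix of discovered signatures (rows with all
#'   zero entries are dropped before matching).
#' @param method Matching semantics.
#' @return Object of class `sparsesigs_match`: data frame with columns
#'   `true` (row name), `estimated`, `cosine`, plus the method as an
#'   attribute.
#' @export
match_signatures <- function(true_beta, est_beta,
                             method = c("per_true_best", "one_to_one")) {
  method <- match.arg(method)
  stopifnot(is.matrix(true_beta), is.matrix(est_beta))
  if (nrow(true_beta) == 0L || nrow(est_beta) == 0L) {
    stop("signature matrices must be non-empty", call. = FALSE)
  }
  nonzero <- rowSums(est_beta^2) > 0
  if (!any(nonzero)) stop("all estimated signatures are zero", call. = FALSE)
  est_beta <- est_beta[nonzero, , drop = FALSE]
  if (is.null(rownames(true_beta))) {
    rownames(true_beta) <- paste0("True_", seq_len(nrow(true_beta)))
  }
  if (is.null(rownames(est_beta))) {
    rownames(est_beta) <- paste0("Est_", seq_len(nrow(est_beta)))
  }
  S <- .cosine_matrix(true_beta, est_beta)
  Tn <- nrow(S); En <- ncol(S)

  if (method == "per_true_best") {
    j <- apply(S, 1L, which.max)
    out <- data.frame(true = rownames(true_beta),
                      estimated = rownames(est_beta)[j],
                      cosine = S[cbind(seq_len(Tn), j)],
                      stringsAsFactors = FALSE)
  } else {
    if (Tn > En) {
      stop("one_to_one matching needs at least as many estimated ",
           "signatures as true signatures", call. = FALSE)
    }
    if (En > 20L) stop("one_to_one matching supports at most 20 estimated signatures",
                       call. = FALSE)
    # DP over subsets of estimated signatures, true signatures in order
    nstate <- bitwShiftL(1L, En)
    best <- matrix(-Inf, Tn + 1L, nstate)
    choice <- matrix(NA_integer_, Tn + 1L, nstate)
    best[1L, 1L] <- 0
    for (t in seq_len(Tn)) {
      for (s in which(is.finite(best[t, ])) - 1L) {
        for (e in seq_len(En)) {
          bit <- bitwShiftL(1L, e - 1L)
          if (bitwAnd(s, bit) == 0L) {
            ns <- bitwOr(s, bit)
            v <- best[t, s + 1L] + S[t, e]
            if (v > best[t + 1L, ns + 1L]) {
              best[t + 1L, ns + 1L] <- v
              choice[t + 1L, ns + 1L] <- e
            }
          }
        }
      }
    }
    final <- which.max(best[Tn + 1L, ])
    assign_e <- integer(Tn)
    s <- final - 1L
    for (t in rev(seq_len(Tn))) {
      e <- choice[t + 1L, s + 1L]
      assign_e[t] <- e
      s <- bitwAnd(s, bitwNot(bitwShiftL(1L, e - 1L)))
    }
    out <- data.frame(true = rownames(true_beta),
                      estimated = rownames(est_beta)[assign_e],
                      cosine = S[cbind(seq_len(Tn), assign_e)],
                      stringsAsFactors = FALSE)
  }
  attr(out, "method") <- method
  class(out) <- c("sparsesigs_match", class(out))
  out
}

#' Exposure recovery error per matched signature
#'
#' For each (true, estimated) pair of a [match_signatures()] report, the
#' mean over samples of the squared difference between the true exposure
#' values and the estimated exposures of the matched signature, on the
#' mutation-count scale.
#'
#' @param true_alpha N x T matrix of generating exposures (columns named
#'   like the true signatures).
#' @param est_alpha N x E matrix of estimated exposures (columns named
#'   like the estimated signatures).
#' @param report A `sparsesigs_match`.
#' @param fraction Compare exposures as per-sample fractions of total
#'   mutations instead of counts.
#' @return Named numeric vector of per-pair mean squared errors.
#' @export
exposure_error <- function(true_alpha, est_alpha, report, fraction = FALSE) {
  if (nrow(true_alpha) != nrow(est_alpha)) {
    stop("exposure matrices disagree on the number of samples", call. = FALSE)
  }
  if (fraction) {
    tot_t <- rowSums(true_alpha); tot_t[tot_t == 0] <- 1
    tot_e <- rowSums(est_alpha); tot_e[tot_e == 0] <- 1
    true_alpha <- true_alpha / tot_t
    est_alpha <- est_alpha / tot_e
  }
  out <- vapply(seq_len(nrow(report)), function(i) {
    ti <- report$true[i]; ei <- report$estimated[i]
    if (!ti %in% colnames(true_alpha) || !ei %in% colnames(est_alpha)) {
      stop("matched signature names not found in the exposure columns",
           call. = FALSE)
    }
    mean((true_alpha[, ti] - est_alpha[, ei])^2)
  }, numeric(1))
  names(out) <- report$true
  out
}

#' Sparsity of a signature matrix
#'
#' Fraction of entries below a threshold: 1e-3 in the simulation
#' benchmarks, 1e-4 in the real-data comparisons. The threshold is
#' always explicit.
#'
#' @param beta K x 96 signature matrix (background excluded by the
#'   caller, or via `exclude_row`).
#' @param threshold Positive cutoff under which an entry counts as zero.
#' @param exclude_row Optional row name/index to drop (e.g. a bound
#'   background row).
#' @export
signature_sparsity <- function(beta, threshold = 1e-3, exclude_row = NULL) {
  stopifnot(threshold > 0)
  if (!is.null(exclude_row)) {
    i <- if (is.character(exclude_row)) match(exclude_row, rownames(beta))
         else as.integer(exclude_row)
    beta <- beta[-i, , drop = FALSE]
  }
  if (length(beta) == 0L) stop("empty signature matrix", call. = FALSE)
  mean(beta < threshold)
}

#' Diagnostics for a fitted model
#'
#' The six summaries used to compare fits on real cohorts:
#'
#' * `mse` — mean squared reconstruction error per cell;
#' * `explained_variance` — `1 - ||M - fit||_F^2 / ||M||_F^2`;
#' * `sparsity` — fraction of signature entries below
#'   `sparsity_threshold` (background excluded);
#' * `cross_signature_similarity` — mean cosine similarity over all
#'   pairs of predicted signatures (background included when fixed);
#'   `NA` when fewer than two signatures;
#' * `background_contamination` — mean cosine similarity between the
#'   background and each non-background signature (`NA` without a
#'   background);
#' * `per_patient_correlation` — per-sample Pearson correlation between
#'   the observed 96-category spectrum and its reconstruction (`NA` for
#'   constant observed rows), with the median reported alongside.
#'
#' @param counts The matrix the model was fitted on.
#' @param fit A `sparsesigs_fit`.
#' @param sparsity_threshold Cutoff for the sparsity metric (default
#'   1e-4, the real-data convention).
#' @return List of class `sparsesigs_diagnostics`.
#' @export
fit_diagnostics <- function(counts, fit, sparsity_threshold = 1e-4) {
  M <- .check_count_matrix(counts)
  pred <- fitted(fit)
  rss <- sum((M - pred)^2)
  all_sigs <- fit$signatures[rowSums(fit$signatures) > 0, , drop = FALSE]
  with_bg <- if (!is.null(fit$background)) {
    rbind(Background = as.numeric(fit$background), all_sigs)
  } else all_sigs

  cross <- if (nrow(with_bg) >= 2L) {
    cm <- .cosine_matrix(with_bg, with_bg)
    mean(cm[upper.tri(cm)])
  } else NA_real_

  contamination <- if (!is.null(fit$background) && nrow(all_sigs) >= 1L) {
    mean(apply(all_sigs, 1L, cosine_similarity, v = as.numeric(fit$background)))
  } else NA_real_

  ppc <- vapply(seq_len(nrow(M)), function(i) {
    if (stats::sd(M[i, ]) == 0 || stats::sd(pred[i, ]) == 0) return(NA_real_)
    stats::cor(M[i, ], pred[i, ])
  }, numeric(1))
  names(ppc) <- rownames(M)

  out <- list(
    mse = rss / length(M),
    explained_variance = 1 - rss / sum(M^2),
    sparsity = if (nrow(all_sigs) > 0)
      signature_sparsity(all_sigs, sparsity_threshold) else NA_real_,
    cross_signature_similarity = cross,
    background_contamination = contamination,
    per_patient_correlation = ppc,
    median_per_patient_correlation = stats::median(ppc, na.rm = TRUE),
    sparsity_threshold = sparsity_threshold
  )
  class(out) <- "sparsesigs_diagnostics"
  out
}

#' @export
print.sparsesigs_diagnostics <- function(x, ...) {
  cat("Fit diagnostics\n")
  cat(sprintf("  MSE per cell: %.6g   explained variance: %.6g\n",
              x$mse, x$explained_variance))
  cat(sprintf("  sparsity (< %g): %.4g\n", x$sparsity_threshold, x$sparsity))
  cat(sprintf("  cross-signature similarity: %s   background contamination: %s\n",
              format(x$cross_signature_similarity, digits = 4),
              format(x$background_contamination, digits = 4)))
  cat(sprintf("  median per-patient correlation: %.4f\n",
              x$median_per_patient_correlation))
  invisible(x)
}

#' Recovery stratified by signature rarity and abundance
#'
#' Pools matching reports over several benchmark datasets and summarizes
#' the median recovery cosine by bins of presence fraction (the share of
#' samples exposed to the signature) and by bins of the total number of
#' mutations the signature contributed.
#'
#' @param reports List of `sparsesigs_match` reports, one per dataset.
#' @param presence List of named numeric vectors giving, per dataset,
#'   the realized presence fraction of each true signature.
#' @param mutations List of named numeric vectors giving, per dataset,
#'   the total mutations contributed by each true signature.
#' @param presence_breaks,mutation_breaks Bin edges.
#' @return List of two data frames (`by_presence`, `by_mutations`) with
#'   the stratum, the number of signatures in it, and the median cosine
#'   (`NA` for empty strata).
#' @export
rare_signature_summary <- function(reports, presence, mutations = NULL,
                                   presence_breaks = c(0, 0.35, 0.7, 1),
                                   mutation_breaks = c(0, 6e3, 3e4, Inf)) {
  stopifnot(length(reports) == length(presence))
  rows <- do.call(rbind, lapply(seq_along(reports), function(d) {
    r <- reports[[d]]
    p <- presence[[d]][r$true]
    m <- if (!is.null(mutations)) mutations[[d]][r$true] else NA_real_
    data.frame(cosine = r$cosine, presence = as.numeric(p),
               mutations = as.numeric(m))
  }))
  summarize <- function(values, breaks) {
    bin <- cut(values, breaks, include.lowest = TRUE)
    med <- tapply(rows$cosine, bin, stats::median)
    data.frame(stratum = levels(bin),
               n = as.integer(table(bin)),
               median_cosine = as.numeric(med[levels(bin)]),
               stringsAsFactors = FALSE)
  }
  out <- list(by_presence = summarize(rows$presence, presence_breaks))
  if (!is.null(mutations)) {
    out$by_mutations <- summarize(rows$mutations, mutation_breaks)
  }
  out
}
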