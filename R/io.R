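# TSV serialization for signature and exposure matrices. All writers
# prepend comment headers naming the category ordering and (for
# exposures) the K-counting convention; readers skip comment lines.

#' Read and write signature matrices as TSV
#'
#' Rows are signatures (first column `signature`, e.g. `Signature_1` or
#' `Background`), followed by 96 columns headed by the category labels
#' in canonical order.
#'
#' @param beta K x 96 matrix; a fitted background can be included as an
#'   extra row via `background`.
#' @param path File path.
#' @param background Optional 96-vector written as a row labelled
#'   `Background`.
#' @return `read_signature_matrix()` returns the numeric matrix with
#'   signature row names.
#' @export
write_signature_matrix <- function(beta, path, background = NULL) {
  stopifnot(is.matrix(beta), ncol(beta) == 96L)
  if (is.null(rownames(beta))) {
    rownames(beta) <- paste0("Signature_", seq_len(nrow(beta)))
  }
  m <- if (!is.null(background)) {
    rbind(Background = as.numeric(background), beta)
  } else beta
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# categories: 96 pyrimidine-centered trinucleotide contexts, type-major order", con)
  df <- data.frame(signature = rownames(m), m, check.names = FALSE)
  colnames(df)[-1L] <- mutation_categories()
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_matrix
#' @export
read_signature_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"signature" %in% names(df)) {
    stop("signature TSV must have a 'signature' column", call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "signature"), drop = FALSE])
  if (ncol(m) != 96L) {
    stop("signature TSV must have 96 category columns", call. = FALSE)
  }
  idx <- match(mutation_categories(), colnames(m))
  if (anyNA(idx)) {
    stop("signature TSV columns do not match the 96 canonical categories",
         call. = FALSE)
  }
  m <- m[, idx, drop = FALSE]
  rownames(m) <- df$signature
  m
}

#' Read and write exposure matrices as TSV
#'
#' Rows are samples (first column `sample`), columns the signatures,
#' values on the mutation-count scale. With `fraction = TRUE` a
#' row-normalized variant (fraction of mutations per tumor) is written
#' instead.
#'
#' @param exposures N x K exposure matrix.
#' @param path File path.
#' @param alpha0 Optional background exposures, written as a leading
#'   `Background` column.
#' @param fraction Write per-sample fractions instead of counts.
#' @export
write_exposures <- function(exposures, path, alpha0 = NULL,
                            fraction = FALSE) {
  m <- if (!is.null(alpha0)) {
    cbind(Background = as.numeric(alpha0), exposures)
  } else as.matrix(exposures)
  if (fraction) {
    tot <- rowSums(m); tot[tot == 0] <- 1
    m <- m / tot
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# exposures per sample and signature; K counts non-background signatures",
    paste0("# scale: ", if (fraction) "fraction of mutations per tumor"
           else "mutation counts")), con)
  df <- data.frame(sample = rownames(m), m, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_exposures
#' @export
read_exposures <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) {
    stop("exposure TSV must have a 'sample' column", call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
  rownames(m) <- df$sample
  m
}
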