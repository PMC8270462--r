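#' Preset background signatures
#'
#' The background signature is a fixed, dense spectrum representing
#' clock-like replication-error mutagenesis, held constant during
#' factorization while the remaining signatures are discovered. Two
#' presets ship with the package:
#'
#' * `"germline"` — modelled on the human germline de novo mutation
#'   spectrum (the default used throughout).
#' * `"sbs5"` — modelled on the ubiquitous, flat SBS5-like spectrum
#'   found across cancer and normal tissues.
#'
#' Both presets have the CpG>TpG adjustment of [cpg_adjust()] already
#' applied, so that cytosine deamination at methylated CpG sites is left
#' for a dedicated discovered signature rather than absorbed into the
#' background. The packaged vectors are synthetic stand-ins constructed
#' to match the documented properties of the published presets (dense
#' support over all 96 categories, CpG-adjusted, mutual cosine
#' similarity 0.998); they are not transcriptions of the published
#' tables, which are not redistributable here.
#'
#' @param name `"germline"` or `"sbs5"`.
#' @return Named numeric vector of 96 probabilities summing to 1, in
#'   canonical category order, with attribute `"background_name"`.
#' @examples
#' b <- load_background_preset("germline")
#' sum(b)  # 1
#' @export
load_background_preset <- function(name = c("germline", "sbs5")) {
  name <- match.arg(name)
  path <- system.file("extdata",
                      paste0("background_", name, "_synthetic.tsv"),
                      package = "sparsesigs", mustWork = TRUE)
  read_background(path, name = name)
}

#' Read and write background signatures as TSV
#'
#' Two tab-separated columns: `category` (the 96 labels) and
#' `probability`. Rows may appear in any order; they are matched to the
#' canonical ordering on read and renormalized to sum exactly 1.
#'
#' @param path File path.
#' @param name Label stored on the returned vector.
#' @param background Background signature vector to write.
#' @export
read_background <- function(path, name = "custom") {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("category", "probability") %in% names(df))) {
    stop("background TSV needs columns 'category' and 'probability'",
         call. = FALSE)
  }
  cats <- mutation_categories()
  idx <- match(cats, df$category)
  if (anyNA(idx)) {
    stop("background TSV does not cover all 96 categories", call. = FALSE)
  }
  v <- as.numeric(df$probability[idx])
  make_background(v, adjust = FALSE, name = name)
}

#' @rdname read_background
#' @export
write_background <- function(background, path) {
  stopifnot(is.numeric(background), length(background) == 96L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# categories: 96 pyrimidine-centered trinucleotide contexts, type-major order", con)
  df <- data.frame(category = mutation_categories(),
                   probability = as.numeric(background))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Equalize CpG>TpG rates with their CpA counterparts
#'
#' Cytosine deamination at methylated CpG sites inflates the four
#' `N[C>T]G` categories of any empirically derived spectrum. To keep DNA
#' methylation effects out of the background signature, the rates of
#' `A[C>T]G`, `C[C>T]G`, `G[C>T]G` and `T[C>T]G` are overwritten with
#' the rates of `A[C>T]A`, `C[C>T]A`, `G[C>T]A` and `T[C>T]A`
#' respectively, and the vector is renormalized to sum 1. The operation
#' is idempotent.
#'
#' @param v Non-negative numeric vector of length 96 in canonical
#'   category order (need not be normalized).
#' @return Adjusted, normalized 96-vector.
#' @export
cpg_adjust <- function(v) {
  stopifnot(is.numeric(v), length(v) == 96L)
  if (any(v < 0)) stop("background entries must be non-negative", call. = FALSE)
  if (all(v == 0)) stop("background vector is all zero", call. = FALSE)
  v <- as.numeric(v)
  cats <- mutation_categories()
  for (n in c("A", "C", "G", "T")) {
    g <- match(paste0(n, "[C>T]G"), cats)
    a <- match(paste0(n, "[C>T]A"), cats)
    v[g] <- v[a]
  }
  names(v) <- cats
  v / sum(v)
}

#' Construct a background signature (or opt out of one)
#'
#' Validates and normalizes a user-supplied 96-vector for use as the
#' fixed background, optionally applying the CpG adjustment of
#' [cpg_adjust()]. Passing `"none"` returns `NULL`, the sentinel
#' understood by [fit_signatures()] and [cross_validate()] to mean "no
#' fixed background": the model then reduces to plain regularized NMF
#' with the penalty applied to every signature.
#'
#' @param v Numeric vector of length 96 (any non-negative scale), or the
#'   string `"none"`.
#' @param adjust Apply the CpG>TpG adjustment (default `FALSE`; the
#'   presets are already adjusted).
#' @param name Label stored on the result.
#' @return Named 96-vector summing to 1, or `NULL` for `"none"`.
#' @export
make_background <- function(v, adjust = FALSE, name = "custom") {
  if (is.character(v) && length(v) == 1L && v == "none") return(NULL)
  if (!is.numeric(v)) stop("background must be numeric or \"none\"", call. = FALSE)
  if (length(v) != 96L) {
    stop("background must have length 96, got ", length(v), call. = FALSE)
  }
  if (any(v < 0)) stop("background entries must be non-negative", call. = FALSE)
  if (all(v == 0)) stop("background vector is all zero", call. = FALSE)
  v <- as.numeric(v)
  if (adjust) v <- cpg_adjust(v)
  v <- v / sum(v)
  names(v) <- mutation_categories()
  attr(v, "background_name") <- name
  v
}
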