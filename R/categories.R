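#' The 96 trinucleotide mutation categories
#'
#' Somatic single-base substitutions are strand-collapsed so that the
#' mutated reference base is always a pyrimidine (C or T), giving six
#' substitution types (C>A, C>G, C>T, T>A, T>C, T>G). Each type is
#' subdivided by the 16 combinations of the 5' and 3' flanking bases,
#' for 6 x 16 = 96 categories.
#'
#' The canonical ordering is type-major (C>A, C>G, C>T, T>A, T>C, T>G),
#' then alphabetical by 5' flank, then by 3' flank, matching the
#' convention used by published signature catalogs.
#'
#' @return Character vector of the 96 category labels, e.g. `"A[C>A]G"`,
#'   in canonical order.
#' @examples
#' head(mutation_categories())
#' @export
mutation_categories <- function() {
  .categories_cache
}

.make_categories <- function() {
  bases <- c("A", "C", "G", "T")
  types <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (ty in types) {
    for (f5 in bases) {
      for (f3 in bases) {
        out <- c(out, paste0(f5, "[", ty, "]", f3))
      }
    }
  }
  out
}

.categories_cache <- .make_categories()

.base_complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify point mutations into trinucleotide categories
#'
#' Assigns each single-nucleotide substitution, described by its
#' reference base, alternate base and the two flanking reference bases,
#' to one of the 96 strand-collapsed categories. When the reference base
#' is a purine (A or G) the whole trinucleotide and the alternate base
#' are reverse-complemented first, so the returned label always carries
#' a pyrimidine as the central reference base.
#'
#' All four arguments are recycled to a common length, so vectors of
#' mutations can be classified in one call.
#'
#' @param ref Reference base(s), single characters in `A`,`C`,`G`,`T`.
#' @param alt Alternate base(s); must differ from `ref` elementwise.
#' @param flank5 Base immediately 5' of the mutated position (reference
#'   strand).
#' @param flank3 Base immediately 3' of the mutated position.
#' @return Character vector of category labels (see
#'   [mutation_categories()]).
#' @examples
#' classify_mutation("C", "T", "A", "G")  # "A[C>T]G"
#' classify_mutation("G", "A", "C", "T")  # also "A[C>T]G" (reverse strand)
#' @export
classify_mutation <- function(ref, alt, flank5, flank3) {
  n <- max(length(ref), length(alt), length(flank5), length(flank3))
  ref    <- toupper(rep_len(as.character(ref), n))
  alt    <- toupper(rep_len(as.character(alt), n))
  flank5 <- toupper(rep_len(as.character(flank5), n))
  flank3 <- toupper(rep_len(as.character(flank3), n))

  bases <- c("A", "C", "G", "T")
  bad <- !(ref %in% bases) | !(alt %in% bases) |
    !(flank5 %in% bases) | !(flank3 %in% bases)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "non-ACGT base in mutation %d: ref=%s alt=%s flank5=%s flank3=%s",
      i, ref[i], alt[i], flank5[i], flank3[i]
    ), call. = FALSE)
  }
  same <- ref == alt
  if (any(same)) {
    i <- which(same)[1L]
    stop(sprintf("mutation %d has alt equal to ref (%s)", i, ref[i]),
         call. = FALSE)
  }

  flip <- ref %in% c("A", "G")
  if (any(flip)) {
    r <- ref[flip]; a <- alt[flip]; f5 <- flank5[flip]; f3 <- flank3[flip]
    ref[flip]    <- .base_complement[r]
    alt[flip]    <- .base_complement[a]
    flank5[flip] <- .base_complement[f3]
    flank3[flip] <- .base_complement[f5]
  }
  paste0(flank5, "[", ref, ">", alt, "]", flank3)
}

#' @rdname classify_mutation
#' @return `category_index()` returns the 1-based position of a label in
#'   the canonical ordering.
#' @param label Category label(s) of the form `"X[R>A]Y"`.
#' @export
category_index <- function(label) {
  idx <- match(label, mutation_categories())
  if (anyNA(idx)) {
    stop("unknown category label: ", label[which(is.na(idx))[1L]],
         call. = FALSE)
  }
  idx
}
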