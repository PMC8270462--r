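#' Read somatic single-nucleotide variants
#'
#' Reads variant calls into the five-column data frame used by
#' [build_count_matrix()]: `sample`, `chrom`, `pos` (1-based), `ref`,
#' `alt`. Three formats are supported:
#'
#' * `tsv` — tab-separated with a header naming the five columns
#'   (case-insensitive).
#' * `vcf` — plain or bgzipped VCF. Multi-allelic records are split into
#'   one row per SNV alternate allele; non-SNV alleles are skipped. When
#'   the VCF carries genotypes, a record is assigned to every sample
#'   whose genotype includes the alternate allele; without genotype
#'   columns all records are assigned to a single sample named after the
#'   file.
#' * `maf` — MAF using the columns `Tumor_Sample_Barcode`, `Chromosome`,
#'   `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2`.
#'
#' @param path Path to the variant file.
#' @param format One of `"auto"`, `"tsv"`, `"vcf"`, `"maf"`. With
#'   `"auto"` the format is inferred from the file extension.
#' @return A data frame with columns `sample`, `chrom`, `pos`, `ref`,
#'   `alt`, one row per single-nucleotide variant per carrying sample.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf", "maf")) {
  format <- match.arg(format)
  if (format == "auto") {
    low <- tolower(path)
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", low)) "vcf"
      else if (grepl("\\.maf(\\.gz)?$", low)) "maf"
      else "tsv"
  }
  if (!file.exists(path)) stop("variant file not found: ", path, call. = FALSE)
  switch(format,
    tsv = .read_variants_tsv(path),
    maf = .read_variants_maf(path),
    vcf = .read_variants_vcf(path)
  )
}

.read_variants_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  names(df) <- tolower(names(df))
  need <- c("sample", "chrom", "pos", "ref", "alt")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("variant TSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    sample = as.character(df$sample),
    chrom = as.character(df$chrom),
    pos = as.integer(df$pos),
    ref = toupper(as.character(df$ref)),
    alt = toupper(as.character(df$alt)),
    stringsAsFactors = FALSE
  )
}

.read_variants_maf <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
            "Reference_Allele", "Tumor_Seq_Allele2")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("MAF is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    sample = as.character(df$Tumor_Sample_Barcode),
    chrom = as.character(df$Chromosome),
    pos = as.integer(df$Start_Position),
    ref = toupper(as.character(df$Reference_Allele)),
    alt = toupper(as.character(df$Tumor_Seq_Allele2)),
    stringsAsFactors = FALSE
  )
}

.read_variants_vcf <- function(path) {
  v <- VariantAnnotation::scanVcf(path)[[1L]]
  rr <- v$rowRanges
  ref <- as.character(v$REF)
  altl <- as.list(v$ALT)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  nalt <- lengths(altl)
  alt_flat <- as.character(unlist(altl, use.names = FALSE))
  rec <- rep(seq_along(ref), nalt)       # VCF record per expanded allele
  aidx <- sequence(nalt)                 # allele number within record

  snv <- nchar(ref[rec]) == 1L & nchar(alt_flat) == 1L &
    ref[rec] %in% c("A", "C", "G", "T") &
    alt_flat %in% c("A", "C", "G", "T") & alt_flat != ref[rec]

  gt <- v$GENO$GT
  samples <- colnames(gt)
  rows <- list()
  if (is.null(gt) || is.null(samples) || length(samples) == 0L) {
    sid <- sub("\\.vcf(\\.gz|\\.bgz)?$", "", basename(path), ignore.case = TRUE)
    keep <- which(snv)
    rows[[1L]] <- data.frame(
      sample = rep(sid, length(keep)),
      chrom = chrom[rec[keep]], pos = pos[rec[keep]],
      ref = ref[rec[keep]], alt = alt_flat[keep],
      stringsAsFactors = FALSE
    )
  } else {
    for (s in samples) {
      g <- gt[, s]
      # genotype carries allele a if the string contains that allele number
      for (k in which(snv)) {
        gk <- g[rec[k]]
        if (is.na(gk) || gk %in% c(".", "./.", ".|.")) next
        alleles <- strsplit(gk, "[/|]")[[1L]]
        if (as.character(aidx[k]) %in% alleles) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = s, chrom = chrom[rec[k]], pos = pos[rec[k]],
            ref = ref[rec[k]], alt = alt_flat[k], stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Build the 96-category count matrix from variant calls
#'
#' Looks up the trinucleotide context of each single-nucleotide variant
#' in an indexed reference FASTA, classifies it with
#' [classify_mutation()], and tallies mutations per sample into an
#' N x 96 count matrix (samples in rows, categories in canonical
#' order in columns).
#'
#' Records whose trinucleotide context contains a non-ACGT character
#' (e.g. `N`) and records that are not simple SNVs are skipped with a
#' warning reporting how many were dropped. A mismatch between the
#' stated reference allele and the genome is an error by default
#' (`strict = TRUE`); with `strict = FALSE` mismatching records are
#' skipped and counted in the warning instead, since silent mismatches
#' corrupt the spectrum.
#'
#' @param variants Data frame with columns `sample`, `chrom`, `pos`,
#'   `ref`, `alt` (see [read_variants()]).
#' @param reference Path to a FASTA file with a `.fai` index, or an
#'   [Rsamtools::FaFile] object.
#' @param strict Logical; treat reference-allele mismatches as errors
#'   (default) rather than skipping them.
#' @return Integer matrix with one row per distinct sample id (in order
#'   of first appearance) and 96 columns named by category. The number
#'   of records skipped is attached as attribute `"skipped"`.
#' @export
build_count_matrix <- function(variants, reference, strict = TRUE) {
  if (!is.data.frame(variants) || nrow(variants) == 0L) {
    stop("no mutations: the variant table is empty", call. = FALSE)
  }
  need <- c("sample", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variants must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  fa <- if (inherits(reference, "FaFile")) reference else {
    if (!file.exists(reference)) {
      stop("reference FASTA not found: ", reference, call. = FALSE)
    }
    if (!file.exists(paste0(reference, ".fai"))) {
      stop("reference FASTA index (.fai) not found for: ", reference,
           "\nCreate one with Rsamtools::indexFa() or `samtools faidx`.",
           call. = FALSE)
    }
    Rsamtools::FaFile(reference)
  }
  sq <- Rsamtools::scanFaIndex(fa)
  contig_len <- stats::setNames(GenomicRanges::width(sq),
                                as.character(GenomicRanges::seqnames(sq)))

  chrom <- as.character(variants$chrom)
  pos <- as.integer(variants$pos)
  ref <- toupper(as.character(variants$ref))
  alt <- toupper(as.character(variants$alt))
  sample_id <- as.character(variants$sample)

  unknown <- setdiff(unique(chrom), names(contig_len))
  if (length(unknown)) {
    stop("contig(s) absent from reference: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out_of_bounds <- pos < 2L | pos + 1L > contig_len[chrom]
  if (any(out_of_bounds)) {
    i <- which(out_of_bounds)[1L]
    stop(sprintf("flank outside contig bounds at %s:%d (record %d)",
                 chrom[i], pos[i], i), call. = FALSE)
  }

  bases <- c("A", "C", "G", "T")
  is_snv <- ref %in% bases & alt %in% bases & alt != ref &
    nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  n_not_snv <- sum(!is_snv)

  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos - 1L, pos + 1L))
  ctx <- as.character(Rsamtools::scanFa(fa, gr))
  ctx <- toupper(ctx)
  f5 <- substr(ctx, 1L, 1L)
  rb <- substr(ctx, 2L, 2L)
  f3 <- substr(ctx, 3L, 3L)

  ambiguous <- !(f5 %in% bases) | !(rb %in% bases) | !(f3 %in% bases)
  mismatch <- is_snv & !ambiguous & rb != ref
  if (strict && any(mismatch)) {
    i <- which(mismatch)[1L]
    stop(sprintf(
      "reference mismatch at %s:%d: variant says %s, genome has %s (record %d); use strict = FALSE to skip",
      chrom[i], pos[i], ref[i], rb[i], i), call. = FALSE)
  }

  keep <- is_snv & !ambiguous & !mismatch
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warning(sprintf(
      "skipped %d record(s): %d non-SNV, %d ambiguous context, %d reference mismatch",
      n_skipped, n_not_snv, sum(ambiguous & is_snv),
      sum(mismatch)), call. = FALSE)
  }
  if (!any(keep)) stop("no mutations left after filtering records", call. = FALSE)

  labels <- classify_mutation(ref[keep], alt[keep], f5[keep], f3[keep])
  cats <- mutation_categories()
  samples <- unique(sample_id)
  tab <- table(factor(sample_id[keep], levels = samples),
               factor(labels, levels = cats))
  counts <- matrix(as.integer(tab), nrow = length(samples),
                   dimnames = list(samples, cats))
  attr(counts, "skipped") <- n_skipped
  counts
}

#' Drop samples with too few mutations
#'
#' Signature discovery is unreliable on sparsely mutated genomes; the
#' recommended minimum is 1000 somatic point mutations per whole genome.
#' Rows whose total mutation count falls below the threshold are removed
#' (the boundary is inclusive: a sample with exactly `min_mutations`
#' mutations is kept).
#'
#' @param counts N x 96 count matrix (see [build_count_matrix()]).
#' @param min_mutations Minimum number of mutations a sample must have
#'   to be retained. Default 1000.
#' @return The filtered matrix, with the ids of removed samples attached
#'   as attribute `"removed_samples"`. Removing every sample is an
#'   error, since no factorization would be possible.
#' @export
filter_samples <- function(counts, min_mutations = 1000) {
  counts <- .check_count_matrix(counts)
  stopifnot(min_mutations >= 0)
  keep <- rowSums(counts) >= min_mutations
  if (!any(keep)) {
    stop("all samples fall below ", min_mutations,
         " mutations; nothing left to factorize", call. = FALSE)
  }
  removed <- rownames(counts)[!keep]
  out <- counts[keep, , drop = FALSE]
  attr(out, "removed_samples") <- removed
  out
}

.check_count_matrix <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (ncol(counts) != 96L) {
    stop("count matrix must have 96 columns, got ", ncol(counts),
         call. = FALSE)
  }
  if (any(counts < 0)) stop("count matrix has negative entries", call. = FALSE)
  if (is.null(colnames(counts))) {
    colnames(counts) <- mutation_categories()
  } else if (!identical(colnames(counts), mutation_categories())) {
    idx <- match(mutation_categories(), colnames(counts))
    if (anyNA(idx)) {
      stop("count matrix columns do not match the 96 canonical categories",
           call. = FALSE)
    }
    counts <- counts[, idx, drop = FALSE]
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("Sample_", seq_len(nrow(counts)))
  }
  counts
}

#' Read and write count matrices as TSV
#'
#' The on-disk format is tab-separated: a `sample` column followed by 96
#' columns headed by the category labels in canonical order. Comment
#' lines starting with `#` record the category convention and are
#' ignored on read.
#'
#' @param counts Count matrix.
#' @param path File path.
#' @return `read_count_matrix()` returns the integer matrix;
#'   `write_count_matrix()` returns `path` invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  counts <- .check_count_matrix(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# categories: 96 pyrimidine-centered trinucleotide contexts, type-major order", con)
  df <- data.frame(sample = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample" %in% names(df)) {
    stop("count matrix TSV must have a 'sample' column", call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample
  .check_count_matrix(m)
}
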