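test_that("classification follows the pyrimidine-centered convention", {
  expect_equal(classify_mutation("C", "T", "A", "G"), "A[C>T]G")
  # purine reference: reverse-complement first; CGT context -> ACG
  expect_equal(classify_mutation("G", "A", "C", "T"), "A[C>T]G")
  expect_equal(classify_mutation("T", "G", "T", "T"), "T[T>G]T")
  expect_equal(classify_mutation("A", "C", "G", "G"), "C[T>G]C")
})

test_that("classification rejects malformed input naming the record", {
  expect_error(classify_mutation("C", "C", "A", "G"), "alt equal to ref")
  expect_error(classify_mutation("N", "T", "A", "G"), "non-ACGT")
  expect_error(classify_mutation(c("C", "X"), c("T", "A"), "A", "G"),
               "mutation 2")
})

test_that("all 192 raw combinations collapse onto the 96 categories, each hit twice", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(ref = bases, alt = bases, f5 = bases, f3 = bases,
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  labels <- classify_mutation(combos$ref, combos$alt, combos$f5, combos$f3)
  expect_length(labels, 192L)
  tab <- table(labels)
  expect_setequal(names(tab), mutation_categories())
  expect_true(all(tab == 2L))  # each category from exactly 2 strands
  # agreement with the first-principles oracle on every combination
  oracle <- mapply(oracle_classify, combos$ref, combos$alt,
                   combos$f5, combos$f3)
  expect_equal(labels, unname(oracle))
})

test_that("pyrimidine-reference combinations enumerate a bijection onto 0..95", {
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(ref = c("C", "T"), alt = bases, f5 = bases,
                        f3 = bases, stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  labels <- classify_mutation(combos$ref, combos$alt, combos$f5, combos$f3)
  expect_equal(sort(labels), sort(mutation_categories()))
  expect_equal(anyDuplicated(labels), 0L)
  expect_equal(category_index(mutation_categories()), 1:96)
})

ref_fa <- system.file("extdata", "toy_reference.fa", package = "sparsesigs")
tsv <- system.file("extdata", "toy_variants.tsv", package = "sparsesigs")

test_that("count matrix matches an independent hand tally of the toy fixture", {
  variants <- read_variants(tsv)
  expect_equal(nrow(variants), 10L)
  counts <- build_count_matrix(variants, ref_fa)
  expect_equal(dim(counts), c(2L, 96L))
  expect_equal(sum(counts), 10L)           # conservation of records
  expect_equal(unname(rowSums(counts)), c(5L, 5L))

  # independent tally: read the contig as text, classify with the oracle
  contig <- paste(readLines(ref_fa)[-1], collapse = "")
  expected <- matrix(0L, 2, 96,
                     dimnames = list(c("S1", "S2"), mutation_categories()))
  for (i in seq_len(nrow(variants))) {
    p <- variants$pos[i]
    lab <- oracle_classify(substr(contig, p, p), variants$alt[i],
                           substr(contig, p - 1, p - 1),
                           substr(contig, p + 1, p + 1))
    expected[variants$sample[i], lab] <- expected[variants$sample[i], lab] + 1L
  }
  expect_equal(unclass(counts)[, ], expected)
})

test_that("VCF and MAF readers agree with the TSV on the same records", {
  v_tsv <- read_variants(tsv)
  v_vcf <- read_variants(system.file("extdata", "toy_variants.vcf",
                                     package = "sparsesigs"))
  v_maf <- read_variants(system.file("extdata", "toy_variants.maf",
                                     package = "sparsesigs"))
  key <- function(v) v[order(v$sample, v$pos),
                       c("sample", "chrom", "pos", "ref", "alt")]
  expect_equal(key(v_vcf), key(v_tsv), ignore_attr = TRUE)
  expect_equal(key(v_maf), key(v_tsv), ignore_attr = TRUE)
})

test_that("degenerate and malformed count-matrix inputs error usefully", {
  expect_error(build_count_matrix(data.frame(), ref_fa), "no mutations")
  bad_contig <- data.frame(sample = "S", chrom = "chrX", pos = 10L,
                           ref = "C", alt = "T")
  expect_error(build_count_matrix(bad_contig, ref_fa), "absent from reference")
  at_edge <- data.frame(sample = "S", chrom = "chr1", pos = 1L,
                        ref = "C", alt = "T")
  expect_error(build_count_matrix(at_edge, ref_fa), "contig bounds")
})

test_that("reference mismatches error in strict mode and are skipped in lenient mode", {
  contig <- paste(readLines(ref_fa)[-1], collapse = "")
  pos <- 50L
  actual <- substr(contig, pos, pos)
  wrong <- setdiff(c("A", "C", "G", "T"), actual)[1]
  alt <- setdiff(c("A", "C", "G", "T"), c(actual, wrong))[1]
  v <- data.frame(sample = c("S", "S"), chrom = "chr1",
                  pos = c(pos, 120L),
                  ref = c(wrong, substr(contig, 120, 120)),
                  alt = c(alt, setdiff(c("A", "C", "G", "T"),
                                       substr(contig, 120, 120))[1]))
  expect_error(build_count_matrix(v, ref_fa), "reference mismatch")
  expect_warning(counts <- build_count_matrix(v, ref_fa, strict = FALSE),
                 "skipped 1 record")
  expect_equal(sum(counts), 1L)
})

test_that("records with ambiguous context are skipped with a count", {
  # position 301 of the toy contig is N
  contig <- paste(readLines(ref_fa)[-1], collapse = "")
  b302 <- substr(contig, 302, 302)
  v <- data.frame(sample = "S", chrom = "chr1", pos = c(302L, 100L),
                  ref = c(b302, substr(contig, 100, 100)),
                  alt = c(setdiff(c("A", "C", "G", "T"), b302)[1],
                          setdiff(c("A", "C", "G", "T"),
                                  substr(contig, 100, 100))[1]))
  expect_warning(counts <- build_count_matrix(v, ref_fa), "ambiguous")
  expect_equal(sum(counts), 1L)
  expect_equal(attr(counts, "skipped"), 1L)
})

test_that("sample filtering respects the inclusive threshold and reports removals", {
  m <- matrix(0L, 3, 96, dimnames = list(c("a", "b", "c"),
                                         mutation_categories()))
  m[1, 1:50] <- 30L  # 1500
  m[2, 1] <- 800L
  m[3, 5] <- 1000L
  f <- filter_samples(m, 1000)
  expect_equal(rownames(f), c("a", "c"))   # boundary is >=
  expect_equal(attr(f, "removed_samples"), "b")
  expect_equal(rownames(filter_samples(m, 0)), rownames(m))  # identity
  expect_error(filter_samples(m, 1e6), "all samples")
})

test_that("count matrices round-trip through TSV unchanged", {
  sim <- toy_cohort(11, n = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(sim$counts, path)
  back <- read_count_matrix(path)
  expect_equal(back[, ], sim$counts[, ])
  expect_identical(colnames(back), mutation_categories())
})
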