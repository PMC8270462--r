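# Builds the plain-text data shipped under inst/extdata/. All values are
# synthetic constructions (see file names); rerunning this script
# regenerates them bit-for-bit. Run from the package root:
#   Rscript tools/make_fixtures.R

suppressMessages(devtools::load_all(".", quiet = TRUE))

out <- file.path("inst", "extdata")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cats <- mutation_categories()
type_of <- sub(".*\\[(.*)\\].*", "\\1", cats)
f5 <- substr(cats, 1, 1)
f3 <- nchar(cats) |> (\(n) substr(cats, n, n))()

## ---- background presets (synthetic stand-ins) ------------------------
# A dense, clock-like spectrum: every category contributes; C>T and T>C
# dominate, as in germline/SBS5-like spectra; smooth variation over
# flanking bases. Calibrated so the two presets have cosine 0.998 after
# the CpG adjustment, the documented similarity of the published pair.
set.seed(20260918)

type_weight <- c("C>A" = 0.09, "C>G" = 0.08, "C>T" = 0.38,
                 "T>A" = 0.07, "T>C" = 0.28, "T>G" = 0.10)
flank_effect <- function(seed_offset) {
  # mild multiplicative structure over the 16 flank combinations
  e5 <- stats::setNames(exp(stats::rnorm(4, 0, 0.25)), c("A", "C", "G", "T"))
  e3 <- stats::setNames(exp(stats::rnorm(4, 0, 0.25)), c("A", "C", "G", "T"))
  e5[f5] * e3[f3]
}

germline_raw <- type_weight[type_of] * flank_effect() *
  exp(stats::rnorm(96, 0, 0.15))
# CpG>TpG spikes present in any empirical spectrum, removed by cpg_adjust
germline_raw[grepl("\\[C>T\\]G$", cats)] <-
  germline_raw[grepl("\\[C>T\\]G$", cats)] * 6
germline <- cpg_adjust(as.numeric(germline_raw))

# sbs5-like stand-in: same backbone, perturbed until the adjusted pair
# has cosine 0.998 (3-decimal target of the published value)
perturb <- exp(stats::rnorm(96, 0, 1))
make_sbs5 <- function(eps) {
  cpg_adjust(as.numeric(germline_raw *
                          pmax(0, 1 + eps * (perturb - mean(perturb)))))
}
cos_at <- function(eps) cosine_similarity(germline, make_sbs5(eps))
lo <- 0; hi <- 1
while (cos_at(hi) > 0.998) hi <- hi * 2
for (i in 1:60) {
  mid <- (lo + hi) / 2
  if (cos_at(mid) > 0.998) lo <- mid else hi <- mid
}
sbs5 <- make_sbs5((lo + hi) / 2)
stopifnot(round(cosine_similarity(germline, sbs5), 3) == 0.998)

write_background(germline, file.path(out, "background_germline_synthetic.tsv"))
write_background(sbs5, file.path(out, "background_sbs5_synthetic.tsv"))

## ---- synthetic signature catalog -------------------------------------
# 12 profiles: 5 dense (>75% of categories contributing at 1/960) and
# 7 sparse (<50% contributing), patterned on recognizable processes.
catalog <- matrix(0, 0, 96)

dense_profile <- function() {
  w <- stats::rgamma(96, shape = 3) * exp(stats::rnorm(96, 0, 0.3))
  w / sum(w)
}
sparse_profile <- function(active_idx, weights = NULL, floor_n = 8) {
  v <- numeric(96)
  if (is.null(weights)) weights <- stats::rgamma(length(active_idx), 3)
  v[active_idx] <- weights
  # a little mass on a few extra categories so profiles are not degenerate
  extra <- sample(setdiff(seq_len(96), active_idx), floor_n)
  v[extra] <- stats::rgamma(floor_n, 1) * 0.01 * max(v)
  v / sum(v)
}

set.seed(4242)
for (i in 1:5) catalog <- rbind(catalog, dense_profile())

# S1: CpG-deamination-like -- C>T at NCG, spiky
catalog <- rbind(catalog, sparse_profile(which(type_of == "C>T" & f3 == "G"),
                                         weights = c(8, 6, 7, 5)))
# S2: oxidative-damage-like -- C>A dominated
catalog <- rbind(catalog, sparse_profile(which(type_of == "C>A" & f5 %in% c("A", "G", "T"))))
# S3: APOBEC-like -- C>G and C>T at TpC
catalog <- rbind(catalog, sparse_profile(which(type_of %in% c("C>G", "C>T") & f5 == "T")))
# S4: UV-like -- C>T at dipyrimidines
catalog <- rbind(catalog, sparse_profile(which(type_of == "C>T" & f5 %in% c("C", "T") & f3 != "G")))
# S5: T>A heavy
catalog <- rbind(catalog, sparse_profile(which(type_of == "T>A" & f3 %in% c("A", "T"))))
# S6: T>C at ApT-like contexts
catalog <- rbind(catalog, sparse_profile(which(type_of == "T>C" & f5 == "A")))
# S7: T>G spikes at TT
catalog <- rbind(catalog, sparse_profile(which(type_of == "T>G" & f5 == "T"),
                                         floor_n = 12))

rownames(catalog) <- c(paste0("SYN-D", 1:5), paste0("SYN-S", 1:7))
colnames(catalog) <- cats
frac <- rowMeans(catalog > 1 / 960)
stopifnot(all(frac[1:5] > 0.75), all(frac[6:12] < 0.5))
# sim1 trio must be well separated
cm <- tcrossprod(catalog / sqrt(rowSums(catalog^2)))
stopifnot(max(cm[c("SYN-S1", "SYN-S2", "SYN-S3"),
                 c("SYN-S1", "SYN-S2", "SYN-S3")][upper.tri(diag(3))]) < 0.25)
write_signature_matrix(round(catalog, 8), file.path(out, "catalog_synthetic.tsv"))

## ---- toy reference + variant fixtures --------------------------------
set.seed(7)
contig <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                collapse = "")
# an ambiguous base for the skip path
substr(contig, 301, 301) <- "N"
fa_path <- file.path(out, "toy_reference.fa")
writeLines(c(">chr1 synthetic toy contig",
             substring(contig, seq(1, 600, 60), seq(60, 600, 60))), fa_path)
Rsamtools::indexFa(fa_path)

base_at <- function(pos) substr(contig, pos, pos)
other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

# 10 hand-placed SNVs for two samples (positions chosen on ACGT context)
ok_pos <- which(strsplit(contig, "")[[1]] %in% c("A", "C", "G", "T"))
ok_pos <- ok_pos[ok_pos >= 2 & ok_pos <= 599 &
                 ok_pos != 300 & ok_pos != 302 & ok_pos != 301]
pos10 <- ok_pos[seq(10, 100, 10)]
variants <- data.frame(
  sample = rep(c("S1", "S2"), each = 5),
  chrom = "chr1",
  pos = pos10,
  ref = vapply(pos10, base_at, ""),
  stringsAsFactors = FALSE
)
variants$alt <- vapply(variants$ref, other_base, "")
utils::write.table(variants, file.path(out, "toy_variants.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# same records as a 2-sample VCF (rows 1-5 carried by S1, 6-10 by S2)
vcf_lines <- c(
  "##fileformat=VCFv4.2",
  "##contig=<ID=chr1,length=600>",
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
  vapply(seq_len(10), function(i) {
    gt <- if (i <= 5) c("0/1", "0/0") else c("0/0", "0/1")
    paste(c("chr1", variants$pos[i], ".", variants$ref[i], variants$alt[i],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, "")
)
writeLines(vcf_lines, file.path(out, "toy_variants.vcf"))

# and as a MAF
maf <- data.frame(
  Tumor_Sample_Barcode = variants$sample,
  Chromosome = variants$chrom,
  Start_Position = variants$pos,
  Reference_Allele = variants$ref,
  Tumor_Seq_Allele2 = variants$alt
)
utils::write.table(maf, file.path(out, "toy_variants.maf"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("fixtures written to", out, "\n")
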