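#' Write a simulated cohort to disk
#'
#' Writes the sample sheet, phenotype table and genotypes (dosage TSV and
#' a minimal unphased GT-only VCF), plus a JSON sidecar with the
#' generative ground-truth parameters, so a simulated cohort can be
#' consumed by external tools or reloaded later.
#'
#' @param dir output directory (created if absent).
#' @param samples sample sheet data frame.
#' @param phenotypes data frame with an `id` column and trait columns.
#' @param genotypes optional `genotype_matrix`.
#' @param truth optional list of generative parameters for the sidecar.
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(dir, samples, phenotypes, genotypes = NULL,
                         truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  wtsv <- function(d, f) {
    path <- file.path(dir, f)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  wtsv(samples, "samples.tsv")
  wtsv(phenotypes, "phenotypes.tsv")
  if (!is.null(genotypes)) {
    dos <- data.frame(id = rownames(genotypes$dosage), genotypes$dosage,
                      check.names = FALSE)
    wtsv(dos, "dosages.tsv")
    vcf <- file.path(dir, "genotypes.vcf")
    write_minimal_vcf(vcf, genotypes)
    files <- c(files, vcf)
  }
  if (!is.null(truth)) {
    path <- file.path(dir, "truth.json")
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA), path)
    files <- c(files, path)
  }
  invisible(files)
}

#' Write genotypes as a minimal VCF
#'
#' Emits a VCFv4.2 file with placeholder positions and a single GT FORMAT
#' field (diploid, unphased): dosage 0 -> `0/0`, 1 -> `0/1`, 2 -> `1/1`.
#'
#' @param path output file.
#' @param genotypes a `genotype_matrix`.
#' @return invisibly, `path`.
#' @export
write_minimal_vcf <- function(path, genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- genotypes$dosage
  gt <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(dos)), collapse = "\t"))
  body <- vapply(seq_len(ncol(dos)), function(j) {
    paste(c("1", j, colnames(dos)[j], "A", "G", ".", "PASS", ".", "GT",
            gt[dos[, j] + 1L]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotype dosages from a minimal VCF
#'
#' Parses the GT field of a VCF into a dosage matrix (individuals x SNPs,
#' counting ALT alleles) through the \pkg{vcfR} package.
#'
#' @param path VCF file.
#' @return a `genotype_matrix`.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  # apply over variants returns individuals x SNPs
  dos <- apply(gt, 1L, function(g) {
    vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), 0L)
  })
  colnames(dos) <- vcfR::getID(v)
  af <- colMeans(dos) / 2
  structure(list(dosage = dos, snp_ids = colnames(dos),
                 maf = pmin(af, 1 - af), allele_freq = af),
            class = "genotype_matrix")
}

#' Read a dosage matrix TSV
#'
#' Expects an `id` column followed by one integer column per SNP, as
#' written by [write_cohort()].
#'
#' @param path TSV file.
#' @return a `genotype_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  stopifnot("id" %in% names(d))
  dos <- as.matrix(d[, setdiff(names(d), "id"), drop = FALSE])
  rownames(dos) <- d$id
  storage.mode(dos) <- "integer"
  af <- colMeans(dos) / 2
  structure(list(dosage = dos, snp_ids = colnames(dos),
                 maf = pmin(af, 1 - af), allele_freq = af),
            class = "genotype_matrix")
}
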