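# Genotype container and VCF I/O.
#
# Markers are biallelic SNPs, so an unordered genotype is stored as the alt
# allele dosage: 0 (ref/ref), 1 (het), 2 (alt/alt), NA (missing). Full
# genotype matrices are marker x sample.

#' Construct a genotype matrix object
#'
#' @param markers A tibble with columns `chrom`, `pos` (1-based, strictly
#'   increasing), `id`, `ref`, `alt` (single bases).
#' @param dosage Integer matrix, markers x samples, entries 0/1/2/NA (alt
#'   allele dosage), with column names equal to `samples$sample`.
#' @param samples A tibble with columns `sample` and `role` (one of
#'   `carrier_parent`, `other_parent`, `reference_relative`, `embryo`,
#'   `other`).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(markers, dosage, samples) {
  stopifnot(is.data.frame(markers),
            all(c("chrom", "pos", "id", "ref", "alt") %in% names(markers)),
            is.matrix(dosage), nrow(dosage) == nrow(markers),
            is.data.frame(samples), all(c("sample", "role") %in% names(samples)),
            ncol(dosage) == nrow(samples),
            identical(colnames(dosage), samples$sample))
  if (is.unsorted(markers$pos, strictly = TRUE)) {
    abort("marker positions must be strictly increasing")
  }
  structure(list(markers = tibble::as_tibble(markers),
                 dosage = dosage,
                 samples = tibble::as_tibble(samples)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$markers), "markers x", nrow(x$samples), "samples\n")
  cat("roles:", paste(paste0(x$samples$sample, "=", x$samples$role), collapse = ", "), "\n")
  invisible(x)
}

gt_to_dosage <- function(gt) {
  # GT strings like "0/0", "0|1", "./.", "1/." (partial missing -> NA)
  gt <- sub(":.*$", "", gt)
  a <- strsplit(gt, "[/|]")
  vapply(a, function(p) {
    if (length(p) != 2L || any(p == ".")) return(NA_integer_)
    sum(as.integer(p))
  }, integer(1))
}

dosage_to_gt <- function(d) {
  out <- rep("./.", length(d))
  out[!is.na(d) & d == 0L] <- "0/0"
  out[!is.na(d) & d == 1L] <- "0/1"
  out[!is.na(d) & d == 2L] <- "1/1"
  out
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Reads the GT field of a VCF (plain text or bgzipped, via `vcfR`), keeps
#' biallelic SNPs only, and attaches sample roles either from a named `roles`
#' vector or from heuristics on sample names (`embryo*` -> embryo).
#'
#' @param path Path to a VCF file.
#' @param roles Named character vector mapping sample name to role; samples
#'   not named get role `"other"` (or `"embryo"` if their name contains
#'   "embryo").
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, roles = NULL) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(vcf)),
                dimnames = list(NULL, colnames(vcfR::getFIX(vcf))))
  keep <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    fix[, "ALT"] %in% c("A", "C", "G", "T")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  markers <- tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0("snp_", seq_len(nrow(fix))), fix[, "ID"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"]
  )
  ord <- order(markers$pos)
  markers <- markers[ord, ]
  gt <- gt[ord, , drop = FALSE]
  dosage <- apply(gt, 2, gt_to_dosage)
  if (!is.matrix(dosage)) dosage <- matrix(dosage, nrow = nrow(markers),
                                           dimnames = list(NULL, colnames(gt)))
  dimnames(dosage) <- list(NULL, colnames(gt))
  sample_names <- colnames(gt)
  role <- rep("other", length(sample_names))
  role[grepl("embryo", sample_names, ignore.case = TRUE)] <- "embryo"
  if (!is.null(roles)) {
    hit <- match(names(roles), sample_names)
    if (anyNA(hit)) {
      abort(paste0("roles name samples absent from the VCF: ",
                   paste(names(roles)[is.na(hit)], collapse = ", ")))
    }
    role[hit] <- unname(roles)
  }
  genotype_matrix(markers, dosage,
                  tibble::tibble(sample = sample_names, role = role))
}

#' Write a genotype matrix to a plain-text VCF 4.2 file
#'
#' Emits GT-only records; missing genotypes are written `./.`. The file
#' round-trips losslessly through [read_genotypes()].
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param source_tag String recorded in the `##source` header line.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, source_tag = "pgtlink") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##source=", source_tag),
    paste0("##contig=<ID=", unique(gm$markers$chrom), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            gm$samples$sample), collapse = "\t")
  ), con)
  gt_cols <- apply(gm$dosage, 2, dosage_to_gt)
  if (!is.matrix(gt_cols)) gt_cols <- matrix(gt_cols, nrow = nrow(gm$markers))
  body <- cbind(gm$markers$chrom, gm$markers$pos, gm$markers$id,
                gm$markers$ref, gm$markers$alt, ".", "PASS", ".", "GT", gt_cols)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}
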