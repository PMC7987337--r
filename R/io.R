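#' Write a synthetic cohort to disk
#'
#' Writes the variant table as a VCF 4.2 file with INFO keys \code{GENE},
#' \code{CSQ}, \code{NFE_AF}, \code{CADD} and one hemizygous GT column per
#' subject (carriers are \code{1}, everyone else \code{0}), plus the subject
#' phenotype table as TSV. Output is plain text and byte-stable for a fixed
#' generator seed.
#'
#' @param cohort an [generate_cohort()] result.
#' @param dir output directory (created if missing).
#' @return named character vector with the paths written (\code{vcf},
#'   \code{subjects}).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "xburden_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vcf_path <- file.path(dir, "cohort.vcf")
  subj_path <- file.path(dir, "subjects.tsv")
  write_variants_vcf(cohort$variants, cohort$subjects$subject_id, vcf_path)
  write.table(cohort$subjects, subj_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(vcf = vcf_path, subjects = subj_path)
}

write_variants_vcf <- function(variants, subject_ids, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=X>",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    paste0("##INFO=<ID=NFE_AF,Number=1,Type=Float,Description=",
           "\"Non-Finnish European allele frequency\">"),
    "##INFO=<ID=CADD,Number=1,Type=Float,Description=\"CADD phred score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", subject_ids), collapse = "\t"))
  body <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    info <- c(paste0("GENE=", v$gene), paste0("CSQ=", v$consequence))
    if (!is.na(v$nfe_af))
      info <- c(info, paste0("NFE_AF=", format(v$nfe_af, digits = 10,
                                               scientific = TRUE)))
    if (!is.na(v$cadd))
      info <- c(info, paste0("CADD=", format(v$cadd, digits = 8)))
    gt <- ifelse(subject_ids %in% v$carriers[[1]], "1", "0")
    body[i] <- paste(c("X", v$pos, ".", v$ref, v$alt, ".", "PASS",
                       paste(info, collapse = ";"), "GT", gt),
                     collapse = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an annotated VCF into a variant table
#'
#' Parses a VCF 4.2 file (via \pkg{vcfR}) carrying per-variant gene symbol,
#' consequence class, population allele frequency and CADD score in INFO
#' fields, and per-subject genotypes. Records with multiple ALT alleles are
#' decomposed into one row per alternate allele; for allele \code{k}, any
#' genotype containing allele index \code{k} marks the subject as a carrier
#' (hemizygous \code{1} as well as diploid-coded \code{0/1}, \code{1/1},
#' phased or not).
#'
#' @param path VCF file.
#' @param info_keys named character vector mapping the fields \code{gene},
#'   \code{csq}, \code{af}, \code{cadd} to the INFO keys used in the file.
#' @return variant data frame with columns chrom, pos, ref, alt, gene,
#'   consequence, nfe_af, cadd and a \code{carriers} list-column.
#' @export
read_vcf_variants <- function(path,
                              info_keys = c(gene = "GENE", csq = "CSQ",
                                            af = "NFE_AF", cadd = "CADD")) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gene <- vcfR::extract.info(vcf, info_keys[["gene"]])
  csq <- vcfR::extract.info(vcf, info_keys[["csq"]])
  af <- suppressWarnings(
    vcfR::extract.info(vcf, info_keys[["af"]], as.numeric = TRUE))
  cadd <- suppressWarnings(
    vcfR::extract.info(vcf, info_keys[["cadd"]], as.numeric = TRUE))
  gt <- vcfR::extract.gt(vcf)
  if (is.null(gt)) stop("VCF has no genotype columns", call. = FALSE)
  subjects <- colnames(gt)

  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gsub("\\||/", " ", gt[i, ]), " ")
    for (k in seq_along(alts)) {
      carr <- subjects[vapply(alleles, function(a) any(a == as.character(k)),
                              logical(1))]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k],
        gene = gene[i], consequence = csq[i],
        nfe_af = af[i], cadd = cadd[i],
        carriers = I(list(carr)), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a subject phenotype table
#'
#' @param path TSV with columns subject_id, sex, age, clinical_category,
#'   cohort, pcr_confirmed (as written by [write_cohort()]).
#' @return data frame.
#' @export
read_subjects <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a Ct table
#'
#' Long-format qPCR table: subject_id, gene, condition, replicate, ct.
#' @param ct data frame as produced by [generate_qpcr_plate()].
#' @param path TSV path.
#' @return `write_ct` returns the path invisibly; `read_ct` the data frame.
#' @export
write_ct <- function(ct, path) {
  write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct
#' @export
read_ct <- function(path) read.delim(path, stringsAsFactors = FALSE)
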