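#' Write genotypes as a minimal VCF
#'
#' One record per SNP with a GT field; dosage 0/1/2 of the minor (ALT)
#' allele maps to 0/0, 0/1, 1/1 and missing to ./.. Arbitrary REF/ALT
#' nucleotides are used since the simulator tracks alleles abstractly.
#'
#' @param genotypes individuals x SNPs matrix of 0/1/2/NA.
#' @param snp_info data frame with `chrom`, `pos_bp`, `id` per SNP.
#' @param path output file.
#' @export
write_vcf <- function(genotypes, snp_info, path) {
  stopifnot(ncol(genotypes) == nrow(snp_info))
  ids <- rownames(genotypes)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=gshybrid",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  gt <- matrix("./.", nrow = ncol(genotypes), ncol = nrow(genotypes))
  for (v in 0:2) gt[t(genotypes) == v] <- gt_code[[as.character(v)]]
  body <- do.call(paste, c(list(snp_info$chrom, snp_info$pos_bp, snp_info$id,
                                "A", "C", ".", "PASS", ".", "GT"),
                           lapply(seq_len(ncol(gt)), function(j) gt[, j]),
                           sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a dosage matrix
#'
#' Uses vcfR; returns minor-allele (ALT) dosages 0/1/2 with NA for missing,
#' individuals in rows.
#' @param path VCF file.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the vcfR package is required to read VCF")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                 dimnames = list(colnames(gt), rownames(gt)))
  for (code in list(c("0/0", 0L), c("0/1", 1L), c("1/0", 1L), c("1/1", 2L)))
    dose[t(gt) == code[1]] <- as.integer(code[2])
  dose
}

#' Write / read an additive genotype table
#'
#' Individuals x SNPs, entries 0/1/2 with NA for missing, individual ids in
#' the first column.
#' @param genotypes matrix; `path` file path.
#' @export
write_additive_tsv <- function(genotypes, path) {
  dt <- data.table::as.data.table(genotypes, keep.rownames = "id")
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_additive_tsv
#' @export
read_additive_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  storage.mode(m) <- "integer"
  rownames(m) <- dt[[1]]
  m
}

#' Write / read tables of the population (pedigree, phenotypes, SNP info)
#' @param x data frame; `path` file path.
#' @export
write_table_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  tibble::as_tibble(data.table::fread(path, sep = "\t", na.strings = "NA"))
}

#' Write / read a simulation config as key: value text
#' @param config a [sim_config()]; `path` file path.
#' @export
write_sim_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    if (is.null(v)) return("NULL")
    if (!is.null(names(v))) paste(names(v), v, sep = "=", collapse = ",")
    else paste(v, collapse = ",")
  }, character(1))
  writeLines(paste0(names(config), ": ", fmt), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    v <- strsplit(x[2], ",", fixed = TRUE)[[1]]
    if (identical(v, "NULL")) return(NULL)
    if (all(grepl("=", v, fixed = TRUE))) {
      parts <- strsplit(v, "=", fixed = TRUE)
      return(stats::setNames(as.numeric(vapply(parts, `[`, "", 2)),
                             vapply(parts, `[`, "", 1)))
    }
    num <- suppressWarnings(as.numeric(v))
    if (!anyNA(num)) num else if (identical(v, "TRUE") || identical(v, "FALSE"))
      as.logical(v) else v
  })
  names(vals) <- vapply(kv, `[`, character(1), 1)
  do.call(sim_config, vals[!vapply(vals, is.null, logical(1))])
}
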