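#' Read a delimited dosage table
#'
#' Expects a header row of SNP ids with a leading sample-id column; each
#' cell is a dosage in `{0, 1, 2}`, or `NA`/empty for missing.
#'
#' @param path Path to the table.
#' @param delimiter Field delimiter (default tab).
#' @return A [dosage_matrix()] preserving row and column order.
#' @export
read_dosage_table <- function(path, delimiter = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""), colClasses = "character",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("dosage table needs a sample-id column and at least one SNP")
  ids <- tab[[1L]]
  snps <- colnames(tab)[-1L]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(as.numeric(vals))
  bad <- !is.na(vals) & (is.na(num) | !(num %in% 0:2))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow = nrow(vals)), arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid dosage '%s' for sample '%s', SNP '%s'",
                 vals[idx[1L], idx[2L]], ids[idx[1L]], snps[idx[2L]]))
  }
  m <- matrix(as.integer(num), nrow = nrow(vals), ncol = ncol(vals))
  colnames(m) <- snps
  dosage_matrix(m, sample_ids = ids)
}

#' Write a dosage table
#'
#' Inverse of [read_dosage_table()]: tab-delimited with a `sample_id`
#' column, `NA` for missing.
#'
#' @param dm A [dosage_matrix()].
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @export
write_dosage_table <- function(dm, path, delimiter = "\t") {
  stopifnot(is.dosage_matrix(dm))
  out <- data.frame(sample_id = rownames(dm$values), dm$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read dosages from a VCF file
#'
#' Biallelic records only; multi-allelic records are skipped with a
#' warning. In `GT` mode the dosage is the ALT-allele count of the call
#' (`./.` is missing); in `DS` mode the DS value rounded to the nearest
#' integer, which must land in `[0, 2]`.
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @param field `"GT"` (default) or `"DS"`.
#' @return A [dosage_matrix()] with one column per retained record
#'   (ids from the ID column, falling back to `chrom:pos`).
#' @export
read_vcf_dosage <- function(path, field = c("GT", "DS")) {
  field <- match.arg(field)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no records")
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
  }
  keep <- !multi
  if (!any(keep)) stop("no biallelic records in VCF")
  gt <- vcfR::extract.gt(vcf, element = field)
  if (is.null(gt) || ncol(gt) == 0L) stop("VCF contains no sample columns")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (field == "GT") {
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_integer_)
      alleles <- strsplit(g, "[/|]")[[1L]]
      if (any(alleles == ".")) return(NA_integer_)
      sum(alleles == "1")
    })
  } else {
    num <- suppressWarnings(matrix(as.numeric(gt), nrow = nrow(gt),
                                   dimnames = dimnames(gt)))
    if (any(!is.na(num) & (num < 0 | num > 2)))
      stop("DS value outside [0, 2]")
    dos <- round(num)
  }
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  meta <- data.frame(id = ids, chrom = fix[, "CHROM"],
                     pos = suppressWarnings(as.integer(fix[, "POS"])),
                     stringsAsFactors = FALSE)
  dosage_matrix(t(dos), sample_ids = colnames(gt), snp_meta = meta)
}

#' Read phenotype labels and align them to a dosage matrix
#'
#' Two-column table (`sample_id`, `label`), labels in `{0, 1}`. When `dm`
#' is given, rows are re-ordered to the matrix's sample order and any
#' mismatch is an error.
#'
#' @param path Path to the label table.
#' @param dm Optional [dosage_matrix()] giving the sample order.
#' @param delimiter Field delimiter.
#' @return Integer vector of 0/1 labels, named by sample id.
#' @export
read_labels <- function(path, dm = NULL, delimiter = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("label table needs sample_id and label columns")
  lab <- suppressWarnings(as.numeric(tab[[2L]]))
  if (any(is.na(lab)) || !all(lab %in% c(0, 1)))
    stop("labels must be 0 or 1")
  labels <- as.integer(lab)
  names(labels) <- as.character(tab[[1L]])
  if (!is.null(dm)) {
    want <- rownames(dm$values)
    if (!setequal(want, names(labels)) || length(labels) != length(want))
      stop("label sample ids do not match genotype sample ids")
    labels <- labels[want]
  }
  labels
}

check_labels <- function(labels, n = NULL) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0 or 1")
  if (!is.null(n) && length(labels) != n)
    stop("label length does not match number of samples")
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  labels
}
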