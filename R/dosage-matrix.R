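#' Construct a dosage matrix
#'
#' A `dosage_matrix` holds a samples x SNPs table of minor-allele counts
#' (dosages), each entry 0, 1, 2 or `NA`, plus per-SNP metadata. It is the
#' common input container for filtering, interaction testing and
#' classification.
#'
#' @param values Integer matrix (samples x SNPs); entries in `{0, 1, 2}` or
#'   `NA` for missing genotypes.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to existing rownames or `sample1..n`.
#' @param snp_meta Data frame with columns `id`, `chrom`, `pos` (1-based;
#'   `chrom`/`pos` may be `NA`). Defaults to colnames as ids.
#'
#' @return An object of class `dosage_matrix` with elements `values`
#'   (integer matrix with dimnames), and `snp_meta`.
#' @export
dosage_matrix <- function(values, sample_ids = NULL, snp_meta = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("dosage matrix must have at least one sample and one SNP")
  storage.mode(values) <- "integer"
  bad <- !is.na(values) & !(values %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("dosage value not in {0,1,2} at row %d, column %d",
                 idx[1L], idx[2L]))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(values)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values))
    stop("length of sample_ids does not match number of rows")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")
  if (is.null(snp_meta)) {
    ids <- colnames(values)
    if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(values)))
    snp_meta <- data.frame(id = ids, chrom = NA_character_,
                           pos = NA_integer_, stringsAsFactors = FALSE)
  }
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  if (!all(c("id", "chrom", "pos") %in% names(snp_meta))) {
    if (!"id" %in% names(snp_meta)) stop("snp_meta needs an 'id' column")
    if (!"chrom" %in% names(snp_meta)) snp_meta$chrom <- NA_character_
    if (!"pos" %in% names(snp_meta)) snp_meta$pos <- NA_integer_
  }
  snp_meta$id <- as.character(snp_meta$id)
  if (nrow(snp_meta) != ncol(values))
    stop("snp_meta rows do not match number of SNP columns")
  if (anyDuplicated(snp_meta$id))
    stop("duplicate SNP ids")
  dimnames(values) <- list(sample_ids, snp_meta$id)
  structure(list(values = values, snp_meta = snp_meta),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d samples x %d SNPs, %d missing entries\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.dosage_matrix <- function(x) dim(x$values)

#' @rdname dosage_matrix
#' @param x Object to test.
#' @export
is.dosage_matrix <- function(x) inherits(x, "dosage_matrix")

#' Impute missing dosages by the per-SNP mode
#'
#' Replaces `NA` entries with the most frequent observed dosage of the same
#' SNP (ties broken toward the smaller dosage). SNPs with no observed value
#' are imputed to 0.
#'
#' @param dm A [dosage_matrix()].
#' @return A `dosage_matrix` without missing entries.
#' @export
impute_mode <- function(dm) {
  stopifnot(is.dosage_matrix(dm))
  v <- dm$values
  for (j in seq_len(ncol(v))) {
    miss <- is.na(v[, j])
    if (!any(miss)) next
    obs <- v[!miss, j]
    fill <- if (length(obs) == 0L) 0L else {
      tab <- tabulate(obs + 1L, nbins = 3L)
      as.integer(which.max(tab) - 1L)  # which.max takes first maximum
    }
    v[miss, j] <- fill
  }
  dosage_matrix(v, rownames(v), dm$snp_meta)
}

#' Re-polarize SNPs whose coded allele is the major allele
#'
#' Flips dosage `x -> 2 - x` for SNPs whose coded-allele frequency exceeds
#' 0.5 in the data, so that dosage counts minor alleles.
#'
#' @param dm A [dosage_matrix()].
#' @return A list with `dm` (re-polarized matrix) and `flipped` (logical
#'   vector per SNP).
#' @export
polarize_minor <- function(dm) {
  stopifnot(is.dosage_matrix(dm))
  v <- dm$values
  freq <- colMeans(v, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) v[, flip] <- 2L - v[, flip]
  list(dm = dosage_matrix(v, rownames(v), dm$snp_meta), flipped = flip)
}
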