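# The Barcode-ID file drives demultiplexing: two tab-separated columns,
# no header, barcode then genotype ID.

#' Read and validate a Barcode-ID table
#'
#' The table must satisfy the constraints that make one-mismatch barcode
#' assignment unambiguous: 6-10 bp uppercase ACGT barcodes, all distinct,
#' and no two same-length barcodes within Hamming distance 1 of each other.
#'
#' @param path Two-column tab-separated file (barcode, genotype ID), no
#'   header.
#' @return A data.frame with columns `barcode`, `genotype_id`.
#' @export
read_barcode_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", col.names = c("barcode", "genotype_id"),
                          stringsAsFactors = FALSE)
  validate_barcode_table(df)
  df
}

#' @param table A data.frame with columns `barcode`, `genotype_id`.
#' @rdname read_barcode_table
#' @export
validate_barcode_table <- function(table) {
  if (!all(c("barcode", "genotype_id") %in% names(table))) {
    stop("barcode table needs columns 'barcode' and 'genotype_id'", call. = FALSE)
  }
  bc <- table$barcode
  if (!length(bc)) stop("barcode table is empty", call. = FALSE)
  if (any(!grepl("^[ACGT]+$", bc))) {
    stop("barcodes must be uppercase A/C/G/T", call. = FALSE)
  }
  if (any(nchar(bc) < 6 | nchar(bc) > 10)) {
    stop("barcodes must be 6-10 bp", call. = FALSE)
  }
  if (anyDuplicated(bc)) stop("duplicated barcode in table", call. = FALSE)
  if (any(is.na(table$genotype_id)) || any(table$genotype_id == "")) {
    stop("missing genotype ID", call. = FALSE)
  }
  # one genotype ID per barcode, and barcodes must be mutually >1 mismatch
  # apart (same length) or one-mismatch assignment becomes ambiguous
  for (L in unique(nchar(bc))) {
    same <- bc[nchar(bc) == L]
    if (length(same) < 2) next
    m <- do.call(rbind, strsplit(same, ""))
    for (i in seq_len(length(same) - 1)) {
      d <- rowSums(m[-seq_len(i), , drop = FALSE] !=
                     matrix(m[i, ], nrow = length(same) - i, ncol = L, byrow = TRUE))
      if (any(d <= 1)) {
        stop("barcodes '", same[i], "' and '", same[-seq_len(i)][which(d <= 1)[1]],
             "' are within Hamming distance 1; table rejected", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' @rdname read_barcode_table
#' @export
write_barcode_table <- function(table, path) {
  utils::write.table(table[, c("barcode", "genotype_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
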