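# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize sample identifiers
#'
#' Trims whitespace, uppercases, and (by default) truncates TCGA-style
#' barcodes to the participant+sample prefix (first 15 characters,
#' `TCGA-XX-XXXX-NN`) so that tables mixing barcode lengths align.
#'
#' @param ids character vector of sample identifiers.
#' @param truncate_tcga truncate `TCGA-` barcodes to 15 characters.
#' @return normalized character vector.
#' @export
normalize_sample_id <- function(ids, truncate_tcga = TRUE) {
  out <- toupper(trimws(as.character(ids)))
  if (truncate_tcga) {
    is_tcga <- startsWith(out, "TCGA-") & nchar(out) > 15L
    out[is_tcga] <- substr(out[is_tcga], 1L, 15L)
  }
  out
}

#' Normalize miRNA identifiers
#'
#' Lowercases so that `miR-21`/`mir-21` unify; the star suffix `*` is
#' preserved verbatim.
#'
#' @param ids character vector of miRNA identifiers.
#' @return normalized character vector.
#' @export
normalize_mirna_id <- function(ids) {
  tolower(trimws(as.character(ids)))
}

# open a connection for TSV readers; "-" means stdin
.open_input <- function(path) {
  if (identical(path, "-")) return(file("stdin"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  path
}

# read a UTF-8, tab-separated table; "#" comment lines ignored
.read_tsv <- function(path, header = TRUE, colClasses = NA) {
  utils::read.delim(.open_input(path), header = header, sep = "\t",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = colClasses,
                    fileEncoding = "UTF-8", na.strings = c("NA", ""))
}

.write_tsv <- function(x, path, row.names = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = row.names, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

# content hash used for report provenance
.hash_object <- function(x) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f), add = TRUE)
  saveRDS(x, f, compress = FALSE, version = 2)
  unname(tools::md5sum(f))
}
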