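#' Write AIRR-style rearrangement records to TSV
#'
#' Standard AIRR Rearrangement column order first (sequence_id, v_call,
#' j_call, junction, junction_length, sequence_alignment,
#' germline_alignment, c_call, cell_id), custom annotation columns after.
#'
#' @param records data.frame of records.
#' @param path output file.
#' @export
write_airr <- function(records, path) {
  core <- c("sequence_id", "v_call", "j_call", "junction", "junction_length",
            "sequence_alignment", "germline_alignment", "c_call", "cell_id")
  cols <- c(intersect(core, names(records)), setdiff(names(records), core))
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read AIRR-style rearrangement records from TSV
#'
#' @param path TSV file with an AIRR header row.
#' @return data.frame of records.
#' @export
read_airr <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = NA, check.names = FALSE)
}

#' Read an HTO count matrix from CSV (cells in rows, hashtags in columns)
#'
#' @param path CSV with a `cell_id` first column.
#' @return integer matrix with cell ids as rownames.
#' @export
read_hto_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write an HTO count matrix to CSV
#'
#' @param hto cells x hashtags matrix with rownames.
#' @param path output file.
#' @export
write_hto_csv <- function(hto, path) {
  utils::write.csv(data.frame(cell_id = rownames(hto), hto,
                              check.names = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
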