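#' Strip allele suffix from an immunoglobulin gene call
#'
#' `IGHV3-30*01` becomes `IGHV3-30`; multi-allele calls keep only the first
#' listed gene. Distinct genes (e.g. IGHV1-69 vs IGHV1-69D) stay distinct.
#'
#' @param call character vector of gene calls.
#' @return character vector of gene-level names.
#' @export
strip_allele <- function(call) {
  sub("\\*.*$", "", sub(",.*$", "", call))
}

# normalized Hamming distance matrix for equal-length strings
junction_dist <- function(junctions) {
  m <- do.call(rbind, strsplit(junctions, ""))
  n <- nrow(m); L <- ncol(m)
  d <- matrix(0, n, n)
  for (j in seq_len(L)) {
    d <- d + outer(m[, j], m[, j], "!=")
  }
  d / L
}

#' Assign B cells to clones
#'
#' Cells are first partitioned by heavy-chain V gene, J gene (both at
#' allele-stripped gene level) and junction length; within each partition,
#' single-linkage hierarchical clustering on the normalized Hamming
#' distance between junctions is cut at `distance_threshold`. Clone ids
#' are stable under input reordering: records are processed in
#' lexicographic `sequence_id` order and clones numbered by first member.
#'
#' @param records heavy-chain AIRR-style data.frame with `sequence_id`,
#'   `cell_id`, `v_call`, `j_call`, `junction`.
#' @param distance_threshold normalized Hamming cut height (default 0.15).
#' @return A `clone_set`: list with `clones` (data.frame: sequence_id,
#'   cell_id, clone_id, vj_group) and `threshold`.
#' @export
assign_clones <- function(records, distance_threshold = 0.15) {
  need <- c("sequence_id", "cell_id", "v_call", "j_call", "junction")
  stopifnot(all(need %in% names(records)))
  if ("chain" %in% names(records) && any(records$chain != "heavy")) {
    stop("assign_clones: heavy-chain records only", call. = FALSE)
  }
  bad <- is.na(records$v_call) | records$v_call == "" |
    is.na(records$j_call) | records$j_call == "" |
    is.na(records$junction) | records$junction == ""
  if (any(bad)) {
    stop("assign_clones: missing v_call/j_call/junction for: ",
         paste(utils::head(records$sequence_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  rec <- records[order(records$sequence_id), , drop = FALSE]
  vj <- paste(strip_allele(rec$v_call), strip_allele(rec$j_call),
              nchar(rec$junction), sep = "|")
  groups <- split(seq_len(nrow(rec)), vj)
  clone_id <- integer(nrow(rec))
  next_id <- 1L
  for (gname in names(groups)[order(vapply(groups, min, 1L))]) {
    idx <- groups[[gname]]
    if (length(idx) == 1L) {
      clone_id[idx] <- next_id
      next_id <- next_id + 1L
      next
    }
    d <- junction_dist(rec$junction[idx])
    hc <- stats::hclust(stats::as.dist(d), method = "single")
    cl <- stats::cutree(hc, h = distance_threshold)
    # renumber by first (lexicographically earliest) member for stability
    first <- tapply(seq_along(idx), cl, min)
    remap <- rank(first)
    clone_id[idx] <- next_id - 1L + as.integer(remap[as.character(cl)])
    next_id <- next_id + max(remap)
  }
  out <- data.frame(sequence_id = rec$sequence_id, cell_id = rec$cell_id,
                    clone_id = sprintf("clone_%04d", clone_id),
                    vj_group = vj, stringsAsFactors = FALSE)
  structure(list(clones = out, threshold = distance_threshold),
            class = "clone_set")
}

#' Bin clone sizes per subject x timepoint
#'
#' Clones are labelled rare (1 cell), small (2 cells), medium (3-5 cells),
#' large (6-10 cells); anything above 10 cells is reported as "larger".
#' Fractions are cell-weighted and sum to 1 within each grouping.
#'
#' @param clone_set a [assign_clones()] result.
#' @param meta optional data.frame with `cell_id`, `subject`, `timepoint`;
#'   when omitted, a single pooled grouping is used.
#' @return data.frame: subject, timepoint, bin, n_cells, fraction.
#' @export
clone_size_bins <- function(clone_set, meta = NULL) {
  cl <- clone_set$clones
  if (is.null(meta)) {
    cl$subject <- "all"; cl$timepoint <- "all"
  } else {
    m <- meta[match(cl$cell_id, meta$cell_id), , drop = FALSE]
    cl$subject <- m$subject; cl$timepoint <- m$timepoint
  }
  bins <- c("rare", "small", "medium", "large", "larger")
  out <- do.call(rbind, lapply(
    split(cl, paste(cl$subject, cl$timepoint, sep = "\r")),
    function(d) {
      sizes <- table(d$clone_id)
      bin_of <- cut(as.integer(sizes), c(0, 1, 2, 5, 10, Inf), labels = bins)
      ncell <- tapply(as.integer(sizes), bin_of, sum, default = 0L)
      data.frame(subject = d$subject[1], timepoint = d$timepoint[1],
                 bin = factor(bins, levels = bins),
                 n_cells = as.integer(ncell),
                 fraction = as.integer(ncell) / nrow(d),
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}
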