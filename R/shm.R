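# standard genetic code, codon order T/C/A/G with first base slowest
.gc_aa <- strsplit(paste0(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
  "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
.gc_bases <- c("T", "C", "A", "G")
.gc_codons <- as.vector(t(outer(
  as.vector(t(outer(.gc_bases, .gc_bases, paste0))), .gc_bases, paste0)))
GENETIC_CODE_STD <- stats::setNames(.gc_aa, .gc_codons)

translate_codon <- function(codon) {
  aa <- GENETIC_CODE_STD[codon]
  ifelse(is.na(aa), NA_character_, aa)
}

#' Somatic hypermutation profile of one aligned sequence pair
#'
#' Compares an observed sequence alignment to its germline over all
#' positions where both carry an unambiguous A/C/G/T base (the
#' denominator). Every difference at such a position is one point
#' mutation, attributed to the region containing it, and classified as
#' Replacement or Silent by translating the observed codon with the
#' germline bases as context at the other two codon positions (frame taken
#' from the alignment start). A codon whose germline context cannot be
#' translated is classified Silent by convention, so that R + S always
#' equals the total mismatch count. SHM frequency is total mutations over
#' the denominator; light chains are profiled identically.
#'
#' @param sequence_alignment,germline_alignment equal-length aligned
#'   nucleotide strings (IUPAC; gaps `.`/`-` allowed).
#' @param region_layout data.frame of 0-based half-open region intervals
#'   tiling the alignment; see [default_region_layout()].
#' @param context `"germline"` (default, order-independent) or
#'   `"observed"`: which sequence supplies the other two codon positions
#'   when classifying R vs S.
#' @return list of class `mutation_profile`: `counts` (data.frame region,
#'   r, s), `total`, `denominator`, `frequency`.
#' @export
mutation_profile <- function(sequence_alignment, germline_alignment,
                             region_layout = default_region_layout(),
                             context = c("germline", "observed")) {
  context <- match.arg(context)
  obs <- strsplit(toupper(sequence_alignment), "")[[1]]
  germ <- strsplit(toupper(germline_alignment), "")[[1]]
  if (length(obs) != length(germ)) {
    stop("mutation_profile: alignment length mismatch (", length(obs),
         " vs ", length(germ), ")", call. = FALSE)
  }
  L <- length(obs)
  layout <- validate_region_layout(region_layout, L)
  comparable <- obs %in% BASES & germ %in% BASES
  denom <- sum(comparable)
  if (denom == 0L) stop("mutation_profile: zero comparable positions", call. = FALSE)
  mism <- which(comparable & obs != germ)
  regions <- layout$region
  r_cnt <- s_cnt <- stats::setNames(integer(length(regions)), regions)
  ctx <- if (context == "germline") germ else obs
  for (pos in mism) {
    reg <- regions[findInterval(pos - 1L, layout$start)]
    c0 <- ((pos - 1L) %/% 3L) * 3L + 1L
    if (c0 + 2L <= L) {
      g_codon <- ctx[c0:(c0 + 2L)]
      o_codon <- g_codon
      g_codon[pos - c0 + 1L] <- germ[pos]
      o_codon[pos - c0 + 1L] <- obs[pos]
      aa_g <- translate_codon(paste(g_codon, collapse = ""))
      aa_o <- translate_codon(paste(o_codon, collapse = ""))
      repl <- !is.na(aa_g) && !is.na(aa_o) && aa_g != aa_o
    } else {
      repl <- FALSE
    }
    if (repl) r_cnt[reg] <- r_cnt[reg] + 1L else s_cnt[reg] <- s_cnt[reg] + 1L
  }
  structure(list(
    counts = data.frame(region = regions, r = as.integer(r_cnt),
                        s = as.integer(s_cnt), stringsAsFactors = FALSE),
    total = length(mism), denominator = denom,
    frequency = length(mism) / denom
  ), class = "mutation_profile")
}

#' Per-record SHM summary table for a repertoire
#'
#' Applies [mutation_profile()] to every record and returns one row per
#' record with total/region-wise counts and the SHM frequency, carrying
#' through the cell annotations needed by downstream group comparisons.
#'
#' @param records AIRR-style data.frame with `sequence_alignment`,
#'   `germline_alignment` and annotation columns.
#' @param region_layout region intervals tiling the alignments.
#' @param context see [mutation_profile()].
#' @return data.frame with one row per record: annotations, `mu_total`,
#'   `mu_denominator`, `mu_freq`, and `r_<region>`/`s_<region>` columns.
#' @export
shm_profiles <- function(records, region_layout = default_region_layout(),
                         context = "germline") {
  keep <- intersect(c("sequence_id", "cell_id", "subject", "group",
                      "timepoint", "subset", "chain", "c_call"),
                    names(records))
  profs <- lapply(seq_len(nrow(records)), function(i) {
    mutation_profile(records$sequence_alignment[i],
                     records$germline_alignment[i],
                     region_layout, context = context)
  })
  regions <- profs[[1]]$counts$region
  rs <- do.call(rbind, lapply(profs, function(p) {
    stats::setNames(c(p$counts$r, p$counts$s),
                    c(paste0("r_", regions), paste0("s_", regions)))
  }))
  out <- cbind(
    records[, keep, drop = FALSE],
    mu_total = vapply(profs, `[[`, 0, "total"),
    mu_denominator = vapply(profs, `[[`, 0, "denominator"),
    mu_freq = vapply(profs, `[[`, 0, "frequency"),
    as.data.frame(rs)
  )
  rownames(out) <- NULL
  out
}
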