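#' Packaged synthetic germline sequences and region layout
#'
#' A fixed, stop-codon-free 300-nt heavy-chain germline and a light-chain
#' counterpart, with an IMGT-like layout of six contiguous regions
#' (FWR1, CDR1, FWR2, CDR2, FWR3, CDR3) in 0-based half-open nucleotide
#' coordinates. These are synthetic stand-ins: retrieval of the real IMGT
#' reference is out of scope, and all region boundaries fall on codon
#' boundaries so replacement/silent calls are well defined end to end.
#'
#' @param chain `"heavy"` or `"light"`.
#' @return A single 300-character ACGT string.
#' @export
#' @examples
#' nchar(synthetic_germline("heavy"))
synthetic_germline <- function(chain = c("heavy", "light")) {
  chain <- match.arg(chain)
  if (chain == "heavy") {
    paste0(
      "AGGTTTCCGGCTGCGCACAATCACGGTTCTATGTCAGCGCCGGTCATCGAATTTAAAGCT",
      "GTCTCCTCAAAAGTAGCCCTGAGTATTAACCCAGATCTGTCACCGGGTGCTAAAGCGCTT",
      "GAAGGGCTGGCTAGGCTGAGGCCGAGACCATCATTGCACAGTTCAAGCCTAATGCCTCAA",
      "GCGAGTGGACTCAATACTTCCTCTGCCCTTTGGGCAGGTGTAGATGCAGCTCAGATGTTC",
      "CCTTTTGTAGAGTCCGATCGAAGACCCCTACTGCTGACTCGAGCGGCGGTGGATGGTGCC"
    )
  } else {
    paste0(
      "CCTATACCCACTGTGGGTTCTATAGAGCCATCGATGGCGCGATGCAATGGAACTCTAATC",
      "AGCTCCTACGTGGTCATATCCATTAATGAACAGCTCAGAGCGGCATGCGCCTTAACAGTT",
      "CCAGGCATAGAACAACGGAATCCATTCGGGGATGTGGCGACAAATACTACACCAACCTCC",
      "CACTGGGATCGAGGAGAACTGTACAAAACCCAAAGATTAAGGGCTTCTGATCAGAAGCCA",
      "AGGGATCTATGGAGGTGGGTCGCTGACGTGTCAGTTACCCGTAGAAGCAGAGGCTTTGCT"
    )
  }
}

#' Default region layout for the packaged 300-nt germline
#'
#' Six contiguous, non-overlapping intervals tiling positions 0..300
#' (0-based, half-open), all starting and ending on codon boundaries.
#'
#' @return A data.frame with columns `region`, `start`, `end`.
#' @export
default_region_layout <- function() {
  data.frame(
    region = c("FWR1", "CDR1", "FWR2", "CDR2", "FWR3", "CDR3"),
    start  = c(0L, 78L, 102L, 153L, 177L, 264L),
    end    = c(78L, 102L, 153L, 177L, 264L, 300L),
    stringsAsFactors = FALSE
  )
}

#' Validate a region layout against an alignment length
#'
#' @param layout data.frame with `region`, `start`, `end` (0-based half-open).
#' @param aln_len alignment length the layout must tile exactly.
#' @return The layout, invisibly, ordered by `start`.
#' @keywords internal
validate_region_layout <- function(layout, aln_len) {
  stopifnot(is.data.frame(layout), all(c("region", "start", "end") %in% names(layout)))
  layout <- layout[order(layout$start), , drop = FALSE]
  if (layout$start[1] != 0L || layout$end[nrow(layout)] != aln_len ||
      any(layout$start[-1] != layout$end[-nrow(layout)]) ||
      any(layout$end <= layout$start)) {
    stop("region layout must tile [0, ", aln_len,
         ") with contiguous, non-overlapping intervals", call. = FALSE)
  }
  invisible(layout)
}

#' Default synthetic V/J gene-usage table
#'
#' Frequencies loosely shaped like a human repertoire spectrum; used by the
#' cohort generator to draw V and J calls per clone. Heavy, kappa and lambda
#' V genes plus heavy J genes, with allele suffixes attached at draw time.
#'
#' @return data.frame with columns `gene`, `chain` ("heavy"/"light"),
#'   `segment` ("V"/"J"), `frequency` (sums to 1 within chain x segment).
#' @export
default_vj_usage <- function() {
  vh <- c("IGHV1-69" = 0.14, "IGHV1-69D" = 0.03, "IGHV3-30" = 0.16,
          "IGHV3-23" = 0.18, "IGHV4-34" = 0.10, "IGHV1-2" = 0.12,
          "IGHV3-53" = 0.09, "IGHV5-51" = 0.08, "IGHV4-59" = 0.06,
          "IGHV2-5" = 0.04)
  jh <- c("IGHJ4" = 0.45, "IGHJ6" = 0.25, "IGHJ3" = 0.15, "IGHJ5" = 0.10,
          "IGHJ2" = 0.05)
  vl <- c("IGKV3-20" = 0.22, "IGKV1-39" = 0.20, "IGKV1-5" = 0.12,
          "IGKV3-11" = 0.10, "IGLV2-14" = 0.14, "IGLV1-51" = 0.12,
          "IGLV3-21" = 0.10)
  jl <- c("IGKJ1" = 0.35, "IGKJ2" = 0.25, "IGLJ2" = 0.22, "IGLJ3" = 0.18)
  rbind(
    data.frame(gene = names(vh), chain = "heavy", segment = "V",
               frequency = unname(vh)),
    data.frame(gene = names(jh), chain = "heavy", segment = "J",
               frequency = unname(jh)),
    data.frame(gene = names(vl), chain = "light", segment = "V",
               frequency = unname(vl)),
    data.frame(gene = names(jl), chain = "light", segment = "J",
               frequency = unname(jl))
  )
}
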