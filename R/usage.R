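#' V-gene usage per group compared with a reference spectrum
#'
#' Gene calls are reduced to gene level (allele suffix stripped; distinct
#' genes such as IGHV1-69 and IGHV1-69D stay distinct). Frequencies are
#' computed per group and per chain, joined against a reference frequency
#' table (e.g. a public antibody-database spectrum), and rows are kept
#' only for genes reaching `min_freq` in at least one of the compared
#' groups (reference included). A paired heavy/light usage table is
#' returned alongside.
#'
#' @param records AIRR-style data.frame with `v_call`, `chain`, `group`,
#'   `cell_id`.
#' @param reference data.frame with `gene` and `frequency` (per chain if a
#'   `chain` column is present); may be NULL to skip the comparison.
#' @param min_freq inclusion threshold (default 0.03, i.e. 3%).
#' @return list: `usage` (gene, chain, group, frequency), `pairs`
#'   (heavy_v, light_v, n).
#' @export
gene_usage <- function(records, reference = NULL, min_freq = 0.03) {
  stopifnot(all(c("v_call", "chain", "group") %in% names(records)))
  if (!nrow(records)) stop("gene_usage: empty input", call. = FALSE)
  rec <- data.frame(gene = strip_allele(records$v_call),
                    chain = records$chain, group = records$group,
                    cell_id = records$cell_id, stringsAsFactors = FALSE)
  tab <- do.call(rbind, lapply(split(rec, list(rec$group, rec$chain), drop = TRUE),
    function(d) {
      f <- table(d$gene) / nrow(d)
      data.frame(gene = names(f), chain = d$chain[1], group = d$group[1],
                 frequency = as.numeric(f), stringsAsFactors = FALSE)
    }))
  if (!is.null(reference)) {
    ref <- data.frame(gene = strip_allele(reference$gene),
                      chain = if ("chain" %in% names(reference)) reference$chain
                              else ifelse(startsWith(reference$gene, "IGH"),
                                          "heavy", "light"),
                      group = "reference", frequency = reference$frequency,
                      stringsAsFactors = FALSE)
    tab <- rbind(tab, ref)
  }
  keep_genes <- unique(tab$gene[tab$frequency >= min_freq])
  tab <- tab[tab$gene %in% keep_genes, , drop = FALSE]
  tab <- tab[order(tab$chain, tab$gene, tab$group), , drop = FALSE]
  rownames(tab) <- NULL
  hv <- rec[rec$chain == "heavy", ]
  lv <- rec[rec$chain == "light", ]
  pairs <- merge(hv[, c("cell_id", "gene")], lv[, c("cell_id", "gene")],
                 by = "cell_id", suffixes = c("_heavy", "_light"))
  if (nrow(pairs)) {
    ptab <- as.data.frame(table(heavy_v = pairs$gene_heavy,
                                light_v = pairs$gene_light),
                          stringsAsFactors = FALSE)
    names(ptab)[3] <- "n"
    ptab <- ptab[ptab$n > 0, , drop = FALSE]
    rownames(ptab) <- NULL
  } else {
    ptab <- data.frame(heavy_v = character(0), light_v = character(0),
                       n = integer(0))
  }
  list(usage = tab, pairs = ptab)
}

KNOWN_ISOTYPES <- c("IGHM", "IGHD", "IGHG1", "IGHG2", "IGHG3", "IGHG4",
                    "IGHA1", "IGHA2", "IGHE")
SWITCHED_ISOTYPES <- c("IGHG1", "IGHG2", "IGHG3", "IGHG4", "IGHA1")

#' Isotype composition per grouping
#'
#' Fractions of heavy-chain cells expressing each isotype within each
#' grouping, plus the class-switched aggregate (IGHG1-4 + IGHA1).
#' Unrecognized isotype labels are pooled under "other" with a warning.
#' Grouping cells with no records are absent from the output (missing, not
#' zero).
#'
#' @param records AIRR-style data.frame with `c_call` and grouping columns;
#'   light chains (IGKC/IGLC) are ignored if present.
#' @param group_by character vector of grouping column names.
#' @return list: `fractions` (grouping cols, isotype, n, fraction),
#'   `switched` (grouping cols, switched_fraction).
#' @export
isotype_fractions <- function(records, group_by = "group") {
  stopifnot("c_call" %in% names(records), all(group_by %in% names(records)))
  rec <- records
  if ("chain" %in% names(rec)) rec <- rec[rec$chain == "heavy", , drop = FALSE]
  if (!nrow(rec)) stop("isotype_fractions: no heavy-chain records", call. = FALSE)
  iso <- rec$c_call
  unknown <- !(iso %in% KNOWN_ISOTYPES)
  if (any(unknown)) {
    warning("isotype_fractions: ", sum(unknown),
            " records with unknown isotype counted as 'other'")
    iso[unknown] <- "other"
  }
  rec$.iso <- iso
  key <- interaction(rec[group_by], drop = TRUE, sep = "\r")
  frac <- do.call(rbind, lapply(split(rec, key), function(d) {
    f <- table(d$.iso) / nrow(d)
    df <- d[rep(1L, length(f)), group_by, drop = FALSE]
    rownames(df) <- NULL
    cbind(df, data.frame(isotype = names(f), n = as.integer(table(d$.iso)),
                         fraction = as.numeric(f), stringsAsFactors = FALSE))
  }))
  sw <- do.call(rbind, lapply(split(rec, key), function(d) {
    cbind(d[1, group_by, drop = FALSE],
          data.frame(switched_fraction = mean(d$.iso %in% SWITCHED_ISOTYPES)))
  }))
  rownames(frac) <- rownames(sw) <- NULL
  list(fractions = frac, switched = sw)
}
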