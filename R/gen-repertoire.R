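BASES <- c("A", "C", "G", "T")

# substitute each position independently with prob `rate`, never to itself
mutate_chars <- function(chars, rate) {
  if (rate <= 0) return(list(seq = chars, n_mut = 0L))
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    idx <- match(chars[hit], BASES)
    off <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- BASES[((idx - 1L + off) %% 4L) + 1L]
  }
  list(seq = chars, n_mut = length(hit))
}

# truncated discrete power law P(s) proportional to s^(-alpha), s = 1..s_max
sample_clone_sizes <- function(n_cells, alpha, s_max = 10L) {
  s <- seq_len(s_max)
  p <- s^(-alpha); p <- p / sum(p)
  sizes <- integer(0)
  while (sum(sizes) < n_cells) {
    sizes <- c(sizes, sample(s, size = max(8L, ceiling(n_cells / 2)),
                             replace = TRUE, prob = p))
  }
  cum <- cumsum(sizes)
  k <- which(cum >= n_cells)[1]
  sizes <- sizes[seq_len(k)]
  sizes[k] <- sizes[k] - (cum[k] - n_cells)
  sizes[sizes > 0L]
}

sample_gene <- function(usage, chain_, segment_, n = 1L) {
  u <- usage[usage$chain == chain_ & usage$segment == segment_, ]
  sample(u$gene, n, replace = TRUE, prob = u$frequency)
}

#' Generate a synthetic BCR repertoire with known ground truth
#'
#' For every subject x timepoint, simulates `cells_per_subject` memory B
#' cells. Cells are organised into clones (sizes from a discrete power law
#' truncated at 10); each clone carries its own V/J call and a diverged
#' CDR3 (junction), and each cell's observed sequence is the clone germline
#' with i.i.d. per-position substitutions at the group/subset SHM rate.
#' One heavy and one light chain are emitted per cell; indels are not
#' simulated. Ground-truth clone id and mutation counts are retained.
#'
#' @param cohort a [cohort_config()].
#' @param rep a [repertoire_config()].
#' @return data.frame of AIRR-style records (two rows per cell), columns:
#'   `sequence_id`, `cell_id`, `subject`, `group`, `timepoint`, `subset`,
#'   `chain`, `v_call`, `j_call`, `junction`, `junction_length`,
#'   `sequence_alignment`, `germline_alignment`, `c_call`,
#'   `true_clone_id`, `true_mut_count`.
#' @export
gen_repertoire <- function(cohort, rep) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(rep, "repertoire_config"))
  set.seed(cohort$seed)
  subsets <- rep$subsets
  shm <- expand_group_subset(rep$shm_rate, cohort$groups, subsets, "shm_rate")
  layout <- validate_region_layout(rep$region_layout, rep$germline_length)
  cdr3 <- layout[layout$region == "CDR3", ]
  gl_h <- strsplit(synthetic_germline("heavy"), "")[[1]][seq_len(rep$germline_length)]
  gl_l <- strsplit(synthetic_germline("light"), "")[[1]][seq_len(rep$germline_length)]
  jpos <- seq.int(cdr3$start + 1L, cdr3$end)

  out <- vector("list", 0L)
  for (g in cohort$groups) {
    for (s in seq_len(cohort$subjects_per_group[[g]])) {
      subj <- sprintf("%s_S%d", gsub("[^A-Za-z0-9]", "", g), s)
      for (tp in cohort$timepoints) {
        n <- rep$cells_per_subject
        sizes <- sample_clone_sizes(n, rep$clone_size_exponent)
        clone_of <- rep.int(seq_along(sizes), sizes)
        vh <- sample_gene(rep$vj_usage, "heavy", "V", length(sizes))
        jh <- sample_gene(rep$vj_usage, "heavy", "J", length(sizes))
        vl <- sample_gene(rep$vj_usage, "light", "V", length(sizes))
        jl <- sample_gene(rep$vj_usage, "light", "J", length(sizes))
        # clone-private CDR3s: heavy divergence keeps clones separable under
        # junction clustering at conventional thresholds
        cl_gl_h <- lapply(seq_along(sizes), function(i) {
          x <- gl_h; x[jpos] <- mutate_chars(gl_h[jpos], 0.30)$seq; x
        })
        cl_gl_l <- lapply(seq_along(sizes), function(i) {
          x <- gl_l; x[jpos] <- mutate_chars(gl_l[jpos], 0.30)$seq; x
        })
        cell_subset <- sample(subsets, n, replace = TRUE,
                              prob = rep$subset_props[g, ])
        iso <- vapply(cell_subset, function(ss) {
          sample(rep$isotypes, 1L, prob = rep$isotype_probs[ss, ])
        }, character(1))
        seq_h <- seq_l <- character(n)
        mut_h <- mut_l <- integer(n)
        for (i in seq_len(n)) {
          rate <- shm[g, cell_subset[i]]
          mh <- mutate_chars(cl_gl_h[[clone_of[i]]], rate)
          ml <- mutate_chars(cl_gl_l[[clone_of[i]]], rate)
          seq_h[i] <- paste(mh$seq, collapse = "")
          seq_l[i] <- paste(ml$seq, collapse = "")
          mut_h[i] <- mh$n_mut; mut_l[i] <- ml$n_mut
        }
        tp_tag <- gsub("[^A-Za-z0-9]", "", tp)
        cell <- sprintf("%s_%s_cell%03d", subj, tp_tag, seq_len(n))
        cid <- sprintf("%s_%s_clone%02d", subj, tp_tag, clone_of)
        gl_h_str <- vapply(cl_gl_h, paste, "", collapse = "")
        gl_l_str <- vapply(cl_gl_l, paste, "", collapse = "")
        lc <- ifelse(startsWith(vl, "IGK"), "IGKC", "IGLC")
        jspan <- function(s) substr(s, cdr3$start + 1L, cdr3$end)
        out[[length(out) + 1L]] <- data.frame(
          sequence_id = c(paste0(cell, "_H"), paste0(cell, "_L")),
          cell_id = c(cell, cell),
          subject = subj, group = g, timepoint = tp,
          subset = c(cell_subset, cell_subset),
          chain = rep(c("heavy", "light"), each = n),
          v_call = paste0(c(vh[clone_of], vl[clone_of]), "*01"),
          j_call = paste0(c(jh[clone_of], jl[clone_of]), "*01"),
          junction = jspan(c(seq_h, seq_l)),
          junction_length = length(jpos),
          sequence_alignment = c(seq_h, seq_l),
          germline_alignment = c(gl_h_str[clone_of], gl_l_str[clone_of]),
          c_call = c(iso, lc[clone_of]),
          true_clone_id = c(cid, cid),
          true_mut_count = c(mut_h, mut_l),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (rep$multiplet_frac > 0) {
    hv <- which(res$chain == "heavy")
    extra <- hv[stats::runif(length(hv)) < rep$multiplet_frac]
    if (length(extra)) {
      dup <- res[extra, , drop = FALSE]
      dup$sequence_id <- paste0(dup$sequence_id, "2")
      # second heavy chain: shuffle junctions so it is a genuinely distinct contig
      dup$junction <- dup$junction[c(seq_len(nrow(dup))[-1], 1L)]
      res <- rbind(res, dup)
      rownames(res) <- NULL
    }
  }
  res
}

#' Drop cells lacking a heavy chain or carrying multiple heavy chains
#'
#' Mirrors the standard contig-level exclusion applied before clonal
#' analysis. Light-chain-only cells and cells with more than one heavy
#' chain are removed entirely.
#'
#' @param records AIRR-style data.frame as from [gen_repertoire()].
#' @return Filtered records with an attribute `excluded_cells` listing the
#'   removed cell ids and the rule that removed them.
#' @export
filter_contigs <- function(records) {
  nh <- tapply(records$chain == "heavy", records$cell_id, sum)
  bad_multi <- names(nh)[nh > 1L]
  bad_none <- names(nh)[nh == 0L]
  keep <- !(records$cell_id %in% c(bad_multi, bad_none))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_cells") <- data.frame(
    cell_id = c(bad_multi, bad_none),
    reason = rep(c("multiple_heavy", "missing_heavy"),
                 c(length(bad_multi), length(bad_none))),
    stringsAsFactors = FALSE
  )
  out
}
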