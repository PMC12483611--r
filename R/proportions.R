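# per-cluster proportions with pseudo-proportion substitution for zeros
cluster_props <- function(counts, n, pseudo) {
  p <- counts / n
  zero <- counts == 0L
  p[zero] <- pseudo
  list(p = p, zero = zero)
}

#' Permutation test for cluster-proportion differences between two groups
#'
#' For each cluster c the observed statistic is
#' log2FD(c) = log2( prop_b(c) / prop_a(c) ) on pooled-cell proportions.
#' The null is built by pooling the two groups' cells and permuting group
#' labels (group sizes preserved); the p-value uses the add-one correction
#' p = (1 + #\{|log2FD_perm| >= |log2FD_obs|\}) / (1 + n_perm). Confidence
#' intervals come from bootstrap resampling cells within each group.
#' P-values are Benjamini-Hochberg adjusted across clusters and a cluster
#' is called significant iff FDR < `fdr_max` and |log2FD| > `lfd_min`.
#' Clusters absent from one group get a pseudo-proportion of
#' 1/(2 * n_group) and are flagged.
#'
#' @param cells data.frame with `cluster` and `group` columns (one row per
#'   cell).
#' @param group_a,group_b group labels to compare (fold difference is
#'   b over a).
#' @param n_perm permutations (default 1000).
#' @param n_boot bootstrap replicates for the CI (default 1000; 0 skips).
#' @param seed integer seed.
#' @param fdr_max,lfd_min the dual significance rule (defaults 0.05, 0.58).
#' @param conf CI level.
#' @param weight_by_subject when TRUE, proportions are averaged over
#'   per-subject proportions ("normalized to each individual"; requires a
#'   `subject` column) and both the permutation and the bootstrap operate
#'   at the subject level. Default FALSE: pooled-cell proportions, cell
#'   labels exchanged.
#' @return data.frame of class `proportion_test`: per cluster the observed
#'   proportions, `log2fd`, `ci_low`/`ci_high`, `p_value`, `fdr`,
#'   `significant`, `zero_substituted`.
#' @export
proportion_test <- function(cells, group_a, group_b, n_perm = 1000L,
                            n_boot = 1000L, seed = 1L,
                            fdr_max = 0.05, lfd_min = 0.58, conf = 0.95,
                            weight_by_subject = FALSE) {
  stopifnot(all(c("cluster", "group") %in% names(cells)))
  if (weight_by_subject) {
    return(proportion_test_subject(cells, group_a, group_b, n_perm, n_boot,
                                   seed, fdr_max, lfd_min, conf))
  }
  a_idx <- cells$group == group_a
  b_idx <- cells$group == group_b
  n_a <- sum(a_idx); n_b <- sum(b_idx)
  if (n_a == 0L || n_b == 0L) {
    stop("proportion_test: both groups must be non-empty", call. = FALSE)
  }
  if (anyNA(cells$cluster)) stop("proportion_test: missing cluster labels", call. = FALSE)
  cl <- factor(cells$cluster[a_idx | b_idx])
  grp_b <- b_idx[a_idx | b_idx]
  K <- nlevels(cl)
  cl_int <- as.integer(cl)
  obs_a <- tabulate(cl_int[!grp_b], K)
  obs_b <- tabulate(cl_int[grp_b], K)
  pa <- cluster_props(obs_a, n_a, 1 / (2 * n_a))
  pb <- cluster_props(obs_b, n_b, 1 / (2 * n_b))
  obs <- log2(pb$p / pa$p)

  set.seed(seed)
  N <- n_a + n_b
  exceed <- integer(K)
  for (i in seq_len(n_perm)) {
    pb_i <- sample.int(N, n_b)
    cb <- tabulate(cl_int[pb_i], K)
    ca <- tabulate(cl_int, K) - cb
    lfd <- log2(cluster_props(cb, n_b, 1 / (2 * n_b))$p /
                  cluster_props(ca, n_a, 1 / (2 * n_a))$p)
    exceed <- exceed + (abs(lfd) >= abs(obs))
  }
  p_val <- (1 + exceed) / (1 + n_perm)

  lo <- hi <- rep(NA_real_, K)
  if (n_boot > 0L) {
    ia <- cl_int[!grp_b]; ib <- cl_int[grp_b]
    boot <- matrix(NA_real_, n_boot, K)
    for (b in seq_len(n_boot)) {
      ca <- tabulate(ia[sample.int(n_a, n_a, TRUE)], K)
      cb <- tabulate(ib[sample.int(n_b, n_b, TRUE)], K)
      boot[b, ] <- log2(cluster_props(cb, n_b, 1 / (2 * n_b))$p /
                          cluster_props(ca, n_a, 1 / (2 * n_a))$p)
    }
    alpha <- (1 - conf) / 2
    lo <- apply(boot, 2L, stats::quantile, probs = alpha)
    hi <- apply(boot, 2L, stats::quantile, probs = 1 - alpha)
  }
  fdr <- stats::p.adjust(p_val, method = "BH")
  out <- data.frame(
    cluster = levels(cl),
    n_a = obs_a, n_b = obs_b,
    prop_a = pa$p, prop_b = pb$p,
    log2fd = obs, ci_low = lo, ci_high = hi,
    p_value = p_val, fdr = fdr,
    significant = fdr < fdr_max & abs(obs) > lfd_min,
    zero_substituted = pa$zero | pb$zero,
    stringsAsFactors = FALSE
  )
  class(out) <- c("proportion_test", class(out))
  out
}

# subject-weighted variant: the exchangeable unit is the subject; observed
# group proportions are means of per-subject cluster proportions
proportion_test_subject <- function(cells, group_a, group_b, n_perm, n_boot,
                                    seed, fdr_max, lfd_min, conf) {
  stopifnot("subject" %in% names(cells))
  keep <- cells$group %in% c(group_a, group_b)
  cells <- cells[keep, , drop = FALSE]
  cl <- factor(cells$cluster)
  K <- nlevels(cl)
  subj <- unique(cells[, c("subject", "group")])
  if (anyDuplicated(subj$subject)) {
    stop("proportion_test: a subject appears in both groups", call. = FALSE)
  }
  n_sa <- sum(subj$group == group_a); n_sb <- sum(subj$group == group_b)
  if (n_sa == 0L || n_sb == 0L) {
    stop("proportion_test: both groups must be non-empty", call. = FALSE)
  }
  # per-subject cluster proportion matrix (subjects x clusters)
  P <- do.call(rbind, lapply(split(as.integer(cl), cells$subject), function(x) {
    tabulate(x, K) / length(x)
  }))
  P <- P[subj$subject, , drop = FALSE]
  pseudo_a <- 1 / (2 * n_sa); pseudo_b <- 1 / (2 * n_sb)
  stat <- function(in_b) {
    pa <- colMeans(P[!in_b, , drop = FALSE])
    pb <- colMeans(P[in_b, , drop = FALSE])
    za <- pa == 0; zb <- pb == 0
    pa[za] <- pseudo_a; pb[zb] <- pseudo_b
    list(lfd = log2(pb / pa), zero = za | zb, pa = pa, pb = pb)
  }
  in_b <- subj$group == group_b
  obs <- stat(in_b)
  set.seed(seed)
  exceed <- integer(K)
  for (i in seq_len(n_perm)) {
    perm <- logical(nrow(subj))
    perm[sample.int(nrow(subj), n_sb)] <- TRUE
    exceed <- exceed + (abs(stat(perm)$lfd) >= abs(obs$lfd))
  }
  p_val <- (1 + exceed) / (1 + n_perm)
  lo <- hi <- rep(NA_real_, K)
  if (n_boot > 0L) {
    ia <- which(!in_b); ib <- which(in_b)
    boot <- matrix(NA_real_, n_boot, K)
    for (b in seq_len(n_boot)) {
      pa <- colMeans(P[ia[sample.int(n_sa, n_sa, TRUE)], , drop = FALSE])
      pb <- colMeans(P[ib[sample.int(n_sb, n_sb, TRUE)], , drop = FALSE])
      pa[pa == 0] <- pseudo_a; pb[pb == 0] <- pseudo_b
      boot[b, ] <- log2(pb / pa)
    }
    alpha <- (1 - conf) / 2
    lo <- apply(boot, 2L, stats::quantile, probs = alpha)
    hi <- apply(boot, 2L, stats::quantile, probs = 1 - alpha)
  }
  fdr <- stats::p.adjust(p_val, method = "BH")
  out <- data.frame(
    cluster = levels(cl),
    n_a = tabulate(as.integer(cl)[cells$group == group_a], K),
    n_b = tabulate(as.integer(cl)[cells$group == group_b], K),
    prop_a = obs$pa, prop_b = obs$pb,
    log2fd = obs$lfd, ci_low = lo, ci_high = hi,
    p_value = p_val, fdr = fdr,
    significant = fdr < fdr_max & abs(obs$lfd) > lfd_min,
    zero_substituted = obs$zero,
    stringsAsFactors = FALSE
  )
  class(out) <- c("proportion_test", class(out))
  out
}

#' Differential expression by rank-sum test with a fold-change gate
#'
#' Per gene: two-sided Wilcoxon rank-sum p-value, Benjamini-Hochberg
#' adjustment across genes, and the average log2 fold change computed as
#' log2 of the ratio of mean expression with a pseudo-count of 1. A gene
#' is called differentially expressed iff adjusted p < `p_max` and
#' log2FC > `lfc_min` (one-sided gate, b over a). Genes with zero variance
#' in both groups get p = 1 by convention.
#'
#' @param expr_a,expr_b genes x cells numeric matrices over the same gene
#'   universe (rownames identify genes).
#' @param p_max,lfc_min significance gates (defaults 0.05 and 0.6).
#' @return data.frame: gene, log2fc, p_value, p_adj, deg.
#' @export
find_degs <- function(expr_a, expr_b, p_max = 0.05, lfc_min = 0.6) {
  stopifnot(is.matrix(expr_a), is.matrix(expr_b),
            nrow(expr_a) == nrow(expr_b))
  if (!is.null(rownames(expr_a)) && !is.null(rownames(expr_b)) &&
      !identical(rownames(expr_a), rownames(expr_b))) {
    stop("find_degs: gene universes differ", call. = FALSE)
  }
  genes <- rownames(expr_a)
  if (is.null(genes)) genes <- sprintf("gene%04d", seq_len(nrow(expr_a)))
  p <- vapply(seq_len(nrow(expr_a)), function(i) {
    xa <- expr_a[i, ]; xb <- expr_b[i, ]
    if (stats::var(c(xa, xb)) == 0) return(1)
    suppressWarnings(stats::wilcox.test(xb, xa)$p.value)
  }, numeric(1))
  lfc <- log2((rowMeans(expr_b) + 1) / (rowMeans(expr_a) + 1))
  padj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = genes, log2fc = lfc, p_value = p, p_adj = padj,
             deg = padj < p_max & lfc > lfc_min,
             stringsAsFactors = FALSE, row.names = NULL)
}
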