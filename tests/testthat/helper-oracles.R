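# Independent oracles used by property and acceptance tests. These are
# deliberately naive implementations kept separate from the package code
# paths they check.

# brute-force single-linkage clonal partition: union-find over all pairs
# sharing gene-level V, J and junction length with normalized Hamming
# distance <= threshold
oracle_clones <- function(v_call, j_call, junction, threshold) {
  n <- length(junction)
  v <- sub("\\*.*$", "", v_call)
  j <- sub("\\*.*$", "", j_call)
  len <- nchar(junction)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (v[a] != v[b] || j[a] != j[b] || len[a] != len[b]) next
      ca <- strsplit(junction[a], "")[[1]]
      cb <- strsplit(junction[b], "")[[1]]
      if (sum(ca != cb) / len[a] <= threshold) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  match(comp, unique(comp))
}

# hand-coded Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# exact permutation p-value for the Kruskal-Wallis statistic on small
# groups: enumerate all distinct assignments of values to group sizes
oracle_kw_exact_p <- function(values, groups) {
  sizes <- table(groups)
  n <- length(values)
  kw_stat <- function(g) stats::kruskal.test(values, factor(g))$statistic
  obs <- kw_stat(groups)
  labs <- rep(names(sizes), sizes)
  idx_all <- seq_len(n)
  count <- 0L; total <- 0L
  combs1 <- utils::combn(idx_all, sizes[[1]], simplify = FALSE)
  for (c1 in combs1) {
    rest <- setdiff(idx_all, c1)
    combs2 <- utils::combn(rest, sizes[[2]], simplify = FALSE)
    for (c2 in combs2) {
      g <- character(n)
      g[c1] <- names(sizes)[1]
      g[c2] <- names(sizes)[2]
      g[setdiff(rest, c2)] <- names(sizes)[3]
      total <- total + 1L
      if (kw_stat(g) >= obs - 1e-12) count <- count + 1L
    }
  }
  count / total
}

# random junction set generator for clone-oracle property tests
random_junction_records <- function(n, seed) {
  set.seed(seed)
  vs <- paste0("IGHV", sample(1:3, n, TRUE), "-", sample(c(23, 30), n, TRUE))
  js <- paste0("IGHJ", sample(4:5, n, TRUE))
  lens <- sample(c(36L, 39L), n, TRUE)
  base_pool <- c("A", "C", "G", "T")
  junc <- character(n)
  for (i in seq_len(n)) {
    # mixture: near-copies of earlier junctions (to exercise linkage
    # chaining) plus fully random ones
    made <- FALSE
    if (i > 1 && stats::runif(1) < 0.5) {
      donor <- sample(seq_len(i - 1), 1)
      d <- strsplit(junc[donor], "")[[1]]
      if (length(d) == lens[i]) {
        flip <- stats::runif(lens[i]) < 0.08
        d[flip] <- sample(base_pool, sum(flip), TRUE)
        junc[i] <- paste(d, collapse = "")
        made <- TRUE
      }
    }
    if (!made) junc[i] <- paste(sample(base_pool, lens[i], TRUE), collapse = "")
  }
  data.frame(sequence_id = sprintf("seq%03d", seq_len(n)),
             cell_id = sprintf("cell%03d", seq_len(n)),
             v_call = vs, j_call = js, junction = junc,
             stringsAsFactors = FALSE)
}

# random gapless alignment pair with mismatches, for SHM accounting tests
random_alignment_pair <- function(len = 300L) {
  germ <- sample(c("A", "C", "G", "T"), len, TRUE)
  obs <- germ
  k <- sample(0:20, 1)
  pos <- sample(len, k)
  for (p in pos) obs[p] <- sample(setdiff(c("A", "C", "G", "T"), germ[p]), 1)
  list(obs = paste(obs, collapse = ""), germ = paste(germ, collapse = ""),
       n_mut = k)
}
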