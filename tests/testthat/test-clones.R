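mk_rec <- function(v, j, junction, id = NULL) {
  n <- length(junction)
  data.frame(sequence_id = id %||% sprintf("s%02d", seq_len(n)),
             cell_id = sprintf("c%02d", seq_len(n)),
             v_call = v, j_call = j, junction = junction,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("assign_clones partitions by V/J/length then junction distance", {
  # identical V/J/junction: one clone of size 2
  r <- mk_rec(rep("IGHV3-23*01", 2), rep("IGHJ4*01", 2),
              rep(strrep("ACG", 12), 2))
  cs <- assign_clones(r)
  expect_length(unique(cs$clones$clone_id), 1L)

  # same V/J, junction lengths 45 and 48: two singleton clones
  r2 <- mk_rec(rep("IGHV3-23*01", 2), rep("IGHJ4*01", 2),
               c(strrep("A", 45), strrep("A", 48)))
  expect_length(unique(assign_clones(r2)$clones$clone_id), 2L)

  # allele differences do not split clones
  r3 <- mk_rec(c("IGHV3-23*01", "IGHV3-23*04"), rep("IGHJ4*01", 2),
               rep(strrep("ACG", 12), 2))
  expect_length(unique(assign_clones(r3)$clones$clone_id), 1L)

  # missing annotations are rejected with the offending id
  r4 <- mk_rec(c("IGHV3-23*01", NA), rep("IGHJ4*01", 2),
               rep(strrep("ACG", 12), 2))
  expect_error(assign_clones(r4), "s02")
})

test_that("clone ids are stable under input reordering", {
  r <- random_junction_records(30, seed = 91)
  cs1 <- assign_clones(r)
  cs2 <- assign_clones(r[rev(seq_len(nrow(r))), ])
  m <- merge(cs1$clones, cs2$clones, by = "sequence_id")
  expect_identical(m$clone_id.x, m$clone_id.y)
})

test_that("assign_clones equals the brute-force single-linkage oracle", {
  for (seed in 1:40) {
    n <- sample(5:50, 1)
    r <- random_junction_records(n, seed = seed)
    cs <- assign_clones(r, distance_threshold = 0.15)
    got <- cs$clones$clone_id[match(r$sequence_id, cs$clones$sequence_id)]
    want <- oracle_clones(r$v_call, r$j_call, r$junction, 0.15)
    # compare as partitions
    expect_identical(as.integer(factor(got, unique(got))),
                     as.integer(factor(want, unique(want))),
                     label = paste("seed", seed))
  }
})

test_that("clone_size_bins uses the printed bin boundaries, cell-weighted", {
  # sizes {1,2,5,10} over 18 cells
  ids <- rep(c("a", "b", "c", "d"), c(1, 2, 5, 10))
  cs <- list(clones = data.frame(sequence_id = sprintf("s%02d", 1:18),
                                 cell_id = sprintf("s%02d", 1:18),
                                 clone_id = ids, vj_group = "g"))
  class(cs) <- "clone_set"
  b <- clone_size_bins(cs)
  frac <- setNames(b$fraction, b$bin)
  expect_equal(frac[["rare"]], 1 / 18)
  expect_equal(frac[["small"]], 2 / 18)
  expect_equal(frac[["medium"]], 5 / 18)   # clone of size 3-5 is medium
  expect_equal(frac[["large"]], 10 / 18)
  expect_equal(sum(b$fraction), 1)

  # all singletons: rare fraction 1; size-3 clone lands in medium
  cs2 <- cs; cs2$clones$clone_id <- sprintf("u%02d", 1:18)
  b2 <- clone_size_bins(cs2)
  expect_equal(b2$fraction[b2$bin == "rare"], 1)
  cs3 <- cs; cs3$clones$clone_id <- rep(c("x", "y"), c(3, 15))
  b3 <- clone_size_bins(cs3)
  expect_equal(b3$fraction[b3$bin == "medium"], 3 / 18)
  expect_equal(b3$fraction[b3$bin == "larger"], 15 / 18)  # >10 reported apart
})

test_that("gene_usage computes per-group spectra with the 3% floor", {
  rec <- data.frame(
    v_call = c(rep("IGHV3-30*01", 10)),
    chain = "heavy", group = "healthy",
    cell_id = sprintf("c%02d", 1:10), stringsAsFactors = FALSE)
  u <- gene_usage(rec, reference = NULL)
  expect_equal(u$usage$frequency, 1.0)

  # counts {5,3,2} over 3 genes
  rec2 <- rec
  rec2$v_call <- rep(c("IGHV1-2*01", "IGHV3-23*01", "IGHV4-34*01"), c(5, 3, 2))
  u2 <- gene_usage(rec2)
  expect_equal(sort(u2$usage$frequency, decreasing = TRUE), c(0.5, 0.3, 0.2))

  # a gene below min_freq everywhere is excluded
  rec3 <- data.frame(
    v_call = rep(c("IGHV3-23*01", "IGHV1-2*01"), c(98, 2)),
    chain = "heavy", group = "healthy",
    cell_id = sprintf("c%03d", 1:100), stringsAsFactors = FALSE)
  ref <- data.frame(gene = c("IGHV3-23", "IGHV1-2"), chain = "heavy",
                    frequency = c(0.97, 0.02))
  u3 <- gene_usage(rec3, reference = ref, min_freq = 0.03)
  expect_false("IGHV1-2" %in% u3$usage$gene)
  expect_true("IGHV3-23" %in% u3$usage$gene)
  expect_error(gene_usage(rec3[0, ]), "empty")
})

test_that("isotype_fractions aggregates switched isotypes and keeps absences missing", {
  rec <- data.frame(group = "g1", c_call = rep("IGHM", 5),
                    stringsAsFactors = FALSE)
  f <- isotype_fractions(rec)
  expect_equal(f$fractions$fraction[f$fractions$isotype == "IGHM"], 1)
  expect_equal(f$switched$switched_fraction, 0)

  rec2 <- data.frame(group = "g1", c_call = c(rep("IGHG1", 3), "IGHM"),
                     stringsAsFactors = FALSE)
  expect_equal(isotype_fractions(rec2)$switched$switched_fraction, 0.75)

  # absent grouping cells are simply not reported
  rec3 <- data.frame(group = factor(c("g1", "g1"), levels = c("g1", "g2")),
                     c_call = c("IGHM", "IGHG1"), stringsAsFactors = FALSE)
  f3 <- isotype_fractions(rec3)
  expect_false("g2" %in% f3$fractions$group)

  expect_warning(isotype_fractions(data.frame(group = "g", c_call = "IGXX")),
                 "other")
})
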