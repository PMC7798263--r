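test_that("overlapping parallel paths merge into one longer motif", {
  ds <- ortho_set(c(s1 = "AAACGTACGTTT", s2 = "GGACGTACGTCC"))
  sol <- discover_motifs(ds, k_max = 8L, k_min = 6L)
  expect_length(sol$motifs, 1L)
  m <- sol$motifs[[1L]]
  expect_equal(m$seq, "ACGTACGT")
  expect_equal(m$depth, 2L)
  expect_equal(m$occ$start, c(3L, 3L))
})

test_that("planted ordered motifs are recovered at full depth in order", {
  gen <- make_planted(c("GCAATAAA", "TGTATAGCA", "TTGCACTTG", "CCATGGAC"),
                      c(5L, 5L, 5L, 5L), n_layers = 5L, len = 1000L,
                      insertions = 100L, seed = 31L)
  sol <- discover_motifs(gen$dataset)
  tab <- synmotif:::motif_table(sol)
  deep <- tab[tab$depth == 5L, , drop = FALSE]
  for (m in unique(gen$truth$motif)) {
    expect_true(any(vapply(deep$seq, grepl, logical(1), x = m, fixed = TRUE) |
                      vapply(deep$seq, function(s) grepl(s, m, fixed = TRUE),
                             logical(1))),
                info = m)
  }
  expect_equal(order_violations(sol), 0L)
  # every reported occurrence re-reads from the input sequences
  for (mm in sol$motifs) {
    expect_true(all(substring(gen$dataset$seqs[mm$occ$layer], mm$occ$start,
                              mm$occ$end) == mm$seq))
  }
})

test_that("merged motif length is at least the base k of its paths", {
  gen <- make_planted(c("GCAATAAAT", "TGTATAGCA"), c(4L, 4L), 4L, len = 500L,
                      seed = 8L)
  sol <- discover_motifs(gen$dataset)
  for (m in sol$motifs) expect_gte(m$len, m$k_base)
})

test_that("identical seed and configuration reproduce the same solution", {
  gen <- make_planted(c("GCAATAAA", "TGTATAGC"), c(4L, 4L), 4L, len = 400L,
                      seed = 12L)
  s1 <- discover_motifs(gen$dataset)
  s2 <- discover_motifs(gen$dataset)
  expect_identical(synmotif:::motif_table(s1), synmotif:::motif_table(s2))
})

test_that("partitioning isolates regions between boundary motifs", {
  ds <- ortho_set(c(a = "TTACGTTTGCATGCATTTCCGGAA", b = "ACGTAAGCATGCAAACCGGAT"))
  g <- build_kmer_graph(ds, 4L)
  # boundary = central GCATGCA-like motif present once per layer
  b <- list(list(depth = 2L, pos = c(10L, 8L), len = 7L))
  subs <- partition_graph(prune_to_depth(g, 2L), b, 2L)
  for (s in subs) {
    left <- all(s$edges$from + s$edges$len - 1L < 10L)
    right <- all(s$edges$from > 16L)
    expect_true(left || right)
  }
  # no boundaries: single subgraph, unchanged
  subs0 <- partition_graph(prune_to_depth(g, 2L), list(), 2L)
  expect_length(subs0, 1L)
  expect_equal(nrow(subs0[[1L]]$edges), nrow(prune_to_depth(g, 2L)$edges))
})

test_that("refinement without stored complex paths is the identity", {
  ds <- ortho_set(c(a = "ACGTACGTTT", b = "CCACGTACGT"))
  g <- build_kmer_graph(ds, 6L)
  r <- refine_complex(list(), 6L, 2L, g)
  expect_length(r$store, 0L)
  expect_length(r$refined, 0L)
})

test_that("the edge cap leaves small solves untouched and rejects <= 50", {
  ds <- ortho_set(c(s1 = "AAACGTACGTTT", s2 = "GGACGTACGTCC"))
  g <- prune_to_depth(build_kmer_graph(ds, 6L), 2L)
  expect_error(enforce_edge_cap(g, list(), 2L, max_edges = 50L), "above 50")
  ps <- enforce_edge_cap(g, list(), 2L, max_edges = 1200L)
  expect_equal(ps$objective, solve_ilp(formulate_ilp(g, 2L))$objective)
})

test_that("sequential cluster optimization approximates the joint solve", {
  # disjoint clusters: sequential per-cluster optimization must reach the
  # unrestricted optimum
  gen <- make_planted(c("GCAATAAA", "TGTATAGC", "TTGCACTT"), c(2L, 2L, 2L),
                      2L, len = 300L, seed = 21L)
  g <- prune_to_depth(build_kmer_graph(gen$dataset, 6L), 2L)
  full <- solve_ilp(formulate_ilp(g, 2L))$objective
  capped <- enforce_edge_cap(g, list(), 2L, max_edges = 51L)
  expect_equal(capped$objective, full)
})

test_that("deep motifs break the chain at a truncated layer", {
  gen <- make_planted(c("GCAATAAAGG", "TGTATAGCAC", "AATTGCACTT", "CCATGGACCA"),
                      c(5L, 5L, 5L, 5L), 5L, len = 600L,
                      truncate = c(0, 0, 0.5, 0, 0), seed = 41L)
  lost <- setdiff(unique(gen$truth$motif),
                  gen$truth$motif[gen$truth$layer == 3L])
  sol <- discover_motifs(gen$dataset, min_depth = 5L)
  tab <- synmotif:::motif_table(sol)
  # motifs missing from the truncated layer cannot be conserved to depth 5
  for (m in lost) {
    expect_false(any(tab$depth >= 5L & grepl(m, tab$seq, fixed = TRUE)))
  }
})

test_that("extension discovery recovers upstream motifs in intact layers", {
  gen <- make_planted(c("GCAATAAAGG", "TGTATAGCAC", "AATTGCACTT", "CCATGGACCA"),
                      c(5L, 5L, 5L, 5L), 5L, len = 600L,
                      truncate = c(0, 0, 0.5, 0, 0), seed = 41L)
  lost <- setdiff(unique(gen$truth$motif),
                  gen$truth$motif[gen$truth$layer == 3L])
  sol <- discover_motifs(gen$dataset, min_depth = 5L)
  tab <- synmotif:::motif_table(sol)
  ext <- tab[tab$source == "5p", , drop = FALSE]
  if (length(lost) > 0L) {
    hits <- vapply(lost, function(m)
      any(grepl(m, ext$seq, fixed = TRUE) |
            vapply(ext$seq, function(s) grepl(s, m, fixed = TRUE), logical(1))),
      logical(1))
    expect_gte(mean(hits), 0.5)
  }
  # with min_depth set, shallower motifs are dropped from the solution
  expect_true(all(tab$depth >= 5L | tab$source != "primary"))
})

test_that("extensions are skipped when no primary motifs exist", {
  set.seed(77)
  seqs <- vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 60L, replace = TRUE), collapse = ""),
    character(1))
  ds <- ortho_set(seqs, labels = paste0("s", 1:3))
  sol <- discover_motifs(ds, k_max = 12L, k_min = 10L)
  expect_length(sol$motifs, 0L)
})

test_that("exhaustive mode still finds planted motifs and guards its input size", {
  gen <- make_planted(c("GCAATAAA", "TGTATAGC"), c(3L, 3L), 3L, len = 300L,
                      seed = 18L)
  sol <- discover_motifs(gen$dataset, k_max = 8L, k_min = 6L,
                         exhaustive = TRUE)
  tab <- synmotif:::motif_table(sol)
  for (m in c("GCAATAAA", "TGTATAGC")) {
    expect_true(any(tab$depth == 3L & (grepl(m, tab$seq, fixed = TRUE) |
                                         vapply(tab$seq, grepl, logical(1),
                                                x = m, fixed = TRUE))),
                info = m)
  }
  big <- make_planted("GCAATAAA", 2L, 2L, len = 6000L, seed = 19L)
  expect_error(discover_motifs(big$dataset, exhaustive = TRUE),
               "below 10 kb")
})

test_that("two-layer datasets run a single elimination pass", {
  ds <- ortho_set(c(a = "TTGCAATAAACC", b = "GGGCAATAAATT"))
  sol <- discover_motifs(ds, k_max = 8L, k_min = 6L)
  expect_true(all(vapply(sol$motifs, `[[`, integer(1), "depth") == 2L))
  expect_true(any(vapply(sol$motifs, `[[`, character(1), "seq") == "GCAATAAA"))
})
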