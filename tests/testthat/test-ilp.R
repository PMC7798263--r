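test_that("two crossing edges of distinct k-mers exclude each other", {
  # ACG appears early in L1 / late in L2, TTT the other way around
  ds <- ortho_set(c(a = "ACGNTTT", b = "TTTNACG"))
  g <- build_kmer_graph(ds, 3L)
  expect_equal(nrow(g$edges), 2L)
  prob <- formulate_ilp(g, 2L)
  expect_equal(nrow(prob$conflicts), 1L)
  ps <- solve_ilp(prob)
  expect_equal(ps$objective, 1L)
})

test_that("parallel edges are all selected and merge into one path", {
  ds <- ortho_set(c(s1 = "AAACGTACGTTT", s2 = "GGACGTACGTCC"))
  g <- build_kmer_graph(ds, 6L)
  ps <- solve_ilp(formulate_ilp(g, 2L))
  expect_equal(ps$objective, 3L)
  expect_equal(brute_force_optimum(g, 2L), 3L)
})

test_that("flow balance forbids dead-end edges below the required depth", {
  # CCGG connects L1->L2 and has no continuation to L3
  ds <- ortho_set(c(l1 = "AAACCGGTTTT", l2 = "TCCGGAAAAAT", l3 = "GGTTGGTTGG"))
  g <- build_kmer_graph(ds, 4L)
  expect_gt(nrow(g$edges), 0L)
  ps <- solve_ilp(formulate_ilp(g, 3L))
  expect_equal(ps$objective, 0L)
})

test_that("unique-symbol two-layer graphs solve to the LCS length", {
  pool <- symbol_pool()
  set.seed(19)
  for (rep in 1:20) {
    n1 <- sample(3:8, 1L); n2 <- sample(3:8, 1L)
    syms <- sample(pool, max(n1, n2) + 4L)
    s1 <- sample(syms, n1); s2 <- sample(syms, n2)
    g <- unique_symbol_graph(s1, s2)
    ps <- solve_ilp(formulate_ilp(g, 2L))
    expect_equal(ps$objective, lcs_length(s1, s2))
  }
})

test_that("solver objective equals the exhaustive optimum on random graphs", {
  for (seed in 1:40) {
    gd <- random_small_graph(seed)
    prob <- formulate_ilp(gd$graph, gd$depth)
    ps <- solve_ilp(prob)
    expect_equal(ps$objective, brute_force_optimum(gd$graph, gd$depth),
                 info = paste("seed", seed))
  }
})

test_that("selected edges are non-crossing and anchored at layer 1", {
  for (seed in 41:55) {
    gd <- random_small_graph(seed, max_edges = 25L)
    ps <- solve_ilp(formulate_ilp(gd$graph, gd$depth))
    e <- ps$edges
    for (l in unique(e$li)) {
      sub <- e[e$li == l, , drop = FALSE]
      if (nrow(sub) < 2L) next
      for (i in seq_len(nrow(sub) - 1L)) {
        for (j in (i + 1L):nrow(sub)) {
          if (sub$kmer[i] == sub$kmer[j]) next
          dm <- sub$from[j] - sub$from[i]; dq <- sub$to[j] - sub$to[i]
          expect_false(dm > 0L && dq < 0L || dm < 0L && dq > 0L)
        }
      }
    }
    # reachability: every path holds a layer-1 node, every edge joins a path
    for (p in ps$paths) {
      expect_true(any(p$edges$li == 1L) || gd$depth == 2L)
    }
  }
})

test_that("adding an edge never decreases the optimum", {
  for (seed in 56:63) {
    gd <- random_small_graph(seed)
    g <- gd$graph
    if (nrow(g$edges) < 2L) next
    g_less <- g
    g_less$edges <- g$edges[-nrow(g$edges), , drop = FALSE]
    o_full <- solve_ilp(formulate_ilp(g, gd$depth))$objective
    o_less <- solve_ilp(formulate_ilp(g_less, gd$depth))$objective
    expect_gte(o_full, o_less)
  }
})

test_that("same-k-mer repeat networks are exempt from crossing constraints", {
  # one k-mer repeated twice in both layers, nothing else: all four
  # repeat-repeat edges may coexist
  ds <- ortho_set(c(a = "ACGNNNNNNACG", b = "ACGNNNNNNACGT"))
  g <- build_kmer_graph(ds, 3L)
  expect_equal(nrow(g$edges), 4L)
  prob <- formulate_ilp(g, 2L)
  expect_equal(nrow(prob$conflicts), 0L)
  expect_equal(solve_ilp(prob)$objective, 4L)
  # a crossing path of a different k-mer activates the constraint
  ds2 <- ortho_set(c(a = "ACGNTTTNNACG", b = "ACGNTTTNNACGT"))
  g2 <- build_kmer_graph(ds2, 3L)
  prob2 <- formulate_ilp(g2, 2L)
  expect_gt(nrow(prob2$conflicts), 0L)
  expect_equal(solve_ilp(prob2)$objective, brute_force_optimum(g2, 2L))
})

test_that("merge-consistency forbids inconsistent overlap offsets", {
  # AAAA run: 3 windows of AAA in L1, 2 in L2; selected overlapping windows
  # must keep equal offsets between layers
  ds <- ortho_set(c(a = "AAAAA", b = "TAAAAT"))
  g <- build_kmer_graph(ds, 3L, max_repeats = 10L)
  ps <- solve_ilp(formulate_ilp(g, 2L))
  expect_equal(ps$objective, brute_force_optimum(g, 2L))
  sel <- ps$edges
  if (nrow(sel) >= 2L) {
    for (i in seq_len(nrow(sel) - 1L)) {
      for (j in (i + 1L):nrow(sel)) {
        dm <- sel$from[j] - sel$from[i]; dq <- sel$to[j] - sel$to[i]
        if (abs(dm) < sel$len[i] || abs(dq) < sel$len[i])
          expect_equal(dm, dq)
      }
    }
  }
})

test_that("favored-path coverage keeps a designated path in the solution", {
  ds <- ortho_set(c(a = "ACGNTTT", b = "TTTNACG"))
  g <- build_kmer_graph(ds, 3L)
  # favor the ACG path (which on its own would tie with TTT)
  fav <- list(list(edges = g$edges[g$edges$kmer == "ACG", , drop = FALSE]))
  ps <- solve_ilp(formulate_ilp(g, 2L, favored = fav))
  expect_true("ACG" %in% ps$edges$kmer)
  # favoring a path with no surviving layer-1 edge is an error
  gone <- list(list(edges = data.frame(li = 1L, from = 99L, to = 99L,
                                       kmer = "ACG", len = 3L)))
  expect_error(formulate_ilp(g, 2L, favored = gone), "favored path")
})

test_that("the LP dump lists every variable and constraint family", {
  ds <- ortho_set(c(a = "ACGNTTT", b = "TTTNACG"))
  g <- build_kmer_graph(ds, 3L)
  prob <- formulate_ilp(g, 2L,
                        favored = list(list(edges = g$edges[g$edges$kmer == "ACG", ,
                                                            drop = FALSE])))
  f <- withr::local_tempfile(fileext = ".lp")
  write_ilp_lp(prob, f)
  lp <- readLines(f)
  expect_equal(lp[1L], "Maximize")
  expect_true(any(grepl("x1 \\+ x2 <= 1|x2 \\+ x1 <= 1", lp)))
  expect_true(any(grepl(">= 1", lp)))
  expect_true(any(lp == "Binary"))
})

test_that("exhaustive enumeration refuses oversized graphs", {
  gd <- random_small_graph(70, max_edges = 12L)
  expect_equal(brute_force_optimum(gd$graph, gd$depth),
               solve_ilp(formulate_ilp(gd$graph, gd$depth))$objective)
  big <- gd$graph
  big$edges <- do.call(rbind, replicate(30, gd$graph$edges, simplify = FALSE))
  expect_error(brute_force_optimum(big, gd$depth), "too large")
})
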