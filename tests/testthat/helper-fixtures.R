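# Shared fixtures and independent oracles used across the suite.

ACGT_ <- c("A", "C", "G", "T")

# dataset whose layers share the given ordered motifs on random background
make_planted <- function(motifs, depths, n_layers, len = 400L, seed = 1L,
                         ...) {
  generate_planted(plant_spec(motifs, depths, n_layers, length = len,
                              seed = seed, ...))
}

# random small layered graph built from real sequences over a two-letter
# alphabet (dense in repeats), pruned to a random depth; edge count capped
random_small_graph <- function(seed, max_edges = 12L) {
  set.seed(seed)
  repeat {
    D <- sample(2:4, 1L)
    seqs <- vapply(seq_len(D), function(i)
      paste(sample(c("A", "C"), sample(8:13, 1L), replace = TRUE),
            collapse = ""), character(1))
    ds <- try(ortho_set(seqs), silent = TRUE)
    if (inherits(ds, "try-error")) next  # duplicated sequences
    y <- sample(2:D, 1L)
    g <- try(prune_to_depth(build_kmer_graph(ds, 2L, max_repeats = 50L), y),
             silent = TRUE)
    if (inherits(g, "try-error")) next
    if (nrow(g$edges) >= 1L && nrow(g$edges) <= max_edges)
      return(list(graph = g, depth = y))
  }
}

# 2-layer graph in which every k-mer occurs exactly once per layer: symbols
# separated by N so that only whole symbols form nodes
unique_symbol_graph <- function(sym1, sym2) {
  ds <- ortho_set(c(paste(sym1, collapse = "N"), paste(sym2, collapse = "N")))
  build_kmer_graph(ds, nchar(sym1[1L]), max_repeats = 5L)
}

# independent longest-common-subsequence oracle (dynamic program)
lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  dp <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      dp[i + 1L, j + 1L] <- if (a[i] == b[j]) dp[i, j] + 1L else
        max(dp[i, j + 1L], dp[i + 1L, j])
    }
  }
  dp[n + 1L, m + 1L]
}

# pool of distinct 3-mers over A/C/G/T used as unique symbols
symbol_pool <- function() {
  p <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"),
                   c = c("A", "C", "G", "T"))
  paste0(p$a, p$b, p$c)
}

# independent naive seed-site scanner: context string contains the motif with
# its real flanks; motif occupies positions (off+1)..(off+len) of context
naive_site_types <- function(motif, context, off, seed7) {
  core <- synmotif:::revcomp_str(substr(seed7, 1L, 6L))
  m8b <- chartr("ACGT", "TGCA", substr(seed7, 7L, 7L))
  types <- character(0)
  L <- nchar(motif)
  for (p in seq_len(max(0L, L - 5L))) {
    if (substr(motif, p, p + 5L) != core) next
    cs <- off + p          # core start within context
    up <- if (cs - 1L >= 1L) substr(context, cs - 1L, cs - 1L) else ""
    dn <- if (cs + 6L <= nchar(context)) substr(context, cs + 6L, cs + 6L) else ""
    has_m8 <- up == m8b
    has_a1 <- dn == "A"
    types <- c(types, if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
               else if (has_a1) "7mer-A1" else "6mer")
  }
  types
}

# check that selected motif occurrences preserve anchor order in every layer
order_violations <- function(sol) {
  viol <- 0L
  tab <- synmotif:::motif_table(sol)
  if (nrow(tab) < 2L) return(0L)
  prim <- which(tab$source == "primary")
  for (i in prim) {
    for (j in prim) {
      if (i >= j) next
      mi <- sol$motifs[[i]]; mj <- sol$motifs[[j]]
      if (!isTRUE(mi$simple) || !isTRUE(mj$simple)) next  # repeat-network exemption
      common <- intersect(mi$occ$layer, mj$occ$layer)
      for (l in common) {
        si <- mi$occ$start[mi$occ$layer == l][1L]
        sj <- mj$occ$start[mj$occ$layer == l][1L]
        s1i <- mi$occ$start[mi$occ$layer == 1L][1L]
        s1j <- mj$occ$start[mj$occ$layer == 1L][1L]
        # strict inversion of linear order relative to the anchor
        if (mi$seq != mj$seq && (s1i - s1j) * (si - sj) < 0L) viol <- viol + 1L
      }
    }
  }
  viol
}

# minimal hand-built motif_solution for report-level tests
toy_solution <- function(seqs, motif_defs) {
  ds <- ortho_set(seqs)
  motifs <- lapply(motif_defs, function(d) {
    occ <- data.frame(layer = seq_len(d$depth), start = d$starts,
                      end = d$starts + nchar(d$seq) - 1L)
    list(seq = d$seq, len = nchar(d$seq), depth = d$depth, pos = d$starts,
         k_base = nchar(d$seq), source = if (is.null(d$source)) "primary"
         else d$source, layers = seq_len(d$depth), simple = TRUE, occ = occ)
  })
  structure(list(dataset = ds, motifs = motifs,
                 options = list(k_max = 15L, k_min = 6L)),
            class = "motif_solution")
}
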