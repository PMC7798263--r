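# Iterative motif discovery engine: for k from k_max down to k_min, build the
# layered graph and eliminate layers from the deepest level to depth 2. Deep
# simple paths found early become partition boundaries that constrain shallower
# and shorter-k iterations; complex (repeat-containing) paths are stored and
# iteratively refined. Overlapping selected nodes are merged into longer
# motifs, and a final 5'/3' extension stage recovers motifs upstream/
# downstream of the primary solution in sequences with extended ends.

# ---- path helpers ----------------------------------------------------------

# start positions (one per layer 1..depth) of a simple path
path_positions <- function(p) {
  pe <- p$edges
  c(pe$from[order(pe$li)], pe$to[which.max(pe$li)])
}

new_motif <- function(seq, depth, pos, len, k_base, source = "primary",
                      layers = seq_len(depth), simple = TRUE, occ = NULL) {
  depth <- unname(as.integer(depth)); pos <- unname(as.integer(pos))
  len <- unname(as.integer(len)); k_base <- unname(as.integer(k_base))
  if (is.null(occ))
    occ <- data.frame(layer = layers, start = pos, end = pos + len - 1L)
  list(seq = unname(seq), len = len, depth = depth, pos = pos, k_base = k_base,
       source = source, layers = layers, simple = simple, occ = occ)
}

# Merge overlapping simple paths of one solve into longer motifs. Two paths
# merge when they have the same depth and the same positional offset in every
# layer (guaranteed for selected edges by the merge-consistency constraint).
merge_simple_paths <- function(paths, seqs) {
  if (length(paths) == 0L) return(list())
  pos_list <- lapply(paths, path_positions)
  depths <- vapply(paths, `[[`, integer(1), "depth")
  ks <- vapply(paths, `[[`, integer(1), "k")
  ord <- order(vapply(pos_list, `[`, integer(1), 1L))
  out <- list()
  cur <- NULL
  for (t in ord) {
    p <- pos_list[[t]]; d <- depths[t]; k <- ks[t]
    if (!is.null(cur) && d == cur$depth &&
        p[1L] <= cur$pos[1L] + cur$len - 1L + 0L &&
        all(p - cur$pos == p[1L] - cur$pos[1L]) && p[1L] >= cur$pos[1L]) {
      cur$len <- max(cur$len, p[1L] - cur$pos[1L] + k)
      cur$k_base <- min(cur$k_base, k)
    } else {
      if (!is.null(cur)) out[[length(out) + 1L]] <- cur
      cur <- list(pos = p, depth = d, len = k, k_base = k)
    }
  }
  out[[length(out) + 1L]] <- cur
  lapply(out, function(m) {
    new_motif(seq = substr(seqs[1L], m$pos[1L], m$pos[1L] + m$len - 1L),
              depth = m$depth, pos = m$pos, len = m$len, k_base = m$k_base)
  })
}

# Complex path -> motif with per-layer occurrence intervals (overlapping
# selected nodes within a layer merged into runs).
complex_to_motif <- function(p, seqs) {
  pe <- p$edges
  k <- p$k
  occ <- list()
  layers <- sort(unique(c(pe$li, pe$li + 1L)))
  for (l in layers) {
    starts <- sort(unique(c(pe$from[pe$li == l], pe$to[pe$li == l - 1L])))
    runs <- split(starts, cumsum(c(1L, diff(starts) >= k)))
    occ[[length(occ) + 1L]] <- data.frame(
      layer = l,
      start = vapply(runs, min, integer(1)),
      end = vapply(runs, max, integer(1)) + k - 1L)
  }
  occ <- do.call(rbind, occ)
  rownames(occ) <- NULL
  new_motif(seq = p$kmer, depth = p$depth,
            pos = occ$start[match(layers, occ$layer)], len = k, k_base = k,
            layers = layers, simple = isTRUE(p$simple), occ = occ)
}

# ---- partitioning ----------------------------------------------------------

# Region index of nodes (layer l, start p, length len) relative to the sorted
# boundary motifs of that layer; NA when the node touches a boundary.
region_index <- function(p, len, b_start, b_end) {
  if (length(b_start) == 0L) return(rep(1L, length(p)))
  r <- rep(0L, length(p))
  bad <- rep(FALSE, length(p))
  for (t in seq_along(b_start)) {
    r <- r + (p > b_end[t])
    bad <- bad | (p <= b_end[t] & p - 1L + len >= b_start[t])
  }
  r[bad] <- NA_integer_
  r + 1L
}

#' Partition a layered graph between simple-path boundaries
#'
#' Splits a depth-pruned graph into independent subgraphs whose nodes lie
#' strictly between consecutive boundary motifs in every layer (nodes touching
#' a boundary are excluded from both sides). Boundaries must be mutually
#' non-crossing simple motifs spanning layers `1..depth`.
#'
#' @param g a `kmer_graph` pruned to `depth`.
#' @param boundaries list of boundary motifs (with `pos` and `len`) of depth
#'   >= the graph depth.
#' @param depth the current elimination depth `y`.
#' @return list of `kmer_graph` subgraphs (possibly of length 1).
#' @export
partition_graph <- function(g, boundaries, depth) {
  e <- g$edges
  if (length(boundaries) == 0L || nrow(e) == 0L) return(list(g))
  ord <- order(vapply(boundaries, function(b) b$pos[1L], integer(1)))
  boundaries <- boundaries[ord]
  bs <- lapply(seq_len(depth), function(l)
    vapply(boundaries, function(b) b$pos[l], integer(1)))
  be <- lapply(seq_len(depth), function(l)
    vapply(boundaries, function(b) b$pos[l] + b$len - 1L, integer(1)))
  rs <- rd <- rep(NA_integer_, nrow(e))
  for (l in unique(e$li)) {
    w <- which(e$li == l)
    rs[w] <- region_index(e$from[w], e$len[w], bs[[l]], be[[l]])
    rd[w] <- region_index(e$to[w], e$len[w], bs[[l + 1L]], be[[l + 1L]])
  }
  keep <- !is.na(rs) & !is.na(rd) & rs == rd
  e <- e[keep, , drop = FALSE]
  reg <- rs[keep]
  lapply(split(seq_len(nrow(e)), reg), function(idx) {
    g2 <- g
    g2$edges <- e[idx, , drop = FALSE]
    g2
  })
}

# ---- complex-path refinement -----------------------------------------------

#' Refine stored complex paths against each other
#'
#' First refinement stage: builds a graph from the stored complex paths of
#' longer k-mers with depth equal to the current elimination depth together
#' with stored complex paths of the current k with strictly greater depth, and
#' re-solves it with a coverage constraint guaranteeing that every deeper path
#' survives in refined form (intersecting branches dropped).
#'
#' @param store list of stored complex paths (each with `edges`, `k`,
#'   `depth`).
#' @param k current k-mer length.
#' @param depth current elimination depth `y`.
#' @param g the current full graph (supplies layer metadata).
#' @return list with `store` (updated) and `refined` (the refreshed paths to
#'   favor when solving the current subgraphs).
#' @export
refine_complex <- function(store, k, depth, g) {
  is_lc <- vapply(store, function(p) p$k > k && p$depth == depth, logical(1))
  is_deep <- vapply(store, function(p) p$k == k && p$depth > depth, logical(1))
  if (!any(is_deep)) {
    return(list(store = store, refined = store[is_lc | is_deep]))
  }
  inv <- store[is_lc | is_deep]
  edges <- unique(do.call(rbind, lapply(inv, `[[`, "edges")))
  g2 <- g
  g2$edges <- edges[order(edges$li, edges$from, edges$to), , drop = FALSE]
  sol <- solve_ilp(formulate_ilp(g2, min_depth = depth, favored = store[is_deep]))
  refined <- anchored_paths(sol$paths)
  list(store = c(store[!(is_lc | is_deep)], refined), refined = refined)
}

# keep only paths anchored in layer 1
anchored_paths <- function(paths) {
  paths[vapply(paths, function(p) any(p$edges$li == 1L), logical(1))]
}

# ---- edge-cap solving ------------------------------------------------------

#' Solve a subgraph under the maximum-edge restriction
#'
#' If the graph fits under `max_edges` it is solved jointly (with refined
#' paths re-inserted and favored). Otherwise its candidate path clusters
#' (connected components over shared nodes) are optimized one at a time
#' against the refined set in ascending order of edge count, each solution
#' being folded into the refined set and the cluster removed, until the
#' remainder fits, followed by a final joint solve. A single cluster larger
#' than the cap is dropped (only previously refined paths are retained for
#' it).
#'
#' @param g a `kmer_graph` subgraph.
#' @param refined list of refined complex paths to re-insert and favor.
#' @param depth minimum depth `y` for the solve.
#' @param max_edges edge cap (> 50).
#' @return a `path_set`.
#' @export
enforce_edge_cap <- function(g, refined, depth, max_edges = 1200L) {
  if (max_edges <= 50L) stop("max_edges must be above 50")
  joint_solve <- function(edges, fav) {
    if (length(fav) > 0L) {
      fe <- do.call(rbind, lapply(fav, `[[`, "edges"))
      edges <- unique(rbind(edges, fe))
    }
    g2 <- g
    g2$edges <- edges[order(edges$li, edges$from, edges$to), , drop = FALSE]
    fav <- fav[vapply(fav, function(p)
      any(edge_key(p$edges[p$edges$li == 1L, , drop = FALSE]) %in%
            edge_key(g2$edges)), logical(1))]
    solve_ilp(formulate_ilp(g2, min_depth = depth, favored = fav))
  }
  if (nrow(g$edges) <= max_edges) return(joint_solve(g$edges, refined))
  clusters <- decompose_paths(g$edges)
  sizes <- vapply(clusters, function(p) nrow(p$edges), integer(1))
  clusters <- clusters[order(sizes)]
  sizes <- sort(sizes)
  cref <- refined
  remaining <- clusters
  total <- sum(sizes)
  while (total > max_edges && length(remaining) > 0L) {
    cl <- remaining[[1L]]
    remaining <- remaining[-1L]
    total <- total - nrow(cl$edges)
    if (nrow(cl$edges) > max_edges) next  # cluster alone exceeds the cap
    sol <- joint_solve(cl$edges, cref)
    cref <- anchored_paths(sol$paths)
  }
  rem_edges <- if (length(remaining) > 0L)
    do.call(rbind, lapply(remaining, `[[`, "edges")) else empty_edges()
  joint_solve(rem_edges, cref)
}

# ---- main engine -----------------------------------------------------------

#' Discover ordered conserved motifs across a homolog set
#'
#' Runs the full iterative discovery: for each k from `k_max` down to `k_min`
#' the layered k-mer graph is built, then solved depth-by-depth from the full
#' dataset depth down to 2, partitioning around previously found simple paths
#' and refining stored complex paths. Overlapping selected nodes are merged
#' into longer motifs, and motifs upstream/downstream of the primary solution
#' are recovered from sequences with extended 5'/3' ends.
#'
#' @param x an [ortho_set()].
#' @param k_max,k_min k-mer length range searched, from long to short.
#' @param max_repeats per-layer occurrence cap before a k-mer is excluded.
#' @param max_edges maximum number of edges in one solved program (> 50).
#' @param hsp logical or an `hsp_set`: restrict edges to high-scoring segment
#'   pairs between consecutive layers.
#' @param min_depth optional minimum conservation depth: motifs conserved
#'   less deeply are removed from the solution, and the 5'/3' extension
#'   boundaries are computed only from motifs at or beyond this depth (so
#'   shallow chance motifs near the ends cannot mask a truncation).
#' @param tolerance tolerance `t` for the 5'/3' extension qualification rules.
#' @param extensions run the 5'/3' extended-region discovery stage (disabled
#'   for two-layer datasets unless `force_extensions`).
#' @param force_extensions run extensions even when D = 2.
#' @param exhaustive store and refine simple paths instead of using them as
#'   partition boundaries, so deeper short k-mers can later displace longer
#'   shallow ones. No partitioning means every program is solved whole;
#'   refused for inputs of 10 kb total and above.
#' @return a `motif_solution`: list with `motifs` (each with sequence, depth,
#'   per-layer occurrences, source), the dataset and the options used.
#' @export
discover_motifs <- function(x, k_max = 15L, k_min = 6L, max_repeats = 15L,
                            max_edges = 1200L, hsp = FALSE, min_depth = NULL,
                            tolerance = 0.5, extensions = TRUE,
                            force_extensions = FALSE, exhaustive = FALSE) {
  k_max <- as.integer(k_max); k_min <- as.integer(k_min)
  if (!is.null(min_depth)) min_depth <- as.integer(min_depth)
  stopifnot(k_max >= k_min, k_min >= 2L)
  if (max_edges <= 50L) stop("max_edges must be above 50")
  if (exhaustive && sum(seq_lengths(x)) >= 10000L)
    stop("exhaustive mode is restricted to inputs below 10 kb total")
  D <- length(x)
  hsps <- if (isTRUE(hsp)) compute_hsps(x) else if (inherits(hsp, "hsp_set")) hsp else NULL
  opts <- list(k_max = k_max, k_min = k_min, max_repeats = max_repeats,
               max_edges = max_edges, hsp = !is.null(hsps),
               min_depth = min_depth, tolerance = tolerance,
               extensions = extensions, force_extensions = force_extensions,
               exhaustive = exhaustive)
  res <- run_core(x, k_max, k_min, max_repeats, max_edges, hsps,
                  y_floor = 2L, store_simple = exhaustive)
  motifs <- res$motifs
  sol <- structure(list(dataset = x, motifs = motifs, options = opts),
                   class = "motif_solution")
  if (extensions && (D > 2L || force_extensions)) {
    ext <- discover_extensions(sol, x, tolerance = tolerance,
                               min_depth = min_depth)
    if (!is.null(min_depth)) {
      sol$motifs <- Filter(function(m) m$depth >= min_depth, sol$motifs)
    }
    sol$motifs <- c(sol$motifs, ext)
  } else if (!is.null(min_depth)) {
    sol$motifs <- Filter(function(m) m$depth >= min_depth, sol$motifs)
  }
  sol$motifs <- order_motifs(sol$motifs)
  sol
}

order_motifs <- function(motifs) {
  if (length(motifs) == 0L) return(motifs)
  ord <- order(vapply(motifs, function(m) m$occ$start[1L], integer(1)),
               -vapply(motifs, `[[`, integer(1), "depth"))
  motifs[ord]
}

# core k-descent / depth-elimination loop (no extensions); with
# store_simple, simple paths join the refinement store instead of becoming
# partition boundaries (no partitioning, no placement constraints)
run_core <- function(x, k_max, k_min, max_repeats, max_edges, hsps, y_floor,
                     store_simple = FALSE) {
  D <- length(x)
  boundaries <- list()   # merged simple motifs, deepest first discovery
  store <- list()        # complex paths under refinement
  minlen <- min(seq_lengths(x))
  if (min(k_max, minlen) < k_min) return(list(motifs = list(), boundaries = list(), store = list()))
  ks <- seq(min(k_max, minlen), k_min, by = -1L)
  for (k in ks) {
    g <- build_kmer_graph(x, k, max_repeats = max_repeats, hsps = hsps)
    if (nrow(g$edges) == 0L && !any(vapply(store, function(p) p$k >= k, logical(1))))
      next
    for (y in seq(D, max(2L, y_floor))) {
      gy <- prune_to_depth(g, y)
      ref <- refine_complex(store, k, y, g)
      store <- ref$store
      if (nrow(gy$edges) == 0L && length(ref$refined) == 0L) next
      bnds <- Filter(function(b) b$depth >= y, boundaries)
      subs <- partition_graph(gy, bnds, y)
      solved_complex <- list()
      touched <- rep(FALSE, length(store))
      for (sub in subs) {
        fav <- paths_in_region(ref$refined, sub, bnds, y)
        if (nrow(sub$edges) == 0L && length(fav) == 0L) next
        ps <- enforce_edge_cap(sub, fav, y, max_edges)
        paths <- anchored_paths(ps$paths)
        simple <- Filter(function(p) p$simple && p$depth == y, paths)
        cplx <- Filter(function(p) !(p$simple && p$depth == y), paths)
        if (length(simple) > 0L && !store_simple) {
          boundaries <- c(boundaries, merge_simple_paths(simple, x$seqs))
        }
        solved_complex <- c(solved_complex, cplx,
                            if (store_simple) simple)
      }
      # refined paths that were re-solved are replaced by the new decomposition
      if (length(ref$refined) > 0L) {
        rkeys <- unlist(lapply(ref$refined, function(p) edge_key(p$edges)))
        store <- Filter(function(p) !any(edge_key(p$edges) %in% rkeys), store)
      }
      store <- c(store, solved_complex)
    }
  }
  motifs <- c(lapply(boundaries, identity),
              lapply(store, complex_to_motif, seqs = x$seqs))
  motifs <- absorb_nested(motifs)
  motifs <- enforce_order_consistency(motifs)
  list(motifs = order_motifs(motifs), boundaries = boundaries, store = store)
}

# refined paths belonging to a subgraph region: paths whose layer-1 interval
# does not touch a boundary and falls in the same region as the subgraph
paths_in_region <- function(refined, sub, bnds, y) {
  if (length(refined) == 0L) return(list())
  if (length(bnds) == 0L || nrow(sub$edges) == 0L) return(refined)
  ordb <- bnds[order(vapply(bnds, function(b) b$pos[1L], integer(1)))]
  b1s <- vapply(ordb, function(b) b$pos[1L], integer(1))
  b1e <- vapply(ordb, function(b) b$pos[1L] + b$len - 1L, integer(1))
  if (!any(sub$edges$li == 1L)) return(list())
  sub_anchor <- min(sub$edges$from[sub$edges$li == 1L])
  sub_reg <- region_index(sub_anchor, 1L, b1s, b1e)
  Filter(function(p) {
    a <- min(p$edges$from[p$edges$li == 1L])
    len <- p$edges$len[1L]
    r <- region_index(a, len, b1s, b1e)
    !is.na(r) && !is.na(sub_reg) && r == sub_reg
  }, refined)
}

# cross-k absorption: a motif wholly inside another motif's anchor span with
# no greater depth is absorbed by it
absorb_nested <- function(motifs) {
  if (length(motifs) <= 1L) return(motifs)
  a_start <- vapply(motifs, function(m) m$occ$start[1L], integer(1))
  a_end <- vapply(motifs, function(m) m$occ$end[1L], integer(1))
  depth <- vapply(motifs, `[[`, integer(1), "depth")
  keep <- rep(TRUE, length(motifs))
  for (i in seq_along(motifs)) {
    for (j in seq_along(motifs)) {
      if (i == j || !keep[i] || !keep[j]) next
      if (a_start[i] >= a_start[j] && a_end[i] <= a_end[j] &&
          depth[i] <= depth[j] &&
          (a_end[i] - a_start[i]) < (a_end[j] - a_start[j])) {
        keep[i] <- FALSE
      }
    }
  }
  motifs[keep]
}

# End-to-end non-intersection: passes at different k values are solved
# independently, so a shallow motif selected at a longer k can invert order
# with a deeper motif discovered later at a shorter k. Deeper (then longer,
# then leftmost) motifs take priority; shallower motifs whose occurrences
# strictly invert order against a kept motif in any shared layer are dropped.
# Repeat networks (complex motifs) are exempt, mirroring the relaxation of
# the crossing constraint for identical k-mers.
enforce_order_consistency <- function(motifs) {
  if (length(motifs) <= 1L) return(motifs)
  depth <- vapply(motifs, `[[`, integer(1), "depth")
  len <- vapply(motifs, `[[`, integer(1), "len")
  a1 <- vapply(motifs, function(m) m$occ$start[m$occ$layer == 1L][1L],
               integer(1))
  ord <- order(-depth, -len, a1)
  kept <- list()
  for (i in ord) {
    mi <- motifs[[i]]
    ok <- TRUE
    if (mi$simple) {
      for (mj in kept) {
        if (!mj$simple || mi$seq == mj$seq) next
        shared <- intersect(mi$occ$layer, mj$occ$layer)
        ai <- mi$occ$start[mi$occ$layer == 1L][1L]
        aj <- mj$occ$start[mj$occ$layer == 1L][1L]
        for (l in shared) {
          si <- mi$occ$start[mi$occ$layer == l][1L]
          sj <- mj$occ$start[mj$occ$layer == l][1L]
          if ((ai - aj) * (si - sj) < 0L) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) kept[[length(kept) + 1L]] <- mi
  }
  kept
}

# ---- 5'/3' extension discovery ---------------------------------------------

#' Discover motifs in extended 5' and 3' regions
#'
#' Layers whose first (last) primary motif lies unusually far from the 5'
#' (3') end relative to the median across layers are taken to carry extended
#' ends; separate graphs restricted to the regions upstream of the first
#' motif / downstream of the last motif of the qualifying layers are built and
#' solved. The stage is skipped entirely unless the anchor sequence
#' contributes extension nodes.
#'
#' @param sol a primary `motif_solution`.
#' @param x the [ortho_set()] the solution was computed on.
#' @param tolerance tolerance `t`: a layer qualifies for 5' extraction when
#'   its first-motif start exceeds `t` times the median first-motif start, and
#'   for 3' extraction when its relative last-motif end is below the median
#'   relative end times `1 + t`.
#' @param min_depth optional: boundary positions are taken from motifs
#'   conserved to at least this depth.
#' @return list of additional motifs with `source` `"5p"` or `"3p"`.
#' @export
discover_extensions <- function(sol, x, tolerance = 0.5, min_depth = NULL) {
  motifs <- sol$motifs
  if (!is.null(min_depth)) motifs <- Filter(function(m) m$depth >= min_depth, motifs)
  if (length(motifs) == 0L) return(list())
  D <- length(x)
  lens <- seq_lengths(x)
  q <- r <- rep(NA_integer_, D)
  for (l in seq_len(D)) {
    st <- unlist(lapply(motifs, function(m) m$occ$start[m$occ$layer == l]))
    en <- unlist(lapply(motifs, function(m) m$occ$end[m$occ$layer == l]))
    if (length(st) > 0L) { q[l] <- min(st); r[l] <- max(en) }
  }
  out <- list()
  opts <- sol$options
  # 5' side
  Mq <- median(q, na.rm = TRUE)
  qual5 <- which(!is.na(q) & q > tolerance * Mq & q > 1L)
  if (1L %in% qual5 && length(qual5) >= 2L) {
    sub <- subset_ortho(x, qual5)
    sub$seqs <- substr(sub$seqs, 1L, q[qual5] - 1L)
    sub$exon_ends <- vector("list", length(qual5))
    out <- c(out, run_extension(sub, qual5, offset = rep(0L, length(qual5)),
                                source = "5p", opts))
  }
  # 3' side
  Re <- r / lens
  MRe <- median(Re, na.rm = TRUE)
  qual3 <- which(!is.na(r) & Re < MRe * (1 + tolerance) & r < lens)
  if (1L %in% qual3 && length(qual3) >= 2L) {
    sub <- subset_ortho(x, qual3)
    sub$seqs <- substr(sub$seqs, r[qual3] + 1L, lens[qual3])
    sub$exon_ends <- vector("list", length(qual3))
    out <- c(out, run_extension(sub, qual3, offset = r[qual3],
                                source = "3p", opts))
  }
  out
}

run_extension <- function(sub, layer_ids, offset, source, opts) {
  if (min(nchar(sub$seqs)) < opts$k_min) return(list())
  res <- tryCatch(
    run_core(sub, min(opts$k_max, min(nchar(sub$seqs))), opts$k_min,
             opts$max_repeats, opts$max_edges, hsps = NULL, y_floor = 2L),
    error = function(e) NULL)
  if (is.null(res)) return(list())
  lapply(res$motifs, function(m) {
    m$source <- source
    m$layers <- layer_ids[m$occ$layer]
    m$occ$start <- m$occ$start + offset[m$occ$layer]
    m$occ$end <- m$occ$end + offset[m$occ$layer]
    m$occ$layer <- layer_ids[m$occ$layer]
    m$pos <- m$occ$start[!duplicated(m$occ$layer)]
    m
  })
}

#' @export
print.motif_solution <- function(x, ...) {
  cat(sprintf("motif_solution: %d motifs over %d layers\n",
              length(x$motifs), length(x$dataset)))
  for (m in x$motifs) {
    cat(sprintf("  %-18s len=%-3d depth=%-2d %s anchor@%d\n",
                m$seq, m$len, m$depth, m$source, m$occ$start[1L]))
  }
  invisible(x)
}
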