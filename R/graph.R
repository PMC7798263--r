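# Layered k-mer graph: one layer per sequence, one node per k-mer window,
# edges between identical k-mers in consecutive layers. Node identity is
# (layer, start, length); start positions are 1-based inclusive.

node_key <- function(layer, pos, len) {
  if (length(pos) == 0L) return(character(0))
  paste(layer, pos, len, sep = ":")
}

# Valid k-mer start positions of a sequence (windows containing only A/C/G/T)
# together with the k-mer strings.
layer_kmer_table <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(data.frame(pos = integer(), kmer = character()))
  chars <- strsplit(seq, "")[[1]]
  bad <- cumsum(!(chars %in% ACGT))
  starts <- 1:(n - k + 1L)
  ok <- (bad[starts + k - 1L] - c(0L, bad)[starts]) == 0L
  starts <- starts[ok]
  data.frame(pos = starts, kmer = substring(seq, starts, starts + k - 1L),
             stringsAsFactors = FALSE)
}

new_kmer_graph <- function(edges, dataset, k, excluded = character(),
                           hsp_active = FALSE) {
  rownames(edges) <- NULL
  structure(list(edges = edges, D = length(dataset),
                 lens = seq_lengths(dataset), seqs = dataset$seqs,
                 labels = dataset$labels, k = k, excluded = excluded,
                 hsp_active = hsp_active),
            class = "kmer_graph")
}

empty_edges <- function() {
  data.frame(li = integer(), from = integer(), to = integer(),
             kmer = character(), len = integer(), stringsAsFactors = FALSE)
}

#' Build the layered k-mer graph for an ordered homolog set
#'
#' One node per valid k-mer window per layer; windows containing non-ACGT
#' characters are skipped. A k-mer occurring more than `max_repeats` times in
#' any single layer is excluded from all layers (and recorded in the returned
#' graph). Edges connect identical k-mers in consecutive layers only. If HSP
#' constraints are supplied, an edge is kept only when both of its nodes are
#' fully contained within the two sides of the same HSP of that layer pair
#' (layer pairs with no HSPs are unrestricted).
#'
#' @param x an [ortho_set()].
#' @param k motif length (>= 2; 6 is the documented practical minimum).
#' @param max_repeats maximum per-layer occurrence count before a k-mer is
#'   excluded everywhere.
#' @param hsps optional `hsp_set` from [compute_hsps()] or [read_hsp_table()].
#' @return a `kmer_graph` with an edge table (`li`, `from`, `to`, `kmer`,
#'   `len`): `li` is the source layer, `from`/`to` are 1-based start
#'   positions in layers `li` and `li + 1`.
#' @export
build_kmer_graph <- function(x, k, max_repeats = 15L, hsps = NULL) {
  k <- as.integer(k)
  stopifnot(k >= 2L, max_repeats >= 1L)
  if (k > min(seq_lengths(x))) stop("k longer than the shortest sequence")
  D <- length(x)
  tabs <- lapply(x$seqs, layer_kmer_table, k = k)
  counts <- lapply(tabs, function(t) table(t$kmer))
  excluded <- unique(unlist(lapply(counts, function(ct) names(ct)[ct > max_repeats])))
  if (length(excluded) > 0L) {
    tabs <- lapply(tabs, function(t) t[!(t$kmer %in% excluded), , drop = FALSE])
  }
  ed <- vector("list", D - 1L)
  for (i in seq_len(D - 1L)) {
    t1 <- tabs[[i]]; t2 <- tabs[[i + 1L]]
    common <- intersect(t1$kmer, t2$kmer)
    if (length(common) == 0L) { ed[[i]] <- empty_edges(); next }
    p1 <- split(t1$pos[t1$kmer %in% common], t1$kmer[t1$kmer %in% common])
    p2 <- split(t2$pos[t2$kmer %in% common], t2$kmer[t2$kmer %in% common])
    parts <- lapply(common, function(km) {
      g <- expand.grid(from = p1[[km]], to = p2[[km]], KEEP.OUT.ATTRS = FALSE)
      g$kmer <- km
      g
    })
    e <- do.call(rbind, parts)
    e <- data.frame(li = i, from = e$from, to = e$to, kmer = e$kmer,
                    len = k, stringsAsFactors = FALSE)
    if (!is.null(hsps) && nrow(hsps[[i]]) > 0L) {
      h <- hsps[[i]]
      keep <- rep(FALSE, nrow(e))
      for (r in seq_len(nrow(h))) {
        keep <- keep | (e$from >= h$start1[r] & e$from + k - 1L <= h$end1[r] &
                        e$to >= h$start2[r] & e$to + k - 1L <= h$end2[r])
      }
      e <- e[keep, , drop = FALSE]
    }
    ed[[i]] <- e
  }
  edges <- do.call(rbind, ed)
  if (is.null(edges)) edges <- empty_edges()
  edges <- edges[order(edges$li, edges$from, edges$to), , drop = FALSE]
  new_kmer_graph(edges, x, k, excluded = excluded,
                 hsp_active = !is.null(hsps))
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat(sprintf("kmer_graph: k=%s, %d layers, %d edges", x$k, x$D, nrow(x$edges)))
  if (length(x$excluded)) cat(sprintf(", %d repeat-excluded k-mers", length(x$excluded)))
  cat("\n")
  invisible(x)
}

#' Prune a layered graph to paths reaching a given depth
#'
#' Restricts the graph to layers `1..depth` and keeps only edges lying on at
#' least one chain of edges from layer 1 to layer `depth`.
#'
#' @param g a `kmer_graph`.
#' @param depth target depth `y` (2 <= y <= D).
#' @return a reduced copy of `g` with `D = depth`.
#' @export
prune_to_depth <- function(g, depth) {
  stopifnot(depth >= 2L, depth <= g$D)
  e <- g$edges[g$edges$li < depth, , drop = FALSE]
  if (nrow(e) > 0L) {
    # forward reachability from layer 1 (layer-1 nodes are all reachable)
    fwd <- unique(node_key(1L, e$from[e$li == 1L], e$len[e$li == 1L]))
    for (i in seq_len(depth - 1L)) {
      sub <- e[e$li == i, , drop = FALSE]
      src_ok <- if (i == 1L) rep(TRUE, nrow(sub)) else
        node_key(i, sub$from, sub$len) %in% fwd
      fwd <- unique(c(fwd, node_key(i + 1L, sub$to[src_ok], sub$len[src_ok])))
    }
    # backward: source nodes that can reach layer `depth`
    bwd <- character()
    for (i in rev(seq_len(depth - 1L))) {
      sub <- e[e$li == i, , drop = FALSE]
      dst_ok <- if (i == depth - 1L) rep(TRUE, nrow(sub)) else
        node_key(i + 1L, sub$to, sub$len) %in% bwd
      bwd <- unique(c(bwd, node_key(i, sub$from[dst_ok], sub$len[dst_ok])))
    }
    src_fwd <- e$li == 1L | node_key(e$li, e$from, e$len) %in% fwd
    dst_bwd <- e$li == depth - 1L | node_key(e$li + 1L, e$to, e$len) %in% bwd
    src_bwd <- node_key(e$li, e$from, e$len) %in% bwd
    e <- e[src_fwd & dst_bwd & src_bwd, , drop = FALSE]
  }
  g2 <- g
  g2$edges <- e
  g2$D <- depth
  g2$lens <- g$lens[seq_len(depth)]
  g2$seqs <- g$seqs[seq_len(depth)]
  g2$labels <- g$labels[seq_len(depth)]
  g2
}
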