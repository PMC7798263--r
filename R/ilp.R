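# Integer linear program over a layered graph: binary variable per edge,
# objective = number of selected edges, subject to
#   C1 crossing:  x_a + x_b <= 1 for inter-layer edge pairs with inverted
#                 endpoint order (same-k-mer repeat networks are exempt unless
#                 a different-k-mer candidate path crosses the network),
#   C2 flow:      sum(out) == sum(in) for nodes in layers strictly between 1
#                 and the minimum depth y (the big-M scaled inequalities of
#                 the formulation reduce to this equality),
#   C3 merge:     x_a + x_b <= 1 for adjacent overlapping-k-mer edge pairs
#                 whose overlap offsets differ between the two layers,
#   C4 favored:   sum over a favored path's layer-1->2 edges >= 1.

edge_key <- function(e) paste(e$li, e$from, e$to, e$len, sep = ":")

#' Formulate the path-selection integer program for a layered graph
#'
#' @param g a `kmer_graph`, pruned to `min_depth` (see [prune_to_depth()]).
#' @param min_depth minimum depth `y`: flow-balance constraints are imposed on
#'   nodes in layers `2..y-1`, so only paths connected from layer 1 down to at
#'   least layer `y` can be selected.
#' @param favored optional list of paths (as returned in a `path_set`); for
#'   each, at least one of its layer-1 to layer-2 edges must be selected.
#' @return an `ilp_problem`.
#' @export
formulate_ilp <- function(g, min_depth, favored = NULL) {
  e <- g$edges
  rownames(e) <- NULL
  n <- nrow(e)
  conflicts <- matrix(integer(), 0L, 2L)
  if (n > 1L) {
    parts <- list()
    for (i in unique(e$li)) {
      idx <- which(e$li == i)
      if (length(idx) < 2L) next
      m <- e$from[idx]; q <- e$to[idx]; len <- e$len[idx]; km <- e$kmer[idx]
      dm <- outer(m, m, function(x, y) y - x)   # dm[a,b] = m_b - m_a
      dq <- outer(q, q, function(x, y) y - x)
      cross <- (dm > 0L & dq < 0L) | (dm < 0L & dq > 0L)
      samek <- outer(km, km, "==")
      # repeat networks: same-k-mer crossings constrained only when a
      # different-k-mer edge crosses an edge of that network
      crossed_kmers <- unique(c(km[rowSums(cross & !samek) > 0L]))
      c1 <- cross & (!samek | matrix(km %in% crossed_kmers, length(idx),
                                     length(idx)))
      lenA <- matrix(len, length(idx), length(idx))
      ovl <- ((dm >= 1L & dm <= lenA - 1L) | (dq >= 1L & dq <= lenA - 1L)) &
        (dm != dq)
      bad <- c1 | ovl | t(ovl)
      bad[lower.tri(bad, diag = TRUE)] <- FALSE
      w <- which(bad, arr.ind = TRUE)
      if (nrow(w) > 0L)
        parts[[length(parts) + 1L]] <- cbind(idx[w[, 1L]], idx[w[, 2L]])
    }
    if (length(parts) > 0L) conflicts <- do.call(rbind, parts)
  }
  # flow balance for middle-layer nodes
  flows_in <- list(); flows_out <- list()
  mid <- seq_len(max(0L, min_depth - 2L)) + 1L  # layers 2..y-1
  for (l in mid) {
    inn <- which(e$li == l - 1L)
    out <- which(e$li == l)
    keys <- unique(c(node_key(l, e$to[inn], e$len[inn]),
                     node_key(l, e$from[out], e$len[out])))
    for (kk in keys) {
      iv <- inn[node_key(l, e$to[inn], e$len[inn]) == kk]
      ov <- out[node_key(l, e$from[out], e$len[out]) == kk]
      if (length(iv) + length(ov) == 0L) next
      flows_in[[length(flows_in) + 1L]] <- iv
      flows_out[[length(flows_out) + 1L]] <- ov
    }
  }
  covers <- list()
  if (!is.null(favored) && length(favored) > 0L) {
    keys <- edge_key(e)
    for (p in favored) {
      pe <- p$edges[p$edges$li == 1L, , drop = FALSE]
      hit <- which(keys %in% edge_key(pe))
      if (length(hit) == 0L)
        stop("favored path has no surviving layer-1 to layer-2 edge")
      covers[[length(covers) + 1L]] <- hit
    }
  }
  structure(list(n = n, edges = e, conflicts = conflicts,
                 flows_in = flows_in, flows_out = flows_out,
                 covers = covers, min_depth = min_depth, big_m = 100),
            class = "ilp_problem")
}

#' Solve a formulated path-selection program exactly
#'
#' Decomposes the program into independent components and solves each with an
#' exact branch-and-bound search; the proven optimal objective and a
#' deterministic optimal assignment are returned, decomposed into maximal
#' connected paths classified as simple (one node per spanned layer) or
#' complex.
#'
#' @param prob an `ilp_problem` from [formulate_ilp()].
#' @return a `path_set`: list with `objective`, `edges` (selected edge table)
#'   and `paths` (each with `edges`, `depth`, `simple`, `k`).
#' @export
solve_ilp <- function(prob) {
  n <- prob$n
  if (n == 0L)
    return(structure(list(objective = 0L, edges = empty_edges(),
                          paths = list()), class = "path_set"))
  comp <- constraint_components(prob)
  assignment <- rep(1L, n)  # unconstrained variables are always selected
  for (vars in comp) {
    map <- match(seq_len(n), vars)
    cf <- prob$conflicts[prob$conflicts[, 1L] %in% vars, , drop = FALSE]
    cf2 <- matrix(map[cf], ncol = 2L)
    fi <- list(); fo <- list()
    for (t in seq_along(prob$flows_in)) {
      iv <- prob$flows_in[[t]]; ov <- prob$flows_out[[t]]
      if (length(iv) + length(ov) == 0L) next
      if (any(c(iv, ov) %in% vars)) {
        fi[[length(fi) + 1L]] <- map[iv]
        fo[[length(fo) + 1L]] <- map[ov]
      }
    }
    cv <- list()
    for (s in prob$covers) {
      if (any(s %in% vars)) cv[[length(cv) + 1L]] <- map[s]
    }
    res <- .bnb_solve(length(vars), cf2, fi, fo, cv)
    assignment[vars] <- res$assignment
  }
  sel <- prob$edges[assignment == 1L, , drop = FALSE]
  structure(list(objective = sum(assignment), edges = sel,
                 paths = decompose_paths(sel)), class = "path_set")
}

# Connected components of variables over shared constraints.
constraint_components <- function(prob) {
  n <- prob$n
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  uni <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  if (nrow(prob$conflicts) > 0L)
    for (r in seq_len(nrow(prob$conflicts)))
      uni(prob$conflicts[r, 1L], prob$conflicts[r, 2L])
  link_set <- function(s) if (length(s) > 1L) for (t in s[-1L]) uni(s[1L], t)
  for (t in seq_along(prob$flows_in))
    link_set(c(prob$flows_in[[t]], prob$flows_out[[t]]))
  for (s in prob$covers) link_set(s)
  roots <- vapply(seq_len(n), find, integer(1))
  grp <- split(seq_len(n), roots)
  grp[vapply(grp, length, integer(1)) > 1L |
        vapply(grp, function(v) constrained_var(prob, v[1L]), logical(1))]
}

constrained_var <- function(prob, v) {
  v %in% prob$conflicts ||
    any(vapply(prob$flows_in, function(s) v %in% s, logical(1))) ||
    any(vapply(prob$flows_out, function(s) v %in% s, logical(1))) ||
    any(vapply(prob$covers, function(s) v %in% s, logical(1)))
}

# Decompose a selected edge table into maximal connected paths (components
# over shared nodes), each classified simple/complex with its depth.
decompose_paths <- function(sel) {
  ne <- nrow(sel)
  if (ne == 0L) return(list())
  src <- node_key(sel$li, sel$from, sel$len)
  dst <- node_key(sel$li + 1L, sel$to, sel$len)
  nodes <- unique(c(src, dst))
  parent <- seq_along(nodes)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  si <- match(src, nodes); di <- match(dst, nodes)
  for (r in seq_len(ne)) {
    ra <- find(si[r]); rb <- find(di[r])
    if (ra != rb) parent[ra] <- rb
  }
  comp <- vapply(si, find, integer(1))
  lapply(split(seq_len(ne), comp), function(idx) {
    pe <- sel[idx, , drop = FALSE]
    pe <- pe[order(pe$li, pe$from, pe$to), , drop = FALSE]
    depth <- max(pe$li) + 1L
    per_layer <- table(c(pe$li, pe$li + 1L)[!duplicated(c(node_key(pe$li, pe$from, pe$len),
                                                          node_key(pe$li + 1L, pe$to, pe$len)))])
    simple <- all(per_layer == 1L)
    list(edges = pe, depth = depth, simple = simple, k = pe$len[1L],
         kmer = pe$kmer[1L])
  })
}

#' Dump a formulated program in LP format
#'
#' Writes the objective and the crossing/merge, flow-balance and coverage
#' constraints of an `ilp_problem` in CPLEX LP format, as a debugging aid and
#' for cross-checking with external solvers.
#'
#' @param prob an `ilp_problem` from [formulate_ilp()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ilp_lp <- function(prob, path) {
  v <- function(i) paste0("x", i)
  lines <- c("Maximize", paste(" obj:", paste(v(seq_len(prob$n)),
                                              collapse = " + ")),
             "Subject To")
  if (nrow(prob$conflicts) > 0L) {
    lines <- c(lines, sprintf(" c%d: %s + %s <= 1",
                              seq_len(nrow(prob$conflicts)),
                              v(prob$conflicts[, 1L]),
                              v(prob$conflicts[, 2L])))
  }
  for (t in seq_along(prob$flows_in)) {
    lhs <- if (length(prob$flows_out[[t]]) > 0L)
      paste(v(prob$flows_out[[t]]), collapse = " + ") else "0 x1"
    rhs <- if (length(prob$flows_in[[t]]) > 0L)
      paste(paste0("- ", v(prob$flows_in[[t]])), collapse = " ") else ""
    lines <- c(lines, sprintf(" f%d: %s %s = 0", t, lhs, rhs))
  }
  for (t in seq_along(prob$covers)) {
    lines <- c(lines, sprintf(" g%d: %s >= 1", t,
                              paste(v(prob$covers[[t]]), collapse = " + ")))
  }
  lines <- c(lines, "Binary", paste("", paste(v(seq_len(prob$n)),
                                              collapse = " ")), "End")
  writeLines(lines, path)
  invisible(path)
}

#' Exhaustive optimum of a small layered graph
#'
#' Enumerates all 2^|E| assignments and returns the maximal feasible objective
#' under the crossing, flow-balance and merge-consistency constraint
#' semantics. Intended as an independent check of the branch-and-bound solver
#' on small graphs.
#'
#' @param g a `kmer_graph` with at most 20 edges, pruned to `min_depth`.
#' @param min_depth minimum depth `y`.
#' @return the optimal objective value (integer).
#' @export
brute_force_optimum <- function(g, min_depth) {
  prob <- formulate_ilp(g, min_depth)
  n <- prob$n
  if (n == 0L) return(0L)
  if (n > 20L) stop("graph too large for enumeration (", n, " edges)")
  masks <- 0:(2^n - 1L)
  ok <- rep(TRUE, length(masks))
  if (nrow(prob$conflicts) > 0L) {
    for (r in seq_len(nrow(prob$conflicts))) {
      pm <- bitwOr(bitwShiftL(1L, prob$conflicts[r, 1L] - 1L),
                   bitwShiftL(1L, prob$conflicts[r, 2L] - 1L))
      ok <- ok & bitwAnd(masks, pm) != pm
    }
  }
  popcount <- function(v) {
    s <- integer(length(v))
    while (any(v > 0L)) { s <- s + bitwAnd(v, 1L); v <- bitwShiftR(v, 1L) }
    s
  }
  for (t in seq_along(prob$flows_in)) {
    im <- sum(bitwShiftL(1L, prob$flows_in[[t]] - 1L))
    om <- sum(bitwShiftL(1L, prob$flows_out[[t]] - 1L))
    ok <- ok & popcount(bitwAnd(masks, im)) == popcount(bitwAnd(masks, om))
  }
  for (s in prob$covers) {
    cm <- sum(bitwShiftL(1L, s - 1L))
    ok <- ok & bitwAnd(masks, cm) != 0L
  }
  if (!any(ok)) stop("infeasible program")
  max(popcount(masks[ok]))
}
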