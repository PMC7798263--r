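# Empirical significance of discovered motifs under two null models:
#   - MSA column shuffle: permute the columns of a multiple sequence
#     alignment of the input (gaps travel with their column), then strip gaps
#     row-wise. Per-row length and composition and the inter-row identity
#     structure are preserved.
#   - dinucleotide shuffle: per layer, a random sequence with identical
#     length and the exact dinucleotide multiset (Eulerian-walk shuffle);
#     inter-layer identity is not preserved.

#' Multiple sequence alignment of a homolog set
#'
#' Uses MAFFT when available on the PATH (the default), otherwise an internal
#' center-star progressive aligner built on [Biostrings::pairwiseAlignment()]
#' with a once-a-gap-always-a-gap merge against the anchor.
#'
#' @param x an [ortho_set()].
#' @param provider `"mafft"`, `"internal"`, or `NULL` to auto-detect.
#' @return list with `matrix` (character matrix of aligned residues and
#'   `"-"`, one row per layer) and `provider`.
#' @export
msa_align <- function(x, provider = NULL) {
  if (is.null(provider)) {
    provider <- if (nzchar(Sys.which("mafft"))) "mafft" else "internal"
  }
  provider <- match.arg(provider, c("mafft", "internal"))
  mat <- if (provider == "mafft") msa_mafft(x) else msa_center_star(x)
  stopifnot(nrow(mat) == length(x))
  list(matrix = mat, provider = provider)
}

msa_mafft <- function(x) {
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  tmp <- x
  tmp$labels <- paste0("s", seq_along(x$seqs))
  write_ortho_fasta(tmp, fin)
  status <- suppressWarnings(
    system2("mafft", c("--retree", "2", "--quiet", shQuote(fin)),
            stdout = fout, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(fout) || file.size(fout) == 0)
    stop("MSA failure: mafft did not produce an alignment")
  aln <- Biostrings::readBStringSet(fout)
  aln <- aln[match(tmp$labels, names(aln))]
  do.call(rbind, strsplit(toupper(as.character(aln)), ""))
}

# Internal center-star fallback: align every sequence to the anchor and merge
# the pairwise alignments on the anchor coordinate system.
msa_center_star <- function(x) {
  D <- length(x)
  anchor <- x$seqs[1L]
  n <- nchar(anchor)
  if (D == 1L) return(matrix(strsplit(anchor, "")[[1]], nrow = 1L))
  mat_sub <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                      baseOnly = FALSE)
  ins <- matrix(0L, D, n + 1L)  # insertions before anchor position i (slot n+1 = after)
  rows <- vector("list", D)
  aligned <- vector("list", D)
  for (j in 2:D) {
    pa <- Biostrings::pairwiseAlignment(x$seqs[j], anchor, type = "global",
                                        substitutionMatrix = mat_sub,
                                        gapOpening = 5, gapExtension = 2)
    ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    slot <- 1L; run <- character(); segs <- vector("list", n + 1L)
    chars <- character(n)
    for (t in seq_along(as_)) {
      if (as_[t] == "-") {
        run <- c(run, ap[t])
      } else {
        segs[[slot]] <- run; run <- character()
        chars[slot] <- ap[t]
        slot <- slot + 1L
      }
    }
    segs[[n + 1L]] <- run
    ins[j, ] <- pmax(ins[j, ], vapply(segs, length, integer(1)))
    aligned[[j]] <- list(segs = segs, chars = chars)
  }
  width <- pmax(0L, apply(ins, 2L, max))
  total <- sum(width) + n
  build_row <- function(segs, chars) {
    out <- character(0)
    for (i in seq_len(n + 1L)) {
      s <- segs[[i]]
      pad <- width[i] - length(s)
      out <- c(out, s, rep("-", pad), if (i <= n) chars[i])
    }
    out
  }
  mat <- matrix("-", D, total)
  mat[1L, ] <- build_row(rep(list(character()), n + 1L), strsplit(anchor, "")[[1]])
  for (j in 2:D) mat[j, ] <- build_row(aligned[[j]]$segs, aligned[[j]]$chars)
  mat
}

#' Shuffle the columns of a multiple sequence alignment
#'
#' Permutes alignment columns uniformly at random (gap characters travel with
#' their column) and deletes gaps row-wise, returning sequences with the same
#' per-row length and composition and the same pairwise column-identity
#' structure as the input.
#'
#' @param x an [ortho_set()].
#' @param msa optional precomputed result of [msa_align()] (recomputed
#'   otherwise). Uses the current RNG state; call `set.seed()` for
#'   reproducibility.
#' @param provider passed to [msa_align()] when `msa` is missing.
#' @return an `ortho_set` of shuffled sequences with the input labels.
#' @export
shuffle_msa_columns <- function(x, msa = NULL, provider = NULL) {
  if (is.null(msa)) msa <- msa_align(x, provider = provider)
  m <- msa$matrix[, sample.int(ncol(msa$matrix)), drop = FALSE]
  seqs <- apply(m, 1L, function(r) paste(r[r != "-"], collapse = ""))
  ortho_set(seqs, labels = x$labels)
}

#' Dinucleotide-preserving shuffle of one sequence
#'
#' Exact-preserving Eulerian-walk shuffle: the returned sequence has identical
#' length and the exact dinucleotide multiset of the input.
#'
#' @param s a nucleotide string (length >= 2 for a non-trivial shuffle).
#' @return a shuffled string.
#' @export
dinucleotide_shuffle_seq <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 3L) return(s)
  verts <- unique(ch)
  vi <- match(ch, verts)
  nv <- length(verts)
  out_edges <- split(vi[-1L], vi[-n])           # successors per vertex
  out_edges <- lapply(seq_len(nv), function(v) {
    e <- out_edges[[as.character(v)]]
    if (is.null(e)) integer() else e
  })
  last_v <- vi[n]
  # pick a random last out-edge per vertex such that every vertex reaches the
  # final vertex through the chosen last edges (spanning in-tree condition)
  active <- which(vapply(out_edges, length, integer(1)) > 0L)
  for (attempt in seq_len(10000L)) {
    last_edge <- rep(NA_integer_, nv)
    for (v in active) {
      if (v == last_v && length(out_edges[[v]]) == 0L) next
      last_edge[v] <- out_edges[[v]][sample.int(length(out_edges[[v]]), 1L)]
    }
    ok <- TRUE
    for (v in setdiff(active, last_v)) {
      cur <- v; steps <- 0L
      while (!is.na(cur) && cur != last_v && steps <= nv) {
        cur <- last_edge[cur]; steps <- steps + 1L
      }
      if (is.na(cur) || cur != last_v) { ok <- FALSE; break }
    }
    if (ok) break
  }
  if (!ok) return(s)
  shuffled <- lapply(seq_len(nv), function(v) {
    e <- out_edges[[v]]
    if (length(e) == 0L) return(e)
    if (!is.na(last_edge[v]) && v != last_v) {
      drop1 <- match(last_edge[v], e)
      rest <- e[-drop1]
      c(if (length(rest) > 0L) rest[sample.int(length(rest))] else integer(),
        last_edge[v])
    } else {
      e[sample.int(length(e))]
    }
  })
  ptr <- rep(1L, nv)
  res <- integer(n)
  res[1L] <- vi[1L]
  cur <- vi[1L]
  for (i in 2:n) {
    nxt <- shuffled[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(verts[res], collapse = "")
}

#' Dinucleotide-preserving shuffle of a homolog set
#'
#' Applies [dinucleotide_shuffle_seq()] independently to every layer: lengths
#' and exact dinucleotide count vectors are preserved per layer, inter-layer
#' identity is not.
#'
#' @param x an [ortho_set()].
#' @return a shuffled `ortho_set`.
#' @export
dinucleotide_shuffle <- function(x) {
  ortho_set(vapply(x$seqs, dinucleotide_shuffle_seq, character(1)),
            labels = x$labels)
}

#' Empirical P values for discovered motifs
#'
#' Runs the full discovery engine (same k range and options as the observed
#' solution) on null replicates and reports, for each observed motif conserved
#' to depth d: `p_exact`, the pseudo-counted probability of finding the
#' precise motif conserved to at least d in a null replicate, and
#' `p_combination`, the probability of finding at least as many motifs of the
#' same length or greater conserved to at least d.
#'
#' @param x the input [ortho_set()].
#' @param sol the observed `motif_solution` from [discover_motifs()].
#' @param iterations number of null replicates (pseudo-count convention
#'   `(r + 1) / (iterations + 1)`, so P values are never 0).
#' @param null `"msa"` (column shuffle, preserves inter-layer identity) or
#'   `"dinucleotide"`.
#' @param seed optional RNG seed fixing the whole computation.
#' @param msa_provider passed to [msa_align()] for the `"msa"` null.
#' @param max_retries replicates whose engine run fails are redrawn at most
#'   this many times (then counted as containing no motifs).
#' @return a `significance_report` data.frame: one row per observed motif
#'   with `seq`, `len`, `depth`, `source`, `p_exact`, `p_combination`.
#' @export
empirical_pvalues <- function(x, sol, iterations = 100L,
                              null = c("msa", "dinucleotide"), seed = NULL,
                              msa_provider = NULL, max_retries = 3L) {
  null <- match.arg(null)
  stopifnot(iterations >= 1L)
  if (!is.null(seed)) set.seed(seed)
  msa <- if (null == "msa") msa_align(x, provider = msa_provider) else NULL
  opts <- sol$options
  run1 <- function(ds) {
    s <- discover_motifs(ds, k_max = opts$k_max, k_min = opts$k_min,
                         max_repeats = opts$max_repeats,
                         max_edges = opts$max_edges, hsp = FALSE,
                         min_depth = opts$min_depth,
                         tolerance = opts$tolerance,
                         extensions = opts$extensions,
                         exhaustive = isTRUE(opts$exhaustive))
    motif_table(s)
  }
  null_tabs <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    tab <- NULL
    for (try in seq_len(max_retries)) {
      nds <- if (null == "msa") shuffle_msa_columns(x, msa = msa)
             else dinucleotide_shuffle(x)
      tab <- tryCatch(run1(nds), error = function(e) NULL)
      if (!is.null(tab)) break
    }
    if (is.null(tab)) tab <- motif_table(NULL)
    null_tabs[[it]] <- tab
  }
  obs <- motif_table(sol)
  p_exact <- p_comb <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    S <- obs$seq[i]; d <- obs$depth[i]; L <- obs$len[i]
    c_obs <- length(unique(obs$seq[obs$len >= L & obs$depth >= d]))
    hit_e <- vapply(null_tabs, function(t)
      any(t$depth >= d & grepl(S, t$seq, fixed = TRUE)), logical(1))
    hit_c <- vapply(null_tabs, function(t)
      length(unique(t$seq[t$len >= L & t$depth >= d])) >= c_obs, logical(1))
    p_exact[i] <- (1 + sum(hit_e)) / (iterations + 1)
    p_comb[i] <- (1 + sum(hit_c)) / (iterations + 1)
  }
  rep <- data.frame(seq = obs$seq, len = obs$len, depth = obs$depth,
                    source = obs$source, p_exact = p_exact,
                    p_combination = p_comb)
  attr(rep, "iterations") <- iterations
  attr(rep, "null") <- null
  class(rep) <- c("significance_report", "data.frame")
  rep
}

# flat motif table of a solution (NULL -> empty table)
motif_table <- function(sol) {
  if (is.null(sol) || length(sol$motifs) == 0L)
    return(data.frame(seq = character(), len = integer(), depth = integer(),
                      source = character(), anchor_start = integer()))
  data.frame(
    seq = vapply(sol$motifs, `[[`, character(1), "seq"),
    len = vapply(sol$motifs, `[[`, integer(1), "len"),
    depth = vapply(sol$motifs, `[[`, integer(1), "depth"),
    source = vapply(sol$motifs, `[[`, character(1), "source"),
    anchor_start = vapply(sol$motifs, function(m) m$occ$start[1L], integer(1)))
}

#' Enrichment of a motif pattern against the dinucleotide null
#'
#' Counts occurrences of an IUPAC pattern (e.g. `WGCAUGA`) in the input
#' sequences and in random sequence sets matching each layer's length and
#' exact dinucleotide composition.
#'
#' @param x an [ortho_set()].
#' @param pattern an IUPAC nucleotide pattern (RNA alphabet accepted).
#' @param iterations number of null sequence sets.
#' @param seed optional RNG seed.
#' @return list with `observed` (mean occurrences per input sequence),
#'   `expected` (mean per sequence over null sets) and `p_value`
#'   (pseudo-counted fraction of null sets with total count >= observed
#'   total).
#' @export
motif_enrichment <- function(x, pattern, iterations = 1000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pattern <- normalize_residues(pattern)
  count_set <- function(seqs) {
    sum(Biostrings::vcountPattern(pattern, Biostrings::DNAStringSet(seqs),
                                  fixed = FALSE))
  }
  obs_total <- count_set(x$seqs)
  null_tot <- vapply(seq_len(iterations), function(i) {
    count_set(vapply(x$seqs, dinucleotide_shuffle_seq, character(1)))
  }, numeric(1))
  list(observed = obs_total / length(x),
       expected = mean(null_tot) / length(x),
       p_value = (1 + sum(null_tot >= obs_total)) / (iterations + 1))
}
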