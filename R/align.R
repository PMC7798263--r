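# Built-in ungapped local alignment (seed-and-extend over shared words, exact
# maximal-segment extraction per diagonal) with BLASTN-like scoring
# (match +2 / mismatch -3) and a Karlin-Altschul E-value approximation.
# Used for sequence ordering and for deriving HSP edge constraints; an
# external aligner can be substituted by injecting an HSP table
# (see read_hsp_table).

.align_cache <- new.env(parent = emptyenv())

# Ungapped lambda for match +2 / mismatch -3 on uniform base composition:
# solves sum_ij p_i p_j exp(lambda * s_ij) = 1.
ka_lambda <- function() {
  if (is.null(.align_cache$lambda)) {
    f <- function(l) 0.25 * exp(2 * l) + 0.75 * exp(-3 * l) - 1
    .align_cache$lambda <- uniroot(f, c(1e-6, 2), tol = 1e-10)$root
  }
  .align_cache$lambda
}

# K is sequence-composition dependent; 0.3 is an adequate constant for the
# threshold decisions made here (ordering fallback, HSP retention).
KA_K <- 0.3

#' Expected chance spacing of a fixed k-mer
#'
#' Under a uniform base composition a fixed k-mer occurs once every `4^k`
#' positions on average, e.g. roughly every 4 kb for a 6-mer — the scale on
#' which two unrelated sequences share short k-mers purely by chance.
#'
#' @param k motif length.
#' @param alphabet_size residue alphabet size (4 for nucleotides).
#' @return expected number of nucleotides per chance occurrence.
#' @export
expected_chance_spacing <- function(k, alphabet_size = 4) {
  alphabet_size^k
}

#' Karlin-Altschul E-value of an ungapped local alignment score
#' @param score raw alignment score (match +2, mismatch -3).
#' @param m,n lengths of the two sequences.
#' @return approximate expected number of chance alignments with >= score.
#' @export
karlin_evalue <- function(score, m, n) {
  KA_K * as.numeric(m) * as.numeric(n) * exp(-ka_lambda() * score)
}

# All ungapped local alignment segments between two sequences with score above
# `min_score`, found on diagonals that contain at least one shared word of
# length `word`. Returns a data.frame(start1, end1, start2, end2, score).
ungapped_segments <- function(s1, s2, word = 7L, min_score = 20L,
                              match = 2L, mismatch = -3L) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  m <- length(a); n <- length(b)
  empty <- data.frame(start1 = integer(), end1 = integer(), start2 = integer(),
                      end2 = integer(), score = integer())
  if (m < word || n < word) return(empty)
  w1 <- substring(s1, 1:(m - word + 1L), word:m)
  w2 <- substring(s2, 1:(n - word + 1L), word:n)
  hit <- match(w1, w2)
  has <- which(!is.na(hit))
  if (length(has) == 0L) return(empty)
  diags <- unique(has - hit[has])  # i - j
  out <- vector("list", length(diags))
  for (t in seq_along(diags)) {
    d <- diags[t]
    i0 <- max(1L, 1L + d); i1 <- min(m, n + d)
    ai <- a[i0:i1]; bj <- b[(i0 - d):(i1 - d)]
    sc <- ifelse(ai == bj, match, mismatch)
    segs <- max_segments(sc, min_score)
    if (nrow(segs) > 0L) {
      out[[t]] <- data.frame(start1 = i0 + segs$from - 1L,
                             end1 = i0 + segs$to - 1L,
                             start2 = i0 - d + segs$from - 1L,
                             end2 = i0 - d + segs$to - 1L,
                             score = segs$score)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) empty else res
}

# Recursive maximal-subarray extraction: the best-scoring segment of `sc`,
# then (disjointly) of the flanks, down to min_score.
max_segments <- function(sc, min_score) {
  n <- length(sc)
  if (n == 0L) return(data.frame(from = integer(), to = integer(), score = integer()))
  best <- -Inf; cur <- 0; cs <- 1L; bf <- 1L; bt <- 0L
  for (i in seq_len(n)) {
    if (cur <= 0) { cur <- 0; cs <- i }
    cur <- cur + sc[i]
    if (cur > best) { best <- cur; bf <- cs; bt <- i }
  }
  if (best < min_score)
    return(data.frame(from = integer(), to = integer(), score = integer()))
  left <- max_segments(sc[seq_len(bf - 1L)], min_score)
  right <- max_segments(if (bt < n) sc[(bt + 1L):n] else integer(), min_score)
  if (nrow(right) > 0L) { right$from <- right$from + bt; right$to <- right$to + bt }
  rbind(left, data.frame(from = bf, to = bt, score = as.integer(best)), right)
}

# Best single ungapped local hit between two sequences (score 0 if none).
best_local_hit <- function(s1, s2, word = 7L) {
  segs <- ungapped_segments(s1, s2, word = word, min_score = 2L * word)
  if (nrow(segs) == 0L) return(list(score = 0))
  segs[which.max(segs$score), , drop = FALSE][1, , drop = TRUE]
}

#' Compute high-scoring segment pair (HSP) constraints between consecutive layers
#'
#' For each consecutive layer pair, significant ungapped local alignments are
#' computed with the built-in aligner and de-redundified: among mutually
#' overlapping HSPs only the most significant pair is retained (lowest
#' E-value, ties broken by higher raw score, then leftmost source start), and
#' a source segment keeps at most one target segment.
#'
#' @param x an [ortho_set()].
#' @param evalue maximum E-value for an HSP to be considered significant.
#' @param word seed word length for the internal aligner.
#' @return an `hsp_set`: a list with one data.frame per consecutive layer
#'   pair (`start1, end1, start2, end2, score, evalue`). An empty data.frame
#'   means "no restriction derivable for that pair".
#' @export
compute_hsps <- function(x, evalue = 1e-3, word = 7L) {
  D <- length(x)
  out <- vector("list", D - 1L)
  for (i in seq_len(D - 1L)) {
    segs <- ungapped_segments(x$seqs[i], x$seqs[i + 1L], word = word)
    if (nrow(segs) > 0L) {
      segs$evalue <- karlin_evalue(segs$score, nchar(x$seqs[i]), nchar(x$seqs[i + 1L]))
      segs <- segs[segs$evalue < evalue, , drop = FALSE]
      segs <- dedup_hsps(segs)
    } else {
      segs$evalue <- numeric()
    }
    out[[i]] <- segs
  }
  structure(out, class = "hsp_set")
}

# Keep a mutually non-overlapping, one-target-per-source subset, most
# significant first.
dedup_hsps <- function(segs) {
  if (nrow(segs) <= 1L) return(segs)
  ord <- order(segs$evalue, -segs$score, segs$start1)
  segs <- segs[ord, , drop = FALSE]
  keep <- logical(nrow(segs))
  for (r in seq_len(nrow(segs))) {
    ok <- TRUE
    for (s in which(keep)) {
      if (segs$start1[r] <= segs$end1[s] && segs$end1[r] >= segs$start1[s]) { ok <- FALSE; break }
      if (segs$start2[r] <= segs$end2[s] && segs$end2[r] >= segs$start2[s]) { ok <- FALSE; break }
    }
    keep[r] <- ok
  }
  res <- segs[keep, , drop = FALSE]
  res[order(res$start1), , drop = FALSE]
}

#' Read an HSP constraint table from a tab-delimited file
#'
#' Columns: `layer_i, start_i, end_i, layer_j, start_j, end_j, score, evalue`
#' with `layer_j == layer_i + 1` and 1-based inclusive coordinates. This lets
#' users inject constraints derived from external aligner output (e.g., BLAST
#' outfmt 6).
#'
#' @param path file path.
#' @param D number of layers in the dataset the constraints apply to.
#' @return an `hsp_set` (see [compute_hsps()]).
#' @export
read_hsp_table <- function(path, D) {
  tb <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("layer_i", "start_i", "end_i", "layer_j",
                                 "start_j", "end_j", "score", "evalue"))
  if (any(tb$layer_j != tb$layer_i + 1L)) stop("HSP rows must link consecutive layers")
  out <- vector("list", D - 1L)
  for (i in seq_len(D - 1L)) {
    sub <- tb[tb$layer_i == i, , drop = FALSE]
    out[[i]] <- dedup_hsps(data.frame(start1 = sub$start_i, end1 = sub$end_i,
                                      start2 = sub$start_j, end2 = sub$end_j,
                                      score = sub$score, evalue = sub$evalue))
  }
  structure(out, class = "hsp_set")
}
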