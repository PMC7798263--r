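# Synthetic benchmark generator: random background layers with planted
# ordered motifs of known depth, plus the disruptive features real homolog
# sets show — lineage-specific insertion blocks, 5' truncations and point
# substitutions — with a ground-truth table of every planted occurrence.

#' Specify a synthetic planted-motif benchmark
#'
#' @param motifs character vector of motif strings to plant (DNA or RNA; RNA
#'   is normalized to DNA).
#' @param depths integer vector, same length: motif `j` is planted, in order,
#'   in layers `1..depths[j]`.
#' @param n_layers number of layers D.
#' @param length background length per layer before insertions (recycled to
#'   `n_layers`).
#' @param insertions integer vector (recycled): length of one extra
#'   lineage-specific random block inserted at a random inter-motif position
#'   of each layer (0 = none).
#' @param truncate numeric vector (recycled): fraction of each layer's 5' end
#'   removed after construction (0 = none).
#' @param subst_rate per-base substitution probability applied to non-motif
#'   positions.
#' @param background `"uniform"` i.i.d. bases or `"markov"` (first-order
#'   chain fitted to `markov_template`).
#' @param markov_template template sequence for the Markov background.
#' @param seed RNG seed used by [generate_planted()].
#' @return a `plant_spec`.
#' @export
plant_spec <- function(motifs, depths, n_layers, length = 1000L,
                       insertions = 0L, truncate = 0, subst_rate = 0,
                       background = c("uniform", "markov"),
                       markov_template = NULL, seed = NULL) {
  background <- match.arg(background)
  motifs <- normalize_residues(motifs)
  stopifnot(length(motifs) == length(depths), all(depths >= 1L),
            all(depths <= n_layers), n_layers >= 2L, subst_rate >= 0,
            subst_rate < 1)
  lens <- rep_len(as.integer(length), n_layers)
  if (any(sum(nchar(motifs)) >= lens)) stop("motifs longer than background")
  structure(list(motifs = motifs, depths = as.integer(depths),
                 n_layers = as.integer(n_layers), lens = lens,
                 insertions = rep_len(as.integer(insertions), n_layers),
                 truncate = rep_len(truncate, n_layers),
                 subst_rate = subst_rate, background = background,
                 markov_template = markov_template, seed = seed),
            class = "plant_spec")
}

rand_bases <- function(n, spec) {
  if (n <= 0L) return("")
  if (spec$background == "uniform") {
    paste(sample(ACGT, n, replace = TRUE), collapse = "")
  } else {
    tm <- markov_matrix(spec$markov_template)
    out <- character(n)
    out[1L] <- sample(ACGT, 1L)
    for (i in seq_len(n - 1L))
      out[i + 1L] <- sample(ACGT, 1L, prob = tm[out[i], ])
    paste(out, collapse = "")
  }
}

markov_matrix <- function(template) {
  template <- normalize_residues(template)
  ch <- strsplit(template, "")[[1]]
  ch <- ch[ch %in% ACGT]
  tm <- matrix(1, 4, 4, dimnames = list(ACGT, ACGT))  # +1 smoothing
  for (i in seq_len(length(ch) - 1L))
    tm[ch[i], ch[i + 1L]] <- tm[ch[i], ch[i + 1L]] + 1
  tm / rowSums(tm)
}

#' Generate a planted-motif benchmark dataset
#'
#' Deterministic given the spec's seed. Planted motifs appear in identical
#' order in every layer down to their intended depth; the truth table lists
#' every planted occurrence, re-readable from the returned sequences.
#'
#' @param spec a [plant_spec()].
#' @return list with `dataset` (an [ortho_set()]) and `truth`
#'   (data.frame `layer`, `start`, `end`, `motif`, `name`).
#' @export
generate_planted <- function(spec) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  D <- spec$n_layers
  seqs <- character(D)
  truth <- list()
  for (l in seq_len(D)) {
    idx <- which(spec$depths >= l)
    mot <- spec$motifs[idx]
    mlen <- nchar(mot)
    nm <- length(mot)
    total_gap <- spec$lens[l] - sum(mlen)
    base <- min(10L, total_gap %/% (nm + 1L))
    w <- runif(nm + 1L)
    extra <- total_gap - base * (nm + 1L)
    gaps <- base + floor(w / sum(w) * extra)
    gaps[nm + 1L] <- gaps[nm + 1L] + (total_gap - sum(gaps))
    pieces <- character(2L * nm + 1L)
    starts <- integer(nm)
    pos <- 0L
    for (j in seq_len(nm)) {
      pieces[2L * j - 1L] <- rand_bases(gaps[j], spec)
      pos <- pos + gaps[j]
      starts[j] <- pos + 1L
      pieces[2L * j] <- mot[j]
      pos <- pos + mlen[j]
    }
    pieces[2L * nm + 1L] <- rand_bases(gaps[nm + 1L], spec)
    s <- paste(pieces, collapse = "")
    ends <- starts + mlen - 1L
    # lineage-specific insertion at a random non-motif position
    ins <- spec$insertions[l]
    if (ins > 0L) {
      allowed <- setdiff(0:nchar(s), unlist(mapply(function(a, b) (a - 1L):b,
                                                   starts, ends,
                                                   SIMPLIFY = FALSE)))
      at <- if (length(allowed) > 0L) sample(allowed, 1L) else nchar(s)
      s <- paste0(substr(s, 1L, at), rand_bases(ins, spec),
                  substr(s, at + 1L, nchar(s)))
      shift <- starts > at
      starts[shift] <- starts[shift] + ins
      ends[shift] <- ends[shift] + ins
    }
    # point substitutions outside motifs
    if (spec$subst_rate > 0) {
      ch <- strsplit(s, "")[[1]]
      protected <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))
      free <- setdiff(seq_along(ch), protected)
      hit <- free[runif(length(free)) < spec$subst_rate]
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(ACGT, b), 1L),
                        character(1))
      s <- paste(ch, collapse = "")
    }
    # 5' truncation
    if (spec$truncate[l] > 0) {
      cut <- floor(spec$truncate[l] * nchar(s))
      s <- substr(s, cut + 1L, nchar(s))
      keep <- starts > cut
      starts <- starts[keep] - cut; ends <- ends[keep] - cut
      idx <- idx[keep]; mot <- mot[keep]
      nm <- length(mot)
    }
    seqs[l] <- s
    if (nm > 0L)
      truth[[length(truth) + 1L]] <- data.frame(
        layer = l, start = starts, end = ends, motif = mot,
        name = paste0("m", idx))
  }
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(layer = integer(), start = integer(), end = integer(),
               motif = character(), name = character())
  rownames(truth) <- NULL
  list(dataset = ortho_set(seqs, labels = paste0("layer", seq_len(D))),
       truth = truth)
}

#' Write a generated benchmark to FASTA plus a truth table
#' @param gen result of [generate_planted()].
#' @param fasta,truth output file paths.
#' @return invisible NULL.
#' @export
write_planted <- function(gen, fasta, truth) {
  write_ortho_fasta(gen$dataset, fasta)
  write.table(gen$truth, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
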