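# Ordered dataset of homologous sequences ("layers"). The first sequence is
# the anchor/query; layer index equals position in the list.

ACGT <- c("A", "C", "G", "T")

normalize_residues <- function(x) {
  x <- toupper(x)
  gsub("U", "T", x, fixed = TRUE)
}

#' Construct an ordered set of homologous sequences
#'
#' The first entry is the anchor (query) sequence and defines layer 1; the
#' order of the remaining entries defines the layer order, ideally with
#' monotonically increasing evolutionary distance from the anchor.
#'
#' @param seqs character vector of nucleotide sequences. Lowercase letters are
#'   uppercased and `U` is mapped to `T`; other IUPAC letters are retained but
#'   no k-mer window may span them.
#' @param labels character vector of species/sequence identifiers; defaults to
#'   `names(seqs)` or `seq1..seqD`.
#' @param exon_ends optional list (one element per sequence) of strictly
#'   increasing 1-based positions of the last base of each non-terminal exon
#'   (exon-exon junction cut points).
#' @return An object of class `ortho_set`: a list with elements `labels`,
#'   `seqs` and `exon_ends`.
#' @export
ortho_set <- function(seqs, labels = NULL, exon_ends = NULL) {
  if (is.null(labels)) {
    labels <- if (!is.null(names(seqs))) names(seqs) else paste0("seq", seq_along(seqs))
  }
  seqs <- normalize_residues(as.character(seqs))
  if (length(seqs) < 2L) stop("fewer than two sequences")
  if (any(!nzchar(seqs))) stop("sequence empty after normalization")
  if (length(labels) != length(seqs)) stop("labels and seqs lengths differ")
  if (!is.null(exon_ends)) {
    if (length(exon_ends) != length(seqs)) stop("exon_ends must have one entry per sequence")
    for (i in seq_along(exon_ends)) {
      e <- exon_ends[[i]]
      if (is.null(e) || length(e) == 0L) next
      e <- as.integer(e)
      if (any(diff(e) <= 0L) || any(e < 1L) || any(e >= nchar(seqs[i])))
        stop("exon_ends must be strictly increasing and < sequence length")
      exon_ends[[i]] <- e
    }
  } else {
    exon_ends <- vector("list", length(seqs))
  }
  structure(list(labels = as.character(labels), seqs = unname(seqs),
                 exon_ends = exon_ends),
            class = "ortho_set")
}

#' @export
length.ortho_set <- function(x) length(x$seqs)

#' @export
print.ortho_set <- function(x, ...) {
  cat("ortho_set with", length(x), "layers\n")
  for (i in seq_along(x$seqs)) {
    cat(sprintf("  L%-2d %-20s %6d nt\n", i, x$labels[i], nchar(x$seqs[i])))
  }
  invisible(x)
}

#' Sequence lengths per layer
#' @param x an `ortho_set`
#' @return integer vector N(i) of per-layer sequence lengths.
#' @export
seq_lengths <- function(x) nchar(x$seqs)

#' Read an ordered homolog set from a FASTA file
#'
#' Records are kept in file order; the first record is the anchor. Sequences
#' are uppercased and `U` is mapped to `T`.
#'
#' @param path path to a (multi-)FASTA file with at least two records.
#' @return an [ortho_set()].
#' @export
read_ortho_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) < 2L) stop("fewer than two sequences in ", path)
  seqs <- as.character(ss)
  ortho_set(seqs, labels = names(ss))
}

#' Write an ordered homolog set to FASTA
#' @param x an `ortho_set`
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ortho_fasta <- function(x, path) {
  ss <- Biostrings::BStringSet(x$seqs)
  names(ss) <- x$labels
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Attach exon-junction annotations from a sidecar table
#'
#' The sidecar is tab-delimited text with two columns: sequence label and a
#' comma-separated list of 1-based junction positions (last base of each
#' non-terminal exon).
#'
#' @param x an `ortho_set`
#' @param path path to the sidecar file.
#' @return `x` with `exon_ends` filled for the listed labels.
#' @export
read_exon_junctions <- function(x, path) {
  tb <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("label", "junctions"))
  for (r in seq_len(nrow(tb))) {
    i <- match(tb$label[r], x$labels)
    if (is.na(i)) {
      warning("exon-junction label not in dataset: ", tb$label[r])
      next
    }
    e <- as.integer(strsplit(tb$junctions[r], ",")[[1]])
    if (any(diff(e) <= 0L) || any(e < 1L) || any(e >= nchar(x$seqs[i])))
      stop("invalid junction positions for ", tb$label[r])
    x$exon_ends[[i]] <- e
  }
  x
}

#' Remove redundant sequences from a homolog set
#'
#' Exact duplicate sequences are always removed (the earliest-listed copy
#' survives). If an identity threshold is given, pairwise percent identity is
#' computed from an MSA of the set and, within each group of sequences whose
#' identity exceeds the threshold, only the earliest-listed member is kept.
#' The anchor is never removed.
#'
#' @param x an `ortho_set`
#' @param identity optional fraction in (0, 1]; pairs with percent identity
#'   above this are collapsed to the earlier sequence.
#' @param msa_provider `"mafft"` or `"internal"`; see [msa_align()].
#' @return a filtered `ortho_set`.
#' @export
filter_redundant <- function(x, identity = NULL, msa_provider = NULL) {
  keep <- !duplicated(x$seqs)
  keep[1] <- TRUE
  x2 <- subset_ortho(x, which(keep))
  if (is.null(identity)) return(x2)
  if (!is.numeric(identity) || identity <= 0 || identity > 1)
    stop("identity threshold must be in (0, 1]")
  if (length(x2) < 2L) return(x2)
  aln <- msa_align(x2, provider = msa_provider)
  n <- nrow(aln$matrix)
  drop <- rep(FALSE, n)
  for (j in 2:n) {
    for (i in seq_len(j - 1L)) {
      if (drop[i]) next
      if (pair_identity(aln$matrix[i, ], aln$matrix[j, ]) > identity) {
        drop[j] <- TRUE
        break
      }
    }
  }
  subset_ortho(x2, which(!drop))
}

# Percent identity between two aligned rows: identical non-gap columns over
# the shorter ungapped length.
pair_identity <- function(a, b) {
  both <- a != "-" & b != "-"
  m <- sum(a[both] == b[both])
  m / max(1L, min(sum(a != "-"), sum(b != "-")))
}

subset_ortho <- function(x, idx) {
  structure(list(labels = x$labels[idx], seqs = x$seqs[idx],
                 exon_ends = x$exon_ends[idx]),
            class = "ortho_set")
}

#' Order sequences by chained pairwise similarity
#'
#' Greedy chain ordering: the anchor stays first; the second sequence is the
#' one with the highest local alignment score to the anchor, and each
#' subsequent sequence is the unordered one with the best score to the
#' previously placed sequence. If no alignment is significant, the next
#' available sequence in the original input order is taken.
#'
#' @param x an `ortho_set`
#' @param evalue significance cutoff for the fallback rule (an alignment with
#'   E-value above this does not count as significant).
#' @return a reordered `ortho_set` (a permutation fixing the anchor).
#' @export
order_by_similarity <- function(x, evalue = 0.05) {
  D <- length(x)
  if (D <= 2L) return(x)
  remaining <- seq(2L, D)
  order_idx <- 1L
  prev <- 1L
  while (length(remaining) > 0L) {
    scores <- vapply(remaining, function(j) {
      best_local_hit(x$seqs[prev], x$seqs[j])$score
    }, numeric(1))
    evs <- vapply(seq_along(remaining), function(t) {
      karlin_evalue(scores[t], nchar(x$seqs[prev]), nchar(x$seqs[remaining[t]]))
    }, numeric(1))
    sig <- evs < evalue
    pick <- if (any(sig)) remaining[which.max(ifelse(sig, scores, -Inf))] else remaining[1L]
    order_idx <- c(order_idx, pick)
    remaining <- setdiff(remaining, pick)
    prev <- pick
  }
  subset_ortho(x, order_idx)
}
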