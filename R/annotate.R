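# Functional annotation of discovered motifs: microRNA seed-site typing
# against a TargetScan-style family table, and overlap with user-supplied
# genomic intervals (e.g. CLIP peaks) after lifting anchor-layer motifs to
# genome coordinates through the exon structure of the query transcript.

revcomp_str <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Read a miRNA seed-family table
#'
#' Tab-delimited TargetScan-style flat file: family name in the first column
#' and the 7-nt seed region (miRNA positions 2-8) in the second; an optional
#' third column carries the conservation class. RNA alphabet is accepted and
#' normalized to DNA; malformed rows are skipped with a warning.
#'
#' @param path file path.
#' @return data.frame with `family`, `seed` (7-nt DNA) and `class`.
#' @export
read_seed_families <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L && grepl("family|seed", lines[1L], ignore.case = TRUE))
    lines <- lines[-1L]
  parts <- strsplit(lines, "\t")
  fam <- character(); seed <- character(); cls <- character()
  for (p in parts) {
    s <- if (length(p) >= 2L) normalize_residues(p[2L]) else ""
    if (nchar(s) != 7L || grepl("[^ACGT]", s)) {
      warning("skipping malformed seed-table row: ", paste(p, collapse = "\t"))
      next
    }
    fam <- c(fam, p[1L]); seed <- c(seed, s)
    cls <- c(cls, if (length(p) >= 3L) p[3L] else NA_character_)
  }
  data.frame(family = fam, seed = seed, class = cls)
}

#' Call miRNA seed sites within discovered motifs
#'
#' A site is called only when the complete 6-mer seed core (the reverse
#' complement of miRNA positions 2-7) lies wholly within the motif. The site
#' type is determined per layer from the motif together with one immediate
#' flanking base on each side: a match to seed position 8 upstream gives the
#' m8 variants, an `A` opposite miRNA position 1 downstream gives the A1
#' variants, both give an 8mer. The strongest type is reported
#' (8mer > 7mer-m8 = 7mer-A1 > 6mer); a flank falling outside the sequence is
#' marked end-truncated and cannot upgrade the site.
#'
#' @param sol a `motif_solution`.
#' @param families data.frame from [read_seed_families()].
#' @param x the [ortho_set()] the solution was computed on.
#' @return data.frame of site calls: `motif`, `layer`, `start`, `end` (core
#'   coordinates in the layer sequence), `family`, `site_type`,
#'   `end_truncated`.
#' @export
call_mirna_sites <- function(sol, families, x) {
  out <- list()
  cores <- revcomp_str(substr(families$seed, 1L, 6L))
  m8 <- chartr("ACGT", "TGCA", substr(families$seed, 7L, 7L))
  mseqs <- vapply(sol$motifs, `[[`, character(1), "seq")
  for (fi in seq_along(cores)) {
    hits <- gregexpr(cores[fi], mseqs, fixed = TRUE)
    for (mi in which(vapply(hits, `[`, integer(1), 1L) != -1L)) {
      m <- sol$motifs[[mi]]
      for (r in seq_len(nrow(m$occ))) {
        l <- m$occ$layer[r]
        seqlen <- nchar(x$seqs[l])
        for (p in as.integer(hits[[mi]])) {
          cs <- m$occ$start[r] + p - 1L
          ce <- cs + 5L
          if (ce > m$occ$end[r]) next  # core must lie inside the occurrence
          up_ok <- cs - 1L >= 1L
          dn_ok <- ce + 1L <= seqlen
          has_m8 <- up_ok && substr(x$seqs[l], cs - 1L, cs - 1L) == m8[fi]
          has_a1 <- dn_ok && substr(x$seqs[l], ce + 1L, ce + 1L) == "A"
          type <- if (has_m8 && has_a1) "8mer" else if (has_m8) "7mer-m8"
                  else if (has_a1) "7mer-A1" else "6mer"
          out[[length(out) + 1L]] <- data.frame(
            motif = m$seq, motif_index = mi, layer = l, start = cs, end = ce,
            family = families$family[fi], site_type = type,
            end_truncated = !(up_ok && dn_ok))
        }
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(motif = character(), motif_index = integer(),
                      layer = integer(), start = integer(), end = integer(),
                      family = character(), site_type = character(),
                      end_truncated = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- transcript/genome coordinate lifting ----------------------------------

#' Read the exon structure of the query transcript from a BED file
#'
#' Accepts a single BED12 record (blocks are the exons) or multiple BED6 rows
#' (one per exon, same strand). Exons must be non-overlapping and are sorted
#' by genome coordinate.
#'
#' @param path BED file path.
#' @return a `GRanges` of exons with a common strand.
#' @export
read_exon_bed <- function(path) {
  gr <- rtracklayer::import(path)
  if (length(gr) == 1L && !is.null(gr$blocks)) {
    ex <- rtracklayer::blocks(gr)[[1L]]
    ex <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                 IRanges::ranges(ex),
                                 strand = GenomicRanges::strand(gr))
  } else {
    ex <- gr
  }
  ex <- GenomicRanges::sort(ex, ignore.strand = TRUE)
  st <- unique(as.character(GenomicRanges::strand(ex)))
  if (length(st) != 1L || !(st %in% c("+", "-")))
    stop("exon BED must carry a single explicit strand")
  if (length(ex) > 1L &&
      any(GenomicRanges::start(ex)[-1L] <= GenomicRanges::end(ex)[-length(ex)]))
    stop("exon blocks must be sorted and non-overlapping")
  ex
}

#' Lift a transcript interval to genome coordinates
#'
#' Walks the exon blocks 5' to 3' (genome-descending for minus-strand
#' transcripts) and returns the genomic blocks covering the transcript
#' interval, split across exon junctions.
#'
#' @param tx_start,tx_end 1-based inclusive transcript coordinates.
#' @param exons a `GRanges` of exons from [read_exon_bed()].
#' @return a `GRanges` of genomic blocks whose widths sum to the interval
#'   length.
#' @export
lift_to_genome <- function(tx_start, tx_end, exons) {
  stopifnot(tx_start >= 1L, tx_end >= tx_start)
  minus <- as.character(GenomicRanges::strand(exons))[1L] == "-"
  ord <- if (minus) rev(seq_along(exons)) else seq_along(exons)
  widths <- GenomicRanges::width(exons)[ord]
  offs <- cumsum(c(0L, widths))[seq_along(widths)]
  if (tx_end > sum(widths)) stop("transcript interval beyond exon span")
  blocks <- list()
  for (t in seq_along(ord)) {
    es <- offs[t] + 1L; ee <- offs[t] + widths[t]
    s <- max(tx_start, es); e <- min(tx_end, ee)
    if (s > e) next
    ex <- exons[ord[t]]
    if (minus) {
      gstart <- GenomicRanges::end(ex) - (e - es)
      gend <- GenomicRanges::end(ex) - (s - es)
    } else {
      gstart <- GenomicRanges::start(ex) + (s - es)
      gend <- GenomicRanges::start(ex) + (e - es)
    }
    blocks[[length(blocks) + 1L]] <-
      GenomicRanges::GRanges(GenomicRanges::seqnames(ex),
                             IRanges::IRanges(gstart, gend),
                             strand = GenomicRanges::strand(ex))
  }
  do.call(c, blocks)
}

#' Project genomic blocks back to transcript coordinates
#'
#' Inverse of [lift_to_genome()]: returns the 1-based transcript interval
#' covered by the given genomic blocks.
#'
#' @param blocks a `GRanges` of genomic blocks lying within the exons.
#' @param exons a `GRanges` of exons from [read_exon_bed()].
#' @return integer vector `c(start, end)` in transcript coordinates.
#' @export
project_to_transcript <- function(blocks, exons) {
  minus <- as.character(GenomicRanges::strand(exons))[1L] == "-"
  ord <- if (minus) rev(seq_along(exons)) else seq_along(exons)
  widths <- GenomicRanges::width(exons)[ord]
  offs <- cumsum(c(0L, widths))[seq_along(widths)]
  tx <- integer()
  for (b in seq_along(blocks)) {
    gs <- GenomicRanges::start(blocks)[b]; ge <- GenomicRanges::end(blocks)[b]
    for (t in seq_along(ord)) {
      ex <- exons[ord[t]]
      if (gs > GenomicRanges::end(ex) || ge < GenomicRanges::start(ex)) next
      if (minus) {
        s <- offs[t] + (GenomicRanges::end(ex) - ge) + 1L
        e <- offs[t] + (GenomicRanges::end(ex) - gs) + 1L
      } else {
        s <- offs[t] + (gs - GenomicRanges::start(ex)) + 1L
        e <- offs[t] + (ge - GenomicRanges::start(ex)) + 1L
      }
      tx <- c(tx, s:e)
    }
  }
  c(min(tx), max(tx))
}

#' Annotate anchor-layer motifs with overlapping genomic intervals
#'
#' Lifts every anchor-layer motif occurrence to genome coordinates through
#' the query transcript's exon structure and reports overlapping peaks with
#' score (enrichment) at or above `min_enrichment`. Peaks covering more than
#' `broad_fraction` of the whole transcript are flagged, since their overlap
#' with any single motif is less informative.
#'
#' @param sol a `motif_solution`.
#' @param exon_bed path to the query transcript's exon BED (BED12 or BED6
#'   rows); block widths must sum to the anchor sequence length.
#' @param peaks_bed path to a BED file of intervals with scores.
#' @param min_enrichment minimum peak score retained.
#' @param broad_fraction transcript-coverage fraction above which a peak is
#'   flagged as a broad binder.
#' @return `sol` with `genome_track` (a `GRanges` of lifted motif blocks)
#'   and `annotations` (data.frame of motif/peak overlaps) attached.
#' @export
overlap_intervals <- function(sol, exon_bed, peaks_bed, min_enrichment = 2.0,
                              broad_fraction = 0.5) {
  exons <- read_exon_bed(exon_bed)
  txlen <- sum(GenomicRanges::width(exons))
  alen <- nchar(sol$dataset$seqs[1L])
  if (txlen != alen)
    stop("exon blocks sum to ", txlen, " nt but the anchor sequence has ",
         alen, " nt")
  blocks <- list(); ids <- integer()
  for (mi in seq_along(sol$motifs)) {
    occ <- sol$motifs[[mi]]$occ
    occ <- occ[occ$layer == 1L, , drop = FALSE]
    for (r in seq_len(nrow(occ))) {
      b <- lift_to_genome(occ$start[r], occ$end[r], exons)
      b$motif_index <- mi
      b$motif <- sol$motifs[[mi]]$seq
      b$depth <- sol$motifs[[mi]]$depth
      blocks[[length(blocks) + 1L]] <- b
    }
  }
  track <- if (length(blocks) > 0L) do.call(c, blocks) else
    GenomicRanges::GRanges()
  peaks <- rtracklayer::import(peaks_bed)
  if (is.null(peaks$score)) stop("peaks BED must carry a score column")
  peaks <- peaks[!is.na(peaks$score) & peaks$score >= min_enrichment]
  cover <- vapply(seq_along(peaks), function(p) {
    sum(GenomicRanges::width(GenomicRanges::intersect(
      peaks[p], exons, ignore.strand = TRUE))) / txlen
  }, numeric(1))
  broad <- cover > broad_fraction
  hits <- GenomicRanges::findOverlaps(track, peaks, ignore.strand = TRUE)
  ann <- data.frame(
    motif_index = track$motif_index[S4Vectors::queryHits(hits)],
    motif = track$motif[S4Vectors::queryHits(hits)],
    peak = if (!is.null(peaks$name))
      peaks$name[S4Vectors::subjectHits(hits)] else
        as.character(S4Vectors::subjectHits(hits)),
    score = peaks$score[S4Vectors::subjectHits(hits)],
    broad_binder = broad[S4Vectors::subjectHits(hits)])
  ann <- unique(ann)
  rownames(ann) <- NULL
  sol$genome_track <- track
  sol$annotations <- ann
  sol
}
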