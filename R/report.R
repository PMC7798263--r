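# Motif modules, neighborhoods and report rendering (text / JSON / HTML /
# genome-browser BED track).

#' Motif modules at each conservation depth
#'
#' A motif module is an ordered combination of at least two unique motifs
#' conserved in all layers down to a given depth; tandem repeats of a motif
#' are collapsed with a multiplicity count. Modules are computed per motif
#' source (primary, 5', 3' extension) at every depth from `min_depth` (or 2)
#' to the dataset depth.
#'
#' @param sol a `motif_solution`.
#' @param min_depth optional minimum depth at which modules are reported.
#' @return list of modules, each with `depth`, `source`, `motifs` (ordered
#'   unique motif strings) and `multiplicity`.
#' @export
compute_modules <- function(sol, min_depth = NULL) {
  D <- length(sol$dataset)
  d0 <- if (is.null(min_depth)) 2L else as.integer(min_depth)
  out <- list()
  tab <- motif_table(sol)
  if (nrow(tab) == 0L) return(out)
  for (src in unique(tab$source)) {
    for (d in seq(d0, D)) {
      sel <- tab[tab$source == src & tab$depth >= d, , drop = FALSE]
      if (nrow(sel) == 0L) next
      sel <- sel[order(sel$anchor_start), , drop = FALSE]
      runs <- rle(sel$seq)
      if (length(unique(runs$values)) < 2L) next
      out[[length(out) + 1L]] <- list(depth = d, source = src,
                                      motifs = runs$values,
                                      multiplicity = runs$lengths)
    }
  }
  out
}

#' Motif neighborhoods around merged anchor-layer regions
#'
#' All overlapping motif occurrences in the anchor layer are combined into
#' reference regions; every motif embedded in a reference region becomes a
#' member of that neighborhood, with its offset and flank lengths relative to
#' the reference sequence.
#'
#' @param sol a `motif_solution`.
#' @return list of neighborhoods, each with `reference` (merged anchor
#'   k-mer), `start`/`end` (anchor coordinates) and a `members` data.frame
#'   (`motif`, `depth`, `offset`, `left_flank`, `right_flank`).
#' @export
compute_neighborhoods <- function(sol) {
  if (length(sol$motifs) == 0L) return(list())
  a_start <- vapply(sol$motifs, function(m) m$occ$start[m$occ$layer == 1L][1L],
                    integer(1))
  a_end <- vapply(sol$motifs, function(m) m$occ$end[m$occ$layer == 1L][1L],
                  integer(1))
  ir <- IRanges::IRanges(a_start, a_end)
  red <- IRanges::reduce(ir)
  ov <- IRanges::findOverlaps(ir, red)
  anchor <- sol$dataset$seqs[1L]
  lapply(seq_along(red), function(r) {
    mem <- S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == r]
    rs <- IRanges::start(red)[r]; re <- IRanges::end(red)[r]
    members <- data.frame(
      motif = vapply(sol$motifs[mem], `[[`, character(1), "seq"),
      depth = vapply(sol$motifs[mem], `[[`, integer(1), "depth"),
      offset = a_start[mem] - rs,
      left_flank = a_start[mem] - rs,
      right_flank = re - a_end[mem])
    list(reference = substr(anchor, rs, re), start = rs, end = re,
         members = members)
  })
}

# fixed ordered palette, recycled past 20 depths
depth_palette <- function(n) {
  pal <- c("#D73027", "#F46D43", "#FDAE61", "#FEE090", "#A6D96A", "#66BD63",
           "#1A9850", "#006837", "#66C2A5", "#3288BD", "#5E4FA2", "#9E0142",
           "#C51B7D", "#DE77AE", "#8C510A", "#BF812D", "#35978F", "#01665E",
           "#542788", "#2D004B")
  pal[((seq_len(n) - 1L) %% length(pal)) + 1L]
}

#' Render a motif solution to report files
#'
#' Writes, per requested format: a tab-delimited motif table (with per-layer
#' positions and P values when available), module and neighborhood tables, a
#' machine-readable JSON dump of the full solution, an HTML report with
#' motifs colored by conservation depth and exon junctions marked, and a
#' genome-browser BED track (requires the exon BED used for coordinate
#' lifting).
#'
#' @param sol a `motif_solution`.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("text", "json", "html", "bed")`.
#' @param pvalues optional `significance_report` from [empirical_pvalues()].
#' @param sites optional site-call table from [call_mirna_sites()].
#' @param modules,neighborhoods optional precomputed summaries (computed
#'   otherwise).
#' @param exon_bed exon BED path, required for the `"bed"` format.
#' @return invisible character vector of written file paths.
#' @export
render_report <- function(sol, dir, formats = c("text", "json", "html"),
                          pvalues = NULL, sites = NULL, modules = NULL,
                          neighborhoods = NULL, exon_bed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  formats <- match.arg(formats, c("text", "json", "html", "bed"),
                       several.ok = TRUE)
  if (is.null(modules)) modules <- compute_modules(sol)
  if (is.null(neighborhoods)) neighborhoods <- compute_neighborhoods(sol)
  written <- character()
  tab <- motif_table(sol)
  if (nrow(tab) > 0L) {
    tab$occurrences <- vapply(sol$motifs, function(m)
      paste(sprintf("%d:%d-%d", m$occ$layer, m$occ$start, m$occ$end),
            collapse = ";"), character(1))
    if (!is.null(pvalues) && nrow(pvalues) == nrow(tab)) {
      tab$p_exact <- pvalues$p_exact
      tab$p_combination <- pvalues$p_combination
    }
  }
  if ("text" %in% formats) {
    f <- file.path(dir, "motifs.tsv")
    write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
    if (length(modules) > 0L) {
      mf <- file.path(dir, "modules.tsv")
      mtab <- do.call(rbind, lapply(modules, function(m)
        data.frame(depth = m$depth, source = m$source,
                   motifs = paste(sprintf("%sx%d", m$motifs, m$multiplicity),
                                  collapse = ";"))))
      write.table(mtab, mf, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, mf)
    }
    if (length(neighborhoods) > 0L) {
      nf <- file.path(dir, "neighborhoods.tsv")
      ntab <- do.call(rbind, lapply(seq_along(neighborhoods), function(i) {
        nb <- neighborhoods[[i]]
        data.frame(neighborhood = i, reference = nb$reference,
                   start = nb$start, end = nb$end,
                   motif = nb$members$motif, depth = nb$members$depth,
                   offset = nb$members$offset,
                   left_flank = nb$members$left_flank,
                   right_flank = nb$members$right_flank)
      }))
      write.table(ntab, nf, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, nf)
    }
    if (!is.null(sites) && nrow(sites) > 0L) {
      sf <- file.path(dir, "mirna_sites.tsv")
      write.table(sites, sf, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, sf)
    }
    if (!is.null(sol$annotations) && nrow(sol$annotations) > 0L) {
      af <- file.path(dir, "interval_annotations.tsv")
      write.table(sol$annotations, af, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      written <- c(written, af)
    }
  }
  if ("json" %in% formats) {
    f <- file.path(dir, "solution.json")
    write_solution_json(sol, f, pvalues = pvalues)
    written <- c(written, f)
  }
  if ("html" %in% formats) {
    f <- file.path(dir, "report.html")
    writeLines(render_html(sol, tab, modules, sites), f)
    written <- c(written, f)
  }
  if ("bed" %in% formats) {
    if (is.null(exon_bed)) stop("BED track output requires an exon BED")
    f <- file.path(dir, "motifs.bed")
    write_motif_bed(sol, exon_bed, f)
    written <- c(written, f)
  }
  invisible(written)
}

#' Serialize a motif solution to JSON
#' @param sol a `motif_solution`.
#' @param path output file.
#' @param pvalues optional `significance_report` merged into the dump.
#' @return `path`, invisibly.
#' @export
write_solution_json <- function(sol, path, pvalues = NULL) {
  motifs <- lapply(seq_along(sol$motifs), function(i) {
    m <- sol$motifs[[i]]
    x <- list(seq = m$seq, len = m$len, depth = m$depth, source = m$source,
              simple = m$simple, occ = m$occ)
    if (!is.null(pvalues) && nrow(pvalues) == length(sol$motifs)) {
      x$p_exact <- pvalues$p_exact[i]
      x$p_combination <- pvalues$p_combination[i]
    }
    x
  })
  obj <- list(labels = sol$dataset$labels, seqs = sol$dataset$seqs,
              options = sol$options, motifs = motifs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Load a motif solution from its JSON dump
#' @param path JSON file from [write_solution_json()].
#' @return a `motif_solution`.
#' @export
load_solution_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  ds <- ortho_set(unlist(obj$seqs), labels = unlist(obj$labels))
  motifs <- lapply(obj$motifs, function(m) {
    occ <- do.call(rbind, lapply(m$occ, function(r)
      data.frame(layer = as.integer(r$layer), start = as.integer(r$start),
                 end = as.integer(r$end))))
    list(seq = m$seq, len = as.integer(m$len), depth = as.integer(m$depth),
         source = m$source, simple = as.logical(m$simple), occ = occ,
         layers = occ$layer[!duplicated(occ$layer)],
         pos = occ$start[!duplicated(occ$layer)],
         k_base = as.integer(m$len))
  })
  opts <- lapply(obj$options, function(o) if (is.list(o)) unlist(o) else o)
  structure(list(dataset = ds, motifs = motifs, options = opts),
            class = "motif_solution")
}

render_html <- function(sol, tab, modules, sites) {
  D <- length(sol$dataset)
  depths <- sort(unique(tab$depth))
  pal <- setNames(depth_palette(length(depths)), depths)
  esc <- function(s) gsub("<", "&lt;", gsub("&", "&amp;", s))
  body <- c("<html><head><meta charset='utf-8'><style>",
            "body{font-family:monospace} .seq{word-wrap:break-word;",
            "max-width:120ch} .lab{font-weight:bold;margin-top:1em}",
            "td,th{padding:2px 8px;border:1px solid #ccc}",
            "</style></head><body>",
            sprintf("<h2>Conserved ordered motifs (%d layers)</h2>", D),
            "<h3>Depth legend</h3><p>")
  for (d in depths) {
    body <- c(body, sprintf(
      "<span style='background:%s'>&nbsp;depth %d&nbsp;</span> ", pal[as.character(d)], d))
  }
  body <- c(body, "</p>")
  for (l in seq_len(D)) {
    s <- sol$dataset$seqs[l]
    n <- nchar(s)
    cov <- character(n)  # color per position ("" = none)
    cov[] <- ""
    for (m in sol$motifs) {
      occ <- m$occ[m$occ$layer == l, , drop = FALSE]
      for (r in seq_len(nrow(occ))) {
        idx <- occ$start[r]:occ$end[r]
        cov[idx] <- pal[as.character(m$depth)]
      }
    }
    juncs <- sol$dataset$exon_ends[[l]]
    chars <- strsplit(s, "")[[1]]
    pieces <- character(0)
    run_col <- NA_character_
    buf <- character(0)
    flush <- function() {
      if (length(buf) == 0L) return(character(0))
      txt <- esc(paste(buf, collapse = ""))
      if (is.na(run_col) || run_col == "") txt
      else sprintf("<span style='background:%s'>%s</span>", run_col, txt)
    }
    for (i in seq_len(n)) {
      if (!identical(cov[i], run_col) && length(buf) > 0L) {
        pieces <- c(pieces, flush()); buf <- character(0)
      }
      run_col <- cov[i]
      buf <- c(buf, chars[i])
      if (!is.null(juncs) && i %in% juncs) {
        pieces <- c(pieces, flush(), "<b>|</b>"); buf <- character(0)
        run_col <- NA_character_
      }
    }
    pieces <- c(pieces, flush())
    body <- c(body,
              sprintf("<div class='lab'>L%d %s (%d nt)</div>", l,
                      esc(sol$dataset$labels[l]), n),
              sprintf("<div class='seq'>%s</div>", paste(pieces, collapse = "")))
  }
  if (nrow(tab) > 0L) {
    body <- c(body, "<h3>Motifs</h3><table><tr>",
              paste0("<th>", colnames(tab), "</th>", collapse = ""), "</tr>")
    for (r in seq_len(nrow(tab))) {
      body <- c(body, "<tr>",
                paste0("<td>", vapply(tab[r, ], as.character, character(1)),
                       "</td>", collapse = ""), "</tr>")
    }
    body <- c(body, "</table>")
  }
  if (!is.null(sites) && nrow(sites) > 0L) {
    body <- c(body, "<h3>miRNA seed sites</h3><table><tr>",
              paste0("<th>", colnames(sites), "</th>", collapse = ""), "</tr>")
    for (r in seq_len(nrow(sites))) {
      body <- c(body, "<tr>",
                paste0("<td>", vapply(sites[r, ], as.character, character(1)),
                       "</td>", collapse = ""), "</tr>")
    }
    body <- c(body, "</table>")
  }
  c(body, "</body></html>")
}

#' Write a genome-browser track of anchor-layer motifs
#'
#' Lifts anchor motifs to genome coordinates through the exon BED and writes
#' a BED9 track with `itemRgb` encoding conservation depth.
#'
#' @param sol a `motif_solution`.
#' @param exon_bed exon BED of the query transcript.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_motif_bed <- function(sol, exon_bed, path) {
  exons <- read_exon_bed(exon_bed)
  depths <- sort(unique(vapply(sol$motifs, `[[`, integer(1), "depth")))
  pal <- setNames(depth_palette(length(depths)), depths)
  hex2rgb <- function(h) paste(strtoi(substring(h, c(2, 4, 6), c(3, 5, 7)),
                                      16L), collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track name=conserved_motifs itemRgb=On"), con)
  for (m in sol$motifs) {
    occ <- m$occ[m$occ$layer == 1L, , drop = FALSE]
    for (r in seq_len(nrow(occ))) {
      blocks <- lift_to_genome(occ$start[r], occ$end[r], exons)
      for (b in seq_along(blocks)) {
        writeLines(sprintf("%s\t%d\t%d\t%s_d%d\t0\t%s\t%d\t%d\t%s",
                           as.character(GenomicRanges::seqnames(blocks))[b],
                           GenomicRanges::start(blocks)[b] - 1L,
                           GenomicRanges::end(blocks)[b],
                           m$seq, m$depth,
                           as.character(GenomicRanges::strand(blocks))[b],
                           GenomicRanges::start(blocks)[b] - 1L,
                           GenomicRanges::end(blocks)[b],
                           hex2rgb(pal[as.character(m$depth)])), con)
      }
    }
  }
  invisible(path)
}
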