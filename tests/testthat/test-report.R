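test_that("modules combine motifs per depth and collapse tandem repeats", {
  seqs <- c(strrep("A", 120), strrep("C", 120), strrep("G", 120),
            strrep("T", 120), strrep("AC", 60))
  sol <- toy_solution(seqs, list(
    list(seq = "GCAATAAA", depth = 5L, starts = c(10L, 12L, 14L, 16L, 18L)),
    list(seq = "TGTATAGC", depth = 5L, starts = c(40L, 42L, 44L, 46L, 48L)),
    list(seq = "TTGCAC", depth = 3L, starts = c(70L, 72L, 74L))))
  mods <- compute_modules(sol)
  d5 <- Filter(function(m) m$depth == 5L, mods)
  d3 <- Filter(function(m) m$depth == 3L, mods)
  expect_length(d5, 1L)
  expect_equal(d5[[1L]]$motifs, c("GCAATAAA", "TGTATAGC"))
  expect_equal(length(d3[[1L]]$motifs), 3L)
  # a single unique motif never forms a module
  solo <- toy_solution(seqs[1:2], list(list(seq = "GCAATAAA", depth = 2L,
                                            starts = c(5L, 7L))))
  expect_length(compute_modules(solo), 0L)
  # tandem repeats collapse with multiplicity
  tand <- toy_solution(seqs[1:2], list(
    list(seq = "GCAATAAA", depth = 2L, starts = c(5L, 7L)),
    list(seq = "GCAATAAA", depth = 2L, starts = c(30L, 33L)),
    list(seq = "TGTATAGC", depth = 2L, starts = c(60L, 62L))))
  m <- compute_modules(tand)[[1L]]
  expect_equal(m$motifs, c("GCAATAAA", "TGTATAGC"))
  expect_equal(m$multiplicity, c(2L, 1L))
})

test_that("neighborhoods group motifs by overlapping anchor regions", {
  seqs <- c(paste0("TT", "ACGTACGTACGT", strrep("C", 40)), strrep("A", 60),
            strrep("G", 60), strrep("T", 60), strrep("C", 60), strrep("AC", 30))
  sol <- toy_solution(seqs, list(
    list(seq = "ACGTACGTACGT", depth = 2L, starts = c(3L, 5L)),
    list(seq = "GTACGT", depth = 6L, starts = c(7L, 9L, 11L, 13L, 15L, 17L)),
    list(seq = "CCCCCC", depth = 2L, starts = c(30L, 32L))))
  nb <- compute_neighborhoods(sol)
  expect_length(nb, 2L)
  first <- nb[[1L]]
  expect_equal(first$reference, "ACGTACGTACGT")
  expect_equal(nrow(first$members), 2L)
  emb <- first$members[first$members$motif == "GTACGT", ]
  expect_equal(emb$offset, 4L)
  expect_equal(emb$left_flank, 4L)
  expect_equal(emb$right_flank, 2L)
  # the merged-overlap case: single reference, zero flanks
  one <- toy_solution(seqs[1:2], list(list(seq = "ACGTACGT", depth = 2L,
                                           starts = c(3L, 4L))))
  nb1 <- compute_neighborhoods(one)
  expect_length(nb1, 1L)
  expect_equal(nb1[[1L]]$members$left_flank, 0L)
  expect_equal(nb1[[1L]]$members$right_flank, 0L)
})

test_that("an empty solution renders valid, empty report files", {
  sol <- toy_solution(c("ACGTACGTAC", "TTTTGGGGCC"), list())
  d <- withr::local_tempdir()
  files <- render_report(sol, d, formats = c("text", "json", "html"))
  expect_true(file.exists(file.path(d, "motifs.tsv")))
  expect_true(file.exists(file.path(d, "solution.json")))
  expect_true(file.exists(file.path(d, "report.html")))
  back <- load_solution_json(file.path(d, "solution.json"))
  expect_length(back$motifs, 0L)
})

test_that("JSON round trip reproduces the solution", {
  gen <- make_planted(c("GCAATAAA", "TGTATAGC"), c(3L, 3L), 3L, len = 300L,
                      seed = 14L)
  sol <- discover_motifs(gen$dataset)
  d <- withr::local_tempdir()
  render_report(sol, d, formats = c("text", "json"))
  back <- load_solution_json(file.path(d, "solution.json"))
  expect_identical(synmotif:::motif_table(back), synmotif:::motif_table(sol))
  expect_identical(back$dataset$seqs, sol$dataset$seqs)
  # text and JSON agree on counts, depths and positions
  tab <- read.table(file.path(d, "motifs.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(tab), length(back$motifs))
  expect_equal(tab$depth, vapply(back$motifs, `[[`, integer(1), "depth"))
  # every reported position re-reads the motif from the input sequences
  for (m in back$motifs) {
    expect_true(all(substring(gen$dataset$seqs[m$occ$layer], m$occ$start,
                              m$occ$end) == m$seq))
  }
})

test_that("depth colors are distinct up to the palette size", {
  pal <- synmotif:::depth_palette(20L)
  expect_equal(length(unique(pal)), 20L)
  expect_equal(synmotif:::depth_palette(21L)[21L], pal[1L])
})

test_that("the genome track requires an exon BED and encodes depth colors", {
  ds <- ortho_set(c(hu = paste0(strrep("T", 10), "GCAATAAA", strrep("C", 22)),
                    mm = paste0("G", "GCAATAAA", strrep("A", 24))))
  sol <- discover_motifs(ds, k_max = 8L, k_min = 6L)
  d <- withr::local_tempdir()
  expect_error(render_report(sol, d, formats = "bed"), "exon BED")
  ebed <- file.path(d, "ex.bed")
  writeLines("chr1\t1000\t1040\ttx\t0\t+", ebed)
  render_report(sol, d, formats = "bed", exon_bed = ebed)
  lines <- readLines(file.path(d, "motifs.bed"))
  expect_gt(length(lines), 1L)
  fields <- strsplit(lines[2L], "\t")[[1L]]
  expect_length(fields, 9L)
  expect_match(fields[9L], "^\\d+,\\d+,\\d+$")
  expect_equal(as.integer(fields[2L]), 1000L + 11L - 1L)  # 0-based start
})
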