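test_that("read_gtf parses exon features into sorted transcript models", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t501\t600\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tx\texon\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t2";',
    'chr1\tx\texon\t501\t600\t.\t+\t.\tgene_id "g1"; transcript_id "t2";'),
    gtf)
  tx <- read_gtf(gtf)
  expect_length(tx, 2L)
  expect_equal(nrow(tx$t1$exons), 3L)
  expect_equal(nrow(tx$t2$exons), 2L)
  # out-of-order exon lines come back ascending, converted to 0-based
  expect_equal(tx$t1$exons[, "start"], c(100L, 300L, 500L))
  expect_equal(tx$t1$exons[, "end"], c(200L, 400L, 600L))
})

test_that("GTF written by the generator round-trips to identical models", {
  tr <- gen_transcriptome(21)
  gtf <- tempfile(fileext = ".gtf")
  write_gtf(tr$transcripts, gtf)
  back <- read_gtf(gtf)
  nm <- sort(names(tr$transcripts))
  expect_identical(nm, sort(names(back)))
  for (id in nm) {
    expect_identical(unname(tr$transcripts[[id]]$exons), unname(back[[id]]$exons))
    expect_identical(tr$transcripts[[id]]$strand, back[[id]]$strand)
    expect_identical(tr$transcripts[[id]]$gene_id, back[[id]]$gene_id)
  }
})

test_that("a single skipped internal exon yields exactly one CASSETTE event", {
  fx <- fixture_cassette()
  evs <- enumerate_events(fx$transcripts)
  expect_length(evs, 1L)
  expect_equal(evs[[1]]$category, "CASSETTE")
  # alt1 carries the cassette exon, alt2 is empty (skipping)
  expect_equal(nrow(evs[[1]]$alt1), 1L)
  expect_equal(nrow(evs[[1]]$alt2), 0L)
  expect_equal(evs[[1]]$flank5, 1200L)
  expect_equal(evs[[1]]$flank3, 2000L)
})

test_that("identical exon chains produce no events", {
  t1 <- transcript_model("a", "g", "c", "+", rbind(c(0, 100), c(200, 300)))
  t2 <- transcript_model("b", "g", "c", "+", rbind(c(0, 100), c(200, 300)))
  expect_length(enumerate_events(list(t1, t2)), 0L)
})

test_that("transcripts from different genes are rejected", {
  t1 <- transcript_model("a", "g1", "c", "+", rbind(c(0, 100)))
  t2 <- transcript_model("b", "g2", "c", "+", rbind(c(0, 100)))
  expect_error(enumerate_events(list(t1, t2)), "one gene")
})

test_that("catalog is invariant to transcript order and duplicated pairs", {
  tr <- gen_transcriptome(31)
  txs <- tr$transcripts
  gene <- txs[vapply(txs, function(t) t$gene_id == "G001", TRUE)]
  base <- enumerate_events(gene)
  rev_ <- enumerate_events(rev(gene))
  expect_identical(vapply(base, `[[`, "", "event_id"),
                   vapply(rev_, `[[`, "", "event_id"))
  # extra transcripts duplicating the same chains change nothing
  dup <- gene[[2]]; dup$transcript_id <- "G001.dup"
  trip <- enumerate_events(c(gene, list(dup)))
  expect_identical(vapply(base, `[[`, "", "event_id"),
                   vapply(trip, `[[`, "", "event_id"))
})

test_that("synthetic truth tables are recovered exactly with no spurious events", {
  for (seed in c(41, 42, 43)) {
    tr <- gen_transcriptome(seed)
    cata <- build_event_catalog(tr$transcripts)
    expect_identical(sort(cata$table$event_id), sort(tr$truth$event_id))
    got <- cata$table[match(tr$truth$event_id, cata$table$event_id), ]
    expect_identical(got$category, tr$truth$category)
    expect_identical(got$alt1, tr$truth$alt1)
    expect_identical(got$alt2, tr$truth$alt2)
    expect_equal(got$flank5, tr$truth$flank5, ignore_attr = TRUE)
  }
  # no events from single-isoform genes
  bg <- gen_transcriptome(44, events_per_category = c(CASSETTE = 0L),
                          n_background = 6, ese2_fixture = FALSE)
  expect_equal(nrow(build_event_catalog(bg$transcripts)$table), 0L)
})

test_that("mirroring gene coordinates swaps INTERNAL3 and INTERNAL5", {
  mirror_tx <- function(tx, span) {
    ex <- cbind(span - tx$exons[, 2], span - tx$exons[, 1])
    transcript_model(tx$transcript_id, tx$gene_id, tx$chrom, tx$strand,
                     ex[order(ex[, 1]), , drop = FALSE])
  }
  tr <- gen_transcriptome(51, events_per_category = c(CASSETTE = 1L,
                                                      INTERNAL3 = 1L,
                                                      INTERNAL5 = 1L,
                                                      MUT_EXCLU = 1L),
                          ese2_fixture = FALSE)
  genes <- split(tr$transcripts, vapply(tr$transcripts, `[[`, "", "gene_id"))
  span <- max(vapply(tr$transcripts, function(t) max(t$exons), 0)) + 1000
  swap <- c(CASSETTE = "CASSETTE", INTERNAL3 = "INTERNAL5",
            INTERNAL5 = "INTERNAL3", MUT_EXCLU = "MUT_EXCLU")
  for (gid in names(genes)) {
    orig <- enumerate_events(genes[[gid]])[[1]]
    mirr <- enumerate_events(lapply(genes[[gid]], mirror_tx, span = span))[[1]]
    expect_equal(mirr$category, unname(swap[orig$category]), label = gid)
  }
})

test_that("unique lengths follow the junction and exon-body position counts", {
  fx <- fixture_cassette(exon_len = 120L)
  ur <- compute_unique_regions(fx$event, read_len = 50L, min_overhang = 1L)

  # brute-force enumeration of skip-junction start positions: a 50 nt read
  # on the skipping isoform spans the junction iff it starts 1..49 nt before
  # the donor, with >= 1 nt on each side
  skp <- fx$transcripts$T2
  w <- skp$exons[, 2] - skp$exons[, 1]
  junction_at <- w[1]                       # transcript coordinate of junction
  L <- sum(w)
  starts <- 0:(L - 50L)
  # read [s, s+50) has >= 1 aligned nt on both sides of the boundary iff
  # s <= junction_at - 1 and s + 50 >= junction_at + 1
  spans <- sum(starts <= junction_at - 1L & starts + 50L >= junction_at + 1L)
  expect_equal(ur$unique_length2, 49L)
  expect_equal(ur$unique_length2, spans)

  # inclusion: two junctions (49 each) plus 120 - 50 + 1 = 71 in-exon starts
  expect_equal(ur$unique_length1, 2L * 49L + 71L)
  expect_gt(ur$unique_length1, ur$unique_length2)

  # m = L/2 boundary: each junction contributes exactly one position
  ur25 <- compute_unique_regions(fx$event, read_len = 50L, min_overhang = 25L)
  expect_equal(ur25$unique_length2, 1L)
  expect_error(compute_unique_regions(fx$event, read_len = 49L,
                                      min_overhang = 25L),
               "min_overhang")
})

test_that("alternative-specific segments of the two alternatives are disjoint", {
  tr <- gen_transcriptome(61)
  cata <- build_event_catalog(tr$transcripts)
  for (ur in cata$unique_regions) {
    if (!nrow(ur$segments1) || !nrow(ur$segments2)) next
    for (i in seq_len(nrow(ur$segments1)))
      for (j in seq_len(nrow(ur$segments2)))
        expect_true(ur$segments1[i, 2] <= ur$segments2[j, 1] ||
                    ur$segments2[j, 2] <= ur$segments1[i, 1])
  }
})
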