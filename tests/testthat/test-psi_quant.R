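sam_fixture <- function(lines, chrom = "chrT", len = 10000L) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", chrom, len), lines), path)
  path
}

test_that("read_sam reconstructs blocks from M/N CIGARs", {
  p <- sam_fixture(c(
    "r1\t0\tchrT\t101\t60\t50M\t*\t0\t0\t*\t*",
    "r2\t0\tchrT\t101\t60\t25M300N25M\t*\t0\t0\t*\t*",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",                    # unmapped: dropped
    "r4\t256\tchrT\t101\t60\t50M\t*\t0\t0\t*\t*"))         # secondary: dropped
  al <- read_sam(p, sample_id = "S1")
  expect_setequal(unique(al$frag_id), c("r1", "r2"))
  r1 <- al[al$frag_id == "r1", ]
  expect_equal(nrow(r1), 1L)
  expect_equal(c(r1$bstart, r1$bend), c(100L, 150L))
  r2 <- al[al$frag_id == "r2", ]
  expect_equal(nrow(r2), 2L)
  expect_equal(r2$bstart, c(100L, 425L))
  expect_equal(r2$bend, c(125L, 450L))
  expect_equal(r2$bstart[2] - r2$bend[1], 300L)            # the N gap
})

test_that("generator SAM output round-trips through read_sam", {
  tr <- gen_transcriptome(71, events_per_category = c(CASSETTE = 1L,
                                                      MUT_EXCLU = 1L),
                          ese2_fixture = FALSE)
  sam <- tempfile(fileext = ".sam")
  rd <- gen_reads(tr$transcripts, depth = 300, seed = 7, sam = sam)
  back <- read_sam(sam, sample_id = "S1")
  cols <- c("read_id", "chrom", "bstart", "bend", "block", "nblocks")
  a <- rd$alignments[order(rd$alignments$read_id, rd$alignments$bstart), cols]
  b <- back[order(back$read_id, back$bstart), cols]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("reads are assigned to the alternative whose unique evidence they carry", {
  fx <- fixture_cassette()
  ur <- compute_unique_regions(fx$event)
  # skip-junction read with 10 nt on each side -> ALT2
  skip <- aln_df("s1/1", rbind(c(1190, 1200), c(2000, 2040)))
  # inclusion-junction read -> ALT1
  incj <- aln_df("s2/1", rbind(c(1180, 1200), c(1500, 1530)))
  # fully inside the cassette exon -> ALT1
  body <- aln_df("s3/1", rbind(c(1520, 1570)))
  # fully inside a constitutive flank -> NEITHER
  flank <- aln_df("s4/1", rbind(c(1020, 1070)))
  al <- rbind(skip, incj, body, flank)
  asg <- assign_reads(fx$event, ur, al)
  expect_equal(unname(asg[c("s1/1", "s2/1", "s3/1", "s4/1")]),
               c("ALT2", "ALT1", "ALT1", "NEITHER"))
})

test_that("junction evidence requires the minimum overhang", {
  fx <- fixture_cassette()
  ur <- compute_unique_regions(fx$event, min_overhang = 5L)
  ok <- aln_df("r1/1", rbind(c(1195, 1200), c(2000, 2045)))   # 5 nt overhang
  short <- aln_df("r2/1", rbind(c(1196, 1200), c(2000, 2046))) # 4 nt left
  asg <- assign_reads(fx$event, ur, rbind(ok, short), min_overhang = 5L)
  expect_equal(unname(asg[c("r1/1", "r2/1")]), c("ALT2", "NEITHER"))
})

test_that("simulated reads are assigned to their source isoform", {
  tr <- gen_transcriptome(81, events_per_category = c(CASSETTE = 1L),
                          ese2_fixture = FALSE)
  cata <- build_event_catalog(tr$transcripts)
  ev <- cata$events[[1]]; ur <- cata$unique_regions[[1]]
  rd <- gen_reads(tr$transcripts, psi = stats::setNames(0.5, ev$gene_id),
                  depth = 500, seed = 9)
  asg <- assign_reads(ev, ur, rd$alignments)
  frag <- sub("/[12]$", "", names(asg))
  iso <- rd$truth$isoform[match(frag, rd$truth$frag_id)]
  informative <- asg %in% c("ALT1", "ALT2")
  expect_gt(sum(informative), 50)
  expect_true(all(asg[informative] == paste0("ALT", iso[informative])))
})

test_that("normalized counts and PSI follow the stated formulas", {
  expect_equal(compute_psi(0.05, 0.1), 1 / 3)
  expect_equal(compute_psi(2, 2), 0.5)
  expect_equal(compute_psi(3, 0), 1.0)
  expect_true(is.na(compute_psi(0, 0)))
  # PSI symmetry whenever defined
  for (c1 in c(0, 0.2, 1.7)) for (c2 in c(0.1, 2)) {
    expect_equal(compute_psi(c1, c2) + compute_psi(c2, c1), 1)
  }
  # c_i = n_i / unique_length_i on a crafted read set
  fx <- fixture_cassette()
  ur <- compute_unique_regions(fx$event)
  reads <- do.call(rbind, c(
    lapply(1:10, function(i)
      aln_df(sprintf("inc%02d/1", i), rbind(c(1520, 1570)))),
    lapply(1:5, function(i)
      aln_df(sprintf("skp%02d/1", i), rbind(c(1190, 1200), c(2000, 2040))))))
  q <- quantify_event(fx$event, ur, reads)
  expect_equal(q$n1, 10); expect_equal(q$n2, 5)
  expect_equal(q$c1, 10 / ur$unique_length1)
  expect_equal(q$c2, 5 / ur$unique_length2)
  expect_equal(q$psi, q$c1 / (q$c1 + q$c2))
})

test_that("zero reads give zero counts and undefined PSI", {
  fx <- fixture_cassette()
  ur <- compute_unique_regions(fx$event)
  empty <- aln_df("x/1", rbind(c(5000, 5050)))  # outside the event
  q <- quantify_event(fx$event, ur, empty)
  expect_equal(c(q$n1, q$n2, q$c1, q$c2, q$density), rep(0, 5))
  expect_true(is.na(q$psi))
})

test_that("fragments with conflicting mate evidence contribute nothing", {
  fx <- fixture_cassette()
  ur <- compute_unique_regions(fx$event)
  m1 <- aln_df("f1/1", rbind(c(1520, 1570)), mate = 1L)               # ALT1
  m2 <- aln_df("f1/2", rbind(c(1190, 1200), c(2000, 2040)), mate = 2L) # ALT2
  q <- quantify_event(fx$event, ur, rbind(m1, m2))
  expect_equal(c(q$n1, q$n2), c(0, 0))
  # concordant mates both count
  m2b <- aln_df("f1/2", rbind(c(1540, 1590)), mate = 2L)               # ALT1
  q2 <- quantify_event(fx$event, ur, rbind(m1, m2b))
  expect_equal(c(q2$n1, q2$n2), c(2, 0))
})

test_that("counting is order-invariant and additive over read sets", {
  tr <- gen_transcriptome(91, events_per_category = c(CASSETTE = 1L),
                          ese2_fixture = FALSE)
  cata <- build_event_catalog(tr$transcripts)
  ev <- cata$events[[1]]; ur <- cata$unique_regions[[1]]
  a <- gen_reads(tr$transcripts, psi = stats::setNames(0.3, ev$gene_id),
                 depth = 300, seed = 1)$alignments
  b <- gen_reads(tr$transcripts, psi = stats::setNames(0.3, ev$gene_id),
                 depth = 200, seed = 2)$alignments
  b$read_id <- sub("^f", "g", b$read_id); b$frag_id <- sub("^f", "g", b$frag_id)
  qa <- quantify_event(ev, ur, a)
  qb <- quantify_event(ev, ur, b)
  qshuf <- quantify_event(ev, ur, a[sample(nrow(a)), ])
  expect_equal(qa[c("n1", "n2")], qshuf[c("n1", "n2")])
  qab <- quantify_event(ev, ur, rbind(a, b))
  expect_equal(qab$n1, qa$n1 + qb$n1)
  expect_equal(qab$n2, qa$n2 + qb$n2)
})

test_that("PSI error shrinks with sequencing depth", {
  tr <- gen_transcriptome(95, events_per_category = c(CASSETTE = 1L),
                          ese2_fixture = FALSE)
  cata <- build_event_catalog(tr$transcripts)
  ev <- cata$events[[1]]; ur <- cata$unique_regions[[1]]
  err <- sapply(c(200, 2000, 20000), function(depth) {
    mean(sapply(1:4, function(r) {
      rd <- gen_reads(tr$transcripts, psi = stats::setNames(0.7, ev$gene_id),
                      depth = depth, seed = depth + r)
      abs(quantify_event(ev, ur, rd$alignments)$psi - 0.7)
    }))
  })
  expect_lt(err[2], err[1])
  expect_lt(err[3], 0.02)
})

test_that("the density filter matches its definition", {
  counts <- data.frame(
    event_id = c("e1", "e1", "e2", "e3"),
    sample_id = c("s1", "s2", "s1", "s1"),
    c1 = c(0.004, 0.0005, 0.0029, 0.0031),
    c2 = c(0.001, 0.0002, 0.0029, 0))
  f <- filter_events(counts, density_min = 0.003)
  expect_true(f$retained[f$event_id == "e1"])    # one variant in one sample
  expect_false(f$retained[f$event_id == "e2"])   # both below threshold
  expect_true(f$retained[f$event_id == "e3"])    # boundary: >= is retained
})

test_that("delta-PSI means, flags and missing propagation behave", {
  d <- delta_psi(rep(0.9, 3), rep(0.2, 3))
  expect_equal(d$delta, 0.7)
  expect_true(d$flagged)
  d0 <- delta_psi(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(d0$delta, 0)
  expect_false(d0$flagged)
  dm <- delta_psi(c(NA, NA), c(0.5, 0.4))
  expect_true(is.na(dm$delta))
  expect_true(is.na(dm$flagged))
  # undefined per-sample values are dropped, not coerced
  dp <- delta_psi(c(0.8, NA, 0.9), c(0.2, 0.2, NA))
  expect_equal(dp$delta, mean(c(0.8, 0.9)) - 0.2)
})

test_that("rpkm follows its closed form and scaling law", {
  expect_equal(compute_rpkm(1000, 2000, 1e7), 50.0)
  expect_equal(compute_rpkm(0, 2000, 1e7), 0.0)
  expect_equal(compute_rpkm(77, 1234, 2e7), compute_rpkm(77, 1234, 1e7) / 2)
  expect_error(compute_rpkm(10, 0, 1e6), "transcript_length")
  expect_error(compute_rpkm(10, 100, 0), "total_mapped")
})

test_that("splice-site spanning counts exclude boundary-touching reads", {
  inside <- aln_df("a/1", rbind(c(90, 140)))
  at_start <- aln_df("b/1", rbind(c(100, 150)))
  at_end <- aln_df("c/1", rbind(c(50, 100)))
  spliced <- aln_df("d/1", rbind(c(80, 99), c(120, 150)))  # gap over the site
  expect_equal(count_splice_site_spanning(inside, 100L), 1L)
  expect_equal(count_splice_site_spanning(at_start, 100L), 0L)
  expect_equal(count_splice_site_spanning(at_end, 100L), 0L)
  expect_equal(count_splice_site_spanning(spliced, 100L), 0L)
  expect_equal(count_splice_site_spanning(rbind(inside, at_start, at_end), 100L), 1L)
})

test_that("spanning counts equal an exhaustive per-read oracle on 500 reads", {
  tr <- gen_transcriptome(97, events_per_category = c(CASSETTE = 1L),
                          ese2_fixture = FALSE)
  ev <- enumerate_events(tr$transcripts)[[1]]
  rd <- gen_reads(tr$transcripts, psi = stats::setNames(0.5, ev$gene_id),
                  depth = 250, seed = 3)
  al <- rd$alignments
  for (site in c(ev$flank5, ev$flank3, ev$alt1[1, 1])) {
    brute <- 0L
    for (id in unique(al$read_id)) {
      bl <- al[al$read_id == id, c("bstart", "bend")]
      pos <- oracle_covered_positions(bl)
      if ((site - 1L) %in% pos && site %in% pos &&
          min(bl$bstart) != site && max(bl$bend) != site)
        brute <- brute + 1L
    }
    expect_equal(count_splice_site_spanning(al, site), brute)
  }
})
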