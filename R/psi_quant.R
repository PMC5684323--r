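# PSI quantification from spliced read alignments.
#
# Alignments are carried as a long-format data.frame with one row per aligned
# block: read_id, frag_id, mate, sample_id, chrom, strand, bstart, bend
# (0-based half-open), block, nblocks. Gaps between consecutive blocks of a
# read are splice junctions.

ALIGN_COLS <- c("read_id", "frag_id", "mate", "sample_id", "chrom", "strand",
                "bstart", "bend", "block", "nblocks")

#' Read spliced alignments from a SAM file
#'
#' Parses M/N (and S/I/D) CIGAR alignments via \pkg{Rsamtools} and
#' \pkg{GenomicAlignments}; unmapped and secondary records are dropped.
#'
#' @param path Path to a SAM file (with header).
#' @param sample_id Sample label attached to all records (default: file name
#'   without extension).
#' @return Long-format block `data.frame` (one row per aligned block).
#' @export
read_sam <- function(path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- sub("\\.[sb]am$", "", basename(path))
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isUnmappedQuery = FALSE)
  ga <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "flag"), flag = flag))
  if (length(ga) == 0L)
    return(stats::setNames(data.frame(matrix(nrow = 0L, ncol = length(ALIGN_COLS))),
                           ALIGN_COLS))
  blocks <- GenomicAlignments::grglist(ga)  # splits on N gaps
  nb <- S4Vectors::elementNROWS(blocks)
  fl <- S4Vectors::mcols(ga)$flag
  mate <- ifelse(bitwAnd(fl, 128L) > 0L, 2L, 1L)
  qname <- S4Vectors::mcols(ga)$qname
  ub <- unlist(blocks, use.names = FALSE)
  idx <- rep(seq_along(ga), nb)
  out <- data.frame(
    read_id = paste0(qname, "/", mate)[idx],
    frag_id = qname[idx],
    mate = mate[idx],
    sample_id = sample_id,
    chrom = as.character(GenomicRanges::seqnames(ub)),
    strand = as.character(GenomicRanges::strand(ga))[idx],
    bstart = GenomicRanges::start(ub) - 1L,
    bend = GenomicRanges::end(ub),
    block = unlist(lapply(nb, seq_len), use.names = FALSE),
    nblocks = nb[idx],
    stringsAsFactors = FALSE)
  out[order(out$read_id, out$bstart), ]
}

#' Assign reads to the alternatives of one event
#'
#' A read supports alternative *i* iff it spans an alternative-*i*-specific
#' junction with at least `min_overhang` aligned nt on both sides, or lies
#' fully within an alternative-*i*-exclusive exon segment. Reads with evidence
#' for both alternatives are `AMBIGUOUS`; all others are `NEITHER`.
#'
#' @param event An `alt_event`.
#' @param ur Matching [compute_unique_regions()] result.
#' @param alignments Long-format block `data.frame` (see [read_sam()]).
#' @param min_overhang Minimum junction overhang in nt (default: the value
#'   stored in `ur`).
#' @return Character vector, one of `ALT1`, `ALT2`, `NEITHER`, `AMBIGUOUS`
#'   per distinct read, named by `read_id`.
#' @export
assign_reads <- function(event, ur, alignments, min_overhang = ur$min_overhang) {
  al <- alignments[alignments$chrom == event$chrom, , drop = FALSE]
  reads <- unique(alignments$read_id)
  res <- stats::setNames(rep("NEITHER", length(reads)), reads)
  if (!nrow(al)) return(res)
  al <- al[order(al$read_id, al$bstart, method = "radix"), ]
  n <- nrow(al)
  w <- al$bend - al$bstart
  # contiguous-group cumulative widths (blocks of one read are adjacent)
  new <- c(TRUE, al$read_id[-1L] != al$read_id[-n])
  gid <- cumsum(new)
  cs <- cumsum(w)
  base <- (cs - w)[new]
  cw <- cs - base[gid]
  gend <- c(which(new)[-1L] - 1L, n)
  tot <- (cs[gend] - base)[gid]
  same_read <- !new[-1L]
  jd <- al$bend[-n]; ja <- al$bstart[-1L]
  left_ok <- cw[-n] >= min_overhang
  right_ok <- (tot[-n] - cw[-n]) >= min_overhang
  jkey <- jd * 2^26 + ja
  hit_j <- function(juncs) {
    if (!nrow(juncs)) return(character(0))
    keep <- same_read & left_ok & right_ok &
      jkey %in% (juncs[, 1L] * 2^26 + juncs[, 2L])
    unique(al$read_id[-n][keep])
  }
  hit_s <- function(segs) {
    if (!nrow(segs)) return(character(0))
    single <- al$nblocks == 1L
    inside <- rep(FALSE, n)
    for (k in seq_len(nrow(segs)))
      inside <- inside | (al$bstart >= segs[k, 1L] & al$bend <= segs[k, 2L])
    unique(al$read_id[single & inside])
  }
  h1 <- union(hit_j(ur$junctions1), hit_s(ur$segments1))
  h2 <- union(hit_j(ur$junctions2), hit_s(ur$segments2))
  res[setdiff(h1, h2)] <- "ALT1"
  res[setdiff(h2, h1)] <- "ALT2"
  res[intersect(h1, h2)] <- "AMBIGUOUS"
  res
}

#' @rdname assign_reads
#' @export
assign_read <- assign_reads

#' Quantify one event in one sample
#'
#' Tallies alternative-specific reads, drops fragments whose two mates support
#' conflicting alternatives, and normalizes counts by the unique evidence
#' length of each alternative (`c_i = n_i / unique_length_i`).
#'
#' @inheritParams assign_reads
#' @param sample_id Optional label; defaults to the (single) sample present.
#' @return One-row `data.frame`: `event_id, sample_id, n1, n2, c1, c2,
#'   density, psi`.
#' @export
quantify_event <- function(event, ur, alignments, sample_id = NULL,
                           min_overhang = ur$min_overhang) {
  if (is.null(sample_id)) {
    sample_id <- unique(alignments$sample_id)
    if (length(sample_id) == 0L) sample_id <- NA_character_
    if (length(sample_id) > 1L)
      stop("alignments contain multiple samples; pass sample_id or use quantify_events()")
  } else {
    alignments <- alignments[alignments$sample_id == sample_id, , drop = FALSE]
  }
  if (ur$unique_length1 <= 0L || ur$unique_length2 <= 0L)
    stop("event '", event$event_id, "' has a zero unique length")
  asg <- assign_reads(event, ur, alignments, min_overhang)
  if (length(asg)) {
    frag <- sub("/[12]$", "", names(asg))
    conflict <- intersect(frag[asg == "ALT1"], frag[asg == "ALT2"])
    if (length(conflict)) asg[frag %in% conflict] <- "NEITHER"
  }
  n1 <- sum(asg == "ALT1"); n2 <- sum(asg == "ALT2")
  c1 <- n1 / ur$unique_length1; c2 <- n2 / ur$unique_length2
  data.frame(event_id = event$event_id, sample_id = sample_id,
             n1 = n1, n2 = n2, c1 = c1, c2 = c2,
             density = max(c1, c2), psi = compute_psi(c1, c2),
             stringsAsFactors = FALSE)
}

#' Quantify a catalog of events across the samples of an alignment set
#'
#' @param catalog Result of [build_event_catalog()].
#' @param alignments Long-format block `data.frame`, possibly multi-sample.
#' @return `data.frame` with one row per event x sample.
#' @export
quantify_events <- function(catalog, alignments) {
  samples <- unique(alignments$sample_id)
  out <- lapply(names(catalog$events), function(id) {
    ev <- catalog$events[[id]]; ur <- catalog$unique_regions[[id]]
    do.call(rbind, lapply(samples, function(s)
      quantify_event(ev, ur, alignments[alignments$sample_id == s, , drop = FALSE],
                     sample_id = s)))
  })
  do.call(rbind, out)
}

#' Percent spliced in
#'
#' `psi = c1 / (c1 + c2)` from the normalized counts of the two alternatives;
#' undefined (`NA`, never 0) when both counts are zero.
#'
#' @param c1,c2 Normalized counts (reads per nt of unique length).
#' @return PSI in `[0, 1]`, or `NA` where `c1 + c2 == 0`.
#' @export
compute_psi <- function(c1, c2) {
  s <- c1 + c2
  ifelse(s > 0, c1 / s, NA_real_)
}

#' Density filter for quantified events
#'
#' An event is retained iff the maximum normalized count over all its samples
#' and both variants reaches `density_min` (default 0.003 reads per nt).
#'
#' @param counts `data.frame` from [quantify_events()] (needs `event_id`,
#'   `c1`, `c2`).
#' @param density_min Retention threshold (reads/nt).
#' @return `data.frame` with one row per event: `event_id`, `max_density`,
#'   `retained`.
#' @export
filter_events <- function(counts, density_min = 0.003) {
  dmax <- tapply(pmax(counts$c1, counts$c2), counts$event_id, max)
  data.frame(event_id = names(dmax),
             max_density = as.numeric(dmax),
             retained = as.numeric(dmax) >= density_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Delta-PSI between a treated and a matched control condition
#'
#' `delta = mean(psi_treated) - mean(psi_control)` over per-sample PSI values
#' (undefined per-sample PSIs are dropped from the means); the event is
#' flagged as changed when `|delta|` exceeds `threshold` (default 0.4).
#'
#' @param psi_treated,psi_control Numeric vectors of per-sample PSI.
#' @param threshold Flagging threshold on `|delta|`.
#' @return One-row `data.frame`: `psi_treated`, `psi_control`, `delta`,
#'   `flagged`.
#' @export
delta_psi <- function(psi_treated, psi_control, threshold = 0.4) {
  mt <- if (all(is.na(psi_treated))) NA_real_ else mean(psi_treated, na.rm = TRUE)
  mc <- if (all(is.na(psi_control))) NA_real_ else mean(psi_control, na.rm = TRUE)
  d <- mt - mc
  data.frame(psi_treated = mt, psi_control = mc, delta = d,
             flagged = if (is.na(d)) NA else abs(d) > threshold)
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param count Mapped reads assigned to the gene/transcript.
#' @param transcript_length Transcript length in nt (> 0).
#' @param total_mapped Total mapped reads in the sample (> 0).
#' @return rpkm value.
#' @export
compute_rpkm <- function(count, transcript_length, total_mapped) {
  if (any(transcript_length <= 0)) stop("transcript_length must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  count / (transcript_length / 1e3) / (total_mapped / 1e6)
}

#' Count reads spanning a splice site
#'
#' A read is counted iff its aligned blocks cover the genomic bases on both
#' sides of the splice-site boundary and neither its start nor its end
#' coordinate falls exactly on the splice site.
#'
#' @param alignments Long-format block `data.frame`.
#' @param site Splice-site boundary coordinate (0-based boundary between the
#'   base `site - 1` and the base `site`).
#' @return Integer count of spanning reads.
#' @export
count_splice_site_spanning <- function(alignments, site) {
  al <- alignments[order(alignments$read_id, alignments$bstart), ]
  if (!nrow(al)) return(0L)
  covers_left <- al$bstart <= site - 1L & al$bend >= site       # base site-1
  covers_right <- al$bstart <= site & al$bend >= site + 1L      # base site
  left <- unique(al$read_id[covers_left])
  right <- unique(al$read_id[covers_right])
  span <- intersect(left, right)
  if (!length(span)) return(0L)
  rstart <- tapply(al$bstart, al$read_id, min)
  rend <- tapply(al$bend, al$read_id, max)
  keep <- span[rstart[span] != site & rend[span] != site]
  length(keep)
}
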