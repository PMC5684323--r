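# Event catalog: local alternative-splicing events from transcript annotations.
#
# Coordinates are 0-based half-open on the genome axis throughout the package;
# GTF input (1-based closed) is converted at the boundary.

EVENT_CATEGORIES <- c("CASSETTE", "INTERNAL3", "INTERNAL5",
                      "LCASSETTE", "MUT_EXCLU", "XCASSETTE", "OTHER")

#' Construct a transcript model
#'
#' A transcript model is the gene-grouped, ordered exon chain of one transcript
#' on the genome axis. Exons are stored 0-based half-open, strictly sorted and
#' non-overlapping.
#'
#' @param transcript_id,gene_id Character scalars.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of exon `start`, `end` (0-based half-open).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) stop("transcript '", transcript_id, "' has no exons")
  exons <- exons[order(exons[, 1L], exons[, 2L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("transcript '", transcript_id, "' has an empty or inverted exon")
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("transcript '", transcript_id, "' has overlapping exons")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(transcript_id = as.character(transcript_id),
                 gene_id = as.character(gene_id),
                 chrom = as.character(chrom),
                 strand = strand,
                 exons = exons),
            class = "transcript_model")
}

#' Read transcript models from a GTF file
#'
#' Parses exon features (via \pkg{rtracklayer}) and returns one
#' [transcript_model()] per transcript, exons sorted in ascending genomic
#' order. Transcripts with zero exon records are skipped with a warning.
#'
#' @param path Path to a GTF file with `exon` features carrying `gene_id` and
#'   `transcript_id` attributes.
#' @return Named list of `transcript_model` objects.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features found in '", path, "'")
  bad <- is.na(gr$gene_id) | is.na(gr$transcript_id)
  if (any(bad))
    stop("malformed attribute block: exon feature(s) ",
         paste(head(which(bad), 5L), collapse = ", "),
         " lack gene_id/transcript_id")
  df <- data.frame(transcript_id = as.character(gr$transcript_id),
                   gene_id = as.character(gr$gene_id),
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # to 0-based
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  out <- lapply(split(df, df$transcript_id), function(d) {
    transcript_model(d$transcript_id[1L], d$gene_id[1L], d$chrom[1L],
                     d$strand[1L], cbind(d$start, d$end))
  })
  out[order(names(out))]
}

#' Write transcript models to GTF
#'
#' Deterministic formatter: identical input always produces byte-identical
#' output, which the simulation round trips rely on.
#'
#' @param transcripts List of `transcript_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- unlist(lapply(transcripts, function(tx) {
    ex <- tx$exons
    sprintf(paste0("%s\tsplicemod\texon\t%d\t%d\t.\t%s\t.\t",
                   "gene_id \"%s\"; transcript_id \"%s\";"),
            tx$chrom, ex[, 1L] + 1L, ex[, 2L], tx$strand,
            tx$gene_id, tx$transcript_id)
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

## ---- pairwise event extraction ---------------------------------------------

# Match identical exons of two chains by a merge walk; first/last exons match
# flexibly on their internal splice site only (terminal differences ignored).
match_exons <- function(exA, exB) {
  m <- nrow(exA); n <- nrow(exB)
  i <- 1L; j <- 1L
  pairs <- matrix(integer(0), ncol = 2L)
  while (i <= m && j <= n) {
    sameS <- exA[i, 1L] == exB[j, 1L]
    sameE <- exA[i, 2L] == exB[j, 2L]
    matched <- (sameS && sameE) ||
      (i == 1L && j == 1L && sameE && m > 1L && n > 1L) ||   # shared donor
      (i == m && j == n && sameS && m > 1L && n > 1L)        # shared acceptor
    if (matched) {
      pairs <- rbind(pairs, c(i, j)); i <- i + 1L; j <- j + 1L
    } else if (exA[i, 2L] < exB[j, 2L] ||
               (exA[i, 2L] == exB[j, 2L] && exA[i, 1L] < exB[j, 1L])) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  pairs
}

# Classify one difference region between shared anchor exons.
classify_region <- function(midA, midB, strand) {
  nA <- nrow(midA); nB <- nrow(midB)
  if (nA > 0L && nB > 0L && nA != 1L) return("OTHER")
  if (nA == 0L || nB == 0L) {
    k <- max(nA, nB)
    return(switch(min(k, 3L), "CASSETTE", "LCASSETTE", "XCASSETTE"))
  }
  if (nB != 1L) return("OTHER")
  a <- midA[1L, ]; b <- midB[1L, ]
  sameS <- a[1L] == b[1L]; sameE <- a[2L] == b[2L]
  if (!sameS && sameE)        # acceptor side on '+', donor side on '-'
    return(if (strand == "+") "INTERNAL3" else "INTERNAL5")
  if (sameS && !sameE)
    return(if (strand == "+") "INTERNAL5" else "INTERNAL3")
  overlap <- a[1L] < b[2L] && b[1L] < a[2L]
  if (!overlap) return("MUT_EXCLU")
  "OTHER"
}

# Full junction chain of an alternative between flank5 and flank3.
alt_junctions <- function(flank5, flank3, exons) {
  if (nrow(exons) == 0L)
    return(matrix(c(flank5, flank3), ncol = 2L,
                  dimnames = list(NULL, c("donor", "acceptor"))))
  d <- c(flank5, exons[, 2L])
  a <- c(exons[, 1L], flank3)
  matrix(c(d, a), ncol = 2L, dimnames = list(NULL, c("donor", "acceptor")))
}

junction_keys <- function(j) if (nrow(j)) paste(j[, 1L], j[, 2L]) else character(0)

# Exonic segments specific to one alternative (set difference of coverage).
exclusive_segments <- function(mine, other) {
  if (nrow(mine) == 0L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  a <- IRanges::IRanges(mine[, 1L] + 1L, mine[, 2L])
  b <- if (nrow(other)) IRanges::IRanges(other[, 1L] + 1L, other[, 2L])
       else IRanges::IRanges()
  d <- IRanges::setdiff(a, b)
  matrix(c(IRanges::start(d) - 1L, IRanges::end(d)), ncol = 2L,
         dimnames = list(NULL, c("start", "end")))
}

make_event <- function(gene_id, chrom, strand, category, flank5, flank3,
                       altA, altB) {
  flank5 <- unname(flank5); flank3 <- unname(flank3)
  # alt1 = alternative with larger exonic content (the inclusion-type
  # alternative for cassette events); deterministic tie-break on start.
  lenA <- if (nrow(altA)) sum(altA[, 2L] - altA[, 1L]) else 0L
  lenB <- if (nrow(altB)) sum(altB[, 2L] - altB[, 1L]) else 0L
  swap <- lenB > lenA || (lenB == lenA && nrow(altB) && nrow(altA) &&
                            altB[1L, 1L] < altA[1L, 1L])
  alt1 <- if (swap) altB else altA
  alt2 <- if (swap) altA else altB
  j1 <- alt_junctions(flank5, flank3, alt1)
  j2 <- alt_junctions(flank5, flank3, alt2)
  shared <- intersect(junction_keys(j1), junction_keys(j2))
  j1u <- j1[!junction_keys(j1) %in% shared, , drop = FALSE]
  j2u <- j2[!junction_keys(j2) %in% shared, , drop = FALSE]
  event_id <- paste(gene_id, category, chrom, strand,
                    paste0(flank5, ":", flank3),
                    coords_key(alt1), coords_key(alt2), sep = "|")
  structure(list(event_id = event_id, gene_id = gene_id, chrom = chrom,
                 strand = strand, category = category,
                 flank5 = flank5, flank3 = flank3,
                 alt1 = alt1, alt2 = alt2,
                 junctions1 = j1u, junctions2 = j2u),
            class = "alt_event")
}

# Events from one ordered transcript pair.
pair_events <- function(txA, txB) {
  exA <- txA$exons; exB <- txB$exons
  pairs <- match_exons(exA, exB)
  if (nrow(pairs) < 2L) return(list())
  out <- list()
  for (k in seq_len(nrow(pairs) - 1L)) {
    i1 <- pairs[k, 1L]; i2 <- pairs[k + 1L, 1L]
    j1 <- pairs[k, 2L]; j2 <- pairs[k + 1L, 2L]
    midA <- exA[seq_len(i2 - i1 - 1L) + i1 - 1L + 1L, , drop = FALSE]
    midB <- exB[seq_len(j2 - j1 - 1L) + j1 - 1L + 1L, , drop = FALSE]
    if (nrow(midA) == 0L && nrow(midB) == 0L) next
    flank5 <- exA[i1, 2L]   # donor of upstream shared exon (genome axis)
    flank3 <- exA[i2, 1L]   # acceptor of downstream shared exon
    if (exB[j1, 2L] != flank5 || exB[j2, 1L] != flank3) next  # unshared anchors
    cat_ <- classify_region(midA, midB, txA$strand)
    out[[length(out) + 1L]] <-
      make_event(txA$gene_id, txA$chrom, txA$strand, cat_, flank5, flank3,
                 midA, midB)
  }
  out
}

#' Enumerate local alternative-splicing events for one gene
#'
#' Compares every transcript pair of a gene, extracts maximal local differences
#' flanked by shared splice sites and classifies them into the six local event
#' categories (`CASSETTE`, `INTERNAL3`, `INTERNAL5`, `LCASSETTE`, `MUT_EXCLU`,
#' `XCASSETTE`); regions not matching any template are labelled `OTHER`.
#' Events are deduplicated across pairs by a canonical coordinate key, and the
#' result is invariant to transcript input order.
#'
#' @param transcripts List of `transcript_model` objects, all from one gene.
#' @param keep_other Keep `OTHER`-category regions in the result
#'   (default `FALSE`; they are excluded from PSI analysis either way).
#' @return List of `alt_event` objects, sorted by `event_id`.
#' @export
enumerate_events <- function(transcripts, keep_other = FALSE) {
  if (length(transcripts) < 2L) return(list())
  gid <- unique(vapply(transcripts, `[[`, "", "gene_id"))
  chr <- unique(vapply(transcripts, `[[`, "", "chrom"))
  str <- unique(vapply(transcripts, `[[`, "", "strand"))
  if (length(gid) != 1L || length(chr) != 1L || length(str) != 1L)
    stop("all transcripts must come from one gene (same gene_id/chrom/strand)")
  transcripts <- transcripts[order(vapply(transcripts, `[[`, "", "transcript_id"))]
  events <- list()
  n <- length(transcripts)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    events <- c(events, pair_events(transcripts[[i]], transcripts[[j]]))
  }
  if (!length(events)) return(list())
  if (!keep_other)
    events <- Filter(function(e) e$category != "OTHER", events)
  if (!length(events)) return(list())
  ids <- vapply(events, `[[`, "", "event_id")
  events <- events[!duplicated(ids)]
  events[order(vapply(events, `[[`, "", "event_id"))]
}

#' Unique evidence regions and lengths for an event's alternatives
#'
#' For each alternative, collects the exonic segments and splice junctions that
#' are specific to it, and counts the number of distinct read-start positions
#' that yield alternative-specific evidence: each unique junction contributes
#' `read_len - 2 * min_overhang + 1` positions and each exclusive exon segment
#' contributes the positions at which a read lies fully within it
#' (`max(segment_length - read_len + 1, 0)`).
#'
#' @param event An `alt_event`.
#' @param read_len Read length in nt (default 50).
#' @param min_overhang Minimum nt required on both sides of a junction
#'   (default 1). Must satisfy `read_len > 2 * min_overhang`.
#' @return An object of class `unique_regions`: per-alternative segment and
#'   junction matrices plus `unique_length`.
#' @export
compute_unique_regions <- function(event, read_len = 50L, min_overhang = 1L) {
  read_len <- as.integer(read_len); min_overhang <- as.integer(min_overhang)
  # equality allowed: at read_len == 2 * min_overhang each junction retains
  # exactly one valid start position
  if (read_len < 2L * min_overhang)
    stop("read_len must be at least 2 * min_overhang")
  seg1 <- exclusive_segments(event$alt1, event$alt2)
  seg2 <- exclusive_segments(event$alt2, event$alt1)
  per_junc <- read_len - 2L * min_overhang + 1L
  seg_positions <- function(seg) {
    if (!nrow(seg)) return(0L)
    sum(pmax(seg[, 2L] - seg[, 1L] - read_len + 1L, 0L))
  }
  ul1 <- nrow(event$junctions1) * per_junc + seg_positions(seg1)
  ul2 <- nrow(event$junctions2) * per_junc + seg_positions(seg2)
  structure(list(event_id = event$event_id,
                 read_len = read_len, min_overhang = min_overhang,
                 segments1 = seg1, segments2 = seg2,
                 junctions1 = event$junctions1, junctions2 = event$junctions2,
                 unique_length1 = ul1, unique_length2 = ul2),
            class = "unique_regions")
}

#' Build the event catalog for a set of transcript models
#'
#' Groups transcripts by gene, enumerates events per gene, computes unique
#' regions and returns catalog, unique regions and a summary table.
#'
#' @param transcripts List of `transcript_model` objects (any number of genes).
#' @inheritParams compute_unique_regions
#' @return List with `events` (named by event_id), `unique_regions` (parallel
#'   list) and `table` (one row per event).
#' @export
build_event_catalog <- function(transcripts, read_len = 50L, min_overhang = 1L) {
  genes <- split(transcripts, vapply(transcripts, `[[`, "", "gene_id"))
  events <- unlist(lapply(genes, function(txs) {
    if (length(txs) < 2L) list() else enumerate_events(txs)
  }), recursive = FALSE, use.names = FALSE)
  names(events) <- vapply(events, `[[`, "", "event_id")
  ur <- lapply(events, compute_unique_regions,
               read_len = read_len, min_overhang = min_overhang)
  tab <- if (length(events)) {
    data.frame(event_id = names(events),
               gene_id = vapply(events, `[[`, "", "gene_id"),
               chrom = vapply(events, `[[`, "", "chrom"),
               strand = vapply(events, `[[`, "", "strand"),
               category = vapply(events, `[[`, "", "category"),
               flank5 = vapply(events, function(e) e$flank5, 0L),
               flank3 = vapply(events, function(e) e$flank3, 0L),
               alt1 = vapply(events, function(e) coords_key(e$alt1), ""),
               alt2 = vapply(events, function(e) coords_key(e$alt2), ""),
               unique_length1 = vapply(ur, function(u) u$unique_length1, 0L),
               unique_length2 = vapply(ur, function(u) u$unique_length2, 0L),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(event_id = character(0))
  }
  list(events = events, unique_regions = ur, table = tab)
}

#' Export an event catalog as JSON lines and a per-alternative TSV
#'
#' @param catalog Result of [build_event_catalog()].
#' @param json,tsv Output paths (either may be `NULL` to skip).
#' @return Invisibly, the catalog.
#' @export
write_event_catalog <- function(catalog, json = NULL, tsv = NULL) {
  if (!is.null(json)) {
    lines <- vapply(catalog$events, function(e) {
      jsonlite::toJSON(list(event_id = e$event_id, gene_id = e$gene_id,
                            chrom = e$chrom, strand = e$strand,
                            category = e$category,
                            flank5 = e$flank5, flank3 = e$flank3,
                            alt1 = apply(e$alt1, 1L, as.list),
                            alt2 = if (nrow(e$alt2)) apply(e$alt2, 1L, as.list)
                                   else list()),
                       auto_unbox = TRUE)
    }, "")
    writeLines(lines, json)
  }
  if (!is.null(tsv)) {
    tab <- catalog$table
    long <- rbind(
      data.frame(tab[c("event_id", "gene_id", "chrom", "strand", "category")],
                 alternative = 1L, exons = tab$alt1,
                 unique_length = tab$unique_length1),
      data.frame(tab[c("event_id", "gene_id", "chrom", "strand", "category")],
                 alternative = 2L, exons = tab$alt2,
                 unique_length = tab$unique_length2))
    long <- long[order(long$event_id, long$alternative), ]
    write_tsv_plain(long, tsv)
  }
  invisible(catalog)
}
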