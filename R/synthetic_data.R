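# Synthetic-data generators with known ground truth: multi-isoform gene
# models covering the six local event classes, spliced paired-end reads at
# specified PSI, SILAC ratio tables with a spiked enriched subset, and
# dose-response abundance matrices with a spiked displaced subset.
#
# Every generator is a pure function of (seed, parameters); the caller's RNG
# state is left untouched.

rint <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1L))

# Build one two-isoform gene realizing a requested event category on a local
# plus-strand axis starting at 0; returns exon matrices and event geometry.
build_gene_geometry <- function(category, n_flank = 3L) {
  exlen <- function(n = 1L) rint(n, 80L, 300L)
  inlen <- function(n = 1L) rint(n, 100L, 2000L)
  # constitutive flanking exons on both sides keep isoform lengths well above
  # the fragment length, as for local events inside real multi-exon genes
  pos <- 0L; FL <- NULL
  for (k in seq_len(n_flank)) {
    l <- exlen(); FL <- rbind(FL, c(pos, pos + l)); pos <- pos + l + inlen()
  }
  F1 <- FL[n_flank, ]  # innermost upstream flank (anchor exon)
  midA <- NULL; midB <- NULL
  if (category == "CASSETTE") {
    l <- exlen(); midA <- rbind(c(pos, pos + l)); pos <- pos + l + inlen()
  } else if (category == "LCASSETTE") {
    for (k in 1:2) { l <- exlen(); midA <- rbind(midA, c(pos, pos + l))
                     pos <- pos + l + inlen() }
  } else if (category == "XCASSETTE") {
    for (k in 1:3) { l <- exlen(); midA <- rbind(midA, c(pos, pos + l))
                     pos <- pos + l + inlen() }
  } else if (category == "INTERNAL3") {
    l <- exlen(); shift <- rint(1L, 20L, min(60L, l - 20L))
    midA <- rbind(c(pos, pos + l))          # long: upstream acceptor
    midB <- rbind(c(pos + shift, pos + l))  # short
    pos <- pos + l + inlen()
  } else if (category == "INTERNAL5") {
    l <- exlen(); shift <- rint(1L, 20L, min(60L, l - 20L))
    midA <- rbind(c(pos, pos + l))          # long: downstream donor
    midB <- rbind(c(pos, pos + l - shift))  # short
    pos <- pos + l + inlen()
  } else if (category == "MUT_EXCLU") {
    l1 <- exlen(); l2 <- l1 + rint(1L, 10L, 40L)  # distinct lengths
    midA <- rbind(c(pos, pos + l1)); pos <- pos + l1 + inlen()
    midB <- rbind(c(pos, pos + l2)); pos <- pos + l2 + inlen()
  } else stop("unknown category ", category)
  FR <- NULL
  for (k in seq_len(n_flank)) {
    l <- exlen(); FR <- rbind(FR, c(pos, pos + l))
    pos <- pos + l + if (k < n_flank) inlen() else 0L
  }
  F2 <- FR[1L, ]  # innermost downstream flank (anchor exon)
  chainA <- rbind(FL, if (!is.null(midA)) midA, FR)
  chainB <- rbind(FL, if (!is.null(midB)) midB, FR)
  rownames(chainA) <- rownames(chainB) <- NULL
  list(chainA = chainA, chainB = chainB,
       midA = if (is.null(midA)) matrix(integer(0), ncol = 2L) else midA,
       midB = if (is.null(midB)) matrix(integer(0), ncol = 2L) else midB,
       flank5 = F1[2L], flank3 = F2[1L], span = pos)
}

mirror_coords <- function(x, span) {
  if (is.null(dim(x))) return(span - rev(x))
  out <- cbind(span - x[, 2L], span - x[, 1L])
  out[order(out[, 1L]), , drop = FALSE]
}

#' Generate a synthetic transcriptome seeded with known splicing events
#'
#' Each requested event is realized as a two-isoform gene with valid exon
#' chains (exon lengths 80-300 nt, introns 100-2000 nt) on a synthetic
#' chromosome; strands are drawn at random and coordinates mirrored for minus
#' strand genes, which leaves the event category invariant. Optionally adds
#' single-isoform background genes and a cassette fixture gene whose cassette
#' exon carries the purine-rich ESE2 enhancer sequence
#' (5'-AAAAAGAAGGAAGG-3').
#'
#' @param seed Integer seed; the generated set is a pure function of
#'   (seed, parameters).
#' @param events_per_category Named integer vector of requested event counts
#'   per category (default: 2 of each of the six classes).
#' @param n_background Number of additional single-isoform genes (default 0).
#' @param ese2_fixture Add the ESE2 cassette fixture gene (default `TRUE`).
#' @param gtf,fasta Optional output paths (deterministic format).
#' @return List: `transcripts` (named list of [transcript_model()]), `truth`
#'   (`data.frame`, one row per seeded event, canonical ids included),
#'   `sequences` (named character; the ESE2 exon sequence), `params`.
#' @export
gen_transcriptome <- function(seed,
                              events_per_category = c(CASSETTE = 2L,
                                                      INTERNAL3 = 2L,
                                                      INTERNAL5 = 2L,
                                                      LCASSETTE = 2L,
                                                      MUT_EXCLU = 2L,
                                                      XCASSETTE = 2L),
                              n_background = 0L,
                              ese2_fixture = TRUE,
                              gtf = NULL, fasta = NULL) {
  if (any(events_per_category < 0L)) stop("event counts must be >= 0")
  bad <- setdiff(names(events_per_category), EVENT_CATEGORIES)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  with_local_seed(seed, {
    chrom <- "synth1"
    requests <- rep(names(events_per_category), events_per_category)
    transcripts <- list()
    truth <- list()
    sequences <- character(0)
    offset <- 10000L
    gidx <- 0L
    add_gene <- function(category, ese2 = FALSE) {
      gidx <<- gidx + 1L
      gid <- sprintf("G%03d", gidx)
      geo <- build_gene_geometry(category)
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      chA <- geo$chainA; chB <- geo$chainB
      mA <- geo$midA; mB <- geo$midB
      f5 <- geo$flank5; f3 <- geo$flank3
      if (strand == "-") {
        chA <- mirror_coords(chA, geo$span); chB <- mirror_coords(chB, geo$span)
        mA <- mirror_coords(mA, geo$span); mB <- mirror_coords(mB, geo$span)
        f5new <- geo$span - f3; f3new <- geo$span - f5
        f5 <- f5new; f3 <- f3new
      }
      chA <- chA + offset; chB <- chB + offset
      mA <- mA + offset; mB <- mB + offset
      f5 <- f5 + offset; f3 <- f3 + offset
      t1 <- transcript_model(paste0(gid, ".1"), gid, chrom, strand, chA)
      t2 <- transcript_model(paste0(gid, ".2"), gid, chrom, strand, chB)
      transcripts[[t1$transcript_id]] <<- t1
      transcripts[[t2$transcript_id]] <<- t2
      ev <- make_event(gid, chrom, strand, category, f5, f3, mA, mB)
      truth[[length(truth) + 1L]] <<- data.frame(
        gene_id = gid, category = category, chrom = chrom, strand = strand,
        flank5 = f5, flank3 = f3,
        alt1 = coords_key(ev$alt1), alt2 = coords_key(ev$alt2),
        event_id = ev$event_id, ese2 = ese2, stringsAsFactors = FALSE)
      offset <<- offset + geo$span + rint(1L, 5000L, 9000L)
      if (ese2) {
        # cassette exon sequence carrying the ESE2 enhancer motif
        exon <- ev$alt1
        len <- exon[1L, 2L] - exon[1L, 1L]
        motif <- "AAAAAGAAGGAAGG"
        at <- rint(1L, 1L, len - nchar(motif) + 1L)
        bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
        bases[seq(at, at + nchar(motif) - 1L)] <- strsplit(motif, "")[[1L]]
        sequences[[gid]] <<- paste(bases, collapse = "")
      }
      invisible(gid)
    }
    for (category in requests) add_gene(category)
    if (isTRUE(ese2_fixture)) add_gene("CASSETTE", ese2 = TRUE)
    for (b in seq_len(n_background)) {
      gidx <- gidx + 1L
      gid <- sprintf("G%03d", gidx)
      nex <- rint(1L, 2L, 5L)
      lens <- rint(nex, 80L, 300L); gaps <- rint(nex, 100L, 2000L)
      starts <- offset + cumsum(c(0L, (lens + gaps)[-nex]))
      ex <- cbind(starts, starts + lens)
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      tx <- transcript_model(paste0(gid, ".1"), gid, chrom, strand, ex)
      transcripts[[tx$transcript_id]] <- tx
      offset <- max(ex) + rint(1L, 5000L, 9000L)
    }
    truth <- do.call(rbind, truth)
    if (!is.null(gtf)) write_gtf(transcripts, gtf)
    if (!is.null(fasta) && length(sequences)) {
      writeLines(as.vector(rbind(paste0(">", names(sequences), "_cassette_exon"),
                                 sequences)), fasta)
    }
    list(transcripts = transcripts, truth = truth, sequences = sequences,
         params = list(seed = seed, events_per_category = events_per_category,
                       n_background = n_background,
                       ese2_fixture = ese2_fixture))
  })
}

# Vectorized mapping of transcript-coordinate intervals [a, b) onto genomic
# blocks of one transcript. Returns a block data.frame with a `row` column
# referencing the input read.
tx_to_genome_blocks <- function(tx, a, b) {
  ex <- tx$exons
  if (tx$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  w <- ex[, 2L] - ex[, 1L]
  cb <- c(0L, cumsum(w))          # transcript-space exon boundaries
  nE <- nrow(ex)
  i <- findInterval(a, cb, rightmost.closed = FALSE)        # first exon (1-based)
  j <- findInterval(b - 1L, cb, rightmost.closed = FALSE)   # last exon
  rows <- integer(0); bs <- integer(0); be <- integer(0)
  maxspan <- max(j - i)
  for (d in 0:maxspan) {
    sel <- which(j - i >= d)
    if (!length(sel)) break
    k <- i[sel] + d
    lo <- pmax(a[sel], cb[k])          # tx coords clipped to exon k
    hi <- pmin(b[sel], cb[k + 1L])
    off_lo <- lo - cb[k]; off_hi <- hi - cb[k]
    if (tx$strand == "+") {
      gs <- ex[k, 1L] + off_lo; ge <- ex[k, 1L] + off_hi
    } else {
      gs <- ex[k, 2L] - off_hi; ge <- ex[k, 2L] - off_lo
    }
    rows <- c(rows, sel); bs <- c(bs, gs); be <- c(be, ge)
  }
  data.frame(row = rows, bstart = as.integer(bs), bend = as.integer(be))
}

#' Simulate spliced reads for two-isoform genes at specified PSI
#'
#' Per fragment an isoform is chosen and the fragment is placed uniformly on
#' it; fragment lengths are normal(250, 30) truncated to the feasible range.
#' `psi` is interpreted as the molar fraction of the inclusion isoform
#' (the longer alternative): with `length_weighted = TRUE` (default) the
#' fragment-level inclusion probability is `psi*L1 / (psi*L1 + (1-psi)*L2)`,
#' which makes the length-normalized PSI estimator consistent;
#' `length_weighted = FALSE` draws the isoform with probability `psi`
#' directly.
#'
#' @param transcripts Named list of [transcript_model()] (from
#'   [gen_transcriptome()]); genes with two isoforms are simulated at their
#'   `psi`, single-isoform genes uniformly.
#' @param psi Named vector of PSI per gene (default 0.5 for all two-isoform
#'   genes).
#' @param depth Fragments per gene.
#' @param read_len Read length (default 50).
#' @param paired Emit 2 x `read_len` paired-end fragments (default `TRUE`).
#' @param seed Integer seed.
#' @param sample_id Sample label.
#' @param frag_mean,frag_sd Fragment-length model.
#' @param length_weighted See above.
#' @param sam Optional SAM output path (deterministic byte layout).
#' @return List: `alignments` (long-format block `data.frame` as in
#'   [read_sam()]), `truth` (`data.frame` per fragment: source gene, isoform,
#'   transcript), `params`.
#' @export
gen_reads <- function(transcripts, psi = NULL, depth = 1000L, read_len = 50L,
                      paired = TRUE, seed = 1L, sample_id = "S1",
                      frag_mean = 250, frag_sd = 30,
                      length_weighted = TRUE, sam = NULL) {
  genes <- split(transcripts, vapply(transcripts, `[[`, "", "gene_id"))
  with_local_seed(seed, {
    aln <- list(); truths <- list(); fragn <- 0L
    for (gid in names(genes)) {
      txs <- genes[[gid]]
      lens <- vapply(txs, function(t) sum(t$exons[, 2L] - t$exons[, 1L]), 0)
      ord <- order(-lens, vapply(txs, `[[`, "", "transcript_id"))
      txs <- txs[ord]; lens <- lens[ord]   # isoform 1 = inclusion (longer)
      if (length(txs) >= 2L) {
        p <- if (!is.null(psi) && gid %in% names(psi)) psi[[gid]] else 0.5
        if (p < 0 || p > 1) stop("psi must lie in [0, 1]")
        el <- pmax(lens - frag_mean + 1, 1)  # effective lengths
        p1 <- if (length_weighted)
          p * el[1L] / (p * el[1L] + (1 - p) * el[2L]) else p
        n1 <- stats::rbinom(1L, depth, p1)
        counts <- c(n1, depth - n1)
      } else counts <- depth
      for (iso in seq_along(counts)) {
        n <- counts[iso]
        if (n == 0L) next
        tx <- txs[[iso]]; L <- lens[iso]
        min_span <- read_len
        flen <- pmin(pmax(round(stats::rnorm(n, frag_mean, frag_sd)),
                          min_span), L)
        fs <- floor(stats::runif(n) * (L - flen + 1))
        ids <- sprintf("f%07d", fragn + seq_len(n)); fragn <- fragn + n
        truths[[length(truths) + 1L]] <- data.frame(
          frag_id = ids, gene_id = gid, isoform = iso,
          transcript_id = tx$transcript_id, tx_start = fs, frag_len = flen,
          stringsAsFactors = FALSE)
        emit <- function(a, b, mate) {
          bl <- tx_to_genome_blocks(tx, a, b)
          nb <- tabulate(bl$row, nbins = n)
          data.frame(read_id = paste0(ids[bl$row], "/", mate),
                     frag_id = ids[bl$row], mate = mate,
                     sample_id = sample_id, chrom = tx$chrom,
                     strand = tx$strand,
                     bstart = bl$bstart, bend = bl$bend,
                     block = 0L, nblocks = nb[bl$row],
                     stringsAsFactors = FALSE)
        }
        aln[[length(aln) + 1L]] <- emit(fs, fs + read_len, 1L)
        if (paired)
          aln[[length(aln) + 1L]] <- emit(fs + flen - read_len, fs + flen, 2L)
      }
    }
    alignments <- if (length(aln)) do.call(rbind, aln)
      else stats::setNames(data.frame(matrix(nrow = 0, ncol = length(ALIGN_COLS))),
                           ALIGN_COLS)
    if (nrow(alignments)) {
      alignments <- alignments[order(alignments$read_id, alignments$bstart,
                                     method = "radix"), ]
      n <- nrow(alignments)
      new <- c(TRUE, alignments$read_id[-1L] != alignments$read_id[-n])
      idx <- seq_len(n)
      alignments$block <- idx - which(new)[cumsum(new)] + 1L
      rownames(alignments) <- NULL
    }
    truth <- if (length(truths)) do.call(rbind, truths)
             else data.frame(frag_id = character(0))
    if (!is.null(sam)) write_sam(alignments, sam, paired = paired)
    list(alignments = alignments, truth = truth,
         params = list(seed = seed, depth = depth, read_len = read_len,
                       paired = paired, sample_id = sample_id,
                       length_weighted = length_weighted))
  })
}

#' Write alignments as a SAM file
#'
#' Deterministic formatter (records sorted by read id); emits M/N CIGAR
#' strings reconstructed from the aligned blocks.
#'
#' @param alignments Long-format block `data.frame`.
#' @param path Output path.
#' @param paired Set mate flags (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, paired = TRUE) {
  al <- alignments[order(alignments$read_id, alignments$bstart), , drop = FALSE]
  chroms <- sort(unique(al$chrom))
  maxlen <- vapply(chroms, function(cc) max(al$bend[al$chrom == cc]) + 1000L, 0L)
  header <- c("@HD\tVN:1.6\tSO:queryname",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms, as.integer(maxlen)))
  if (!nrow(al)) { writeLines(header, path); return(invisible(path)) }
  first <- !duplicated(al$read_id)
  widths <- al$bend - al$bstart
  gap_after <- c(al$bstart[-1L] - al$bend[-nrow(al)], 0L)
  gap_after[c(which(first[-1L]), nrow(al))] <- 0L
  piece <- paste0(widths, "M", ifelse(gap_after > 0L,
                                      paste0(gap_after, "N"), ""))
  cigar <- vapply(split(piece, factor(al$read_id, levels = unique(al$read_id))),
                  paste0, "", collapse = "")
  rec <- al[first, , drop = FALSE]
  flag <- if (paired) ifelse(rec$mate == 1L, 65L, 129L) else 0L
  flag <- flag + ifelse(rec$strand == "-", 16L, 0L)
  lines <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                   rec$frag_id, flag, rec$chrom, rec$bstart + 1L, cigar)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Generate a SILAC ratio table with a spiked enriched subset
#'
#' Null proteins have mean log2 ratio 0, enriched proteins mean
#' `effect_log2`; per-sample noise is normal with standard deviation `sd`,
#' values are missing completely at random at `missing_rate`, and the
#' designated label-swap samples are emitted with inverted linear ratios.
#' Decoy rows exercising every branch of the filter chain (single-peptide
#' rows, sub-threshold scores, sparse detection, duplicate lower-abundance
#' bands) are appended; the truth table marks the row expected to survive the
#' filter chain.
#'
#' @param seed Integer seed.
#' @param n_proteins,n_enriched Spike design (defaults 500, 25).
#' @param effect_log2 Mean log2 ratio of enriched proteins (default 2).
#' @param sd Per-sample noise sd on the log2 scale (default 0.3).
#' @param n_samples Number of pulldown samples (default 10).
#' @param swap_samples Indices of label-swapped samples (default 6:10).
#' @param missing_rate MCAR missingness (default 0.05).
#' @param n_decoys Filter-exercising decoy rows (default 30).
#' @param tsv Optional output path.
#' @return List: `table` (`data.frame`), `truth` (`data.frame` per row:
#'   `enriched`, `true_mean_log2`, `expect_retained`), `swap_samples`,
#'   `params`.
#' @export
gen_silac <- function(seed, n_proteins = 500L, n_enriched = 25L,
                      effect_log2 = 2, sd = 0.3, n_samples = 10L,
                      swap_samples = 6:10, missing_rate = 0.05,
                      n_decoys = 30L, tsv = NULL) {
  if (n_enriched > n_proteins) stop("n_enriched must be <= n_proteins")
  with_local_seed(seed, {
    sample_cols <- sprintf("ratio_S%02d", seq_len(n_samples))
    enriched_ids <- sort(sample.int(n_proteins, n_enriched))
    mu <- rep(0, n_proteins); mu[enriched_ids] <- effect_log2
    make_rows <- function(ids, mu, peptides, score, band, miss_k = NULL) {
      n <- length(ids)
      vals <- matrix(stats::rnorm(n * n_samples, mean = mu, sd = sd),
                     nrow = n)  # mu recycled down rows
      lin <- 2^vals
      lin[, swap_samples] <- 1 / lin[, swap_samples, drop = FALSE]
      if (is.null(miss_k)) {
        drop <- matrix(stats::runif(n * n_samples) < missing_rate, nrow = n)
      } else {  # force >= miss_k missing per row
        drop <- matrix(FALSE, n, n_samples)
        for (r in seq_len(n))
          drop[r, sample.int(n_samples, miss_k)] <- TRUE
      }
      lin[drop] <- NA_real_
      out <- data.frame(protein_id = ids, band_id = band,
                        n_quant_peptides = peptides, score = score,
                        intensity = round(10^stats::runif(n, 5, 8)),
                        stringsAsFactors = FALSE)
      out[sample_cols] <- round(lin, 6)
      out
    }
    ids <- sprintf("PRT%04d", seq_len(n_proteins))
    tab <- make_rows(ids, mu,
                     peptides = 2L + stats::rpois(n_proteins, 4),
                     score = round(stats::runif(n_proteins, 35, 200), 1),
                     band = rint(n_proteins, 1L, 7L))
    truth <- data.frame(protein_id = ids, band_id = tab$band_id,
                        enriched = seq_len(n_proteins) %in% enriched_ids,
                        true_mean_log2 = mu, expect_retained = TRUE,
                        kind = "analysis", stringsAsFactors = FALSE)
    if (n_decoys > 0L) {
      kinds <- rep(c("few_peptides", "low_score", "sparse", "dup_band"),
                   length.out = n_decoys)
      dec <- list(); dtr <- list()
      for (k in seq_len(n_decoys)) {
        kind <- kinds[k]
        if (kind == "dup_band") {
          host <- sample(ids, 1L)
          row <- make_rows(host, 0,
                           peptides = 2L + stats::rpois(1L, 2),
                           score = round(stats::runif(1L, 35, 200), 1),
                           band = tab$band_id[match(host, tab$protein_id)] %% 7L + 1L)
          row$intensity <- round(tab$intensity[match(host, tab$protein_id)] / 10)
          did <- host
        } else {
          did <- sprintf("DEC%04d", k)
          row <- switch(kind,
            few_peptides = make_rows(did, 0, peptides = 1L,
                                     score = round(stats::runif(1L, 35, 200), 1),
                                     band = rint(1L, 1L, 7L)),
            low_score = make_rows(did, 0, peptides = 3L,
                                  score = round(stats::runif(1L, 10, 31), 1),
                                  band = rint(1L, 1L, 7L)),
            sparse = make_rows(did, 0, peptides = 3L,
                               score = round(stats::runif(1L, 35, 200), 1),
                               band = rint(1L, 1L, 7L),
                               miss_k = n_samples - 5L))
        }
        dec[[k]] <- row
        dtr[[k]] <- data.frame(protein_id = did, band_id = row$band_id,
                               enriched = FALSE, true_mean_log2 = 0,
                               expect_retained = FALSE, kind = kind,
                               stringsAsFactors = FALSE)
      }
      tab <- rbind(tab, do.call(rbind, dec))
      truth <- rbind(truth, do.call(rbind, dtr))
    }
    # bookkeeping: which row actually survives the filter chain, given the
    # realized missingness and metadata
    detected <- rowSums(!is.na(tab[sample_cols]))
    pass <- tab$n_quant_peptides >= 2L & tab$score > 31 & detected >= 7L
    best <- rep(FALSE, nrow(tab))
    for (pid in unique(tab$protein_id[pass])) {
      rows <- which(pass & tab$protein_id == pid)
      best[rows[order(-tab$intensity[rows], -tab$score[rows])[1L]]] <- TRUE
    }
    truth$expect_retained <- best
    if (!is.null(tsv)) write_tsv_plain(tab, tsv)
    list(table = tab, truth = truth, swap_samples = swap_samples,
         params = list(seed = seed, n_proteins = n_proteins,
                       n_enriched = n_enriched, effect_log2 = effect_log2,
                       sd = sd, n_samples = n_samples,
                       missing_rate = missing_rate, n_decoys = n_decoys))
  })
}

#' Generate a dose-response abundance matrix with displaced proteins
#'
#' Null proteins are flat; displaced proteins decrease monotonically with
#' concentration, losing `drop_per_level` per ordered level step (total drop
#' `(K - 1) * drop_per_level` over `K` levels), with Gaussian noise of
#' standard deviation `sd` on every observation.
#'
#' @param seed Integer seed.
#' @param n_proteins,n_displaced Spike design (defaults 200, 10).
#' @param drop_per_level Abundance decrease per level step (log scale;
#'   default `2 * sd`).
#' @param sd Observation noise sd (default 0.25).
#' @param levels Ordered concentration levels (default 0, 0.5, 1, 5, 10 uM).
#' @param replicates Replicates per level (default 3).
#' @param baseline_mean,baseline_sd Distribution of per-protein baselines.
#' @param matrix_tsv,design_tsv Optional output paths.
#' @return List: `mat` (proteins x samples), `design` (`sample_id`,
#'   `concentration`, `replicate`), `truth` (per protein: `displaced`),
#'   `params`.
#' @export
gen_dose_response <- function(seed, n_proteins = 200L, n_displaced = 10L,
                              drop_per_level = 2 * sd, sd = 0.25,
                              levels = c(0, 0.5, 1, 5, 10),
                              replicates = 3L,
                              baseline_mean = 20, baseline_sd = 2,
                              matrix_tsv = NULL, design_tsv = NULL) {
  if (n_displaced > n_proteins) stop("n_displaced must be <= n_proteins")
  with_local_seed(seed, {
    K <- length(levels)
    ns <- K * replicates
    design <- data.frame(
      sample_id = sprintf("C%g_R%d", rep(levels, each = replicates),
                          rep(seq_len(replicates), K)),
      concentration = rep(levels, each = replicates),
      replicate = rep(seq_len(replicates), K),
      stringsAsFactors = FALSE)
    ids <- sprintf("PRT%04d", seq_len(n_proteins))
    displaced <- sort(sample.int(n_proteins, n_displaced))
    base <- stats::rnorm(n_proteins, baseline_mean, baseline_sd)
    lvl_idx <- match(design$concentration, sort(unique(levels))) - 1L
    mu <- matrix(base, n_proteins, ns)
    mu[displaced, ] <- mu[displaced, , drop = FALSE] -
      outer(rep(drop_per_level, length(displaced)), lvl_idx)
    mat <- mu + matrix(stats::rnorm(n_proteins * ns, 0, sd), n_proteins)
    dimnames(mat) <- list(ids, design$sample_id)
    truth <- data.frame(protein_id = ids,
                        displaced = seq_len(n_proteins) %in% displaced,
                        stringsAsFactors = FALSE)
    if (!is.null(matrix_tsv))
      write_tsv_plain(data.frame(protein_id = ids, round(mat, 6),
                                 check.names = FALSE), matrix_tsv)
    if (!is.null(design_tsv)) write_tsv_plain(design, design_tsv)
    list(mat = mat, design = design, truth = truth,
         params = list(seed = seed, n_proteins = n_proteins,
                       n_displaced = n_displaced,
                       drop_per_level = drop_per_level, sd = sd,
                       levels = levels, replicates = replicates))
  })
}
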