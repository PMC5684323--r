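# Independent brute-force oracles used to check the package implementations.
# These deliberately re-derive every quantity from first principles (loops,
# direct summation, exhaustive enumeration) and never call the code paths
# they verify.

# Benjamini-Hochberg step-up from the textbook definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- rep(NA_real_, m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# One-sided Fisher p as a hypergeometric upper tail by direct summation:
# universe N, K category members, n hits, a category hits observed.
oracle_hypergeom_tail <- function(a, K, n, N) {
  ks <- seq(a, min(K, n))
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Brute-force SILAC filter chain with explicit loops.
oracle_silac_filter <- function(tab, min_peptides = 2, min_score = 31,
                                min_samples = 7) {
  rc <- grep("^ratio", names(tab), value = TRUE)
  pass <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    det <- sum(!is.na(unlist(tab[i, rc])))
    pass[i] <- tab$n_quant_peptides[i] >= min_peptides &&
      tab$score[i] > min_score && det >= min_samples
  }
  keep <- logical(nrow(tab))
  for (pid in unique(tab$protein_id)) {
    rows <- which(pass & tab$protein_id == pid)
    if (!length(rows)) next
    ab <- if ("intensity" %in% names(tab)) tab$intensity[rows]
          else tab$n_quant_peptides[rows]
    best <- rows[order(-ab, -tab$score[rows], tab$band_id[rows])[1]]
    keep[best] <- TRUE
  }
  tab[keep, , drop = FALSE]
}

# Distinct assignments of a label multiset, re-derived independently.
oracle_label_assignments <- function(labels) {
  n <- length(labels)
  all_perms <- function(idx) {
    if (length(idx) == 1) return(list(idx))
    out <- list()
    for (k in seq_along(idx))
      out <- c(out, lapply(all_perms(idx[-k]), function(p) c(idx[k], p)))
    out
  }
  unique(lapply(all_perms(seq_len(n)), function(o) labels[o]))
}

# Moderated monotonic-contrast max-t per protein for one label assignment,
# computed with plain loops; variance moderation through limma (independent
# of the package's own estimator).
oracle_max_t <- function(mat, conc) {
  levs <- sort(unique(conc))
  K <- length(levs)
  m <- nrow(mat)
  s2 <- numeric(m); df <- numeric(m)
  gmean <- matrix(NA_real_, m, K)
  for (i in seq_len(m)) {
    res <- c()
    for (k in seq_len(K)) {
      v <- mat[i, conc == levs[k]]
      v <- v[!is.na(v)]
      gmean[i, k] <- mean(v)
      res <- c(res, v - mean(v))
    }
    df[i] <- length(res) - K
    s2[i] <- sum(res^2) / df[i]
  }
  sq <- limma::squeezeVar(s2, df)
  tmax <- numeric(m)
  for (i in seq_len(m)) {
    ts <- numeric(0)
    for (k in seq_len(K - 1)) {
      lo <- mat[i, conc %in% levs[1:k]]; lo <- lo[!is.na(lo)]
      hi <- mat[i, conc %in% levs[(k + 1):K]]; hi <- hi[!is.na(hi)]
      ts <- c(ts, (mean(lo) - mean(hi)) /
                sqrt(sq$var.post[i] * (1 / length(lo) + 1 / length(hi))))
    }
    tmax[i] <- max(ts)
  }
  tmax
}

# Full Westfall-Young step-down minP over an exhaustive label enumeration,
# from the definitions.
oracle_minp_exhaustive <- function(mat, design) {
  conc <- design$concentration
  assigns <- oracle_label_assignments(conc)
  N <- length(assigns)
  m <- nrow(mat)
  Tb <- matrix(NA_real_, m, N)
  for (b in seq_len(N)) Tb[, b] <- oracle_max_t(mat, assigns[[b]])
  t_obs <- oracle_max_t(mat, conc)
  p_raw <- numeric(m)
  for (i in seq_len(m)) p_raw[i] <- sum(Tb[i, ] >= t_obs[i]) / N
  P <- matrix(NA_real_, m, N)
  for (i in seq_len(m)) for (b in seq_len(N))
    P[i, b] <- sum(Tb[i, ] >= Tb[i, b]) / N
  ord <- order(p_raw, -t_obs)
  adj <- numeric(m)
  q <- rep(1, N)
  adj_ord <- numeric(m)
  for (j in seq(m, 1)) {
    q <- pmin(q, P[ord[j], ])
    adj_ord[j] <- sum(q <= p_raw[ord[j]]) / N
  }
  adj_ord <- cummax(adj_ord)
  adj[ord] <- adj_ord
  list(p_raw = p_raw, p_minp = adj)
}

# Positions covered by a read (from its blocks), for splice-site oracles.
oracle_covered_positions <- function(blocks) {
  unlist(lapply(seq_len(nrow(blocks)),
                function(i) seq(blocks$bstart[i], blocks$bend[i] - 1L)))
}

# Hand-built cassette-event fixture: one plus-strand gene, cassette exon of
# `exon_len` nt at [1500, 1500 + exon_len), flanks [1000,1200) and
# [2000,2300).
fixture_cassette <- function(exon_len = 120L) {
  inc <- transcript_model("T1", "G1", "chrT", "+",
                          rbind(c(1000L, 1200L),
                                c(1500L, 1500L + exon_len),
                                c(2000L, 2300L)))
  skp <- transcript_model("T2", "G1", "chrT", "+",
                          rbind(c(1000L, 1200L), c(2000L, 2300L)))
  txs <- list(T1 = inc, T2 = skp)
  ev <- enumerate_events(txs)[[1]]
  list(transcripts = txs, event = ev)
}

# One-row alignment data.frame builder (single- or multi-block reads).
aln_df <- function(read_id, blocks, sample_id = "S1", chrom = "chrT",
                   mate = 1L) {
  nb <- nrow(blocks)
  data.frame(read_id = read_id, frag_id = sub("/[12]$", "", read_id),
             mate = mate, sample_id = sample_id, chrom = chrom, strand = "+",
             bstart = blocks[, 1], bend = blocks[, 2],
             block = seq_len(nb), nblocks = nb, stringsAsFactors = FALSE)
}
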