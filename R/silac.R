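# SILAC affinity-enrichment statistics: ratio harmonization, the protein
# filter chain, one-sided tests with BH adjustment, and Fisher category
# enrichment with an optional exclusion re-run.

#' Harmonize SILAC heavy/light ratios to a log2 matrix
#'
#' Label-swapped samples' linear ratios are inverted (`r -> 1/r`) so that all
#' samples measure enrichment in the same orientation, then all ratios are
#' log2-transformed. Non-positive ratios are set missing with a warning.
#'
#' @param ratios Numeric matrix (proteins x samples) of linear H:L ratios.
#' @param swapped Logical vector, one per sample (column): `TRUE` where the
#'   labels were swapped.
#' @return Matrix of log2 ratios, same dimensions.
#' @export
harmonize_ratios <- function(ratios, swapped) {
  ratios <- as.matrix(ratios)
  if (length(swapped) != ncol(ratios))
    stop("'swapped' must have one entry per sample column")
  bad <- !is.na(ratios) & ratios <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive ratio(s) set to NA")
    ratios[bad] <- NA_real_
  }
  ratios[, swapped] <- 1 / ratios[, swapped, drop = FALSE]
  log2(ratios)
}

#' Filter chain for protein quantitation tables
#'
#' Retains rows with at least `min_peptides` quantified peptides, a search
#' score strictly greater than `min_score`, and a non-missing ratio in at
#' least `min_samples` of the sample columns. Where a protein was identified
#' in several gel bands, only the band with the highest abundance is kept
#' (total intensity when an `intensity` column is present, otherwise the
#' quantified peptide count as a proxy). The operation is idempotent.
#'
#' @param tab `data.frame` with columns `protein_id`, `band_id`,
#'   `n_quant_peptides`, `score`, optionally `intensity`, and the per-sample
#'   ratio columns named in `ratio_cols`.
#' @param min_peptides,min_score,min_samples Filter thresholds (defaults 2,
#'   31, 7 for a 10-sample design).
#' @param ratio_cols Names of the per-sample ratio columns (default: all
#'   columns starting with `"ratio"`).
#' @return The retained rows of `tab` (one per protein).
#' @export
filter_protein_table <- function(tab, min_peptides = 2L, min_score = 31,
                                 min_samples = 7L,
                                 ratio_cols = grep("^ratio", names(tab),
                                                   value = TRUE)) {
  if (!length(ratio_cols)) stop("no ratio columns found")
  detected <- rowSums(!is.na(tab[, ratio_cols, drop = FALSE]))
  keep <- tab$n_quant_peptides >= min_peptides &
    tab$score > min_score &
    detected >= min_samples
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab)) return(tab)
  abundance <- if ("intensity" %in% names(tab)) tab$intensity
               else tab$n_quant_peptides
  # best band per protein; deterministic tie-break on score then band order
  ord <- order(tab$protein_id, -abundance, -tab$score, tab$band_id)
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(tab$protein_id), , drop = FALSE]
  tab[order(tab$protein_id), , drop = FALSE]
}

#' One-sided enrichment tests on a log2-ratio matrix
#'
#' Per protein, a one-sample t-test of the null that the mean log2 ratio is 0
#' against the alternative that it is greater (enrichment with the active
#' ligand), Benjamini-Hochberg adjustment across proteins, and an enrichment
#' call requiring both `p_adj <= alpha` and a fold-change criterion.
#'
#' The fold-change criterion follows the linear-ratio reading by default
#' (`fold_scale = "linear"`: mean linear ratio > `fold`, i.e. mean log2 ratio
#' > `log2(fold)`); `fold_scale = "log2"` instead requires the mean log2 ratio
#' itself to exceed `fold`.
#'
#' @param log2_ratios Numeric matrix (proteins x samples) of harmonized log2
#'   ratios; rows must be named by protein.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param fold Fold-change cutoff (default 1.5).
#' @param fold_scale `"linear"` (default) or `"log2"`.
#' @return `data.frame`: `protein_id`, `n`, `mean_log2_ratio`, `t_statistic`,
#'   `df`, `p_value`, `p_adj`, `enriched`. Proteins with fewer than two
#'   non-missing ratios get `NA` statistics and are never called enriched.
#' @export
test_enrichment <- function(log2_ratios, alpha = 0.05, fold = 1.5,
                            fold_scale = c("linear", "log2")) {
  fold_scale <- match.arg(fold_scale)
  x <- as.matrix(log2_ratios)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  n <- rowSums(!is.na(x))
  m <- rowMeans(x, na.rm = TRUE)
  m[n == 0L] <- NA_real_
  ss <- rowSums((x - m)^2, na.rm = TRUE)
  s2 <- ifelse(n >= 2L, ss / pmax(n - 1L, 1L), NA_real_)
  se <- sqrt(s2 / n)
  tstat <- ifelse(se > 0, m / se,
                  ifelse(m > 0, Inf, ifelse(m < 0, -Inf, 0)))
  tstat[n < 2L] <- NA_real_
  df <- n - 1L
  p <- ifelse(is.na(tstat), NA_real_,
              stats::pt(tstat, df = df, lower.tail = FALSE))
  p_adj <- rep(NA_real_, length(p))
  p_adj[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
  cut_log2 <- if (fold_scale == "linear") log2(fold) else fold
  enriched <- !is.na(p_adj) & p_adj <= alpha & m > cut_log2
  data.frame(protein_id = rownames(x), n = n, mean_log2_ratio = m,
             t_statistic = tstat, df = df, p_value = p, p_adj = p_adj,
             enriched = enriched, row.names = NULL, stringsAsFactors = FALSE)
}

#' Fisher category enrichment of a hit list against a background
#'
#' Per category, a one-sided Fisher exact test on the 2x2 table
#' (hit / non-hit) x (in category / not in category) over the background
#' universe. When `exclude` is non-empty (for instance all ribosomal
#' proteins), hits and background are re-derived without those ids before
#' testing; categories emptied by the exclusion disappear from the result.
#'
#' @param hits Character vector of hit ids (must be a subset of `background`).
#' @param background Character vector: the tested universe.
#' @param annotation `data.frame` with columns `id`, `category` (an id may
#'   appear in several categories).
#' @param p_cutoff Enrichment call cutoff (default 0.001).
#' @param exclude Ids removed from hits and background before testing.
#' @return `data.frame` sorted by p: `category`, `hit_count`, `hit_total`,
#'   `background_count`, `background_total`, `p_value`, `neg_log10_p`,
#'   `enriched`.
#' @export
fisher_category_enrichment <- function(hits, background, annotation,
                                       p_cutoff = 0.001,
                                       exclude = character(0)) {
  if (!length(background)) stop("background must be non-empty")
  if (!all(hits %in% background))
    stop("hits must be a subset of the background")
  background <- setdiff(unique(background), exclude)
  hits <- setdiff(unique(hits), exclude)
  ann <- annotation[annotation$id %in% background, , drop = FALSE]
  cats <- sort(unique(ann$category))
  if (!length(cats))
    return(data.frame(category = character(0)))
  res <- lapply(cats, function(cc) {
    members <- unique(ann$id[ann$category == cc])
    a <- length(intersect(hits, members))
    b <- length(hits) - a
    c_ <- length(members) - a
    d <- length(background) - length(members) - b
    p <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2L),
                            alternative = "greater")$p.value
    data.frame(category = cc, hit_count = a, hit_total = length(hits),
               background_count = length(members),
               background_total = length(background),
               p_value = p, neg_log10_p = -log10(p),
               enriched = p <= p_cutoff, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res[order(res$p_value, res$category), , drop = FALSE]
}
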