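# Dose-dependent protein displacement test: empirical-Bayes variance
# moderation, monotonic above/below-cut contrasts, per-protein max-t, and
# Westfall-Young step-down minP permutation p-values.

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` (monotone decreasing). Used by the
#' moment-matching estimator of the variance prior.
#'
#' @param y Positive value(s).
#' @return `x` with `trigamma(x) = y`; `Inf` where `y` is (numerically) 0.
#' @keywords internal
trigamma_inverse <- function(y) {
  vapply(y, function(yy) {
    if (!is.finite(yy) || yy <= 1e-10) return(Inf)
    if (yy > 1e7) return(1 / sqrt(yy))
    stats::uniroot(function(x) trigamma(x) - yy,
                   interval = c(1e-8, 1e10), tol = 1e-10)$root
  }, 0)
}

# Moment-matching fit of a scaled inverse chi-square prior to residual
# variances: log s^2 follows (up to constants) a log-F distribution; matching
# mean and variance of the log variances yields the prior dof d0 and prior
# variance s0^2 (the empirical-Bayes scheme of moderated t-statistics).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & df > 0
  if (sum(ok) < 2L) stop("need at least two proteins with positive residual dof")
  # exactly-zero variances carry no scale information for log-moment matching
  pos <- ok & s2 > 0
  if (sum(pos) < 2L) {
    s0 <- if (any(pos)) s2[pos][1L] else 0
    return(list(df_prior = Inf, s2_prior = s0))
  }
  s2 <- s2[pos]; df <- df[pos]
  z <- log(s2)
  if (max(z) - min(z) < 1e-12) {
    # degenerate input: no between-protein spread, prior collapses onto the
    # common observed variance
    return(list(df_prior = Inf, s2_prior = s2[1L]))
  }
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1L) - mean(trigamma(df / 2))
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  list(df_prior = d0, s2_prior = s02)
}

#' Moderated one-way fit of an abundance matrix against a dose design
#'
#' Fits per-protein group means for each concentration level, estimates the
#' residual variance, and shrinks it towards a prior estimated across all
#' proteins by moment matching of the log residual variances (prior dof `d0`
#' and prior variance `s0^2`); the posterior variance is
#' `(d0*s0^2 + d*s^2) / (d0 + d)`.
#'
#' @param mat Numeric matrix (proteins x samples) of log-scale abundances;
#'   missing values allowed. Columns must match `design$sample_id`.
#' @param design `data.frame` with columns `sample_id` and `concentration`
#'   (ordered dose levels; any units).
#' @return An object of class `moderated_fit`: per-protein `group_means`,
#'   `s2`, `df`, `s2_post`, per-level sample counts, and the global prior
#'   (`df_prior`, `s2_prior`).
#' @export
fit_moderated <- function(mat, design) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- seq_len(nrow(mat))
  if (!all(colnames(mat) == design$sample_id) && !is.null(colnames(mat)))
    mat <- mat[, design$sample_id, drop = FALSE]
  conc <- design$concentration
  levels_ <- sort(unique(conc))
  K <- length(levels_)
  if (K < 2L) stop("need at least two concentration levels")
  obs <- !is.na(mat)
  # per-level means and counts
  gm <- matrix(NA_real_, nrow(mat), K,
               dimnames = list(rownames(mat), as.character(levels_)))
  gn <- matrix(0L, nrow(mat), K, dimnames = dimnames(gm))
  for (k in seq_len(K)) {
    cols <- which(conc == levels_[k])
    sub <- mat[, cols, drop = FALSE]
    cnt <- rowSums(!is.na(sub))
    sm <- rowSums(sub, na.rm = TRUE)
    gm[, k] <- ifelse(cnt > 0L, sm / cnt, NA_real_)
    gn[, k] <- cnt
  }
  fitted <- gm[, match(conc, levels_), drop = FALSE]
  resid <- mat - fitted
  ss <- rowSums(resid^2, na.rm = TRUE)
  nobs <- rowSums(obs)
  klev <- rowSums(gn > 0L)
  df <- nobs - klev
  s2 <- ifelse(df > 0L, ss / pmax(df, 1L), NA_real_)
  prior <- fit_variance_prior(s2, df)
  d0 <- prior$df_prior; s02 <- prior$s2_prior
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + df * s2) / (d0 + df)
  s2_post[df <= 0L] <- if (is.infinite(d0)) s02 else s02  # pure prior
  structure(list(group_means = gm, group_n = gn, levels = levels_,
                 s2 = s2, df = df, s2_post = s2_post,
                 df_prior = d0, s2_prior = s02,
                 df_total = df + d0),
            class = "moderated_fit")
}

#' Monotonic above/below-cut contrast t-statistics
#'
#' For each cut point between consecutive ordered concentration levels, the
#' moderated two-group t comparing the samples at or below the cut with the
#' samples above it:
#' `t_k = (mean_low - mean_high) / sqrt(s2_post * (1/n_low + 1/n_high))`.
#' Positive values indicate displacement (abundance falling with
#' concentration). Cuts with an empty side for a protein are `NA`.
#'
#' @param fit A [fit_moderated()] result.
#' @param design The matching dose design.
#' @return Matrix (proteins x K-1 cuts) of t-statistics.
#' @export
monotonic_contrast_ts <- function(fit, design) {
  levels_ <- fit$levels
  K <- length(levels_)
  gm <- fit$group_means; gn <- fit$group_n
  out <- matrix(NA_real_, nrow(gm), K - 1L,
                dimnames = list(rownames(gm),
                                paste0("cut", seq_len(K - 1L))))
  for (k in seq_len(K - 1L)) {
    lo <- seq_len(k); hi <- seq(k + 1L, K)
    n_lo <- rowSums(gn[, lo, drop = FALSE])
    n_hi <- rowSums(gn[, hi, drop = FALSE])
    m_lo <- rowSums(gm[, lo, drop = FALSE] * gn[, lo, drop = FALSE],
                    na.rm = TRUE) / pmax(n_lo, 1L)
    m_hi <- rowSums(gm[, hi, drop = FALSE] * gn[, hi, drop = FALSE],
                    na.rm = TRUE) / pmax(n_hi, 1L)
    se <- sqrt(fit$s2_post * (1 / n_lo + 1 / n_hi))
    t_ <- (m_lo - m_hi) / se
    t_[n_lo == 0L | n_hi == 0L | !is.finite(se) | se <= 0] <- NA_real_
    out[, k] <- t_
  }
  out
}

#' Per-protein maximum of a t-statistic series
#'
#' The maximum over cut points, kept signed (an all-negative series yields its
#' negative maximum, never 0). All-`NA` series give `NA`.
#'
#' @param t_series Matrix (proteins x cuts) or numeric vector.
#' @return Numeric vector of per-protein maxima.
#' @export
max_t <- function(t_series) {
  if (is.null(dim(t_series)))
    t_series <- matrix(t_series, nrow = 1L)
  apply(t_series, 1L, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else max(x)
  })
}

# Observed pipeline: returns max-t vector for a label assignment.
pipeline_max_t <- function(mat, design, conc, prior = NULL) {
  d2 <- design; d2$concentration <- conc
  fit <- fit_moderated(mat, d2)
  if (!is.null(prior)) {  # frozen moderation
    fit$s2_post <- (prior$df_prior * prior$s2_prior + fit$df * fit$s2) /
      (prior$df_prior + fit$df)
    if (is.infinite(prior$df_prior)) fit$s2_post <- rep(prior$s2_prior, length(fit$s2))
  }
  max_t(monotonic_contrast_ts(fit, d2))
}

# All distinct assignments of a label multiset (for exhaustive enumeration).
distinct_label_permutations <- function(labels) {
  n <- length(labels)
  if (n > 10L) stop("exhaustive enumeration limited to <= 10 samples")
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (u in unique(v)) {
      rest <- v[-match(u, v)]
      out <- c(out, lapply(perms(rest), function(p) c(u, p)))
    }
    out
  }
  unique(perms(labels))
}

#' Dose-response displacement test with step-down minP permutation p-values
#'
#' Runs the full displacement pipeline (variance moderation, monotonic
#' contrasts, per-protein max-t), then permutes the concentration labels
#' across all samples to build the permutation null. Raw per-protein p-values
#' come from each protein's own null distribution with add-one smoothing,
#' `p = (1 + #\{T_perm >= T_obs\}) / (B + 1)`; family-wise adjustment uses the
#' Westfall-Young step-down minP procedure (single-pass variant over the
#' shared permutations, one-sided, with enforced monotonicity). Proteins with
#' adjusted p below `alpha` are called binders.
#'
#' @param mat Numeric matrix (proteins x samples), log-scale abundances.
#' @param design `data.frame` with `sample_id`, `concentration`.
#' @param B Number of random permutations (default 1000). Ignored when
#'   `exhaustive = TRUE`.
#' @param seed Integer seed for the permutation draw (required unless
#'   `exhaustive`).
#' @param exhaustive Enumerate all distinct label assignments instead of
#'   sampling; the identity assignment is then part of the null set and
#'   p-values are exact rational multiples of `1/N`.
#' @param refit_moderation Re-estimate the variance prior within each
#'   permutation (default `TRUE`); `FALSE` freezes the observed prior.
#' @param alpha Binder-call cutoff on the adjusted p (default 0.05, strict
#'   `<`).
#' @param adjust `"minp"` (default: the step-down minP p is the adjusted p),
#'   `"bh"` (Benjamini-Hochberg on the raw permutation p-values), or
#'   `"minp_bh"` (a further BH pass applied to the step-down p-values).
#' @return `data.frame` with one row per protein: the per-cut t-statistics,
#'   `max_t`, `p_raw`, `p_minp`, `p_adj`, `binder`. Proteins lacking an
#'   observation at some level are reported untested (`NA`).
#' @export
displacement_test <- function(mat, design, B = 1000L, seed = NULL,
                              exhaustive = FALSE, refit_moderation = TRUE,
                              alpha = 0.05,
                              adjust = c("minp", "bh", "minp_bh")) {
  adjust <- match.arg(adjust)
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("P", seq_len(nrow(mat)))
  conc <- design$concentration
  levels_ <- sort(unique(conc))
  # testable: every level observed at least once
  testable <- vapply(seq_len(nrow(mat)), function(i) {
    all(vapply(levels_, function(l)
      any(!is.na(mat[i, conc == l])), TRUE))
  }, TRUE)
  fit <- fit_moderated(mat, design)
  tser <- monotonic_contrast_ts(fit, design)
  t_obs <- max_t(tser)
  t_obs[!testable] <- NA_real_
  prior <- if (refit_moderation) NULL
           else list(df_prior = fit$df_prior, s2_prior = fit$s2_prior)

  if (exhaustive) {
    plist <- distinct_label_permutations(conc)
    N <- length(plist)
    Tb <- vapply(plist, function(p) pipeline_max_t(mat, design, p, prior),
                 numeric(nrow(mat)))
    denom <- N
    count_plus <- 0L   # identity is in the enumerated set
  } else {
    if (B < 1L) stop("B must be >= 1")
    if (is.null(seed)) stop("a seed is required for random permutations")
    Tb <- with_local_seed(seed, {
      vapply(seq_len(B), function(b)
        pipeline_max_t(mat, design, sample(conc), prior),
        numeric(nrow(mat)))
    })
    denom <- B + 1L
    count_plus <- 1L
  }
  Tb <- matrix(Tb, nrow = nrow(mat))
  m <- nrow(mat)

  # raw permutation p per protein (ties counted with >=)
  p_raw <- vapply(seq_len(m), function(i) {
    if (is.na(t_obs[i])) return(NA_real_)
    (count_plus + sum(Tb[i, ] >= t_obs[i], na.rm = TRUE)) / denom
  }, 0)

  # per-permutation p-values from each protein's own null distribution
  nb <- ncol(Tb)
  P <- t(vapply(seq_len(m), function(i) {
    x <- Tb[i, ]
    if (all(is.na(x))) return(rep(NA_real_, nb))
    r <- rank(-x, ties.method = "max", na.last = "keep")
    p <- r / sum(!is.na(x))
    p[is.na(p)] <- 1
    p
  }, numeric(nb)))

  # step-down minP over testable proteins, ordered by raw p (most significant
  # first); successive minima taken from the least significant end
  idx <- which(!is.na(p_raw))
  p_sd <- rep(NA_real_, m)
  if (length(idx)) {
    ord <- idx[order(p_raw[idx], -t_obs[idx])]
    r <- length(ord)
    Q <- matrix(1, r, nb)
    qnext <- rep(1, nb)
    for (j in rev(seq_len(r))) {
      qnext <- pmin(qnext, P[ord[j], ])
      Q[j, ] <- qnext
    }
    adj <- vapply(seq_len(r), function(j)
      (count_plus + sum(Q[j, ] <= p_raw[ord[j]], na.rm = TRUE)) / denom, 0)
    adj <- cummax(adj)
    p_sd[ord] <- adj
  }

  p_adj <- switch(adjust,
                  minp = p_sd,
                  bh = {
                    out <- rep(NA_real_, m)
                    out[idx] <- stats::p.adjust(p_raw[idx], "BH")
                    out
                  },
                  minp_bh = {
                    out <- rep(NA_real_, m)
                    out[idx] <- stats::p.adjust(p_sd[idx], "BH")
                    out
                  })
  res <- data.frame(protein_id = rownames(mat), stringsAsFactors = FALSE)
  for (k in seq_len(ncol(tser))) res[[colnames(tser)[k]]] <- tser[, k]
  res$max_t <- t_obs
  res$p_raw <- p_raw
  res$p_minp <- p_sd
  res$p_adj <- p_adj
  res$binder <- ifelse(is.na(p_adj), NA, p_adj < alpha)
  res
}
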