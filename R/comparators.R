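#' Maxmean statistic of a gene set
#'
#' The larger of the positive-part mean and the negative-part mean of the
#' set's gene scores, both divided by the full set size: with set scores
#' `z`, `maxmean = max(sum(pmax(z, 0)), sum(pmax(-z, 0))) / length(z)`.
#' Symmetric in the sign of `z` and always non-negative.
#'
#' @param z Numeric vector of the set's per-gene scores (e.g. t-statistics).
#' @return The scalar maxmean statistic.
#' @examples
#' maxmean(c(2, -1, -1, 0))  # 0.5
#' @export
maxmean <- function(z) {
  stopifnot(length(z) >= 1L)
  max(sum(pmax(z, 0)), sum(pmax(-z, 0))) / length(z)
}

# Restandardization moments: mean and sd of the maxmean statistic of a random
# gene set of size n drawn (without replacement) from the score vector of one
# permutation column. The positive-part and negative-part set means are
# asymptotically bivariate normal (CLT, with finite-population correction and
# the exact negative cross-covariance -m+ m-), and the moments of the max of
# a bivariate normal follow Clark's formulas. Vectorized over columns.
#' @noRd
restd_moments <- function(m_pos, m_neg, v_pos, v_neg, N, n) {
  fpc <- (N - n) / (N - 1)
  VA <- v_pos / n * fpc
  VB <- v_neg / n * fpc
  CAB <- -(m_pos * m_neg) / n * fpc
  theta2 <- pmax(VA + VB - 2 * CAB, 0)
  theta <- sqrt(theta2)
  delta <- ifelse(theta > 0, (m_pos - m_neg) / theta, 0)
  Phi <- stats::pnorm(delta)
  phi <- stats::dnorm(delta)
  Emax <- ifelse(theta > 0,
                 m_pos * Phi + m_neg * (1 - Phi) + theta * phi,
                 pmax(m_pos, m_neg))
  E2 <- (m_pos^2 + VA) * Phi + (m_neg^2 + VB) * (1 - Phi) +
    (m_pos + m_neg) * theta * phi
  Vmax <- ifelse(theta > 0, pmax(E2 - Emax^2, 1e-12), pmax(VA, VB, 1e-12))
  list(mean = Emax, sd = sqrt(Vmax))
}

# Maxmean + restandardization for every set across all permutation columns.
#' @noRd
gsa_score_cols <- function(Zmat, set_ind, sizes) {
  Zp <- pmax(Zmat, 0)
  Zn <- pmax(-Zmat, 0)
  Sp <- (set_ind %*% Zp) / sizes
  Sn <- (set_ind %*% Zn) / sizes
  Smax <- pmax(Sp, Sn)
  N <- nrow(Zmat)
  m_pos <- colMeans(Zp); m_neg <- colMeans(Zn)
  v_pos <- col_sds(Zp)^2; v_neg <- col_sds(Zn)^2
  S_restd <- Smax
  for (n in unique(sizes)) {
    mom <- restd_moments(m_pos, m_neg, v_pos, v_neg, N, n)
    rows <- which(sizes == n)
    S_restd[rows, ] <- sweep(sweep(Smax[rows, , drop = FALSE], 2L, mom$mean, "-"),
                             2L, mom$sd, "/")
  }
  list(S_max = Smax, S_restd = S_restd)
}

#' Gene set analysis with the maxmean statistic (GSA comparator)
#'
#' Scores each set by the maxmean of its genes' ordinary t-scores, then
#' restandardizes the score by the mean and standard deviation a random gene
#' set of the same size would attain (estimated in closed form from the
#' catch-all distribution of individual gene scores; see the methods
#' vignette). Significance comes from sample-label permutations with a
#' one-sided \eqn{\ge} test on the restandardized (non-negative-scale) score,
#' so shifts in either direction count as significant.
#'
#' @inheritParams padog
#' @return A `padog_fit` object whose results carry `S0` = maxmean and
#'   `S0_star` = restandardized maxmean.
#' @export
gsa_analyze <- function(expr, design, gene_sets, n_perm = 1000, seed = NULL,
                        min_size = 3L, add_one = FALSE) {
  ds <- prepare_dataset(expr, design)
  gene_sets <- restrict_to_measured(gene_sets, rownames(ds$expr), min_size = min_size)
  genes <- unique(gene_sets$gene_id)
  ds$expr <- ds$expr[genes, , drop = FALSE]
  perms <- make_perms(ds, n_perm, seed = seed)
  st <- perm_stats(ds, perms, need_moderated = FALSE)
  Z <- st$t_ord
  Z[!is.finite(Z)] <- sign(Z[!is.finite(Z)]) * max(abs(Z[is.finite(Z)]), 1)
  set_ind <- set_indicator(gene_sets, genes)
  sizes <- as.vector(set_ind %*% rep(1, length(genes)))
  sc <- gsa_score_cols(Z, set_ind, sizes)
  p <- perm_p_values(sc$S_restd, add_one = add_one)
  res <- tibble::tibble(
    set_id = rownames(set_ind),
    size = as.integer(sizes),
    S0 = unname(sc$S_max[, 1L]),
    S0_row = unname(sc$S_restd[, 1L]),
    S0_star = unname(sc$S_restd[, 1L]),
    p = unname(p),
    q = unname(bh_fdr(p)),
    rank_pct = rank(p, ties.method = "average") / length(p) * 100
  )
  nm <- dplyr::distinct(gene_sets, .data$set_id, .data$set_name)
  res <- dplyr::left_join(res, nm, by = "set_id")
  res <- dplyr::arrange(res, .data$p, .data$set_id)
  res <- res[, c("set_id", "set_name", "size", "S0", "S0_row", "S0_star",
                 "p", "q", "rank_pct")]
  new_padog_fit(res, method = "gsa", n_perm = perms$n_perm,
                enumerated = perms$enumerated, seed = seed,
                n_genes = length(genes), add_one = add_one)
}

# ---------------------------------------------------------------------------
# Weighted Kolmogorov-Smirnov enrichment score (GSEA comparator)

# ES for one set across all columns. rank_pos: n_set x K matrix of the set
# genes' positions in the (descending-metric) ranking of each column;
# hit_wt: matching matrix of |metric|^p_w values. N = total genes.
# Running sum: +|m|^p/sum(hits) at hits, -1/(N - n) at misses; ES is the
# extremum of maximal absolute deviation from zero.
#' @noRd
es_for_set <- function(rank_pos, hit_wt, N) {
  n <- nrow(rank_pos)
  K <- ncol(rank_pos)
  if (n >= N) {
    # degenerate: set covers the whole universe, no misses to walk through
    return(rep(0, K))
  }
  o <- order(rep(seq_len(K), each = n), as.vector(rank_pos))
  q <- matrix(as.vector(rank_pos)[o], n, K)
  a <- matrix(as.vector(hit_wt)[o], n, K)
  cs <- apply(a, 2L, cumsum)
  tot <- cs[n, ]
  tot[tot <= 0] <- 1  # all-zero metric: hits contribute equally nothing
  cs <- sweep(cs, 2L, tot, "/")
  miss <- (q - seq_len(n)) / (N - n)          # misses walked before hit j
  up <- cs - miss                              # running sum just after hit j
  down <- rbind(0, cs[-n, , drop = FALSE]) - miss  # just before hit j
  es_max <- as.vector(do.call(pmax, c(asplit(up, 1L), list(0))))
  es_min <- as.vector(do.call(pmin, c(asplit(down, 1L), list(0))))
  ifelse(es_max >= -es_min, es_max, es_min)
}

#' Gene set analysis with a weighted Kolmogorov-Smirnov score (GSEA comparator)
#'
#' Ranks all genes by a two-group metric (signal-to-noise ratio by default;
#' moderated t via `metric = "moderated"`), walks the ranked list accumulating
#' `|metric|^p_w / sum` at set members and a uniform decrement at non-members,
#' and takes the maximal deviation from zero as the enrichment score (ES).
#' The normalized ES divides by the mean absolute permuted ES of matching
#' sign; the nominal p-value is the fraction of same-signed permutation ES
#' values at least as extreme. This is a faithful-algorithm reimplementation
#' of the classic weighted-KS procedure, not a line-by-line port of any
#' particular distribution of it.
#'
#' @inheritParams padog
#' @param metric Ranking metric: `"s2n"` (signal-to-noise, default; paired
#'   designs fall back to the paired t) or `"moderated"` (moderated t).
#' @param p_w Hit-weight exponent (default 1; 0 gives the unweighted KS).
#' @return A `padog_fit` object whose results carry `ES`, `NES`, `p`, `q`,
#'   `rank_pct`.
#' @export
gsea_analyze <- function(expr, design, gene_sets, n_perm = 1000, seed = NULL,
                         metric = c("s2n", "moderated"), p_w = 1,
                         min_size = 3L, add_one = FALSE) {
  metric <- match.arg(metric)
  ds <- prepare_dataset(expr, design)
  gene_sets <- restrict_to_measured(gene_sets, rownames(ds$expr), min_size = min_size)
  genes <- unique(gene_sets$gene_id)
  ds$expr <- ds$expr[genes, , drop = FALSE]
  perms <- make_perms(ds, n_perm, seed = seed)
  st <- perm_stats(ds, perms, need_moderated = metric == "moderated",
                   need_s2n = metric == "s2n" && is.null(ds$block))
  Z <- if (metric == "moderated") st$t_mod else if (!is.null(st$s2n)) st$s2n else st$t_ord
  Z[!is.finite(Z)] <- sign(Z[!is.finite(Z)]) * max(abs(Z[is.finite(Z)]), 1)
  N <- nrow(Z)
  K <- ncol(Z)
  ranks <- apply(-Z, 2L, rank, ties.method = "first")
  hit_w <- abs(Z)^p_w
  sets <- split(match(gene_sets$gene_id, genes),
                factor(gene_sets$set_id, levels = unique(gene_sets$set_id)))
  ES <- matrix(NA_real_, length(sets), K, dimnames = list(names(sets), NULL))
  for (i in seq_along(sets)) {
    gs <- sets[[i]]
    ES[i, ] <- es_for_set(ranks[gs, , drop = FALSE], hit_w[gs, , drop = FALSE], N)
  }
  es_obs <- ES[, 1L]
  ES_perm <- ES[, -1L, drop = FALSE]
  nes <- p <- rep(NA_real_, length(sets))
  for (i in seq_along(sets)) {
    ep <- ES_perm[i, ]
    if (es_obs[i] >= 0) {
      pool <- ep[ep >= 0]
      p[i] <- if (length(pool)) mean(pool >= es_obs[i]) else 0
      nes[i] <- if (length(pool) && mean(pool) > 0) es_obs[i] / mean(pool) else NA_real_
    } else {
      pool <- ep[ep <= 0]
      p[i] <- if (length(pool)) mean(pool <= es_obs[i]) else 0
      nes[i] <- if (length(pool) && mean(pool) < 0) -es_obs[i] / mean(pool) else NA_real_
    }
  }
  if (add_one) {
    # conservative analogue of (b+1)/(K+1) on the same-sign pool
    p <- (p * perms$n_perm + 1) / (perms$n_perm + 1)
  }
  sizes <- lengths(sets)
  res <- tibble::tibble(
    set_id = names(sets),
    size = as.integer(unname(sizes)),
    S0 = unname(es_obs),
    ES = unname(es_obs),
    NES = unname(nes),
    S0_star = unname(nes),
    p = unname(p),
    q = unname(bh_fdr(p)),
    rank_pct = rank(p, ties.method = "average") / length(p) * 100
  )
  nm <- dplyr::distinct(gene_sets, .data$set_id, .data$set_name)
  res <- dplyr::left_join(res, nm, by = "set_id")
  res <- dplyr::arrange(res, .data$p, .data$set_id)
  res <- res[, c("set_id", "set_name", "size", "S0", "ES", "NES", "S0_star",
                 "p", "q", "rank_pct")]
  new_padog_fit(res, method = "gsea", n_perm = perms$n_perm,
                enumerated = perms$enumerated, seed = seed,
                n_genes = length(genes), add_one = add_one)
}
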