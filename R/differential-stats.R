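#' Per-gene ordinary t-scores
#'
#' Two-sample pooled-variance t for unpaired designs (df = n1 + n2 - 2), or a
#' one-sample t on within-block case-minus-control differences for paired
#' designs (df = number of blocks - 1). Effects are always case minus control.
#' Genes with zero residual variance get an infinite t and are flagged rather
#' than dropped.
#'
#' @param expr Expression matrix (genes x samples, row names = gene ids) or a
#'   data frame whose first column holds gene ids.
#' @param design Tibble with columns `sample_id` (optional if `expr` has no
#'   column names), `group`, and optionally `block`.
#' @return Tibble: `gene_id`, `effect`, `s2`, `df`, `t_ordinary`,
#'   `zero_variance`.
#' @export
ordinary_t <- function(expr, design) {
  ds <- prepare_dataset(expr, design)
  st <- gene_stats_table(ds, moderated = FALSE)
  st
}

#' Per-gene moderated t-scores
#'
#' Like [ordinary_t()], but the per-gene residual variances are shrunk toward
#' a common prior value before forming the t-statistic: the shrunken variance
#' is `(d0 * s0_sq + df * s2) / (d0 + df)` where `(d0, s0_sq)` come from
#' [fit_variance_prior()]. Shrinkage keeps genes from looking significant
#' purely because their sample standard deviation happens to be tiny; a gene
#' with zero sample variance still receives a finite moderated t when
#' `d0 > 0`.
#'
#' @inheritParams ordinary_t
#' @param d0,s0_sq Optional fixed prior degrees of freedom and prior variance;
#'   when `NULL` (default) they are estimated from the data. `d0 = 0` disables
#'   shrinkage (moderated t then equals ordinary t); `d0 = Inf` gives every
#'   gene the common variance `s0_sq`.
#' @return Tibble: `gene_id`, `effect`, `s2`, `df`, `t_ordinary`,
#'   `t_moderated`, `zero_variance`, with the prior recorded in attributes
#'   `d0` and `s0_sq` and total moderated df in `df_total`.
#' @export
moderated_t <- function(expr, design, d0 = NULL, s0_sq = NULL) {
  ds <- prepare_dataset(expr, design)
  gene_stats_table(ds, moderated = TRUE, d0 = d0, s0_sq = s0_sq)
}

#' @noRd
gene_stats_table <- function(ds, moderated, d0 = NULL, s0_sq = NULL) {
  perms <- observed_perms(ds)
  st <- perm_stats(ds, perms, need_moderated = moderated,
                   fixed_d0 = d0, fixed_s0 = s0_sq)
  out <- tibble::tibble(
    gene_id = rownames(ds$expr),
    effect = unname(st$effect[, 1L]),
    s2 = unname(st$s2[, 1L]),
    df = st$df,
    t_ordinary = unname(st$t_ord[, 1L]),
    zero_variance = unname(st$s2[, 1L] <= 0)
  )
  if (moderated) {
    out$t_moderated <- unname(st$t_mod[, 1L])
    attr(out, "d0") <- st$d0[1L]
    attr(out, "s0_sq") <- st$s0_sq[1L]
    attr(out, "df_total") <- st$d0[1L] + st$df
  }
  out
}

#' Fit the empirical-Bayes variance prior
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq` of
#' the scaled inverse-chi-squared model for gene-wise residual variances, by
#' moment-matching the log sample variances to a scaled F distribution: the
#' mean and variance of `log(s2)` relate to `(d0, s0_sq)` through digamma and
#' trigamma functions, and the trigamma relation is inverted numerically
#' (Newton, tolerance 1e-8, at most 50 iterations). When the empirical
#' dispersion of `log(s2)` falls at or below its theoretical minimum,
#' `d0 = Inf` and `s0_sq` is the (geometric-mean) common variance.
#'
#' @param s2 Numeric vector of per-gene residual variances.
#' @param df Residual degrees of freedom (scalar, shared by all genes).
#' @return List with elements `d0` and `s0_sq`. With fewer than 10 finite
#'   positive variances the fallback `d0 = 0` (no shrinkage) is returned with
#'   a warning.
#' @export
fit_variance_prior <- function(s2, df) {
  stopifnot(length(df) == 1L, df >= 1)
  fit <- fit_prior_cols(matrix(s2, ncol = 1L), df)
  list(d0 = fit$d0[1L], s0_sq = fit$s0_sq[1L])
}

# Column-wise prior fit: S2 is genes x K (one column per permutation).
# Returns vectors d0, s0_sq of length K. Non-positive / non-finite variances
# are excluded from the fit (they still get shrunk afterwards).
#' @noRd
fit_prior_cols <- function(S2, df) {
  K <- ncol(S2)
  ok <- is.finite(S2) & S2 > 0
  n_ok <- colSums(ok)
  E <- matrix(NA_real_, nrow(S2), K)
  E[ok] <- log(S2[ok])
  E <- E - digamma(df / 2) + log(df / 2)
  emean <- colMeans(E, na.rm = TRUE)
  evar <- colSums((E - rep(emean, each = nrow(E)))^2, na.rm = TRUE) / pmax(n_ok - 1L, 1L)
  excess <- evar - trigamma(df / 2)
  d0 <- rep(Inf, K)
  # at or below the theoretical log-variance dispersion: a point-mass prior;
  # the common value is the plain mean of the sample variances
  SY <- S2
  SY[!ok] <- NA_real_
  s0 <- colMeans(SY, na.rm = TRUE)
  pos <- which(excess > 0 & n_ok >= 10L)
  if (length(pos) > 0L) {
    half_d0 <- trigamma_inverse(excess[pos])
    d0[pos] <- 2 * half_d0
    s0[pos] <- exp(emean[pos] + digamma(half_d0) - log(half_d0))
  }
  few <- which(n_ok < 10L)
  if (length(few) > 0L) {
    warning("fewer than 10 finite positive variances; no shrinkage applied (d0 = 0)",
            call. = FALSE)
    d0[few] <- 0
    s0[few] <- NA_real_
  }
  list(d0 = d0, s0_sq = s0)
}

# Solve trigamma(y) = x for y > 0, vectorized Newton on the log scale
# (monotone decreasing function; asymptotes 1/x at 0+ and 1/sqrt(x) at Inf).
#' @noRd
trigamma_inverse <- function(x, tol = 1e-8, max_iter = 50L) {
  y <- 0.5 + 1 / x
  for (i in seq_len(max_iter)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (max(abs(dif / y)) < tol) break
  }
  y
}

# Observed labeling only, as a one-column permutation object.
#' @noRd
observed_perms <- function(ds) {
  if (!is.null(ds$block)) {
    list(signs = matrix(1, length(unique(ds$block)), 1L))
  } else {
    list(ind = matrix(ds$group2, ncol = 1L))
  }
}

# ---------------------------------------------------------------------------
# Vectorized permutation-stat engine.
#
# `perms$ind` is an n_samples x K logical matrix; each column marks the
# samples assigned to the case group (column 1 is conventionally the observed
# labeling). For paired designs `perms$signs` is a B x K matrix of +-1 block
# sign flips instead. All per-gene statistics are computed for every column
# at once through matrix products.
#' @noRd
perm_stats <- function(ds, perms, need_moderated = TRUE, need_s2n = FALSE,
                       fixed_d0 = NULL, fixed_s0 = NULL) {
  X <- ds$expr
  if (!is.null(ds$block)) {
    stats <- paired_stats(X, ds, perms)
  } else {
    stats <- unpaired_stats(X, ds, perms, need_s2n = need_s2n)
  }
  if (all(stats$s2 <= 0)) {
    stop("zero residual variance in every gene", call. = FALSE)
  }
  stats$t_ord <- stats$effect / sqrt(stats$s2 * stats$unit_sq)
  zero <- stats$s2 <= 0
  if (any(zero)) {
    stats$t_ord[zero] <- sign(stats$effect[zero]) * Inf
    stats$t_ord[zero & stats$effect == 0] <- 0
  }
  if (need_moderated) {
    if (!is.null(fixed_d0)) {
      K <- ncol(stats$s2)
      fit <- list(d0 = rep(fixed_d0, K),
                  s0_sq = rep(if (is.null(fixed_s0)) stop("s0_sq required with fixed d0") else fixed_s0, K))
      if (fixed_d0 == 0) fit$s0_sq <- rep(0, K)
    } else {
      fit <- fit_prior_cols(stats$s2, stats$df)
    }
    stats$d0 <- fit$d0
    stats$s0_sq <- fit$s0_sq
    s2t <- shrink_variances(stats$s2, stats$df, fit$d0, fit$s0_sq)
    stats$t_mod <- stats$effect / sqrt(s2t * stats$unit_sq)
    still_zero <- s2t <= 0
    if (any(still_zero)) {
      stats$t_mod[still_zero] <- sign(stats$effect[still_zero]) * Inf
      stats$t_mod[still_zero & stats$effect == 0] <- 0
    }
  }
  stats
}

#' @noRd
shrink_variances <- function(S2, df, d0, s0_sq) {
  K <- ncol(S2)
  s2t <- S2
  for (k in seq_len(K)) {
    if (is.infinite(d0[k])) {
      s2t[, k] <- s0_sq[k]
    } else if (d0[k] == 0) {
      # no shrinkage
    } else {
      s2t[, k] <- (d0[k] * s0_sq[k] + df * S2[, k]) / (d0[k] + df)
    }
  }
  s2t
}

#' @noRd
unpaired_stats <- function(X, ds, perms, need_s2n = FALSE) {
  P <- perms$ind
  storage.mode(P) <- "double"
  n <- ncol(X)
  n2 <- sum(perms$ind[, 1L])
  n1 <- n - n2
  row_tot <- rowSums(X)
  row_sq <- rowSums(X^2)
  S2sum <- X %*% P
  SQsum <- (X * X) %*% P
  m2 <- S2sum / n2
  m1 <- (row_tot - S2sum) / n1
  ss2 <- pmax(SQsum - n2 * m2^2, 0)
  ss1 <- pmax((row_sq - SQsum) - n1 * m1^2, 0)
  out <- list(
    effect = m2 - m1,
    s2 = (ss1 + ss2) / (n1 + n2 - 2L),
    df = n1 + n2 - 2L,
    unit_sq = 1 / n1 + 1 / n2
  )
  if (need_s2n) {
    sd_sum <- sqrt(ss1 / (n1 - 1L)) + sqrt(ss2 / (n2 - 1L))
    out$s2n <- out$effect / pmax(sd_sum, 1e-8)
  }
  out
}

#' @noRd
paired_stats <- function(X, ds, perms) {
  blocks <- ds$block
  ublk <- unique(blocks)
  B <- length(ublk)
  case_col <- integer(B); ctrl_col <- integer(B)
  for (b in seq_len(B)) {
    i <- which(blocks == ublk[b])
    case_col[b] <- i[ds$group2[i]]
    ctrl_col[b] <- i[!ds$group2[i]]
  }
  D <- X[, case_col, drop = FALSE] - X[, ctrl_col, drop = FALSE]
  Q <- perms$signs
  storage.mode(Q) <- "double"
  M <- (D %*% Q) / B
  d_sq <- rowSums(D^2)  # invariant under sign flips
  s2 <- pmax((d_sq - B * M^2) / (B - 1L), 0)
  list(effect = M, s2 = s2, df = B - 1L, unit_sq = 1 / B)
}
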