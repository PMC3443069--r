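#' Gene frequencies across a gene set collection
#'
#' Counts, for every gene in the analysis universe, the number of sets that
#' contain it, then caps heavy-tailed frequencies: values above the
#' `cap_quantile` quantile of the raw frequencies are replaced by that
#' quantile value (an order statistic, so capped frequencies stay integers).
#' Capping keeps a handful of ubiquitous genes from flattening the weighting
#' curve for everyone else; set `cap_quantile = 1` to disable it for
#' collections without a heavy frequency tail.
#'
#' @param gene_sets Tibble with columns `set_id`, `gene_id` (already
#'   restricted to measured genes; see [restrict_to_measured()]).
#' @param cap_quantile Quantile in (0, 1] at which frequencies are capped
#'   (default 0.99).
#' @return Tibble `gene_id`, `f` (capped frequency), with attributes `f_min`,
#'   `f_max` (post-capping bounds) and `f_raw_max`.
#' @export
gene_frequencies <- function(gene_sets, cap_quantile = 0.99) {
  gene_sets <- validate_gene_sets(gene_sets)
  freq <- dplyr::count(gene_sets, .data$gene_id, name = "f")
  raw_max <- max(freq$f)
  if (cap_quantile < 1) {
    cap <- stats::quantile(freq$f, cap_quantile, type = 1L, names = FALSE)
    freq$f[freq$f > cap] <- cap
  }
  out <- tibble::as_tibble(freq)
  attr(out, "f_min") <- min(out$f)
  attr(out, "f_max") <- max(out$f)
  attr(out, "f_raw_max") <- raw_max
  out
}

#' Down-weighting of overlapping genes
#'
#' Maps capped gene frequencies to weights
#' `w(g) = 1 + ((f_max - f(g)) / (f_max - f_min))^alpha`,
#' so the most frequently occurring gene gets weight 1.0 and set-specific
#' genes get double weight 2.0. Weights are bounded in \[1, 2\] and
#' non-increasing in frequency. With `alpha = 1` the decay is linear in
#' frequency; the default `alpha = 0.5` makes the weight drop faster as the
#' frequency rises from its minimum, which matches the published weighting
#' curve. When every gene has the same frequency all weights are 1.0.
#'
#' @param freqs Output of [gene_frequencies()] (tibble with `gene_id`, `f`).
#' @param alpha Positive exponent of the weighting curve (default 0.5).
#' @return The input tibble with a `w` column added.
#' @export
gene_weights <- function(freqs, alpha = 0.5) {
  stopifnot(alpha > 0)
  f_min <- attr(freqs, "f_min") %||% min(freqs$f)
  f_max <- attr(freqs, "f_max") %||% max(freqs$f)
  if (f_max > f_min) {
    freqs$w <- 1 + ((f_max - freqs$f) / (f_max - f_min))^alpha
  } else {
    freqs$w <- rep(1, nrow(freqs))
  }
  freqs
}

#' Weighted mean absolute score of one gene set
#'
#' The raw set score: the mean over the set's genes of the absolute per-gene
#' score times the gene weight.
#'
#' @param abs_scores Named numeric vector of non-negative per-gene scores
#'   (typically `|moderated t|`), names = gene ids.
#' @param weights Named numeric vector of gene weights (or a tibble with
#'   `gene_id` and `w`).
#' @param set_genes Character vector of the set's gene ids.
#' @return The scalar score.
#' @export
set_score <- function(abs_scores, weights, set_genes) {
  if (length(set_genes) == 0L) stop("empty gene set", call. = FALSE)
  if (is.data.frame(weights)) weights <- stats::setNames(weights$w, weights$gene_id)
  mean(abs_scores[set_genes] * weights[set_genes])
}

#' Two-stage standardization of raw set scores
#'
#' First stage (row randomization): each raw score is centered at the mean of
#' the per-gene weighted absolute scores over the whole analysis universe and
#' scaled by their standard deviation divided by the square root of the set
#' size — the mean and standard deviation a random set of that size would
#' have, by the central limit theorem, so no actual random draws are needed.
#' Second stage: the row-standardized scores are centered and scaled across
#' the sets of the collection.
#'
#' @param S0 Numeric vector of raw set scores.
#' @param abs_weighted Numeric vector of per-gene `|score| * w` values over
#'   the analysis universe.
#' @param sizes Integer vector of set sizes, parallel to `S0`.
#' @return Tibble with `S0`, `S0_row`, `S0_star`.
#' @export
standardize_scores <- function(S0, abs_weighted, sizes) {
  stopifnot(length(S0) == length(sizes), length(S0) >= 2L)
  mu <- mean(abs_weighted)
  sdv <- stats::sd(abs_weighted)
  if (!is.finite(sdv) || sdv <= 0) {
    stop("standard deviation of weighted absolute scores is zero", call. = FALSE)
  }
  S0_row <- (S0 - mu) / (sdv / sqrt(sizes))
  sd_row <- stats::sd(S0_row)
  if (!is.finite(sd_row) || sd_row <= 0) {
    warning("row-standardized scores are constant; standardized scores set to 0",
            call. = FALSE)
    S0_star <- rep(0, length(S0))
  } else {
    S0_star <- (S0_row - mean(S0_row)) / sd_row
  }
  tibble::tibble(S0 = S0, S0_row = S0_row, S0_star = S0_star)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` kept for interface
#' completeness.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

# ---------------------------------------------------------------------------
# Permutation engine

# Build the label-permutation matrix. Unpaired: columns are case-group
# indicator vectors; paired: columns are per-block +-1 sign flips. Column 1 is
# always the observed labeling. If the space of distinct non-identity
# labelings is no larger than n_perm, it is enumerated in full instead of
# sampled (message logged).
#' @noRd
make_perms <- function(ds, n_perm, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(ds$block)) {
    ublk <- unique(ds$block)
    B <- length(ublk)
    total <- 2^B - 1  # distinct non-identity sign patterns
    if (total <= n_perm) {
      signs <- matrix(1, B, total + 1L)
      for (j in seq_len(total)) {
        bits <- as.integer(intToBits(j))[seq_len(B)]
        signs[, j + 1L] <- 1 - 2 * bits
      }
      message("enumerating all ", total, " distinct paired label swaps")
      return(list(signs = signs, n_perm = total, enumerated = TRUE))
    }
    signs <- matrix(1, B, n_perm + 1L)
    for (j in seq_len(n_perm)) {
      repeat {
        s <- sample(c(-1, 1), B, replace = TRUE)
        if (any(s < 0)) break
      }
      signs[, j + 1L] <- s
    }
    return(list(signs = signs, n_perm = n_perm, enumerated = FALSE))
  }
  n <- length(ds$group2)
  n2 <- sum(ds$group2)
  obs <- which(ds$group2)
  total <- choose(n, n2) - 1  # distinct non-identity assignments
  if (total <= n_perm) {
    combs <- utils::combn(n, n2)
    ind <- matrix(FALSE, n, ncol(combs))
    for (j in seq_len(ncol(combs))) ind[combs[, j], j] <- TRUE
    is_obs <- colSums(ind[obs, , drop = FALSE]) == n2
    ind <- cbind(ds$group2, ind[, !is_obs, drop = FALSE])
    message("enumerating all ", total, " distinct label permutations")
    return(list(ind = ind, n_perm = total, enumerated = TRUE))
  }
  ind <- matrix(FALSE, n, n_perm + 1L)
  ind[obs, 1L] <- TRUE
  for (j in seq_len(n_perm)) {
    repeat {
      pick <- sample.int(n, n2)
      if (!setequal(pick, obs)) break
    }
    ind[pick, j + 1L] <- TRUE
  }
  list(ind = ind, n_perm = n_perm, enumerated = FALSE)
}

# Set membership as a dense 0/1 matrix (sets x genes) aligned to `genes`.
#' @noRd
set_indicator <- function(gene_sets, genes) {
  sid <- unique(gene_sets$set_id)
  M <- matrix(0, length(sid), length(genes),
              dimnames = list(sid, NULL))
  gi <- match(gene_sets$gene_id, genes)
  si <- match(gene_sets$set_id, sid)
  keep <- !is.na(gi)
  M[cbind(si[keep], gi[keep])] <- 1
  M
}

# Column-wise sd of a matrix without extra dependencies.
#' @noRd
col_sds <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  sqrt(pmax(colMeans(M * M) - mu^2, 0) * n / (n - 1L))
}

# PADOG scoring across all permutation columns. Tmat is genes x K (column 1 =
# observed); w a per-gene weight vector aligned to rows.
#' @noRd
padog_score_cols <- function(Tmat, w, set_ind, sizes) {
  A <- abs(Tmat) * w
  A[!is.finite(A)] <- max(A[is.finite(A)], 1)  # infinite t: dominate, don't poison
  nG <- nrow(A)
  mu <- colMeans(A)
  sdv <- col_sds(A)
  sdv[sdv <= 0] <- NA_real_
  S0 <- (set_ind %*% A) / sizes
  S0_row <- sweep(sweep(S0, 2L, mu, "-"), 2L, sdv, "/") * sqrt(sizes)
  cmu <- colMeans(S0_row)
  csd <- col_sds(S0_row)
  degenerate <- !is.finite(csd) | csd <= 0
  csd[degenerate] <- 1
  S_star <- sweep(sweep(S0_row, 2L, cmu, "-"), 2L, csd, "/")
  S_star[, degenerate] <- 0
  if (any(degenerate)) {
    warning("constant row-standardized scores in ", sum(degenerate),
            " permutation column(s); standardized scores set to 0", call. = FALSE)
  }
  list(S0 = S0, S0_row = S0_row, S_star = S_star)
}

# Eq.-style permutation p: fraction of permuted standardized scores >= the
# observed one (ties count against significance). add_one gives (b+1)/(K+1).
#' @noRd
perm_p_values <- function(S_star, add_one = FALSE) {
  K <- ncol(S_star) - 1L
  # small tolerance so that mathematically tied permutations (e.g. the
  # complement labeling under equal group sizes, which yields identical |t|)
  # count as >= despite floating-point noise
  thr <- S_star[, 1L] - 1e-9 * pmax(1, abs(S_star[, 1L]))
  b <- rowSums(S_star[, -1L, drop = FALSE] >= thr)
  if (add_one) (b + 1) / (K + 1) else b / K
}

#' Gene set analysis with down-weighting of overlapping genes
#'
#' Scores each gene set by the mean of absolute moderated t-scores of its
#' genes, each t-score weighted by how specific the gene is to the set
#' (see [gene_weights()]); scores are standardized in two stages
#' ([standardize_scores()]) and significance is assessed by permuting sample
#' labels: the p-value is the fraction of permutations whose standardized
#' score meets or exceeds the observed one. The variance prior of the
#' moderated t is re-estimated within every permutation, so each permutation
#' is a complete re-analysis.
#'
#' @inheritParams ordinary_t
#' @param gene_sets Gene set collection tibble (`set_id`, `gene_id`,
#'   optionally `set_name`).
#' @param n_perm Number of sample-label permutations (default 1000). When the
#'   space of distinct non-identity permutations is at most `n_perm`, it is
#'   enumerated exhaustively instead.
#' @param seed Optional integer seed for the permutation stream.
#' @param use_weights Use gene down-weighting (default TRUE). `FALSE` gives
#'   the unweighted variant.
#' @param use_moderated Use moderated t-scores (default TRUE). `FALSE` gives
#'   the ordinary-t variant.
#' @param alpha_weight Exponent of the weighting curve (default 0.5).
#' @param cap_quantile Frequency-cap quantile (default 0.99); 1 disables.
#' @param min_size Minimum analyzable set size (default 3).
#' @param add_one Use the (b+1)/(N+1) permutation p instead of the literal
#'   b/N (default FALSE).
#' @return An object of class `padog_fit`; `tidy()` it for the per-set table
#'   (`set_id`, `set_name`, `size`, `S0`, `S0_star`, `p`, `q`, `rank_pct`,
#'   sorted by ascending p).
#' @examples
#' sim <- make_null_dataset(n_genes = 60, n_per_group = 5, seed = 1)
#' sets <- make_sim_collection(setup = "I", scenario = 1, n_sets = 3, set_size = 20)
#' fit <- padog(sim$expr, sim$design, sets, n_perm = 50, seed = 1)
#' tidy(fit)
#' @export
padog <- function(expr, design, gene_sets, n_perm = 1000, seed = NULL,
                  use_weights = TRUE, use_moderated = TRUE,
                  alpha_weight = 0.5, cap_quantile = 0.99,
                  min_size = 3L, add_one = FALSE) {
  ds <- prepare_dataset(expr, design)
  gene_sets <- restrict_to_measured(gene_sets, rownames(ds$expr), min_size = min_size)
  genes <- unique(gene_sets$gene_id)
  ds$expr <- ds$expr[genes, , drop = FALSE]
  perms <- make_perms(ds, n_perm, seed = seed)
  st <- perm_stats(ds, perms, need_moderated = use_moderated)
  Tmat <- if (use_moderated) st$t_mod else st$t_ord
  fr <- gene_frequencies(gene_sets, cap_quantile = cap_quantile)
  fr <- gene_weights(fr, alpha = alpha_weight)
  w <- if (use_weights) stats::setNames(fr$w, fr$gene_id)[genes] else
    stats::setNames(rep(1, length(genes)), genes)
  set_ind <- set_indicator(gene_sets, genes)
  sizes <- as.vector(set_ind %*% rep(1, length(genes)))
  sc <- padog_score_cols(Tmat, unname(w), set_ind, sizes)
  p <- perm_p_values(sc$S_star, add_one = add_one)
  res <- tibble::tibble(
    set_id = rownames(set_ind),
    size = as.integer(sizes),
    S0 = unname(sc$S0[, 1L]),
    S0_row = unname(sc$S0_row[, 1L]),
    S0_star = unname(sc$S_star[, 1L]),
    p = unname(p),
    q = unname(bh_fdr(p)),
    rank_pct = rank(p, ties.method = "average") / length(p) * 100
  )
  nm <- dplyr::distinct(gene_sets, .data$set_id, .data$set_name)
  res <- dplyr::left_join(res, nm, by = "set_id")
  res <- dplyr::arrange(res, .data$p, .data$set_id)
  res <- res[, c("set_id", "set_name", "size", "S0", "S0_row", "S0_star",
                 "p", "q", "rank_pct")]
  new_padog_fit(res,
                method = variant_name(use_weights, use_moderated),
                n_perm = perms$n_perm, enumerated = perms$enumerated,
                seed = seed, n_genes = length(genes),
                d0 = st$d0[1L], s0_sq = st$s0_sq[1L],
                weights = fr, add_one = add_one)
}

#' @noRd
variant_name <- function(use_weights, use_moderated) {
  if (use_weights && use_moderated) "padog"
  else if (use_weights) "noM"
  else if (use_moderated) "noW"
  else "noMnoW"
}

#' @noRd
new_padog_fit <- function(results, ...) {
  structure(list(results = results, ...), class = "padog_fit")
}

#' Dispatch a gene set analysis by method name
#'
#' Runs one of the implemented set-scoring methods under the shared
#' sample-permutation engine: the PADOG variants (`padog`, `noM`, `noW`,
#' `noMnoW`), the maxmean comparator (`gsa`) or the weighted
#' Kolmogorov-Smirnov comparator (`gsea`). Identical `seed` values give all
#' methods the identical permutation stream, so p-value differences between
#' methods reflect the statistic, not Monte-Carlo noise.
#'
#' @inheritParams padog
#' @param method One of `"padog"`, `"noM"`, `"noW"`, `"noMnoW"`, `"gsa"`,
#'   `"gsea"`.
#' @param ... Passed to the method function.
#' @return A `padog_fit` object.
#' @export
run_gene_set_analysis <- function(expr, design, gene_sets,
                                  method = c("padog", "noM", "noW", "noMnoW",
                                             "gsa", "gsea"),
                                  n_perm = 1000, seed = NULL, ...) {
  method <- match.arg(method)
  switch(method,
    padog = padog(expr, design, gene_sets, n_perm = n_perm, seed = seed, ...),
    noM = padog(expr, design, gene_sets, n_perm = n_perm, seed = seed,
                use_moderated = FALSE, ...),
    noW = padog(expr, design, gene_sets, n_perm = n_perm, seed = seed,
                use_weights = FALSE, ...),
    noMnoW = padog(expr, design, gene_sets, n_perm = n_perm, seed = seed,
                   use_weights = FALSE, use_moderated = FALSE, ...),
    gsa = gsa_analyze(expr, design, gene_sets, n_perm = n_perm, seed = seed, ...),
    gsea = gsea_analyze(expr, design, gene_sets, n_perm = n_perm, seed = seed, ...)
  )
}
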