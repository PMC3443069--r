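# Small programmatic fixtures shared across test files.

# genes x (n1 + n2) normal dataset with optional mean shifts in the case group
tiny_dataset <- function(n_genes = 9, n1 = 3, n2 = 3, seed = 1,
                         shift = NULL) {
  set.seed(seed)
  expr <- matrix(rnorm(n_genes * (n1 + n2)), n_genes,
                 dimnames = list(sprintf("G%02d", seq_len(n_genes)),
                                 sprintf("s%02d", seq_len(n1 + n2))))
  if (!is.null(shift)) {
    expr[seq_along(shift), n1 + seq_len(n2)] <-
      expr[seq_along(shift), n1 + seq_len(n2)] + shift
  }
  design <- tibble::tibble(sample_id = colnames(expr),
                           group = rep(c("control", "case"), c(n1, n2)))
  list(expr = expr, design = design)
}

tiny_sets <- function(n_genes = 9, sets = list(S1 = 1:3, S2 = 4:6, S3 = 7:9)) {
  purrr::map_dfr(names(sets), function(s) {
    tibble::tibble(set_id = s, set_name = s,
                   gene_id = sprintf("G%02d", sets[[s]]))
  })
}

# Independent brute-force PADOG p-values by full enumeration of group
# assignments. Moderation is delegated to limma (an independent
# implementation of the variance prior) when moderated = TRUE.
brute_force_padog <- function(expr, n1, n2, sets, weights, moderated = FALSE,
                              use_weights = TRUE) {
  n <- n1 + n2
  genes <- rownames(expr)
  w <- if (use_weights) weights[genes] else setNames(rep(1, length(genes)), genes)
  combs <- utils::combn(n, n2)
  obs <- (n1 + 1):n
  score_sets <- function(case_idx) {
    ctrl_idx <- setdiff(seq_len(n), case_idx)
    m2 <- rowMeans(expr[, case_idx, drop = FALSE])
    m1 <- rowMeans(expr[, ctrl_idx, drop = FALSE])
    ss <- apply(expr[, case_idx, drop = FALSE], 1, var) * (n2 - 1) +
      apply(expr[, ctrl_idx, drop = FALSE], 1, var) * (n1 - 1)
    s2 <- ss / (n - 2)
    if (moderated) {
      sq <- limma::squeezeVar(s2, df = n - 2)
      s2 <- sq$var.post
    }
    tt <- (m2 - m1) / sqrt(s2 * (1 / n1 + 1 / n2))
    aw <- abs(tt) * w
    s0 <- vapply(sets, function(g) mean(aw[g]), 0)
    sizes <- lengths(sets)
    srow <- (s0 - mean(aw)) / (sd(aw) / sqrt(sizes))
    (srow - mean(srow)) / sd(srow)
  }
  s_obs <- score_sets(obs)
  is_obs <- apply(combs, 2, function(cc) setequal(cc, obs))
  s_perm <- apply(combs[, !is_obs, drop = FALSE], 2, score_sets)
  # tolerance so exact mathematical ties (complement labelings) count as >=
  rowMeans(s_perm >= s_obs - 1e-9 * pmax(1, abs(s_obs)))
}

# Naive weighted-KS running sum for one metric vector and one gene set.
brute_force_es <- function(metric, set_genes, p_w = 1) {
  ord <- order(metric, decreasing = TRUE)
  hits <- names(metric)[ord] %in% set_genes
  inc <- abs(metric[ord])^p_w
  inc[!hits] <- 0
  denom_hit <- sum(inc)
  rs <- 0
  path <- numeric(length(metric))
  for (i in seq_along(ord)) {
    rs <- if (hits[i]) rs + inc[i] / denom_hit else rs - 1 / (sum(!hits))
    path[i] <- rs
  }
  path[which.max(abs(path))]
}
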