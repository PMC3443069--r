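#' Null expression dataset
#'
#' A genes x samples matrix of i.i.d. standard normal values with two
#' equal-size groups — the raw material of the sensitivity and specificity
#' simulations. Defaults match the simulation design used throughout the
#' package's validation: 1000 genes, 50 samples per group.
#'
#' @param n_genes Number of genes (default 1000).
#' @param n_per_group Samples per group (default 50).
#' @param seed Optional seed; seeded calls are bit-reproducible.
#' @param n1,n2 Optional unequal group sizes (override `n_per_group`).
#' @return List with `expr` (matrix, row names `g0001`, ...) and `design`
#'   (tibble `sample_id`, `group` with levels control/case).
#' @export
make_null_dataset <- function(n_genes = 1000, n_per_group = 50, seed = NULL,
                              n1 = n_per_group, n2 = n_per_group) {
  if (!is.null(seed)) set.seed(seed)
  n <- n1 + n2
  expr <- matrix(stats::rnorm(n_genes * n), n_genes, n)
  rownames(expr) <- sprintf("g%04d", seq_len(n_genes))
  colnames(expr) <- sprintf("s%03d", seq_len(n))
  design <- tibble::tibble(
    sample_id = colnames(expr),
    group = rep(c("control", "case"), c(n1, n2))
  )
  list(expr = expr, design = design)
}

#' Differential-expression scenario definitions
#'
#' The five injection recipes of the sensitivity study, applied to the first
#' genes of the target set: scenario 1 shifts 15 genes up by 0.3; scenario 2,
#' 10 up / 5 down by 0.3; scenario 3, 8 up / 7 down by 0.3; scenario 4,
#' 7 up / 3 down by 0.4; scenario 5, 5 up / 5 down by 0.4. Scenario 0 is a
#' pure null (no injection).
#'
#' @param scenario Integer 0-5.
#' @return List with `n_up`, `n_down`, `delta`.
#' @export
scenario_spec <- function(scenario) {
  stopifnot(scenario %in% 0:5)
  switch(as.character(scenario),
    "0" = list(n_up = 0L, n_down = 0L, delta = 0),
    "1" = list(n_up = 15L, n_down = 0L, delta = 0.3),
    "2" = list(n_up = 10L, n_down = 5L, delta = 0.3),
    "3" = list(n_up = 8L, n_down = 7L, delta = 0.3),
    "4" = list(n_up = 7L, n_down = 3L, delta = 0.4),
    "5" = list(n_up = 5L, n_down = 5L, delta = 0.4)
  )
}

#' Inject a differential-expression effect into a dataset
#'
#' Adds `+delta` to the case-group values of the first `n_up` target genes
#' and `-delta` to the next `n_down`, leaving all other cells untouched.
#'
#' @param expr Expression matrix (genes x samples).
#' @param design Design tibble with `sample_id`, `group`.
#' @param target_genes Character vector of candidate genes, in order.
#' @param n_up,n_down Numbers of up-/down-shifted genes.
#' @param delta Shift magnitude in expression units (> 0 unless both counts
#'   are 0).
#' @return The modified expression matrix.
#' @export
inject_effect <- function(expr, design, target_genes, n_up, n_down, delta) {
  if (n_up + n_down > length(target_genes)) {
    stop("n_up + n_down exceeds the number of target genes", call. = FALSE)
  }
  if (n_up + n_down == 0L || delta == 0) return(expr)
  lev <- group_levels(as.character(design$group))
  case_cols <- which(as.character(design$group) == lev[2L])
  if (n_up > 0L) {
    up <- target_genes[seq_len(n_up)]
    expr[up, case_cols] <- expr[up, case_cols] + delta
  }
  if (n_down > 0L) {
    dn <- target_genes[n_up + seq_len(n_down)]
    expr[dn, case_cols] <- expr[dn, case_cols] - delta
  }
  expr
}

#' Simulated gene set collection with controlled overlap
#'
#' Partitions `n_sets * set_size` genes into consecutive disjoint sets
#' (`GS1`, `GS2`, ...) and then, per the overlap setup, augments the last set
#' `GS50`: setup `"I"` leaves the partition disjoint; `"II"` adds the target
#' set GS1's differentially expressed genes (the first `n_up + n_down` of
#' GS1, per the scenario) to GS50, so their frequency doubles and their
#' weight drops; `"III"` adds GS1's non-DE genes to GS50 instead, leaving the
#' DE genes set-specific.
#'
#' @param setup `"I"`, `"II"` or `"III"`.
#' @param scenario Scenario number (0-5), defining which GS1 genes count as
#'   DE for setups II/III.
#' @param n_sets Number of sets (default 50).
#' @param set_size Genes per set (default 20).
#' @return Gene set tibble (`set_id`, `set_name`, `gene_id`).
#' @export
make_sim_collection <- function(setup = c("I", "II", "III"), scenario = 1,
                                n_sets = 50, set_size = 20) {
  setup <- match.arg(setup)
  genes <- sprintf("g%04d", seq_len(n_sets * set_size))
  sets <- tibble::tibble(
    set_id = rep(sprintf("GS%d", seq_len(n_sets)), each = set_size),
    gene_id = genes
  )
  sp <- scenario_spec(scenario)
  n_de <- sp$n_up + sp$n_down
  gs1 <- genes[seq_len(set_size)]
  extra <- switch(setup,
    I = character(0),
    II = gs1[seq_len(n_de)],
    III = gs1[setdiff(seq_len(set_size), seq_len(n_de))]
  )
  if (length(extra) > 0L) {
    sets <- dplyr::bind_rows(
      sets, tibble::tibble(set_id = sprintf("GS%d", n_sets), gene_id = extra))
  }
  sets$set_name <- sets$set_id
  sets[, c("set_id", "set_name", "gene_id")]
}

#' Synthetic overlap-bearing gene set collection
#'
#' Emulates the overlap structure of a curated pathway collection (e.g. KEGG)
#' without bundling one: set sizes are drawn uniformly from `size_range`, and
#' members are sampled with heavy-tailed gene "popularity" weights so that a
#' sizeable fraction of genes belongs to several sets and a few hub genes
#' belong to many, giving the frequency distribution its long tail. Entirely
#' synthetic — gene and set identifiers carry no biological meaning.
#'
#' @param n_sets Number of sets (default 150).
#' @param n_genes Size of the gene pool sets draw from (default 3000).
#' @param size_range Inclusive range of set sizes (default c(10, 80)).
#' @param tail Pareto tail exponent of the popularity weights; smaller is
#'   heavier (default 1.5).
#' @param seed Optional seed.
#' @return Gene set tibble (`set_id`, `set_name`, `gene_id`).
#' @export
make_overlap_collection <- function(n_sets = 150, n_genes = 3000,
                                    size_range = c(10, 80), tail = 1.5,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- (1 - stats::runif(n_genes))^(-1 / tail)
  genes <- sprintf("g%04d", seq_len(n_genes))
  sizes <- sample(size_range[1L]:size_range[2L], n_sets, replace = TRUE)
  purrr::map_dfr(seq_len(n_sets), function(i) {
    members <- sample.int(n_genes, sizes[i], prob = pop)
    tibble::tibble(set_id = sprintf("SET%03d", i),
                   set_name = sprintf("SET%03d", i),
                   gene_id = genes[sort(members)])
  })
}

# ---------------------------------------------------------------------------
# Fast evaluation paths shared by the simulation drivers. These reuse exactly
# the scoring internals the public fitting functions use; what they save is
# recomputing the permutation t-matrices once per method/setup.

#' @noRd
padog_p_from_T <- function(Tmat, gene_sets, genes, alpha_weight = 0.5,
                           cap_quantile = 1, use_weights = TRUE) {
  w <- if (use_weights) {
    fr <- gene_weights(gene_frequencies(gene_sets, cap_quantile = cap_quantile),
                       alpha = alpha_weight)
    stats::setNames(fr$w, fr$gene_id)[genes]
  } else {
    stats::setNames(rep(1, length(genes)), genes)
  }
  set_ind <- set_indicator(gene_sets, genes)
  sizes <- as.vector(set_ind %*% rep(1, length(genes)))
  sc <- padog_score_cols(Tmat, unname(w), set_ind, sizes)
  stats::setNames(perm_p_values(sc$S_star), rownames(set_ind))
}

#' @noRd
gsa_p_from_Z <- function(Zmat, gene_sets, genes) {
  set_ind <- set_indicator(gene_sets, genes)
  sizes <- as.vector(set_ind %*% rep(1, length(genes)))
  sc <- gsa_score_cols(Zmat, set_ind, sizes)
  stats::setNames(perm_p_values(sc$S_restd), rownames(set_ind))
}

#' @noRd
gsea_p_from_Z <- function(Zmat, gene_sets, genes, p_w = 1) {
  N <- nrow(Zmat)
  ranks <- apply(-Zmat, 2L, rank, ties.method = "first")
  hit_w <- abs(Zmat)^p_w
  sets <- split(match(gene_sets$gene_id, genes),
                factor(gene_sets$set_id, levels = unique(gene_sets$set_id)))
  p <- stats::setNames(rep(NA_real_, length(sets)), names(sets))
  for (i in seq_along(sets)) {
    gs <- sets[[i]]
    es <- es_for_set(ranks[gs, , drop = FALSE], hit_w[gs, , drop = FALSE], N)
    obs <- es[1L]; ep <- es[-1L]
    pool <- if (obs >= 0) ep[ep >= 0] else ep[ep <= 0]
    p[i] <- if (length(pool) == 0L) 0 else if (obs >= 0) mean(pool >= obs) else mean(pool <= obs)
  }
  p
}

# Deterministic sub-seed streams (kept under 2^31).
#' @noRd
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}

#' Sensitivity simulation study
#'
#' Runs the replicate simulation behind the sensitivity comparison: for each
#' scenario, `n_rep` datasets of `n_genes` x (2 x `n_per_group`) i.i.d.
#' N(0,1) values are generated, the scenario's effect is injected into the
#' target set GS1, and each requested method is run; the p-value GS1 receives
#' is recorded. Overlap setups affect only the PADOG-family variants (the
#' comparators ignore set overlap), so `gsa`/`gsea` are evaluated once per
#' replicate on the disjoint collection and reported with `setup = NA`.
#' Replicate r of every method and setup sees the same data matrix and the
#' same permutation stream, so contrasts between methods are paired.
#' Frequency capping is disabled here: simulated frequencies are only 1 or 2,
#' and capping at the 99th percentile would erase the overlap the setups
#' exist to create.
#'
#' @param methods Subset of `c("padog", "noM", "noW", "noMnoW", "gsa",
#'   "gsea")`.
#' @param scenarios Scenario numbers (default 1:5; see [scenario_spec()]).
#' @param setups Overlap setups for the PADOG variants (default I, II, III).
#' @param n_rep Replicates per scenario (default 50).
#' @param n_perm Permutations per analysis (default 1000).
#' @param n_genes,n_per_group,n_sets,set_size Data dimensions (defaults 1000,
#'   50, 50, 20).
#' @param seed Integer seed governing the whole study.
#' @return Tibble `scenario`, `setup`, `method`, `replicate`, `p` (the target
#'   set's p-value).
#' @export
run_sensitivity <- function(methods = c("padog", "gsa"), scenarios = 1:5,
                            setups = c("I", "II", "III"), n_rep = 50,
                            n_perm = 1000, n_genes = 1000, n_per_group = 50,
                            n_sets = 50, set_size = 20, seed = 1) {
  methods <- match.arg(methods, c("padog", "noM", "noW", "noMnoW", "gsa", "gsea"),
                       several.ok = TRUE)
  padog_like <- intersect(methods, c("padog", "noM", "noW", "noMnoW"))
  seeds <- derive_seeds(seed, length(scenarios) * n_rep * 2L)
  si <- 0L
  out <- vector("list", 0L)
  colls <- list()
  for (scen in scenarios) {
    sp <- scenario_spec(scen)
    for (setup in setups) {
      colls[[paste(scen, setup)]] <-
        make_sim_collection(setup, scen, n_sets = n_sets, set_size = set_size)
    }
    for (r in seq_len(n_rep)) {
      si <- si + 1L
      sim <- make_null_dataset(n_genes, n_per_group, seed = seeds[2L * si - 1L])
      gs1 <- sprintf("g%04d", seq_len(set_size))
      sim$expr <- inject_effect(sim$expr, sim$design, gs1,
                                sp$n_up, sp$n_down, sp$delta)
      ds <- prepare_dataset(sim$expr, sim$design)
      perms <- make_perms(ds, n_perm, seed = seeds[2L * si])
      st <- perm_stats(ds, perms,
                       need_moderated = any(c("padog", "noW") %in% methods),
                       need_s2n = "gsea" %in% methods)
      genes <- rownames(ds$expr)
      for (m in padog_like) {
        Tm <- if (m %in% c("padog", "noW")) st$t_mod else st$t_ord
        for (setup in setups) {
          coll <- colls[[paste(scen, setup)]]
          p <- padog_p_from_T(Tm, coll, genes, cap_quantile = 1,
                              use_weights = m %in% c("padog", "noM"))
          out[[length(out) + 1L]] <- tibble::tibble(
            scenario = scen, setup = setup, method = m, replicate = r,
            p = unname(p["GS1"]))
        }
      }
      if ("gsa" %in% methods) {
        p <- gsa_p_from_Z(st$t_ord, colls[[paste(scen, "I")]], genes)
        out[[length(out) + 1L]] <- tibble::tibble(
          scenario = scen, setup = NA_character_, method = "gsa",
          replicate = r, p = unname(p["GS1"]))
      }
      if ("gsea" %in% methods) {
        Z <- if (!is.null(st$s2n)) st$s2n else st$t_ord
        p <- gsea_p_from_Z(Z, colls[[paste(scen, "I")]], genes)
        out[[length(out) + 1L]] <- tibble::tibble(
          scenario = scen, setup = NA_character_, method = "gsea",
          replicate = r, p = unname(p["GS1"]))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Aggregate a sensitivity study
#'
#' @param results Output of [run_sensitivity()].
#' @return Tibble with mean and median target-set p per scenario/setup/method
#'   and the replicate count and standard error of the mean.
#' @export
summarize_sensitivity <- function(results) {
  dplyr::summarise(
    dplyr::group_by(results, .data$scenario, .data$setup, .data$method),
    mean_p = mean(.data$p),
    median_p = stats::median(.data$p),
    se_p = stats::sd(.data$p) / sqrt(dplyr::n()),
    n = dplyr::n(),
    .groups = "drop")
}

#' Specificity study on fully random data
#'
#' Generates replica datasets entirely from N(0,1) — so every null hypothesis
#' is true — while keeping a fixed, overlap-bearing gene set collection, runs
#' each method, and pools all per-set p-values; the fraction below each
#' threshold estimates the method's false positive rate.
#'
#' @param methods Methods to evaluate (default padog + gsa).
#' @param gene_sets Gene set collection; default is a
#'   [make_overlap_collection()] draw (seeded from `seed`).
#' @param shapes Tibble with columns `n1`, `n2` (per-replicate sample sizes),
#'   recycled over replicates. Default: 24 shapes with sizes drawn from
#'   10..60, emulating a typical panel of two-group microarray studies.
#' @param n_rep Number of replica datasets (default 100).
#' @param n_perm Permutations per analysis (default 500).
#' @param alphas Significance thresholds (default 0.05, 0.01).
#' @param seed Integer seed.
#' @return Tibble `method`, `alpha`, `fp_rate`, `n_tests`, with the full
#'   per-set p-values in attribute `p_values`.
#' @export
run_specificity_random <- function(methods = c("padog", "gsa"),
                                   gene_sets = NULL, shapes = NULL,
                                   n_rep = 100, n_perm = 500,
                                   alphas = c(0.05, 0.01), seed = 1) {
  methods <- match.arg(methods, c("padog", "noM", "noW", "noMnoW", "gsa", "gsea"),
                       several.ok = TRUE)
  seeds <- derive_seeds(seed, 2L + 3L * n_rep)
  if (is.null(gene_sets)) {
    gene_sets <- make_overlap_collection(seed = seeds[1L])
  }
  gene_sets <- validate_gene_sets(gene_sets)
  genes <- unique(gene_sets$gene_id)
  if (is.null(shapes)) {
    set.seed(seeds[2L])
    shapes <- tibble::tibble(n1 = sample(10:60, 24, replace = TRUE),
                             n2 = sample(10:60, 24, replace = TRUE))
  }
  shapes <- shapes[rep_len(seq_len(nrow(shapes)), n_rep), ]
  pvals <- stats::setNames(vector("list", length(methods)), methods)
  for (r in seq_len(n_rep)) {
    sim <- make_null_dataset(n_genes = length(genes), n1 = shapes$n1[r],
                             n2 = shapes$n2[r], seed = seeds[2L + 2L * r - 1L])
    rownames(sim$expr) <- genes
    ds <- prepare_dataset(sim$expr, sim$design)
    perms <- make_perms(ds, n_perm, seed = seeds[2L + 2L * r])
    st <- perm_stats(ds, perms,
                     need_moderated = any(c("padog", "noW") %in% methods),
                     need_s2n = "gsea" %in% methods)
    for (m in methods) {
      p <- switch(m,
        padog = padog_p_from_T(st$t_mod, gene_sets, genes, cap_quantile = 0.99),
        noM = padog_p_from_T(st$t_ord, gene_sets, genes, cap_quantile = 0.99),
        noW = padog_p_from_T(st$t_mod, gene_sets, genes, use_weights = FALSE),
        noMnoW = padog_p_from_T(st$t_ord, gene_sets, genes, use_weights = FALSE),
        gsa = gsa_p_from_Z(st$t_ord, gene_sets, genes),
        gsea = gsea_p_from_Z(if (!is.null(st$s2n)) st$s2n else st$t_ord,
                             gene_sets, genes)
      )
      pvals[[m]] <- c(pvals[[m]], unname(p))
    }
  }
  out <- purrr::map_dfr(methods, function(m) {
    purrr::map_dfr(alphas, function(a) {
      tibble::tibble(method = m, alpha = a,
                     fp_rate = mean(pvals[[m]] < a),
                     n_tests = length(pvals[[m]]))
    })
  })
  attr(out, "p_values") <- pvals
  out
}

#' Specificity study by label permutation of supplied datasets
#'
#' Shuffles the group labels of each supplied dataset before analysis (which
#' preserves the between-gene correlation structure), repeats over
#' `n_trials` trials, and summarizes how the target sets behave under this
#' simulated null: their median p-value should sit near 0.5, their median
#' percentile rank near 50, and about 5% of all sets should reach p < 0.05.
#'
#' @param datasets Named list; each element a list with `expr` and `design`.
#' @param gene_sets Gene set collection tibble.
#' @param targets Tibble `dataset_id`, `target_set_id` naming each dataset's
#'   target set; `dataset_id` must match `names(datasets)`.
#' @param methods Methods to evaluate.
#' @param n_trials Number of label-shuffle trials (default 100).
#' @param n_perm Permutations per analysis (default 500).
#' @param seed Integer seed.
#' @return Tibble `method`, `p_median`, `rank_median`, `pct_p_lt_05`
#'   (averages of the per-trial statistics), plus `n_trials`.
#' @export
run_specificity_label_perm <- function(datasets, gene_sets, targets,
                                       methods = c("padog", "gsa"),
                                       n_trials = 100, n_perm = 500, seed = 1) {
  stopifnot(!is.null(names(datasets)),
            all(targets$dataset_id %in% names(datasets)))
  methods <- match.arg(methods, c("padog", "noM", "noW", "noMnoW", "gsa", "gsea"),
                       several.ok = TRUE)
  seeds <- derive_seeds(seed, n_trials * length(datasets) * 2L)
  k <- 0L
  rows <- vector("list", 0L)
  for (tr in seq_len(n_trials)) {
    for (d in names(datasets)) {
      k <- k + 1L
      dat <- datasets[[d]]
      set.seed(seeds[2L * k - 1L])
      shuffled <- dat$design
      shuffled$group <- sample(shuffled$group)
      # degenerate shuffles (a group lost) are re-drawn
      while (length(unique(shuffled$group)) < 2L ||
             min(table(shuffled$group)) < 2L) {
        shuffled$group <- sample(shuffled$group)
      }
      tgt <- targets$target_set_id[targets$dataset_id == d][1L]
      for (m in methods) {
        fit <- run_gene_set_analysis(dat$expr, shuffled, gene_sets, method = m,
                                     n_perm = n_perm, seed = seeds[2L * k])
        res <- fit$results
        i <- match(tgt, res$set_id)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          trial = tr, dataset_id = d, method = m,
          p = res$p[i], rank_pct = res$rank_pct[i],
          pct_p_lt_05 = mean(res$p < 0.05) * 100)
      }
    }
  }
  per_trial <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(rows), .data$method, .data$trial),
    p_median = stats::median(.data$p),
    rank_median = stats::median(.data$rank_pct),
    pct_p_lt_05 = mean(.data$pct_p_lt_05),
    .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(per_trial, .data$method),
    p_median = mean(.data$p_median),
    rank_median = mean(.data$rank_median),
    pct_p_lt_05 = mean(.data$pct_p_lt_05),
    n_trials = dplyr::n(),
    .groups = "drop")
}
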