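test_that("null datasets have the declared shape and distribution", {
  sim <- make_null_dataset(seed = 123)
  expect_equal(dim(sim$expr), c(1000L, 100L))
  expect_equal(unname(table(sim$design$group)), c(50L, 50L), ignore_attr = TRUE)
  sim2 <- make_null_dataset(seed = 123)
  expect_identical(sim$expr, sim2$expr)
  n <- length(sim$expr)
  expect_lt(abs(mean(sim$expr)), 3 / sqrt(n))
  expect_lt(abs(var(as.vector(sim$expr)) - 1), 3 * sqrt(2 / n))
})

test_that("overlap setups shape the collection as designed", {
  cI <- make_sim_collection("I", 1)
  ovl <- function(coll, a, b) {
    length(intersect(coll$gene_id[coll$set_id == a],
                     coll$gene_id[coll$set_id == b]))
  }
  sizes <- dplyr::count(cI, set_id)
  expect_equal(nrow(sizes), 50L)
  expect_true(all(sizes$n == 20L))
  expect_equal(ovl(cI, "GS1", "GS50"), 0L)

  cII <- make_sim_collection("II", 1)
  expect_equal(ovl(cII, "GS1", "GS50"), 15L)
  fr <- gene_frequencies(cII, cap_quantile = 1)
  shared <- fr$f[fr$gene_id %in% sprintf("g%04d", 1:15)]
  expect_true(all(shared == 2))

  cIII <- make_sim_collection("III", 5)
  expect_equal(ovl(cIII, "GS1", "GS50"), 10L)  # the 10 non-DE genes
  cIII1 <- make_sim_collection("III", 1)
  expect_equal(ovl(cIII1, "GS1", "GS50"), 5L)
})

test_that("effect injection shifts only the case group of the targeted genes", {
  sim <- make_null_dataset(n_genes = 50, n_per_group = 4, seed = 9)
  before <- sim$expr
  after <- inject_effect(sim$expr, sim$design, sprintf("g%04d", 1:20), 10, 5, 0.3)
  case_cols <- which(sim$design$group == "case")
  ctrl_cols <- which(sim$design$group == "control")
  expect_equal(after[1:10, case_cols], before[1:10, case_cols] + 0.3)
  expect_equal(after[11:15, case_cols], before[11:15, case_cols] - 0.3)
  expect_equal(after[16:50, ], before[16:50, ])
  expect_equal(after[, ctrl_cols], before[, ctrl_cols])
  expect_identical(inject_effect(before, sim$design, sprintf("g%04d", 1:20),
                                 0, 0, 0), before)
  expect_error(inject_effect(before, sim$design, sprintf("g%04d", 1:3), 2, 2, 0.3),
               "exceeds")
})

test_that("a single-replicate sensitivity run emits one p per method/setup", {
  res <- run_sensitivity(methods = c("padog", "gsa", "gsea"), scenarios = 2,
                         setups = c("I", "II"), n_rep = 1, n_perm = 30,
                         n_genes = 200, n_per_group = 6, n_sets = 10,
                         set_size = 20, seed = 2)
  expect_equal(nrow(res), 4L)  # padog x 2 setups + gsa + gsea
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(is.na(res$setup[res$method %in% c("gsa", "gsea")])))
})

test_that("the sensitivity driver reproduces a direct padog() call", {
  seeds <- padog:::derive_seeds(77, 2)
  res <- run_sensitivity(methods = "padog", scenarios = 3, setups = "I",
                         n_rep = 1, n_perm = 60, n_genes = 200,
                         n_per_group = 8, n_sets = 10, set_size = 20, seed = 77)
  sim <- make_null_dataset(200, 8, seed = seeds[1])
  sp <- scenario_spec(3)
  sim$expr <- inject_effect(sim$expr, sim$design, sprintf("g%04d", 1:20),
                            sp$n_up, sp$n_down, sp$delta)
  sets <- make_sim_collection("I", 3, n_sets = 10, set_size = 20)
  fit <- padog(sim$expr, sim$design, sets, n_perm = 60, seed = seeds[2],
               cap_quantile = 1)
  expect_equal(res$p, fit$results$p[fit$results$set_id == "GS1"])
})

test_that("synthetic overlap collections have a heavy-tailed frequency profile", {
  coll <- make_overlap_collection(n_sets = 80, n_genes = 1500, seed = 3)
  fr <- gene_frequencies(coll, cap_quantile = 1)
  expect_gt(mean(fr$f > 1), 0.2)     # sizeable overlap fraction
  expect_gt(max(fr$f), 5)            # hub genes exist
  sizes <- dplyr::count(coll, set_id)
  expect_true(all(sizes$n >= 10 & sizes$n <= 80))
})

test_that("random-data specificity rates are monotone in alpha and reproducible", {
  coll <- make_overlap_collection(n_sets = 15, n_genes = 300,
                                  size_range = c(8, 25), seed = 5)
  res <- run_specificity_random(methods = "padog", gene_sets = coll,
                                n_rep = 4, n_perm = 60,
                                alphas = c(0.01, 0.05, 0.2), seed = 11)
  fp <- res$fp_rate[order(res$alpha)]
  expect_true(all(diff(fp) >= 0))
  res2 <- run_specificity_random(methods = "padog", gene_sets = coll,
                                 n_rep = 4, n_perm = 60,
                                 alphas = c(0.01, 0.05, 0.2), seed = 11)
  expect_equal(res$fp_rate, res2$fp_rate)
})

test_that("label-permutation specificity on null stand-ins looks uniform", {
  coll <- make_overlap_collection(n_sets = 12, n_genes = 240,
                                  size_range = c(8, 25), seed = 7)
  genes <- unique(coll$gene_id)
  datasets <- lapply(1:3, function(i) {
    sim <- make_null_dataset(n_genes = length(genes), n_per_group = 8,
                             seed = 100 + i)
    rownames(sim$expr) <- genes
    sim
  })
  names(datasets) <- paste0("d", 1:3)
  targets <- tibble::tibble(dataset_id = names(datasets),
                            target_set_id = c("SET001", "SET002", "SET003"))
  res <- run_specificity_label_perm(datasets, coll, targets,
                                    methods = "padog", n_trials = 4,
                                    n_perm = 60, seed = 13)
  expect_equal(nrow(res), 1L)
  # medians should be mid-scale, not near zero, under a shuffled-label null
  expect_gt(res$p_median, 0.1)
  expect_gt(res$rank_median, 15)
  expect_lt(res$pct_p_lt_05, 30)
})
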