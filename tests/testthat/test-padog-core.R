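test_that("weights hit the endpoints and the printed curve values", {
  fr <- tibble::tibble(gene_id = c("a", "b", "c"), f = c(10, 1, 5.5))
  attr(fr, "f_min") <- 1; attr(fr, "f_max") <- 10
  w1 <- gene_weights(fr, alpha = 1)
  expect_equal(w1$w, c(1, 2, 1.5))
  w05 <- gene_weights(fr, alpha = 0.5)
  expect_equal(w05$w, c(1, 2, 1 + sqrt(0.5)))
})

test_that("weights are bounded, monotone and extreme at the frequency extremes", {
  set.seed(4)
  for (i in 1:20) {
    n_sets <- sample(3:30, 1)
    gs <- purrr::map_dfr(seq_len(n_sets), function(s) {
      tibble::tibble(set_id = paste0("S", s),
                     gene_id = sample(sprintf("g%03d", 1:120),
                                      sample(5:40, 1)))
    })
    fr <- gene_weights(gene_frequencies(gs, cap_quantile = 1))
    expect_true(all(fr$w >= 1 & fr$w <= 2))
    ord <- order(fr$f)
    expect_true(all(diff(fr$w[ord]) <= 1e-12))
    if (max(fr$f) > min(fr$f)) {
      expect_equal(fr$w[which.max(fr$f)], 1)
      expect_equal(fr$w[which.min(fr$f)], 2)
    } else {
      expect_true(all(fr$w == 1))
    }
  }
})

test_that("frequency capping replaces only the heavy tail", {
  gs <- dplyr::bind_rows(
    purrr::map_dfr(1:100, ~tibble::tibble(set_id = paste0("S", .x),
                                          gene_id = c(paste0("u", .x), "hub"))),
    tibble::tibble(set_id = "S1", gene_id = "u2"))
  fr <- gene_frequencies(gs, cap_quantile = 0.99)
  expect_lt(max(fr$f), 100)                       # hub capped
  expect_equal(attr(fr, "f_raw_max"), 100)
  fr_off <- gene_frequencies(gs, cap_quantile = 1)
  expect_equal(max(fr_off$f), 100)                # cap disabled
  expect_equal(min(fr_off$f), 1)
})

test_that("set scores are weighted means of absolute scores", {
  s <- c(A = 1, B = 2)
  w <- c(A = 2, B = 1)
  expect_equal(set_score(s, w, c("A", "B")), 2)
  expect_equal(set_score(s, c(A = 1, B = 1), c("A", "B")), mean(s))
  expect_equal(set_score(c(A = 0, B = 0), w, c("A", "B")), 0)
  expect_error(set_score(s, w, character(0)), "empty")
})

test_that("two-stage standardization has the documented invariances", {
  aw <- c(rexp(50), 2, 3)
  S0 <- c(2.0, 2.0)
  out <- standardize_scores(S0, aw, sizes = c(25, 100))
  expect_equal(out$S0_row[2] / out$S0_row[1], 2)  # sqrt(100/25)

  out2 <- standardize_scores(c(1, 2, 4), aw, sizes = c(10, 10, 10))
  out2x <- standardize_scores(2 * c(1, 2, 4), 2 * aw, sizes = c(10, 10, 10))
  expect_equal(out2$S0_star, out2x$S0_star, tolerance = 1e-12)

  expect_warning(
    flat <- standardize_scores(rep(mean(aw), 3), aw, sizes = c(5, 5, 5)),
    "constant")
  expect_equal(flat$S0_star, c(0, 0, 0))
})

test_that("BH adjustment matches hand computation and edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 4)), rep(1, 4))
})

test_that("sampling engine equals exhaustive enumeration on tiny designs", {
  # 2v2: choose(4,2) - 1 = 5 distinct non-identity labelings -> enumerated
  d <- tiny_dataset(n_genes = 9, n1 = 2, n2 = 2, seed = 31,
                    shift = rep(1.2, 3))
  sets <- tiny_sets()
  fr <- gene_weights(gene_frequencies(sets, cap_quantile = 1))
  w <- setNames(fr$w, fr$gene_id)
  set_list <- split(sets$gene_id, factor(sets$set_id, unique(sets$set_id)))

  suppressMessages(
    fit <- padog(d$expr, d$design, sets, n_perm = 1000, seed = 1,
                 use_moderated = FALSE, cap_quantile = 1))
  expect_true(fit$enumerated)
  expect_equal(fit$n_perm, 5)
  oracle <- brute_force_padog(d$expr, 2, 2, set_list, w, moderated = FALSE)
  res <- fit$results[match(names(set_list), fit$results$set_id), ]
  expect_equal(res$p, unname(oracle))
})

test_that("enumeration agrees with an independently-moderated oracle", {
  skip_if_not_installed("limma")
  d <- tiny_dataset(n_genes = 12, n1 = 3, n2 = 2, seed = 37,
                    shift = rep(1, 4))
  sets <- tiny_sets(sets = list(S1 = 1:4, S2 = 5:8, S3 = c(9:12, 1)))
  fr <- gene_weights(gene_frequencies(sets, cap_quantile = 1))
  w <- setNames(fr$w, fr$gene_id)
  set_list <- split(sets$gene_id, factor(sets$set_id, unique(sets$set_id)))
  suppressMessages(
    fit <- padog(d$expr, d$design, sets, n_perm = 100, seed = 1,
                 cap_quantile = 1))
  expect_true(fit$enumerated)
  expect_equal(fit$n_perm, choose(5, 2) - 1)
  oracle <- brute_force_padog(d$expr, 3, 2, set_list, w, moderated = TRUE)
  res <- fit$results[match(names(set_list), fit$results$set_id), ]
  expect_equal(res$p, unname(oracle))
})

test_that("relabeling case and control leaves every p unchanged", {
  d <- tiny_dataset(n_genes = 30, n1 = 4, n2 = 4, seed = 41,
                    shift = rep(0.8, 6))
  sets <- tiny_sets(sets = list(S1 = 1:10, S2 = 11:20, S3 = 21:30))
  f1 <- suppressMessages(
    padog(d$expr, d$design, sets, n_perm = 200, seed = 3, cap_quantile = 1))
  swapped <- d$design
  swapped$group <- ifelse(swapped$group == "case", "control", "case")
  f2 <- suppressMessages(
    padog(d$expr, swapped, sets, n_perm = 200, seed = 3, cap_quantile = 1))
  expect_equal(f1$results$p, f2$results$p)
})

test_that("ablation variants are the documented identities", {
  d <- tiny_dataset(n_genes = 30, n1 = 5, n2 = 5, seed = 43,
                    shift = rep(0.7, 8))
  sets <- tiny_sets(sets = list(S1 = 1:10, S2 = c(8:20), S3 = 21:30))
  fit <- run_gene_set_analysis(d$expr, d$design, sets, method = "noMnoW",
                               n_perm = 50, seed = 9, cap_quantile = 1)
  st <- ordinary_t(d$expr, d$design)
  tt <- setNames(abs(st$t_ordinary), st$gene_id)
  s0_expected <- tapply(tt[sets$gene_id], sets$set_id, mean)
  res <- fit$results
  expect_equal(res$S0[match(names(s0_expected), res$set_id)],
               as.vector(s0_expected), tolerance = 1e-12)
  expect_equal(fit$method, "noMnoW")

  # seeded identically, noM differs from noMnoW only through weights
  f_noM <- run_gene_set_analysis(d$expr, d$design, sets, method = "noM",
                                 n_perm = 50, seed = 9, cap_quantile = 1)
  fr <- gene_weights(gene_frequencies(sets, cap_quantile = 1))
  w <- setNames(fr$w, fr$gene_id)
  s0_w <- tapply(tt[sets$gene_id] * w[sets$gene_id], sets$set_id, mean)
  expect_equal(f_noM$results$S0[match(names(s0_w), f_noM$results$set_id)],
               as.vector(s0_w), tolerance = 1e-12)
})

test_that("literal and add-one permutation p-values relate as (b+1)/(K+1)", {
  d <- tiny_dataset(n_genes = 30, n1 = 4, n2 = 4, seed = 47,
                    shift = rep(1.5, 10))
  sets <- tiny_sets(sets = list(S1 = 1:10, S2 = 11:20, S3 = 21:30))
  f0 <- suppressMessages(
    padog(d$expr, d$design, sets, n_perm = 100, seed = 5, cap_quantile = 1))
  f1 <- suppressMessages(
    padog(d$expr, d$design, sets, n_perm = 100, seed = 5, cap_quantile = 1,
          add_one = TRUE))
  K <- f0$n_perm
  b <- f0$results$p * K
  expect_equal(f1$results$p[match(f0$results$set_id, f1$results$set_id)],
               (b + 1) / (K + 1))
  expect_true(all(f1$results$p > 0))
})

test_that("a set with set-specific DE genes beats an equal set with shared DE genes", {
  # two sets, same size, same number of equally-shifted DE genes; set A's DE
  # genes belong only to A, set B's DE genes are shared with two other sets
  p_diff <- replicate(8, {
    seed <- sample.int(1e6, 1)
    d <- tiny_dataset(n_genes = 80, n1 = 8, n2 = 8, seed = seed)
    de <- c(1:5, 21:25)
    d$expr[de, 9:16] <- d$expr[de, 9:16] + 1
    sets <- tiny_sets(sets = list(
      A = 1:20, B = 21:40,
      C = c(21:25, 41:55), D = c(21:25, 56:70)))
    fit <- padog(d$expr, d$design, sets, n_perm = 150,
                 seed = seed, cap_quantile = 1)
    r <- fit$results
    r$p[r$set_id == "A"] - r$p[r$set_id == "B"]
  })
  expect_lte(median(p_diff), 0)
})
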