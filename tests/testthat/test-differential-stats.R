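test_that("unpaired pooled t matches the closed form and t.test", {
  expr <- matrix(c(0, 2, 1, 3), 1, dimnames = list("G1", paste0("s", 1:4)))
  design <- tibble::tibble(sample_id = paste0("s", 1:4),
                           group = c("control", "control", "case", "case"))
  st <- ordinary_t(expr, design)
  expect_equal(st$effect, 1)
  expect_equal(st$s2, 2)
  expect_equal(st$df, 2)
  expect_equal(st$t_ordinary, 1 / sqrt(2 * (1 / 2 + 1 / 2)), tolerance = 1e-12)

  d <- tiny_dataset(n_genes = 20, n1 = 4, n2 = 5, seed = 3)
  st <- ordinary_t(d$expr, d$design)
  ref <- apply(d$expr, 1, function(x) {
    t.test(x[5:9], x[1:4], var.equal = TRUE)$statistic
  })
  expect_equal(st$t_ordinary, unname(ref), tolerance = 1e-10)
})

test_that("sample order within groups does not change t", {
  d <- tiny_dataset(n_genes = 10, seed = 5)
  st1 <- ordinary_t(d$expr, d$design)
  perm <- c(3, 1, 2, 6, 4, 5)  # shuffle within each group
  st2 <- ordinary_t(d$expr[, perm], d$design[perm, ])
  expect_equal(st1$t_ordinary, st2$t_ordinary)
})

test_that("zero-variance genes are flagged with infinite ordinary t", {
  d <- tiny_dataset(n_genes = 5, seed = 2)
  d$expr[1, ] <- rep(c(0, 1), each = 3)
  st <- ordinary_t(d$expr, d$design)
  expect_true(st$zero_variance[1])
  expect_identical(st$t_ordinary[1], Inf)
  d$expr[] <- 1
  expect_error(ordinary_t(d$expr, d$design), "zero residual variance")
})

test_that("paired t runs on within-block differences", {
  d <- tiny_dataset(n_genes = 12, n1 = 4, n2 = 4, seed = 7)
  d$design$block <- rep(paste0("p", 1:4), 2)
  st <- ordinary_t(d$expr, d$design)
  ref <- apply(d$expr, 1, function(x) {
    t.test(x[5:8], x[1:4], paired = TRUE)$statistic
  })
  expect_equal(st$t_ordinary, unname(ref), tolerance = 1e-10)
  expect_equal(st$df[1], 3)
})

test_that("variance prior: degenerate, scale-equivariant, recovers truth", {
  fit <- fit_variance_prior(rep(1.7, 100), df = 4)
  expect_identical(fit$d0, Inf)
  expect_equal(fit$s0_sq, 1.7, tolerance = 1e-9)

  set.seed(11)
  d0_true <- 6; s0_true <- 2; df <- 4
  s2 <- s0_true * df / rchisq(5000, df) * rchisq(5000, df) / df  # placeholder shape
  # draw from the actual scaled-F model: s2 | s_g^2 ~ s_g^2 chi2_df / df,
  # s_g^2 ~ s0 * d0 / chi2_d0
  sg2 <- s0_true * d0_true / rchisq(5000, d0_true)
  s2 <- sg2 * rchisq(5000, df) / df
  fit <- fit_variance_prior(s2, df)
  expect_lt(abs(fit$d0 - d0_true) / d0_true, 0.2)
  expect_lt(abs(fit$s0_sq - s0_true) / s0_true, 0.2)

  fit_scaled <- fit_variance_prior(10 * s2, df)
  expect_equal(fit_scaled$d0, fit$d0, tolerance = 1e-8)
  expect_equal(fit_scaled$s0_sq, 10 * fit$s0_sq, tolerance = 1e-8)
})

test_that("variance prior agrees with the limma estimator", {
  skip_if_not_installed("limma")
  set.seed(21)
  s2 <- 0.8 * 5 / rchisq(2000, 5) * rchisq(2000, 6) / 6
  ours <- fit_variance_prior(s2, df = 6)
  ref <- limma::fitFDist(s2, df1 = 6)
  expect_equal(ours$d0, ref$df2, tolerance = 1e-6)
  expect_equal(ours$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("moderated t reduces to ordinary at d0 = 0 and matches the shrinkage formula", {
  d <- tiny_dataset(n_genes = 30, seed = 9)
  m0 <- moderated_t(d$expr, d$design, d0 = 0, s0_sq = 1)
  o <- ordinary_t(d$expr, d$design)
  expect_equal(m0$t_moderated, m0$t_ordinary)
  expect_equal(m0$t_moderated, o$t_ordinary)

  # crafted gene: df = 2, pooled s2 = 3, effect = 2, unit = 1 (n1 = n2 = 2)
  a <- sqrt(1.5)
  expr <- matrix(c(-a, a, 2 - a, 2 + a), 1, dimnames = list("G1", paste0("s", 1:4)))
  design <- tibble::tibble(sample_id = paste0("s", 1:4),
                           group = c("control", "control", "case", "case"))
  m <- moderated_t(expr, design, d0 = 4, s0_sq = 1)
  expect_equal(m$t_moderated, 2 / sqrt((4 * 1 + 2 * 3) / 6), tolerance = 1e-9)
  expect_equal(m$t_moderated, 1.5492, tolerance = 1e-4)
})

test_that("shrinkage keeps zero-variance genes finite and preserves effect signs", {
  d <- tiny_dataset(n_genes = 40, seed = 13)
  d$expr[1, ] <- rep(c(0, 1), each = 3)  # zero within-group variance
  m <- moderated_t(d$expr, d$design)
  expect_true(is.finite(m$t_moderated[1]))
  expect_true(all(sign(m$t_moderated) == sign(m$effect) |
                    m$effect == 0))
})

test_that("moderated t matches limma's empirical Bayes pipeline", {
  skip_if_not_installed("limma")
  d <- tiny_dataset(n_genes = 200, n1 = 5, n2 = 5, seed = 17)
  m <- moderated_t(d$expr, d$design)
  mm <- stats::model.matrix(~factor(d$design$group, c("control", "case")))
  fit <- limma::eBayes(limma::lmFit(d$expr, mm))
  expect_equal(m$t_moderated, fit$t[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(attr(m, "d0"), fit$df.prior, tolerance = 1e-6)
})
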