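#' Percentile rank of a target set in an analysis result
#'
#' A set with the i-th smallest p-value out of `N` analyzed sets gets rank
#' `i / N * 100` (lower is better; ties take the average rank).
#'
#' @param results Per-set result tibble with columns `set_id` and `p` (e.g.
#'   `tidy()` of a fit).
#' @param target_set_id The target set's identifier.
#' @return The target's percentile rank.
#' @export
target_rank <- function(results, target_set_id) {
  i <- match(target_set_id, results$set_id)
  if (is.na(i)) {
    stop("target set '", target_set_id, "' absent from results", call. = FALSE)
  }
  r <- rank(results$p, ties.method = "average")
  r[i] / nrow(results) * 100
}

#' Summarize target-set benchmark records
#'
#' Aggregates one method's per-dataset target-set records into the summary
#' statistics of the ranking benchmark: geometric mean and median of the
#' target p-values (lower is better), the percentages of targets with
#' p < 0.05 and q < 0.05 (sensitivity estimates), and mean/median percentile
#' rank. A target p of exactly zero (possible with a finite permutation
#' count) is floored at `1 / (2 * n_perm)` before the geometric mean, with a
#' message.
#'
#' @param records Tibble with columns `p`, `q`, `rank_pct` (one row per
#'   dataset), e.g. built from [target_rank()] and `tidy()` output.
#' @param n_perm The permutation count the p-values were computed with
#'   (default 1000), used for the zero floor.
#' @return One-row tibble: `n`, `p_geomean`, `p_median`, `pct_p_lt_05`,
#'   `pct_q_lt_05`, `rank_mean`, `rank_median`.
#' @export
summarize_benchmark <- function(records, n_perm = 1000) {
  stopifnot(nrow(records) >= 1L)
  p <- records$p
  if (any(p == 0)) {
    message(sum(p == 0), " zero p-value(s) floored at 1/(2*", n_perm,
            ") for the geometric mean")
    p[p == 0] <- 1 / (2 * n_perm)
  }
  tibble::tibble(
    n = nrow(records),
    p_geomean = exp(mean(log(p))),
    p_median = stats::median(records$p),
    pct_p_lt_05 = mean(records$p < 0.05) * 100,
    pct_q_lt_05 = if (is.null(records$q)) NA_real_ else mean(records$q < 0.05) * 100,
    rank_mean = mean(records$rank_pct),
    rank_median = stats::median(records$rank_pct)
  )
}

#' Compare a method's target ranks to a reference method
#'
#' Tests whether method A ranks the target sets better (lower) than the
#' reference, pairing at the dataset level: a one-tailed paired Wilcoxon
#' signed-rank test, and optionally a linear mixed-effects model of the
#' pooled ranks on method and dataset with a random intercept per target set
#' (accounting for the same target pathway recurring across datasets). The
#' LME path requires the lme4 package and `target_set_id` in both record
#' tables.
#'
#' @param records_a,records_ref Tibbles with `dataset_id`, `rank_pct` (and
#'   `target_set_id` for the LME), one row per dataset.
#' @param lme Also fit the mixed-effects model (default FALSE).
#' @return One-row tibble `wilcoxon_p`, `lme_coef`, `lme_p`, `degenerate`
#'   (TRUE when all paired differences were zero, in which case
#'   `wilcoxon_p = 0.5` by convention).
#' @export
compare_to_reference <- function(records_a, records_ref, lme = FALSE) {
  mism <- c(setdiff(records_a$dataset_id, records_ref$dataset_id),
            setdiff(records_ref$dataset_id, records_a$dataset_id))
  if (length(mism) > 0L) {
    stop("datasets not paired between methods: ",
         paste(unique(mism), collapse = ", "), call. = FALSE)
  }
  ref <- records_ref[match(records_a$dataset_id, records_ref$dataset_id), ]
  d <- records_a$rank_pct - ref$rank_pct
  degenerate <- all(d == 0)
  w_p <- if (degenerate) {
    warning("all paired rank differences are zero; Wilcoxon p set to 0.5",
            call. = FALSE)
    0.5
  } else {
    suppressWarnings(
      stats::wilcox.test(records_a$rank_pct, ref$rank_pct, paired = TRUE,
                         alternative = "less")$p.value)
  }
  lme_coef <- lme_p <- NA_real_
  if (lme) {
    if (!requireNamespace("lme4", quietly = TRUE)) {
      warning("lme4 not available; skipping the mixed-effects comparison",
              call. = FALSE)
    } else {
      long <- dplyr::bind_rows(
        dplyr::mutate(records_a, method = "a"),
        dplyr::mutate(ref, method = "ref"))
      long$method <- stats::relevel(factor(long$method), ref = "ref")
      fit <- lme4::lmer(rank_pct ~ method + dataset_id + (1 | target_set_id),
                        data = long)
      co <- summary(fit)$coefficients
      lme_coef <- co["methoda", "Estimate"]
      lme_p <- stats::pnorm(co["methoda", "t value"])  # one-tailed: a < ref
    }
  }
  tibble::tibble(wilcoxon_p = w_p, lme_coef = lme_coef, lme_p = lme_p,
                 degenerate = degenerate)
}

#' Reference table of benchmark datasets and their target pathways
#'
#' The packaged mapping from the 24 public two-group expression datasets used
#' for target-pathway benchmarking to the KEGG pathway describing each
#' dataset's disease (identifiers only; no expression data is bundled).
#'
#' @return Tibble `dataset_id`, `geo_id`, `target_set_id`, `disease`,
#'   `tissue`.
#' @export
benchmark_targets <- function() {
  path <- system.file("extdata", "benchmark_targets.tsv", package = "padog")
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      quote = "", stringsAsFactors = FALSE))
}
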