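#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data %||%
NULL

#' Tidy a gene set analysis fit
#'
#' @param x A `padog_fit` object.
#' @param ... Unused.
#' @return The per-set result tibble, sorted by ascending p.
#' @export
tidy.padog_fit <- function(x, ...) {
  x$results
}

#' One-row summary of a gene set analysis fit
#'
#' @param x A `padog_fit` object.
#' @param ... Unused.
#' @return Tibble with the method, problem sizes, permutation count, and the
#'   counts of sets reaching p < 0.05 and q < 0.05.
#' @export
glance.padog_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_sets = nrow(x$results),
    n_genes = x$n_genes,
    n_perm = x$n_perm,
    enumerated = isTRUE(x$enumerated),
    d0 = x$d0 %||% NA_real_,
    s0_sq = x$s0_sq %||% NA_real_,
    n_p_lt_05 = sum(x$results$p < 0.05),
    n_q_lt_05 = sum(x$results$q < 0.05)
  )
}

#' @export
print.padog_fit <- function(x, ...) {
  cat("Gene set analysis (", x$method, "), ", nrow(x$results), " sets, ",
      x$n_genes, " genes, ", x$n_perm,
      if (isTRUE(x$enumerated)) " permutations (exhaustive)" else " permutations",
      "\n", sep = "")
  if (!is.null(x$d0)) {
    cat("variance prior: d0 = ", format(x$d0, digits = 4),
        ", s0^2 = ", format(x$s0_sq, digits = 4), "\n", sep = "")
  }
  print(x$results, n = 10)
  invisible(x)
}

#' Plot a gene set analysis fit
#'
#' Standardized set scores against their permutation p-values (log10 scale),
#' highlighting sets significant at the given threshold.
#'
#' @param object A `padog_fit`.
#' @param alpha Highlight threshold on p (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.padog_fit <- function(object, alpha = 0.05, ...) {
  df <- object$results
  floor_p <- 1 / (2 * object$n_perm)
  df$p_plot <- pmax(df$p, floor_p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$S0_star, y = -log10(.data$p_plot),
                                   colour = .data$p < alpha)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
                                 name = paste0("p < ", alpha)) +
    ggplot2::labs(x = "standardized set score",
                  y = expression(-log[10](p)),
                  title = paste0("Gene set analysis (", object$method, ")")) +
    ggplot2::theme_minimal()
}

#' Plot the down-weighting curve of a collection
#'
#' Gene frequency distribution (how many sets each gene belongs to, after
#' capping) and the resulting weights.
#'
#' @param freqs Output of [gene_weights()] (tibble with `f` and `w`).
#' @return A ggplot object.
#' @export
plot_gene_weights <- function(freqs) {
  stopifnot(all(c("f", "w") %in% names(freqs)))
  curve <- dplyr::distinct(freqs, .data$f, .data$w)
  counts <- dplyr::count(freqs, .data$f)
  curve <- dplyr::left_join(curve, counts, by = "f")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$f, y = .data$w)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.7) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_size_area(name = "genes") +
    ggplot2::ylim(1, 2) +
    ggplot2::labs(x = "gene frequency across sets (capped)", y = "weight") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity study
#'
#' Boxplots of the target set's p-values per scenario, faceted by overlap
#' setup, one colour per method.
#'
#' @param results Output of [run_sensitivity()].
#' @param log10 Plot p on a log10 axis (default TRUE; zeros floored at the
#'   smallest positive value observed).
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(results, log10 = TRUE) {
  df <- results
  df$setup <- ifelse(is.na(df$setup), "any", df$setup)
  if (log10) {
    floor_p <- min(df$p[df$p > 0], 1e-4)
    df$p <- pmax(df$p, floor_p)
  }
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$scenario), y = .data$p,
                                         fill = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~setup) +
    ggplot2::labs(x = "scenario", y = "target set p-value") +
    ggplot2::theme_minimal()
  if (log10) gg <- gg + ggplot2::scale_y_log10()
  gg
}
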