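#' Read a gene set collection from a GMT file
#'
#' GMT is the de-facto exchange format for gene set collections: one set per
#' line, tab-separated, with the set identifier in the first field, a free-text
#' description in the second, and the member gene identifiers in the remaining
#' fields. Gene identifiers are treated as opaque strings; callers are expected
#' to supply expression data with one row per gene under the same identifier
#' scheme (probe-to-gene collapsing happens upstream of this package).
#'
#' @param path Path to a GMT file.
#' @return A tibble with columns `set_id`, `set_name`, `gene_id`, one row per
#'   set membership. Duplicate gene ids within a line are dropped; set order
#'   and within-set gene order are preserved.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines(c("S1\tfirst set\tG1\tG2\tG2", "S2\tsecond\tG3\tG4\tG5"), tf)
#' read_gmt(tf)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("no gene sets in '", path, "'", call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad) > 0L) {
    stop("malformed GMT line ", bad[1L], " in '", path,
         "': fewer than 3 tab-separated fields", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate set_id in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  purrr::map_dfr(fields, function(f) {
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    tibble::tibble(set_id = f[[1L]], set_name = f[[2L]], gene_id = genes)
  })
}

#' Write a gene set collection to a GMT file
#'
#' @param gene_sets A tibble with columns `set_id`, `gene_id` and optionally
#'   `set_name` (empty string used when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path) {
  gene_sets <- validate_gene_sets(gene_sets)
  split_genes <- split(gene_sets$gene_id, factor(gene_sets$set_id, levels = unique(gene_sets$set_id)))
  names_by_set <- tapply(gene_sets$set_name, factor(gene_sets$set_id, levels = unique(gene_sets$set_id)),
                         function(x) x[[1L]])
  lines <- vapply(seq_along(split_genes), function(i) {
    paste(c(names(split_genes)[i], names_by_set[[i]], split_genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @noRd
validate_gene_sets <- function(gene_sets) {
  if (!is.data.frame(gene_sets)) {
    stop("`gene_sets` must be a data frame with columns set_id and gene_id", call. = FALSE)
  }
  if (!all(c("set_id", "gene_id") %in% names(gene_sets))) {
    stop("`gene_sets` must have columns set_id and gene_id", call. = FALSE)
  }
  gene_sets <- tibble::as_tibble(gene_sets)
  if (!"set_name" %in% names(gene_sets)) gene_sets$set_name <- ""
  gene_sets <- dplyr::distinct(gene_sets, .data$set_id, .data$gene_id, .keep_all = TRUE)
  gene_sets[, c("set_id", "set_name", "gene_id")]
}

#' Restrict a gene set collection to the genes present in an expression matrix
#'
#' Intersects every set with the measured genes and drops sets that fall below
#' the minimum analyzable size. The union of the surviving sets defines the
#' analysis universe: genes measured on the array but belonging to no set take
#' no part in the analysis.
#'
#' @param gene_sets Tibble with columns `set_id`, `gene_id` (and optionally
#'   `set_name`).
#' @param measured Character vector of measured gene identifiers, or an
#'   expression matrix / data frame from which row identifiers are taken.
#' @param min_size Minimum set size after restriction (default 3); smaller
#'   sets are dropped with a warning. Sets emptied entirely are dropped
#'   silently except for a summary warning.
#' @return The restricted collection as a tibble; the analysis universe is
#'   `unique(result$gene_id)`.
#' @export
restrict_to_measured <- function(gene_sets, measured, min_size = 3L) {
  gene_sets <- validate_gene_sets(gene_sets)
  if (is.matrix(measured)) measured <- rownames(measured)
  if (is.data.frame(measured)) measured <- as.character(measured[[1L]])
  measured <- unique(as.character(measured))
  kept <- dplyr::filter(gene_sets, .data$gene_id %in% measured)
  sizes <- dplyr::count(kept, .data$set_id)
  small <- setdiff(unique(gene_sets$set_id), sizes$set_id[sizes$n >= min_size])
  if (length(small) > 0L) {
    warning(length(small), " gene set(s) dropped (fewer than ", min_size,
            " measured genes): ", paste(utils::head(small, 5L), collapse = ", "),
            if (length(small) > 5L) ", ..." else "", call. = FALSE)
    kept <- dplyr::filter(kept, !.data$set_id %in% small)
  }
  if (nrow(kept) == 0L) {
    stop("no overlap between expression data and gene sets", call. = FALSE)
  }
  kept
}

#' Read an expression matrix and its two-group design
#'
#' The expression file is TSV/CSV with gene identifiers in the first column and
#' one column per sample (log-scale values). The design file has columns
#' `sample_id`, `group` and optionally `block` for paired designs; every
#' expression column must appear in the design and vice versa.
#'
#' @param path Expression matrix file (TSV, or CSV if the extension is .csv).
#' @param design_path Design file in the same delimiter convention.
#' @return A list with elements `expr` (numeric matrix, genes x samples, row
#'   names = gene ids, columns ordered as in the design) and `design` (tibble).
#' @export
read_expression <- function(path, design_path) {
  delim <- function(p) if (grepl("\\.csv$", p, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = delim(path),
                           check.names = FALSE, stringsAsFactors = FALSE)
  design <- tibble::as_tibble(
    utils::read.table(design_path, header = TRUE, sep = delim(design_path),
                      check.names = FALSE, stringsAsFactors = FALSE))
  if (!all(c("sample_id", "group") %in% names(design))) {
    stop("design file must have columns sample_id and group", call. = FALSE)
  }
  gene_ids <- as.character(raw[[1L]])
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids in expression file: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 3L), collapse = ", "),
         call. = FALSE)
  }
  mat <- raw[, -1L, drop = FALSE]
  for (j in seq_along(mat)) {
    v <- suppressWarnings(as.numeric(mat[[j]]))
    if (anyNA(v) && !anyNA(mat[[j]])) {
      i <- which(is.na(v))[1L]
      stop("non-numeric value at gene '", gene_ids[i], "', sample '",
           names(mat)[j], "'", call. = FALSE)
    }
    mat[[j]] <- v
  }
  mat <- as.matrix(mat)
  rownames(mat) <- gene_ids
  miss_in_design <- setdiff(colnames(mat), design[["sample_id"]])
  miss_in_expr <- setdiff(design[["sample_id"]], colnames(mat))
  if (length(miss_in_design) || length(miss_in_expr)) {
    stop("sample mismatch between expression and design files: ",
         paste(c(miss_in_design, miss_in_expr), collapse = ", "), call. = FALSE)
  }
  mat <- mat[, design[["sample_id"]], drop = FALSE]
  validate_design(design)
  list(expr = mat, design = design)
}

#' @noRd
validate_design <- function(design) {
  grp <- as.character(design$group)
  lev <- group_levels(grp)
  if (length(lev) != 2L) {
    stop("`group` must have exactly 2 levels, got: ",
         paste(unique(grp), collapse = ", "), call. = FALSE)
  }
  if (min(table(grp)) < 2L) {
    stop("both groups must have at least 2 samples", call. = FALSE)
  }
  if (!is.null(design[["block"]]) && !all(is.na(design[["block"]]))) {
    tab <- table(design[["block"]], grp)
    if (any(tab != 1L)) {
      stop("each block must contain exactly one sample per group", call. = FALSE)
    }
  }
  invisible(design)
}

# Control is the reference level: an explicit "control"/"c"/"0" label wins,
# otherwise the first sorted level.
#' @noRd
group_levels <- function(grp) {
  lev <- sort(unique(as.character(grp)))
  ref_like <- lev[tolower(lev) %in% c("control", "ctrl", "c", "0", "normal")]
  if (length(ref_like) == 1L) lev <- c(ref_like, setdiff(lev, ref_like))
  lev
}

# Normalize user expression input (matrix with rownames, or data frame with
# gene ids in column 1) plus a design tibble into the internal representation.
#' @noRd
prepare_dataset <- function(expr, design) {
  if (is.data.frame(expr)) {
    ids <- as.character(expr[[1L]])
    expr <- as.matrix(expr[, -1L, drop = FALSE])
    rownames(expr) <- ids
  }
  if (is.null(rownames(expr))) {
    stop("`expr` must have gene identifiers (row names or a first column)", call. = FALSE)
  }
  storage.mode(expr) <- "double"
  design <- tibble::as_tibble(design)
  if (!is.null(design[["sample_id"]]) && !is.null(colnames(expr))) {
    if (!setequal(colnames(expr), design[["sample_id"]])) {
      stop("sample mismatch between `expr` columns and `design$sample_id`", call. = FALSE)
    }
    expr <- expr[, design[["sample_id"]], drop = FALSE]
  }
  if (ncol(expr) != nrow(design)) {
    stop("`design` must have one row per expression column", call. = FALSE)
  }
  validate_design(design)
  lev <- group_levels(as.character(design$group))
  grp2 <- as.character(design$group) == lev[2L]
  block <- NULL
  if (!is.null(design[["block"]]) && !all(is.na(design[["block"]]))) block <- as.character(design[["block"]])
  list(expr = expr, group2 = grp2, levels = lev, block = block, design = design)
}
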