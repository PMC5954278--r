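#' Read an expression matrix with biotype (and optional tissue) metadata
#'
#' Assembles the canonical expression tibble used throughout the package:
#' one row per gene, a `gene_id` column, a `biotype` column (`"coding"` or
#' `"lncRNA"`) and one numeric column per sample holding FPKM-like
#' nonnegative abundances.
#'
#' @param path Tab-separated expression table: header row with `gene_id`
#'   followed by sample ids; one row per gene.
#' @param biotype_path Two-column tab-separated table `gene_id`, `biotype`.
#'   Every gene in the expression table must appear here.
#' @param tissue_path Optional two-column table `sample_id`, `tissue`.
#'   Attached as the `"tissues"` attribute.
#' @return A tibble with columns `gene_id`, `biotype`, then one column per
#'   sample. Tissue labels, when given, are available via
#'   `attr(x, "tissues")`.
#' @export
read_expression <- function(path, biotype_path, tissue_path = NULL) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(expr)[1] != "gene_id") {
    names(expr)[1] <- "gene_id"
  }
  bio <- readr::read_tsv(biotype_path, col_names = c("gene_id", "biotype"),
                         show_col_types = FALSE, progress = FALSE, skip = 0)
  # tolerate a header row in the biotype table
  if (identical(tolower(bio$gene_id[1]), "gene_id")) {
    bio <- bio[-1, , drop = FALSE]
  }
  if (anyDuplicated(bio$gene_id)) {
    dup <- unique(bio$gene_id[duplicated(bio$gene_id)])
    stop_lncnet(paste0("duplicated biotype entries: ",
                       paste(head(dup, 5), collapse = ", ")),
                class = "lncnet_format_error")
  }
  missing <- setdiff(expr$gene_id, bio$gene_id)
  if (length(missing) > 0) {
    stop_lncnet(paste0("no biotype for gene(s): ",
                       paste(head(missing, 5), collapse = ", ")),
                class = "lncnet_validation_error")
  }
  out <- expr |>
    left_join(bio, by = "gene_id") |>
    select("gene_id", "biotype", dplyr::everything())
  validate_expression(out)
  if (!is.null(tissue_path)) {
    tis <- readr::read_tsv(tissue_path, col_names = c("sample_id", "tissue"),
                           show_col_types = FALSE, progress = FALSE)
    if (identical(tolower(tis$sample_id[1]), "sample_id")) {
      tis <- tis[-1, , drop = FALSE]
    }
    attr(out, "tissues") <- as_tibble(tis)
  }
  out
}

#' Write an expression tibble to a tab-separated file
#'
#' Writes the sample columns with `gene_id` as the first column; the biotype
#' column goes to its own two-column file so that the pair round-trips
#' through [read_expression()].
#'
#' @param expr Expression tibble.
#' @param path Output TSV path for the matrix.
#' @param biotype_path Optional output path for the `gene_id`/`biotype` table.
#' @return `expr`, invisibly.
#' @export
write_expression <- function(expr, path, biotype_path = NULL) {
  validate_expression(expr)
  readr::write_tsv(select(expr, -"biotype"), path, progress = FALSE)
  if (!is.null(biotype_path)) {
    readr::write_tsv(select(expr, "gene_id", "biotype"), biotype_path,
                     progress = FALSE)
  }
  invisible(expr)
}

#' Merge replicate samples by arithmetic mean
#'
#' Collapses replicate columns of an expression tibble to one column per
#' group, each entry being the arithmetic mean of the member columns.
#'
#' @param expr Expression tibble (see [read_expression()]).
#' @param grouping Data frame with columns `sample_id`, `group_id` covering
#'   every sample column of `expr`.
#' @return Expression tibble with one column per group, group columns in
#'   first-appearance order of `group_id`.
#' @export
merge_replicates <- function(expr, grouping) {
  validate_expression(expr)
  smp <- sample_columns(expr)
  grouping <- as_tibble(grouping)
  if (!all(c("sample_id", "group_id") %in% names(grouping))) {
    stop_lncnet("`grouping` needs columns sample_id and group_id",
                class = "lncnet_validation_error")
  }
  unmapped <- setdiff(smp, grouping$sample_id)
  if (length(unmapped) > 0) {
    stop_lncnet(paste0("sample(s) not mapped to a group: ",
                       paste(head(unmapped, 5), collapse = ", ")),
                class = "lncnet_validation_error")
  }
  grouping <- filter(grouping, .data$sample_id %in% smp)
  groups <- unique(grouping$group_id)
  m <- expr_matrix(expr)
  merged <- vapply(groups, function(g) {
    members <- grouping$sample_id[grouping$group_id == g]
    if (length(members) == 0) {
      stop_lncnet(paste0("empty replicate group: ", g),
                  class = "lncnet_validation_error")
    }
    rowMeans(m[, members, drop = FALSE])
  }, numeric(nrow(m)))
  out <- dplyr::bind_cols(
    select(expr, "gene_id", "biotype"),
    as_tibble(matrix(merged, nrow = nrow(m),
                     dimnames = list(NULL, groups)))
  )
  attr(out, "tissues") <- attr(expr, "tissues")
  out
}

#' Upper-quartile normalization of an expression matrix
#'
#' For each sample \eqn{i}, let \eqn{k_i} be the 75th percentile of its
#' nonzero expression values. The scaling factor is
#' \eqn{\rho_i = \bar{k} / k_i} with \eqn{\bar{k}} the mean of the
#' \eqn{k_i} across samples, and every value in sample \eqn{i} is multiplied
#' by \eqn{\rho_i}. Zeros stay zero, and after scaling the nonzero upper
#' quartile is the same (\eqn{\bar{k}}) in every sample, which makes the
#' transform idempotent.
#'
#' @param expr Expression tibble; every sample must have at least 4 nonzero
#'   values.
#' @return The normalized expression tibble. The per-sample factors are
#'   attached as attribute `"scaling_factors"`, a tibble with columns
#'   `sample_id`, `k`, `rho` (see [scaling_factors()]).
#' @export
upper_quartile_normalize <- function(expr) {
  validate_expression(expr)
  m <- expr_matrix(expr)
  smp <- sample_columns(expr)
  nz_counts <- colSums(m > 0)
  if (any(nz_counts == 0)) {
    stop_lncnet(paste0("sample(s) with all-zero expression: ",
                       paste(smp[nz_counts == 0], collapse = ", ")),
                class = "lncnet_validation_error")
  }
  if (any(nz_counts < 4)) {
    stop_lncnet(paste0("sample(s) with fewer than 4 nonzero values: ",
                       paste(smp[nz_counts < 4], collapse = ", ")),
                class = "lncnet_validation_error")
  }
  k <- vapply(seq_along(smp), function(j) {
    v <- m[, j]
    quantile(v[v > 0], 0.75, type = 7, names = FALSE)
  }, numeric(1))
  rho <- mean(k) / k
  scaled <- sweep(m, 2, rho, `*`)
  out <- dplyr::bind_cols(
    select(expr, "gene_id", "biotype"),
    as_tibble(as.data.frame(scaled))
  )
  names(out) <- c("gene_id", "biotype", smp)
  attr(out, "tissues") <- attr(expr, "tissues")
  attr(out, "scaling_factors") <- tibble(sample_id = smp, k = k, rho = rho)
  out
}

#' Per-sample scaling factors from a normalized expression tibble
#'
#' @param expr Result of [upper_quartile_normalize()].
#' @return Tibble with columns `sample_id`, `k` (nonzero upper quartile
#'   before scaling) and `rho` (scaling factor).
#' @export
scaling_factors <- function(expr) {
  sf <- attr(expr, "scaling_factors")
  if (is.null(sf)) {
    stop_lncnet("no scaling factors attached; run upper_quartile_normalize() first",
                class = "lncnet_validation_error")
  }
  sf
}

#' Keep the most variable genes
#'
#' Ranks genes by unbiased sample variance across samples (descending) and
#' keeps the top `ceil(keep_fraction * G)`, preserving the input row order
#' of the retained genes. Ties are broken by input order.
#'
#' @param expr Expression tibble.
#' @param keep_fraction Fraction of genes to keep, in (0, 1]; default 0.75
#'   (drop the least-variable quarter).
#' @return Filtered expression tibble.
#' @export
variance_filter <- function(expr, keep_fraction = 0.75) {
  validate_expression(expr)
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1 ||
      keep_fraction <= 0 || keep_fraction > 1) {
    stop_lncnet("`keep_fraction` must be in (0, 1]",
                class = "lncnet_validation_error")
  }
  m <- expr_matrix(expr)
  v <- apply(m, 1, var)
  n_keep <- as.integer(ceiling(keep_fraction * nrow(m)))
  if (n_keep == 0) {
    stop_lncnet("variance filter would drop every gene",
                class = "lncnet_validation_error")
  }
  keep_idx <- sort(order(-v)[seq_len(n_keep)])
  out <- expr[keep_idx, , drop = FALSE]
  attr(out, "tissues") <- attr(expr, "tissues")
  out
}
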