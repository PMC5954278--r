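outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read a 12-column tabular alignment hit table (outfmt-6 dialect)
#'
#' @param path Tab-separated file with the 12 standard columns and no
#'   header: qseqid, sseqid, pident, length, mismatch, gapopen, qstart,
#'   qend, sstart, send, evalue, bitscore.
#' @return Tibble with those columns.
#' @export
read_blast_hits <- function(path) {
  hits <- suppressWarnings(
    readr::read_tsv(path, col_names = outfmt6_cols,
                    col_types = "ccddiiiiiidd", progress = FALSE)
  )
  probs <- readr::problems(hits)
  if (nrow(probs) > 0) {
    stop_lncnet(paste0("malformed hit row at line ", probs$row[1],
                       " of ", path),
                class = "lncnet_format_error")
  }
  if (any(is.na(hits$evalue)) || any(hits$evalue < 0)) {
    bad <- which(is.na(hits$evalue) | hits$evalue < 0)[1]
    stop_lncnet(paste0("invalid E-value at line ", bad, " of ", path),
                class = "lncnet_format_error")
  }
  hits
}

# Best hit per query: lowest E-value, ties by highest bit score, then
# lexicographic subject id.
best_hits <- function(hits) {
  hits |>
    arrange(.data$qseqid, .data$evalue, dplyr::desc(.data$bitscore),
            .data$sseqid) |>
    dplyr::slice_head(n = 1, by = "qseqid")
}

#' Reciprocal-best-hit ortholog pairs from bidirectional hit tables
#'
#' Hits with E-value above `e_max` are discarded; the remaining best hit is
#' found per query in each direction (lowest E-value, ties by bit score
#' then subject id) and a pair (a, b) is reported iff a's best forward hit
#' is b and b's best reverse hit is a. Each id therefore appears in at most
#' one pair.
#'
#' @param forward,reverse Hit tibbles (see [read_blast_hits()]); `forward`
#'   queries species A against species B, `reverse` the converse.
#' @param e_max E-value threshold, default `1e-5`.
#' @return Tibble `gene_a`, `gene_b`, `evalue_forward`, `evalue_reverse`,
#'   sorted by `gene_a`.
#' @export
reciprocal_best_hits <- function(forward, reverse, e_max = 1e-5) {
  forward <- filter(as_tibble(forward), .data$evalue <= e_max)
  reverse <- filter(as_tibble(reverse), .data$evalue <= e_max)
  if (nrow(forward) == 0 || nrow(reverse) == 0) {
    return(tibble(gene_a = character(), gene_b = character(),
                  evalue_forward = numeric(), evalue_reverse = numeric()))
  }
  bf <- best_hits(forward) |>
    select(gene_a = "qseqid", gene_b = "sseqid", evalue_forward = "evalue")
  br <- best_hits(reverse) |>
    select(gene_b = "qseqid", gene_a = "sseqid", evalue_reverse = "evalue")
  inner_join(bf, br, by = c("gene_a", "gene_b")) |>
    arrange(.data$gene_a)
}

#' Collapse transcript-level ortholog pairs to genes
#'
#' A gene counts as conserved once if any of its transcripts has a
#' reciprocal-best-hit partner; the retained representative is the
#' transcript pair with the smallest forward E-value.
#'
#' @param pairs Output of [reciprocal_best_hits()] on transcript ids.
#' @param tx2gene_a,tx2gene_b Two-column data frames (`transcript_id`,
#'   `gene_id`) for each species; ids missing from a map are treated as
#'   already gene-level.
#' @return Tibble `gene_a`, `gene_b`, `evalue_forward`, `evalue_reverse`,
#'   one row per species-A gene.
#' @export
collapse_to_genes <- function(pairs, tx2gene_a = NULL, tx2gene_b = NULL) {
  remap <- function(ids, map) {
    if (is.null(map)) return(ids)
    map <- as_tibble(map)
    names(map)[1:2] <- c("transcript_id", "gene_id")
    hit <- match(ids, map$transcript_id)
    ifelse(is.na(hit), ids, map$gene_id[hit])
  }
  pairs |>
    mutate(gene_a = remap(.data$gene_a, tx2gene_a),
           gene_b = remap(.data$gene_b, tx2gene_b)) |>
    arrange(.data$gene_a, .data$evalue_forward) |>
    dplyr::slice_head(n = 1, by = "gene_a")
}

#' Tissue specificity index
#'
#' `tsi(x) = max(x) / sum(x)` for a nonnegative expression vector over
#' tissues; 1 means expression confined to a single tissue, `1/n` a
#' perfectly uniform profile over `n` tissues.
#'
#' @param x Nonnegative numeric vector with positive sum.
#' @return A single number in `[1/length(x), 1]`.
#' @export
tsi <- function(x) {
  if (anyNA(x) || any(x < 0)) {
    stop_lncnet("`x` must be nonnegative with no missing values",
                class = "lncnet_validation_error")
  }
  if (sum(x) == 0) {
    stop_lncnet("TSI undefined for an all-zero vector",
                class = "lncnet_validation_error")
  }
  max(x) / sum(x)
}

#' Tissue specificity index for every gene of a profile table
#'
#' @param profiles Tibble with `gene_id` then one numeric column per
#'   tissue.
#' @return Tibble `gene_id`, `tsi`; all-zero genes are dropped with a
#'   warning.
#' @export
tsi_table <- function(profiles) {
  profiles <- as_tibble(profiles)
  m <- as.matrix(profiles[, setdiff(names(profiles), "gene_id"), drop = FALSE])
  zero <- rowSums(m) == 0
  if (any(zero)) {
    warn(paste0("dropping ", sum(zero), " all-zero gene(s) from TSI"))
  }
  tibble(gene_id = profiles$gene_id[!zero],
         tsi = apply(m[!zero, , drop = FALSE], 1, tsi))
}

#' Mean expression profile per tissue
#'
#' Collapses an expression tibble with attached tissue labels to one
#' column per tissue (arithmetic mean over that tissue's samples), the
#' input expected by [tsi_table()] and
#' [ortholog_expression_correlation()].
#'
#' @param expr Expression tibble with a `"tissues"` attribute (or pass
#'   `tissues` explicitly).
#' @param tissues Optional tibble `sample_id`, `tissue`.
#' @return Tibble `gene_id` plus one numeric column per tissue.
#' @export
tissue_profiles <- function(expr, tissues = NULL) {
  tissues <- tissues %||% attr(expr, "tissues")
  if (is.null(tissues)) {
    stop_lncnet("no tissue labels available", class = "lncnet_validation_error")
  }
  grouping <- tibble(sample_id = tissues$sample_id, group_id = tissues$tissue)
  merged <- merge_replicates(expr, grouping)
  select(merged, -"biotype")
}

#' Spearman correlation of ortholog tissue profiles
#'
#' For each ortholog pair, computes the Spearman coefficient (rank-Pearson,
#' as in the network edge test) between the two genes' ordered tissue
#' profiles. Both profile tables must share the same tissue columns in the
#' same order. Pairs with a constant or missing profile are skipped with a
#' warning.
#'
#' @param pairs Tibble `gene_a`, `gene_b`.
#' @param profiles_a,profiles_b Tibbles `gene_id` + tissue columns.
#' @return `pairs` with an added `rs` column (skipped pairs dropped).
#' @export
ortholog_expression_correlation <- function(pairs, profiles_a, profiles_b) {
  ta <- setdiff(names(profiles_a), "gene_id")
  tb <- setdiff(names(profiles_b), "gene_id")
  if (!identical(ta, tb)) {
    stop_lncnet("tissue columns of the two profile tables do not match",
                class = "lncnet_validation_error")
  }
  ma <- as.matrix(profiles_a[, ta, drop = FALSE])
  rownames(ma) <- profiles_a$gene_id
  mb <- as.matrix(profiles_b[, tb, drop = FALSE])
  rownames(mb) <- profiles_b$gene_id
  rs <- purrr::map_dbl(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    if (!a %in% rownames(ma) || !b %in% rownames(mb)) return(NA_real_)
    xa <- ma[a, ]; xb <- mb[b, ]
    if (stats::sd(xa) == 0 || stats::sd(xb) == 0) return(NA_real_)
    stats::cor(rank(xa), rank(xb))
  })
  skipped <- sum(is.na(rs))
  if (skipped > 0) {
    warn(paste0("skipping ", skipped,
                " pair(s) with constant or missing profiles"))
  }
  out <- mutate(pairs, rs = rs)
  filter(out, !is.na(.data$rs))
}

#' Intersection-over-union of two TF-family sets
#'
#' `S = |a intersect b| / |a union b|`; undefined (error) when both sets
#' are empty.
#'
#' @param set_a,set_b Character vectors of family names (duplicates
#'   ignored).
#' @return A single number in `[0, 1]`; 1 iff the sets are equal and
#'   nonempty.
#' @export
tf_family_iou <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- union(set_a, set_b)
  if (length(u) == 0) {
    stop_lncnet("IoU undefined when both sets are empty",
                class = "lncnet_validation_error")
  }
  length(intersect(set_a, set_b)) / length(u)
}

#' IoU of upstream TF families for a set of gene pairs
#'
#' Pairs where both genes have empty family sets are excluded from the
#' distribution (the ratio is 0/0) rather than scored.
#'
#' @param pairs Tibble `gene_a`, `gene_b`.
#' @param tf_a,tf_b Two-column data frames (`gene_id`, `tf_family`) per
#'   species.
#' @return `pairs` with an added `iou` column (both-empty pairs dropped).
#' @export
tf_iou_table <- function(pairs, tf_a, tf_b) {
  tf_a <- as_tibble(tf_a); names(tf_a)[1:2] <- c("gene_id", "tf_family")
  tf_b <- as_tibble(tf_b); names(tf_b)[1:2] <- c("gene_id", "tf_family")
  sets_a <- split(tf_a$tf_family, tf_a$gene_id)
  sets_b <- split(tf_b$tf_family, tf_b$gene_id)
  iou <- purrr::map_dbl(seq_len(nrow(pairs)), function(i) {
    a <- sets_a[[pairs$gene_a[i]]] %||% character()
    b <- sets_b[[pairs$gene_b[i]]] %||% character()
    if (length(a) == 0 && length(b) == 0) return(NA_real_)
    tf_family_iou(a, b)
  })
  filter(mutate(pairs, iou = iou), !is.na(.data$iou))
}

#' Read a 4-column bedGraph conservation track
#'
#' @param path bedGraph file (chrom, start, end, score; 0-based half-open),
#'   optionally with `track`/comment header lines.
#' @return Tibble `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tibble(chrom = as.character(GenomeInfoDb::seqnames(gr)),
         start = BiocGenerics::start(gr) - 1L,
         end = BiocGenerics::end(gr),
         score = gr$score)
}

#' Length-weighted mean conservation score over exonic bases
#'
#' Averages a per-base score track over the exonic bases of each
#' transcript; bases not covered by the track score 0, so a transcript
#' entirely outside the track scores 0. The result is invariant to
#' splitting an exon into adjacent sub-intervals.
#'
#' @param models Gene-model tibble (one row per exon; see
#'   [generate_genome_layout()] for the layout) or a subset thereof.
#' @param track Tibble `chrom`, `start`, `end`, `score` (0-based half-open)
#'   or a path to a bedGraph file.
#' @return Tibble `transcript_id`, `gene_id`, `exonic_length`, `score`.
#' @export
conservation_score <- function(models, track) {
  if (is.character(track)) track <- read_bedgraph(track)
  track <- as_tibble(track)
  if (any(track$end < track$start)) {
    stop_lncnet("track interval with end < start",
                class = "lncnet_format_error")
  }
  if (any(models$end <= models$start)) {
    stop_lncnet("exon with nonpositive width", class = "lncnet_format_error")
  }
  exons <- GenomicRanges::GRanges(
    models$chrom, IRanges::IRanges(models$start + 1L, models$end)
  )
  tgr <- GenomicRanges::GRanges(
    track$chrom, IRanges::IRanges(track$start + 1L, track$end),
    score = track$score
  )
  ov <- GenomicRanges::findOverlaps(exons, tgr)
  widths <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(exons)[S4Vectors::queryHits(ov)],
    IRanges::ranges(tgr)[S4Vectors::subjectHits(ov)]
  ))
  contrib <- tibble(
    row = S4Vectors::queryHits(ov),
    weighted = widths * track$score[S4Vectors::subjectHits(ov)]
  )
  per_exon <- models |>
    mutate(row = row_number(), width = .data$end - .data$start) |>
    left_join(summarise(group_by(contrib, .data$row),
                        weighted = sum(.data$weighted), .groups = "drop"),
              by = "row") |>
    mutate(weighted = dplyr::coalesce(.data$weighted, 0))
  per_exon |>
    group_by(.data$transcript_id, .data$gene_id) |>
    summarise(exonic_length = sum(.data$width),
              score = sum(.data$weighted) / sum(.data$width),
              .groups = "drop")
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Computes the KS statistic \eqn{D = \sup_x |F_a(x) - F_b(x)|} over the
#' pooled sample points and its asymptotic p-value from the standard
#' limiting series \eqn{p = 2\sum_{j\ge1} (-1)^{j-1} e^{-2 j^2 \lambda^2}}
#' with \eqn{\lambda = \sqrt{n_a n_b / (n_a + n_b)}\, D}.
#'
#' @param a,b Numeric vectors (non-empty).
#' @return One-row tibble `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_distributions <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop_lncnet("both samples must be non-empty",
                class = "lncnet_validation_error")
  }
  if (anyNA(a) || anyNA(b)) {
    stop_lncnet("missing values not allowed", class = "lncnet_validation_error")
  }
  pts <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(pts)
  fb <- stats::ecdf(b)(pts)
  d <- max(abs(fa - fb))
  ne <- length(a) * length(b) / (length(a) + length(b))
  lambda <- sqrt(ne) * d
  p <- if (lambda < 1e-10) 1 else {
    j <- seq_len(200)
    min(1, max(0, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))))
  }
  tibble(statistic = d, p_value = p,
         n_a = length(a), n_b = length(b))
}
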