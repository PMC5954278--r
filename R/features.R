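# Gene models are tabular throughout: one row per exon with columns
# gene_id, transcript_id, chrom, strand, start, end (0-based half-open),
# biotype. GFF3 files (1-based closed) are converted on read/write.

validate_gene_models <- function(models) {
  needed <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(needed, names(models))
  if (length(miss) > 0) {
    stop_lncnet(paste0("gene models missing column(s): ",
                       paste(miss, collapse = ", ")),
                class = "lncnet_validation_error")
  }
  if (any(models$end <= models$start)) {
    stop_lncnet("exon with end <= start", class = "lncnet_format_error")
  }
  if (!all(models$strand %in% c("+", "-"))) {
    stop_lncnet("strand must be '+' or '-'", class = "lncnet_format_error")
  }
  invisible(models)
}

models_to_exon_granges <- function(models) {
  GenomicRanges::GRanges(
    models$chrom,
    IRanges::IRanges(models$start + 1L, models$end),
    strand = models$strand,
    gene_id = models$gene_id,
    transcript_id = models$transcript_id
  )
}

# One range per gene spanning all its exons (strand kept).
gene_spans <- function(models) {
  models |>
    group_by(.data$gene_id) |>
    summarise(chrom = dplyr::first(.data$chrom),
              strand = dplyr::first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
}

spans_to_granges <- function(spans) {
  GenomicRanges::GRanges(
    spans$chrom, IRanges::IRanges(spans$start + 1L, spans$end),
    strand = spans$strand, gene_id = spans$gene_id
  )
}

#' Write gene models as GFF3
#'
#' Emits gene, transcript and exon features with `ID`/`Parent` links and a
#' `biotype` attribute on genes, converting from the package's 0-based
#' half-open exon table to GFF3's 1-based closed coordinates.
#'
#' @param models Gene-model exon tibble (with `biotype`).
#' @param path Output path.
#' @return `models`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  validate_gene_models(models)
  genes <- models |>
    group_by(.data$gene_id) |>
    summarise(chrom = dplyr::first(.data$chrom),
              strand = dplyr::first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              biotype = dplyr::first(.data$biotype), .groups = "drop")
  txs <- models |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(chrom = dplyr::first(.data$chrom),
              strand = dplyr::first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  gr_gene <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand, type = "gene", ID = genes$gene_id,
    biotype = genes$biotype
  )
  gr_tx <- GenomicRanges::GRanges(
    txs$chrom, IRanges::IRanges(txs$start + 1L, txs$end),
    strand = txs$strand, type = "transcript", ID = txs$transcript_id,
    Parent = txs$gene_id
  )
  gr_ex <- GenomicRanges::GRanges(
    models$chrom, IRanges::IRanges(models$start + 1L, models$end),
    strand = models$strand, type = "exon", ID = NA_character_,
    Parent = models$transcript_id
  )
  all <- c(gr_gene, gr_tx, gr_ex)
  rtracklayer::export(all, path, format = "gff3")
  invisible(models)
}

#' Read gene models from GFF3
#'
#' Expects gene / transcript (or mRNA) / exon features linked by
#' `ID`/`Parent`; the gene `biotype` (or `gene_biotype`) attribute is kept
#' when present, else `default_biotype` applies.
#'
#' @param path GFF3 file.
#' @param default_biotype Biotype for genes without an attribute.
#' @return Gene-model exon tibble (0-based half-open).
#' @export
read_gene_models_gff3 <- function(path, default_biotype = "coding") {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  first_or_na <- function(x) {
    vapply(x, function(v) if (length(v)) as.character(v[1]) else NA_character_,
           character(1))
  }
  if ("Parent" %in% names(df)) df$parent1 <- first_or_na(df$Parent)
  genes <- filter(df, .data$type == "gene")
  gene_bio <- tibble(
    gene_id = genes$ID,
    biotype = if ("biotype" %in% names(genes)) {
      dplyr::coalesce(as.character(genes$biotype), default_biotype)
    } else if ("gene_biotype" %in% names(genes)) {
      dplyr::coalesce(as.character(genes$gene_biotype), default_biotype)
    } else {
      default_biotype
    }
  )
  txs <- filter(df, .data$type %in% c("transcript", "mRNA")) |>
    select(transcript_id = "ID", gene_id = "parent1")
  exons <- filter(df, .data$type == "exon") |>
    select(chrom = "seqnames", "start", "end", "strand",
           transcript_id = "parent1") |>
    mutate(start = .data$start - 1L)  # back to 0-based half-open
  out <- exons |>
    inner_join(txs, by = "transcript_id") |>
    inner_join(gene_bio, by = "gene_id") |>
    mutate(chrom = as.character(.data$chrom),
           strand = as.character(.data$strand)) |>
    select("gene_id", "transcript_id", "chrom", "strand",
           "start", "end", "biotype") |>
    arrange(.data$gene_id, .data$transcript_id, .data$start)
  validate_gene_models(out)
  out
}

#' Write transcripts as BED12
#'
#' One BED12 line per transcript with exons as blocks; gene ids and
#' biotypes are not representable in BED12 and must be carried separately.
#'
#' @param models Gene-model exon tibble.
#' @param path Output path.
#' @return `models`, invisibly.
#' @export
write_gene_models_bed12 <- function(models, path) {
  validate_gene_models(models)
  ex <- models_to_exon_granges(models)
  grl <- S4Vectors::split(ex, ex$transcript_id)
  bed <- rtracklayer::asBED(grl)
  rtracklayer::export(bed, path, format = "bed")
  invisible(models)
}

#' Read transcript models from BED12
#'
#' @param path BED12 file (blocks are exons).
#' @param tx2gene Optional two-column data frame (`transcript_id`,
#'   `gene_id`); defaults to gene id = transcript id.
#' @param biotypes Optional two-column data frame (`gene_id`, `biotype`);
#'   defaults to `default_biotype`.
#' @param default_biotype Fallback biotype.
#' @return Gene-model exon tibble (0-based half-open).
#' @export
read_gene_models_bed12 <- function(path, tx2gene = NULL, biotypes = NULL,
                                   default_biotype = "lncRNA") {
  gr <- rtracklayer::import(path, format = "bed")
  blocks <- gr$blocks
  out <- purrr::map_dfr(seq_along(gr), function(i) {
    b <- blocks[[i]]
    tx_start <- BiocGenerics::start(gr)[i] - 1L
    tibble(
      transcript_id = gr$name[i],
      chrom = as.character(GenomeInfoDb::seqnames(gr))[i],
      strand = as.character(BiocGenerics::strand(gr))[i],
      start = tx_start + BiocGenerics::start(b) - 1L,
      end = tx_start + BiocGenerics::end(b)
    )
  })
  if (!is.null(tx2gene)) {
    tx2gene <- as_tibble(tx2gene)
    names(tx2gene)[1:2] <- c("transcript_id", "gene_id")
    out <- left_join(out, tx2gene, by = "transcript_id")
    out$gene_id <- dplyr::coalesce(out$gene_id, out$transcript_id)
  } else {
    out$gene_id <- out$transcript_id
  }
  if (!is.null(biotypes)) {
    biotypes <- as_tibble(biotypes)
    names(biotypes)[1:2] <- c("gene_id", "biotype")
    out <- left_join(out, biotypes, by = "gene_id")
    out$biotype <- dplyr::coalesce(out$biotype, default_biotype)
  } else {
    out$biotype <- default_biotype
  }
  out <- select(out, "gene_id", "transcript_id", "chrom", "strand",
                "start", "end", "biotype")
  validate_gene_models(out)
  out
}

#' Classify lncRNA genes by genomic location relative to coding genes
#'
#' Deterministic precedence per transcript: (1) any exon-exon overlap with
#' a coding gene on the same strand is `sense_overlapping`; (2) else any
#' overlap with a coding gene span on the opposite strand is `antisense`;
#' (3) else full containment in a same-strand coding gene span without exon
#' overlap is `intronic`; (4) else `intergenic`. A gene whose transcripts
#' disagree takes the subtype of its first transcript in coordinate order
#' (a message notes this).
#'
#' @param lnc_models Exon tibble of lncRNA models.
#' @param coding_models Exon tibble of coding models.
#' @param chrom_sizes Optional tibble `chrom`, `size`; lncRNAs on a
#'   chromosome absent from it are flagged with a warning (and classified
#'   by the same rules, usually `intergenic`).
#' @return Tibble `gene_id`, `subtype`; transcript-level calls in attribute
#'   `"transcripts"`.
#' @export
classify_subtype <- function(lnc_models, coding_models, chrom_sizes = NULL) {
  validate_gene_models(lnc_models)
  validate_gene_models(coding_models)
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(lnc_models$chrom), chrom_sizes$chrom)
    if (length(unknown) > 0) {
      warn(paste0("lncRNA(s) on chromosome(s) absent from the genome: ",
                  paste(unknown, collapse = ", ")))
    }
  }
  lnc_ex <- models_to_exon_granges(lnc_models)
  cod_ex <- models_to_exon_granges(coding_models)
  cod_sp_tbl <- gene_spans(coding_models)
  cod_sp <- spans_to_granges(cod_sp_tbl)

  tx_tbl <- lnc_models |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(chrom = dplyr::first(.data$chrom),
              strand = dplyr::first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  tx_sp <- GenomicRanges::GRanges(
    tx_tbl$chrom, IRanges::IRanges(tx_tbl$start + 1L, tx_tbl$end),
    strand = tx_tbl$strand
  )

  # disjoint chromosome sets between the two inputs are legitimate here, so
  # the seqlevel mismatch warnings from findOverlaps are noise
  quiet_overlaps <- function(...) suppressWarnings(GenomicRanges::findOverlaps(...))

  # rule 1: same-strand exon-exon overlap
  ov_ex <- quiet_overlaps(lnc_ex, cod_ex, ignore.strand = FALSE)
  sense_tx <- unique(lnc_ex$transcript_id[S4Vectors::queryHits(ov_ex)])

  # rule 2: opposite-strand overlap with a coding gene span
  ov_sp <- quiet_overlaps(tx_sp, cod_sp, ignore.strand = TRUE)
  anti_tx <- unique(tx_tbl$transcript_id[
    S4Vectors::queryHits(ov_sp)[
      as.character(BiocGenerics::strand(tx_sp))[S4Vectors::queryHits(ov_sp)] !=
        as.character(BiocGenerics::strand(cod_sp))[S4Vectors::subjectHits(ov_sp)]
    ]
  ])

  # rule 3: same-strand full containment in a coding span
  ov_within <- quiet_overlaps(tx_sp, cod_sp, type = "within",
                              ignore.strand = FALSE)
  intronic_tx <- unique(tx_tbl$transcript_id[S4Vectors::queryHits(ov_within)])

  tx_calls <- tx_tbl |>
    mutate(subtype = dplyr::case_when(
      .data$transcript_id %in% sense_tx ~ "sense_overlapping",
      .data$transcript_id %in% anti_tx ~ "antisense",
      .data$transcript_id %in% intronic_tx ~ "intronic",
      TRUE ~ "intergenic"
    )) |>
    arrange(.data$gene_id, .data$chrom, .data$start, .data$transcript_id)
  gene_calls <- tx_calls |>
    group_by(.data$gene_id) |>
    summarise(subtype = dplyr::first(.data$subtype),
              n_subtypes = dplyr::n_distinct(.data$subtype),
              .groups = "drop")
  mixed <- sum(gene_calls$n_subtypes > 1)
  if (mixed > 0) {
    inform(paste0(mixed, " gene(s) with disagreeing transcript subtypes; ",
                  "using the first transcript by coordinate order"))
  }
  out <- select(gene_calls, "gene_id", "subtype")
  attr(out, "transcripts") <- select(tx_calls, "gene_id", "transcript_id",
                                     "subtype")
  out
}

#' Expression-level transcript filters
#'
#' Applies, in order: drop already-known coding transcripts; drop
#' transcripts shorter than 200 nt; multi-exon transcripts kept iff
#' FPKM > 0.1; single-exon transcripts kept iff FPKM > 5 and length
#' > 2000 nt. The `reason` column records the first failing rule.
#'
#' @param metrics Tibble with columns `transcript_id`, `fpkm`, `length`,
#'   `exon_count` and optionally logical `known_coding` (default `FALSE`).
#' @return `metrics` with added logical `keep` and character `reason`
#'   (`NA` for kept transcripts).
#' @export
transcript_filter <- function(metrics) {
  metrics <- as_tibble(metrics)
  if (!"known_coding" %in% names(metrics)) {
    metrics$known_coding <- FALSE
  }
  metrics |>
    mutate(reason = dplyr::case_when(
      .data$known_coding ~ "known_coding",
      .data$length < 200 ~ "shorter_than_200nt",
      .data$exon_count >= 2 & .data$fpkm <= 0.1 ~ "multi_exon_fpkm_below_0.1",
      .data$exon_count == 1 & .data$fpkm <= 5 ~ "single_exon_fpkm_below_5",
      .data$exon_count == 1 & .data$length <= 2000 ~ "single_exon_length_below_2000",
      TRUE ~ NA_character_
    ), keep = is.na(.data$reason))
}

#' Gene density per fixed-size chromosome window
#'
#' Each gene is counted once, in the window containing its 5'-most
#' coordinate (transcription start, strand-aware). Genes beyond the stated
#' chromosome size are clamped into the last window with a warning.
#'
#' @param models Gene-model exon tibble with `biotype`.
#' @param chrom_sizes Tibble `chrom`, `size`.
#' @param window Window size in bases, default 1e7 (10 Mb).
#' @return Tibble `chrom`, `window_start`, `window_end`, `biotype`,
#'   `n_genes`, covering every window of every chromosome (zero counts
#'   included).
#' @export
chromosome_density <- function(models, chrom_sizes, window = 1e7) {
  validate_gene_models(models)
  spans <- models |>
    group_by(.data$gene_id) |>
    summarise(chrom = dplyr::first(.data$chrom),
              strand = dplyr::first(.data$strand),
              biotype = dplyr::first(.data$biotype),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    mutate(tss = if_else(.data$strand == "+", .data$start, .data$end - 1L))
  spans <- inner_join(spans, as_tibble(chrom_sizes), by = "chrom")
  beyond <- spans$tss >= spans$size
  if (any(beyond)) {
    warn(paste0(sum(beyond), " gene(s) beyond the stated chromosome size; clamped"))
    spans$tss[beyond] <- spans$size[beyond] - 1L
  }
  grid <- as_tibble(chrom_sizes) |>
    mutate(n_windows = pmax(1L, as.integer(ceiling(.data$size / window)))) |>
    tidyr::uncount(.data$n_windows, .id = "win") |>
    mutate(window_start = (.data$win - 1) * window,
           window_end = pmin(.data$size, .data$win * window)) |>
    select("chrom", "window_start", "window_end")
  biotypes <- unique(models$biotype)
  grid <- tidyr::crossing(grid, biotype = biotypes)
  counts <- spans |>
    mutate(window_start = floor(.data$tss / window) * window) |>
    count(.data$chrom, .data$window_start, .data$biotype, name = "n_genes")
  grid |>
    left_join(counts, by = c("chrom", "window_start", "biotype")) |>
    mutate(n_genes = dplyr::coalesce(.data$n_genes, 0L)) |>
    arrange(.data$chrom, .data$window_start, .data$biotype)
}

#' Isoform- and exon-count summaries per biotype
#'
#' Bins per-gene isoform counts as 1, 2, 3, ">=4" and per-transcript exon
#' counts as 1, 2, 3, 4, ">=5".
#'
#' @param models Gene-model exon tibble with `biotype`.
#' @return Tibble `summary` (`"isoforms"` or `"exons"`), `biotype`, `bin`,
#'   `n`, `fraction`.
#' @export
structure_summaries <- function(models) {
  validate_gene_models(models)
  iso <- models |>
    distinct(.data$gene_id, .data$transcript_id, .data$biotype) |>
    count(.data$gene_id, .data$biotype, name = "k") |>
    mutate(bin = if_else(.data$k >= 4, ">=4", as.character(.data$k)))
  iso_bins <- iso |>
    count(.data$biotype, .data$bin, name = "n") |>
    group_by(.data$biotype) |>
    mutate(fraction = .data$n / sum(.data$n), summary = "isoforms") |>
    ungroup()
  ex <- models |>
    count(.data$transcript_id, .data$biotype, name = "k") |>
    mutate(bin = if_else(.data$k >= 5, ">=5", as.character(.data$k)))
  ex_bins <- ex |>
    count(.data$biotype, .data$bin, name = "n") |>
    group_by(.data$biotype) |>
    mutate(fraction = .data$n / sum(.data$n), summary = "exons") |>
    ungroup()
  bind_rows(iso_bins, ex_bins) |>
    select("summary", "biotype", "bin", "n", "fraction") |>
    arrange(.data$summary, .data$biotype, .data$bin)
}

#' Accuracy of subtype calls against truth labels
#'
#' @param predicted Tibble `gene_id`, `subtype`.
#' @param truth Tibble `gene_id`, `subtype`.
#' @return Fraction of truth genes whose predicted subtype matches.
#' @export
subtype_accuracy <- function(predicted, truth) {
  joined <- inner_join(as_tibble(truth), as_tibble(predicted),
                       by = "gene_id", suffix = c("_true", "_pred"))
  if (nrow(joined) == 0) {
    stop_lncnet("no overlapping genes between truth and prediction",
                class = "lncnet_validation_error")
  }
  mean(joined$subtype_true == joined$subtype_pred)
}
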