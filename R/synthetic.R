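#' Configuration for the synthetic-data generators
#'
#' Bundles and validates the parameters that control every synthetic input:
#' planted co-expression modules in an FPKM-like matrix, module-linked term
#' assignments, ortholog hit tables with decoys, a genome layout realizing
#' the four lncRNA subtypes, and TF-family sets with controlled overlap.
#'
#' @param n_coding,n_lnc Number of coding genes / lncRNAs (each >= n_modules
#'   so both biotypes occur in every module).
#' @param n_modules Number of planted co-expression modules.
#' @param n_samples Number of samples (>= 4; the edge test is degenerate
#'   below that).
#' @param n_tissues Number of tissue labels; samples are partitioned evenly
#'   (must not exceed `n_samples`). Default 5, matching a heart / liver /
#'   muscle / brain / blood style organ panel.
#' @param module_effect Amplitude multiplying the module's latent per-sample
#'   profile before the softplus link.
#' @param noise_sd Standard deviation of the per-gene, per-sample Gaussian
#'   noise added on the latent scale. `0` gives the exact noise-free limit.
#' @param terms_per_module Number of functional terms planted per module
#'   (disjoint across modules).
#' @param background_rate Probability that a coding gene additionally picks
#'   up any given foreign (other-module) term.
#' @param n_decoy_hits Number of decoy alignment rows added per direction in
#'   [generate_hit_tables()].
#' @param seed Integer seed; all generators are deterministic given it.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_coding = 60, n_lnc = 30, n_modules = 4,
                             n_samples = 20, n_tissues = 5,
                             module_effect = 3, noise_sd = 0.5,
                             terms_per_module = 3, background_rate = 0.05,
                             n_decoy_hits = 20, seed = 1) {
  cfg <- list(
    n_coding = as.integer(n_coding), n_lnc = as.integer(n_lnc),
    n_modules = as.integer(n_modules), n_samples = as.integer(n_samples),
    n_tissues = as.integer(n_tissues), module_effect = module_effect,
    noise_sd = noise_sd, terms_per_module = as.integer(terms_per_module),
    background_rate = background_rate,
    n_decoy_hits = as.integer(n_decoy_hits), seed = as.integer(seed)
  )
  counts <- c("n_coding", "n_lnc", "n_modules", "n_samples", "n_tissues",
              "terms_per_module")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1) {
      stop_lncnet(paste0("`", f, "` must be a count >= 1"),
                  class = "lncnet_validation_error")
    }
  }
  if (cfg$n_samples < 4) {
    stop_lncnet("`n_samples` must be >= 4 (rank correlation test degenerate below)",
                class = "lncnet_validation_error")
  }
  if (cfg$n_tissues > cfg$n_samples) {
    stop_lncnet("`n_tissues` must not exceed `n_samples`",
                class = "lncnet_validation_error")
  }
  if (cfg$noise_sd < 0 || cfg$module_effect <= 0) {
    stop_lncnet("`noise_sd` must be >= 0 and `module_effect` > 0",
                class = "lncnet_validation_error")
  }
  if (cfg$n_coding < cfg$n_modules || cfg$n_lnc < cfg$n_modules) {
    stop_lncnet("need at least one coding gene and one lncRNA per module",
                class = "lncnet_validation_error")
  }
  if (cfg$background_rate < 0 || cfg$background_rate >= 1) {
    stop_lncnet("`background_rate` must be in [0, 1)",
                class = "lncnet_validation_error")
  }
  if (cfg$n_decoy_hits < 0) {
    stop_lncnet("`n_decoy_hits` must be >= 0",
                class = "lncnet_validation_error")
  }
  structure(cfg, class = "synthetic_config")
}

module_term_ids <- function(m, terms_per_module) {
  sprintf("TERM_M%02d_%02d", m, seq_len(terms_per_module))
}

#' Ground truth attached to a synthetic object
#'
#' @param x An object produced by one of the `generate_*()` functions.
#' @return The list of truth tibbles recorded at generation time (module
#'   membership, planted terms, held-out lncRNA term sets, true ortholog
#'   pairs, or true subtype labels, depending on the generator).
#' @export
ground_truth <- function(x) {
  gt <- attr(x, "truth")
  if (is.null(gt)) {
    stop_lncnet("object carries no ground truth", class = "lncnet_validation_error")
  }
  gt
}

#' Generate an FPKM-like expression matrix with planted modules
#'
#' Each module gets one latent per-sample profile built from random tissue
#' effects plus a small per-sample jitter; the first module is made
#' tissue-restricted (high in the first tissue, suppressed elsewhere) so
#' tissue-specificity scoring has a nontrivial spread. A member gene's
#' expression is `softplus(module_effect * profile + N(0, noise_sd))`,
#' guaranteeing nonnegative values while preserving the rank structure of
#' the shared profile. Genes (coding and lncRNA ids interleaved) are
#' assigned to modules round-robin so both biotypes occur in every module.
#'
#' @param config A [synthetic_config()].
#' @return Expression tibble (`gene_id`, `biotype`, sample columns) with
#'   attributes: `"tissues"` (sample -> tissue tibble) and `"truth"`, a list
#'   with tibbles `modules` (gene_id, biotype, module), `module_terms`
#'   (module, term_id) and `lnc_terms` (gene_id, term_id; the held-out truth
#'   for annotation recovery).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::local_seed(derive_seed(config$seed, 1L))
  n_genes <- config$n_coding + config$n_lnc
  gene_id <- c(sprintf("CG%04d", seq_len(config$n_coding)),
               sprintf("LNC%04d", seq_len(config$n_lnc)))
  biotype <- rep(c("coding", "lncRNA"), c(config$n_coding, config$n_lnc))
  module <- c(
    rep_len(seq_len(config$n_modules), config$n_coding),
    rep_len(seq_len(config$n_modules), config$n_lnc)
  )
  sample_id <- sprintf("S%03d", seq_len(config$n_samples))
  tissue <- sprintf("tissue%02d",
                    rep_len(seq_len(config$n_tissues), config$n_samples) |> sort())
  # latent per-sample profile per module
  profiles <- vapply(seq_len(config$n_modules), function(m) {
    base <- rnorm(config$n_tissues)
    if (m == 1L) {
      # tissue-restricted module: expressed in the first tissue only
      base <- ifelse(seq_len(config$n_tissues) == 1L, 2.5, -2.5)
    }
    base[match(tissue, unique(tissue))] + rnorm(config$n_samples, sd = 0.3)
  }, numeric(config$n_samples))
  vals <- matrix(0, nrow = n_genes, ncol = config$n_samples)
  for (g in seq_len(n_genes)) {
    latent <- config$module_effect * profiles[, module[g]] +
      rnorm(config$n_samples, sd = config$noise_sd)
    vals[g, ] <- softplus(latent)
  }
  out <- dplyr::bind_cols(
    tibble(gene_id = gene_id, biotype = biotype),
    as_tibble(matrix(vals, nrow = n_genes, dimnames = list(NULL, sample_id)))
  )
  module_terms <- tibble(
    module = rep(seq_len(config$n_modules), each = config$terms_per_module),
    term_id = unlist(lapply(seq_len(config$n_modules), module_term_ids,
                            terms_per_module = config$terms_per_module))
  )
  modules <- tibble(gene_id = gene_id, biotype = biotype, module = module)
  lnc_terms <- modules |>
    filter(.data$biotype == "lncRNA") |>
    inner_join(module_terms, by = "module",
               relationship = "many-to-many") |>
    select("gene_id", "term_id")
  attr(out, "tissues") <- tibble(sample_id = sample_id, tissue = tissue)
  attr(out, "truth") <- list(modules = modules, module_terms = module_terms,
                             lnc_terms = lnc_terms)
  out
}

#' Generate coding-gene term annotations from planted module truth
#'
#' Coding genes receive their module's planted terms, plus any foreign
#' (other-module) term independently with probability
#' `config$background_rate`. lncRNAs receive no annotations: their true term
#' sets stay held out in the ground truth so annotation recovery can be
#' scored against them.
#'
#' @param truth Ground-truth list from [generate_expression()] (or the
#'   expression tibble itself).
#' @param config The [synthetic_config()] used to generate the truth.
#' @return Tibble with columns `gene_id`, `term_id` (coding genes only).
#' @export
generate_annotations <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.data.frame(truth)) truth <- ground_truth(truth)
  withr::local_seed(derive_seed(config$seed, 2L))
  coding <- filter(truth$modules, .data$biotype == "coding")
  planted <- coding |>
    inner_join(truth$module_terms, by = "module",
               relationship = "many-to-many") |>
    select("gene_id", "term_id")
  foreign <- coding |>
    dplyr::cross_join(truth$module_terms |> rename(term_module = "module")) |>
    filter(.data$module != .data$term_module) |>
    select("gene_id", "term_id")
  if (nrow(foreign) > 0 && config$background_rate > 0) {
    keep <- runif(nrow(foreign)) < config$background_rate
    background <- foreign[keep, , drop = FALSE]
  } else {
    background <- foreign[0, , drop = FALSE]
  }
  bind_rows(planted, background) |>
    distinct() |>
    arrange(.data$gene_id, .data$term_id)
}

random_evalues <- function(n, lo, hi) {
  10^runif(n, log10(lo), log10(hi))
}

outfmt6_row <- function(qseqid, sseqid, evalue, bitscore, length) {
  tibble(
    qseqid = qseqid, sseqid = sseqid,
    pident = round(runif(base::length(qseqid), 85, 100), 2),
    length = length,
    mismatch = sample.int(10L, base::length(qseqid), replace = TRUE) - 1L,
    gapopen = sample.int(3L, base::length(qseqid), replace = TRUE) - 1L,
    qstart = 1L, qend = length, sstart = 1L, send = length,
    evalue = evalue, bitscore = bitscore
  )
}

#' Generate bidirectional alignment hit tables with decoys
#'
#' Every lncRNA is paired one-to-one with a counterpart gene in a second
#' species; both directions get a mutual best hit with E-value at most
#' 1e-8. Decoy rows are added with E-values drawn log-uniformly in
#' `[1e-4, 1]`, straddling the conventional 1e-5 orthology threshold from
#' above, so they are removed by the threshold and never displace a true
#' best hit.
#'
#' @param truth Ground-truth list from [generate_expression()] (or the
#'   expression tibble).
#' @param config The [synthetic_config()].
#' @return List with elements `forward` and `reverse`, each a 12-column
#'   tabular-alignment tibble (outfmt-6 column semantics), carrying the true
#'   pairs as attribute `"truth"` (tibble `gene_a`, `gene_b`).
#' @export
generate_hit_tables <- function(truth, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.data.frame(truth)) truth <- ground_truth(truth)
  withr::local_seed(derive_seed(config$seed, 3L))
  lnc <- filter(truth$modules, .data$biotype == "lncRNA")$gene_id
  counterpart <- sprintf("HSLNC%04d", seq_along(lnc))
  pairs <- tibble(gene_a = lnc, gene_b = counterpart)
  len <- sample(200:2000, length(lnc), replace = TRUE)
  ev <- random_evalues(length(lnc), 1e-30, 1e-8)
  bs <- round(500 - 12 * log10(ev) + runif(length(lnc), 0, 20), 1)
  forward <- outfmt6_row(lnc, counterpart, ev, bs, len)
  reverse <- outfmt6_row(counterpart, lnc, ev, bs, len)
  if (config$n_decoy_hits > 0) {
    mk_decoys <- function(queries, subjects) {
      q <- sample(queries, config$n_decoy_hits, replace = TRUE)
      s <- sample(subjects, config$n_decoy_hits, replace = TRUE)
      dev <- random_evalues(config$n_decoy_hits, 1e-4, 1)
      dbs <- round(40 - 5 * log10(dev) + runif(config$n_decoy_hits, 0, 5), 1)
      dl <- sample(50:300, config$n_decoy_hits, replace = TRUE)
      d <- outfmt6_row(q, s, dev, dbs, dl)
      # never duplicate a true pair row
      anti_join(d, pairs, by = c(qseqid = "gene_a", sseqid = "gene_b")) |>
        anti_join(pairs, by = c(qseqid = "gene_b", sseqid = "gene_a"))
    }
    forward <- bind_rows(forward, mk_decoys(lnc, counterpart))
    reverse <- bind_rows(reverse, mk_decoys(counterpart, lnc))
  }
  out <- list(forward = forward, reverse = reverse)
  attr(out, "truth") <- list(pairs = pairs)
  out
}

#' Generate a genome layout realizing all four lncRNA subtypes
#'
#' Coding genes are placed every 100 kb on one chromosome, each with two
#' exons separated by an 8 kb intron, on alternating strands. Each lncRNA is
#' then placed relative to a host coding gene so its true subtype is known:
#' intergenic (45 kb clear of any coding span), sense overlapping (exon
#' overlapping a host exon, same strand), antisense (inside the host span on
#' the opposite strand) or intronic (inside the host intron, same strand).
#' Coordinates are 0-based half-open.
#'
#' @param config A [synthetic_config()].
#' @return Gene-model tibble (one row per exon: `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `start`, `end`, `biotype`) with attributes
#'   `"truth"` (list with tibble `subtypes`: gene_id, subtype) and
#'   `"chrom_sizes"` (tibble chrom, size).
#' @export
generate_genome_layout <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  spacing <- 100000L
  coding <- purrr::map_dfr(seq_len(config$n_coding), function(j) {
    s <- (j - 1L) * spacing
    strand <- if (j %% 2L == 1L) "+" else "-"
    tibble(
      gene_id = sprintf("CG%04d", j),
      transcript_id = sprintf("CG%04d.t1", j),
      chrom = "chr1", strand = strand,
      start = c(s, s + 9000L), end = c(s + 1000L, s + 10000L),
      biotype = "coding"
    )
  })
  subtypes <- c("intergenic", "sense_overlapping", "antisense", "intronic")
  lnc <- purrr::map_dfr(seq_len(config$n_lnc), function(i) {
    host <- ((i - 1L) %% config$n_coding) + 1L
    sub <- subtypes[((i - 1L) %% 4L) + 1L]
    wave <- ((i - 1L) %/% (4L * config$n_coding)) * 20L  # avoid identical stacking
    s <- (host - 1L) * spacing
    host_strand <- if (host %% 2L == 1L) "+" else "-"
    flip <- function(x) if (x == "+") "-" else "+"
    coords <- switch(sub,
      intergenic = list(start = s + 50000L + wave, end = s + 51000L + wave,
                        strand = "+"),
      sense_overlapping = list(start = s + 500L + wave, end = s + 1500L + wave,
                               strand = host_strand),
      antisense = list(start = s + 3000L + wave, end = s + 4000L + wave,
                       strand = flip(host_strand)),
      intronic = list(start = s + 5000L + wave, end = s + 6000L + wave,
                      strand = host_strand)
    )
    tibble(
      gene_id = sprintf("LNC%04d", i),
      transcript_id = sprintf("LNC%04d.t1", i),
      chrom = "chr1", strand = coords$strand,
      start = coords$start, end = coords$end,
      biotype = "lncRNA",
      true_subtype = sub
    )
  })
  truth <- list(subtypes = distinct(select(lnc, "gene_id",
                                           subtype = "true_subtype")))
  out <- bind_rows(coding, select(lnc, -"true_subtype"))
  attr(out, "truth") <- truth
  attr(out, "chrom_sizes") <- tibble(
    chrom = "chr1", size = config$n_coding * spacing + spacing
  )
  out
}

#' Generate per-gene TF-family sets with controlled cross-species overlap
#'
#' True ortholog pairs share most upstream transcription-factor families
#' (high intersection-over-union), while unrelated genes draw independent
#' sets, so the IoU distribution separates true pairs from shuffled pairs.
#'
#' @param truth Ground-truth list carrying `pairs` (from
#'   [generate_hit_tables()]) or an object with that truth attached.
#' @param config The [synthetic_config()].
#' @param n_families Size of the TF-family vocabulary.
#' @return List with tibbles `species_a` and `species_b`, each two columns
#'   (`gene_id`, `tf_family`).
#' @export
generate_tf_families <- function(truth, config, n_families = 30) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.data.frame(truth) || !is.null(attr(truth, "truth"))) {
    truth <- attr(truth, "truth")
  }
  if (is.null(truth$pairs)) {
    stop_lncnet("`truth` must carry ortholog pairs (run generate_hit_tables())",
                class = "lncnet_validation_error")
  }
  pairs <- truth$pairs
  withr::local_seed(derive_seed(config$seed, 4L))
  fams <- sprintf("TF%02d", seq_len(n_families))
  draw <- function(k) sample(fams, k)
  a <- list(); b <- list()
  for (i in seq_len(nrow(pairs))) {
    core <- draw(5)
    a[[i]] <- tibble(gene_id = pairs$gene_a[i],
                     tf_family = c(core, draw(1)))
    b[[i]] <- tibble(gene_id = pairs$gene_b[i],
                     tf_family = c(core, draw(1)))
  }
  list(
    species_a = bind_rows(a) |> distinct(),
    species_b = bind_rows(b) |> distinct()
  )
}

#' Write a complete synthetic input bundle to disk
#'
#' Materializes every file the pipeline consumes (expression TSV, biotype
#' TSV, tissue TSV, term TSV, forward/reverse hit TSVs, TF-family TSVs,
#' GFF3 gene models, chromosome sizes) plus the ground truth under
#' `truth/`, so a full run needs no external data.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named list of the written paths.
#' @export
write_synthetic_bundle <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  expr <- generate_expression(config)
  truth <- ground_truth(expr)
  ann <- generate_annotations(truth, config)
  hits <- generate_hit_tables(truth, config)
  hit_truth <- attr(hits, "truth")
  tf <- generate_tf_families(hit_truth, config)
  layout <- generate_genome_layout(config)
  layout_truth <- ground_truth(layout)

  p <- list(
    expression = file.path(dir, "expression.tsv"),
    biotype = file.path(dir, "biotype.tsv"),
    tissues = file.path(dir, "tissues.tsv"),
    terms = file.path(dir, "terms.tsv"),
    hits_forward = file.path(dir, "hits_forward.tsv"),
    hits_reverse = file.path(dir, "hits_reverse.tsv"),
    tf_a = file.path(dir, "tf_species_a.tsv"),
    tf_b = file.path(dir, "tf_species_b.tsv"),
    gene_models = file.path(dir, "gene_models.gff3"),
    chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
    truth_modules = file.path(dir, "truth", "modules.tsv"),
    truth_lnc_terms = file.path(dir, "truth", "lnc_terms.tsv"),
    truth_pairs = file.path(dir, "truth", "ortholog_pairs.tsv"),
    truth_subtypes = file.path(dir, "truth", "subtypes.tsv")
  )
  write_expression(expr, p$expression, p$biotype)
  readr::write_tsv(attr(expr, "tissues"), p$tissues, progress = FALSE)
  readr::write_tsv(ann, p$terms, col_names = FALSE, progress = FALSE)
  readr::write_tsv(hits$forward, p$hits_forward, col_names = FALSE, progress = FALSE)
  readr::write_tsv(hits$reverse, p$hits_reverse, col_names = FALSE, progress = FALSE)
  readr::write_tsv(tf$species_a, p$tf_a, col_names = FALSE, progress = FALSE)
  readr::write_tsv(tf$species_b, p$tf_b, col_names = FALSE, progress = FALSE)
  write_gene_models_gff3(layout, p$gene_models)
  readr::write_tsv(attr(layout, "chrom_sizes"), p$chrom_sizes, progress = FALSE)
  readr::write_tsv(truth$modules, p$truth_modules, progress = FALSE)
  readr::write_tsv(truth$lnc_terms, p$truth_lnc_terms, progress = FALSE)
  readr::write_tsv(hit_truth$pairs, p$truth_pairs, progress = FALSE)
  readr::write_tsv(layout_truth$subtypes, p$truth_subtypes, progress = FALSE)
  invisible(p)
}
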