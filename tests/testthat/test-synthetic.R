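tiny_cfg <- function(...) {
  synthetic_config(n_coding = 8, n_lnc = 4, n_modules = 2, n_samples = 20,
                   n_tissues = 4, ...)
}

test_that("generators are deterministic for a fixed seed", {
  a <- generate_expression(tiny_cfg(seed = 42))
  b <- generate_expression(tiny_cfg(seed = 42))
  expect_identical(as.data.frame(a), as.data.frame(b))
  truth <- ground_truth(a)
  cfg <- tiny_cfg(seed = 42)
  expect_identical(generate_annotations(truth, cfg),
                   generate_annotations(truth, cfg))
  h1 <- generate_hit_tables(truth, cfg)
  h2 <- generate_hit_tables(truth, cfg)
  expect_identical(h1$forward, h2$forward)
  expect_identical(h1$reverse, h2$reverse)
  c <- generate_expression(tiny_cfg(seed = 43))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("noise-free modules give perfect within-module rank agreement", {
  expr <- generate_expression(tiny_cfg(noise_sd = 0, seed = 7))
  truth <- ground_truth(expr)
  m <- as.matrix(expr[, -(1:2)])
  rownames(m) <- expr$gene_id
  mods <- split(truth$modules$gene_id, truth$modules$module)
  for (members in mods) {
    for (i in seq_along(members)) {
      for (j in seq_along(members)) {
        if (i < j) {
          rs <- spearman_edge_test(m[members[i], ], m[members[j], ])$rs
          expect_equal(rs, 1)
        }
      }
    }
  }
})

test_that("within-module correlation decays with the noise level", {
  mean_within_rs <- function(noise_sd, seed) {
    expr <- generate_expression(tiny_cfg(noise_sd = noise_sd, seed = seed))
    truth <- ground_truth(expr)
    m <- as.matrix(expr[, -(1:2)])
    rownames(m) <- expr$gene_id
    vals <- c()
    for (members in split(truth$modules$gene_id, truth$modules$module)) {
      rs <- cor(apply(m[members, ], 1, rank))
      vals <- c(vals, rs[upper.tri(rs)])
    }
    mean(vals)
  }
  reps <- 50
  low <- vapply(seq_len(reps), function(s) mean_within_rs(0.3, s), numeric(1))
  high <- vapply(seq_len(reps), function(s) mean_within_rs(3, s), numeric(1))
  expect_gt(mean(low), mean(high))
})

test_that("within-module edge recall is non-increasing in noise over a grid", {
  recall_at <- function(noise_sd, seed) {
    expr <- generate_expression(tiny_cfg(noise_sd = noise_sd, seed = seed))
    net <- build_network(upper_quartile_normalize(expr))
    edge_recall(net, ground_truth(expr))
  }
  grid <- c(0.2, 1.5, 6)
  recalls <- vapply(grid, function(ns) {
    mean(vapply(1:20, function(s) recall_at(ns, s), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(recalls) <= 1e-9))
})

test_that("annotations plant module terms on coding genes and hold out lncRNAs", {
  cfg <- synthetic_config(n_coding = 12, n_lnc = 8, n_modules = 4,
                          n_samples = 8, n_tissues = 2, terms_per_module = 3,
                          background_rate = 0, seed = 5)
  expr <- generate_expression(cfg)
  truth <- ground_truth(expr)
  ann <- generate_annotations(truth, cfg)
  # background rate 0: every coding gene gets exactly its module's terms
  planted <- dplyr::inner_join(
    dplyr::filter(truth$modules, biotype == "coding"),
    truth$module_terms, by = "module", relationship = "many-to-many")
  expect_setequal(paste(ann$gene_id, ann$term_id),
                  paste(planted$gene_id, planted$term_id))
  # lncRNAs are absent from the emitted map
  lnc_ids <- truth$modules$gene_id[truth$modules$biotype == "lncRNA"]
  expect_length(intersect(ann$gene_id, lnc_ids), 0)
  # disjoint planting across 4 modules x 3 terms
  expect_gte(length(unique(truth$module_terms$term_id)), 12)
  # with a positive background rate annotations are a superset of planted
  cfg_bg <- synthetic_config(n_coding = 12, n_lnc = 8, n_modules = 4,
                             n_samples = 8, n_tissues = 2,
                             background_rate = 0.5, seed = 5)
  ann_bg <- generate_annotations(truth, cfg_bg)
  expect_gt(nrow(ann_bg), nrow(ann))
})

test_that("hit tables embed recoverable reciprocal best hits despite decoys", {
  cfg0 <- tiny_cfg(n_decoy_hits = 0, seed = 11)
  expr <- generate_expression(cfg0)
  truth <- ground_truth(expr)
  h0 <- generate_hit_tables(truth, cfg0)
  p0 <- reciprocal_best_hits(h0$forward, h0$reverse)
  true_pairs <- attr(h0, "truth")$pairs
  expect_setequal(paste(p0$gene_a, p0$gene_b),
                  paste(true_pairs$gene_a, true_pairs$gene_b))
  # decoys all have E-value > 1e-5, so the recovered set is unchanged
  cfgd <- tiny_cfg(n_decoy_hits = 40, seed = 11)
  hd <- generate_hit_tables(truth, cfgd)
  expect_gt(min(setdiff(hd$forward$evalue, h0$forward$evalue)), 1e-5)
  pd <- reciprocal_best_hits(hd$forward, hd$reverse)
  expect_setequal(paste(pd$gene_a, pd$gene_b),
                  paste(true_pairs$gene_a, true_pairs$gene_b))
})

test_that("a best hit in only one direction breaks the pair", {
  cfg0 <- tiny_cfg(n_decoy_hits = 0, seed = 13)
  truth <- ground_truth(generate_expression(cfg0))
  h <- generate_hit_tables(truth, cfg0)
  victim <- h$forward$qseqid[1]
  other <- h$forward$sseqid[2]
  # a forward-only decoy that outcompetes the victim's true best hit
  decoy <- h$forward[1, ]
  decoy$sseqid <- other
  decoy$evalue <- min(h$forward$evalue) / 100
  pairs <- reciprocal_best_hits(dplyr::bind_rows(h$forward, decoy), h$reverse)
  expect_false(victim %in% pairs$gene_a)
  # every other true pair survives
  true_pairs <- attr(h, "truth")$pairs
  rest <- dplyr::filter(true_pairs, gene_a != victim)
  expect_setequal(paste(pairs$gene_a, pairs$gene_b),
                  paste(rest$gene_a, rest$gene_b))
})

test_that("genome layout realizes all four subtypes with truth labels", {
  cfg <- tiny_cfg(seed = 3)
  layout <- generate_genome_layout(cfg)
  truth <- ground_truth(layout)$subtypes
  expect_setequal(unique(truth$subtype),
                  c("intergenic", "sense_overlapping", "antisense", "intronic"))
  expect_true(all(layout$end > layout$start))
  expect_setequal(unique(layout$strand), c("+", "-"))
})

test_that("a written bundle round-trips through the package readers", {
  cfg <- tiny_cfg(seed = 17)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_bundle(cfg, dir)
  expr <- generate_expression(cfg)
  back <- read_expression(paths$expression, paths$biotype, paths$tissues)
  expect_equal(as.data.frame(back), as.data.frame(expr), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "tissues"), attr(expr, "tissues"))
  ann <- read_annotations(paths$terms)
  expect_equal(ann, generate_annotations(ground_truth(expr), cfg))
  hits <- generate_hit_tables(ground_truth(expr), cfg)
  fwd <- read_blast_hits(paths$hits_forward)
  expect_equal(as.data.frame(fwd), as.data.frame(hits$forward),
               tolerance = 1e-12, ignore_attr = TRUE)
  models <- read_gene_models_gff3(paths$gene_models)
  layout <- generate_genome_layout(cfg)
  expect_equal(
    as.data.frame(dplyr::arrange(models, gene_id, start)),
    as.data.frame(dplyr::arrange(layout, gene_id, start)),
    ignore_attr = TRUE
  )
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(n_samples = 3), class = "lncnet_validation_error")
  expect_error(synthetic_config(n_tissues = 30, n_samples = 20),
               class = "lncnet_validation_error")
  expect_error(synthetic_config(n_modules = 0), class = "lncnet_validation_error")
  expect_error(synthetic_config(noise_sd = -1), class = "lncnet_validation_error")
  expect_error(synthetic_config(n_coding = 2, n_modules = 4),
               class = "lncnet_validation_error")
})
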