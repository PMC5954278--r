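hit_row <- function(q, s, e, bits = 100) {
  tibble::tibble(qseqid = q, sseqid = s, pident = 95, length = 500,
                 mismatch = 2, gapopen = 0, qstart = 1, qend = 500,
                 sstart = 1, send = 500, evalue = e, bitscore = bits)
}

test_that("reciprocal best hits require mutual best hits under the threshold", {
  fwd <- dplyr::bind_rows(
    hit_row("z1", "h1", 1e-20),
    hit_row("z2", "h2", 1e-15),
    hit_row("z3", "h1", 1e-30)   # z3's best is h1, but h1 prefers z1...
  )
  rev <- dplyr::bind_rows(
    hit_row("h1", "z1", 1e-20),
    hit_row("h2", "z2", 1e-15)
  )
  pairs <- reciprocal_best_hits(fwd, rev)
  expect_setequal(paste(pairs$gene_a, pairs$gene_b), c("z1 h1", "z2 h2"))
  # one-directional best hit is excluded
  expect_false("z3" %in% pairs$gene_a)
  # everything above the threshold -> empty
  weak <- hit_row("z1", "h1", 1e-3)
  expect_equal(nrow(reciprocal_best_hits(weak, weak)), 0)
  # each id appears at most once
  expect_false(any(duplicated(pairs$gene_a)))
  expect_false(any(duplicated(pairs$gene_b)))
})

test_that("RBH is symmetric under swapping the two directions", {
  cfg <- synthetic_config(n_coding = 8, n_lnc = 6, n_modules = 2,
                          n_samples = 8, n_tissues = 2, seed = 4)
  truth <- ground_truth(generate_expression(cfg))
  h <- generate_hit_tables(truth, cfg)
  ab <- reciprocal_best_hits(h$forward, h$reverse)
  ba <- reciprocal_best_hits(h$reverse, h$forward)
  expect_setequal(paste(ab$gene_a, ab$gene_b), paste(ba$gene_b, ba$gene_a))
})

test_that("ties in E-value break by bit score then subject id", {
  fwd <- dplyr::bind_rows(hit_row("z1", "hB", 1e-10, bits = 50),
                          hit_row("z1", "hA", 1e-10, bits = 80))
  rev <- hit_row("hA", "z1", 1e-10)
  expect_equal(reciprocal_best_hits(fwd, rev)$gene_b, "hA")
  fwd2 <- dplyr::bind_rows(hit_row("z1", "hB", 1e-10, bits = 50),
                           hit_row("z1", "hA", 1e-10, bits = 50))
  expect_equal(reciprocal_best_hits(fwd2, rev)$gene_b, "hA")
})

test_that("transcript pairs collapse to one row per gene", {
  pairs <- tibble::tibble(gene_a = c("t1", "t2", "t3"),
                          gene_b = c("u1", "u2", "u3"),
                          evalue_forward = c(1e-10, 1e-20, 1e-5),
                          evalue_reverse = c(1e-10, 1e-20, 1e-5))
  tx2gene <- tibble::tibble(transcript_id = c("t1", "t2"), gene_id = "gA")
  collapsed <- collapse_to_genes(pairs, tx2gene)
  expect_equal(nrow(collapsed), 2)
  # representative is the lowest forward E-value transcript
  expect_equal(collapsed$gene_b[collapsed$gene_a == "gA"], "u2")
})

test_that("tissue specificity index follows its closed forms", {
  expect_equal(tsi(c(0, 0, 7, 0)), 1)
  expect_equal(tsi(rep(3, 5)), 1 / 5)
  expect_equal(tsi(c(1, 2, 3, 4)), 0.4)
  expect_error(tsi(c(0, 0)), class = "lncnet_validation_error")
  expect_error(tsi(c(-1, 2)), class = "lncnet_validation_error")
  # TSI in [1/n, 1] for positive vectors
  withr::local_seed(5)
  for (i in 1:25) {
    x <- rexp(sample(2:10, 1))
    expect_gte(tsi(x), 1 / length(x))
    expect_lte(tsi(x), 1)
  }
})

test_that("ortholog profile correlation separates true pairs from shuffled", {
  withr::local_seed(77)
  tissues <- sprintf("t%d", 1:5)
  n <- 30
  base <- matrix(rexp(n * 5), nrow = n)
  prof_a <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("z%02d", 1:n)),
    tibble::as_tibble(base, .name_repair = ~tissues))
  prof_b <- dplyr::bind_cols(
    tibble::tibble(gene_id = sprintf("h%02d", 1:n)),
    tibble::as_tibble(base + matrix(rnorm(n * 5, sd = 0.1), nrow = n),
                      .name_repair = ~tissues))
  true_pairs <- tibble::tibble(gene_a = prof_a$gene_id,
                               gene_b = prof_b$gene_id)
  shuffled <- tibble::tibble(gene_a = prof_a$gene_id,
                             gene_b = sample(prof_b$gene_id))
  rs_true <- ortholog_expression_correlation(true_pairs, prof_a, prof_b)$rs
  rs_rand <- ortholog_expression_correlation(shuffled, prof_a, prof_b)$rs
  expect_gt(mean(rs_true), mean(rs_rand))
  expect_gt(compare_distributions(rs_true, rs_rand)$statistic, 0.3)
  # identical profiles give rs = 1; reversed ranks give -1
  p1 <- prof_a[1, ]
  p2 <- p1; p2$gene_id <- "h"
  expect_equal(ortholog_expression_correlation(
    tibble::tibble(gene_a = p1$gene_id, gene_b = "h"), p1, p2)$rs, 1)
  p3 <- p1
  v <- as.numeric(p1[1, tissues])
  p3[1, tissues] <- as.list(max(v) + 1 - v)  # antitone: ranks exactly reversed
  p3$gene_id <- "h"
  expect_equal(ortholog_expression_correlation(
    tibble::tibble(gene_a = p1$gene_id, gene_b = "h"), p1, p3)$rs, -1)
  # mismatched tissue columns rejected
  bad <- prof_b
  names(bad)[2:6] <- rev(tissues)
  expect_error(ortholog_expression_correlation(true_pairs, prof_a, bad),
               class = "lncnet_validation_error")
})

test_that("TF-family IoU follows set arithmetic", {
  expect_equal(tf_family_iou(c("A", "B"), c("A", "B")), 1)
  expect_equal(tf_family_iou(c("A"), c("B")), 0)
  expect_equal(tf_family_iou(c("A", "B"), c("B", "C")), 1 / 3)
  expect_equal(tf_family_iou(c("A", "A"), c("A")), 1)  # duplicates ignored
  expect_error(tf_family_iou(character(), character()),
               class = "lncnet_validation_error")
  # both-empty pairs are excluded from the table, not scored 0
  pairs <- tibble::tibble(gene_a = c("z1", "z2"), gene_b = c("h1", "h2"))
  tf_a <- tibble::tibble(gene_id = "z1", tf_family = "A")
  tf_b <- tibble::tibble(gene_id = "h1", tf_family = "A")
  tab <- tf_iou_table(pairs, tf_a, tf_b)
  expect_equal(tab$gene_a, "z1")
  expect_equal(tab$iou, 1)
})

test_that("conservation score is an exon-length-weighted mean", {
  mdl <- tibble::tibble(gene_id = "g", transcript_id = "t", chrom = "chr1",
                        strand = "+", start = c(100, 500), end = c(110, 530),
                        biotype = "lncRNA")
  track <- tibble::tibble(chrom = "chr1", start = c(100, 500),
                          end = c(110, 530), score = c(1, 0))
  expect_equal(conservation_score(mdl, track)$score, 0.25)  # (10*1 + 30*0)/40
  # uniform track
  uni <- tibble::tibble(chrom = "chr1", start = 0, end = 1000, score = 0.8)
  expect_equal(conservation_score(mdl, uni)$score, 0.8)
  # transcript fully outside the track scores 0
  far <- tibble::tibble(chrom = "chr1", start = 5000, end = 6000, score = 1)
  expect_equal(conservation_score(mdl, far)$score, 0)
  # invariance to splitting track intervals into adjacent pieces
  split_track <- tibble::tibble(chrom = "chr1",
                                start = c(100, 105, 500, 510),
                                end = c(105, 110, 510, 530),
                                score = c(1, 1, 0, 0))
  expect_equal(conservation_score(mdl, split_track)$score, 0.25)
  expect_error(conservation_score(
    mdl, tibble::tibble(chrom = "chr1", start = 10, end = 5, score = 1)),
    class = "lncnet_format_error")
})

test_that("KS comparison matches brute force and the stats oracle", {
  same <- compare_distributions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disjoint <- compare_distributions(runif(10), runif(10) + 5)
  expect_equal(disjoint$statistic, 1)
  withr::local_seed(44)
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1), mean = runif(1, 0, 2))
    res <- compare_distributions(a, b)
    # brute force: sup over all pooled points of |ECDF difference|
    pts <- c(a, b)
    d_brute <- max(vapply(pts, function(t) {
      abs(mean(a <= t) - mean(b <= t))
    }, numeric(1)))
    expect_equal(res$statistic, d_brute)
  }
  # asymptotic p agrees with the reference implementation
  a <- rnorm(60); b <- rnorm(60, 0.6)
  res <- compare_distributions(a, b)
  ref <- suppressWarnings(ks.test(a, b, exact = FALSE))
  expect_equal(res$statistic, unname(ref$statistic))
  # both are the asymptotic limiting series, truncated differently
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-4)
  expect_error(compare_distributions(numeric(), 1:3),
               class = "lncnet_validation_error")
})

test_that("hit-table reader enforces the 12-column dialect", {
  dir <- withr::local_tempdir()
  good <- file.path(dir, "good.tsv")
  readr::write_tsv(hit_row("a", "b", 1e-9), good, col_names = FALSE)
  hits <- read_blast_hits(good)
  expect_equal(hits$evalue, 1e-9)
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("a\tb\tnot_a_number\t1\t1\t1\t1\t1\t1\t1\t1e-5\t50"), bad)
  expect_error(read_blast_hits(bad), class = "lncnet_format_error")
})
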