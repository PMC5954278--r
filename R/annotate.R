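#' Exact hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more annotated genes among `n` draws
#' without replacement from a universe of `N` genes of which `M` carry the
#' annotation:
#' \deqn{P = 1 - \sum_{i=0}^{k-1} \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n},}
#' evaluated as the direct upper-tail sum in log space for stability.
#' `k = 0` gives exactly 1.
#'
#' @param N Universe size (genes in the network).
#' @param M Genes carrying the term.
#' @param n Neighborhood size (draws).
#' @param k Neighbors carrying the term. All arguments vectorized.
#' @return Numeric vector of upper-tail probabilities in (0, 1].
#' @export
hypergeom_upper_tail <- function(N, M, n, k) {
  args <- vctrs_recycle(N, M, n, k)
  N <- args[[1]]; M <- args[[2]]; n <- args[[3]]; k <- args[[4]]
  if (any(M < 0 | M > N) || any(n < 0 | n > N) ||
      any(k < 0 | k > pmin(M, n))) {
    stop_lncnet("require 0 <= M <= N, 0 <= n <= N, 0 <= k <= min(M, n)",
                class = "lncnet_validation_error")
  }
  vapply(seq_along(N), function(j) {
    if (k[j] == 0) return(1)
    i <- k[j]:min(M[j], n[j])
    lt <- lchoose(M[j], i) + lchoose(N[j] - M[j], n[j] - i) -
      lchoose(N[j], n[j])
    min(1, exp(logsumexp(lt)))
  }, numeric(1))
}

# base-R recycling of equal-or-length-1 argument vectors
vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(lengths(args))
  lapply(args, function(a) {
    if (length(a) == len) a else rep_len(a, len)
  })
}

# Validate and normalize an annotation table to tibble(gene_id, term_id).
as_annotation_map <- function(ann) {
  ann <- as_tibble(ann)
  if (ncol(ann) < 2) {
    stop_lncnet("annotation map needs two columns (gene, term)",
                class = "lncnet_validation_error")
  }
  names(ann)[1:2] <- c("gene_id", "term_id")
  distinct(ann[, c("gene_id", "term_id")])
}

#' Read a two-column gene-to-term annotation table
#'
#' @param path Tab-separated file, two columns (gene id, term id), no header.
#' @return Tibble `gene_id`, `term_id`.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path, col_names = c("gene_id", "term_id"),
                         col_types = "cc", progress = FALSE)
  as_annotation_map(ann)
}

#' Close an annotation map under a term ancestor relation
#'
#' Every gene annotated with a term also receives all of that term's
#' ancestors, the standard convention for hierarchical (GO-style)
#' vocabularies. The parent relation must be acyclic.
#'
#' @param ann Annotation tibble (`gene_id`, `term_id`).
#' @param parents Two-column data frame (`child`, `parent`).
#' @return Closed annotation tibble.
#' @export
propagate_ancestors <- function(ann, parents) {
  ann <- as_annotation_map(ann)
  parents <- as_tibble(parents)
  names(parents)[1:2] <- c("child", "parent")
  assert_acyclic(parents)
  n_terms <- length(unique(c(parents$child, parents$parent)))
  out <- ann
  for (step in seq_len(n_terms + 1)) {
    grown <- out |>
      inner_join(parents, by = c(term_id = "child"),
                 relationship = "many-to-many") |>
      select("gene_id", term_id = "parent")
    new <- anti_join(grown, out, by = c("gene_id", "term_id"))
    if (nrow(new) == 0) {
      return(arrange(out, .data$gene_id, .data$term_id))
    }
    if (step > n_terms) {
      stop_lncnet("cycle detected in term parent relation",
                  class = "lncnet_validation_error")
    }
    out <- bind_rows(out, new)
  }
  arrange(out, .data$gene_id, .data$term_id)
}

# Topological-elimination acyclicity check on the child -> parent relation.
assert_acyclic <- function(parents) {
  g <- parents[, c("child", "parent")]
  nodes <- unique(c(g$child, g$parent))
  while (nrow(g) > 0) {
    roots <- setdiff(nodes, g$child)  # terms with no outgoing edge
    if (length(roots) == 0) {
      stop_lncnet("cycle detected in term parent relation",
                  class = "lncnet_validation_error")
    }
    g <- g[!g$parent %in% roots, , drop = FALSE]
    nodes <- setdiff(nodes, roots)
  }
  invisible(TRUE)
}

# Precomputed lookup for fast repeated enrichment: per-gene term lists and
# per-term gene counts (M).
annotation_index <- function(ann) {
  list(
    gene2terms = split(ann$term_id, ann$gene_id),
    term_counts = table(ann$term_id)
  )
}

# Core enrichment of a neighbor set against an annotation index.
# N = universe size; returns tibble(term_id, N, M, n, k, p) unfiltered.
enrich_neighbor_terms <- function(neighbor_ids, index, N) {
  empty <- tibble(term_id = character(), N = integer(), M = integer(),
                  n = integer(), k = integer(), p = numeric())
  n <- length(neighbor_ids)
  if (n == 0) return(empty)
  hit_terms <- unlist(
    index$gene2terms[intersect(neighbor_ids, names(index$gene2terms))],
    use.names = FALSE
  )
  if (length(hit_terms) == 0) return(empty)
  k <- table(hit_terms)
  terms <- names(k)
  M <- as.integer(index$term_counts[terms])
  tibble(term_id = terms, N = as.integer(N), M = M, n = as.integer(n),
         k = as.integer(k),
         p = hypergeom_upper_tail(N, M, n, as.integer(k)))
}

# Tibble-free variant for tight resampling loops: just the term ids with
# enrichment p below the threshold.
enriched_term_ids <- function(neighbor_ids, index, N, p_threshold) {
  if (length(neighbor_ids) == 0) return(character())
  hit_terms <- unlist(
    index$gene2terms[intersect(neighbor_ids, names(index$gene2terms))],
    use.names = FALSE
  )
  if (length(hit_terms) == 0) return(character())
  k <- table(hit_terms)
  terms <- names(k)
  M <- as.integer(index$term_counts[terms])
  p <- hypergeom_upper_tail(N, M, length(neighbor_ids), as.integer(k))
  terms[p < p_threshold]
}

#' Guilt-by-association term enrichment for one gene
#'
#' For every term carried by at least one immediate neighbor of `gene`, the
#' hypergeometric upper tail is evaluated with `N` = number of genes in the
#' network, `M` = network genes carrying the term, `n` = the gene's
#' (optionally biotype-filtered) neighbor count, and `k` = such neighbors
#' carrying the term. Results with `p < p_threshold` are returned sorted by
#' `p`, ties by term id.
#'
#' @param net A `"coexpression_network"`.
#' @param ann Annotation tibble (`gene_id`, `term_id`).
#' @param gene Focal gene id.
#' @param p_threshold Raw p-value cutoff, default 0.05. No multiplicity
#'   correction is applied by default; see `adjust`.
#' @param neighbors `"all"` (default) to count neighbors of any biotype, or
#'   `"coding"` to restrict the neighborhood to coding genes.
#' @param adjust Optional p.adjust method (e.g. `"BH"`) applied across the
#'   gene's terms before thresholding; `"none"` (default) uses raw p-values.
#' @return Tibble `gene_id`, `term_id`, `N`, `M`, `n`, `k`, `p`.
#' @export
annotate_gene <- function(net, ann, gene, p_threshold = 0.05,
                          neighbors = c("all", "coding"), adjust = "none") {
  stopifnot(inherits(net, "coexpression_network"))
  neighbors <- match.arg(neighbors)
  ann <- as_annotation_map(ann)
  if (!gene %in% net$nodes$gene_id) {
    stop_lncnet(paste0("gene not in network: ", gene),
                class = "lncnet_validation_error")
  }
  nb <- neighbors_of(net, gene)
  if (neighbors == "coding") {
    coding_ids <- net$nodes$gene_id[net$nodes$biotype == "coding"]
    nb <- intersect(nb, coding_ids)
  }
  ann_net <- filter(ann, .data$gene_id %in% net$nodes$gene_id)
  res <- enrich_neighbor_terms(nb, annotation_index(ann_net),
                               N = nrow(net$nodes))
  if (adjust != "none" && nrow(res) > 0) {
    res$p <- stats::p.adjust(res$p, method = adjust)
  }
  res |>
    filter(.data$p < p_threshold) |>
    arrange(.data$p, .data$term_id) |>
    mutate(gene_id = gene, .before = 1)
}

#' Annotate every lncRNA in the network by neighbor enrichment
#'
#' Applies [annotate_gene()] to each lncRNA node. By default only coding
#' neighbors are counted, reflecting annotation transfer from characterized
#' coding genes.
#'
#' @inheritParams annotate_gene
#' @param neighbors Neighborhood restriction, default `"coding"`.
#' @return Tibble of enriched terms across all lncRNAs (zero rows for
#'   lncRNAs with no enriched term), with attribute `"summary"`: a one-row
#'   tibble `n_lncRNA`, `n_annotated`.
#' @export
annotate_all_lncrnas <- function(net, ann, p_threshold = 0.05,
                                 neighbors = "coding", adjust = "none") {
  stopifnot(inherits(net, "coexpression_network"))
  lnc <- net$nodes$gene_id[net$nodes$biotype == "lncRNA"]
  out <- purrr::map_dfr(lnc, function(g) {
    annotate_gene(net, ann, g, p_threshold = p_threshold,
                  neighbors = neighbors, adjust = adjust)
  })
  if (nrow(out) == 0) {
    out <- tibble(gene_id = character(), term_id = character(),
                  N = integer(), M = integer(), n = integer(),
                  k = integer(), p = numeric())
  }
  attr(out, "summary") <- tibble(
    n_lncRNA = length(lnc),
    n_annotated = length(unique(out$gene_id))
  )
  out
}

#' Evaluate annotation-prediction performance against a random baseline
#'
#' Coding genes with at least `min_neighbors` annotated coding neighbors
#' form the test set. For each test gene its own annotations are hidden,
#' terms are predicted from its coding neighborhood, and sensitivity is the
#' fraction of its true terms recovered; the network value is the mean over
#' test genes. The baseline repeats the prediction with the gene's
#' neighborhood replaced by uniformly random same-size sets of annotated
#' coding genes, averaged over `n_random` draws.
#'
#' @param net A `"coexpression_network"`.
#' @param ann Annotation tibble (`gene_id`, `term_id`).
#' @param min_neighbors Minimum number of annotated coding neighbors for a
#'   gene to enter the test set (default 10).
#' @param n_random Random neighborhood draws per test gene (default 100).
#' @param p_threshold Enrichment p-value cutoff (default 0.05).
#' @param seed Integer seed for the random draws.
#' @return One-row tibble `sensitivity`, `random_sensitivity`,
#'   `n_test_genes`, `n_random`; per-gene values in attribute `"by_gene"`.
#' @export
evaluate_prediction <- function(net, ann, min_neighbors = 10, n_random = 100,
                                p_threshold = 0.05, seed = 1) {
  stopifnot(inherits(net, "coexpression_network"))
  ann <- as_annotation_map(ann)
  ann_net <- filter(ann, .data$gene_id %in% net$nodes$gene_id)
  coding_ids <- net$nodes$gene_id[net$nodes$biotype == "coding"]
  annotated <- intersect(coding_ids, unique(ann_net$gene_id))
  N <- nrow(net$nodes)
  test_genes <- purrr::keep(annotated, function(g) {
    nb <- intersect(neighbors_of(net, g), annotated)
    length(setdiff(nb, g)) >= min_neighbors
  })
  if (length(test_genes) == 0) {
    stop_lncnet("no test genes with enough annotated coding neighbors",
                class = "lncnet_validation_error")
  }
  withr::local_seed(derive_seed(seed, 7L))
  by_gene <- purrr::map_dfr(test_genes, function(g) {
    truth <- unique(ann_net$term_id[ann_net$gene_id == g])
    index <- annotation_index(filter(ann_net, .data$gene_id != g))
    nb <- setdiff(intersect(neighbors_of(net, g), coding_ids), g)
    predict_sens <- function(neighbor_ids) {
      pred <- enriched_term_ids(neighbor_ids, index, N, p_threshold)
      length(intersect(pred, truth)) / length(truth)
    }
    sens <- predict_sens(nb)
    pool <- setdiff(annotated, g)
    rand <- vapply(seq_len(n_random), function(r) {
      predict_sens(sample(pool, min(length(nb), length(pool))))
    }, numeric(1))
    tibble(gene_id = g, sensitivity = sens,
           random_sensitivity = mean(rand), n_neighbors = length(nb))
  })
  out <- tibble(
    sensitivity = mean(by_gene$sensitivity),
    random_sensitivity = mean(by_gene$random_sensitivity),
    n_test_genes = nrow(by_gene),
    n_random = n_random
  )
  attr(out, "by_gene") <- by_gene
  out
}
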