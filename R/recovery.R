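# Recovery metrics against synthetic ground truth.

#' Recall of planted within-module edges
#'
#' Fraction of all unordered within-module gene pairs (among genes present
#' as network nodes) that are connected by an edge.
#'
#' @param net A `"coexpression_network"`.
#' @param truth Ground-truth list with a `modules` tibble (`gene_id`,
#'   `module`), or an object carrying it.
#' @return A number in \[0, 1\].
#' @export
edge_recall <- function(net, truth) {
  stopifnot(inherits(net, "coexpression_network"))
  if (is.data.frame(truth) || !is.null(attr(truth, "truth"))) {
    truth <- attr(truth, "truth")
  }
  mods <- filter(truth$modules, .data$gene_id %in% net$nodes$gene_id)
  expected <- mods |>
    inner_join(mods, by = "module", suffix = c("_a", "_b"),
               relationship = "many-to-many") |>
    filter(.data$gene_id_a < .data$gene_id_b) |>
    select(gene_a = "gene_id_a", gene_b = "gene_id_b")
  if (nrow(expected) == 0) {
    stop_lncnet("no within-module pairs among network nodes",
                class = "lncnet_validation_error")
  }
  found <- semi_join(expected, net$edges, by = c("gene_a", "gene_b"))
  nrow(found) / nrow(expected)
}

#' Recovery of held-out lncRNA term sets
#'
#' Mean over lncRNAs (with non-empty truth) of the fraction of true terms
#' present among the predicted enriched terms.
#'
#' @param predicted Enrichment tibble from [annotate_all_lncrnas()].
#' @param truth Ground-truth list with `lnc_terms` (`gene_id`, `term_id`),
#'   or an object carrying it.
#' @return A number in \[0, 1\].
#' @export
annotation_recovery <- function(predicted, truth) {
  if (!is.null(attr(truth, "truth"))) truth <- attr(truth, "truth")
  lnc_terms <- truth$lnc_terms
  genes <- unique(lnc_terms$gene_id)
  sens <- vapply(genes, function(g) {
    true_terms <- lnc_terms$term_id[lnc_terms$gene_id == g]
    pred <- predicted$term_id[predicted$gene_id == g]
    length(intersect(pred, true_terms)) / length(true_terms)
  }, numeric(1))
  mean(sens)
}

#' Recovery of true ortholog pairs
#'
#' @param pairs Tibble `gene_a`, `gene_b` from [reciprocal_best_hits()].
#' @param truth Tibble of true pairs (`gene_a`, `gene_b`), or a ground-truth
#'   list/object carrying `pairs`.
#' @return Fraction of true pairs recovered.
#' @export
rbh_recovery <- function(pairs, truth) {
  if (!is.data.frame(truth)) {
    if (!is.null(attr(truth, "truth"))) truth <- attr(truth, "truth")
    truth <- truth$pairs
  }
  found <- semi_join(as_tibble(truth), as_tibble(pairs),
                     by = c("gene_a", "gene_b"))
  nrow(found) / nrow(truth)
}
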