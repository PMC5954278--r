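# Internal helpers shared across modules.

# Abort with a classed condition so callers/tests can match on class.
stop_lncnet <- function(msg, class = "lncnet_error", ...) {
  rlang::abort(msg, class = c(class, "lncnet_error"), ...)
}

# Percentage rounded for display, e.g. 70.93 for 17800940/25097918.
percent <- function(x, digits = 2) {
  round(100 * x, digits)
}

# Stable log-sum-exp for vectors of log-scale terms.
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# Numerically safe softplus, strictly increasing, maps R -> (0, Inf).
softplus <- function(x) {
  ifelse(x > 30, x, log1p(exp(x)))
}

# Column names of an expression tibble that hold sample values.
sample_columns <- function(expr) {
  setdiff(names(expr), c("gene_id", "biotype"))
}

# Extract the numeric gene x sample matrix from an expression tibble.
expr_matrix <- function(expr) {
  smp <- sample_columns(expr)
  m <- as.matrix(expr[, smp, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

# Validate the canonical expression tibble layout (gene_id, biotype, samples).
validate_expression <- function(expr, require_biotype = TRUE) {
  if (!is.data.frame(expr)) {
    stop_lncnet("`expr` must be a data frame", class = "lncnet_validation_error")
  }
  if (!"gene_id" %in% names(expr)) {
    stop_lncnet("expression table must have a `gene_id` column",
                class = "lncnet_validation_error")
  }
  if (anyDuplicated(expr$gene_id)) {
    dup <- unique(expr$gene_id[duplicated(expr$gene_id)])
    stop_lncnet(
      paste0("duplicated gene id(s): ", paste(head(dup, 5), collapse = ", ")),
      class = "lncnet_format_error"
    )
  }
  if (require_biotype) {
    if (!"biotype" %in% names(expr)) {
      stop_lncnet("expression table must have a `biotype` column",
                  class = "lncnet_validation_error")
    }
    bad <- !expr$biotype %in% c("coding", "lncRNA")
    if (any(is.na(expr$biotype)) || any(bad)) {
      stop_lncnet(
        paste0("biotype must be 'coding' or 'lncRNA' for every gene; offending id(s): ",
               paste(head(expr$gene_id[bad | is.na(expr$biotype)], 5), collapse = ", ")),
        class = "lncnet_validation_error"
      )
    }
  }
  smp <- sample_columns(expr)
  if (length(smp) == 0) {
    stop_lncnet("expression table has no sample columns",
                class = "lncnet_validation_error")
  }
  m <- expr_matrix(expr)
  if (anyNA(m)) {
    stop_lncnet("expression values must not be missing",
                class = "lncnet_validation_error")
  }
  if (any(m < 0)) {
    stop_lncnet("expression values must be nonnegative",
                class = "lncnet_validation_error")
  }
  invisible(expr)
}

# Deterministic child seed derived from a base seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 10007L * as.integer(offset)) %% 2147483629L
}
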