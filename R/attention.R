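make_attention_report <- function(datatype, feature_ids, mean_attention,
                                  per_sample = NULL) {
  ord <- order(-mean_attention, feature_ids)
  rank <- integer(length(ord))
  rank[ord] <- seq_along(ord)
  structure(data.frame(feature_id = feature_ids,
                       mean_attention = mean_attention,
                       rank = rank, stringsAsFactors = FALSE),
            datatype = datatype, per_sample = per_sample,
            class = c("attention_report", "data.frame"))
}

#' Per-gene attention values of a fitted network
#'
#' Evaluates each datatype's attention layer on every cohort sample and
#' averages the per-sample attention per feature, attaching ranks
#' (1 = highest mean attention; ties broken by feature-ID lexicographic
#' order).  The attention value of a gene is its learned multiplicative
#' gate in (0, 1): genes the model considers prognostic receive values
#' near 1, uninformative genes values near 0.
#'
#' @param fit A fitted `"multipen"` object (or a bare
#'   `"multipen_model"`).
#' @param data List of preprocessed matrices `mrna`, `mirna`, optionally
#'   `clinical`, matching the model's feature counts.
#' @param keep_per_sample Attach the full features x samples attention
#'   matrix as an attribute (`attr(report, "per_sample")`).
#' @return Named list of `"attention_report"` data.frames (one per
#'   datatype) with columns `feature_id`, `mean_attention`, `rank`.
#' @export
compute_gene_attention <- function(fit, data, keep_per_sample = FALSE) {
  model <- if (inherits(fit, "multipen")) fit$model else fit
  check_data_dims(model, data)
  layers <- list(mrna = data$mrna, mirna = data$mirna)
  if (!is.null(model$attention$clinical)) layers$clinical <- data$clinical
  out <- lapply(names(layers), function(layer) {
    X <- layers[[layer]]
    A <- attention_forward(model$attention[[layer]], X)$a
    ids <- rownames(X)
    if (is.null(ids)) ids <- sprintf("feature%04d", seq_len(nrow(X)))
    make_attention_report(layer, ids, rowMeans(A),
                          per_sample = if (keep_per_sample) A)
  })
  names(out) <- names(layers)
  out
}

#' Top-ranked prognostic features of an attention report
#'
#' @param report An `"attention_report"` (one element of
#'   [compute_gene_attention()]'s result).
#' @param top_k Number of rows to return; clamped (with a warning) to
#'   the number of features.  Reports conventionally show the top 50.
#' @return The `top_k` highest-attention rows, ordered by rank;
#'   deterministic under ties.
#' @export
rank_genes <- function(report, top_k = 50L) {
  stopifnot(inherits(report, "attention_report"), top_k >= 0)
  if (top_k > nrow(report)) {
    warning("top_k = ", top_k, " exceeds feature count ", nrow(report),
            "; clamped")
    top_k <- nrow(report)
  }
  out <- report[order(report$rank), , drop = FALSE]
  out <- out[seq_len(top_k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutation test for attention enrichment of a gene set
#'
#' Tests (one-sided) whether a designated gene set — e.g. the planted
#' prognostic genes of a synthetic cohort — has a higher mean attention
#' than the remaining genes, by permuting the set labels.
#'
#' @param report An `"attention_report"`.
#' @param gene_set Character vector of feature IDs forming the set.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Seed for the permutation draws.
#' @return List with `observed` (mean attention difference, set minus
#'   complement), `p_value` (one-sided, with the +1 correction) and
#'   `n_perm`.
#' @export
attention_permutation_test <- function(report, gene_set, n_perm = 10000L,
                                       seed = 1L) {
  stopifnot(inherits(report, "attention_report"))
  in_set <- report$feature_id %in% gene_set
  if (!any(in_set) || all(in_set)) {
    stop("gene set must be a non-empty proper subset of the report")
  }
  att <- report$mean_attention
  m <- sum(in_set)
  observed <- mean(att[in_set]) - mean(att[!in_set])
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(derive_seed(seed, 606L))
  perm <- replicate(n_perm, {
    idx <- sample.int(length(att), m)
    mean(att[idx]) - mean(att[-idx])
  })
  p <- (1 + sum(perm >= observed)) / (1 + n_perm)
  list(observed = observed, p_value = p, n_perm = n_perm)
}

#' Write attention reports as TSV, one file per datatype
#' @param reports List from [compute_gene_attention()].
#' @param dir Output directory (created if needed).
#' @return Written file paths, invisibly.
#' @export
write_attention_reports <- function(reports, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(reports), function(layer) {
    path <- file.path(dir, paste0("attention_", layer, ".tsv"))
    utils::write.table(as.data.frame(reports[[layer]]), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' Bar plot of the top-ranked features of an attention report
#' @param x An `"attention_report"`.
#' @param top_k How many features to show (default 20).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.attention_report <- function(x, top_k = 20L, ...) {
  top <- rank_genes(x, min(top_k, nrow(x)))
  graphics::barplot(rev(top$mean_attention), names.arg = rev(top$feature_id),
                    horiz = TRUE, las = 1, xlab = "mean attention",
                    main = paste("Top", nrow(top), attr(x, "datatype"),
                                 "features"), ...)
  invisible(x)
}
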