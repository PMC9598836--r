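#' Fit the full preprocessing pipeline on a training partition
#'
#' Combines the per-layer gene filters ([filter_genes()]), the log
#' transform constant, and the clinical encoder
#' ([fit_clinical_encoder()]) into a single fitted object.  Every
#' statistic is computed on the training partition only; applying the
#' fitted object to new data (via [predict.multipen_preprocessor()])
#' never consults the new data's statistics — the leakage-free contract
#' under which repeated cross-validation is run.
#'
#' @param mrna,mirna Raw-scale expression matrices (genes x training
#'   samples); `mirna` may be `NULL`.
#' @param clinical Clinical data.frame for the training samples, or
#'   `NULL` when the model is expression-only.
#' @param log_base Log base for normalization: `"log2"` (default),
#'   `"ln"`, `"log10"`.
#' @param standardize Additionally z-score every kept gene with its
#'   training-set mean and sd (computed on the log scale).  Off by
#'   default, which reproduces plain log normalization; recommended when
#'   the network is trained at learning rates well above 1e-4, since
#'   uncentered log expression otherwise saturates the attention gates
#'   and the tanh head (see the methods vignette).
#' @return An object of class `"multipen_preprocessor"` recording the
#'   kept gene IDs per layer, the log base, per-gene log-scale
#'   means/sds when `standardize` is on, and the clinical encoder.
#' @export
fit_preprocessor <- function(mrna, mirna = NULL, clinical = NULL,
                             log_base = c("log2", "ln", "log10"),
                             standardize = FALSE) {
  log_base <- match.arg(log_base)
  layer_fit <- function(m) {
    kept <- filter_genes(m)
    stats <- NULL
    if (standardize) {
      lg <- log_normalize(kept, log_base)
      sdv <- apply(lg, 1L, stats::sd)
      sdv[sdv == 0] <- 1
      stats <- list(mean = rowMeans(lg), sd = sdv)
    }
    list(ids = rownames(kept), stats = stats)
  }
  fm <- layer_fit(mrna)
  kept <- list(mrna = fm$ids)
  gene_stats <- list(mrna = fm$stats)
  if (!is.null(mirna)) {
    fmi <- layer_fit(mirna)
    kept$mirna <- fmi$ids
    gene_stats$mirna <- fmi$stats
  }
  encoder <- if (!is.null(clinical)) fit_clinical_encoder(clinical)
  structure(list(kept_genes = kept, log_base = log_base,
                 standardize = standardize, gene_stats = gene_stats,
                 encoder = encoder),
            class = "multipen_preprocessor")
}

#' Apply a fitted preprocessor to (new) data
#'
#' Restricts each expression layer to the training-derived gene list,
#' log-normalizes, and encodes the clinical table with the
#' training-fitted encoder.  Missing values that appear in a kept gene
#' (possible only on non-training data) are treated as raw zeros, with a
#' warning.
#'
#' @param object A fitted `"multipen_preprocessor"`.
#' @param mrna,mirna Raw expression matrices covering at least the kept
#'   genes; `mirna` optional if absent at fitting time.
#' @param clinical Clinical data.frame, required iff fitted with one.
#' @param ... Unused.
#' @return List with elements `mrna`, `mirna`, `clinical` (each a
#'   features x samples matrix, or `NULL`).
#' @export
predict.multipen_preprocessor <- function(object, mrna, mirna = NULL,
                                          clinical = NULL, ...) {
  take <- function(m, key, label) {
    ids <- object$kept_genes[[key]]
    miss <- setdiff(ids, rownames(m))
    if (length(miss)) {
      stop(label, " matrix lacks ", length(miss), " kept gene(s), e.g. ",
           miss[1L])
    }
    m <- m[ids, , drop = FALSE]
    if (anyNA(m)) {
      warning("missing values in kept ", label,
              " genes treated as raw zeros")
      m[is.na(m)] <- 0
    }
    lg <- log_normalize(m, object$log_base)
    st <- object$gene_stats[[key]]
    if (isTRUE(object$standardize) && !is.null(st)) {
      lg <- sweep(sweep(lg, 1L, st$mean), 1L, st$sd, "/")
    }
    lg
  }
  out <- list(mrna = take(mrna, "mrna", "mRNA"),
              mirna = NULL, clinical = NULL)
  if (!is.null(object$kept_genes$mirna)) {
    if (is.null(mirna)) stop("preprocessor was fitted with a miRNA layer")
    out$mirna <- take(mirna, "mirna", "miRNA")
  }
  if (!is.null(object$encoder)) {
    if (is.null(clinical)) stop("preprocessor was fitted with clinical data")
    out$clinical <- encode_clinical(clinical, object$encoder)
  }
  out
}

#' @export
print.multipen_preprocessor <- function(x, ...) {
  cat("Fitted preprocessing pipeline\n")
  for (layer in names(x$kept_genes)) {
    cat(sprintf("  %-6s: %d genes kept\n", layer, length(x$kept_genes[[layer]])))
  }
  cat("  log base:", x$log_base, "\n")
  if (!is.null(x$encoder)) {
    cat("  clinical variables:", paste(x$encoder$variables, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a fitted preprocessor to JSON
#' @param object A `"multipen_preprocessor"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_preprocessor <- function(object, path) {
  stopifnot(inherits(object, "multipen_preprocessor"))
  payload <- list(kept_genes = object$kept_genes, log_base = object$log_base,
                  standardize = isTRUE(object$standardize))
  if (isTRUE(object$standardize)) {
    payload$gene_stats <- lapply(object$gene_stats, function(st) {
      if (!is.null(st)) list(mean = unname(st$mean), sd = unname(st$sd))
    })
  }
  if (!is.null(object$encoder)) {
    payload$encoder <- list(
      variables = object$encoder$variables,
      vocab = object$encoder$vocab,
      num_stats = lapply(object$encoder$num_stats, as.list)
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized preprocessor back from JSON
#' @param path Path written by [write_preprocessor()].
#' @return A `"multipen_preprocessor"`.
#' @export
read_preprocessor <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  encoder <- NULL
  if (!is.null(payload$encoder)) {
    enc <- payload$encoder
    num_stats <- lapply(enc$num_stats, function(s) {
      c(mean = as.numeric(s$mean), sd = as.numeric(s$sd))
    })
    encoder <- structure(list(variables = enc$variables,
                              vocab = as.list(enc$vocab),
                              num_stats = num_stats),
                         class = "clinical_encoder")
  }
  gene_stats <- lapply(payload$kept_genes, function(x) NULL)
  if (isTRUE(payload$standardize)) {
    gene_stats <- lapply(payload$gene_stats, function(st) {
      if (!is.null(st)) list(mean = as.numeric(st$mean), sd = as.numeric(st$sd))
    })
    for (k in names(gene_stats)) {
      if (!is.null(gene_stats[[k]])) {
        names(gene_stats[[k]]$mean) <- payload$kept_genes[[k]]
        names(gene_stats[[k]]$sd) <- payload$kept_genes[[k]]
      }
    }
  }
  structure(list(kept_genes = lapply(payload$kept_genes, as.character),
                 log_base = payload$log_base,
                 standardize = isTRUE(payload$standardize),
                 gene_stats = gene_stats, encoder = encoder),
            class = "multipen_preprocessor")
}
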