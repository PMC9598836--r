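#' Read a clinical table
#'
#' A clinical table is delimited text with a header row and a `sample_id`
#' column; remaining columns are clinical variables.  Columns that parse
#' fully as numbers are treated as numeric variables, all others as
#' categorical.  Empty cells are missing.
#'
#' @param path Path to the file.
#' @param delimiter Field separator.
#' @return A data.frame with a `sample_id` character column first.
#' @export
read_clinical_table <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "",
                          check.names = FALSE, colClasses = "character")
  if (!"sample_id" %in% names(df)) stop("clinical table lacks a sample_id column")
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stop("duplicate sample ID(s): ", paste(dup, collapse = ", "))
  for (v in setdiff(names(df), "sample_id")) {
    num <- suppressWarnings(as.numeric(df[[v]]))
    if (!any(!is.na(df[[v]]) & is.na(num))) df[[v]] <- num
  }
  df
}

#' Write a clinical table
#' @param t Clinical data.frame (see [read_clinical_table()]).
#' @param path Output path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(t, path, delimiter = "\t") {
  utils::write.table(t, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read survival labels (sample_id, time, event)
#' @param path TSV with columns `sample_id`, `time`, `event`.
#' @param delimiter Field separator.
#' @return data.frame with character `sample_id`, numeric `time`,
#'   integer `event`.
#' @export
read_survival_labels <- function(path, delimiter = "\t") {
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "time", "event") %in% names(df)))
  if (any(df$time <= 0)) stop("survival times must be strictly positive")
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0/1")
  df$sample_id <- as.character(df$sample_id)
  df
}

#' Fit a one-hot / z-score encoder on training clinical data
#'
#' Records, per categorical variable, the category vocabulary in
#' first-seen order plus one reserved `"unknown"` slot (used at encoding
#' time for missing values and categories never seen in training), and
#' per numeric variable the training mean and standard deviation.  A
#' numeric variable with zero variance gets sd 1 (with a warning) so
#' z-scoring stays defined.
#'
#' @param t Training-partition clinical data.frame with a `sample_id`
#'   column (see [read_clinical_table()]).
#' @return An object of class `"clinical_encoder"`.
#' @export
fit_clinical_encoder <- function(t) {
  stopifnot(is.data.frame(t), "sample_id" %in% names(t))
  vars <- setdiff(names(t), "sample_id")
  vocab <- list()
  num_stats <- list()
  for (v in vars) {
    x <- t[[v]]
    if (is.numeric(x)) {
      mu <- mean(x, na.rm = TRUE)
      sdv <- stats::sd(x, na.rm = TRUE)
      if (is.na(mu)) mu <- 0
      if (is.na(sdv) || sdv == 0) {
        warning("numeric clinical variable '", v, "' has zero variance; sd set to 1")
        sdv <- 1
      }
      num_stats[[v]] <- c(mean = mu, sd = sdv)
    } else {
      seen <- unique(as.character(x))
      seen <- seen[!is.na(seen)]
      if (!length(seen)) {
        warning("categorical clinical variable '", v, "' is entirely missing")
      }
      vocab[[v]] <- c(seen, "unknown")
    }
  }
  structure(list(variables = vars, vocab = vocab, num_stats = num_stats),
            class = "clinical_encoder")
}

#' Encode a clinical table with a fitted encoder
#'
#' Produces the features-by-samples design block: one-hot blocks for each
#' categorical variable (missing or unseen labels routed to the
#' `"unknown"` slot) concatenated with z-scored numerics, in the variable
#' order fixed at fitting time.  Every categorical block of every sample
#' sums to exactly 1.
#'
#' @param t Clinical data.frame (train or validation samples).
#' @param encoder A fitted [fit_clinical_encoder()] object.
#' @return Numeric matrix (features x samples); feature names are
#'   `"var=level"` for one-hot slots and the bare variable name for
#'   numerics.
#' @export
encode_clinical <- function(t, encoder) {
  stopifnot(inherits(encoder, "clinical_encoder"))
  missing_vars <- setdiff(encoder$variables, names(t))
  if (length(missing_vars)) {
    stop("clinical variable(s) missing from table: ",
         paste(missing_vars, collapse = ", "))
  }
  n <- nrow(t)
  blocks <- list()
  for (v in encoder$variables) {
    x <- t[[v]]
    if (v %in% names(encoder$num_stats)) {
      st <- encoder$num_stats[[v]]
      z <- (as.numeric(x) - st[["mean"]]) / st[["sd"]]
      z[is.na(z)] <- 0
      blocks[[v]] <- matrix(z, nrow = 1L, dimnames = list(v, NULL))
    } else {
      voc <- encoder$vocab[[v]]
      lab <- as.character(x)
      idx <- match(lab, voc)
      idx[is.na(idx)] <- length(voc)  # unseen or missing -> unknown slot
      block <- matrix(0, nrow = length(voc), ncol = n,
                      dimnames = list(paste0(v, "=", voc), NULL))
      block[cbind(idx, seq_len(n))] <- 1
      blocks[[v]] <- block
    }
  }
  out <- do.call(rbind, blocks)
  colnames(out) <- t$sample_id
  out
}
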