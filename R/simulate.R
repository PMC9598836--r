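#' Specification of a synthetic multi-omics survival cohort
#'
#' Describes a cohort with known prognostic structure: log-normal
#' expression for two omics layers, a small planted set of prognostic
#' genes per layer (planted miRNAs negatively coupled to their target
#' planted mRNAs, mimicking miRNA-mediated repression), clinical
#' covariates with specified log-risk effects, and uncensored survival
#' times driven by the planted signal through a log-linear hazard.
#'
#' @param n_samples Cohort size (default 125, the modeled uncensored
#'   cohort size).
#' @param p_mrna,p_mirna Genes per layer (defaults 1000 / 200).
#' @param n_prognostic_mrna,n_prognostic_mirna Planted prognostic genes
#'   per layer (defaults 20 / 10).
#' @param beta Prognostic effect size: log-hazard units per standard
#'   deviation of the planted expression signal (default 1.5).
#' @param rho Target absolute correlation between a planted miRNA and
#'   its target mRNA, encoded with a negative sign (default 0.6).
#' @param zero_rate Zero-inflation probability per raw-scale entry
#'   (default 0.05).
#' @param missing_rate Probability of a missing marker per entry
#'   (default 0).
#' @param sd_noise Residual log2-scale expression noise sd (default 1).
#' @param clinical_effects Named numeric log-risk effects:
#'   `age` (per sd of age), `grade` (G3 vs G2), `idh` (IDH wild-type vs
#'   mutant).
#' @param weibull_shape Shape of the Weibull survival law; 1 (default)
#'   is the exponential case.
#' @param time_scale Baseline survival time scale in days
#'   (default 1000).
#' @param seed Integer seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_samples = 125L, p_mrna = 1000L, p_mirna = 200L,
                        n_prognostic_mrna = 20L, n_prognostic_mirna = 10L,
                        beta = 1.5, rho = 0.6, zero_rate = 0.05,
                        missing_rate = 0, sd_noise = 1,
                        clinical_effects = c(age = 0.3, grade = 0.5,
                                             idh = 0.7),
                        weibull_shape = 1, time_scale = 1000, seed = 1L) {
  stopifnot(n_samples >= 2, p_mrna >= 1, p_mirna >= 1,
            n_prognostic_mrna <= p_mrna, n_prognostic_mirna <= p_mirna,
            n_prognostic_mrna >= 0, n_prognostic_mirna >= 0,
            rho >= -1, rho <= 1, zero_rate >= 0, zero_rate < 1,
            missing_rate >= 0, missing_rate < 1, sd_noise > 0,
            weibull_shape > 0, time_scale > 0)
  structure(list(n_samples = as.integer(n_samples),
                 p_mrna = as.integer(p_mrna), p_mirna = as.integer(p_mirna),
                 n_prognostic_mrna = as.integer(n_prognostic_mrna),
                 n_prognostic_mirna = as.integer(n_prognostic_mirna),
                 beta = beta, rho = rho, zero_rate = zero_rate,
                 missing_rate = missing_rate, sd_noise = sd_noise,
                 clinical_effects = clinical_effects,
                 weibull_shape = weibull_shape, time_scale = time_scale,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

std <- function(x) (x - mean(x)) / stats::sd(x)

#' Generate a synthetic multi-omics cohort
#'
#' Log2-scale expression is Gaussian around per-gene baselines; planted
#' genes additionally load on a latent per-sample prognostic factor
#' (mRNAs positively, their target miRNAs negatively, with loadings set
#' so the planted miRNA-mRNA correlation is about `-rho`).  The latent
#' risk is `beta * (standardized mean planted mRNA signal - standardized
#' mean planted miRNA signal)` plus the clinical effects; survival times
#' follow a Weibull (default exponential) law with log-linear hazard
#' `exp(risk)`, all events observed.  Zero-inflation and missingness are
#' applied on the raw scale afterwards, so the risk is a deterministic
#' function of the planted signal.
#'
#' @param spec A [cohort_spec()].
#' @return List with `mrna`, `mirna` (raw-scale matrices, genes x
#'   samples), `clinical` (data.frame), `survival` (data.frame with
#'   `sample_id`, `time`, `event`) and `truth` (planted gene IDs,
#'   per-sample latent `risk`, spec echo).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(derive_seed(spec$seed, 707L))
  n <- spec$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  z <- stats::rnorm(n)                      # latent prognostic factor
  # loading giving |cor(planted gene, its partner)| ~ rho
  lambda <- if (spec$rho > 0) {
    spec$sd_noise * sqrt(spec$rho / (1 - spec$rho))
  } else 0

  gen_layer <- function(p, n_prog, prefix, sign) {
    ids <- sprintf("%s%04d", prefix, seq_len(p))
    mu <- stats::runif(p, 3, 9)
    L <- matrix(stats::rnorm(p * n, sd = spec$sd_noise), p, n) + mu
    prog <- ids[seq_len(n_prog)]
    if (n_prog > 0) {
      L[seq_len(n_prog), ] <- L[seq_len(n_prog), ] +
        sign * lambda * rep(z, each = n_prog)
    }
    dimnames(L) <- list(ids, sample_ids)
    list(L = L, prognostic = prog)
  }
  mr <- gen_layer(spec$p_mrna, spec$n_prognostic_mrna, "MRNA", +1)
  mi <- gen_layer(spec$p_mirna, spec$n_prognostic_mirna, "MIR", -1)

  signal <- numeric(n)
  if (spec$n_prognostic_mrna > 0) {
    signal <- signal + std(colMeans(mr$L[mr$prognostic, , drop = FALSE]))
  }
  if (spec$n_prognostic_mirna > 0) {
    signal <- signal - std(colMeans(mi$L[mi$prognostic, , drop = FALSE]))
  }

  age <- round(stats::rnorm(n, 45, 12))
  grade <- sample(c("G2", "G3"), n, replace = TRUE)
  idh <- sample(c("IDHmut-codel", "IDHmut-non-codel", "IDHwt"), n,
                replace = TRUE, prob = c(0.3, 0.4, 0.3))
  clinical <- data.frame(
    sample_id = sample_ids,
    sex = sample(c("male", "female"), n, replace = TRUE),
    race = sample(c("white", "black", "asian", "other"), n, replace = TRUE,
                  prob = c(0.7, 0.12, 0.12, 0.06)),
    ethnicity = sample(c("hispanic", "non-hispanic"), n, replace = TRUE,
                       prob = c(0.1, 0.9)),
    tumor_grade = grade,
    idh_codel_subtype = idh,
    codel_1p19q = ifelse(idh == "IDHmut-codel", "codel", "non-codel"),
    age_at_diagnosis = age,
    mutation_count = stats::rpois(n, 40),
    stringsAsFactors = FALSE
  )
  eff <- spec$clinical_effects
  risk_clin <- eff[["age"]] * std(age) +
    eff[["grade"]] * (grade == "G3") +
    eff[["idh"]] * (idh == "IDHwt")
  risk <- spec$beta * signal + risk_clin

  rate <- exp(risk) / spec$time_scale
  time <- (stats::rexp(n) / rate)^(1 / spec$weibull_shape)
  survival <- data.frame(sample_id = sample_ids, time = time,
                         event = 1L, stringsAsFactors = FALSE)

  corrupt <- function(L) {
    raw <- 2^L
    if (spec$zero_rate > 0) {
      raw[matrix(stats::runif(length(raw)) < spec$zero_rate,
                 nrow(raw), ncol(raw))] <- 0
    }
    if (spec$missing_rate > 0) {
      raw[matrix(stats::runif(length(raw)) < spec$missing_rate,
                 nrow(raw), ncol(raw))] <- NA_real_
    }
    raw
  }
  list(mrna = corrupt(mr$L), mirna = corrupt(mi$L), clinical = clinical,
       survival = survival,
       truth = list(prognostic_mrna = mr$prognostic,
                    prognostic_mirna = mi$prognostic,
                    risk = stats::setNames(risk, sample_ids),
                    spec = spec))
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `mrna.tsv`, `mirna.tsv` (the expression dialect read by
#' [read_expression_matrix()]), `clinical.tsv`, `survival.tsv` and
#' `truth.json`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$mrna, file.path(dir, "mrna.tsv"))
  write_expression_matrix(cohort$mirna, file.path(dir, "mirna.tsv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  utils::write.table(cohort$survival, file.path(dir, "survival.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(prognostic_mrna = truth$prognostic_mrna,
         prognostic_mirna = truth$prognostic_mirna,
         risk = as.list(truth$risk),
         spec = unclass(truth$spec)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir Cohort directory.
#' @return List with the same shape as [generate_cohort()]'s result
#'   (the `truth` spec echo is a plain list).
#' @export
read_cohort <- function(dir) {
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  list(mrna = read_expression_matrix(file.path(dir, "mrna.tsv")),
       mirna = read_expression_matrix(file.path(dir, "mirna.tsv")),
       clinical = read_clinical_table(file.path(dir, "clinical.tsv")),
       survival = read_survival_labels(file.path(dir, "survival.tsv")),
       truth = list(prognostic_mrna = as.character(truth$prognostic_mrna),
                    prognostic_mirna = as.character(truth$prognostic_mirna),
                    risk = unlist(truth$risk), spec = truth$spec))
}
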