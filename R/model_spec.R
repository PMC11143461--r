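#' @keywords internal
"_PACKAGE"

#' Covariates of the GEST risk score
#'
#' Canonical covariate names used throughout the package: demographics,
#' first-encounter labs, first-4-hour vital summaries, utilization and
#' diagnosis-history flags. `outpatient_cv_meds` is typically unavailable in
#' an external validation cohort and is scored through its imputation value.
#'
#' @format Character vector of covariate names.
#' @export
GEST_COVARIATES <- c(
  "age", "hemoglobin", "hematocrit", "blood_urea_nitrogen",
  "red_cell_distribution_width", "lymphocyte_count",
  "mean_corpuscular_volume", "mean_heart_rate", "min_systolic_bp",
  "supplemental_oxygen", "admissions_past_year", "dx_secondary_cancer",
  "dx_cognitive_disorder", "dx_lung_cancer", "dx_pancreatic_cancer",
  "ed_dx_syncope_or_cva", "outpatient_cv_meds"
)

# columns of a feature table that are bookkeeping, not model covariates
META_COLUMNS <- c("encounter_id", "patient_id", "arrival_date", "year", "sex")

#' Construct a declarative logistic risk model
#'
#' A `gest_model` carries, for every covariate, the value used to impute
#' missing measurements (raw units), the standardization mean and SD
#' (raw units), the log-odds coefficient (per SD for standardized
#' covariates, per unit otherwise), plus a global intercept.  Scoring a
#' record is then impute -> standardize -> linear predictor -> logistic.
#' Coefficients are data, not code: transcribing a published model or
#' fitting a synthetic stand-in are both just files (see
#' [read_gest_model()]).
#'
#' @param covariates Data frame with columns `name`, `imputation`, `mean`,
#'   `sd`, `coefficient` and logical `standardize`.  `sd` must be positive
#'   even for pass-through covariates (it is ignored when
#'   `standardize = FALSE`).
#' @param intercept Log-odds intercept (finite scalar).
#' @param name Label for the model (free text; used in printing and files).
#' @return Object of class `gest_model`.
#' @seealso [predict.gest_model()], [read_gest_model()], [refit()],
#'   [recalibrate_intercept()]
#' @examples
#' m <- gest_model(
#'   data.frame(name = "age", imputation = 77, mean = 77, sd = 8,
#'              coefficient = 0.5, standardize = TRUE),
#'   intercept = -2)
#' predict(m, data.frame(age = 85))
#' @export
gest_model <- function(covariates, intercept, name = "unnamed") {
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  required <- c("name", "imputation", "mean", "sd", "coefficient")
  missing_cols <- setdiff(required, names(covariates))
  if (length(missing_cols) > 0L) {
    stop("model specification lacks covariate column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(covariates$standardize)) covariates$standardize <- TRUE
  covariates$standardize <- as.logical(covariates$standardize)
  if (anyDuplicated(covariates$name)) {
    stop("duplicate covariate name(s): ",
         paste(unique(covariates$name[duplicated(covariates$name)]),
               collapse = ", "))
  }
  for (col in c("imputation", "mean", "sd", "coefficient")) {
    bad <- !is.finite(covariates[[col]])
    if (any(bad)) {
      stop("non-finite '", col, "' for covariate(s): ",
           paste(covariates$name[bad], collapse = ", "))
    }
  }
  bad_sd <- covariates$sd <= 0
  if (any(bad_sd)) {
    stop("standardization sd must be > 0; offending covariate(s): ",
         paste(covariates$name[bad_sd], collapse = ", "))
  }
  if (length(intercept) != 1L || !is.finite(intercept)) {
    stop("'intercept' must be a single finite number")
  }
  rownames(covariates) <- NULL
  structure(
    list(covariates = covariates[c("name", "imputation", "mean", "sd",
                                   "coefficient", "standardize")],
         intercept = as.numeric(intercept),
         name = as.character(name)),
    class = "gest_model")
}

#' Read a model specification from a JSON file
#'
#' The file holds `name`, `intercept` and a `covariates` array of
#' `{name, imputation, mean, sd, coefficient, standardize}` entries.
#' Numbers are written at full double precision so that a
#' write-then-read round trip reproduces the model bit for bit.
#'
#' @param path Path to a model-specification JSON file.
#' @return A [gest_model()].
#' @export
read_gest_model <- function(path) {
  if (!file.exists(path)) stop("model specification file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.null(raw$intercept)) {
    stop("model specification is missing required key 'intercept' (", path, ")")
  }
  if (is.null(raw$covariates)) {
    stop("model specification is missing required key 'covariates' (", path, ")")
  }
  gest_model(raw$covariates, intercept = raw$intercept,
             name = if (is.null(raw$name)) "unnamed" else raw$name)
}

#' Write a model specification to a JSON file
#'
#' @param model A [gest_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gest_model <- function(model, path) {
  stopifnot(inherits(model, "gest_model"))
  jsonlite::write_json(
    list(name = model$name, intercept = model$intercept,
         covariates = model$covariates),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' The synthetic placeholder GEST specification shipped with the package
#'
#' The published coefficient, imputation and standardization values of the
#' original derivation study are not reproduced here; this specification is
#' a synthetic stand-in with clinically plausible directions of effect
#' (older age, higher BUN/RDW/heart rate and lower hemoglobin/SBP/lymphocytes
#' increase risk) on the same covariate set.  Drop in a transcription of the
#' real values via [read_gest_model()] to score with the published model.
#'
#' @return A [gest_model()] named `"synthetic-placeholder"`.
#' @export
gest_model_synthetic <- function() {
  read_gest_model(system.file("extdata", "gest_model_synthetic.json",
                              package = "gestval", mustWork = TRUE))
}

#' @export
print.gest_model <- function(x, ...) {
  cat("GEST-style logistic risk model: ", x$name, "\n", sep = "")
  cat("  intercept (log-odds): ", format(x$intercept, digits = 4), "\n",
      sep = "")
  cat("  covariates:\n")
  print(x$covariates, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.gest_model <- function(object, ...) {
  c("(intercept)" = object$intercept,
    stats::setNames(object$covariates$coefficient, object$covariates$name))
}

#' Impute and standardize a feature table against a model specification
#'
#' Absent values are replaced by the per-covariate imputation value, then
#' standardized `z = (x - mean)/sd` for covariates with `standardize = TRUE`;
#' pass-through covariates (typically 0/1 flags) are coerced to numeric
#' unchanged.  A covariate column entirely missing from `features` is treated
#' as absent for every record (this is how unavailable outpatient medication
#' data is scored).  Feature columns that the model does not know are an
#' error, as are non-finite measured values.
#'
#' @param features Data frame, one row per record; covariate columns plus
#'   optional bookkeeping columns (`encounter_id`, `patient_id`,
#'   `arrival_date`, `year`, `sex`) which are ignored.
#' @param model A [gest_model()].
#' @return List with `z` (numeric matrix, one column per model covariate)
#'   and `imputed` (logical matrix marking which entries were imputed).
#' @export
impute_and_standardize <- function(features, model) {
  stopifnot(inherits(model, "gest_model"))
  features <- as.data.frame(features)
  spec <- model$covariates
  extra <- setdiff(setdiff(names(features), META_COLUMNS), spec$name)
  if (length(extra) > 0L) {
    stop("feature column(s) with no model specification entry: ",
         paste(extra, collapse = ", "))
  }
  n <- nrow(features)
  z <- matrix(NA_real_, n, nrow(spec), dimnames = list(NULL, spec$name))
  imputed <- matrix(FALSE, n, nrow(spec), dimnames = list(NULL, spec$name))
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]
    x <- if (nm %in% names(features)) features[[nm]] else rep(NA, n)
    if (is.logical(x)) x <- as.numeric(x)
    x <- as.numeric(x)
    miss <- is.na(x)
    if (any(!miss & !is.finite(x))) {
      stop("non-finite value(s) in covariate '", nm, "'")
    }
    x[miss] <- spec$imputation[i]
    imputed[, i] <- miss
    z[, i] <- if (spec$standardize[i]) (x - spec$mean[i]) / spec$sd[i] else x
  }
  list(z = z, imputed = imputed)
}

#' Score records with a declarative risk model
#'
#' @param object A [gest_model()].
#' @param newdata Feature data frame (see [impute_and_standardize()]).
#' @param type `"response"` for probabilities, `"link"` for the log-odds
#'   linear predictor.
#' @param ... Unused.
#' @return Numeric vector, one score per row of `newdata`.
#' @export
predict.gest_model <- function(object, newdata,
                               type = c("response", "link"), ...) {
  type <- match.arg(type)
  std <- impute_and_standardize(newdata, object)
  eta <- drop(object$intercept + std$z %*% object$covariates$coefficient)
  if (any(!is.finite(eta))) stop("non-finite linear predictor produced")
  if (type == "link") eta else stats::plogis(eta)
}

#' Simulate binary outcomes from a risk model
#'
#' Draws independent Bernoulli outcomes with the model-assigned
#' probabilities, the mechanism the synthetic cohort generator uses.
#'
#' @param object A [gest_model()].
#' @param nsim Number of replicate outcome vectors.
#' @param seed Optional integer seed.
#' @param newdata Feature data frame.
#' @param ... Unused.
#' @return Data frame of `nsim` 0/1 columns, `nrow(newdata)` rows.
#' @export
simulate.gest_model <- function(object, nsim = 1, seed = NULL,
                                newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, newdata, type = "response")
  out <- as.data.frame(
    replicate(nsim, stats::rbinom(length(p), 1L, p), simplify = FALSE),
    col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' Bernoulli log-likelihood of outcomes under a model
#'
#' @param model A [gest_model()].
#' @param features Feature data frame.
#' @param outcomes 0/1 or logical outcome vector.
#' @return Scalar log-likelihood.
#' @export
logLik_gest <- function(model, features, outcomes) {
  y <- as.integer(outcomes)
  eta <- predict(model, features, type = "link")
  sum(y * eta - log1p(exp(eta)))
}
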