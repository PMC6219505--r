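# Shared containers: feature matrices and right-censored outcomes.

#' Construct a feature matrix
#'
#' A samples-by-features numeric matrix with a per-feature kind tag. Kinds
#' follow the molecular platforms feeding the risk model: binary mutation
#' calls, signed arm-level copy-number fractions (dichotomized upstream),
#' focal copy-number events, protein abundances, log-scale expression, and
#' clinical covariates.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature names). No missing values.
#' @param kinds character vector, one of `"mutation"`, `"cna_arm"`,
#'   `"cna_focal"`, `"protein"`, `"expression"`, `"clinical"` per column.
#'   A single value is recycled.
#' @return a `feature_matrix`: the matrix with a `kinds` attribute.
#' @export
feature_matrix <- function(values, kinds = "mutation") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%03d", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("s%04d", seq_len(nrow(values)))
  }
  if (anyNA(values)) {
    stop("feature_matrix must not contain missing values; impute or drop upstream")
  }
  valid <- c("mutation", "cna_arm", "cna_focal", "protein", "expression", "clinical")
  kinds <- rep_len(as.character(kinds), ncol(values))
  if (!all(kinds %in% valid)) {
    stop("unknown feature kind(s): ", paste(setdiff(kinds, valid), collapse = ", "))
  }
  mut <- values[, kinds == "mutation", drop = FALSE]
  if (length(mut) && !all(mut %in% c(0, 1))) {
    stop("mutation features must be binary 0/1")
  }
  structure(values, kinds = stats::setNames(kinds, colnames(values)),
            class = c("feature_matrix", class(values)))
}

#' @export
print.feature_matrix <- function(x, ...) {
  k <- table(attr(x, "kinds"))
  cat(sprintf("<feature_matrix> %d samples x %d features (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s: %d", names(k), k), collapse = ", ")))
  invisible(x)
}

feature_kinds <- function(x) attr(x, "kinds")

#' Construct right-censored survival outcomes
#'
#' @param time follow-up in months, strictly positive.
#' @param event 1 if the endpoint (death for OS, progression or death for
#'   PFS) was observed, 0 if right-censored.
#' @param endpoint `"OS"` or `"PFS"`.
#' @param sample_ids optional identifiers aligned with `time`.
#' @return a `survival_outcome` data frame with columns `sample_id`, `time`,
#'   `event` and an `endpoint` attribute.
#' @export
survival_outcome <- function(time, event, endpoint = c("OS", "PFS"),
                             sample_ids = NULL) {
  endpoint <- match.arg(endpoint)
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) {
    stop("survival times must be finite and strictly positive")
  }
  if (!all(event %in% c(0, 1))) stop("event indicators must be 0 or 1")
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_along(time))
  structure(
    data.frame(sample_id = as.character(sample_ids), time = time,
               event = event, stringsAsFactors = FALSE),
    endpoint = endpoint,
    class = c("survival_outcome", "data.frame")
  )
}

as_surv <- function(outcomes) survival::Surv(outcomes$time, outcomes$event)

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive independent sub-seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
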