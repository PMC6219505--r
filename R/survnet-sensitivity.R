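# Derivative-based prognostic significance: how sensitive the predicted
# risk is to changes in each feature, evaluated at the observed data.

#' Per-sample gradients of risk with respect to the inputs
#'
#' Analytic backpropagation through the trained network with dropout off.
#' Gradients are taken with respect to the normalized inputs (the scale the
#' network sees); divide by the per-feature scale for raw units.
#'
#' @param model a trained `risk_model`.
#' @param features a [feature_matrix()] matching the model schema.
#' @return samples-by-features matrix of `d risk / d x`.
#' @keywords internal
input_gradients <- function(model, features) {
  X <- unclass_matrix(features)
  Z <- apply_normalization(X, model$normalization)
  L <- length(model$weights)
  fp <- forward_pass(model, Z, keep = TRUE)
  delta <- matrix(1, nrow(Z), 1L)
  for (l in rev(seq_len(L))) {
    delta <- delta %*% t(model$weights[[l]])
    if (l > 1L && model$activation == "relu") {
      delta <- delta * (fp$pres[[l - 1L]] > 0)
    }
  }
  if (!all(is.finite(delta))) stop("non-finite gradients")
  dimnames(delta) <- dimnames(X)
  delta
}

#' Derivative-based prognostic significance of each feature
#'
#' The score of a feature is the mean over samples of the derivative of the
#' predicted risk with respect to that feature, evaluated at the observed
#' data points with dropout off. Positive scores indicate that increasing
#' the feature increases predicted risk (a negative impact on survival).
#'
#' @param model a trained `risk_model`.
#' @param features the data at which to evaluate the derivatives (typically
#'   the model's training samples).
#' @param scale `"normalized"` (default; per normalized unit, the scale the
#'   network was trained on) or `"raw"` (per original feature unit).
#' @param aggregate within-model aggregator over samples, `"mean"` (default)
#'   or `"median"`.
#' @return a `prognostic_scores` data frame with columns `feature` and
#'   `score`, carrying the per-sample gradient matrix as an attribute.
#' @export
feature_sensitivity <- function(model, features,
                                scale = c("normalized", "raw"),
                                aggregate = c("mean", "median")) {
  scale <- match.arg(scale)
  aggregate <- match.arg(aggregate)
  G <- input_gradients(model, features)
  if (scale == "raw") G <- sweep(G, 2, model$normalization$scale, "/")
  agg <- if (aggregate == "mean") colMeans(G) else apply(G, 2, median)
  res <- data.frame(feature = colnames(G), score = unname(agg),
                    stringsAsFactors = FALSE)
  structure(res, gradients = G,
            class = c("prognostic_scores", "data.frame"))
}

#' Replicate-aggregated prognostic scores from cross-validation models
#'
#' Computes [feature_sensitivity()] for each model kept by
#' [monte_carlo_cv()] (each evaluated at its own training samples) and
#' aggregates replicate-level scores by the per-feature median.
#'
#' @param cv a `cv_result` from `monte_carlo_cv(..., keep_models = TRUE)`.
#' @param features the full feature matrix the CV was run on.
#' @param ... passed to [feature_sensitivity()].
#' @return a `prognostic_scores` data frame (`feature`, `score` = median
#'   across replicates) with the replicates-by-features score matrix as a
#'   `replicates` attribute.
#' @export
cv_prognostic_scores <- function(cv, features, ...) {
  if (is.null(cv$models)) {
    stop("run monte_carlo_cv() with keep_models = TRUE")
  }
  X <- unclass_matrix(features)
  reps <- t(vapply(seq_along(cv$models), function(i) {
    ids <- cv$splits[[i]]$train
    s <- feature_sensitivity(cv$models[[i]],
                             X[ids, , drop = FALSE], ...)
    stats::setNames(s$score, s$feature)
  }, numeric(ncol(X))))
  med <- apply(reps, 2, median)
  res <- data.frame(feature = colnames(X), score = unname(med),
                    stringsAsFactors = FALSE)
  structure(res, replicates = reps,
            class = c("prognostic_scores", "data.frame"))
}

#' Rank features by prognostic score
#'
#' Orders features by descending median prognostic score (largest risk
#' factors first), with a stable alphabetical tie-break on the feature name.
#'
#' @param scores a `prognostic_scores` object (from [feature_sensitivity()]
#'   or [cv_prognostic_scores()]).
#' @param top optional number of top risk factors to keep.
#' @return data frame with columns `rank`, `feature`, `score` and `sign`
#'   (`"risk"` for positive, `"protective"` for negative scores); replicate
#'   distributions, when present, are carried along for boxplots.
#' @export
rank_features <- function(scores, top = NULL) {
  o <- order(-scores$score, scores$feature)
  out <- data.frame(rank = seq_along(o),
                    feature = scores$feature[o],
                    score = scores$score[o],
                    sign = ifelse(scores$score[o] >= 0, "risk", "protective"),
                    stringsAsFactors = FALSE)
  reps <- attr(scores, "replicates")
  if (!is.null(reps)) attr(out, "replicates") <- reps[, out$feature, drop = FALSE]
  if (!is.null(top)) out <- out[seq_len(min(top, nrow(out))), , drop = FALSE]
  out
}
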