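# Cellular density from nuclei point patterns: KD-tree nearest-neighbor
# spacings, the 2-D Poisson NN-distance law, EM deconvolution of a
# two-component mixture, and the cohort-level median density split.

#' Construct a nuclei point pattern
#'
#' @param x,y coordinates in micrometers.
#' @param field_width,field_height field dimensions in micrometers; all
#'   points must lie inside `[0, width] x [0, height]`.
#' @param sample_id optional identifier.
#' @param magnification free-text note (e.g. `"20x"`).
#' @return a `point_pattern` list.
#' @export
point_pattern <- function(x, y, field_width, field_height,
                          sample_id = NA_character_, magnification = "20x") {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (field_width <= 0 || field_height <= 0) stop("degenerate field")
  if (length(x) && (any(x < 0 | x > field_width) ||
                    any(y < 0 | y > field_height))) {
    stop("all points must lie inside the field")
  }
  structure(list(x = x, y = y,
                 field_width = field_width, field_height = field_height,
                 sample_id = sample_id, magnification = magnification),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("<point_pattern> %d nuclei in %.0f x %.0f um field (%s)\n",
              length(x$x), x$field_width, x$field_height,
              ifelse(is.na(x$sample_id), "unnamed", x$sample_id)))
  invisible(x)
}

#' Nearest-neighbor distance of every nucleus
#'
#' Euclidean distance from each point to its closest other point, computed
#' with a KD-tree; the query is exact, so results equal exhaustive pairwise
#' search.
#'
#' @param pattern a [point_pattern()] with at least 2 points, or an optional
#'   margin-excluded subset of one (see `border_margin`).
#' @param border_margin optional width (micrometers) of a border strip whose
#'   points are dropped from the *returned* distances (their neighbors still
#'   count); 0 disables edge correction (the default, matching the model's
#'   neglect of edge effects).
#' @return numeric vector of strictly positive distances (micrometers),
#'   one per retained point.
#' @export
nearest_neighbor_distances <- function(pattern, border_margin = 0) {
  stopifnot(inherits(pattern, "point_pattern"))
  n <- length(pattern$x)
  if (n < 2) stop("need at least 2 points for nearest-neighbor distances")
  d <- .kdtree_nn(pattern$x, pattern$y)
  if (border_margin > 0) {
    inner <- pattern$x >= border_margin &
      pattern$x <= pattern$field_width - border_margin &
      pattern$y >= border_margin &
      pattern$y <= pattern$field_height - border_margin
    d <- d[inner]
  }
  if (any(d == 0)) {
    # coincident nuclei centroids: nudge to the smallest positive spacing
    d[d == 0] <- min(d[d > 0], .Machine$double.eps)
  }
  d
}

#' Nearest-neighbor distance density of a 2-D homogeneous Poisson process
#'
#' `f(r; lambda) = 2 * pi * lambda * r * exp(-pi * lambda * r^2)`: the law
#' of the distance from a point of the process to its nearest neighbor.
#' Its mean is `1 / (2 * sqrt(lambda))`.
#'
#' @param r distances (micrometers), `>= 0`.
#' @param lambda intensity in points per square micrometer, `> 0`.
#' @return density values.
#' @export
nn_pdf <- function(r, lambda) {
  if (any(r < 0)) stop("distances must be nonnegative")
  if (!(lambda > 0)) stop("lambda must be positive")
  2 * pi * lambda * r * exp(-pi * lambda * r^2)
}

# Maximum-likelihood intensity of a single Poisson NN sample.
pooled_lambda <- function(r) length(r) / (pi * sum(r^2))

#' EM deconvolution of a two-component Poisson nearest-neighbor mixture
#'
#' Fits `w * f(r; lambda1) + (1 - w) * f(r; lambda2)` where `f` is
#' [nn_pdf()]. The E-step computes posterior responsibilities; the M-step
#' has the closed form `lambda_k = sum(gamma_k) / (pi * sum(gamma_k * r^2))`
#' and `w = mean(gamma_1)`. Iteration stops when the relative log-likelihood
#' gain drops below `tol` or at `max_iter`. The larger-intensity component
#' is labelled tumor. If a component collapses (weight below 1e-6) the fit
#' is restarted from quantile-based initial values; a persistent collapse is
#' flagged and the pooled single-component estimate reported for both
#' intensities.
#'
#' @param distances numeric vector of nearest-neighbor distances
#'   (micrometers), at least 10.
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood tolerance (default 1e-6).
#' @param init_strategy `"median_split"` (default: method-of-moments on the
#'   two halves around the median) or `"quantile"` (spread initial
#'   intensities from the 0.25/0.75 distance quantiles).
#' @param seed reserved for stochastic initializations; the default
#'   strategies are deterministic.
#' @return a `density_fit`: `lambda_tumor`, `lambda_normal` (per square
#'   micrometer), their inverses (`spacing_scale_*`), `mixing_weight`
#'   (tumor-component fraction), `loglik_trace`, `converged`, `n_iter` and
#'   a `collapsed` flag.
#' @export
fit_poisson_mixture <- function(distances, max_iter = 500L, tol = 1e-6,
                                init_strategy = c("median_split", "quantile"),
                                seed = 1L) {
  init_strategy <- match.arg(init_strategy)
  r <- as.numeric(distances)
  if (length(r) < 10) stop("need at least 10 distances")
  if (any(r <= 0)) stop("distances must be strictly positive")

  init <- function(strategy) {
    if (strategy == "median_split") {
      medr <- median(r)
      lo <- r[r <= medr]; hi <- r[r > medr]
      c(pooled_lambda(lo), pooled_lambda(hi))
    } else {
      q <- quantile(r, c(0.25, 0.75))
      # invert the NN mean relation lambda = 1 / (2 r)^2 at the quantiles
      c(1 / (2 * q[[1]])^2, 1 / (2 * q[[2]])^2)
    }
  }

  run_em <- function(lam) {
    w <- 0.5
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    collapsed <- FALSE
    for (it in seq_len(max_iter)) {
      d1 <- w * nn_pdf(r, lam[1])
      d2 <- (1 - w) * nn_pdf(r, lam[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      g <- d1 / tot
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      s1 <- sum(g); s2 <- length(r) - s1
      if (min(s1, s2) / length(r) < 1e-6) { collapsed <- TRUE; break }
      lam <- c(s1 / (pi * sum(g * r^2)), s2 / (pi * sum((1 - g) * r^2)))
      w <- s1 / length(r)
      if (it > 1 && (ll - ll_old) < tol * abs(ll_old)) { converged <- TRUE; break }
      ll_old <- ll
    }
    list(lambda = lam, w = w, trace = trace, converged = converged,
         n_iter = length(trace), collapsed = collapsed)
  }

  fit <- run_em(init(init_strategy))
  if (fit$collapsed) {
    alt <- setdiff(c("median_split", "quantile"), init_strategy)
    fit <- run_em(init(alt))
  }
  if (fit$collapsed) {
    lam0 <- pooled_lambda(r)
    fit$lambda <- c(lam0, lam0)
    fit$w <- 1
  }
  tumor_first <- fit$lambda[1] >= fit$lambda[2]
  lam_t <- if (tumor_first) fit$lambda[1] else fit$lambda[2]
  lam_n <- if (tumor_first) fit$lambda[2] else fit$lambda[1]
  w_t <- if (tumor_first) fit$w else 1 - fit$w
  structure(list(lambda_tumor = lam_t, lambda_normal = lam_n,
                 spacing_scale_tumor = 1 / lam_t,
                 spacing_scale_normal = 1 / lam_n,
                 mixing_weight = w_t,
                 loglik_trace = fit$trace,
                 converged = fit$converged,
                 collapsed = fit$collapsed,
                 n_iter = fit$n_iter),
            class = "density_fit")
}

#' @export
print.density_fit <- function(x, ...) {
  cat(sprintf(paste0("<density_fit> lambda_tumor %.4g, lambda_normal %.4g ",
                     "per um^2; w %.3f (%d EM iterations%s)\n"),
              x$lambda_tumor, x$lambda_normal, x$mixing_weight, x$n_iter,
              if (x$collapsed) ", collapsed to pooled estimate" else ""))
  invisible(x)
}

#' Classify a cohort into less dense and more dense tumors
#'
#' Splits per-sample tumor intensities at the across-patient median:
#' `"more dense"` strictly above the median, `"less dense"` at or below it
#' (ties go to less dense).
#'
#' @param fits a list of `density_fit` objects, or a numeric vector of
#'   per-sample `lambda_tumor` values; at least 2 samples.
#' @return a `density_classification` data frame with columns `sample`,
#'   `lambda_tumor` and `label`, plus a `median` attribute.
#' @export
classify_cohort <- function(fits) {
  lam <- if (is.numeric(fits)) fits
         else vapply(fits, function(f) f$lambda_tumor, numeric(1))
  if (length(lam) < 2) stop("need at least 2 samples")
  if (is.null(names(lam))) names(lam) <- sprintf("s%04d", seq_along(lam))
  med <- median(lam)
  structure(
    data.frame(sample = names(lam), lambda_tumor = unname(lam),
               label = ifelse(lam > med, "more dense", "less dense"),
               stringsAsFactors = FALSE),
    median = med,
    class = c("density_classification", "data.frame")
  )
}
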