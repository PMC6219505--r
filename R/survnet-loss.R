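# Cox partial-likelihood loss (Breslow ties) and Harrell's c-index.

#' Negative Cox log partial likelihood of a risk vector
#'
#' Computes `-sum over events i of (r_i - log sum_{j: t_j >= t_i} exp(r_j))`
#' with the Breslow convention for tied event times (tied events share the
#' full risk set at their common time). This is the training loss of the
#' neural risk model and is invariant to adding a constant to all risks.
#'
#' @param risks per-sample real-valued risk scores, aligned with `outcomes`.
#' @param outcomes a [survival_outcome()] (or any data frame with `time` and
#'   `event` columns); at least one event is required.
#' @return nonnegative scalar loss.
#' @export
cox_partial_loss <- function(risks, outcomes) {
  cox_loss_grad(risks, outcomes$time, outcomes$event)$loss
}

# Loss and its gradient with respect to the risks, shared by the trainer.
# Gradient: dL/dr_k = -event_k + exp(r_k) * sum_{events i: t_k >= t_i} 1/S_i.
cox_loss_grad <- function(risks, time, event) {
  n <- length(risks)
  if (length(time) != n || length(event) != n) {
    stop("risks and outcomes are not aligned")
  }
  if (sum(event) < 1) stop("Cox partial likelihood undefined with zero events")
  o <- order(time)
  ro <- risks[o]; ev <- event[o]; tt <- time[o]
  m <- max(ro)                               # stabilize exp
  er <- exp(ro - m)
  S <- rev(cumsum(rev(er)))                  # sum_{j >= i} exp(r_j - m)
  S <- stats::ave(S, tt, FUN = max)          # ties share the full risk set
  loss <- -sum(ev * (ro - m - log(S)))
  h <- cumsum(ev / S)
  h <- stats::ave(h, tt, FUN = max)          # tied samples are in the risk
  g <- -ev + er * h                          # sets of events at their time
  grad <- numeric(n); grad[o] <- g
  list(loss = loss, grad = grad)
}

#' Harrell's concordance index
#'
#' Fraction of admissible pairs ranked concordantly by the risk scores. A
#' pair `(i, j)` is admissible when `i` is usable as the earlier event:
#' `event_i = 1` and either `t_i < t_j`, or `t_i = t_j` with `j` censored.
#' Pairs with equal times and both events are inadmissible. Concordance
#' requires the earlier-event sample to carry the higher risk; ties in risk
#' count one half.
#'
#' @param risks per-sample risk scores.
#' @param outcomes a [survival_outcome()] aligned with `risks`.
#' @return concordance in `[0, 1]`; 0.5 is random, 1 perfect.
#' @export
concordance_index <- function(risks, outcomes) {
  time <- outcomes$time; event <- outcomes$event
  n <- length(risks)
  if (length(time) != n) stop("risks and outcomes are not aligned")
  idx_e <- which(event == 1)
  if (length(idx_e) == 0) stop("no admissible pairs: no events")
  num <- 0; den <- 0
  for (i in idx_e) {
    admiss <- (time > time[i]) | (time == time[i] & event == 0)
    admiss[i] <- FALSE
    k <- sum(admiss)
    if (k == 0) next
    den <- den + k
    num <- num + sum(risks[i] > risks[admiss]) +
      0.5 * sum(risks[i] == risks[admiss])
  }
  if (den == 0) stop("no admissible pairs")
  num / den
}
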