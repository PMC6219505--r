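# Independent oracles used across the suite: naive re-implementations by
# direct summation/enumeration, kept deliberately simple and separate from
# the package's own code paths.

# Cox partial likelihood by direct double summation (Breslow ties).
brute_cox_loss <- function(risks, time, event) {
  -sum(vapply(which(event == 1), function(i) {
    risks[i] - log(sum(exp(risks[time >= time[i]])))
  }, numeric(1)))
}

# Harrell c-index by exhaustive pair enumeration.
brute_cindex <- function(risks, time, event) {
  num <- 0; den <- 0
  n <- length(risks)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || event[i] != 1) next
    if (time[i] < time[j] || (time[i] == time[j] && event[j] == 0)) {
      den <- den + 1
      num <- num + (risks[i] > risks[j]) + 0.5 * (risks[i] == risks[j])
    }
  }
  num / den
}

# Nearest-neighbor distances by O(n^2) exhaustive search.
brute_nn <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    d2 <- (x - x[i])^2 + (y - y[i])^2
    sqrt(min(d2[-i]))
  }, numeric(1))
}

# Two-sided Fisher p by full enumeration over margin-preserving tables
# (probability-mass method).
enum_fisher <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(a_range, r1, n - r1, c1)
  p_obs <- dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# GSEA enrichment score by explicit running sum over every ranked gene.
brute_es <- function(scores, members, exponent = 1) {
  genes <- names(scores)
  o <- order(-scores, genes)
  ranked <- genes[o]
  w <- abs(scores[o])^exponent
  hit <- ranked %in% members
  W <- sum(w[hit])
  inc <- ifelse(hit, if (W > 0) w / W else 1 / sum(hit),
                -1 / sum(!hit))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

# Small proportional-hazards cohort with one planted binary covariate.
sim_ph_cohort <- function(n, beta, freq, seed, censor_rate = 0.02) {
  withr::with_seed(seed, {
    x <- rbinom(n, 1, freq)
    t_ev <- rexp(n, rate = exp(beta * x) / 60)
    t_c <- rexp(n, censor_rate)
    list(x = x, time = pmin(t_ev, t_c), event = as.numeric(t_ev <= t_c))
  })
}
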