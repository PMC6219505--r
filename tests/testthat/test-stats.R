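# Statistics layer: dichotomization and filters, contingency tests with
# the expected-count rule, rank/correlation tests, Ki-67 calibration, and
# survival models against hand-computed oracles.

test_that("arm-CNA dichotomization applies the strict 0.10 boundary", {
  expect_equal(dichotomize_arm_cna(c(0.10, -0.10, 0, 0.099, -0.101)),
               c("gain", "loss", "neutral", "neutral", "loss"))
  m <- matrix(c(0.2, -0.3, 0.05, 0.10), 2, 2,
              dimnames = list(c("s1", "s2"), c("7p", "11p")))
  expect_equal(dichotomize_arm_cna(m),
               matrix(c("gain", "loss", "neutral", "gain"), 2, 2,
                      dimnames = dimnames(m)))
  expect_error(dichotomize_arm_cna(1.5), "\\[-1, 1\\]")
})

test_that("feature preparation applies calls, score filters and frequency", {
  n <- 169
  samples <- sprintf("s%04d", 1:n)
  mk_bin <- function(k) { v <- rep(0, n); v[seq_len(k)] <- 1; v }
  # 6 candidate mutation features; mutB fails MutSig q; mutC is below 5%
  mut <- cbind(mutA = mk_bin(30), mutB = mk_bin(25), mutC = mk_bin(7),
               mutD = mk_bin(12))
  rownames(mut) <- samples
  mutsig <- data.frame(gene = c("mutA", "mutB", "mutC", "mutD"),
                       q = c(0.01, 0.2, 0.01, 0.04))
  cna <- matrix(0, n, 2, dimnames = list(samples, c("7p", "15q")))
  cna[1:20, 1] <- 0.3          # 7p gain in 20/169 (~12%)
  cna[1:6, 2] <- -0.5          # 15q loss in 6/169 (~3.6%, below 5%)
  gistic <- data.frame(arm = c("7p", "15q"), p = c(0.01, 0.02))
  fm <- prepare_features(mut, arm_cna = cna, mutsig = mutsig,
                         gistic = gistic)
  expect_setequal(colnames(fm), c("mutA", "mutD", "7p_gain"))
  expect_true(all(c("mutB", "mutC", "15q_loss") %in% attr(fm, "dropped")))
  # a 4%-frequency feature in 169 samples is dropped by the 5% rule
  expect_true("mutC" %in% attr(fm, "dropped"))
})

test_that("variant tables count only amino-acid-changing calls", {
  variants <- data.frame(
    sample = c("s1", "s1", "s2", "s3"),
    gene = c("NOTCH1", "CIC", "NOTCH1", "NOTCH1"),
    protein_change = c("p.C478F", NA, "", "p.Q610*"),
    stringsAsFactors = FALSE)
  m <- oligoprog:::build_mutation_matrix(variants)
  expect_equal(m["s1", "NOTCH1"], 1)
  expect_equal(m["s1", "CIC"], 0)      # silent: no amino-acid change
  expect_equal(m["s2", "NOTCH1"], 0)
  expect_equal(m["s3", "NOTCH1"], 1)
})

test_that("expected counts and the test-selection rule follow the tables", {
  t1 <- contingency_table(13, 1, 22, 19)
  expect_equal(min(expected_counts(t1)), 14 * 20 / 55)
  expect_equal(select_test(t1), "chi_square")
  t2 <- contingency_table(9, 0, 26, 20)
  expect_equal(min(expected_counts(t2)), 9 * 20 / 55)
  expect_equal(select_test(t2), "fisher_exact")
  t3 <- contingency_table(5, 5, 5, 5)
  expect_true(all(expected_counts(t3) == 5))
  expect_equal(select_test(contingency_table(50, 50, 50, 50)), "chi_square")
})

test_that("the chi-square statistic matches the textbook formula", {
  res <- chi_square_test(contingency_table(13, 1, 22, 19))
  stat_hand <- 55 * (13 * 19 - 1 * 22)^2 / (14 * 41 * 35 * 20)
  expect_equal(res$statistic, stat_hand)
  expect_equal(res$p_two_sided, pchisq(stat_hand, 1, lower.tail = FALSE))
  expect_equal(chi_square_test(contingency_table(10, 10, 10, 10))$statistic, 0)
  expect_equal(chi_square_test(contingency_table(10, 10, 10, 10))$p_two_sided, 1)
  withr::with_seed(81, {
    for (rep in 1:5) {
      v <- rpois(4, 20) + 1
      m <- matrix(v, 2, 2)
      hand <- sum(m) * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
        prod(c(rowSums(m), colSums(m)))
      expect_equal(chi_square_test(m)$statistic, hand)
    }
  })
  expect_error(chi_square_test(contingency_table(0, 0, 5, 5)), "marginal")
})

test_that("chi-square is invariant to transposition and label swaps", {
  m <- matrix(c(13, 22, 1, 19), 2, 2)
  expect_equal(chi_square_test(m)$statistic, chi_square_test(t(m))$statistic)
  expect_equal(chi_square_test(m)$statistic,
               chi_square_test(m[2:1, 2:1])$statistic)
})

test_that("Fisher's exact test equals full hypergeometric enumeration", {
  tables <- list(c(9, 0, 26, 20), c(6, 0, 29, 20), c(5, 0, 30, 20),
                 c(3, 7, 12, 2), c(1, 9, 9, 1), c(8, 2, 3, 9))
  for (v in tables) {
    m <- matrix(v, 2, 2, byrow = TRUE)
    expect_equal(fisher_exact_test(m)$p_two_sided, enum_fisher(m),
                 tolerance = 1e-12)
  }
  withr::with_seed(83, {
    for (rep in 1:10) {
      m <- matrix(rpois(4, 6), 2, 2)
      if (sum(m) == 0) next
      expect_equal(fisher_exact_test(m)$p_two_sided, enum_fisher(m),
                   tolerance = 1e-12)
    }
  })
})

test_that("Wilcoxon rank-sum uses the exact law on small tie-free data", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_two_sided, 0.1)  # 2/20 orderings are as extreme
  expect_equal(res$notes, "exact")
  same <- wilcoxon_rank_sum(c(2, 2, 5), c(2, 2, 5))
  expect_equal(same$p_two_sided, 1)
  # tie-corrected normal approximation, frozen against the hand formula
  x <- c(1, 2, 2, 5, 7, 9); y <- c(3, 3, 4, 8, 10, 11, 12)
  big <- wilcoxon_rank_sum(x, y)
  expect_equal(big$p_two_sided, 0.1150803, tolerance = 1e-6)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "nonempty")
})

test_that("Pearson correlation and its t-transform p-value", {
  x <- 1:10
  expect_equal(pearson_with_p(x, 2 * x + 3)$estimate, 1)
  expect_equal(pearson_with_p(x, -x)$estimate, -1)
  withr::with_seed(85, {
    a <- rnorm(20); b <- 0.5 * a + rnorm(20)
    res <- pearson_with_p(a, b)
    r <- cor(a, b)
    tstat <- r * sqrt(18 / (1 - r^2))
    expect_equal(res$p_two_sided, 2 * pt(-abs(tstat), 18))
  })
  expect_error(pearson_with_p(rep(1, 5), 1:5), "variance")
})

test_that("Ki-67 calibration inverts the regression at the target index", {
  # noiseless line through (700, 15)
  pairs <- generate_ki67_pairs(slope = 15 / 700, intercept = 0,
                               noise_sd = 0, n = 60, seed = 91)
  fit <- calibrate_mki67(pairs)
  expect_equal(fit$threshold, 700, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  expect_equal(mki67_high(c(699, 700, 701), fit), c("low", "high", "high"))
  # analytic inversion: zero intercept, slope 0.02 -> 15 / 0.02 = 750
  p2 <- data.frame(expression = c(0, 500, 1000),
                   labeling_index = 0.02 * c(0, 500, 1000))
  expect_equal(calibrate_mki67(p2)$threshold, 750)
})

test_that("label noise moves the threshold less than 3 delta-method SEs", {
  noisy <- generate_ki67_pairs(slope = 15 / 700, intercept = 0,
                               noise_sd = 3, n = 150, seed = 92)
  fit <- calibrate_mki67(noisy)
  lmfit <- lm(labeling_index ~ expression, data = noisy)
  V <- vcov(lmfit); b <- coef(lmfit)
  grad <- c(-1 / b[2], -(15 - b[1]) / b[2]^2)
  se_thr <- sqrt(drop(t(grad) %*% V %*% grad))
  expect_lt(abs(fit$threshold - 700), 3 * se_thr)
})

test_that("Kaplan-Meier matches hand-computed product-limit tables", {
  oc <- survival_outcome(c(1, 2, 3, 4), c(1, 1, 1, 1))
  km <- km_estimate(oc)
  expect_equal(km$curves$all$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median_survival[["all"]], 2)
  # all censored: flat curve, median undefined
  km2 <- km_estimate(survival_outcome(c(2, 4, 6), c(0, 0, 0)))
  expect_true(all(km2$curves$all$surv == 1))
  expect_true(is.na(km2$median_survival[["all"]]))
  # mixed fixture: S = 0.8, 0.5333, 0 at the event times 1, 3, 5
  km3 <- km_estimate(survival_outcome(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1)))
  cv <- km3$curves$all
  expect_equal(cv$surv[cv$n_event > 0], c(0.8, 0.8 * 2 / 3, 0))
  expect_equal(km3$median_survival[["all"]], 5)
})

test_that("KM without censoring equals the empirical survival function", {
  withr::with_seed(95, t_ev <- round(rexp(30, 1 / 40), 1) + 0.1)
  km <- km_estimate(survival_outcome(t_ev, rep(1, 30)))
  cv <- km$curves$all
  emp <- vapply(cv$time, function(tt) mean(t_ev > tt), numeric(1))
  expect_equal(cv$surv, emp)
})

test_that("log-rank matches the hand-tabulated observed-minus-expected", {
  oc <- survival_outcome(c(1, 3, 2, 4), c(1, 1, 1, 0))
  res <- logrank_test(oc, c("A", "A", "B", "B"))
  expect_equal(res$statistic, 0.6153846, tolerance = 1e-6)
  expect_equal(res$p_two_sided, pchisq(0.6153846, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  # identical groups: statistic 0, p 1
  oc2 <- survival_outcome(rep(c(1, 2, 3), 2), rep(c(1, 0, 1), 2))
  res2 <- logrank_test(oc2, rep(c("A", "B"), each = 3))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_two_sided, 1)
  # complete separation at n = 10 per arm
  oc3 <- survival_outcome(c(1:10, 21:30), rep(1, 20))
  expect_lt(logrank_test(oc3, rep(c("early", "late"), each = 10))$p_two_sided,
            0.01)
})

test_that("Cox fits solve the partial-likelihood score equation", {
  # 4 samples, binary covariate, all events: score equation solved
  # independently by uniroot on the hand-written partial likelihood
  x <- c(1, 0, 1, 0)
  oc <- survival_outcome(c(1, 2, 3, 4), rep(1, 4))
  score <- function(b) {
    (1 - 2 * exp(b) / (2 * exp(b) + 2)) +
      (0 - exp(b) / (exp(b) + 2)) +
      (1 - exp(b) / (exp(b) + 1))
  }
  b_oracle <- uniroot(score, c(-5, 5), tol = 1e-10)$root
  fit <- cox_fit(data.frame(x = x), oc, "x")
  expect_equal(log(fit$hr), b_oracle, tolerance = 1e-6)
})

test_that("a planted hazard ratio is covered at the nominal rate", {
  covered <- vapply(1:100, function(s) {
    d <- sim_ph_cohort(500, log(2), 0.4, seed = 2000 + s)
    fit <- cox_fit(data.frame(x = d$x),
                   survival_outcome(d$time, d$event), "x")
    fit$ci_low <= 2 && 2 <= fit$ci_high
  }, logical(1))
  expect_gt(mean(covered), 0.89)
  expect_lt(mean(covered), 0.995)
})

test_that("null covariates give hazard ratios near one", {
  ok <- vapply(1:20, function(s) {
    d <- sim_ph_cohort(150, 0, 0.3, seed = 3000 + s)
    fit <- cox_fit(data.frame(x = d$x),
                   survival_outcome(d$time, d$event), "x")
    se <- abs(log(fit$hr) - log(fit$ci_low)) / 1.96
    abs(log(fit$hr)) < 2 * se
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("Cox unit scaling reports HRs per stated unit", {
  withr::with_seed(97, {
    age <- runif(200, 20, 80)
    t_ev <- rexp(200, exp(0.05 * age) / 5000)
    oc <- survival_outcome(pmax(t_ev, 0.01), rep(1, 200))
  })
  per1 <- cox_fit(data.frame(age = age), oc, "age")
  per10 <- cox_fit(data.frame(age = age), oc, "age",
                   units = c(age = 10))
  expect_equal(log(per10$hr), 10 * log(per1$hr), tolerance = 1e-6)
  expect_equal(per10$unit, "per 10 units")
})

test_that("Cox score test agrees with the log-rank direction at beta = 0", {
  d <- sim_ph_cohort(120, log(2.5), 0.5, seed = 98)
  oc <- survival_outcome(d$time, d$event)
  lr <- logrank_test(oc, d$x)
  sc <- summary(attr(cox_fit(data.frame(x = d$x), oc, "x"),
                     "coxph"))$sctest[["test"]]
  expect_equal(sc, lr$statistic, tolerance = 1e-6)
})

test_that("the association screen reproduces per-feature tables and rules", {
  # a feature identical to the label attains the enumeration minimum p
  lab <- rep(c(1, 0), c(8, 22))
  X <- cbind(exact = lab,
             null = rep(c(1, 0), 15))
  rownames(X) <- sprintf("s%02d", 1:30)
  screen <- association_screen(X, lab)
  expect_equal(screen$feature[1], "exact")
  m <- matrix(c(8, 0, 0, 22), 2, 2, byrow = TRUE)
  a_range <- 0:8
  p_min <- min(vapply(a_range, function(a) {
    enum_fisher(matrix(c(a, 8 - a, 8 - a, 14 + a), 2, 2, byrow = TRUE))
  }, numeric(1)))
  expect_equal(screen$p[screen$feature == "exact"], p_min)
})

test_that("a label-permuted screen yields near-uniform p-values", {
  # n = 400 keeps every table on the chi-square branch and limits the
  # discreteness of 2x2 p-values, which the uniformity premise assumes away
  withr::with_seed(99, {
    n <- 400
    X <- vapply(runif(200, 0.25, 0.6), function(f) rbinom(n, 1, f),
                numeric(n))
    colnames(X) <- sprintf("f%03d", 1:200)
    rownames(X) <- sprintf("s%03d", 1:n)
    lab <- sample(rep(c(1, 0), each = n / 2))
  })
  screen <- association_screen(X, lab)
  ks <- suppressWarnings(ks.test(screen$p, "punif"))
  expect_gt(ks$p.value, 0.05)
})
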