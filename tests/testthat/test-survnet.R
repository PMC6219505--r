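# Neural Cox risk model: loss closed forms, c-index oracles, training
# sanity, the linear-Cox equivalence, and derivative-based sensitivities.

make_outcomes <- function(time, event) survival_outcome(time, event)

test_that("constant risks give the log risk-set-size closed form", {
  oc <- make_outcomes(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0))
  # risk-set sizes at the event times 1, 3, 4 are 5, 3, 2
  expect_equal(cox_partial_loss(rep(0.3, 5), oc), log(5) + log(3) + log(2))
})

test_that("two-sample loss matches the hand expansion", {
  oc <- make_outcomes(c(1, 2), c(1, 0))
  a <- 0.7; b <- -1.2
  expect_equal(cox_partial_loss(c(a, b), oc), log(exp(a) + exp(b)) - a)
})

test_that("loss equals brute-force evaluation and is translation invariant", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      n <- 8
      time <- sample(c(1, 2, 2, 3, 5, 7, 7, 9))  # includes ties
      event <- rbinom(n, 1, 0.7); event[1] <- 1
      risks <- rnorm(n)
      oc <- make_outcomes(time, event)
      expect_equal(cox_partial_loss(risks, oc),
                   brute_cox_loss(risks, time, event))
      expect_equal(cox_partial_loss(risks + 5.3, oc),
                   cox_partial_loss(risks, oc))
    }
  })
})

test_that("the loss gradient matches central finite differences", {
  withr::with_seed(23, {
    time <- c(2, 1, 4, 3, 3, 6); event <- c(1, 1, 0, 1, 1, 0)
    risks <- rnorm(6)
    g <- oligoprog:::cox_loss_grad(risks, time, event)$grad
    h <- 1e-6
    g_num <- vapply(1:6, function(k) {
      rp <- risks; rp[k] <- rp[k] + h
      rm_ <- risks; rm_[k] <- rm_[k] - h
      (brute_cox_loss(rp, time, event) - brute_cox_loss(rm_, time, event)) /
        (2 * h)
    }, numeric(1))
    expect_equal(g, g_num, tolerance = 1e-5)
  })
})

test_that("zero events make the loss undefined", {
  oc <- make_outcomes(c(1, 2), c(0, 0))
  expect_error(cox_partial_loss(c(0, 0), oc), "zero events")
})

test_that("c-index hits its closed-form extremes", {
  oc <- make_outcomes(c(3, 1, 4, 2), c(1, 1, 1, 1))
  expect_equal(concordance_index(-c(3, 1, 4, 2), oc), 1)
  expect_equal(concordance_index(rep(0, 4), oc), 0.5)
})

test_that("c-index equals exhaustive pair enumeration with mixed censoring", {
  withr::with_seed(29, {
    for (rep in 1:10) {
      time <- sample(c(1, 2, 2, 4, 5, 5))
      event <- rbinom(6, 1, 0.6); event[which.min(time)] <- 1
      risks <- rnorm(6)
      oc <- make_outcomes(time, event)
      expect_equal(concordance_index(risks, oc),
                   brute_cindex(risks, time, event))
    }
  })
})

test_that("c-index is antisymmetric when risks are tie-free", {
  withr::with_seed(31, {
    time <- rexp(20, 1 / 50); event <- rbinom(20, 1, 0.6); event[1] <- 1
    risks <- rnorm(20)
    oc <- make_outcomes(time, event)
    expect_equal(concordance_index(risks, oc) +
                   concordance_index(-risks, oc), 1)
  })
})

train_fixture <- function(n = 120, p = 8, seed = 301,
                          betas = c(1.5, -1, rep(0, 6))) {
  cfg <- simulation_config(n_samples = n, n_features = p,
                           alteration_freqs = seq(0.2, 0.5, length.out = p),
                           planted_effects = betas,
                           censoring_rate_target = 0.3, seed = seed)
  generate_cohort(cfg)
}

test_that("training is deterministic given the seed", {
  co <- train_fixture()
  cfg <- training_config(epochs = 5, seed = 99)
  m1 <- train_risk_model(co$features, co$outcomes, cfg)
  m2 <- train_risk_model(co$features, co$outcomes, cfg)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_risk_model(co$features, co$outcomes,
                         training_config(epochs = 5, seed = 100))
  expect_false(identical(m1$weights, m3$weights))
})

test_that("training reduces the loss on a well-conditioned cohort", {
  co <- train_fixture(n = 300, p = 10,
                      betas = c(1.5, -1, 1, rep(0, 7)), seed = 311)
  decreased <- vapply(1:10, function(s) {
    m <- train_risk_model(co$features, co$outcomes,
                          training_config(dropout_rate = 0, seed = s))
    tail(m$loss_trace, 1) < m$loss_trace[1]
  }, logical(1))
  expect_gte(mean(decreased), 0.9)
})

test_that("a linear model reproduces classical Cox coefficients", {
  co <- train_fixture(n = 300, p = 10,
                      betas = c(0.9, -0.7, 0.5, rep(0, 7)), seed = 321)
  m <- train_risk_model(co$features, co$outcomes,
                        training_config(n_layers = 0, epochs = 3000,
                                        learning_rate = 1e-2,
                                        dropout_rate = 0,
                                        activation = "identity", seed = 5))
  w <- drop(m$weights[[1]])
  Z <- scale(unclass(co$features))
  cf <- coef(survival::coxph(
    survival::Surv(co$outcomes$time, co$outcomes$event) ~ Z,
    ties = "breslow"))
  cosine <- sum(w * cf) / sqrt(sum(w^2) * sum(cf^2))
  expect_gt(cosine, 0.95)
  # sensitivities of the linear model are exactly its weights
  s <- feature_sensitivity(m, co$features)
  expect_equal(unname(s$score), unname(w), tolerance = 1e-12)
})

test_that("predicted risks are reproducible and schema-checked", {
  co <- train_fixture()
  m <- train_risk_model(co$features, co$outcomes,
                        training_config(epochs = 5, seed = 1))
  r <- predict_risk(m, co$features)
  # duplicated sample gets an identical risk
  X2 <- unclass(co$features)[c(1, 1, 2), ]
  rownames(X2) <- c("a", "b", "c")
  r2 <- predict_risk(m, X2)
  expect_equal(r2[1], r2[2], ignore_attr = TRUE)
  # schema mismatch rejected
  bad <- unclass(co$features)[, c(2:ncol(co$features), 1)]
  expect_error(predict_risk(m, bad), "schema")
})

test_that("risks track the true linear predictor on a strong cohort", {
  co <- train_fixture(n = 300, p = 10,
                      betas = c(2, -1.5, 1.5, rep(0, 7)), seed = 331)
  m <- train_risk_model(co$features, co$outcomes,
                        training_config(seed = 2))
  r <- predict_risk(m, co$features)
  expect_gt(cor(r, co$truth$eta, method = "spearman"), 0.5)
})

test_that("analytic input gradients match central differences", {
  co <- train_fixture(n = 80, p = 6, betas = c(1, rep(0, 5)), seed = 341)
  m <- train_risk_model(co$features, co$outcomes,
                        training_config(epochs = 10, seed = 3))
  G <- oligoprog:::input_gradients(m, co$features)
  Z <- oligoprog:::apply_normalization(unclass(co$features),
                                       m$normalization)
  h <- 1e-5
  withr::with_seed(7, idx <- sample(nrow(Z), 10))
  for (i in idx) {
    for (j in seq_len(ncol(Z))) {
      zp <- Z[i, , drop = FALSE]; zp[j] <- zp[j] + h
      zm <- Z[i, , drop = FALSE]; zm[j] <- zm[j] - h
      fd <- (oligoprog:::forward_pass(m, zp)$risks -
               oligoprog:::forward_pass(m, zm)$risks) / (2 * h)
      expect_equal(G[i, j], fd, tolerance = 1e-4, ignore_attr = TRUE)
    }
  }
})

test_that("null-feature sensitivities concentrate near zero", {
  co <- train_fixture(n = 300, p = 20,
                      betas = c(rep(2, 3), rep(0, 17)), seed = 351)
  cv <- monte_carlo_cv(co$features, co$outcomes,
                       training_config(seed = 1), n_splits = 10,
                       seed = 11, keep_models = TRUE)
  scores <- cv_prognostic_scores(cv, co$features)
  planted <- abs(scores$score[1:3])
  nulls <- abs(scores$score[4:20])
  expect_lt(median(nulls), quantile(planted, 0.05) + 1e-12)
})

test_that("feature ranking is stable, order-invariant and tie-broken by name", {
  s <- structure(data.frame(feature = c("b", "a", "c"),
                            score = c(1, 2, 1),
                            stringsAsFactors = FALSE),
                 class = c("prognostic_scores", "data.frame"))
  rk <- rank_features(s)
  expect_equal(rk$feature, c("a", "b", "c"))  # ties b/c alphabetical
  expect_equal(rk$sign, c("risk", "risk", "risk"))
  s_perm <- s[c(3, 1, 2), ]
  expect_equal(rank_features(s_perm)$feature, rk$feature)
})

test_that("the strongest planted feature ranks near the top across replicates", {
  co <- train_fixture(n = 300, p = 50,
                      betas = c(2.5, rep(0, 49)),
                      seed = 361)
  cv <- monte_carlo_cv(co$features, co$outcomes,
                       training_config(seed = 1), n_splits = 10,
                       seed = 13, keep_models = TRUE)
  scores <- cv_prognostic_scores(cv, co$features)
  reps <- attr(scores, "replicates")
  in_top3 <- apply(reps, 1, function(r) {
    "alt001" %in% names(sort(r, decreasing = TRUE))[1:3]
  })
  expect_gte(mean(in_top3), 0.8)
})

test_that("Monte-Carlo CV records the requested splits and is seeded", {
  co <- train_fixture(n = 100, p = 5, betas = c(1.5, rep(0, 4)), seed = 371)
  cfg <- training_config(epochs = 5, seed = 1)
  cv <- monte_carlo_cv(co$features, co$outcomes, cfg, n_splits = 20,
                       seed = 3)
  expect_length(cv$cindex, 20)
  expect_true(all(cv$cindex >= 0 & cv$cindex <= 1))
  cv2 <- monte_carlo_cv(co$features, co$outcomes, cfg, n_splits = 20,
                        seed = 3)
  expect_identical(cv$cindex, cv2$cindex)
})

test_that("label-permuted outcomes give chance-level concordance", {
  co <- train_fixture(n = 300, p = 10,
                      betas = c(2, -1.5, 1, rep(0, 7)), seed = 381)
  oc <- co$outcomes
  perm <- withr::with_seed(5, sample(nrow(oc)))
  oc_perm <- survival_outcome(oc$time[perm], oc$event[perm],
                              sample_ids = oc$sample_id)
  cv <- monte_carlo_cv(co$features, oc_perm, training_config(seed = 1),
                       n_splits = 10, seed = 7)
  expect_lt(abs(cv$median - 0.5), 0.08)
})
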