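# ROC/AUC machinery, logistic baselines and the neural network.

test_that("rank-statistic AUC matches the exhaustive pairwise oracle", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(10:200, 1)
    scores <- sample(round(runif(n), 2))   # rounded -> plenty of ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc, auc_bruteforce(scores, labels))
  }
})

test_that("ROC handles the degenerate ranking cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2),
                       c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
})

test_that("the ROC curve is monotone from (0,0) to (1,1) and integrates to the AUC", {
  set.seed(8)
  scores <- runif(50)
  labels <- runif(50) < 0.5
  r <- roc_auc(scores, labels)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
  trapz <- sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
  expect_equal(trapz, r$auc, tolerance = 1e-12)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  scores <- rnorm(100)
  labels <- runif(100) < 0.3
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(scores), labels)$auc, a0)
  expect_equal(roc_auc(5 * scores - 2, labels)$auc, a0)
  expect_equal(roc_auc(plogis(scores), labels)$auc, a0)
})

test_that("paired AUC comparison behaves like a chi-square test", {
  set.seed(10)
  n <- 2000
  labels <- runif(n) < 0.3
  informative <- rnorm(n, mean = ifelse(labels, 1, 0))
  null_scores <- rnorm(n)

  self <- compare_auc(informative, informative, labels)
  expect_equal(self$statistic, 0)
  expect_equal(self$p.value, 1)

  cmp <- compare_auc(informative, null_scores, labels)
  expect_lt(cmp$p.value, 0.01)

  # invariant to monotone transforms of either score vector
  cmp2 <- compare_auc(exp(informative), null_scores, labels)
  expect_equal(cmp2$statistic, cmp$statistic, tolerance = 1e-9)

  expect_error(compare_auc(informative[-1], null_scores, labels), "paired")
})

test_that("the DeLong machinery agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(11)
  n <- 300
  labels <- runif(n) < 0.4
  s1 <- rnorm(n, ifelse(labels, 0.8, 0))
  s2 <- rnorm(n, ifelse(labels, 0.3, 0))
  ours <- compare_auc(s1, s2, labels)
  ref <- pROC::roc.test(
    pROC::roc(labels, s1, quiet = TRUE, direction = "<"),
    pROC::roc(labels, s2, quiet = TRUE, direction = "<"),
    method = "delong", paired = TRUE)
  expect_equal(ours$auc_a, as.numeric(pROC::auc(pROC::roc(labels, s1,
    quiet = TRUE, direction = "<"))))
  # our statistic is the squared z of the two-sided DeLong test
  expect_equal(ours$statistic, unname(ref$statistic)^2, tolerance = 1e-9)
  expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
})

test_that("single-feature logistic recovers degenerate and generative cases", {
  set.seed(12)
  labels <- rep(c(TRUE, FALSE), 50)
  flat <- fit_single_feature_logistic(rep(3, 100), labels)
  expect_equal(flat$roc$auc, 0.5)

  x <- c(rnorm(50, 5), rnorm(50, -5))
  expect_warning(
    sep <- fit_single_feature_logistic(x, c(rep(TRUE, 50), rep(FALSE, 50))),
    "separation")
  expect_equal(sep$roc$auc, 1.0)

  expect_error(fit_single_feature_logistic(rnorm(10), rep(TRUE, 10)),
               "single-class")

  n <- 20000
  x2 <- rnorm(n)
  y2 <- runif(n) < plogis(-2 + 0.8 * x2)
  fit <- fit_single_feature_logistic(x2, y2)
  expect_equal(fit$coef[2], 0.8, tolerance = 0.1 / 0.8)
  expect_lt(abs(fit$coef[2] - 0.8), 0.1)
})

test_that("the network forward pass matches hand-computed arithmetic", {
  zero <- structure(list(center = rep(0, 6), scale = rep(1, 6),
                         W1 = matrix(0, 6, 3), b1 = rep(0, 3),
                         W2 = rep(0, 3), b2 = 0), class = "saphire_nn")
  expect_equal(nn_forward(zero, rep(1, 6)), 0.5)

  sat <- zero; sat$b2 <- 30
  expect_gt(nn_forward(sat, rep(1, 6)), 1 - 1e-10)

  # 2-feature toy network, evaluated by hand
  toy <- structure(list(center = c(1, 2), scale = c(2, 4),
                        W1 = matrix(c(0.5, -0.3, 0.2, 0.1, 0, 0.7), 2, 3),
                        b1 = c(0.1, -0.2, 0), W2 = c(1, -2, 0.5), b2 = 0.3),
                   class = "saphire_nn")
  x <- c(3, 0)
  xs <- c((3 - 1) / 2, (0 - 2) / 4)
  h <- tanh(c(0.5 * xs[1] - 0.3 * xs[2] + 0.1,
              0.2 * xs[1] + 0.1 * xs[2] - 0.2,
              0 * xs[1] + 0.7 * xs[2] + 0))
  manual <- plogis(sum(c(1, -2, 0.5) * h) + 0.3)
  expect_equal(nn_forward(toy, x), manual, tolerance = 1e-12)

  expect_error(nn_forward(toy, c(NA, 1)), "non-finite")
})

test_that("the analytic gradient matches numeric differentiation", {
  set.seed(13)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- as.numeric(runif(40) < 0.4)
  par <- runif(6 * 3 + 3 + 3 + 1, -0.5, 0.5)
  an <- saphire:::nn_loss_grad(par, X, y, 1e-3, 6, 3)
  num <- vapply(seq_along(par), function(k) {
    e <- rep(0, length(par)); e[k] <- 1e-6
    (saphire:::nn_loss_grad(par + e, X, y, 1e-3, 6, 3)$loss -
     saphire:::nn_loss_grad(par - e, X, y, 1e-3, 6, 3)$loss) / 2e-6
  }, numeric(1))
  expect_equal(an$grad, num, tolerance = 1e-5)
})

test_that("training is deterministic for a fixed seed and guards its preconditions", {
  set.seed(14)
  X <- matrix(rnorm(400 * 6), 400, 6)
  y <- runif(400) < plogis(X[, 1])
  m1 <- train_saphire_nn(X, y, seed = 5, maxit = 50)
  m2 <- train_saphire_nn(X, y, seed = 5, maxit = 50)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$b2, m2$b2)
  expect_identical(m1$valid_idx, m2$valid_idx)

  expect_error(train_saphire_nn(X[1:100, ], y[1:100], seed = 1), "200")
  expect_error(train_saphire_nn(X, y), "seed")
})

test_that("a label-independent fixture gives a near-chance validation AUC", {
  cfg <- simulation_config(seed = 21,
                           label_coefficients = c(ptm_count = 0, sasa = 0,
                                                  conservation = 0, ppi = 0,
                                                  nc = 0, nkc = 0),
                           label_intercept = qlogis(0.3))
  fx <- simulate_map_features(5000, cfg)
  m <- train_saphire_nn(fx$features, fx$labels, seed = 22, maxit = 150)
  expect_gte(m$roc_valid$auc, 0.45)
  expect_lte(m$roc_valid$auc, 0.55)
})

test_that("models round-trip through JSON serialization", {
  set.seed(15)
  X <- matrix(rnorm(300 * 6), 300, 6)
  colnames(X) <- c("ptm_count", "sasa", "conservation", "ppi", "nc", "nkc")
  y <- runif(300) < plogis(X[, 2])
  m <- train_saphire_nn(X, y, seed = 6, maxit = 50)
  p <- tempfile(fileext = ".json")
  write_nn_model(m, p)
  back <- read_nn_model(p)
  expect_equal(nn_forward(back, X), nn_forward(m, X), tolerance = 1e-12)
})

test_that("the PTM-count-threshold sweep restricts and evaluates correctly", {
  set.seed(16)
  n <- 600
  pc <- sample(1:8, n, replace = TRUE, prob = 8:1)
  other <- rnorm(n)
  labels <- runif(n) < plogis(-2 + 0.4 * pc + 1.2 * other)
  pc_scores <- plogis(-2 + 0.4 * pc)          # PC-only model
  nn_scores <- plogis(-2 + 0.4 * pc + 1.2 * other)
  tab <- auc_vs_ptm_count_threshold(
    list(pc = pc_scores, nn = nn_scores), labels, pc, thresholds = 1:8)
  # at threshold 1 all PC values are equal -> AUC exactly 0.5
  expect_equal(tab$pc[1], 0.5)
  expect_gt(tab$nn[1], tab$pc[1])
  # the threshold-3 restriction keeps exactly pc in {1,2,3}
  expect_equal(tab$n[3], sum(pc <= 3))
  # at the maximal threshold the AUC equals the full-set AUC
  expect_equal(tab$pc[8], roc_auc(pc_scores, labels)$auc)
  expect_equal(tab$nn[8], roc_auc(nn_scores, labels)$auc)
})

test_that("KFSC-stratified AUC handles monotone, single-positive and null cases", {
  # constructed monotone fixture: higher-KFSC positives score higher
  bins <- c("1", "2", "3", "4", "5-10", "11+")
  neg <- (1:40) / 41
  pos_scores <- c(0.3, 0.45, 0.6, 0.75, 0.9, 0.99)
  scores <- c(neg, pos_scores)
  labels <- c(rep(FALSE, 40), rep(TRUE, 6))
  kb <- c(rep("none", 40), bins)
  tab <- auc_by_kfsc(scores, labels, kb)
  expect_true(all(diff(tab$auc) > 0))

  # single positive: AUC = fraction of negatives it outscores (+ half ties)
  one <- tab$auc[tab$bin == "1"]
  expect_equal(one, mean(0.3 > neg) + 0.5 * mean(0.3 == neg))

  # label-independent scores: every bin near 0.5
  set.seed(17)
  s <- runif(3000)
  l <- runif(3000) < 0.2
  kb2 <- ifelse(l, sample(bins, 3000, TRUE), "none")
  tab2 <- auc_by_kfsc(s, l, kb2)
  expect_true(all(abs(tab2$auc - 0.5) < 0.08))
})

test_that("retraining with a different seed leaves the model's ranking stable", {
  cfg <- simulation_config(seed = 30)
  fx <- simulate_map_features(20000, cfg)
  m1 <- train_saphire_nn(fx$features, fx$labels, seed = 101, maxit = 300)
  m2 <- train_saphire_nn(fx$features, fx$labels, seed = 202, maxit = 300)
  a1 <- roc_auc(nn_forward(m1, fx$features), fx$labels)$auc
  a2 <- roc_auc(nn_forward(m2, fx$features), fx$labels)$auc
  expect_lt(abs(a1 - a2), 0.02)
})
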