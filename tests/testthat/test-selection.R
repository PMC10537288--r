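test_that("built selectors have the contracted output shape and determinism", {
  set.seed(9)
  X <- matrix(runif(7 * 180), 7, 180)
  for (kind in c("cnn", "lstm", "lstm_fcn")) {
    cfg <- tiny_selector_cfg(kind)
    m1 <- icpratio:::with_seed(5, build_selector(cfg))
    m2 <- icpratio:::with_seed(5, build_selector(cfg))
    expect_identical(m1$params, m2$params)  # same seed, same init
    logits <- icpratio:::model_fwd(m1, X, training = FALSE)$out
    expect_length(logits, 7L)
    expect_true(all(plogis(logits) > 0 & plogis(logits) < 1))
  }
  expect_error(selector_config("mlp"))
  expect_error(selector_config("cnn", dropout = 0.5), class = "icpr_error")
})

test_that("a CNN selector separates a toy two-class pulse set", {
  ds <- simulate_pulse_dataset(200, frac_noncalc = 0.5, seed = 5)
  tc <- train_config(epochs = 30, batch_size = 64, seed = 2)
  m <- train_selector(ds$pulses, ds$labels$calculable, tc,
                      selector_config("cnn"))
  acc <- mean((predict_selection(m, ds$pulses) >= 0.5) == ds$labels$calculable)
  expect_gte(acc, 0.95)
  expect_identical(nrow(m$history), 30L)

  # same seed twice: identical history
  m2 <- train_selector(ds$pulses, ds$labels$calculable, tc,
                       selector_config("cnn"))
  expect_identical(m$history, m2$history)
  expect_identical(m$params, m2$params)

  expect_error(train_selector(ds$pulses, rep(TRUE, nrow(ds$pulses)), tc,
                              selector_config("cnn")),
               class = "icpr_single_class")
})

test_that("roc_auc matches its definition and the rank-statistic oracle", {
  expect_identical(roc_auc(c(0, 0, 1, 1), c(.1, .2, .8, .9)), 1)
  expect_identical(roc_auc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  expect_error(roc_auc(c(1, 1), c(.2, .3)), class = "icpr_single_class")

  mann_whitney_auc <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(33)
  for (i in 1:10) {
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(30), 1)  # coarse scores force ties
    expect_equal(roc_auc(y, s), mann_whitney_auc(y, s), tolerance = 1e-12)
  }

  # cross-check against an established ROC implementation
  skip_if_not_installed("pROC")
  set.seed(34)
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
  s <- rnorm(60)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(y, s), ref, tolerance = 1e-12)
})

test_that("roc_auc is invariant under strictly increasing score transforms", {
  set.seed(4)
  y <- rbinom(50, 1, 0.5)
  s <- rnorm(50)
  a <- roc_auc(y, s)
  expect_equal(roc_auc(y, exp(s)), a, tolerance = 1e-12)
  expect_equal(roc_auc(y, plogis(3 * s + 1)), a, tolerance = 1e-12)
})

test_that("youden_threshold maximizes TPR - FPR over all midpoints", {
  # perfectly separated
  yt <- youden_threshold(c(0, 0, 1, 1), c(.1, .2, .8, .9))
  expect_identical(yt$tpr, 1)
  expect_identical(yt$fpr, 0)

  # anti-separated: the best achievable J is 0 at an extreme threshold
  yt <- youden_threshold(c(1, 1, 0, 0), c(.1, .2, .8, .9))
  expect_identical(yt$tpr - yt$fpr, 0)

  brute <- function(y, s) {
    su <- sort(unique(s))
    cand <- c(-Inf, if (length(su) > 1) (head(su, -1) + tail(su, -1)) / 2, Inf)
    best <- -Inf
    for (thr in cand) {
      p <- s >= thr
      j <- sum(p & y == 1) / sum(y == 1) - sum(p & y == 0) / sum(y == 0)
      best <- max(best, j)
    }
    best
  }
  set.seed(44)
  for (i in 1:10) {
    y <- rbinom(25, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- round(runif(25), 2)
    yt <- youden_threshold(y, s)
    expect_equal(yt$tpr - yt$fpr, brute(y, s), tolerance = 1e-12)
    # the returned operating point is consistent with recomputed confusion
    cc <- confusion_counts(y == 1, s >= yt$threshold)
    r <- rates(cc)
    expect_equal(unname(r["tpr_pct"] / 100), yt$tpr, tolerance = 1e-12)
    expect_equal(unname(r["fpr_pct"] / 100), yt$fpr, tolerance = 1e-12)
  }
})

test_that("select_pulses is monotone in the threshold", {
  ds <- simulate_pulse_dataset(40, frac_noncalc = 0.5, seed = 6)
  m <- icpratio:::with_seed(1, build_selector(tiny_selector_cfg("cnn")))
  masks <- lapply(c(-Inf, 0.2, 0.5, 0.8, Inf),
                  function(th) select_pulses(m, ds$pulses, th))
  expect_true(all(masks[[1]]))
  expect_false(any(masks[[5]]))
  for (i in 1:4) expect_true(all(masks[[i]] | !masks[[i + 1]]))
})
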