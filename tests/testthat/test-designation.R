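test_that("target_vector evaluates the two-Gaussian formula", {
  y <- target_vector(90, 90)
  expect_identical(y[90], 1)  # coincident labels: both exponents are zero
  y <- target_vector(60, 90)
  expect_equal(y[60], 0.5 * (1 + exp(-450)), tolerance = 1e-12)
  expect_lt(y[75], 1e-40)  # both exponents at least 112.5 in magnitude
  expect_error(target_vector(0, 0), class = "icpr_noncalculable_label")
})

test_that("target_vector is symmetric and translation-covariant", {
  expect_identical(target_vector(50, 120), target_vector(120, 50))
  y1 <- target_vector(50, 90, sigma = 2)
  y2 <- target_vector(60, 100, sigma = 2)
  expect_equal(y1[20:160], y2[30:170], tolerance = 1e-12)
})

test_that("designate picks the two best-scored candidates in temporal order", {
  dens <- rep(0, 180)
  dens[c(30, 60, 120)] <- c(0.1, 0.9, 0.8)
  cands <- structure(list(indices = c(30L, 60L, 120L),
                          curvature_values = c(1, 1, 1)),
                     class = "candidate_set")
  d <- designate(dens, cands, "curvature")
  expect_true(d$calculable)
  expect_identical(c(d$i1, d$i2), c(60L, 120L))

  # curvature mode always returns members of the candidate set
  set.seed(8)
  for (i in 1:15) {
    idx <- sort(sample(2:179, sample(2:6, 1)))
    cs <- structure(list(indices = idx, curvature_values = runif(length(idx))),
                    class = "candidate_set")
    dd <- designate(runif(180), cs, "curvature")
    expect_true(all(c(dd$i1, dd$i2) %in% idx))
  }

  # nn mode: two local maxima taken directly
  dens2 <- 0.5 * exp(-(seq_len(180) - 45)^2 / 8) + 0.4 * exp(-(seq_len(180) - 95)^2 / 8)
  d2 <- designate(dens2, mode = "nn_output")
  expect_identical(c(d2$i1, d2$i2), c(45L, 95L))

  # fewer than two candidates: non-calculable, not an error
  one <- structure(list(indices = 40L, curvature_values = 1),
                   class = "candidate_set")
  expect_false(designate(dens, one, "curvature")$calculable)
  expect_false(designate(rep(0, 180), mode = "nn_output")$calculable)
})

test_that("p2p1_ratio is the normalized amplitude quotient", {
  v <- rep(0.2, 180)
  v[40] <- 1.0; v[90] <- 0.8
  expect_identical(p2p1_ratio(v, 40, 90), 0.8)
  v[40] <- 0.5; v[90] <- 0.75
  expect_identical(p2p1_ratio(v, 40, 90), 1.5)
  v[40] <- 0
  expect_error(p2p1_ratio(v, 40, 90), class = "icpr_degenerate_designation")
})

test_that("a U-Net designator overfits a small clean pulse set", {
  ds <- simulate_pulse_dataset(50, frac_noncalc = 0, noise_sd = 0.005, seed = 19)
  tc <- train_config(epochs = 60, batch_size = 16, learning_rate = 0.003,
                     validation_fraction = 0, seed = 3)
  cfg <- designator_config("unet", mode = "nn_output", target_sigma = 3)
  m <- train_designator(ds$pulses, ds$labels, tc, cfg)

  # training loss is non-increasing over 10-epoch windows, allowing jitter at
  # the minibatch-noise level of the converged plateau
  tl <- m$history$train_loss
  w <- sapply(seq_len(length(tl) - 10), function(i) tl[i + 10] - tl[i])
  expect_true(all(w < 5e-4))
  expect_lt(tl[length(tl)], tl[1] / 10)

  # on the training set the two best-scored local maxima sit near the labels
  dens <- predict_density(m, ds$pulses)
  hits <- vapply(seq_len(nrow(dens)), function(i) {
    d <- designate(dens[i, ], mode = "nn_output")
    d$calculable &&
      all(abs(c(d$i1, d$i2) - c(ds$labels$p1[i], ds$labels$p2[i])) <= 3)
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # determinism: same seed reproduces the weights exactly
  m2 <- train_designator(ds$pulses, ds$labels, tc, cfg)
  expect_identical(m$params, m2$params)

  # non-calculable labels are rejected
  bad <- ds$labels; bad$p1[1] <- 0; bad$p2[1] <- 0; bad$calculable[1] <- FALSE
  expect_error(train_designator(ds$pulses, bad, tc, cfg),
               class = "icpr_noncalculable_label")
})

test_that("the curvature-only baseline designates the two earliest candidates", {
  ds <- simulate_pulse_dataset(30, frac_noncalc = 0, noise_sd = 0, seed = 23)
  base <- designate_curvature_baseline(ds$pulses)
  expect_gte(mean(base$calculable), 0.9)
  ok <- base$calculable
  am <- appearance_mae(ds$labels[ok, ], base[ok, ])
  expect_lt(am["p1_mae_pct"], 5)
})

test_that("model checkpoints round-trip through JSON", {
  m <- icpratio:::with_seed(2, build_selector(tiny_selector_cfg("lstm")))
  fp <- tempfile(fileext = ".json")
  save_model(m, fp)
  m2 <- load_model(fp)
  expect_identical(m2$task, m$task)
  expect_identical(m2$kind, m$kind)
  for (nm in names(m$params))
    expect_equal(m2$params[[nm]], m$params[[nm]], tolerance = 1e-15,
                 ignore_attr = FALSE)
  X <- matrix(runif(3 * 180), 3, 180)
  expect_equal(predict_selection(m2, X), predict_selection(m, X),
               tolerance = 1e-12)
  unlink(fp)
})
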