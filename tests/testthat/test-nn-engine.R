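# The training engine is authored in this package, so its backward passes are
# verified against central finite differences. Losses used for the checks are
# smooth; conv biases are randomized because zero-initialized biases put
# zero-padded receptive fields exactly on the ReLU kink, where a finite
# difference is one-sided by construction.

ns <- asNamespace("icpratio")

num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x[i] + eps
    x2 <- x; x2[i] <- x[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}
max_rel <- function(a, b) max(abs(a - b) / pmax(1e-6, abs(a) + abs(b)))

test_that("convolution, batch-norm, pooling and upsampling gradients are exact", {
  set.seed(1)
  B <- 4L; L <- 12L; C <- 3L; K <- 5L; Fo <- 4L
  X <- array(rnorm(B * L * C), c(B, L, C))

  cv <- ns$conv1d_init(K, C, Fo)
  fw <- ns$conv1d_fwd(X, cv$W, cv$b, K)
  bw <- ns$conv1d_bwd(2 * fw$out, cv$W, fw$cache, K)
  nW <- num_grad(function(w) sum(ns$conv1d_fwd(X, w, cv$b, K)$out^2), cv$W)
  expect_lt(max_rel(nW, bw$dW), 1e-6)
  nX <- num_grad(function(v) sum(ns$conv1d_fwd(array(v, dim(X)), cv$W, cv$b, K)$out^2),
                 as.numeric(X))
  expect_lt(max_rel(nX, as.numeric(bw$dX)), 1e-6)

  g <- runif(C, 0.5, 1.5); be <- rnorm(C)
  st <- ns$bn_state_init(C)
  fo <- ns$bn_fwd(X, g, be, st, training = TRUE)
  bo <- ns$bn_bwd(3 * fo$out^2, g, fo$cache)
  loss_bn <- function(XX, gg, bb) sum(ns$bn_fwd(XX, gg, bb, st, TRUE)$out^3)
  expect_lt(max_rel(num_grad(function(v) loss_bn(X, v, be), g), bo$dg), 1e-6)
  expect_lt(max_rel(num_grad(function(v) loss_bn(X, g, v), be), bo$db), 1e-6)
  expect_lt(max_rel(num_grad(function(v) loss_bn(array(v, dim(X)), g, be),
                             as.numeric(X)), as.numeric(bo$dX)), 1e-5)

  fo <- ns$maxpool2_fwd(X)
  bo <- ns$maxpool2_bwd(2 * fo$out, fo$cache)
  nX <- num_grad(function(v) sum(ns$maxpool2_fwd(array(v, dim(X)))$out^2),
                 as.numeric(X))
  expect_lt(max_rel(nX, as.numeric(bo)), 1e-5)

  fo <- ns$upsample2_fwd(X)
  bo <- ns$upsample2_bwd(2 * fo)
  nX <- num_grad(function(v) sum(ns$upsample2_fwd(array(v, dim(X)))^2),
                 as.numeric(X))
  expect_lt(max_rel(nX, as.numeric(bo)), 1e-6)
})

test_that("bidirectional LSTM kernel gradients match finite differences", {
  set.seed(3)
  B <- 3L; L <- 20L; H <- 6L
  X <- matrix(rnorm(B * L), B, L)
  pf <- ns$lstm_init(H); pb <- ns$lstm_init(H)
  R <- matrix(rnorm(B * 2L * H), B, 2L * H)
  loss <- function(pf_, pb_) sum(ns$bilstm_fwd(X, pf_, pb_)$out * R)
  fw <- ns$bilstm_fwd(X, pf, pb)
  bw <- ns$bilstm_bwd(R, pf, pb, fw$cache, H)
  # single-precision kernels: compare where the gradient magnitude is
  # meaningful, at a tolerance matching float32 round-off
  check <- function(num, ana) {
    big <- abs(ana) > 0.05 * max(abs(ana))
    expect_lt(max(abs(num[big] - ana[big]) /
                    pmax(1e-4, abs(num[big]) + abs(ana[big]))), 2e-2)
  }
  eps <- 1e-3
  for (nm in c("Wx", "Wh", "b")) {
    num_f <- pf[[nm]]
    for (i in seq_along(num_f)) {
      p1 <- pf; p1[[nm]][i] <- pf[[nm]][i] + eps
      p2 <- pf; p2[[nm]][i] <- pf[[nm]][i] - eps
      num_f[i] <- (loss(p1, pb) - loss(p2, pb)) / (2 * eps)
    }
    check(num_f, bw$f[[paste0("d", nm)]])
  }
  numX <- X
  for (i in seq_along(X)) {
    X1 <- X; X1[i] <- X[i] + eps
    X2 <- X; X2[i] <- X[i] - eps
    numX[i] <- (sum(ns$bilstm_fwd(X1, pf, pb)$out * R) -
                  sum(ns$bilstm_fwd(X2, pf, pb)$out * R)) / (2 * eps)
  }
  check(numX, bw$dX)
})

test_that("full architectures backpropagate correctly end to end", {
  set.seed(7)
  X <- matrix(runif(5 * 180), 5, 180)
  ysel <- c(0, 1, 0, 1, 1)
  ydes <- t(sapply(c(40, 60, 80, 100, 55),
                   function(p) target_vector(p, p + 40, sigma = 3)))
  rand_bias <- function(m) {
    for (nm in grep("_b$", names(m$params), value = TRUE))
      m$params[[nm]] <- rnorm(length(m$params[[nm]]), sd = 0.1)
    m
  }
  check_arch <- function(m, target, task, eps, tol) {
    m$cfg$dropout <- 0  # deterministic forward for the finite difference
    loss_of <- function(mm) {
      out <- ns$model_fwd(mm, X, training = TRUE)$out
      if (task == "sel") ns$bce_logits_loss(out, target)$loss
      else ns$mse_loss(out, target)$loss
    }
    fw <- ns$model_fwd(m, X, training = TRUE)
    ls <- if (task == "sel") ns$bce_logits_loss(fw$out, target)
          else ns$mse_loss(fw$out, target)
    g <- ns$model_bwd(m, fw$cache, ls$dz)
    set.seed(101)
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      for (ci in sample(length(p), min(3L, length(p)))) {
        m1 <- m; m1$params[[nm]][ci] <- p[ci] + eps
        m2 <- m; m2$params[[nm]][ci] <- p[ci] - eps
        num <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
        ana <- g[[nm]][ci]
        if (max(abs(num), abs(ana)) < 1e-4) next  # below float noise floor
        expect_lt(abs(num - ana) / max(abs(num), abs(ana)), tol)
      }
    }
  }
  set.seed(11)
  m <- rand_bias(build_selector(tiny_selector_cfg("cnn")))
  check_arch(m, ysel, "sel", eps = 1e-6, tol = 0.01)
  set.seed(12)
  m <- rand_bias(build_selector(tiny_selector_cfg("lstm")))
  check_arch(m, ysel, "sel", eps = 2e-3, tol = 0.05)
  set.seed(13)
  m <- rand_bias(build_selector(tiny_selector_cfg("lstm_fcn")))
  check_arch(m, ysel, "sel", eps = 2e-3, tol = 0.05)
  set.seed(14)
  m <- rand_bias(build_designator(designator_config("unet", channels = c(3L, 4L, 5L))))
  check_arch(m, ydes, "des", eps = 1e-6, tol = 0.01)
})

test_that("losses and Adam behave as specified", {
  # BCE with logits agrees with the direct formula
  z <- c(-2, -0.5, 0.3, 1.7)
  y <- c(0, 1, 1, 0)
  l <- ns$bce_logits_loss(z, y)
  expect_equal(l$loss, mean(-y * log(plogis(z)) - (1 - y) * log(1 - plogis(z))),
               tolerance = 1e-12)
  expect_equal(l$dz, (plogis(z) - y) / 4, tolerance = 1e-12)

  # Adam: first step moves each coordinate by about lr in the -grad direction
  p <- list(w = c(1, -2))
  st <- ns$adam_init(p)
  up <- ns$adam_step(p, list(w = c(0.3, -0.1)), st, lr = 0.01, t = 1)
  expect_equal(up$params$w, c(1 - 0.01, -2 + 0.01), tolerance = 1e-6)
})
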