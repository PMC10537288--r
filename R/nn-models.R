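# Architecture definitions: parameter initialization, forward and backward
# passes for the three pulse-selection networks (1-D CNN, bidirectional LSTM,
# LSTM-FCN) and the two subpeak-designation networks (1-D U-Net, bidirectional
# LSTM). Input pulses are always 180-sample rows of a matrix.

PULSE_LEN <- 180L

#' Pulse-selection network configuration
#'
#' @param kind One of `"cnn"`, `"lstm"`, `"lstm_fcn"`.
#' @param channels Channel widths of the three convolutional encoder blocks.
#' @param kernel Convolution kernel size (odd).
#' @param lstm_hidden Hidden size of the (bidirectional) LSTM cell.
#' @param dense_width Width of the first dense layer.
#' @param dropout Dropout probability (fixed at 0.2).
#' @param pos_weight Loss weight of the positive (calculable) class; 1 leaves
#'   the ~9:1 class imbalance unweighted.
#' @return An object of class `selector_config`.
#' @export
selector_config <- function(kind = c("lstm", "cnn", "lstm_fcn"),
                            channels = c(32L, 64L, 128L),
                            kernel = 7L,
                            lstm_hidden = 64L,
                            dense_width = NULL,
                            dropout = 0.2,
                            pos_weight = 1) {
  kind <- match.arg(kind)
  stopifnot(length(channels) == 3L, all(channels > 0),
            kernel %% 2L == 1L, kernel > 0, lstm_hidden > 0)
  if (dropout != 0.2)
    icpr_stop("icpr_invalid_config", "dropout probability is fixed at 0.2")
  if (is.null(dense_width))
    dense_width <- if (kind == "lstm") 64L else 128L
  structure(list(kind = kind, channels = as.integer(channels),
                 kernel = as.integer(kernel),
                 lstm_hidden = as.integer(lstm_hidden),
                 dense_width = as.integer(dense_width), dropout = dropout,
                 pos_weight = pos_weight),
            class = "selector_config")
}

#' Subpeak-designation network configuration
#'
#' @param kind `"lstm"` (bidirectional cell, hidden size 180, dense layers
#'   (360, 360) and (360, 180)) or `"unet"` (three-level 1-D encoder-decoder
#'   with skip connections).
#' @param mode Designation strategy: `"curvature"` scores curvature-derived
#'   candidates with the network output; `"nn_output"` takes the two highest
#'   local maxima of the output directly.
#' @param channels U-Net encoder channel widths.
#' @param kernel Convolution kernel size (odd).
#' @param dropout Dropout probability (fixed at 0.2).
#' @param target_sigma Standard deviation, in samples, of the two Gaussians of
#'   the training target (see [target_vector()]); 1 by construction of the
#'   target, widenable for denser supervision.
#' @return An object of class `designator_config`.
#' @export
designator_config <- function(kind = c("lstm", "unet"),
                              mode = c("curvature", "nn_output"),
                              channels = c(16L, 32L, 64L),
                              kernel = 7L,
                              dropout = 0.2,
                              target_sigma = 1) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  stopifnot(length(channels) == 3L, kernel %% 2L == 1L, target_sigma > 0)
  if (dropout != 0.2)
    icpr_stop("icpr_invalid_config", "dropout probability is fixed at 0.2")
  structure(list(kind = kind, mode = mode, channels = as.integer(channels),
                 kernel = as.integer(kernel), lstm_hidden = 180L,
                 dropout = dropout, target_sigma = target_sigma),
            class = "designator_config")
}

# encoder length after the three pool-by-2 stages (180 -> 90 -> 45 -> 22)
enc_out_len <- function(L = PULSE_LEN) ((L %/% 2L) %/% 2L) %/% 2L

# -- three-block convolutional encoder (conv - BN - ReLU - maxpool) -----------

enc_init <- function(channels, K) {
  cin <- c(1L, channels[1:2])
  p <- list()
  st <- list()
  for (l in 1:3) {
    cv <- conv1d_init(K, cin[l], channels[l])
    p[[paste0("e", l, "_W")]] <- cv$W
    p[[paste0("e", l, "_b")]] <- cv$b
    bn <- bn_init(channels[l])
    p[[paste0("bn", l, "_g")]] <- bn$g
    p[[paste0("bn", l, "_b")]] <- bn$b
    st[[paste0("bn", l)]] <- bn_state_init(channels[l])
  }
  list(params = p, state = st)
}

enc_fwd <- function(X, p, st, training, K) {
  cache <- list()
  out <- X
  for (l in 1:3) {
    cv <- conv1d_fwd(out, p[[paste0("e", l, "_W")]], p[[paste0("e", l, "_b")]], K)
    bn <- bn_fwd(cv$out, p[[paste0("bn", l, "_g")]], p[[paste0("bn", l, "_b")]],
                 st[[paste0("bn", l)]], training)
    st[[paste0("bn", l)]] <- bn$state
    rl <- relu_fwd(bn$out)
    mp <- maxpool2_fwd(rl$out)
    cache[[l]] <- list(cv = cv$cache, bn = bn$cache, rl = rl$cache, mp = mp$cache)
    out <- mp$out
  }
  list(out = out, cache = cache, state = st)
}

enc_bwd <- function(dOut, p, cache, K) {
  g <- list()
  d <- dOut
  for (l in 3:1) {
    d <- maxpool2_bwd(d, cache[[l]]$mp)
    d <- relu_bwd(d, cache[[l]]$rl)
    bn <- bn_bwd(d, p[[paste0("bn", l, "_g")]], cache[[l]]$bn)
    g[[paste0("bn", l, "_g")]] <- bn$dg
    g[[paste0("bn", l, "_b")]] <- bn$db
    cv <- conv1d_bwd(bn$dX, p[[paste0("e", l, "_W")]], cache[[l]]$cv, K)
    g[[paste0("e", l, "_W")]] <- cv$dW
    g[[paste0("e", l, "_b")]] <- cv$db
    d <- cv$dX
  }
  list(dX = d, grads = g)
}

# -- model construction -------------------------------------------------------

#' Build an untrained pulse-selection model
#'
#' Architectures follow the selection stage of the pipeline: `cnn` is three
#' blocks of convolution - batch normalization - ReLU - max pooling followed
#' by two dense layers; `lstm` is a single bidirectional LSTM cell whose two
#' final direction states are concatenated and passed to two dense layers;
#' `lstm_fcn` runs the convolutional encoder and an LSTM cell in parallel and
#' concatenates their outputs before the dense head. Dropout 0.2 is applied
#' at the end of the encoder / cell and to the first dense layer; the scalar
#' output is a pre-sigmoid logit. Initialization draws from the current RNG
#' stream, so two builds under the same seed are identical.
#'
#' @param cfg A [selector_config()].
#' @return An object of class `icpr_model`.
#' @export
build_selector <- function(cfg) {
  if (!inherits(cfg, "selector_config"))
    icpr_stop("icpr_invalid_config", "`cfg` must be a selector_config")
  K <- cfg$kernel; H <- cfg$lstm_hidden
  p <- list(); st <- list()
  flat <- 0L
  if (cfg$kind %in% c("cnn", "lstm_fcn")) {
    e <- enc_init(cfg$channels, K)
    p <- c(p, e$params); st <- e$state
    flat <- enc_out_len() * cfg$channels[3]
  }
  if (cfg$kind %in% c("lstm", "lstm_fcn")) {
    lf <- lstm_init(H); lb <- lstm_init(H)
    p$lf_Wx <- lf$Wx; p$lf_Wh <- lf$Wh; p$lf_b <- lf$b
    p$lb_Wx <- lb$Wx; p$lb_Wh <- lb$Wh; p$lb_b <- lb$b
  }
  din <- switch(cfg$kind, cnn = flat, lstm = 2L * H, lstm_fcn = flat + 2L * H)
  d1 <- dense_init(din, cfg$dense_width)
  d2 <- dense_init(cfg$dense_width, 1L)
  p$d1_W <- d1$W; p$d1_b <- d1$b; p$d2_W <- d2$W; p$d2_b <- d2$b
  structure(list(task = "selection", kind = cfg$kind, cfg = cfg,
                 params = p, bn = st),
            class = "icpr_model")
}

#' Build an untrained subpeak-designation model
#'
#' `lstm`: bidirectional cell with hidden size 180; the 360-dimensional
#' concatenated state feeds dense layers (360, 360) and (360, 180) with ReLU
#' between and dropout 0.2 on the first dense layer. `unet`: three-level 1-D
#' encoder-decoder (convolution - ReLU - dropout blocks, max-pool down,
#' nearest-neighbour upsampling with skip concatenation) and a final
#' one-channel projection. The output is a 180-point score vector.
#'
#' @param cfg A [designator_config()].
#' @return An object of class `icpr_model`.
#' @export
build_designator <- function(cfg) {
  if (!inherits(cfg, "designator_config"))
    icpr_stop("icpr_invalid_config", "`cfg` must be a designator_config")
  K <- cfg$kernel
  p <- list()
  if (cfg$kind == "lstm") {
    H <- cfg$lstm_hidden
    lf <- lstm_init(H); lb <- lstm_init(H)
    p$lf_Wx <- lf$Wx; p$lf_Wh <- lf$Wh; p$lf_b <- lf$b
    p$lb_Wx <- lb$Wx; p$lb_Wh <- lb$Wh; p$lb_b <- lb$b
    d1 <- dense_init(2L * H, 2L * H)
    d2 <- dense_init(2L * H, PULSE_LEN)
    p$d1_W <- d1$W; p$d1_b <- d1$b; p$d2_W <- d2$W; p$d2_b <- d2$b
  } else {
    ch <- cfg$channels
    cin <- c(1L, ch[1], ch[2], ch[3] + ch[2], ch[2] + ch[1])
    cout <- c(ch, ch[2], ch[1])
    nms <- c("u1", "u2", "u3", "d2", "d1")
    for (l in seq_along(nms)) {
      cv <- conv1d_init(K, cin[l], cout[l])
      p[[paste0(nms[l], "_W")]] <- cv$W
      p[[paste0(nms[l], "_b")]] <- cv$b
    }
    fin <- conv1d_init(1L, ch[1], 1L)
    p$out_W <- fin$W; p$out_b <- fin$b
  }
  structure(list(task = "designation", kind = cfg$kind, cfg = cfg,
                 params = p, bn = list()),
            class = "icpr_model")
}

# -- forward / backward dispatch ---------------------------------------------

# X: matrix B x 180. Returns list(out, cache, bn); `out` is a vector of
# logits (selection) or a B x 180 matrix of scores (designation).
model_fwd <- function(model, X, training = FALSE) {
  p <- model$params; cfg <- model$cfg; K <- cfg$kernel
  drop <- cfg$dropout
  B <- nrow(X)
  cache <- list()
  bn <- model$bn
  branch <- NULL

  if (model$task == "selection") {
    if (model$kind %in% c("cnn", "lstm_fcn")) {
      X3 <- X; dim(X3) <- c(B, PULSE_LEN, 1L)
      e <- enc_fwd(X3, p, bn, training, K)
      bn <- e$state
      flat <- e$out; dim(flat) <- c(B, prod(dim(e$out)[2:3]))
      cache$enc <- e$cache
      cache$enc_dims <- dim(e$out)
      branch <- flat
    }
    if (model$kind %in% c("lstm", "lstm_fcn")) {
      bl <- bilstm_fwd(X, list(Wx = p$lf_Wx, Wh = p$lf_Wh, b = p$lf_b),
                       list(Wx = p$lb_Wx, Wh = p$lb_Wh, b = p$lb_b))
      cache$lstm <- bl$cache
      branch <- if (is.null(branch)) bl$out else cbind(branch, bl$out)
    }
    if (model$kind == "cnn") {
      dr0 <- dropout_fwd(branch, drop, training)  # end of encoder
      cache$dr0 <- dr0$cache
      branch <- dr0$out
    } else if (model$kind == "lstm") {
      dr0 <- dropout_fwd(branch, drop, training)  # end of the cell
      cache$dr0 <- dr0$cache
      branch <- dr0$out
    }
    d1 <- dense_fwd(branch, p$d1_W, p$d1_b); cache$d1 <- d1$cache
    r1 <- relu_fwd(d1$out); cache$r1 <- r1$cache
    dr1 <- dropout_fwd(r1$out, drop, training); cache$dr1 <- dr1$cache
    d2 <- dense_fwd(dr1$out, p$d2_W, p$d2_b); cache$d2 <- d2$cache
    return(list(out = as.numeric(d2$out), cache = cache, bn = bn))
  }

  # designation
  if (model$kind == "lstm") {
    bl <- bilstm_fwd(X, list(Wx = p$lf_Wx, Wh = p$lf_Wh, b = p$lf_b),
                     list(Wx = p$lb_Wx, Wh = p$lb_Wh, b = p$lb_b))
    cache$lstm <- bl$cache
    d1 <- dense_fwd(bl$out, p$d1_W, p$d1_b); cache$d1 <- d1$cache
    r1 <- relu_fwd(d1$out); cache$r1 <- r1$cache
    dr1 <- dropout_fwd(r1$out, drop, training); cache$dr1 <- dr1$cache
    d2 <- dense_fwd(dr1$out, p$d2_W, p$d2_b); cache$d2 <- d2$cache
    return(list(out = d2$out, cache = cache, bn = bn))
  }

  # unet
  X3 <- X; dim(X3) <- c(B, PULSE_LEN, 1L)
  blk <- function(inp, nm) {
    cv <- conv1d_fwd(inp, p[[paste0(nm, "_W")]], p[[paste0(nm, "_b")]], K)
    rl <- relu_fwd(cv$out)
    dr <- dropout_fwd(rl$out, drop, training)
    cache[[nm]] <<- list(cv = cv$cache, rl = rl$cache, dr = dr$cache)
    dr$out
  }
  e1 <- blk(X3, "u1")                       # B x 180 x c1
  p1 <- maxpool2_fwd(e1); cache$p1 <- p1$cache
  e2 <- blk(p1$out, "u2")                   # B x 90 x c2
  p2 <- maxpool2_fwd(e2); cache$p2 <- p2$cache
  bt <- blk(p2$out, "u3")                   # B x 45 x c3
  up2 <- upsample2_fwd(bt)                  # B x 90 x c3
  cat2 <- array(c(up2, e2), c(B, 90L, dim(up2)[3] + dim(e2)[3]))
  cache$cat2_split <- dim(up2)[3]
  d2o <- blk(cat2, "d2")                    # B x 90 x c2
  up1 <- upsample2_fwd(d2o)                 # B x 180 x c2
  cat1 <- array(c(up1, e1), c(B, 180L, dim(up1)[3] + dim(e1)[3]))
  cache$cat1_split <- dim(up1)[3]
  d1o <- blk(cat1, "d1")                    # B x 180 x c1
  fo <- conv1d_fwd(d1o, p$out_W, p$out_b, 1L); cache$fo <- fo$cache
  out <- fo$out; dim(out) <- c(B, PULSE_LEN)
  list(out = out, cache = cache, bn = bn)
}

# dOut matches model_fwd's `out` shape. Returns named list of parameter grads.
model_bwd <- function(model, cache, dOut) {
  p <- model$params; cfg <- model$cfg; K <- cfg$kernel
  g <- list()

  if (model$task == "selection") {
    dz <- matrix(dOut, ncol = 1L)
    d2 <- dense_bwd(dz, p$d2_W, cache$d2)
    g$d2_W <- d2$dW; g$d2_b <- d2$db
    d <- dropout_bwd(d2$dX, cache$dr1)
    d <- relu_bwd(d, cache$r1)
    d1 <- dense_bwd(d, p$d1_W, cache$d1)
    g$d1_W <- d1$dW; g$d1_b <- d1$db
    d <- d1$dX
    if (model$kind %in% c("cnn", "lstm")) d <- dropout_bwd(d, cache$dr0)
    if (model$kind == "cnn") {
      dim(d) <- cache$enc_dims
      eb <- enc_bwd(d, p, cache$enc, K)
      g <- c(g, eb$grads)
    } else if (model$kind == "lstm") {
      H <- cfg$lstm_hidden
      lb <- bilstm_bwd(d, list(Wx = p$lf_Wx, Wh = p$lf_Wh, b = p$lf_b),
                       list(Wx = p$lb_Wx, Wh = p$lb_Wh, b = p$lb_b),
                       cache$lstm, H)
      g$lf_Wx <- lb$f$dWx; g$lf_Wh <- lb$f$dWh; g$lf_b <- lb$f$db
      g$lb_Wx <- lb$r$dWx; g$lb_Wh <- lb$r$dWh; g$lb_b <- lb$r$db
    } else { # lstm_fcn: split the concatenated branch gradient
      flat <- prod(cache$enc_dims[2:3])
      denc <- d[, seq_len(flat), drop = FALSE]
      dim(denc) <- cache$enc_dims
      eb <- enc_bwd(denc, p, cache$enc, K)
      g <- c(g, eb$grads)
      H <- cfg$lstm_hidden
      dl <- d[, flat + seq_len(2L * H), drop = FALSE]
      lb <- bilstm_bwd(dl, list(Wx = p$lf_Wx, Wh = p$lf_Wh, b = p$lf_b),
                       list(Wx = p$lb_Wx, Wh = p$lb_Wh, b = p$lb_b),
                       cache$lstm, H)
      g$lf_Wx <- lb$f$dWx; g$lf_Wh <- lb$f$dWh; g$lf_b <- lb$f$db
      g$lb_Wx <- lb$r$dWx; g$lb_Wh <- lb$r$dWh; g$lb_b <- lb$r$db
    }
    return(g)
  }

  if (model$kind == "lstm") {
    d2 <- dense_bwd(dOut, p$d2_W, cache$d2)
    g$d2_W <- d2$dW; g$d2_b <- d2$db
    d <- dropout_bwd(d2$dX, cache$dr1)
    d <- relu_bwd(d, cache$r1)
    d1 <- dense_bwd(d, p$d1_W, cache$d1)
    g$d1_W <- d1$dW; g$d1_b <- d1$db
    H <- cfg$lstm_hidden
    lb <- bilstm_bwd(d1$dX, list(Wx = p$lf_Wx, Wh = p$lf_Wh, b = p$lf_b),
                     list(Wx = p$lb_Wx, Wh = p$lb_Wh, b = p$lb_b),
                     cache$lstm, H)
    g$lf_Wx <- lb$f$dWx; g$lf_Wh <- lb$f$dWh; g$lf_b <- lb$f$db
    g$lb_Wx <- lb$r$dWx; g$lb_Wh <- lb$r$dWh; g$lb_b <- lb$r$db
    return(g)
  }

  # unet
  B <- dim(dOut)[1]
  dfo <- dOut; dim(dfo) <- c(B, PULSE_LEN, 1L)
  fo <- conv1d_bwd(dfo, p$out_W, cache$fo, 1L)
  g$out_W <- fo$dW; g$out_b <- fo$db
  blk_bwd <- function(dY, nm) {
    d <- dropout_bwd(dY, cache[[nm]]$dr)
    d <- relu_bwd(d, cache[[nm]]$rl)
    cv <- conv1d_bwd(d, p[[paste0(nm, "_W")]], cache[[nm]]$cv, K)
    g[[paste0(nm, "_W")]] <<- cv$dW
    g[[paste0(nm, "_b")]] <<- cv$db
    cv$dX
  }
  dcat1 <- blk_bwd(fo$dX, "d1")
  s1 <- cache$cat1_split
  dup1 <- dcat1[, , seq_len(s1), drop = FALSE]
  de1_skip <- dcat1[, , s1 + seq_len(dim(dcat1)[3] - s1), drop = FALSE]
  dd2 <- upsample2_bwd(dup1)
  dcat2 <- blk_bwd(dd2, "d2")
  s2 <- cache$cat2_split
  dup2 <- dcat2[, , seq_len(s2), drop = FALSE]
  de2_skip <- dcat2[, , s2 + seq_len(dim(dcat2)[3] - s2), drop = FALSE]
  dbt <- upsample2_bwd(dup2)
  dp2 <- blk_bwd(dbt, "u3")
  de2 <- maxpool2_bwd(dp2, cache$p2) + de2_skip
  dp1 <- blk_bwd(de2, "u2")
  de1 <- maxpool2_bwd(dp1, cache$p1) + de1_skip
  blk_bwd(de1, "u1")
  g
}
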