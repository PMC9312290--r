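# Compact CNN-GRU fusion classifier for windowed ECG feature matrices.
#
# Input is one window-feature matrix per record (rows = windows along the
# record, columns = signal summary + selected attributes). Each row is
# pushed through a stack of 1-D convolution + max-pooling blocks (the
# spatial part), producing one feature vector per window; a GRU then runs
# across the window sequence (the temporal part) and its final hidden state
# feeds a small dense stack ending in one sigmoid per label. Training is
# plain minibatch SGD on the summed per-label binary cross-entropy.
#
# Everything — convolution, pooling, GRU and dense forward passes and their
# analytic gradients (backpropagation through time included) — is authored
# here in plain R and verified against scalar oracles and finite
# differences in the test suite. The default layer stack uses kernel sizes
# (20, 10, 5), filter counts (3, 6, 6), pool size 2 and GRU width 20;
# output lengths follow standard convolution arithmetic with 'same' zero
# padding.

#' CNN-GRU network configuration
#'
#' @param n_labels Number of output labels m (sigmoid outputs).
#' @param input_channels Columns of the window matrix (1 signal summary +
#'   number of selected features).
#' @param conv_blocks List of blocks, each a list with `kernel`, `filters`,
#'   `stride`; each block is followed by a max-pool.
#' @param pool_size,pool_stride Max-pooling geometry (default 2/2).
#' @param padding `"same"` (default) or `"valid"` zero-padding policy.
#' @param gru_hidden GRU hidden width (default 20).
#' @param dense_sizes Hidden dense layer widths before the output layer.
#' @return A `network_config` list, with the derived per-layer lengths in
#'   `$shapes`.
#' @export
network_config <- function(n_labels, input_channels,
                           conv_blocks = list(
                             list(kernel = 20, filters = 3, stride = 1),
                             list(kernel = 10, filters = 6, stride = 1),
                             list(kernel = 5, filters = 6, stride = 1)
                           ),
                           pool_size = 2, pool_stride = 2,
                           padding = c("same", "valid"),
                           gru_hidden = 20, dense_sizes = c(20, 10)) {
  padding <- match.arg(padding)
  if (n_labels < 1 || gru_hidden < 1) stopf("`n_labels` and `gru_hidden` must be >= 1")
  for (b in conv_blocks) if (b$kernel < 1) stopf("kernel sizes must be >= 1")
  # derive the length/channel shape after each block
  len <- input_channels
  ch <- 1L
  shapes <- list(c(len, ch))
  for (b in conv_blocks) {
    len_out <- if (padding == "same") {
      floor((len - 1) / (b$stride %||% 1)) + 1
    } else {
      floor((len - b$kernel) / (b$stride %||% 1)) + 1
    }
    if (len_out < 1) stopf("conv kernel (%d) does not fit input length %d", b$kernel, len)
    len <- len_out
    ch <- b$filters
    if (len >= pool_size) len <- floor((len - pool_size) / pool_stride) + 1
    shapes <- c(shapes, list(c(len, ch)))
  }
  structure(
    list(n_labels = n_labels, input_channels = input_channels,
         conv_blocks = conv_blocks, pool_size = pool_size,
         pool_stride = pool_stride, padding = padding,
         gru_hidden = gru_hidden, dense_sizes = dense_sizes,
         flat_dim = len * ch, shapes = shapes),
    class = "network_config"
  )
}

#' Training configuration
#'
#' @param learning_rate SGD step size (default 0.001).
#' @param batch_size Minibatch size in records (default 150).
#' @param epochs Number of passes over the training set (default 100).
#' @param patience Early-stopping patience on validation loss; `Inf`
#'   disables early stopping when no validation set is given.
#' @param seed Integer seed controlling initialisation and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 150,
                         epochs = 100, patience = 10, seed = 1) {
  if (learning_rate < 0) stopf("`learning_rate` must be >= 0")
  if (batch_size < 1) stopf("`batch_size` must be >= 1")
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, patience = patience, seed = seed),
            class = "train_config")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- convolution ----------------------------------------------------------

#' 1-D convolutional layer forward pass
#'
#' Valid cross-correlation of a (length x channels) map with a bank of
#' kernels, optional zero padding, plus bias and activation. Output length
#' is `floor((L + pad - kernel) / stride) + 1`.
#'
#' @param A Input map: length x channels matrix (a vector is one channel).
#' @param K Kernel array `dim = c(kernel, in_channels, out_channels)`.
#' @param b Bias vector, one per output channel.
#' @param stride Positive integer stride.
#' @param padding `"valid"` (none) or `"same"` (zero pad `kernel - 1`,
#'   split left/right).
#' @param activation `"relu"` or `"identity"`.
#' @return Output map: length_out x out_channels matrix.
#' @examples
#' conv_forward(matrix(1:5), array(c(1, 0, -1), c(3, 1, 1)), 0,
#'              activation = "identity")
#' @export
conv_forward <- function(A, K, b, stride = 1,
                         padding = c("valid", "same"),
                         activation = c("relu", "identity")) {
  padding <- match.arg(padding)
  activation <- match.arg(activation)
  .conv_fwd(A, K, b, stride, padding, activation)$out
}

.conv_fwd <- function(A, K, b, stride, padding, activation) {
  if (is.vector(A)) A <- matrix(A, ncol = 1)
  k <- dim(K)[1]; cin <- dim(K)[2]; cout <- dim(K)[3]
  if (ncol(A) != cin) stopf("input has %d channels, kernels expect %d", ncol(A), cin)
  L <- nrow(A)
  pad_l <- pad_r <- 0L
  if (padding == "same") {
    pad_tot <- k - 1L
    pad_l <- pad_tot %/% 2L
    pad_r <- pad_tot - pad_l
  }
  if (L + pad_l + pad_r < k) stopf("kernel (%d) longer than padded input (%d)", k, L + pad_l + pad_r)
  Ap <- rbind(matrix(0, pad_l, cin), A, matrix(0, pad_r, cin))
  L_out <- (nrow(Ap) - k) %/% stride + 1L
  pre <- matrix(rep(b, each = L_out), L_out, cout)
  base <- (seq_len(L_out) - 1L) * stride
  for (j in seq_len(k)) {
    rows <- base + j
    for (o in seq_len(cout)) {
      pre[, o] <- pre[, o] + Ap[rows, , drop = FALSE] %*% K[j, , o]
    }
  }
  out <- if (activation == "relu") pmax(pre, 0) else pre
  list(out = out, pre = pre, Ap = Ap, pad_l = pad_l, pad_r = pad_r,
       stride = stride, k = k, A_rows = L, activation = activation)
}

.conv_bwd <- function(cache, K, dOut) {
  k <- cache$k; stride <- cache$stride
  cin <- dim(K)[2]; cout <- dim(K)[3]
  dPre <- if (cache$activation == "relu") dOut * (cache$pre > 0) else dOut
  L_out <- nrow(dPre)
  base <- (seq_len(L_out) - 1L) * stride
  dK <- array(0, dim(K))
  dAp <- matrix(0, nrow(cache$Ap), cin)
  for (j in seq_len(k)) {
    rows <- base + j
    dK[j, , ] <- t(cache$Ap[rows, , drop = FALSE]) %*% dPre
    dAp[rows, ] <- dAp[rows, ] + dPre %*% t(matrix(K[j, , ], cin, cout))
  }
  db <- colSums(dPre)
  dA <- dAp[(cache$pad_l + 1):(cache$pad_l + cache$A_rows), , drop = FALSE]
  list(dA = dA, dK = dK, db = db)
}

# ---- pooling --------------------------------------------------------------

#' Max-pooling over a 1-D map
#'
#' Per-channel maximum over sliding windows; a trailing partial window is
#' dropped. Depth (channel count) is unchanged.
#'
#' @param G Input map: length x channels matrix (vector = one channel).
#' @param size,stride Window size and stride (defaults 2/2).
#' @return Pooled map.
#' @examples
#' max_pool(c(1, 3, 2, 5))
#' @export
max_pool <- function(G, size = 2, stride = 2) {
  .pool_fwd(G, size, stride)$out
}

.pool_fwd <- function(G, size, stride) {
  if (is.vector(G)) G <- matrix(G, ncol = 1)
  L <- nrow(G)
  if (L < size) {
    # degenerate map shorter than one window: pass through unchanged
    return(list(out = G, argmax = matrix(seq_len(L), L, ncol(G)),
                identity = TRUE, L = L))
  }
  n_out <- (L - size) %/% stride + 1L
  out <- matrix(0, n_out, ncol(G))
  am <- matrix(0L, n_out, ncol(G))
  for (i in seq_len(n_out)) {
    win <- ((i - 1L) * stride + 1L):((i - 1L) * stride + size)
    for (c0 in seq_len(ncol(G))) {
      w <- which.max(G[win, c0])
      am[i, c0] <- win[w]
      out[i, c0] <- G[win[w], c0]
    }
  }
  list(out = out, argmax = am, identity = FALSE, L = L)
}

.pool_bwd <- function(cache, dOut) {
  if (cache$identity) return(dOut)
  dG <- matrix(0, cache$L, ncol(dOut))
  for (c0 in seq_len(ncol(dOut))) {
    for (i in seq_len(nrow(dOut))) {
      dG[cache$argmax[i, c0], c0] <- dG[cache$argmax[i, c0], c0] + dOut[i, c0]
    }
  }
  dG
}

# ---- GRU ------------------------------------------------------------------

#' One GRU step
#'
#' Update gate `z = sigmoid(Wz f + Uz h + bz)`, reset gate
#' `r = sigmoid(Wr f + Ur h + br)`, candidate
#' `hc = tanh(Wc f + Uc (r * h) + bc)`, new state
#' `h' = z * h + (1 - z) * hc`.
#'
#' @param f Input vector.
#' @param h_prev Previous hidden state.
#' @param weights List with `Wz, Uz, bz, Wr, Ur, br, Wc, Uc, bc`.
#' @return The new hidden state vector.
#' @export
gru_cell <- function(f, h_prev, weights) {
  .gru_step(f, h_prev, weights)$h
}

.gru_step <- function(f, h, w) {
  if (length(f) != ncol(w$Wz) || length(h) != ncol(w$Uz)) {
    stopf("GRU input/hidden dimensions do not match the weights")
  }
  z <- .sigmoid(drop(w$Wz %*% f + w$Uz %*% h + w$bz))
  r <- .sigmoid(drop(w$Wr %*% f + w$Ur %*% h + w$br))
  rh <- r * h
  hc <- tanh(drop(w$Wc %*% f + w$Uc %*% rh + w$bc))
  list(h = z * h + (1 - z) * hc, z = z, r = r, hc = hc, rh = rh,
       f = f, h_prev = h)
}

# BPTT through one step: returns gradient contributions and dh_prev, df.
.gru_step_bwd <- function(cache, w, dh) {
  z <- cache$z; r <- cache$r; hc <- cache$hc
  h <- cache$h_prev; f <- cache$f
  dz <- dh * (h - hc)
  dhc <- dh * (1 - z)
  dh_prev <- dh * z
  dhc_pre <- dhc * (1 - hc^2)
  drh <- drop(crossprod(w$Uc, dhc_pre))
  dr <- drh * h
  dh_prev <- dh_prev + drh * r
  dz_pre <- dz * z * (1 - z)
  dr_pre <- dr * r * (1 - r)
  dh_prev <- dh_prev + drop(crossprod(w$Uz, dz_pre)) +
    drop(crossprod(w$Ur, dr_pre))
  df <- drop(crossprod(w$Wz, dz_pre)) + drop(crossprod(w$Wr, dr_pre)) +
    drop(crossprod(w$Wc, dhc_pre))
  grads <- list(
    Wz = dz_pre %o% f, Uz = dz_pre %o% h, bz = dz_pre,
    Wr = dr_pre %o% f, Ur = dr_pre %o% h, br = dr_pre,
    Wc = dhc_pre %o% f, Uc = dhc_pre %o% cache$rh, bc = dhc_pre
  )
  list(grads = grads, dh_prev = dh_prev, df = df)
}

# ---- parameter initialisation --------------------------------------------

.unif_init <- function(nr, nc, fan_in) {
  lim <- 1 / sqrt(max(fan_in, 1))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialise CNN-GRU parameters
#'
#' Uniform fan-in scaled initialisation (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`)
#' for all weights; biases start at zero.
#'
#' @param config A [network_config()].
#' @param seed Integer seed.
#' @return Parameter list with components `conv`, `gru`, `dense`.
#' @export
init_params <- function(config, seed = 1) {
  with_seed(seed, {
    cin <- 1L
    conv <- lapply(config$conv_blocks, function(b) {
      fan <- b$kernel * cin
      K <- array(stats::runif(b$kernel * cin * b$filters,
                              -1 / sqrt(fan), 1 / sqrt(fan)),
                 dim = c(b$kernel, cin, b$filters))
      out <- list(K = K, b = rep(0, b$filters), stride = b$stride %||% 1)
      cin <<- b$filters
      out
    })
    p <- config$flat_dim
    q <- config$gru_hidden
    gru <- list(
      Wz = .unif_init(q, p, p), Uz = .unif_init(q, q, q), bz = rep(0, q),
      Wr = .unif_init(q, p, p), Ur = .unif_init(q, q, q), br = rep(0, q),
      Wc = .unif_init(q, p, p), Uc = .unif_init(q, q, q), bc = rep(0, q)
    )
    sizes <- c(q, config$dense_sizes, config$n_labels)
    dense <- lapply(seq_len(length(sizes) - 1), function(i) {
      list(W = .unif_init(sizes[i + 1], sizes[i], sizes[i]),
           b = rep(0, sizes[i + 1]))
    })
    list(conv = conv, gru = gru, dense = dense)
  })
}

# ---- full forward / backward ---------------------------------------------

# Forward pass for one record's window matrix M (T x C). Returns per-label
# probabilities and, when `keep = TRUE`, every cache needed for backprop.
.net_forward <- function(M, params, config, keep = FALSE) {
  M <- as.matrix(M)
  T_ <- nrow(M)
  if (T_ < 1) stopf("window matrix has no rows")
  if (ncol(M) != config$input_channels) {
    stopf("window matrix has %d columns, config expects %d",
          ncol(M), config$input_channels)
  }
  caches <- if (keep) vector("list", T_) else NULL
  feats <- matrix(0, T_, config$flat_dim)
  for (t in seq_len(T_)) {
    A <- matrix(M[t, ], ncol = 1)
    tc <- list()
    for (l in seq_along(params$conv)) {
      pl <- params$conv[[l]]
      cf <- .conv_fwd(A, pl$K, pl$b, pl$stride, config$padding, "relu")
      pf <- .pool_fwd(cf$out, config$pool_size, config$pool_stride)
      if (keep) tc[[l]] <- list(conv = cf, pool = pf)
      A <- pf$out
    }
    feats[t, ] <- as.vector(A)
    if (keep) caches[[t]] <- list(blocks = tc, out_dim = dim(A))
  }
  q <- config$gru_hidden
  h <- rep(0, q)
  gru_caches <- if (keep) vector("list", T_) else NULL
  for (t in seq_len(T_)) {
    st <- .gru_step(feats[t, ], h, params$gru)
    if (keep) gru_caches[[t]] <- st
    h <- st$h
  }
  a <- h
  dense_caches <- if (keep) vector("list", length(params$dense)) else NULL
  n_dense <- length(params$dense)
  for (i in seq_len(n_dense)) {
    pre <- drop(params$dense[[i]]$W %*% a + params$dense[[i]]$b)
    out <- if (i < n_dense) pmax(pre, 0) else pre
    if (keep) dense_caches[[i]] <- list(a_in = a, pre = pre)
    a <- out
  }
  yhat <- .sigmoid(a)
  list(prob = yhat, feats = feats, caches = caches, gru_caches = gru_caches,
       dense_caches = dense_caches, h_final = h)
}

# Backward pass for one record; returns gradients shaped like `params`.
# dlogits = yhat - y is the exact gradient of summed per-label BCE through
# the sigmoid.
.net_backward <- function(fw, y, params, config) {
  dlog <- fw$prob - y
  n_dense <- length(params$dense)
  dense_g <- vector("list", n_dense)
  da <- dlog
  for (i in rev(seq_len(n_dense))) {
    cache <- fw$dense_caches[[i]]
    dpre <- if (i < n_dense) da * (cache$pre > 0) else da
    dense_g[[i]] <- list(W = dpre %o% cache$a_in, b = dpre)
    da <- drop(crossprod(params$dense[[i]]$W, dpre))
  }
  # BPTT
  q <- config$gru_hidden
  T_ <- length(fw$gru_caches)
  gru_g <- list(
    Wz = 0 * params$gru$Wz, Uz = 0 * params$gru$Uz, bz = 0 * params$gru$bz,
    Wr = 0 * params$gru$Wr, Ur = 0 * params$gru$Ur, br = 0 * params$gru$br,
    Wc = 0 * params$gru$Wc, Uc = 0 * params$gru$Uc, bc = 0 * params$gru$bc
  )
  dfeats <- matrix(0, T_, config$flat_dim)
  dh <- da
  for (t in rev(seq_len(T_))) {
    bw <- .gru_step_bwd(fw$gru_caches[[t]], params$gru, dh)
    for (nm in names(gru_g)) gru_g[[nm]] <- gru_g[[nm]] + bw$grads[[nm]]
    dfeats[t, ] <- bw$df
    dh <- bw$dh_prev
  }
  # conv blocks per timestamp
  conv_g <- lapply(params$conv, function(pl) list(K = 0 * pl$K, b = 0 * pl$b))
  for (t in seq_len(T_)) {
    tc <- fw$caches[[t]]
    dA <- matrix(dfeats[t, ], tc$out_dim[1], tc$out_dim[2])
    for (l in rev(seq_along(params$conv))) {
      blk <- tc$blocks[[l]]
      dPool <- .pool_bwd(blk$pool, dA)
      bw <- .conv_bwd(blk$conv, params$conv[[l]]$K, dPool)
      conv_g[[l]]$K <- conv_g[[l]]$K + bw$dK
      conv_g[[l]]$b <- conv_g[[l]]$b + bw$db
      dA <- bw$dA
    }
  }
  list(conv = conv_g, gru = gru_g, dense = dense_g)
}

#' Forward pass: per-label probabilities for one window matrix
#'
#' @param M Window-feature matrix (rows = windows, columns matching the
#'   config's `input_channels`).
#' @param params Parameters from [init_params()] or a fitted model's
#'   `$params`.
#' @param config The [network_config()].
#' @return Numeric vector of m probabilities in (0, 1).
#' @export
nn_forward <- function(M, params, config) {
  .net_forward(M, params, config)$prob
}

#' Multi-label cross-entropy loss
#'
#' Mean over instances of the summed per-label binary cross-entropy
#' `-[y log(p) + (1 - y) log(1 - p)]`, with probabilities clamped to
#' `[1e-12, 1 - 1e-12]`.
#'
#' @param Y n x m binary matrix (or vector for one instance).
#' @param P n x m probability matrix, same shape.
#' @return Scalar loss.
#' @export
nn_loss <- function(Y, P) {
  Y <- rbind(Y); P <- rbind(P)
  if (!all(dim(Y) == dim(P))) stopf("Y and P must have identical shape")
  eps <- 1e-12
  P <- pmin(pmax(P, eps), 1 - eps)
  mean(rowSums(-(Y * log(P) + (1 - Y) * log(1 - P))))
}

.apply_grads <- function(params, grads, lr, scale) {
  for (l in seq_along(params$conv)) {
    params$conv[[l]]$K <- params$conv[[l]]$K - lr * grads$conv[[l]]$K / scale
    params$conv[[l]]$b <- params$conv[[l]]$b - lr * grads$conv[[l]]$b / scale
  }
  for (nm in names(params$gru)) {
    params$gru[[nm]] <- params$gru[[nm]] - lr * grads$gru[[nm]] / scale
  }
  for (i in seq_along(params$dense)) {
    params$dense[[i]]$W <- params$dense[[i]]$W - lr * grads$dense[[i]]$W / scale
    params$dense[[i]]$b <- params$dense[[i]]$b - lr * grads$dense[[i]]$b / scale
  }
  params
}

.zero_like <- function(params) {
  list(
    conv = lapply(params$conv, function(pl) list(K = 0 * pl$K, b = 0 * pl$b)),
    gru = lapply(params$gru, function(x) 0 * x),
    dense = lapply(params$dense, function(pl) list(W = 0 * pl$W, b = 0 * pl$b))
  )
}

.acc_grads <- function(acc, g) {
  for (l in seq_along(acc$conv)) {
    acc$conv[[l]]$K <- acc$conv[[l]]$K + g$conv[[l]]$K
    acc$conv[[l]]$b <- acc$conv[[l]]$b + g$conv[[l]]$b
  }
  for (nm in names(acc$gru)) acc$gru[[nm]] <- acc$gru[[nm]] + g$gru[[nm]]
  for (i in seq_along(acc$dense)) {
    acc$dense[[i]]$W <- acc$dense[[i]]$W + g$dense[[i]]$W
    acc$dense[[i]]$b <- acc$dense[[i]]$b + g$dense[[i]]$b
  }
  acc
}

#' Train the CNN-GRU classifier
#'
#' Minibatch stochastic gradient descent on the multi-label cross-entropy.
#' Deterministic given the training config's seed (initialisation and
#' epoch shuffling both derive from it).
#'
#' @param matrices List of window-feature matrices, one per record.
#' @param Y n x m binary label matrix, rows aligned with `matrices`.
#' @param config A [network_config()]; built automatically when `NULL`.
#' @param tc A [train_config()].
#' @param validation Optional list with `matrices` and `Y` for
#'   early-stopping on validation loss.
#' @param params Optional warm-start parameters (e.g. a previous fit's
#'   `$params`); fresh seeded initialisation when `NULL`.
#' @param verbose Print per-epoch losses.
#' @return A `cnn_gru_model`: list with `params`, `config`, `loss_trace`
#'   (training loss per epoch), `val_trace`, `epochs_run`.
#' @export
cnn_gru_train <- function(matrices, Y, config = NULL, tc = train_config(),
                          validation = NULL, params = NULL, verbose = FALSE) {
  Y <- as.matrix(Y)
  n <- length(matrices)
  if (!n) stopf("empty training set")
  if (nrow(Y) != n) stopf("label matrix rows must match the number of records")
  config <- config %||% network_config(ncol(Y), ncol(matrices[[1]]))
  params <- params %||% init_params(config, seed = tc$seed)
  loss_trace <- numeric(0)
  val_trace <- numeric(0)
  best_val <- Inf
  best_params <- params
  wait <- 0L

  epoch_seeds <- with_seed(tc$seed, sample.int(.Machine$integer.max %/% 2L, tc$epochs))
  for (ep in seq_len(tc$epochs)) {
    ord <- with_seed(epoch_seeds[ep], sample.int(n))
    ep_loss <- 0
    for (b0 in seq(1, n, by = tc$batch_size)) {
      idx <- ord[b0:min(b0 + tc$batch_size - 1, n)]
      acc <- .zero_like(params)
      for (i in idx) {
        fw <- .net_forward(matrices[[i]], params, config, keep = TRUE)
        ep_loss <- ep_loss + nn_loss(Y[i, ], fw$prob)
        acc <- .acc_grads(acc, .net_backward(fw, Y[i, ], params, config))
      }
      params <- .apply_grads(params, acc, tc$learning_rate, length(idx))
    }
    ep_loss <- ep_loss / n
    if (!is.finite(ep_loss)) {
      stopf("training diverged at epoch %d (loss %g); lower the learning rate",
            ep, ep_loss)
    }
    loss_trace <- c(loss_trace, ep_loss)
    if (!is.null(validation)) {
      P <- t(vapply(validation$matrices, function(M)
        .net_forward(M, params, config)$prob, numeric(config$n_labels)))
      vl <- nn_loss(validation$Y, P)
      val_trace <- c(val_trace, vl)
      if (vl < best_val - 1e-9) {
        best_val <- vl
        best_params <- params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= tc$patience) {
          params <- best_params
          if (verbose) message(sprintf("early stop at epoch %d", ep))
          break
        }
      }
    }
    if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, ep_loss))
  }
  structure(
    list(params = params, config = config, loss_trace = loss_trace,
         val_trace = val_trace, epochs_run = length(loss_trace),
         train_config = tc),
    class = "cnn_gru_model"
  )
}

#' Predict multi-label probabilities or binary labels
#'
#' @param object A fitted `cnn_gru_model`.
#' @param matrices List of window-feature matrices.
#' @param threshold Probability cut-off for binarisation; probabilities
#'   `>= threshold` map to 1.
#' @param type `"class"` (binary matrix, default) or `"prob"`.
#' @param ... Unused.
#' @return n x m matrix of {0,1} labels or probabilities.
#' @export
predict.cnn_gru_model <- function(object, matrices, threshold = 0.5,
                                  type = c("class", "prob"), ...) {
  type <- match.arg(type)
  P <- t(vapply(matrices, function(M)
    .net_forward(M, object$params, object$config)$prob,
    numeric(object$config$n_labels)))
  if (type == "prob") return(P)
  (P >= threshold) * 1L
}

#' @export
print.cnn_gru_model <- function(x, ...) {
  cat(sprintf("<cnn_gru_model> %d conv blocks -> GRU(%d) -> dense(%s) -> %d sigmoid labels\n",
              length(x$config$conv_blocks), x$config$gru_hidden,
              paste(x$config$dense_sizes, collapse = ", "),
              x$config$n_labels))
  cat(sprintf("trained %d epochs, final loss %.5f\n", x$epochs_run,
              x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Tidy a fitted CNN-GRU model
#'
#' @param x A `cnn_gru_model`.
#' @param ... Unused.
#' @return Tibble of per-epoch training (and validation) losses.
#' @method tidy cnn_gru_model
#' @export
tidy.cnn_gru_model <- function(x, ...) {
  out <- tibble::tibble(epoch = seq_along(x$loss_trace),
                        train_loss = x$loss_trace)
  if (length(x$val_trace)) out$val_loss <- x$val_trace[seq_len(nrow(out))]
  out
}

#' Glance at a fitted CNN-GRU model
#'
#' @param x A `cnn_gru_model`.
#' @param ... Unused.
#' @return One-row tibble with final losses, epoch count and layer summary.
#' @method glance cnn_gru_model
#' @export
glance.cnn_gru_model <- function(x, ...) {
  tibble::tibble(
    epochs = x$epochs_run,
    final_loss = x$loss_trace[length(x$loss_trace)],
    final_val_loss = if (length(x$val_trace)) x$val_trace[length(x$val_trace)] else NA_real_,
    gru_hidden = x$config$gru_hidden,
    n_labels = x$config$n_labels
  )
}

#' Plot the training loss trace
#'
#' @param object A `cnn_gru_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cnn_gru_model
#' @export
autoplot.cnn_gru_model <- function(object, ...) {
  df <- tidy(object)
  df_long <- tidyr::pivot_longer(df, -"epoch", names_to = "series",
                                 values_to = "loss")
  ggplot2::ggplot(df_long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                        colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "CNN-GRU training loss") +
    ggplot2::theme_minimal()
}
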