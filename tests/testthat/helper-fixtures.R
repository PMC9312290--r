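# Shared fixtures, built once per test run and memoised.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

normal_record <- function() {
  fixture("normal", function() {
    generate_record(rhythm_spec("Normal", heart_rate_bpm = 60, rr_jitter = 0),
                    duration_s = 10, fs = 500, noise_sd = 0, seed = 1)
  })
}

af_record <- function() {
  fixture("af", function() {
    generate_record(rhythm_spec("AF"), duration_s = 10, fs = 500,
                    noise_sd = 0, seed = 4)
  })
}

pvc_record <- function() {
  fixture("pvc", function() {
    generate_record(rhythm_spec("PVC"), duration_s = 10, fs = 500,
                    noise_sd = 0, seed = 5)
  })
}

# Template bump offsets (samples at 500 Hz) used by delineation accuracy
# tests; mirrors the generator's archetypal beat.
template_offsets <- function(fs = 500) {
  c(p = -0.160, q = -0.035, r = 0, s = 0.035, t = 0.250) * fs
}

# Brute-force sample entropy: direct template counting with explicit loops.
# Independent of the package implementation.
oracle_sampen <- function(x, m, r_abs) {
  n <- length(x)
  count_m <- function(mm) {
    cnt <- 0L
    for (i in 1:(n - m)) {
      for (j in 1:(n - m)) {
        if (i >= j) next
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r_abs) cnt <- cnt + 1L
      }
    }
    cnt
  }
  B <- count_m(m)
  A <- count_m(m + 1)
  -log(A / B)
}

# Scalar-loop 1-D convolution oracle (valid cross-correlation + padding).
oracle_conv <- function(A, K, b, stride = 1, padding = "valid",
                        activation = "identity") {
  if (is.vector(A)) A <- matrix(A, ncol = 1)
  k <- dim(K)[1]; cin <- dim(K)[2]; cout <- dim(K)[3]
  pad_l <- 0; pad_r <- 0
  if (padding == "same") {
    pad_l <- (k - 1) %/% 2
    pad_r <- (k - 1) - pad_l
  }
  Ap <- rbind(matrix(0, pad_l, cin), A, matrix(0, pad_r, cin))
  L_out <- (nrow(Ap) - k) %/% stride + 1
  out <- matrix(0, L_out, cout)
  for (o in seq_len(cout)) {
    for (i in seq_len(L_out)) {
      acc <- b[o]
      for (j in seq_len(k)) {
        for (c0 in seq_len(cin)) {
          acc <- acc + Ap[(i - 1) * stride + j, c0] * K[j, c0, o]
        }
      }
      out[i, o] <- if (activation == "relu") max(acc, 0) else acc
    }
  }
  out
}

oracle_pool <- function(G, size = 2, stride = 2) {
  if (is.vector(G)) G <- matrix(G, ncol = 1)
  L <- nrow(G)
  n_out <- (L - size) %/% stride + 1
  out <- matrix(0, n_out, ncol(G))
  for (i in seq_len(n_out)) {
    for (c0 in seq_len(ncol(G))) {
      out[i, c0] <- max(G[((i - 1) * stride + 1):((i - 1) * stride + size), c0])
    }
  }
  out
}

# Scalar GRU oracle: one step computed element by element.
oracle_gru <- function(f, h, w) {
  q <- length(h)
  sig <- function(v) 1 / (1 + exp(-v))
  z <- r <- hc <- hn <- numeric(q)
  for (i in seq_len(q)) {
    z[i] <- sig(sum(w$Wz[i, ] * f) + sum(w$Uz[i, ] * h) + w$bz[i])
    r[i] <- sig(sum(w$Wr[i, ] * f) + sum(w$Ur[i, ] * h) + w$br[i])
  }
  for (i in seq_len(q)) {
    hc[i] <- tanh(sum(w$Wc[i, ] * f) + sum(w$Uc[i, ] * (r * h)) + w$bc[i])
    hn[i] <- z[i] * h[i] + (1 - z[i]) * hc[i]
  }
  hn
}

random_gru_weights <- function(q, p) {
  rand <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.5), nr, nc)
  list(Wz = rand(q, p), Uz = rand(q, q), bz = stats::rnorm(q),
       Wr = rand(q, p), Ur = rand(q, q), br = stats::rnorm(q),
       Wc = rand(q, p), Uc = rand(q, q), bc = stats::rnorm(q))
}

random_label_matrix <- function(n, m, p = 0.4) {
  Y <- matrix(stats::rbinom(n * m, 1, p), n, m)
  for (i in which(rowSums(Y) == 0)) Y[i, sample(m, 1)] <- 1
  for (j in which(colSums(Y) == 0)) Y[sample(n, 1), j] <- 1
  Y
}
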