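test_that("cosine label similarity matches hand values", {
  Y <- cbind(a = c(1, 1, 0), b = c(1, 1, 0), c = c(0, 0, 1),
             d = c(1, 0, 1))
  S <- cosine_label_similarity(Y)
  expect_equal(S["a", "b"], 1)
  expect_equal(S["a", "c"], 0)
  expect_equal(S["a", "d"], 0.5) # dot 1 over sqrt(2) * sqrt(2)
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, 4))
  expect_error(cosine_label_similarity(cbind(c(1, 1), c(0, 0))), "degenerate")
})

test_that("the KNN instance graph is symmetric with sensible weights", {
  X <- matrix(c(0, 1, 10), ncol = 1)
  C <- knn_instance_similarity(X, k = 1)
  expect_equal(C, t(C))
  expect_equal(unname(diag(C)), rep(0, 3))
  expect_gt(C[1, 2], 0) # middle point links to its nearest endpoint
  expect_equal(C[1, 3], 0)

  Xd <- rbind(matrix(rnorm(10), 5, 2), matrix(rnorm(10), 5, 2))
  Xd[2, ] <- Xd[1, ] # exact duplicates
  Cd <- knn_instance_similarity(Xd, k = 3)
  expect_equal(Cd[1, 2], max(Cd[1, ])) # zero distance gets maximal weight

  Cf <- knn_instance_similarity(matrix(rnorm(12), 6, 2), k = 5)
  expect_true(all(Cf[upper.tri(Cf)] > 0)) # k = n - 1 connects everything
  expect_error(knn_instance_similarity(matrix(rnorm(6), 3, 2), k = 3), "k")
})

test_that("the Laplacian satisfies the textbook identities", {
  A <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(graph_laplacian(A), matrix(c(1, -1, -1, 1), 2, 2))
  set.seed(31)
  for (i in 1:5) {
    B <- matrix(runif(25), 5, 5)
    B <- (B + t(B)) / 2
    diag(B) <- 0
    L <- graph_laplacian(B)
    expect_lt(max(abs(L %*% rep(1, 5))), 1e-12)
    expect_gt(min(eigen(L, symmetric = TRUE)$values), -1e-9)
  }
  expect_error(graph_laplacian(matrix(1:4, 2, 2)), "symmetric")
})

test_that("the objective equals its five-term hand computation", {
  set.seed(7)
  X <- matrix(rnorm(60), 12, 5)
  Y <- random_label_matrix(12, 3)
  W0 <- matrix(0, 5, 3)
  expect_equal(mlfs_objective(X, Y, W0), sum(Y^2))

  W <- matrix(rnorm(15), 5, 3)
  base <- mlfs_objective(X, Y, W, gamma2 = 0.3)
  expect_equal(mlfs_objective(X, Y, W, gamma2 = 0.6),
               base + 0.3 * sum(abs(W)))

  # all penalties zero at the least-squares solution: residual sum of
  # squares from the normal equations
  W_ls <- solve(crossprod(X), crossprod(X, Y))
  expect_equal(mlfs_objective(X, Y, W_ls), sum((X %*% W_ls - Y)^2),
               tolerance = 1e-8)
  expect_error(mlfs_objective(X, Y, W, alpha = -1), "nonnegative")

  # norm helpers against direct summation
  expect_equal(norm_l21(W), sum(apply(W, 1, function(r) sqrt(sum(r^2)))),
               tolerance = 1e-12)
  expect_equal(norm_l1(W), sum(abs(W)), tolerance = 1e-12)
})

test_that("the solver hits the closed-form and penalty-dominated limits", {
  set.seed(11)
  X <- matrix(rnorm(500), 50, 10)
  Y <- random_label_matrix(50, 3)
  fit <- mlfs_fit(X, Y, alpha = 0, beta = 0, gamma1 = 0, gamma2 = 0,
                  max_iter = 3000, tol = 1e-13)
  W_ls <- solve(crossprod(X), crossprod(X, Y))
  expect_lt(max(abs(fit$W - W_ls)), 1e-5)

  fit0 <- mlfs_fit(X, Y, alpha = 0, beta = 0, gamma1 = 1e6, gamma2 = 1e6,
                   max_iter = 50)
  expect_equal(unname(fit0$W), matrix(0, 10, 3))
})

test_that("the objective trace never increases", {
  set.seed(13)
  for (i in 1:5) {
    X <- standardize_columns(matrix(rnorm(40 * 8), 40, 8))$X
    Y <- random_label_matrix(40, 4)
    fit <- mlfs_fit(X, Y, alpha = 0.2, beta = 0.2, gamma1 = 0.3,
                    gamma2 = 0.1, k_neighbors = 5, max_iter = 150)
    expect_true(all(diff(fit$trace) <= 1e-8))
  }
})

test_that("feature ranking follows row norms with index tie-breaks", {
  W <- matrix(0, 4, 2)
  W[3, ] <- c(1, 1)
  expect_equal(rank_features(W)[1], 3)

  W2 <- rbind(c(1, 1), c(5, 0), c(0, 5)) # rows 2 and 3 tie at norm 5
  expect_equal(rank_features(W2), c(2, 3, 1))

  set.seed(17)
  W3 <- matrix(rnorm(40), 10, 4)
  expect_equal(rank_features(W3),
               order(-sqrt(rowSums(W3^2)), seq_len(10)))
})

test_that("top-k selection preserves rank order and validates k", {
  set.seed(19)
  X <- standardize_columns(matrix(rnorm(200), 20, 10))$X
  colnames(X) <- paste0("feat", 1:10)
  Y <- random_label_matrix(20, 3)
  fit <- mlfs_fit(X, Y, alpha = 0, beta = 0, gamma1 = 0.05, gamma2 = 0.05)
  expect_identical(select_top_k(fit, 10), fit$ranking$feature)
  expect_identical(select_top_k(fit, 1), fit$ranking$feature[1])
  expect_error(select_top_k(fit, 11), "k")
  expect_error(select_top_k(fit, 0), "k")
})

test_that("permuting feature columns permutes the ranking identically", {
  set.seed(23)
  X <- standardize_columns(matrix(rnorm(30 * 6), 30, 6))$X
  colnames(X) <- paste0("f", 1:6)
  Y <- random_label_matrix(30, 3)
  fit1 <- mlfs_fit(X, Y, alpha = 0.1, beta = 0.1, gamma1 = 0.1,
                   gamma2 = 0.1, k_neighbors = 5)
  perm <- c(4, 1, 6, 2, 5, 3)
  fit2 <- mlfs_fit(X[, perm], Y, alpha = 0.1, beta = 0.1, gamma1 = 0.1,
                   gamma2 = 0.1, k_neighbors = 5)
  # the step-size probe is not permutation-covariant, so iterates agree only
  # approximately; the ranking must agree exactly
  expect_equal(unname(fit2$W), unname(fit1$W[perm, ]), tolerance = 1e-3)
  expect_identical(fit2$ranking$feature, fit1$ranking$feature)
})

test_that("planted sparse rows are recovered into the top ranks", {
  set.seed(29)
  n <- 200; d <- 40; m <- 4
  X <- standardize_columns(matrix(rnorm(n * d), n, d))$X
  supp <- sample(d, 5)
  Wstar <- matrix(0, d, m)
  Wstar[supp, ] <- matrix(rnorm(5 * m), 5, m)
  S <- X %*% Wstar
  Y <- S + matrix(rnorm(n * m, sd = sqrt(var(as.vector(S)) / 10)), n, m)
  fit <- suppressWarnings( # support recovery, not convergence, is tested
    mlfs_fit(X, Y, alpha = 0, beta = 0, gamma1 = 0.5, gamma2 = 0.1,
             max_iter = 300))
  top <- rank_features(fit$W)[1:10]
  expect_gte(length(intersect(top, supp)), 4)
})

test_that("tidy, glance and the selection report expose the fit", {
  set.seed(37)
  X <- standardize_columns(matrix(rnorm(30 * 118), 30, 118))$X
  colnames(X) <- feature_catalog()$name
  Y <- random_label_matrix(30, 3)
  fit <- suppressWarnings( # short run; the tidiers, not convergence, matter
    mlfs_fit(X, Y, alpha = 0, beta = 0, gamma1 = 0.1, gamma2 = 0.1,
             max_iter = 100))
  td <- tidy(fit)
  expect_equal(nrow(td), 118)
  expect_true(all(c("rank", "feature", "row_norm", "category", "selected")
                  %in% names(td)))
  expect_equal(sum(td$selected), 20)
  gl <- glance(fit)
  expect_equal(gl$objective, fit$trace[length(fit$trace)])

  json <- withr::local_tempfile(fileext = ".json")
  write_selection_report(fit, json)
  back <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(back$ranking$feature[1], td$feature[1])
})
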