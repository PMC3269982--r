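toy_set <- function() {
  # fixed 6-point 2-D toy set, linearly non-separable after overlap
  tibble::tibble(
    x1 = c(-1.2, -0.8, -1.0, 0.9, 1.1, 0.4),
    x2 = c(-0.5, -1.1, 0.6, 0.8, -0.2, 0.1),
    label = c(-1, -1, -1, 1, 1, 1)
  )
}

libsvm_reference <- function(data, cost, gamma_pkg) {
  # independent dual solver; e1071 parameterizes the kernel as
  # exp(-g ||.||^2), so g = 1 / (2 gamma^2)
  X <- as.matrix(data[, c("x1", "x2")])
  fit <- e1071::svm(
    x = X, y = factor(data$label, levels = c(-1, 1)),
    kernel = "radial", gamma = 1 / (2 * gamma_pkg^2), cost = cost,
    scale = FALSE, tolerance = 1e-10
  )
  score <- function(newX) {
    dv <- attr(predict(fit, newX, decision.values = TRUE), "decision.values")
    sgn <- if (colnames(dv)[1] == "-1/1") -1 else 1
    sgn * as.vector(dv)
  }
  alpha_full <- numeric(nrow(X))
  alpha_full[fit$index] <- abs(as.vector(fit$coefs))
  list(score = score, alpha = alpha_full)
}

test_that("the RBF kernel follows the 2 gamma^2 convention and is positive semi-definite", {
  x <- c(0.3, -1.2)
  expect_equal(rbf_kernel(x, x), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 1), gamma = 1), exp(-1))
  expect_equal(rbf_kernel(c(0, 0), c(2, 0), gamma = 2), exp(-4 / 8))
  expect_equal(rbf_kernel(x, c(1, 1)), rbf_kernel(c(1, 1), x))
  expect_error(rbf_kernel(x, x, gamma = 0), "positive")

  set.seed(61)
  P <- matrix(rnorm(10), 5, 2)
  K <- outer(1:5, 1:5, Vectorize(function(i, j) rbf_kernel(P[i, ], P[j, ])))
  expect_gte(min(eigen(K, symmetric = TRUE)$values), -1e-10)
  expect_true(all(K > 0 & K <= 1))
})

test_that("training satisfies the dual constraints and the minimal separable case", {
  d2 <- tibble::tibble(x1 = c(-1, 1), x2 = c(0, 0), label = c(-1, 1))
  m2 <- train_svm(d2, cost = 10, gamma = 1, scale = FALSE)
  expect_length(m2$alphas, 2L)
  expect_equal(m2$alphas[1], m2$alphas[2], tolerance = 1e-8)
  sc <- decision_score(m2, d2)
  expect_equal(sc, c(-1, 1), tolerance = 1e-6)
  expect_equal(ifelse(sc >= 0, 1, -1), d2$label)

  set.seed(62)
  for (cost in c(0.5, 1, 5)) {
    d <- generate_feature_cohort(cohort_spec(n_low = 15, n_normal = 15, seed = 62))
    m <- train_svm(d, cost = cost)
    expect_lt(abs(sum(m$alphas * m$labels)), 1e-6)
    expect_true(all(m$alphas >= 0 & m$alphas <= cost + 1e-12))
  }

  one_class <- tibble::tibble(x1 = rnorm(5), x2 = rnorm(5), label = rep(1, 5))
  expect_error(train_svm(one_class), "both classes")
})

test_that("dual objective, coefficients and scores agree with an independent QP solver", {
  d <- toy_set()
  for (cost in c(1, 10)) {
    m <- train_svm(d, feature_cols = c("x1", "x2"), cost = cost, gamma = 1, scale = FALSE)
    ref <- libsvm_reference(d, cost, 1)
    # same dual solution
    alpha_full <- numeric(nrow(d))
    sv_rows <- match(
      apply(m$support_vectors, 1, paste, collapse = ","),
      apply(as.matrix(d[, c("x1", "x2")]), 1, paste, collapse = ",")
    )
    alpha_full[sv_rows] <- m$alphas
    expect_equal(alpha_full, ref$alpha, tolerance = 1e-4)
    # same dual objective
    K <- rbf_kernel_matrix_for_test(as.matrix(d[, c("x1", "x2")]))
    y <- d$label
    obj <- function(a) sum(a) - 0.5 * as.numeric(t(a * y) %*% K %*% (a * y))
    expect_equal(obj(alpha_full), obj(ref$alpha), tolerance = 1e-4)
    expect_equal(m$objective, obj(ref$alpha), tolerance = 1e-4)
    # same decision scores on a grid of new points
    set.seed(63)
    grid <- matrix(runif(20, -1.5, 1.5), 10, 2)
    colnames(grid) <- c("x1", "x2")
    expect_equal(decision_score(m, grid), ref$score(grid), tolerance = 1e-4)
  }
})

test_that("a margin support vector scores +/- 1 and scores match term-by-term recomputation", {
  set.seed(64)
  d <- generate_feature_cohort(cohort_spec(n_low = 20, n_normal = 20, seed = 64))
  m <- train_svm(d)
  free <- which(m$alphas > 1e-6 & m$alphas < m$cost - 1e-6)
  expect_gt(length(free), 0L)
  Xs_sv <- m$support_vectors
  # naive expanded recomputation of the decision sum
  naive_score <- function(z) {
    acc <- 0
    for (i in seq_along(m$alphas)) {
      acc <- acc + m$alphas[i] * m$labels[i] *
        exp(-sum((z - Xs_sv[i, ])^2) / (2 * m$gamma^2))
    }
    acc + m$bias
  }
  for (i in head(free, 3)) {
    expect_equal(abs(naive_score(Xs_sv[i, ])), 1, tolerance = 1e-5)
  }
  pts <- d[sample(nrow(d), 5), ]
  mine <- decision_score(m, pts)
  Z <- sweep(sweep(as.matrix(pts[, c("mean_width_mm", "var_width_mm2")]),
    2, m$center
  ), 2, m$scale, "/")
  expect_equal(mine, apply(Z, 1, naive_score), tolerance = 1e-10)
})

test_that("training hinge loss never increases with the cost parameter", {
  d <- toy_set()
  d$x1[1] <- 0.5 # force overlap so the set is non-separable
  hinge <- sapply(c(0.1, 1, 10), function(cost) {
    m <- train_svm(d, feature_cols = c("x1", "x2"), cost = cost, scale = FALSE)
    f <- decision_score(m, d)
    sum(pmax(0, 1 - d$label * f))
  })
  expect_true(all(diff(hinge) <= 1e-6))
})

test_that("cutoff selection returns the largest threshold meeting the target sensitivity", {
  # perfectly separated scores: the gap cutoff achieves sensitivity 1
  sep_scores <- c(-3, -2, -1.5, 1, 2, 2.5)
  sep_labels <- c(-1, -1, -1, 1, 1, 1)
  op <- choose_cutoff(sep_scores, sep_labels, target_sensitivity = 1)
  expect_equal(op$cutoff, (-1.5 + 1) / 2)
  expect_equal(op$achieved_sensitivity, 1)

  # 10 positives, target 0.9: at least 9 admitted
  set.seed(65)
  scores <- c(rnorm(10, 1), rnorm(10, -1))
  labels <- rep(c(1, -1), each = 10)
  op2 <- choose_cutoff(scores, labels, 0.9)
  expect_gte(sum(scores[labels == 1] >= op2$cutoff), 9)

  # overlapping scores: matches an exhaustive sweep over all candidates
  for (rep in 1:10) {
    sc <- rnorm(30)
    lb <- sample(c(-1, 1), 30, replace = TRUE, prob = c(0.5, 0.5))
    if (!any(lb == 1)) lb[1] <- 1
    op3 <- choose_cutoff(sc, lb, 0.8)
    u <- sort(unique(sc))
    cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2)
    sens <- sapply(cand, function(ct) mean(sc[lb == 1] >= ct))
    expect_equal(op3$cutoff, max(cand[sens >= 0.8]))
  }

  expect_error(choose_cutoff(scores, labels, 1.2), "target_sensitivity")
  expect_error(choose_cutoff(rnorm(5), rep(-1, 5)), "positive label")
})

test_that("models survive a JSON round-trip with identical scores", {
  d <- generate_feature_cohort(cohort_spec(n_low = 10, n_normal = 10, seed = 66))
  m <- train_svm(d)
  op <- choose_cutoff(decision_score(m, d), d$label, 0.9)
  m <- set_cutoff(m, op, 0.9)
  f <- withr::local_tempfile(fileext = ".json")
  write_svm_model(m, f)
  m2 <- read_svm_model(f)
  expect_equal(decision_score(m2, d), decision_score(m, d), tolerance = 1e-12)
  expect_equal(m2$cutoff, m$cutoff)
  expect_error(read_svm_model(withr::local_tempfile(fileext = ".json", lines = "{}")),
               "not an mcwscreen SVM model")
})
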