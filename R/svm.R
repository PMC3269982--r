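#' Radial basis function kernel
#'
#' `K(xi, xj) = exp(-||xi - xj||^2 / (2 gamma^2))`. Note the `2 gamma^2`
#' denominator (a Gaussian bandwidth parameterization): libraries that
#' write the RBF kernel as `exp(-g ||.||^2)` correspond to
#' `g = 1 / (2 gamma^2)`, so `gamma = 1` here equals `g = 0.5` there.
#'
#' @param xi,xj Numeric feature vectors of equal length.
#' @param gamma Positive kernel width.
#' @return A scalar in `(0, 1]`.
#' @examples
#' rbf_kernel(c(0, 0), c(1, 1), gamma = 1) # exp(-1)
#' @export
rbf_kernel <- function(xi, xj, gamma = 1) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    abort("gamma must be a single positive number")
  }
  if (length(xi) != length(xj) || anyNA(xi) || anyNA(xj)) {
    abort("xi and xj must be finite vectors of equal length")
  }
  exp(-sum((xi - xj)^2) / (2 * gamma^2))
}

# Kernel matrix between the rows of X and Y (Y defaults to X).
rbf_kernel_matrix <- function(X, Y = NULL, gamma = 1) {
  if (is.null(Y)) Y <- X
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-pmax(d2, 0) / (2 * gamma^2))
}

normalize_labels <- function(y) {
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) y <- ifelse(y == 1, 1, -1)
  if (!all(y %in% c(-1, 1))) {
    abort("labels must be coded -1/+1 (or 0/1, mapped to -1/+1)")
  }
  y
}

#' Train a soft-margin RBF support vector machine
#'
#' Maximizes the SVM dual
#' `sum(alpha) - 1/2 sum_ij alpha_i alpha_j y_i y_j K(x_i, x_j)` subject to
#' `sum(alpha_i y_i) = 0` and `0 <= alpha_i <= C`, using a sequential
#' minimal optimization (SMO) solver with maximal-violating-pair working
#' set selection. The bias is the mean KKT estimate over the free (margin)
#' support vectors, `y_i - sum_j alpha_j y_j K(x_i, x_j)`, falling back to
#' the midpoint of the KKT interval when every support vector is at bound.
#'
#' Features are z-scored on the training set by default (the mean width in
#' mm and its variance in mm^2 live on different scales); the transform is
#' stored in the model and applied to new data automatically.
#'
#' @param data A data frame of features plus a label column. Labels may be
#'   coded -1/+1 or 0/1 (0 maps to -1, the normal class; 1 maps to +1, low
#'   bone mineral density).
#' @param feature_cols Character vector of feature column names; default is
#'   every numeric column except the label.
#' @param label_col Name of the label column.
#' @param cost Box constraint `C`.
#' @param gamma RBF width (see [rbf_kernel()]).
#' @param scale Z-score the features on the training set?
#' @param tol KKT violation tolerance for the SMO stopping rule.
#' @param max_iter Iteration cap; exceeding it is a solver error.
#' @return An object of class `mcw_svm`.
#' @examples
#' set.seed(1)
#' d <- generate_feature_cohort(cohort_spec(n_low = 20, n_normal = 20, seed = 1))
#' fit <- train_svm(d)
#' glance(fit)
#' @export
train_svm <- function(data, feature_cols = NULL, label_col = "label",
                      cost = 1, gamma = 1, scale = TRUE,
                      tol = 1e-8, max_iter = 1e6) {
  data <- as.data.frame(data)
  if (!label_col %in% names(data)) {
    abort(paste0("label column '", label_col, "' not found"))
  }
  if (is.null(feature_cols)) {
    feature_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))], label_col)
  }
  if (length(feature_cols) == 0L) abort("no numeric feature columns found")
  X <- as.matrix(data[feature_cols])
  if (anyNA(X) || any(!is.finite(X))) abort("features must be finite")
  y <- normalize_labels(data[[label_col]])
  n <- nrow(X)
  if (n < 2L) abort("at least two training samples are required")
  if (length(unique(y)) < 2L) {
    abort("degenerate training set: both classes must be present")
  }
  if (!is.numeric(cost) || cost <= 0) abort("cost must be positive")

  if (scale) {
    center <- colMeans(X)
    scl <- apply(X, 2L, sd)
    scl[scl == 0] <- 1
  } else {
    center <- rep(0, ncol(X))
    scl <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2L, center), 2L, scl, "/")
  K <- rbf_kernel_matrix(Xs, gamma = gamma)

  sol <- smo_solve(K, y, cost, tol, max_iter)
  alpha <- sol$alpha
  sv_floor <- 1e-8 * cost
  sv <- which(alpha > sv_floor)

  s <- as.vector(K %*% (alpha * y)) # sum_j alpha_j y_j K(x_i, x_j)
  free <- which(alpha > sv_floor & alpha < cost - sv_floor)
  if (length(free) > 0L) {
    b <- mean(y[free] - s[free])
  } else {
    up <- (y == 1 & alpha < cost - sv_floor) | (y == -1 & alpha > sv_floor)
    low <- (y == 1 & alpha > sv_floor) | (y == -1 & alpha < cost - sv_floor)
    b <- (max(y[low] - s[low]) + min(y[up] - s[up])) / 2
  }
  objective <- sum(alpha) - 0.5 * sum((alpha * y) * s)

  structure(
    list(
      support_vectors = Xs[sv, , drop = FALSE],
      alphas = alpha[sv],
      labels = y[sv],
      bias = b,
      gamma = gamma,
      cost = cost,
      center = center,
      scale = scl,
      feature_cols = feature_cols,
      objective = objective,
      iterations = sol$iterations,
      cutoff = 0,
      target_sensitivity = NA_real_,
      n_train = n
    ),
    class = "mcw_svm"
  )
}

# SMO with maximal-violating-pair selection (exact integer-free arithmetic
# on a dense precomputed kernel; n is at most a few hundred here).
smo_solve <- function(K, y, cost, tol, max_iter) {
  n <- length(y)
  alpha <- rep(0, n)
  grad <- rep(-1, n) # gradient of 1/2 a'Qa - sum(a) at a = 0
  Q <- K * tcrossprod(y)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) {
      abort(paste0("SMO did not converge within ", max_iter, " iterations"))
    }
    up <- (y == 1 & alpha < cost) | (y == -1 & alpha > 0)
    low <- (y == 1 & alpha > 0) | (y == -1 & alpha < cost)
    viol_up <- -y * grad
    i <- which(up)[which.max(viol_up[up])]
    j <- which(low)[which.min(viol_up[low])]
    if (viol_up[i] - viol_up[j] < tol) break
    a <- K[i, i] + K[j, j] - 2 * K[i, j]
    t_un <- if (a > 1e-12) (viol_up[i] - viol_up[j]) / a else Inf
    t_max_i <- if (y[i] == 1) cost - alpha[i] else alpha[i]
    t_max_j <- if (y[j] == 1) alpha[j] else cost - alpha[j]
    t_step <- min(t_un, t_max_i, t_max_j)
    d_i <- y[i] * t_step
    d_j <- -y[j] * t_step
    alpha[i] <- alpha[i] + d_i
    alpha[j] <- alpha[j] + d_j
    grad <- grad + Q[, i] * d_i + Q[, j] * d_j
  }
  list(alpha = alpha, iterations = it)
}

#' Decision score of a trained SVM
#'
#' The pre-sign decision value `sum_i alpha_i y_i K(x, x_i) + b`. The
#' predicted class is the sign of the score relative to the model's
#' operating cutoff (default 0), with a tied score classified as +1 (low
#' bone mineral density) — the conservative choice for a screening test.
#'
#' @param model An `mcw_svm` model.
#' @param newdata A data frame containing the model's feature columns, or a
#'   numeric matrix/vector in feature order.
#' @return A numeric vector of scores.
#' @export
decision_score <- function(model, newdata) {
  if (!inherits(model, "mcw_svm")) abort("`model` must be an mcw_svm object")
  X <- coerce_features(model, newdata)
  Xs <- sweep(sweep(X, 2L, model$center), 2L, model$scale, "/")
  Kx <- rbf_kernel_matrix(Xs, model$support_vectors, gamma = model$gamma)
  as.vector(Kx %*% (model$alphas * model$labels)) + model$bias
}

coerce_features <- function(model, newdata) {
  p <- length(model$feature_cols)
  if (is.data.frame(newdata)) {
    missing <- setdiff(model$feature_cols, names(newdata))
    if (length(missing) > 0L) {
      abort(paste0(
        "schema mismatch: feature column(s) ",
        paste(missing, collapse = ", "), " not found in new data"
      ))
    }
    X <- as.matrix(as.data.frame(newdata)[model$feature_cols])
  } else if (is.matrix(newdata)) {
    if (ncol(newdata) != p) abort("schema mismatch: wrong number of feature columns")
    X <- newdata
  } else if (is.numeric(newdata) && length(newdata) == p) {
    X <- matrix(newdata, nrow = 1L)
  } else {
    abort("newdata must be a data frame, matrix, or a single feature vector")
  }
  storage.mode(X) <- "double"
  X
}

#' @param object An `mcw_svm` model.
#' @param cutoff Decision-score threshold; defaults to the model's stored
#'   operating point (0 if none has been set).
#' @param ... Unused.
#' @rdname decision_score
#' @export
predict.mcw_svm <- function(object, newdata, cutoff = NULL, ...) {
  if (is.null(cutoff)) cutoff <- object$cutoff
  score <- decision_score(object, newdata)
  ifelse(score >= cutoff, 1, -1)
}

#' @export
print.mcw_svm <- function(x, ...) {
  cat(sprintf(
    "<mcw_svm> RBF (2*gamma^2 convention) gamma=%g, C=%g; %d support vectors of %d; bias %.4f; cutoff %.4f\n",
    x$gamma, x$cost, length(x$alphas), x$n_train, x$bias, x$cutoff
  ))
  invisible(x)
}

#' Tidy and summarize an SVM fit
#'
#' `tidy()` returns one row per support vector (dual coefficient, label and
#' the standardized feature values); `glance()` returns a one-row model
#' summary with the dual objective, support-vector count and operating
#' point.
#'
#' @param x An `mcw_svm` model.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mcw_svm
#' @export
tidy.mcw_svm <- function(x, ...) {
  sv <- as_tibble(as.data.frame(x$support_vectors))
  names(sv) <- paste0(x$feature_cols, "_scaled")
  dplyr::bind_cols(tibble(alpha = x$alphas, label = x$labels), sv)
}

#' @rdname tidy.mcw_svm
#' @method glance mcw_svm
#' @export
glance.mcw_svm <- function(x, ...) {
  tibble(
    n_train = x$n_train,
    n_support_vectors = length(x$alphas),
    n_bound = sum(x$alphas > x$cost * (1 - 1e-8)),
    bias = x$bias,
    gamma = x$gamma,
    cost = x$cost,
    dual_objective = x$objective,
    iterations = x$iterations,
    cutoff = x$cutoff,
    target_sensitivity = x$target_sensitivity
  )
}

#' Choose the operating cutoff for a target sensitivity
#'
#' Scans the midpoints between consecutive distinct decision scores (plus
#' one candidate below the minimum, which classifies everything positive)
#' and returns the largest cutoff whose sensitivity is at least the target
#' — i.e. the most specific operating point that still meets the required
#' sensitivity. A sample scoring exactly at the cutoff is called positive.
#'
#' @param scores Numeric decision scores.
#' @param labels Labels (-1/+1 or 0/1) aligned with `scores`.
#' @param target_sensitivity Required sensitivity, in `(0, 1]`.
#' @return A list of class `mcw_operating_point` with `cutoff` and
#'   `achieved_sensitivity`.
#' @export
choose_cutoff <- function(scores, labels, target_sensitivity = 0.90) {
  if (!is.numeric(target_sensitivity) || length(target_sensitivity) != 1L ||
      target_sensitivity <= 0 || target_sensitivity > 1) {
    abort("target_sensitivity must be a single value in (0, 1]")
  }
  y <- normalize_labels(labels)
  if (length(scores) != length(y)) abort("scores and labels must have equal length")
  pos <- scores[y == 1]
  if (length(pos) == 0L) abort("at least one positive label is required")
  u <- sort(unique(scores))
  cand <- c(u[1L] - 1, if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2)
  sens <- vapply(cand, function(ct) mean(pos >= ct), numeric(1))
  ok <- which(sens >= target_sensitivity)
  cutoff <- cand[max(ok)]
  structure(
    list(cutoff = cutoff, achieved_sensitivity = sens[max(ok)]),
    class = "mcw_operating_point"
  )
}

#' @export
print.mcw_operating_point <- function(x, ...) {
  cat(sprintf(
    "<mcw_operating_point> cutoff %.4f (training sensitivity %.3f)\n",
    x$cutoff, x$achieved_sensitivity
  ))
  invisible(x)
}

#' Store an operating point in a model
#'
#' @param model An `mcw_svm` model.
#' @param operating_point An `mcw_operating_point` from [choose_cutoff()].
#' @param target_sensitivity The sensitivity that was targeted (recorded
#'   for reporting).
#' @return The model with `cutoff` (and `target_sensitivity`) set.
#' @export
set_cutoff <- function(model, operating_point, target_sensitivity = NA_real_) {
  if (!inherits(model, "mcw_svm")) abort("`model` must be an mcw_svm object")
  if (!inherits(operating_point, "mcw_operating_point")) {
    abort("`operating_point` must come from choose_cutoff()")
  }
  model$cutoff <- operating_point$cutoff
  model$target_sensitivity <- target_sensitivity
  model
}

#' Serialize an SVM model to and from JSON
#'
#' The JSON file stores the support vectors (already standardized), dual
#' coefficients, labels, bias, kernel and cost parameters, the
#' standardization constants and the operating cutoff — everything needed
#' to reproduce decision scores exactly.
#'
#' @param model An `mcw_svm` model.
#' @param path JSON file path.
#' @return `write_svm_model()` returns `path` invisibly; `read_svm_model()`
#'   returns the model.
#' @export
write_svm_model <- function(model, path) {
  if (!inherits(model, "mcw_svm")) abort("`model` must be an mcw_svm object")
  payload <- list(
    format = "mcwscreen-svm",
    version = 1L,
    feature_cols = model$feature_cols,
    support_vectors = unname(apply(model$support_vectors, 1L, identity, simplify = FALSE)),
    alphas = model$alphas,
    labels = model$labels,
    bias = model$bias,
    gamma = model$gamma,
    cost = model$cost,
    center = as.list(setNames(model$center, model$feature_cols)),
    scale = as.list(setNames(model$scale, model$feature_cols)),
    cutoff = model$cutoff,
    target_sensitivity = model$target_sensitivity,
    n_train = model$n_train,
    objective = model$objective
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "mcwscreen-svm") {
    abort(paste0("not an mcwscreen SVM model file: ", path))
  }
  sv <- p$support_vectors
  if (is.list(sv)) {
    sv <- do.call(rbind, lapply(sv, as.numeric))
  } else {
    sv <- matrix(as.numeric(sv), nrow = NROW(sv), ncol = NCOL(sv))
  }
  structure(
    list(
      support_vectors = sv,
      alphas = as.numeric(p$alphas),
      labels = as.numeric(p$labels),
      bias = p$bias,
      gamma = p$gamma,
      cost = p$cost,
      center = unlist(p$center),
      scale = unlist(p$scale),
      feature_cols = p$feature_cols,
      objective = p$objective,
      iterations = NA_integer_,
      cutoff = p$cutoff,
      target_sensitivity = p$target_sensitivity,
      n_train = p$n_train
    ),
    class = "mcw_svm"
  )
}
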