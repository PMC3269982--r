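# Independent brute-force oracles. Each recomputes the quantity under test
# by direct definition (exhaustive search, naive loops), sharing no code
# path with the package implementation.

# Chessboard distance of every foreground pixel to the nearest background
# pixel, with the image border counting as background, by minimising over
# all background positions (border included) explicitly.
oracle_chessboard <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  bg <- which(mask == 0, arr.ind = TRUE)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (mask[i, j] == 0) next
      d <- min(i, j, nr - i + 1L, nc - j + 1L) # to outside the image
      if (nrow(bg) > 0L) {
        d <- min(d, min(pmax(abs(bg[, 1L] - i), abs(bg[, 2L] - j))))
      }
      out[i, j] <- d
    }
  }
  out
}

# Exhaustively enumerate every left-to-right path over the positive span of
# a distance map (row steps in {-1, 0, +1}, positive cells only), return the
# maximal sum and the tie-broken canonical path: among maximal paths, the
# lexicographically smallest by the per-column key (start row first, then
# (|step|, row) at each subsequent column).
oracle_dp <- function(dmap) {
  pos_cols <- which(apply(dmap > 0, 2L, any))
  span <- min(pos_cols):max(pos_cols)
  v <- dmap[, span, drop = FALSE]
  nr <- nrow(v)
  w <- ncol(v)
  if (w == 1L) {
    rows <- which(v[, 1L] > 0)
    best <- max(v[rows, 1L])
    cand <- rows[v[rows, 1L] == best]
    return(list(sum = best, rows = min(cand), span = span))
  }
  steps <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), w - 1L)))
  best_sum <- -Inf
  best_key <- NULL
  best_rows <- NULL
  cums <- steps
  if (ncol(steps) > 1L) {
    for (j in 2:ncol(steps)) cums[, j] <- cums[, j - 1L] + steps[, j]
  }
  for (r0 in seq_len(nr)) {
    rows_mat <- r0 + cbind(0L, cums)
    ok <- rowSums(rows_mat < 1L | rows_mat > nr) == 0L
    if (!any(ok)) next
    rm_ok <- rows_mat[ok, , drop = FALSE]
    st_ok <- steps[ok, , drop = FALSE]
    vals <- matrix(v[cbind(as.vector(rm_ok), rep(seq_len(w), each = nrow(rm_ok)))],
      nrow(rm_ok), w
    )
    feas <- rowSums(vals <= 0) == 0L
    if (!any(feas)) next
    sums <- rowSums(vals[feas, , drop = FALSE])
    rm_f <- rm_ok[feas, , drop = FALSE]
    st_f <- st_ok[feas, , drop = FALSE]
    for (k in seq_along(sums)) {
      key <- c(rm_f[k, 1L], as.vector(rbind(abs(st_f[k, ]), rm_f[k, -1L])))
      if (sums[k] > best_sum ||
        (sums[k] == best_sum && key_less(key, best_key))) {
        best_sum <- sums[k]
        best_key <- key
        best_rows <- rm_f[k, ]
      }
    }
  }
  list(sum = best_sum, rows = best_rows, span = span)
}

key_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

# Per-column envelope of the union of discs placed on the trace, computed
# pointwise with its own rounding helpers.
oracle_envelope <- function(trace, shape, rad) {
  span <- trace$col
  up <- numeric(length(span))
  lo <- numeric(length(span))
  for (ci in seq_along(span)) {
    c_val <- span[ci]
    u <- Inf
    l <- -Inf
    for (k in seq_len(nrow(trace))) {
      dc <- abs(c_val - trace$col[k])
      r <- rad[k]
      if (dc > r) next
      half <- if (shape == "euclidean") sqrt(r^2 - dc^2) else r
      u <- min(u, trace$row[k] - half)
      l <- max(l, trace$row[k] + half)
    }
    # round half away from the band centre
    up[ci] <- if (u %% 1 == 0.5) floor(u) else round(u)
    lo[ci] <- if (l %% 1 == 0.5) ceiling(l) else round(l)
  }
  list(upper = as.integer(up), lower = as.integer(lo))
}

# Otsu threshold by directly computing the between-class variance of the
# two pixel groups at every candidate threshold.
oracle_otsu <- function(image) {
  lev <- as.integer(round(image))
  best_t <- NA_integer_
  best_v <- -Inf
  for (t in 0:255) {
    lower <- lev[lev <= t]
    upper <- lev[lev > t]
    if (length(lower) == 0L || length(upper) == 0L) next
    w0 <- length(lower) / length(lev)
    v <- w0 * (1 - w0) * (mean(lower) - mean(upper))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# Sliding-window mean by explicit window extraction with replicated edges.
oracle_boxmean <- function(image, k) {
  half <- (k - 1L) %/% 2L
  nr <- nrow(image)
  nc <- ncol(image)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- pmin(pmax((i - half):(i + half), 1L), nr)
      cj <- pmin(pmax((j - half):(j + half), 1L), nc)
      out[i, j] <- mean(image[ri, cj])
    }
  }
  out
}

# 8-connected component sizes by breadth-first flood fill.
oracle_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  comps <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (mask[i, j] == 0 || seen[i, j]) next
      queue <- list(c(i, j))
      seen[i, j] <- TRUE
      members <- matrix(0L, 0L, 2L)
      while (length(queue) > 0L) {
        p <- queue[[1L]]
        queue <- queue[-1L]
        members <- rbind(members, p)
        for (di in -1:1) {
          for (dj in -1:1) {
            qi <- p[1L] + di
            qj <- p[2L] + dj
            if (qi >= 1L && qi <= nr && qj >= 1L && qj <= nc &&
              mask[qi, qj] != 0 && !seen[qi, qj]) {
              seen[qi, qj] <- TRUE
              queue[[length(queue) + 1L]] <- c(qi, qj)
            }
          }
        }
      }
      comps[[length(comps) + 1L]] <- members
    }
  }
  comps
}

# A random elongated positive band for trace tests: one positive cell per
# column, connected with |row step| <= 1, random positive values; returned
# as a small distance-map-like matrix.
random_band_map <- function(nr, nc, max_halfheight = 1L) {
  m <- matrix(0L, nr, nc)
  r <- sample.int(nr, 1L)
  for (j in seq_len(nc)) {
    r <- min(max(r + sample(-1:1, 1L), 1L), nr)
    rows <- max(1L, r - sample.int(max_halfheight, 1L) + 1L):
      min(nr, r + sample.int(max_halfheight, 1L) - 1L)
    m[rows, j] <- sample.int(5L, length(rows), replace = TRUE)
    m[r, j] <- m[r, j] + 3L
  }
  m
}

random_mask <- function(nr, nc, p = 0.5) {
  matrix(as.integer(stats::runif(nr * nc) < p), nr, nc)
}

expect_margin_class <- function(x) {
  testthat::expect_s3_class(x, "mcw_margins")
}

# Dense RBF kernel matrix by explicit double loop (2*gamma^2 convention, gamma = 1).
rbf_kernel_matrix_for_test <- function(X) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- exp(-sum((X[i, ] - X[j, ])^2) / 2)
  K
}

# Independent reference dual solver (libsvm via e1071); e1071 parameterizes
# the kernel as exp(-g ||.||^2), so g = 1 / (2 gamma^2).
libsvm_reference <- function(data, cost, gamma_pkg) {
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

# Maximum feasible left-to-right path sum by exhaustive enumeration,
# vectorized over all step sequences (no tie-break, sum only).
oracle_dp_sum <- function(dmap) {
  pos_cols <- which(apply(dmap > 0, 2L, any))
  span <- min(pos_cols):max(pos_cols)
  v <- dmap[, span, drop = FALSE]
  nr <- nrow(v)
  w <- ncol(v)
  if (w == 1L) return(max(v[v > 0]))
  steps <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), w - 1L)))
  cums <- steps
  if (ncol(steps) > 1L) {
    for (j in 2:ncol(steps)) cums[, j] <- cums[, j - 1L] + steps[, j]
  }
  best <- -Inf
  for (r0 in seq_len(nr)) {
    rows_mat <- r0 + cbind(0L, cums)
    ok <- rowSums(rows_mat < 1L | rows_mat > nr) == 0L
    if (!any(ok)) next
    rm_ok <- rows_mat[ok, , drop = FALSE]
    vals <- matrix(v[cbind(as.vector(rm_ok), rep(seq_len(w), each = nrow(rm_ok)))],
      nrow(rm_ok), w)
    feas <- rowSums(vals <= 0) == 0L
    if (any(feas)) best <- max(best, max(rowSums(vals[feas, , drop = FALSE])))
  }
  best
}
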