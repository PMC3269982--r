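#' Keep the largest 8-connected component of a binary mask
#'
#' The cortical band is the biggest bright object left after enhancement;
#' trabecular clutter and noise specks are discarded by keeping only the
#' 8-connected component with the most pixels. When two components tie in
#' size, the one whose first pixel in row-major order (smallest row, then
#' column) comes first is kept, so the result is reproducible.
#'
#' @param mask A 0/1 matrix with at least one foreground pixel.
#' @return A 0/1 matrix containing exactly one connected component.
#' @examples
#' m <- matrix(0L, 5, 5); m[2, 1:3] <- 1L; m[5, 5] <- 1L
#' largest_component(m)
#' @export
largest_component <- function(mask) {
  check_binary_mask(mask)
  fg <- which(mask != 0)
  if (length(fg) == 0L) abort("no object: the mask has no foreground pixel")
  labels <- label_components8(mask)
  sizes <- tabulate(labels[fg])
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  if (length(cand) > 1L) {
    # row-major tie-break: component containing the earliest (row, col) pixel
    nr <- nrow(mask)
    rows <- (fg - 1L) %% nr + 1L
    cols <- (fg - 1L) %/% nr + 1L
    ord <- order(rows, cols)
    first_seen <- labels[fg][ord]
    cand <- first_seen[first_seen %in% cand][1L]
  }
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[labels == cand] <- 1L
  out
}

# 8-connected labeling through the pixel adjacency graph.
label_components8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- which(mask != 0)
  labels <- matrix(0L, nr, nc)
  if (length(fg) == 0L) return(labels)
  idx <- matrix(0L, nr, nc)
  idx[fg] <- seq_along(fg)
  rows <- (fg - 1L) %% nr + 1L
  cols <- (fg - 1L) %/% nr + 1L
  edges <- list()
  # half the neighbourhood suffices for an undirected graph
  offsets <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (off in offsets) {
    r2 <- rows + off[1L]
    c2 <- cols + off[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    if (!any(ok)) next
    nb <- idx[cbind(r2[ok], c2[ok])]
    hit <- nb > 0L
    if (any(hit)) {
      edges[[length(edges) + 1L]] <-
        rbind(idx[fg[ok]][hit], nb[hit])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges) > 0L) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  }
  comp <- igraph::components(g)$membership
  labels[fg] <- as.integer(comp)
  labels
}

#' Eight-neighbourhood distance function (chessboard distance transform)
#'
#' Assigns every object pixel its chessboard (Chebyshev, 8-connectivity)
#' distance to the nearest background pixel; background pixels get 0 and the
#' image border counts as background, so every object is finite. Computed by
#' the classic two-pass raster scan (forward then backward), which is exact
#' for this metric.
#'
#' @param mask A 0/1 matrix.
#' @return An integer matrix of distances, same shape as `mask`.
#' @examples
#' m <- matrix(0L, 7, 7); m[2:6, 2:6] <- 1L
#' endf(m)
#' @export
endf <- function(mask) {
  check_binary_mask(mask)
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- mask != 0
  d <- matrix(0, nr, nc)
  inf <- nr + nc + 2 # larger than any possible distance
  # forward pass, top-left to bottom-right
  above <- rep(0, nc) # distances of the row above (border = background = 0)
  for (i in seq_len(nr)) {
    topmin <- pmin(c(0, above[-nc]), above, c(above[-1L], 0))
    e <- ifelse(fg[i, ], topmin + 1, 0)
    d[i, ] <- running_min_step1(e)
    above <- d[i, ]
  }
  # backward pass, bottom-right to top-left
  below <- rep(0, nc)
  for (i in rev(seq_len(nr))) {
    botmin <- pmin(c(0, below[-nc]), below, c(below[-1L], 0))
    e <- ifelse(fg[i, ], pmin(d[i, ], botmin + 1), 0)
    d[i, ] <- rev(running_min_step1(rev(e)))
    below <- d[i, ]
  }
  storage.mode(d) <- "integer"
  d
}

# Solves d[j] = min(e[j], d[j-1] + 1) with a virtual d[0] = 0, vectorized:
# subtracting the index turns the recurrence into a running minimum.
running_min_step1 <- function(e) {
  n <- length(e)
  idx <- 0:n
  g <- cummin(c(0, e) - idx) + idx
  g[-1L]
}

check_binary_mask <- function(mask) {
  if (!is.matrix(mask) || !is.numeric(mask)) {
    abort("mask must be a numeric 0/1 matrix")
  }
  if (!all(mask %in% c(0, 1))) abort("mask must contain only 0 and 1")
  invisible(mask)
}

#' Trace the medial axis by dynamic programming
#'
#' Finds, among all left-to-right paths that advance one column per step,
#' move at most one row per column, and visit only strictly positive
#' distance values, the path maximizing the summed distance values. That
#' ridge of locally maximal distances is the medial axis of the elongated
#' cortical object. Ties are broken deterministically: walking from the
#' left, prefer the smaller row step magnitude, then the smaller row index
#' (so a uniform band yields the straight topmost path).
#'
#' @param dmap An integer distance map from [endf()].
#' @return A tibble of class `mcw_trace` with columns `col`, `row`, `value`,
#'   one row per image column spanned by the object.
#' @examples
#' m <- matrix(0L, 9, 12); m[3:7, ] <- 1L
#' trace_medial_axis(endf(m))
#' @export
trace_medial_axis <- function(dmap) {
  if (!is.matrix(dmap) || !is.numeric(dmap)) abort("dmap must be a numeric matrix")
  pos_cols <- which(apply(dmap > 0, 2L, any))
  if (length(pos_cols) == 0L) abort("no object: the distance map has no positive cell")
  c0 <- min(pos_cols)
  c1 <- max(pos_cols)
  nr <- nrow(dmap)
  span <- c0:c1
  w <- length(span)
  v <- dmap[, span, drop = FALSE]
  # g[r, j]: best achievable sum from column j to the end starting at row r
  g <- matrix(-Inf, nr, w)
  g[, w] <- ifelse(v[, w] > 0, v[, w], -Inf)
  if (w > 1L) {
    for (j in (w - 1L):1L) {
      nxt <- g[, j + 1L]
      best <- pmax(c(-Inf, nxt[-nr]), nxt, c(nxt[-1L], -Inf))
      g[, j] <- ifelse(v[, j] > 0, v[, j] + best, -Inf)
    }
  }
  if (!any(is.finite(g[, 1L]))) {
    abort("discontinuous object: no 8-connected left-to-right path spans the positive columns")
  }
  rows <- integer(w)
  rows[1L] <- which(g[, 1L] == max(g[, 1L]))[1L]
  if (w > 1L) {
    for (j in 1:(w - 1L)) {
      r <- rows[j]
      remaining <- g[r, j] - v[r, j]
      for (dr in c(0L, -1L, 1L)) { # smaller |step| first, then smaller row
        r2 <- r + dr
        if (r2 >= 1L && r2 <= nr && is.finite(g[r2, j + 1L]) &&
            g[r2, j + 1L] == remaining) {
          rows[j + 1L] <- r2
          break
        }
      }
    }
  }
  new_trace(tibble(
    col = span, row = rows,
    value = as.numeric(v[cbind(rows, seq_len(w))])
  ))
}

new_trace <- function(df) {
  structure(df, class = c("mcw_trace", class(tibble())))
}

#' Reconstruct cortical margins as a disc envelope
#'
#' Places a disc at every medial-axis point, sized by its distance value,
#' and takes the per-column extremes of the union of discs as the upper and
#' lower cortical margins. The default disc is the chessboard (square) ball
#' — the ball of the same metric the distance transform uses, so the
#' envelope reconstructs the object at any band orientation — with radius
#' `v - 1/2`: a distance value of `v` means the boundary lies between the
#' radius `v - 1` ball (wholly inside the object) and the radius `v` ball
#' (first touching background), and the midpoint is the unbiased estimate
#' of the continuous boundary. A Euclidean disc shape, the uncorrected
#' radius, and a half-value radius (reading the distance value as the disc
#' diameter) are available for sensitivity checks; the half-value
#' convention roughly halves the reconstructed width and is not used by
#' the pipeline.
#'
#' Margins are real-valued before rounding; they are rounded to integer rows
#' half away from the band centre and reported only over the trace's column
#' span.
#'
#' @param trace An `mcw_trace` from [trace_medial_axis()].
#' @param shape `"square"` (chessboard ball, default) or `"euclidean"`.
#' @param radius `"corrected"` (radius = value - 1/2, default),
#'   `"distance"` (radius = value) or `"half"` (radius = value / 2, i.e.
#'   the value read as the disc diameter).
#' @return A tibble of class `mcw_margins` with columns `col`, `upper`,
#'   `lower` (integer rows, `upper <= lower`).
#' @examples
#' m <- matrix(0L, 15, 20); m[5:11, ] <- 1L
#' disc_envelope(trace_medial_axis(endf(m)))
#' @export
disc_envelope <- function(trace, shape = c("square", "euclidean"),
                          radius = c("corrected", "distance", "half")) {
  shape <- arg_match(shape)
  radius <- arg_match(radius)
  if (!inherits(trace, "mcw_trace")) abort("`trace` must come from trace_medial_axis()")
  span <- trace$col
  rad <- switch(radius,
    corrected = pmax(trace$value - 0.5, 0.5),
    distance = trace$value,
    half = trace$value / 2
  )
  up <- rep(Inf, length(span))
  lo <- rep(-Inf, length(span))
  c0 <- span[1L]
  for (k in seq_along(span)) {
    r <- trace$row[k]
    v <- rad[k]
    js <- max(span[1L], span[k] - floor(v)):min(span[length(span)], span[k] + floor(v))
    dc <- js - span[k]
    half <- if (shape == "euclidean") sqrt(pmax(0, v^2 - dc^2)) else v
    j <- js - c0 + 1L
    up[j] <- pmin(up[j], r - half)
    lo[j] <- pmax(lo[j], r + half)
  }
  new_margins(tibble(
    col = span,
    upper = as.integer(ceiling(up - 0.5)), # half rounds away from the centre
    lower = as.integer(floor(lo + 0.5))
  ))
}

new_margins <- function(df) {
  structure(df, class = c("mcw_margins", class(tibble())))
}
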