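#' Histogram equalization
#'
#' Remaps intensities through the cumulative histogram so the output occupies
#' the full \[0, 255\] range roughly uniformly. The map is the classic CDF
#' lookup `round(cdf(v) * 255)` computed over integer levels, so it is
#' monotone non-decreasing in the input intensity and idempotent up to one
#' quantization level. A constant image maps to a constant image.
#'
#' @param image A grayscale image matrix (intensities \[0, 255\]).
#' @return An equalized grayscale image of the same size.
#' @examples
#' equalize_histogram(matrix(c(0, 85, 170, 255), 2, 2))
#' @export
equalize_histogram <- function(image) {
  image <- as_gray_image(image)
  lev <- as.integer(round(image))
  counts <- tabulate(lev + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(lev)
  lut <- floor(cdf * 255 + 0.5)
  matrix(lut[lev + 1L], nrow(image), ncol(image))
}

#' Between-class-variance threshold (Otsu's method)
#'
#' Sweeps all 256 integer thresholds and picks the one maximizing the
#' between-class variance of the two intensity classes (equivalently,
#' minimizing the pooled within-class variance). Pixels strictly above the
#' threshold are object (1), the rest background (0); ties in the objective
#' resolve to the lowest maximizing threshold. The sweep is exhaustive over
#' the 8-bit levels, so the result is exact, not an approximation.
#'
#' @param image A grayscale image matrix with at least two distinct levels.
#' @return A list with `threshold` (integer level) and `mask` (0/1 matrix).
#' @examples
#' img <- matrix(c(rep(40, 8), rep(200, 8)), 4, 4)
#' variance_threshold(img)$threshold
#' @export
variance_threshold <- function(image) {
  image <- as_gray_image(image)
  lev <- as.integer(round(image))
  counts <- tabulate(lev + 1L, nbins = 256L)
  if (sum(counts > 0L) < 2L) {
    abort("degenerate histogram: the image has a single intensity level, no separable classes")
  }
  n <- length(lev)
  p <- counts / n
  omega <- cumsum(p)              # class-0 mass for threshold t = level index - 1
  mu <- cumsum(p * (0:255))       # partial first moment
  mu_t <- mu[256]
  # between-class variance at each candidate threshold t = 0..255
  valid <- omega > 0 & omega < 1
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (mu_t * omega[valid] - mu[valid])^2 /
    (omega[valid] * (1 - omega[valid]))
  threshold <- which.max(sigma_b) - 1L
  mask <- matrix(as.integer(lev > threshold), nrow(image), ncol(image))
  list(threshold = threshold, mask = mask)
}

#' Remove background by mask multiplication
#'
#' Keeps the original grey level wherever the binary mask is 1 and zeroes
#' everything else, so object pixels retain their full intensity detail
#' while the background is removed outright.
#'
#' @param image A grayscale image matrix.
#' @param mask A 0/1 matrix of the same shape.
#' @return The masked grayscale image.
#' @export
mask_multiply <- function(image, mask) {
  image <- as_gray_image(image)
  if (!is.matrix(mask) || !identical(dim(mask), dim(image))) {
    abort("mask shape must match the image shape")
  }
  if (!all(mask %in% c(0, 1))) abort("mask must contain only 0 and 1")
  image * mask
}

#' High-pass filter by moving-average subtraction
#'
#' Estimates the low-frequency background with a `kernel_size` x
#' `kernel_size` box average (borders handled by edge replication) and
#' subtracts it from the image. Output values are signed and deliberately
#' not clipped. The kernel must be odd and no larger than the image; it
#' should also be wider than the cortical band itself so the window always
#' reaches true background (see the package vignette for the sizing
#' argument behind the default).
#'
#' @param image A grayscale image matrix.
#' @param kernel_size Odd window side length in pixels, `>= 3`.
#' @return A signed numeric matrix, `image - boxmean(image)`.
#' @examples
#' hp <- highpass(matrix(runif(100, 0, 255), 10, 10), 5)
#' @export
highpass <- function(image, kernel_size = 101L) {
  image <- as_gray_image(image)
  k <- kernel_size
  if (length(k) != 1L || !is.numeric(k) || k != round(k)) {
    abort("kernel_size must be a single whole number")
  }
  if (k %% 2 == 0) abort("kernel_size must be odd")
  if (k < 3) abort("kernel_size must be at least 3")
  if (k > min(dim(image))) {
    abort(paste0(
      "kernel_size ", k, " exceeds the smallest image dimension ",
      min(dim(image))
    ))
  }
  image - box_mean_replicate(image, as.integer(k))
}

# Box mean with edge-replicated borders, exact via integral image.
box_mean_replicate <- function(image, k) {
  half <- (k - 1L) %/% 2L
  nr <- nrow(image)
  nc <- ncol(image)
  ridx <- pmin(pmax(seq(1L - half, nr + half), 1L), nr)
  cidx <- pmin(pmax(seq(1L - half, nc + half), 1L), nc)
  pad <- image[ridx, cidx, drop = FALSE]
  # summed-area table with a zero first row/column
  sat <- matrix(0, nrow(pad) + 1L, ncol(pad) + 1L)
  sat[-1L, -1L] <- apply(apply(pad, 2L, cumsum), 1L, cumsum) |> t()
  r0 <- seq_len(nr)
  c0 <- seq_len(nc)
  r1 <- r0 + k
  c1 <- c0 + k
  sums <- sat[r1, c1, drop = FALSE] - sat[r0, c1, drop = FALSE] -
    sat[r1, c0, drop = FALSE] + sat[r0, c0, drop = FALSE]
  sums / (k * k)
}

#' Binarize a signed image at its global mean
#'
#' Marks as object every pixel whose value strictly exceeds the mean of all
#' pixels. The strict comparison makes the degenerate constant input well
#' defined: no pixel exceeds the mean, so the mask is all zero.
#'
#' @param hp A numeric matrix (typically the [highpass()] output).
#' @return A 0/1 integer matrix of the same shape.
#' @examples
#' binarize_mean(matrix(c(1, 1, 1, 5), 2, 2))
#' @export
binarize_mean <- function(hp) {
  if (!is.matrix(hp) || !is.numeric(hp) || length(hp) == 0L) {
    abort("`hp` must be a non-empty numeric matrix")
  }
  matrix(as.integer(hp > mean(hp)), nrow(hp), ncol(hp))
}

#' Segment the cortical object in an ROI crop
#'
#' Runs the enhancement chain on one cropped region: histogram equalization,
#' between-class-variance thresholding, background removal by mask
#' multiplication, moving-average high-pass filtering, and mean-threshold
#' binarization. The final binary image is intersected with the
#' variance-threshold foreground mask: the high-pass stage is only
#' meaningful where background illumination has already been removed, and
#' the intersection keeps pixels that were classified as background from
#' re-entering when the high-pass image has a non-positive global mean
#' (which happens whenever the object touches the ROI border).
#'
#' @param image A cropped grayscale ROI.
#' @param kernel_size High-pass averaging window, passed to [highpass()].
#' @return A list with the intermediate stages: `equalized`, `threshold`,
#'   `otsu_mask`, `multiplied`, `highpass`, `binary` (the final 0/1 mask).
#' @examples
#' rib <- render_ribbon(ribbon_spec(seed = 1))
#' seg <- segment_cortex(rib$image)
#' sum(seg$binary)
#' @export
segment_cortex <- function(image, kernel_size = 101L) {
  eq <- equalize_histogram(image)
  vt <- variance_threshold(eq)
  mult <- mask_multiply(eq, vt$mask)
  hp <- highpass(mult, kernel_size)
  bin <- binarize_mean(hp) * vt$mask
  list(
    equalized = eq, threshold = vt$threshold, otsu_mask = vt$mask,
    multiplied = mult, highpass = hp, binary = bin
  )
}
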