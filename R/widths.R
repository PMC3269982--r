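#' Fit a second-order polynomial to the upper cortical margin
#'
#' Ordinary least squares of `upper row ~ col + col^2` over the margin span.
#' The fitted curve defines the local direction of the cortex; widths are
#' then measured perpendicular to its tangent. At least three distinct
#' columns are required to support a quadratic.
#'
#' @param margins An `mcw_margins` tibble from [disc_envelope()].
#' @return A named numeric vector `c(a0, a1, a2)` of class `mcw_poly`, the
#'   coefficients of `row(col) = a0 + a1 col + a2 col^2`.
#' @examples
#' m <- tibble::tibble(col = 1:20, upper = 5 + 0 * (1:20), lower = 15)
#' fit_upper_polynomial(structure(m, class = c("mcw_margins", class(m))))
#' @export
fit_upper_polynomial <- function(margins) {
  check_margins(margins)
  if (length(unique(margins$col)) < 3L) {
    abort("insufficient support: the margin span covers fewer than 3 columns")
  }
  fit <- lm(upper ~ col + I(col^2), data = margins)
  co <- unname(coef(fit))
  co[is.na(co)] <- 0 # exactly collinear designs cannot occur with >= 3 distinct cols
  structure(setNames(co, c("a0", "a1", "a2")), class = "mcw_poly")
}

#' @export
print.mcw_poly <- function(x, ...) {
  cat(sprintf(
    "<mcw_poly> row(col) = %.6g + %.6g col + %.6g col^2\n",
    x[["a0"]], x[["a1"]], x[["a2"]]
  ))
  invisible(x)
}

predict_poly <- function(poly, col) {
  poly[["a0"]] + poly[["a1"]] * col + poly[["a2"]] * col^2
}

check_margins <- function(margins) {
  if (!inherits(margins, "mcw_margins")) {
    abort("`margins` must be an mcw_margins object (see disc_envelope())")
  }
  invisible(margins)
}

#' Measure cortical width perpendicular to the fitted upper margin
#'
#' At every column of the margin span, a ray is cast from the upper margin
#' point along the normal of the fitted polynomial (slope `a1 + 2 a2 col`)
#' towards the lower margin, which is interpolated linearly between integer
#' columns for sub-pixel intersection. The width is the Euclidean length of
#' that ray segment, reported in pixels and millimetres. Columns whose
#' normal ray fails to meet the lower margin inside the span are skipped;
#' if more than 20 percent of columns are skipped the measurement is deemed
#' to have failed and an error is raised.
#'
#' @param margins An `mcw_margins` tibble.
#' @param poly An `mcw_poly` fit, or `NULL` to fit one from `margins`.
#' @param spacing_mm Physical pixel size in millimetres; the default is a
#'   300 dpi scan, 25.4/300 mm per pixel.
#' @param side Which side of the mandible the profile belongs to.
#' @return A tibble of class `mcw_width_profile` with columns `column`,
#'   `width_px`, `width_mm` and attributes `pixel_spacing_mm`, `side`,
#'   `n_skipped`.
#' @examples
#' m <- tibble::tibble(col = 1:30, upper = 10L, lower = 20L)
#' m <- structure(m, class = c("mcw_margins", class(m)))
#' measure_widths(m)
#' @export
measure_widths <- function(margins, poly = NULL,
                           spacing_mm = 25.4 / 300,
                           side = c("right", "left")) {
  check_margins(margins)
  side <- arg_match(side)
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0) {
    abort("spacing_mm must be a single positive number")
  }
  if (is.null(poly)) poly <- fit_upper_polynomial(margins)
  if (!inherits(poly, "mcw_poly")) abort("`poly` must be an mcw_poly fit")
  cols <- margins$col
  up <- as.numeric(margins$upper)
  lo <- as.numeric(margins$lower)
  n <- length(cols)
  widths <- rep(NA_real_, n)
  if (n >= 2L) {
    seg_x0 <- cols[-n]
    seg_dx <- diff(cols)
    seg_sl <- diff(lo) / seg_dx
  }
  for (i in seq_len(n)) {
    ci <- cols[i]
    m <- poly[["a1"]] + 2 * poly[["a2"]] * ci
    s <- sqrt(1 + m^2)
    # downward normal through (ci, up[i]): x(t) = ci - m t / s, y(t) = up + t / s
    if (n == 1L) {
      widths[i] <- lo[1L] - up[1L]
      next
    }
    denom <- 1 + seg_sl * m
    valid <- abs(denom) > 1e-12
    t_cand <- rep(NA_real_, n - 1L)
    t_cand[valid] <- s * (lo[-n][valid] + seg_sl[valid] * (ci - seg_x0[valid]) - up[i]) /
      denom[valid]
    x_cand <- ci - m * t_cand / s
    ok <- valid & t_cand >= -1e-9 &
      x_cand >= seg_x0 - 1e-9 & x_cand <= seg_x0 + seg_dx + 1e-9
    if (any(ok, na.rm = TRUE)) {
      widths[i] <- max(0, min(t_cand[which(ok)]))
    }
  }
  skipped <- is.na(widths)
  if (mean(skipped) > 0.20) {
    abort(paste0(
      "measurement failure: ", sum(skipped), " of ", n,
      " columns (", round(100 * mean(skipped)), "%) had no normal-ray ",
      "intersection with the lower margin"
    ))
  }
  out <- tibble(
    column = cols[!skipped],
    width_px = widths[!skipped],
    width_mm = widths[!skipped] * spacing_mm
  )
  structure(out,
    class = c("mcw_width_profile", class(tibble())),
    pixel_spacing_mm = spacing_mm, side = side, n_skipped = sum(skipped)
  )
}

#' Reduce two width profiles to the classifier feature vector
#'
#' Computes the mean and population (divide-by-n) variance of the
#' millimetre widths on each side, then averages the two sides, giving the
#' two-dimensional feature vector `(mean_width_mm, var_width_mm2)` used by
#' the SVM. If one side failed to produce any measurement the other side is
#' used alone, with a warning; two empty profiles are an error.
#'
#' @param right,left `mcw_width_profile` tibbles (either may be `NULL` or
#'   empty for the single-side fallback).
#' @return A one-row tibble with `mean_width_mm` and `var_width_mm2`.
#' @export
extract_features <- function(right, left) {
  side_stats <- function(p) {
    if (is.null(p) || nrow(p) == 0L) return(NULL)
    w <- p$width_mm
    c(mean = mean(w), var = mean((w - mean(w))^2))
  }
  r <- side_stats(right)
  l <- side_stats(left)
  if (is.null(r) && is.null(l)) {
    abort("both width profiles are empty; no features can be extracted")
  }
  if (is.null(r) || is.null(l)) {
    warn("one width profile is empty; features computed from a single side")
  }
  st <- rbind(r, l)
  tibble(
    mean_width_mm = mean(st[, "mean"]),
    var_width_mm2 = mean(st[, "var"])
  )
}
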