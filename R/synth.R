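#' Specification of a synthetic cortical ribbon image
#'
#' Describes a bright, gently curved band of constant normal width over a
#' darker noisy background — the geometry of the inferior mandibular cortex
#' inside a 300 x 300 px region of interest. The band runs along the
#' quadratic axis `row(col) = a0 + a1 col + a2 col^2` and extends
#' `true_width_px / 2` on either side of it, measured perpendicular to the
#' axis. Optional band-limited clutter below the band stands in for
#' trabecular texture.
#'
#' The band must be brighter than the background by at least three noise
#' standard deviations (otherwise no thresholding method is expected to
#' find it) and must stay inside the frame over at least 80 percent of
#' columns.
#'
#' @param image_size `c(rows, cols)` of the image.
#' @param axis Numeric `c(a0, a1, a2)` of the true medial axis quadratic.
#' @param true_width_px Normal width of the band in pixels.
#' @param band_intensity,background_intensity Mean grey levels in \[0, 255\].
#' @param noise_sd Gaussian intensity noise standard deviation.
#' @param texture Amplitude of smoothed trabecular clutter below the band
#'   (0 disables it).
#' @param seed RNG seed; the rendered image is a pure function of the spec.
#' @return A list of class `mcw_ribbon_spec`.
#' @export
ribbon_spec <- function(image_size = c(300L, 300L),
                        axis = c(a0 = 150, a1 = 0, a2 = 0),
                        true_width_px = 40,
                        band_intensity = 170,
                        background_intensity = 70,
                        noise_sd = 5,
                        texture = 10,
                        seed = 1L) {
  if (length(image_size) != 2L || any(image_size < 32)) {
    abort("image_size must be two dimensions of at least 32 px")
  }
  if (length(axis) != 3L || anyNA(axis)) abort("axis must be c(a0, a1, a2)")
  if (true_width_px < 2) abort("true_width_px must be at least 2")
  if (band_intensity <= background_intensity) {
    abort("the band must be brighter than the background")
  }
  if (noise_sd < 0 || texture < 0) abort("noise_sd and texture must be non-negative")
  if (band_intensity - background_intensity < 3 * noise_sd) {
    abort("detectability: band must exceed background by at least 3 * noise_sd")
  }
  spec <- structure(
    list(
      image_size = as.integer(image_size),
      axis = setNames(as.numeric(axis), c("a0", "a1", "a2")),
      true_width_px = true_width_px,
      band_intensity = band_intensity,
      background_intensity = background_intensity,
      noise_sd = noise_sd,
      texture = texture,
      seed = as.integer(seed)
    ),
    class = "mcw_ribbon_spec"
  )
  env <- ribbon_envelope(spec)
  outside <- mean(env$upper < 1 | env$lower > image_size[1L])
  if (outside > 0.20) {
    abort(paste0(
      "the band leaves the frame on ", round(100 * outside),
      "% of columns (at most 20% allowed)"
    ))
  }
  spec
}

# Exact sub-pixel band envelope: the band of constant normal width is the
# union of Euclidean discs of radius width/2 along the axis, whose
# per-column extremes are computed from a densely sampled axis.
ribbon_envelope <- function(spec) {
  nc <- spec$image_size[2L]
  R <- spec$true_width_px / 2
  xs <- seq(1 - R - 1, nc + R + 1, by = 0.25)
  ys <- spec$axis[["a0"]] + spec$axis[["a1"]] * xs + spec$axis[["a2"]] * xs^2
  upper <- rep(Inf, nc)
  lower <- rep(-Inf, nc)
  for (k in seq_along(xs)) {
    j0 <- max(1L, ceiling(xs[k] - R))
    j1 <- min(nc, floor(xs[k] + R))
    if (j0 > j1) next
    js <- j0:j1
    half <- sqrt(pmax(0, R^2 - (js - xs[k])^2))
    upper[js] <- pmin(upper[js], ys[k] - half)
    lower[js] <- pmax(lower[js], ys[k] + half)
  }
  tibble(col = seq_len(nc), upper = upper, lower = lower)
}

#' Render a synthetic cortical ribbon with exact ground truth
#'
#' Rasterizes the band described by a [ribbon_spec()] (a pixel belongs to
#' the band when its centre lies within `true_width_px / 2` of the axis,
#' normal distance), adds seeded Gaussian noise and optional clutter, and
#' returns the 8-bit image together with the exact sub-pixel truth margins
#' and the constant truth width profile.
#'
#' @param spec An `mcw_ribbon_spec`.
#' @param spacing_mm Pixel size used for the truth width profile.
#' @return A list with `image` (grayscale matrix), `truth_margins`
#'   (sub-pixel `mcw_margins` tibble), `truth_widths` (an
#'   `mcw_width_profile` tibble with the constant true width), and `spec`.
#' @examples
#' rib <- render_ribbon(ribbon_spec(true_width_px = 12, noise_sd = 0, texture = 0))
#' range(rib$image)
#' @export
render_ribbon <- function(spec, spacing_mm = 25.4 / 300) {
  if (!inherits(spec, "mcw_ribbon_spec")) abort("`spec` must come from ribbon_spec()")
  nr <- spec$image_size[1L]
  nc <- spec$image_size[2L]
  env <- ribbon_envelope(spec)
  rows <- matrix(seq_len(nr), nr, nc)
  upper_m <- matrix(env$upper, nr, nc, byrow = TRUE)
  lower_m <- matrix(env$lower, nr, nc, byrow = TRUE)
  band <- rows >= upper_m & rows <= lower_m

  img <- withr::with_seed(spec$seed, {
    base <- matrix(spec$background_intensity, nr, nc)
    base[band] <- spec$band_intensity
    if (spec$noise_sd > 0) {
      base <- base + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    }
    if (spec$texture > 0) {
      clutter <- box_mean_replicate(matrix(stats::rnorm(nr * nc, 0, 3 * spec$texture), nr, nc), 5L)
      below <- rows > lower_m + 3
      base[below] <- base[below] + clutter[below]
    }
    base
  })
  img <- pmin(pmax(round(img), 0), 255)

  truth_margins <- new_margins(env)
  widths <- rep(spec$true_width_px, nc)
  truth_widths <- structure(
    tibble(
      column = seq_len(nc),
      width_px = widths,
      width_mm = widths * spacing_mm
    ),
    class = c("mcw_width_profile", class(tibble())),
    pixel_spacing_mm = spacing_mm, side = "right", n_skipped = 0L
  )
  list(image = img, truth_margins = truth_margins, truth_widths = truth_widths, spec = spec)
}

#' Specification of a synthetic screening cohort
#'
#' Class-conditional ground truth for a two-class cohort: subjects with low
#' bone mineral density have thinner inferior cortices (default mean 3.0 mm)
#' than subjects with normal density (default 4.2 mm), both with 0.4 mm
#' between-subject standard deviation, truncated at 0.5 mm. The
#' within-subject width-variance feature is drawn from class-conditional
#' gamma distributions (low-density cortices are more eroded, hence more
#' variable). Defaults represent published separations of mandibular
#' cortical width around the low-density screening threshold.
#'
#' @param n_low,n_normal Class sizes (low = +1, the screening-positive class).
#' @param width_mean_low_mm,width_mean_normal_mm Class mean cortical widths.
#' @param width_sd_mm Between-subject width standard deviation (both classes).
#' @param var_mean_low,var_mean_normal Mean within-subject width variance
#'   (mm^2) per class, used by [generate_feature_cohort()].
#' @param pixel_spacing_mm Pixel size (default 300 dpi).
#' @param image_size,band_intensity,background_intensity,noise_sd,texture
#'   Imaging parameters passed to [ribbon_spec()] by [generate_cohort()].
#' @param seed RNG seed; cohorts are pure functions of their spec.
#' @return A list of class `mcw_cohort_spec`.
#' @export
cohort_spec <- function(n_low = 50L, n_normal = 50L,
                        width_mean_low_mm = 3.0, width_mean_normal_mm = 4.2,
                        width_sd_mm = 0.4,
                        var_mean_low = 0.015, var_mean_normal = 0.008,
                        pixel_spacing_mm = 25.4 / 300,
                        image_size = c(300L, 300L),
                        band_intensity = 170, background_intensity = 70,
                        noise_sd = 5, texture = 10,
                        seed = 1L) {
  if (n_low < 1L || n_normal < 1L) abort("class sizes must be positive")
  if (width_mean_low_mm == width_mean_normal_mm) {
    abort("class mean widths must be distinct")
  }
  if (width_sd_mm <= 0 || pixel_spacing_mm <= 0) {
    abort("width_sd_mm and pixel_spacing_mm must be positive")
  }
  if (var_mean_low <= 0 || var_mean_normal <= 0) {
    abort("class variance means must be positive")
  }
  structure(
    list(
      n_low = as.integer(n_low), n_normal = as.integer(n_normal),
      width_mean_low_mm = width_mean_low_mm,
      width_mean_normal_mm = width_mean_normal_mm,
      width_sd_mm = width_sd_mm,
      var_mean_low = var_mean_low, var_mean_normal = var_mean_normal,
      pixel_spacing_mm = pixel_spacing_mm,
      image_size = as.integer(image_size),
      band_intensity = band_intensity,
      background_intensity = background_intensity,
      noise_sd = noise_sd, texture = texture,
      seed = as.integer(seed)
    ),
    class = "mcw_cohort_spec"
  )
}

# normal draw truncated below at `lower`
rnorm_trunc <- function(n, mean, sd, lower = 0.5) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out < lower)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

#' Generate a synthetic image cohort
#'
#' Draws each subject's true cortical width from the class-conditional
#' truncated normal distribution and renders a right and a left ribbon
#' image with independent noise and per-side axis geometry (position,
#' gentle slope and curvature vary across subjects the way manually placed
#' boxes do). Labels are +1 for the low-density class.
#'
#' @param spec An `mcw_cohort_spec`.
#' @return A tibble with one row per subject: `subject_id`, `label`,
#'   `true_width_mm`, and list-columns `image_right`, `image_left`,
#'   `truth_right`, `truth_left` holding the rendered images and their
#'   ground truth.
#' @examples
#' co <- generate_cohort(cohort_spec(n_low = 2, n_normal = 2, seed = 7))
#' nrow(co)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "mcw_cohort_spec")) abort("`spec` must come from cohort_spec()")
  n <- spec$n_low + spec$n_normal
  withr::with_seed(spec$seed, {
    label <- rep(c(1, -1), c(spec$n_low, spec$n_normal))
    mu <- ifelse(label == 1, spec$width_mean_low_mm, spec$width_mean_normal_mm)
    width_mm <- rnorm_trunc(n, mu, spec$width_sd_mm)
    width_px <- width_mm / spec$pixel_spacing_mm
    nr <- spec$image_size[1L]
    render_side <- function(i) {
      ax <- c(
        a0 = stats::runif(1, 0.42 * nr, 0.58 * nr),
        a1 = stats::runif(1, -0.25, 0.25),
        a2 = stats::runif(1, -4e-4, 4e-4)
      )
      ax[["a0"]] <- ax[["a0"]] - ax[["a1"]] * spec$image_size[2L] / 2 # recentre
      rs <- ribbon_spec(
        image_size = spec$image_size, axis = ax,
        true_width_px = width_px[i],
        band_intensity = spec$band_intensity,
        background_intensity = spec$background_intensity,
        noise_sd = spec$noise_sd, texture = spec$texture,
        seed = sample.int(.Machine$integer.max - 1L, 1L)
      )
      render_ribbon(rs, spacing_mm = spec$pixel_spacing_mm)
    }
    right <- lapply(seq_len(n), render_side)
    left <- lapply(seq_len(n), render_side)
    tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      label = label,
      true_width_mm = width_mm,
      image_right = lapply(right, `[[`, "image"),
      image_left = lapply(left, `[[`, "image"),
      truth_right = right,
      truth_left = left
    )
  })
}

#' Generate a feature-level synthetic cohort
#'
#' Draws the `(mean width, width variance)` feature vectors directly from
#' the class-conditional distributions, bypassing the imaging pipeline.
#' These fast fixtures drive the classifier studies; the image-level
#' generator above exercises the full measurement chain.
#'
#' @param spec An `mcw_cohort_spec`.
#' @return A tibble with `subject_id`, `mean_width_mm`, `var_width_mm2`,
#'   `label` (+1 = low bone mineral density).
#' @examples
#' generate_feature_cohort(cohort_spec(n_low = 3, n_normal = 3, seed = 1))
#' @export
generate_feature_cohort <- function(spec) {
  if (!inherits(spec, "mcw_cohort_spec")) abort("`spec` must come from cohort_spec()")
  n <- spec$n_low + spec$n_normal
  withr::with_seed(spec$seed, {
    label <- rep(c(1, -1), c(spec$n_low, spec$n_normal))
    mu <- ifelse(label == 1, spec$width_mean_low_mm, spec$width_mean_normal_mm)
    vmu <- ifelse(label == 1, spec$var_mean_low, spec$var_mean_normal)
    tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      mean_width_mm = rnorm_trunc(n, mu, spec$width_sd_mm),
      var_width_mm2 = stats::rgamma(n, shape = 4, rate = 4 / vmu),
      label = label
    )
  })
}
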