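predict_poly_for_test <- function(p, x) p[["a0"]] + p[["a1"]] * x + p[["a2"]] * x^2

mk_margins <- function(col, upper, lower) {
  structure(
    tibble::tibble(col = col, upper = upper, lower = lower),
    class = c("mcw_margins", class(tibble::tibble()))
  )
}

test_that("the quadratic fit to the upper margin matches a direct normal-equations solve", {
  const <- mk_margins(1:20, rep(7, 20), rep(17, 20))
  expect_equal(unclass(fit_upper_polynomial(const)),
               c(a0 = 7, a1 = 0, a2 = 0), tolerance = 1e-12)

  cols <- 0:50
  exact <- mk_margins(cols, 2 + 0.5 * cols - 0.01 * cols^2, 60)
  expect_equal(unclass(fit_upper_polynomial(exact)),
               c(a0 = 2, a1 = 0.5, a2 = -0.01), tolerance = 1e-9)

  set.seed(51)
  cols <- 1:100
  up <- 30 + 0.2 * cols - 0.002 * cols^2 + rnorm(100)
  noisy <- mk_margins(cols, up, 90)
  fit <- fit_upper_polynomial(noisy)
  X <- cbind(1, cols, cols^2)
  beta <- solve(t(X) %*% X, t(X) %*% up) # independent 3x3 linear-system oracle
  expect_equal(as.numeric(unclass(fit)), as.numeric(beta), tolerance = 1e-6)

  expect_error(fit_upper_polynomial(mk_margins(1:2, c(1, 2), c(5, 6))),
               "insufficient support")
})

test_that("quadratic residuals never exceed those of the best constant fit", {
  set.seed(52)
  for (rep in 1:10) {
    cols <- 1:40
    up <- runif(1, 10, 30) + runif(1, -0.3, 0.3) * cols + rnorm(40, 0, 2)
    m <- mk_margins(cols, up, 80)
    fit <- fit_upper_polynomial(m)
    resid_poly <- sum((up - predict_poly_for_test(fit, cols))^2)
    resid_const <- sum((up - mean(up))^2)
    expect_lte(resid_poly, resid_const + 1e-8)
  }
})

test_that("widths are measured along the normal of the fitted tangent", {
  flat <- mk_margins(1:50, rep(10, 50), rep(20, 50))
  prof <- measure_widths(flat)
  expect_true(all(prof$width_px == 10))

  # a 45-degree sheared band of vertical extent 10 has normal width 10 cos(45)
  cols <- 1:80
  sheared <- mk_margins(cols, 100 + cols, 110 + cols)
  prof45 <- measure_widths(sheared)
  inner <- prof45$width_px[prof45$column < 70] # last columns skip (ray exits span)
  expect_equal(inner, rep(10 * cos(pi / 4), length(inner)), tolerance = 1e-6)

  # millimetre conversion at 300 dpi
  expect_equal(unique(prof$width_mm), 10 * 25.4 / 300, tolerance = 1e-12)
  expect_equal(attr(prof, "pixel_spacing_mm"), 25.4 / 300)
})

test_that("widths fail loudly when too many normal rays miss the lower margin", {
  # a 2-column margin cannot skip more than 20% without erroring:
  # force a steep fitted slope via an artificial polynomial
  steep <- structure(setNames(c(0, 30, 0), c("a0", "a1", "a2")), class = "mcw_poly")
  m <- mk_margins(1:10, rep(5, 10), rep(8, 10))
  expect_error(measure_widths(m, steep), "measurement failure")
})

test_that("feature extraction averages per-side means and population variances", {
  mk_profile <- function(w_mm) {
    structure(
      tibble::tibble(column = seq_along(w_mm), width_px = w_mm / (25.4 / 300), width_mm = w_mm),
      class = c("mcw_width_profile", class(tibble::tibble())),
      pixel_spacing_mm = 25.4 / 300, side = "right", n_skipped = 0L
    )
  }
  r <- mk_profile(c(2.8, 3.0, 3.2)) # mean 3.0, pop var 0.0266...
  l <- mk_profile(c(3.8, 4.0, 4.2))
  fv <- extract_features(r, l)
  expect_equal(fv$mean_width_mm, 3.5)
  pop_var <- function(x) mean((x - mean(x))^2)
  expect_equal(fv$var_width_mm2, (pop_var(c(2.8, 3.0, 3.2)) + pop_var(c(3.8, 4.0, 4.2))) / 2)

  const <- mk_profile(rep(2.5, 10))
  fv2 <- extract_features(const, const)
  expect_equal(fv2$mean_width_mm, 2.5)
  expect_equal(fv2$var_width_mm2, 0)

  set.seed(53)
  wr <- runif(40, 2, 5)
  wl <- runif(40, 2, 5)
  fv3 <- extract_features(mk_profile(wr), mk_profile(wl))
  expect_equal(fv3$mean_width_mm, (mean(wr) + mean(wl)) / 2)
  expect_equal(fv3$var_width_mm2, (pop_var(wr) + pop_var(wl)) / 2)

  empty <- mk_profile(numeric(0))
  expect_warning(fv4 <- extract_features(mk_profile(wr), empty), "single side")
  expect_equal(fv4$mean_width_mm, mean(wr))
  expect_error(
    suppressWarnings(extract_features(empty, empty)), "both width profiles"
  )
})

test_that("measured width is invariant to translation and horizontal mirroring", {
  sp <- ribbon_spec(
    axis = c(a0 = 170, a1 = -0.2, a2 = 3e-4),
    true_width_px = 16, noise_sd = 0, texture = 0, seed = 54
  )
  rib <- render_ribbon(sp)
  base <- mean(measure_side(rib$image, "right")$profile$width_px)

  shifted <- rbind(
    matrix(rib$image[1, ], 20, 300, byrow = TRUE),
    rib$image[1:280, ]
  )
  w_shift <- mean(measure_side(as_gray_image(shifted), "right")$profile$width_px)
  expect_lt(abs(w_shift - base), 0.3)

  mirrored <- rib$image[, 300:1]
  w_mirror <- mean(measure_side(as_gray_image(mirrored), "left")$profile$width_px)
  expect_lt(abs(w_mirror - base), 0.3)
})

test_that("mean width of straight and curved synthetic bands is recovered within tolerance", {
  # straight bands, a couple of widths and orientations (full grid in the
  # acceptance suite)
  for (case in list(c(10, 0), c(14, 15))) {
    W <- case[1]
    th <- case[2] * pi / 180
    a0 <- if (th > 0) 60 + 300 * tan(th) else 150.3
    sp <- ribbon_spec(
      axis = c(a0 = a0, a1 = -tan(th), a2 = 0),
      true_width_px = W, noise_sd = 0, texture = 0, seed = 55
    )
    prof <- measure_side(render_ribbon(sp)$image, "right")$profile
    expect_lt(abs(mean(prof$width_px) - W), 1)
  }
  # curved parabolic band, constant normal width
  spc <- ribbon_spec(
    axis = c(a0 = 200, a1 = -0.35, a2 = 6e-4),
    true_width_px = 12, noise_sd = 0, texture = 0, seed = 56
  )
  profc <- measure_side(render_ribbon(spc)$image, "right")$profile
  expect_lt(abs(mean(profc$width_px) - 12), 1.5)
})
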