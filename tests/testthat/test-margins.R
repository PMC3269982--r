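test_that("largest_component keeps the biggest 8-connected object with a row-major tie-break", {
  m <- matrix(0L, 10, 10)
  m[2:6, 2:6] <- 1L # 25 px
  m[9:10, 8:10] <- 1L # 6 px
  out <- largest_component(m)
  expect_identical(sum(out), 25L)
  expect_identical(out[2:6, 2:6], matrix(1L, 5, 5))

  single <- matrix(0L, 4, 4)
  single[2, 2:3] <- 1L
  expect_identical(largest_component(single), single)

  # two equal components; the one whose first row-major pixel is earlier wins
  tie <- matrix(0L, 6, 6)
  tie[4, 1:3] <- 1L
  tie[2, 4:6] <- 1L
  kept <- largest_component(tie)
  comps <- oracle_components(tie)
  firsts <- sapply(comps, function(mm) {
    o <- order(mm[, 1L], mm[, 2L])
    mm[o[1L], 1L] * 1000 + mm[o[1L], 2L]
  })
  winner <- comps[[which.min(firsts)]]
  expect_identical(sum(kept), nrow(winner))
  expect_true(all(kept[winner] == 1L))

  # diagonal connectivity joins pixels into one component
  diag2 <- matrix(0L, 4, 4)
  diag2[1, 1] <- 1L
  diag2[2, 2] <- 1L
  expect_identical(largest_component(diag2), diag2)

  expect_error(largest_component(matrix(0L, 3, 3)), "no object")
})

test_that("endf equals the brute-force chessboard oracle and handles degenerate masks", {
  single <- matrix(0L, 5, 5)
  single[3, 3] <- 1L
  expect_identical(endf(single)[3, 3], 1L)

  block <- matrix(0L, 7, 7)
  block[2:6, 2:6] <- 1L
  d <- endf(block)
  expect_identical(d[4, 4], 3L)
  expect_identical(d[2, 2], 1L)
  expect_identical(d, oracle_chessboard(block))

  expect_identical(endf(matrix(0L, 4, 6)), matrix(0L, 4, 6))

  # the border counts as background: a full-foreground mask is still finite
  full <- matrix(1L, 6, 9)
  expect_identical(endf(full), oracle_chessboard(full))

  set.seed(31)
  for (rep in 1:25) {
    m <- random_mask(sample(3:15, 1), sample(3:15, 1), runif(1, 0.3, 0.8))
    expect_identical(endf(m), oracle_chessboard(m))
  }
})

test_that("dilating a mask never decreases any distance value", {
  set.seed(32)
  for (rep in 1:10) {
    m <- random_mask(12, 12, 0.5)
    d1 <- endf(m)
    grow <- m
    grow[sample(which(grow == 0), 10)] <- 1L
    d2 <- endf(grow)
    expect_true(all(d2 >= d1))
  }
})

test_that("the medial-axis trace attains the exhaustive-enumeration optimum with the stated tie-break", {
  # a one-pixel-high band admits a unique feasible path
  thin <- matrix(0L, 5, 8)
  thin[3, ] <- 2L
  tr <- trace_medial_axis(thin)
  expect_identical(tr$row, rep(3L, 8))
  expect_identical(tr$col, 1:8)

  # uniform band: tie-break selects the straight topmost path
  uni <- matrix(0L, 6, 4)
  uni[2:5, ] <- 1L
  expect_identical(trace_medial_axis(uni)$row, rep(2L, 4))

  # off-axis ridge: must follow the high-value ridge found by enumeration
  set.seed(33)
  for (rep in 1:20) {
    m <- random_band_map(sample(4:6, 1), sample(4:8, 1), 2L)
    tr <- trace_medial_axis(m)
    orc <- oracle_dp(m)
    expect_equal(sum(m[cbind(tr$row, tr$col)]), orc$sum)
    expect_identical(tr$row, as.integer(orc$rows))
  }

  # a gap in the positive band is a discontinuity error
  gap <- matrix(0L, 4, 6)
  gap[2, c(1, 2, 5, 6)] <- 3L
  expect_error(trace_medial_axis(gap), "discontinuous")
})

test_that("disc envelopes equal the pointwise union-of-discs oracle for every convention", {
  set.seed(34)
  for (rep in 1:15) {
    nc <- sample(5:12, 1)
    rows <- cumsum(c(sample(5:15, 1), sample(-1:1, nc - 1, replace = TRUE)))
    tr <- structure(
      tibble::tibble(
        col = seq_len(nc) + sample(0:3, 1), row = rows,
        value = sample(1:6, nc, replace = TRUE)
      ),
      class = c("mcw_trace", class(tibble::tibble()))
    )
    for (shape in c("square", "euclidean")) {
      for (radius in c("corrected", "distance", "half")) {
        env <- disc_envelope(tr, shape = shape, radius = radius)
        rad <- switch(radius,
          corrected = pmax(tr$value - 0.5, 0.5),
          distance = tr$value,
          half = tr$value / 2
        )
        orc <- oracle_envelope(tr, shape, rad)
        expect_identical(env$upper, orc$upper)
        expect_identical(env$lower, orc$lower)
        expect_true(all(env$upper <= tr$row & tr$row <= env$lower))
      }
    }
  }
})

test_that("a constant trace reading the value as the diameter gives centre +/- value/2", {
  tr <- structure(
    tibble::tibble(col = 1:30, row = 10L, value = 8),
    class = c("mcw_trace", class(tibble::tibble()))
  )
  env <- disc_envelope(tr, shape = "euclidean", radius = "half")
  mid <- 5:26 # away from the span ends the envelope is a constant band
  expect_true(all(env$upper[mid] == 6L))
  expect_true(all(env$lower[mid] == 14L))

  one <- structure(
    tibble::tibble(col = 5L, row = 10L, value = 8),
    class = c("mcw_trace", class(tibble::tibble()))
  )
  env1 <- disc_envelope(one, shape = "euclidean", radius = "half")
  expect_identical(env1$upper, 6L)
  expect_identical(env1$lower, 14L)
})

test_that("margin extraction is deterministic end to end", {
  rib <- render_ribbon(ribbon_spec(true_width_px = 24, seed = 35))
  run <- function() {
    mask <- largest_component(segment_cortex(rib$image)$binary)
    disc_envelope(trace_medial_axis(endf(mask)))
  }
  expect_identical(run(), run())
})
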