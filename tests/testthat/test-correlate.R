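test_that("both correlation backends match the brute-force oracle", {
  set.seed(11)
  fa <- matrix(runif(96 * 160), 96, 160)
  fb <- matrix(runif(96 * 160), 96, 160)
  for (w in c(16L, 48L)) {
    r <- if (w == 16) 5L else 8L
    ctr <- c(80L, 48L)
    reg <- extract_region(fb, ctr, w, r)
    A <- extract_region(fa, ctr, w, r)$A
    oracle <- naive_zncc(A, reg$B, r)
    d <- correlate_window_pair(fa, fb, ctr, w, r, method = "direct")
    f <- correlate_window_pair(fa, fb, ctr, w, r, method = "fft")
    expect_lt(max(abs(d$values - oracle)), 1e-8)
    expect_lt(max(abs(f$values - oracle)), 1e-8)
    expect_true(all(d$values >= -1 - 1e-12 & d$values <= 1 + 1e-12))
  }
})

test_that("a constructed shift is found with perfect correlation", {
  set.seed(4)
  fa <- matrix(runif(60 * 90), 60, 90)
  fb <- matrix(0, 60, 90)
  fb[2:60, 4:90] <- fa[1:59, 1:87]     # shift by (dx, dy) = (3, 1)
  p <- correlate_window_pair(fa, fb, c(45, 30), 16, 5)
  expect_equal(p$values[5 + 1 + 1, 5 + 3 + 1], 1, tolerance = 1e-12)
  pk <- locate_peak(p)
  expect_equal(unname(round(pk$displacement)), c(3, 1))
  # identity pair peaks at the origin
  pk0 <- locate_peak(correlate_window_pair(fa, fa, c(45, 30), 16, 5))
  expect_lt(sqrt(sum(pk0$displacement^2)), 0.05)
  expect_equal(pk0$peak_value, 1, tolerance = 1e-12)
})

test_that("swapping the frames negates the displacement", {
  for (s in c(1.5, 2.5, 4)) {
    pair <- shifted_pair(s, seed = s * 10)
    fwd <- locate_peak(correlate_window_pair(pair$f1, pair$f2,
                                             c(64, 32), 24, 6))
    bwd <- locate_peak(correlate_window_pair(pair$f2, pair$f1,
                                             c(64, 32), 24, 6))
    expect_lt(max(abs(fwd$displacement + bwd$displacement)), 0.05)
  }
})

test_that("degenerate and out-of-frame windows are handled", {
  flat <- matrix(7, 40, 40)
  p <- correlate_window_pair(flat, flat, c(20, 20), 16, 4)
  expect_true(p$degenerate)
  expect_true(all(p$values == 0))
  expect_error(locate_peak(p), "degenerate")
  img <- matrix(runif(1600), 40, 40)
  expect_error(correlate_window_pair(img, img, c(3, 20), 16, 4), "outside")
})

test_that("subpixel peaks, borders and ties behave as specified", {
  # symmetric Gaussian peak at integer lag (3, 1) -> exactly (3, 1)
  r <- 5
  lag <- expand.grid(dy = -r:r, dx = -r:r)
  vals <- matrix(exp(-((lag$dx - 3)^2 + (lag$dy - 1)^2) / 2), 2 * r + 1)
  pk <- locate_peak(vals)
  expect_equal(unname(pk$displacement), c(3, 1), tolerance = 1e-9)
  expect_false(pk$border_limited)
  # border peak is flagged and not refined
  valsb <- matrix(exp(-((lag$dx - 5)^2 + lag$dy^2) / 2), 2 * r + 1)
  pkb <- locate_peak(valsb)
  expect_true(pkb$border_limited)
  expect_equal(unname(pkb$displacement), c(5, 0))
  # exact tie between (2,0) and (-2,0): lexicographic tie-break
  valst <- matrix(0, 2 * r + 1, 2 * r + 1)
  valst[r + 1, r + 1 + 2] <- 0.9; valst[r + 1, r + 1 - 2] <- 0.9
  expect_equal(unname(locate_peak(valst)$displacement)[1], -2)
  # tie between magnitudes 1 and 3 resolves to the smaller displacement
  valsm <- matrix(0, 2 * r + 1, 2 * r + 1)
  valsm[r + 1, r + 1 + 1] <- 0.8; valsm[r + 1, r + 1 + 3] <- 0.8
  expect_equal(unname(locate_peak(valsm)$displacement)[1], 1)
})

test_that("rendered fractional shifts are located to better than 0.05 px", {
  pair <- shifted_pair(2.5, seed = 21)
  pk <- locate_peak(correlate_window_pair(pair$f1, pair$f2, c(64, 32), 16, 6))
  expect_lt(abs(pk$displacement[1] - 2.5), 0.05)
  expect_lt(abs(pk$displacement[2]), 0.05)
})
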