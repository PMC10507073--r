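kb <- loadKnowledgeBase()

test_that("state discretization follows the half-open guideline intervals", {
  ser <- data.frame(time = 1:5,
                    value = c(36.0, 36.8, 37.5, 36.2, 37.2))
  st <- discretize(ser, kb, "body_temperature")
  expect_equal(st$state,
               c("Hypothermia", "Normal", "Fever", "Normal", "Fever"))
  expect_equal(st$time, ser$time)
  expect_error(discretize(data.frame(time = 1, value = NaN), kb,
                          "body_temperature"), "non-finite")
})

test_that("interpolation places the grid on the union of timestamps", {
  out <- interpolateToGrid(list(
    a = data.frame(time = c(0, 2), value = c(0, 4)),
    b = data.frame(time = 1, value = 9)))
  expect_equal(out$time, c(0, 1, 2))
  expect_equal(out$values[, "a"], c(0, 2, 4))   # midpoint
  expect_equal(out$values[, "b"], c(9, 9, 9))   # boundary carry

  out2 <- interpolateToGrid(list(
    a = data.frame(time = c(0, 4), value = c(0, 4)),
    b = data.frame(time = 1, value = 5)))
  expect_equal(out2$values[out2$time == 1, "a"], c(a = 1))
  expect_error(interpolateToGrid(list()), "empty")
})

test_that("interpolation matches the two-point line equation everywhere", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(2:20, 1)
    tt <- sort(runif(n, 0, 100))
    vv <- rnorm(n)
    other <- data.frame(time = runif(8, -5, 105), value = rnorm(8))
    out <- interpolateToGrid(list(
      x = data.frame(time = tt, value = vv), o = other))
    for (g in seq_along(out$time)) {
      tau <- out$time[g]
      expected <- if (tau <= tt[1]) vv[1]
      else if (tau >= tt[n]) vv[n]
      else {
        j <- max(which(tt <= tau))
        if (tt[j] == tau) vv[j]
        else vv[j] + (vv[j + 1] - vv[j]) * (tau - tt[j]) / (tt[j + 1] - tt[j])
      }
      expect_lt(abs(out$values[g, "x"] - expected), 1e-9)
    }
  }
})

test_that("simple gradients encode the sign of consecutive differences", {
  ser <- data.frame(time = 1:4, value = c(3, 5, 5, 2))
  g <- computeGradients(ser, kb, "heart_rate", mode = "simple")
  expect_equal(g$gradient, c("Increasing", "Stable", "Decreasing"))
  expect_equal(g$time, 2:4)
  expect_equal(nrow(g), nrow(ser) - 1)
  expect_error(computeGradients(data.frame(time = 1, value = 1), kb,
                                "heart_rate"), "at least 2")
})

test_that("thresholded gradients respect delta and the stable window", {
  t0 <- 0
  ser <- data.frame(time = c(t0, t0 + 1800), value = c(70, 75))
  g <- computeGradients(ser, kb, "heart_rate", mode = "thresholded")
  expect_equal(g$gradient, "Stable")   # |5| <= 10 within 1 h
  ser2 <- data.frame(time = c(t0, t0 + 1800), value = c(70, 85))
  g2 <- computeGradients(ser2, kb, "heart_rate", mode = "thresholded")
  expect_equal(g2$gradient, "Increasing")  # |15| > 10
  ser3 <- data.frame(time = c(t0, t0 + 7200), value = c(70, 75))
  g3 <- computeGradients(ser3, kb, "heart_rate", mode = "thresholded")
  expect_equal(g3$gradient, "Increasing")  # small move but gap > 1 h
})

test_that("simple gradients are shift-invariant and negation-equivariant", {
  set.seed(4)
  for (rep in 1:20) {
    ser <- data.frame(time = 1:12, value = rnorm(12))
    g0 <- computeGradients(ser, kb, "wbc")$gradient
    shifted <- ser; shifted$value <- shifted$value + rnorm(1)
    expect_equal(computeGradients(shifted, kb, "wbc")$gradient, g0)
    neg <- ser; neg$value <- -neg$value
    gneg <- computeGradients(neg, kb, "wbc")$gradient
    flip <- c(Increasing = "Decreasing", Decreasing = "Increasing",
              Stable = "Stable")
    expect_equal(gneg, unname(flip[g0]))
  }
})

test_that("flattening orders by time, then knowledge-base concept order", {
  st_hr <- data.frame(time = c(1, 3), state = c("Normal", "Tachycardia"))
  st_rr <- data.frame(time = c(1, 2), state = c("Normal", "High"))
  flat <- flattenEvents(list(heart_rate = st_hr, respiratory_rate = st_rr),
                        NULL, kb)
  # heart_rate precedes respiratory_rate in the knowledge base
  expect_equal(flat$symbol,
               c("heart_rate:Normal", "respiratory_rate:Normal",
                 "respiratory_rate:High", "heart_rate:Tachycardia"))
  single <- flattenEvents(list(heart_rate = st_hr), NULL, kb)
  expect_equal(single$symbol,
               c("heart_rate:Normal", "heart_rate:Tachycardia"))
})

test_that("states precede gradients at identical time and concept", {
  st <- data.frame(time = c(1, 2), state = c("Normal", "Tachycardia"))
  gr <- data.frame(time = 2, gradient = "Increasing")
  flat <- flattenEvents(list(heart_rate = st), list(heart_rate = gr), kb)
  expect_equal(flat$symbol[2:3],
               c("heart_rate:Tachycardia", "heart_rate:Increasing"))
})

test_that("one-hot padding truncates from the start and pads at the end", {
  vocab <- c("<pad>", letters[1:6])
  enc <- encodeOnehotPad(c("a", "b", "c"), vocab, 5)
  expect_equal(enc$indices, c(2L, 3L, 4L, 1L, 1L))
  expect_equal(enc$mask, c(1, 1, 1, 0, 0))
  enc2 <- encodeOnehotPad(letters[c(1:6, 1)], vocab, 5)
  expect_equal(enc2$indices, c(4L, 5L, 6L, 7L, 2L))  # last five kept
  enc3 <- encodeOnehotPad(character(0), vocab, 4)
  expect_equal(enc3$indices, rep(1L, 4))
  expect_equal(enc3$mask, rep(0, 4))
  expect_error(encodeOnehotPad("zz", vocab, 4), "unknown symbol")
})

test_that("discretization commutes with interpolation at observed points", {
  set.seed(7)
  tt <- sort(runif(10, 0, 50))
  vv <- runif(10, 50, 95)
  ser <- data.frame(time = tt, value = vv)
  other <- data.frame(time = runif(6, 0, 50), value = runif(6, 50, 95))
  grid <- interpolateToGrid(list(heart_rate = ser, x = other))
  direct <- discretize(ser, kb, "heart_rate")
  at_obs <- grid$values[match(tt, grid$time), "heart_rate"]
  through <- discretize(data.frame(time = tt, value = at_obs), kb,
                        "heart_rate")
  expect_equal(through$state, direct$state)
})

test_that("encoded chart samples have a stable vocabulary and valid masks", {
  tabs <- generateEHR(synthConfig(n_patients = 20, seed = 2), kb)
  cohort <- buildCohort(tabs, kb)$cohort
  smp <- encodeChartsSamples(tabs, cohort, kb, L = 40, gradients = "simple")
  expect_s4_class(smp, "EncodedSampleSet")
  expect_identical(smp@vocab, kbVocabulary(kb, gradients = TRUE))
  expect_true(all(smp@indices[smp@mask == 0] == 1L))
  expect_true(all(smp@indices >= 1 & smp@indices <= length(smp@vocab)))
  expect_equal(length(smp), nrow(cohort))
})
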