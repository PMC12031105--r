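test_that("analytic-signal phase matches identities and the Hilbert oracle", {
  fs <- 200
  t <- seq(0, 3 - 1e-9, by = 1 / fs)
  ph <- instantaneous_phase(sin(2 * pi * 10 * t))
  i <- 100:500
  step <- diff(ph)[i]
  step <- step[abs(step) < pi] # unwrap jumps
  expect_equal(mean(step), 2 * pi * 10 / fs, tolerance = 0.01)

  # cos leads sin by pi/2 at the same frequency
  pc <- instantaneous_phase(cos(2 * pi * 10 * t))
  ps <- instantaneous_phase(sin(2 * pi * 10 * t))
  d <- atan2(sin(pc - ps), cos(pc - ps))
  expect_equal(mean(d[i]), pi / 2, tolerance = 0.05)

  # arbitrary band-limited signal vs direct-convolution Hilbert oracle
  set.seed(1)
  x <- as.numeric(stats::filter(rnorm(256), rep(1, 8), sides = 2))
  x[is.na(x)] <- 0
  expect_equal(instantaneous_phase(x), oracle_analytic_phase(x),
    tolerance = 1e-8)

  expect_error(instantaneous_phase(rep(2, 100)), "constant")
})

test_that("PLV obeys its synchrony and invariance contracts", {
  ph <- seq(0, 20 * pi, length.out = 600)
  expect_equal(plv(ph, ph), 1)
  expect_equal(plv(ph, ph - pi / 3), 1, tolerance = 1e-12)
  # offset invariance: adding a constant to one series changes nothing
  set.seed(2)
  pa <- runif(600, -pi, pi)
  pb <- runif(600, -pi, pi)
  expect_equal(plv(pa, pb), plv(pa + 1.23, pb), tolerance = 1e-12)
  # i.i.d. uniform phase differences: Rayleigh floor ~ 1/sqrt(n)
  nulls <- vapply(1:50, function(s) {
    set.seed(s)
    plv(runif(600, -pi, pi), runif(600, -pi, pi))
  }, numeric(1))
  expect_lt(max(nulls), 0.15)
  expect_error(plv(pa, pb[1:10]), "mismatch")
})

test_that("PLI detects consistent lags and ignores symmetric ones", {
  ph <- cumsum(rep(0.1, 600))
  expect_equal(pli(ph, ph - pi / 3), 1)
  expect_equal(pli(ph, ph), 0)
  half <- rep(c(pi / 4, -pi / 4), 300)
  expect_equal(pli(ph, ph - half), 0)
  expect_equal(pli(ph, ph - pi / 3), pli(ph - pi / 3, ph))
})

test_that("PCC matches affine identities and a hand-computed case", {
  x <- c(1, 2, 3, 4)
  expect_equal(pcc(x, 2 * x + 3), 1)
  expect_equal(pcc(x, -x), -1)
  expect_equal(pcc(x, c(2, 1, 4, 3)), 0.6)
  expect_error(pcc(x, rep(1, 4)), "zero-variance")
})

test_that("histogram MI matches entropy identities and the null oracle", {
  set.seed(3)
  x <- rnorm(600)
  # y = x gives I = H(X) exactly
  bx <- cut(x, breaks = seq(min(x), max(x), length.out = 17),
    include.lowest = TRUE)
  px <- as.numeric(table(bx)) / 600
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  expect_equal(mutual_information(x, x, 16), hx, tolerance = 1e-10)

  # two equiprobable values, y = x: exactly 1 bit
  b <- rep(c(0, 1), 300)
  expect_equal(mutual_information(b, b, 2), 1)

  # independence null: plug-in positive bias ~ (B-1)^2/(2N ln 2);
  # frozen bounds computed from the Monte-Carlo null oracle
  nulls <- vapply(1:30, function(s) {
    set.seed(s)
    mutual_information(runif(600), runif(600), 16)
  }, numeric(1))
  expect_lt(mean(nulls), 0.32)
  expect_lt(max(nulls), 0.40)
  expect_gt(min(nulls), 0)

  expect_warning(v <- mutual_information(rep(1, 100), rnorm(100)),
    "constant")
  expect_equal(v, 0)
})

test_that("connectivity matrices are symmetric, bounded and well-shaped", {
  set.seed(4)
  fs <- 200
  n_ch <- 8L
  ep <- array(rnorm(2 * n_ch * 600), dim = c(2, n_ch, 600))
  es <- epoch_set(ep, labels = c("low", "low"), task_tags = c("t", "t"),
    fs = fs, band = "theta")
  for (method in c("plv", "pli", "pcc", "mi")) {
    mats <- connectivity_matrix(es, method)
    expect_length(mats, 2L)
    M <- unclass(mats[[1]])
    expect_true(all(abs(M - t(M)) < 1e-9))
    expect_true(all(diag(M) == 0))
    expect_true(all(M >= 0))
    if (method %in% c("plv", "pli")) expect_true(all(M <= 1))
    if (method == "pcc") {
      expect_true(all(abs(attr(mats[[1]], "signed")) <= 1 + 1e-12))
    }
    expect_identical(attr(mats[[1]], "method"), method)
    expect_identical(attr(mats[[1]], "band"), "theta")
  }
  avg <- connectivity_matrix(es, "plv", average_epochs = TRUE)
  expect_equal(unclass(avg),
    (unclass(connectivity_matrix(es, "plv")[[1]]) +
      unclass(connectivity_matrix(es, "plv")[[2]])) / 2,
    tolerance = 1e-12)
})

test_that("59 channels give 1711 pairs per band and 6844 across bands", {
  n <- 59
  expect_equal(n * (n - 1) / 2, 1711)
  expect_equal(4 * n * (n - 1) / 2, 6844)
  # and the feature matrix layout agrees on a small montage
  set.seed(5)
  rec <- recording(matrix(rnorm(6 * 1200), 6), fs = 200,
    meta = list(task = "t", level = "low"))
  fm <- connectivity_feature_matrix(list(rec), notch = NULL)
  expect_equal(ncol(fm$features), 4 * 6 * 5 / 2)
  expect_equal(nrow(fm$feature_info), ncol(fm$features))
})

test_that("mean PLV rises monotonically over the coupling grid", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  n_ep <- 30L
  mean_plv <- vapply(seq_along(grid), function(k) {
    vals <- vapply(seq_len(n_ep), function(e) {
      # independent 3-s epoch realizations at this coupling
      p <- generate_coupled_pair(
        freq = 6, phase_lag = pi / 4, coupling = grid[k],
        duration = 3, fs = 200, noise_sd = 0, seed = 100 * k + e
      )
      plv(p$phase_x, p$phase_y)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_equal(cor(mean_plv, grid, method = "spearman"), 1)
})
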