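# Richardson order estimation and the truncation order of the discrete
# momentum operators.

test_that("discrete momentum operators are second order on a manufactured field", {
  a <- 2 * pi
  Re <- 10
  errs <- sapply(c(16L, 32L, 64L), function(n) {
    h <- 1 / n
    xf <- (seq_len(n + 1) - 1) * h          # u: x-faces
    yc <- (seq_len(n) - 0.5) * h            # u: y-centers
    xc <- (seq_len(n) - 0.5) * h            # v: x-centers
    yf <- (seq_len(n + 1) - 1) * h          # v: y-faces
    u <- outer(xf, yc, function(x, y) sin(a * x) * cos(a * y))
    v <- outer(xc, yf, function(x, y) 0.5 * cos(a * x) * sin(a * y))
    F <- aneuflow:::momentum_rhs_2d(u, v, h, Re)
    # closed forms of the conservative advective + diffusive right-hand sides
    Fu_exact <- outer(xf[2:n], yc, function(x, y)
      -(a * sin(2 * a * x) * cos(a * y)^2 +
          0.25 * a * sin(2 * a * x) * cos(2 * a * y)) -
        (2 * a^2 / Re) * sin(a * x) * cos(a * y))
    Fv_exact <- outer(xc, yf[2:n], function(x, y)
      -(0.25 * a * cos(2 * a * x) * sin(2 * a * y) +
          0.25 * a * cos(a * x)^2 * sin(2 * a * y)) -
        (a^2 / Re) * cos(a * x) * sin(a * y))
    mar <- 3
    iu <- mar:(n - 1 - mar); ju <- mar:(n - mar)
    iv <- mar:(n - mar); jv <- mar:(n - 1 - mar)
    max(abs(F$Fu[iu, ju] - Fu_exact[iu, ju]),
        abs(F$Fv[iv, jv] - Fv_exact[iv, jv]))
  })
  orders <- log2(errs[-3] / errs[-1])
  expect_gt(min(orders), 1.8)
  expect_lt(max(orders), 2.2)
})

test_that("grid-independent fields are reported as converged, not as an order", {
  sols <- lapply(c(16L, 32L, 64L), function(n) {
    st <- init_flow(channel_mask(n), solver_config(reynolds = 10))
    st$u[] <- 1; st$v[] <- 0
    st
  })
  est <- estimate_convergence_order(sols[[1]], sols[[2]], sols[[3]])
  expect_true(est$converged)
  expect_true(is.na(est$order))
})

test_that("non-nested grids are a usage error", {
  s16 <- init_flow(channel_mask(16), solver_config(reynolds = 10))
  s24 <- init_flow(channel_mask(24), solver_config(reynolds = 10))
  s32 <- init_flow(channel_mask(32), solver_config(reynolds = 10))
  expect_error(estimate_convergence_order(s16, s24, s32),
               class = "aneuflow_usage_error")
})
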