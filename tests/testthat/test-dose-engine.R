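test_that("beam arrangements follow start + k * interval (mod 360)", {
  expect_equal(beamset(9, 40)$angles, seq(0, 320, by = 40))
  expect_equal(beamset(7, 50)$angles, seq(0, 300, by = 50))
  expect_equal(beamset(1, 0, 90)$angles, 90)
  expect_equal(beamset(4, 180, 90)$angles, c(90, 270, 90, 270))
})

test_that("influence entries follow the closed-form ray model", {
  ph <- tiny_cshape()
  # zero attenuation: dose constant along each central ray inside the body
  inf0 <- dose_influence(ph, beamset(1, 0, 0),
                         engine_kernel(mu = 0, sigma_mm = 1e6))
  expect_true(all(inf0$A >= 0))
  col <- inf0$A[, ceiling(ncol(inf0$A) / 2)]
  expect_lt(diff(range(col)), 1e-8)

  # with attenuation, entry = exp(-mu * depth) relative to the surface value
  mu <- 0.01
  inf1 <- dose_influence(ph, beamset(1, 0, 0),
                         engine_kernel(mu = mu, sigma_mm = 1e6))
  j <- ceiling(ncol(inf1$A) / 2)
  gs <- ph$grid_shape
  body_rows <- which(ph$masks$body[, gs[2] / 2])
  # voxels in one column of the body, beam from the top: depth grows by one
  # spacing per row
  idx <- which(inf1$body_idx %in% ((gs[2] / 2 - 1) * gs[1] + body_rows))
  vals <- inf1$A[idx, j]
  depths <- (seq_along(vals) - 1) * ph$spacing
  expect_equal(vals, vals[1] * exp(-mu * depths), tolerance = 1e-10)
})

test_that("dose is linear in fluence and zero fluence gives zero dose", {
  ph <- tiny_cshape()
  inf <- dose_influence(ph, beamset(3, 120), tiny_kernel())
  set.seed(1)
  f1 <- runif(ncol(inf$A)); f2 <- runif(ncol(inf$A))
  expect_equal(as.vector(inf$A %*% (2 * f1 + f2)),
               as.vector(2 * (inf$A %*% f1) + inf$A %*% f2), tolerance = 1e-12)
  expect_equal(max(abs(inf$A %*% numeric(ncol(inf$A)))), 0)
})

test_that("quadratic objective matches a term-by-term brute force", {
  set.seed(42)
  dose <- runif(20, 0, 120)
  omega <- list(ptv = 1:8, core = 9:12, nt = 13:20)
  spec <- objective_spec(c(ptv = 100, oar = 30, nt = 15),
                         c(ptv = 2, oar = 1.5, nt = 0.5), ptv_margin = 0.05)
  # independent direct summation with the positive operator
  pos <- function(x) ifelse(x > 0, x, 0)
  manual <- 2 * sum(pos(100 - dose[1:8])^2) +
    2 * sum(pos(dose[1:8] - 105)^2) +
    1.5 * sum(pos(dose[9:12] - 30)^2) +
    0.5 * sum(pos(dose[13:20] - 15)^2)
  expect_equal(dose_objective(dose, spec, omega), manual, tolerance = 1e-12)

  # all doses inside their bands: the positive operator vanishes
  dose_ok <- c(rep(102, 8), rep(10, 4), rep(5, 8))
  expect_equal(dose_objective(dose_ok, spec, omega), 0)

  # single underdosed target voxel: (100 - 90)^2 = 100
  spec1 <- objective_spec(c(ptv = 100, oar = 30, nt = 15),
                          c(ptv = 1, oar = 0, nt = 0), ptv_margin = 10)
  dose1 <- c(90, rep(101, 7), rep(0, 12))
  expect_equal(dose_objective(dose1, spec1, omega), 100)

  expect_error(objective_spec(c(ptv = 100, oar = 30, nt = 15),
                              c(ptv = -1, oar = 1, nt = 1)),
               class = "fuzzyplan_error_spec")
})

test_that("fluence optimization solves analytic and brute-force cases", {
  # single voxel, single beamlet, unit influence, d_min = d_max = 100
  inf <- structure(list(A = matrix(1, 1, 1), body_idx = 1L,
                        omega = list(ptv = 1L, nt = integer())),
                   class = "influence")
  spec <- objective_spec(c(ptv = 100, oar = 50, nt = 50),
                         c(ptv = 1, oar = 1, nt = 1), ptv_margin = 0)
  res <- optimize_fluence(inf, spec, init = 1)
  expect_equal(res$fluence, 100, tolerance = 1e-4)
  expect_true(res$converged)

  # all weights zero: objective is identically zero, init returned unchanged
  spec0 <- objective_spec(c(ptv = 100, oar = 50, nt = 50),
                          c(ptv = 0, oar = 0, nt = 0))
  res0 <- optimize_fluence(inf, spec0, init = 7)
  expect_equal(res0$F, 0)
  expect_equal(res0$fluence, 7)

  # 3-beamlet instance vs an exhaustive fluence grid search
  set.seed(5)
  A <- matrix(runif(30, 0, 1), 10, 3)
  infg <- structure(list(A = A, body_idx = 1:10,
                         omega = list(ptv = 1:4, core = 5:7, nt = 8:10)),
                    class = "influence")
  specg <- objective_spec(c(ptv = 100, oar = 30, nt = 20),
                          c(ptv = 1, oar = 0.5, nt = 0.2))
  resg <- optimize_fluence(infg, specg, control = list(max_iter = 2000,
                                                       tol = 1e-9))
  grid <- seq(0, 300, by = 2)
  best <- Inf
  for (f1 in grid) for (f2 in grid) {
    # vectorize the innermost loop over f3
    doses <- A[, 1] %o% rep(1, length(grid)) * f1 +
      A[, 2] %o% rep(1, length(grid)) * f2 + A[, 3] %o% grid
    under <- pmax(100 - doses[1:4, , drop = FALSE], 0)
    overp <- pmax(doses[1:4, , drop = FALSE] - 105, 0)
    overo <- pmax(doses[5:7, , drop = FALSE] - 30, 0)
    overn <- pmax(doses[8:10, , drop = FALSE] - 20, 0)
    F <- colSums(under^2) + colSums(overp^2) + 0.5 * colSums(overo^2) +
      0.2 * colSums(overn^2)
    best <- min(best, min(F))
  }
  expect_lt(resg$F, best * 1.01 + 1e-9)
})

test_that("accepted iterates never increase the objective", {
  ph <- tiny_cshape()
  inf <- dose_influence(ph, beamset(5, 72), tiny_kernel())
  spec <- objective_spec(c(ptv = 100, oar = 20, nt = 15),
                         c(ptv = 1 / 50, oar = 1 / 20, nt = 1 / 500))
  res <- optimize_fluence(inf, spec)
  expect_true(all(diff(res$trace) <= 1e-9))
})

test_that("raising the OAR weight never increases the converged OAR mean", {
  ph <- tiny_cshape()
  inf <- dose_influence(ph, beamset(5, 72), tiny_kernel())
  n_oar <- length(inf$omega$core)
  oar_means <- vapply(c(0.5, 1, 2, 5, 20), function(w_oar) {
    spec <- objective_spec(
      c(ptv = 100, oar = 20, nt = 25),
      c(ptv = 1 / length(inf$omega$ptv), oar = w_oar / n_oar,
        nt = 1 / length(inf$omega$nt))
    )
    res <- optimize_fluence(inf, spec, control = list(max_iter = 2000,
                                                      tol = 1e-8))
    mean(res$dose[inf$omega$core]) / mean(res$dose[inf$omega$ptv])
  }, numeric(1))
  expect_true(all(diff(oar_means) <= 1e-6))
})

test_that("dose normalization rescales the target mean exactly", {
  dose <- c(50, 60, 10)
  out <- normalize_dose(dose, 1:2, to = 100)
  expect_equal(mean(out[1:2]), 100)
  expect_equal(out[3] / out[1], dose[3] / dose[1])
})
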