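test_that("relative dose deviation follows (D - PD) / PD", {
  traj <- toy_trajectory()
  s1 <- traj[traj$t == 1, ]
  expect_equal(delta_dose(s1, "ptv"), (90 - 100) / 100)
  expect_equal(delta_dose(s1, "oar"), (22 - 20) / 20)
  s_eq <- s1
  s_eq$pd[s_eq$channel == "ptv"] <- 90
  expect_equal(delta_dose(s_eq, "ptv"), 0)
  s_bad <- s1
  s_bad$pd[1] <- 0
  expect_error(delta_dose(s_bad, "ptv"), class = "fuzzyplan_error_snapshot")
})

test_that("DVH-derived mean tracks the voxel mean within one volume bin", {
  set.seed(21)
  for (k in 1:10) {
    dose <- runif(200, 0, 120)
    rec <- fuzzyplan:::dvh_record(dose)
    expect_lt(abs(dvh_mean(rec) - mean(dose)),
              (max(dose) - min(dose)) / 10 + 1e-9)
  }
  # a flat record integrates to the constant dose exactly
  flat <- tibble::tibble(volume = seq(0, 100, 10), dose = 42)
  expect_equal(dvh_mean(flat), 42)
})

test_that("plan-parameter deltas follow the relative-difference formulas", {
  traj <- toy_trajectory()
  d <- delta_tpp(traj[traj$t == 1, ], traj[traj$t == 2, ])
  expect_equal(d$d_pd[d$channel == "ptv"], 0.10)
  expect_equal(d$d_pd[d$channel == "oar"], (18 - 20) / 20)
  expect_equal(d$d_wf[d$channel == "ptv"], 0.5)
  # unchanged parameters give zero deltas
  same <- delta_tpp(traj[traj$t == 1, ], traj[traj$t == 1, ])
  expect_equal(same$d_pd, rep(0, 3))
  expect_equal(same$d_wf, rep(0, 3))
  bad <- traj[traj$t == 1, ]
  bad$wf[2] <- 0
  expect_error(delta_tpp(bad, traj[traj$t == 2, ]),
               class = "fuzzyplan_error_snapshot")
})

test_that("dataset construction yields n-1 sample rows per network", {
  traj <- toy_trajectory()
  ds <- build_dataset(traj)
  expect_equal(nrow(ds), 2 * 6)
  expect_setequal(unique(ds$target),
                  c("pd_ptv", "pd_oar", "pd_nt", "wf_ptv", "wf_oar", "wf_nt"))
  # hand-computed first-pair values
  r <- ds[ds$t == 1 & ds$target == "wf_ptv", ]
  expect_equal(r$dd_ptv, -0.10)
  expect_equal(r$dd_oar, 0.10)
  expect_equal(r$dd_nt, 0.20)
  expect_equal(r$y, 0.5)
  expect_equal(ds$y[ds$t == 1 & ds$target == "pd_oar"], -0.10)

  expect_equal(nrow(build_dataset(list())), 0)
  one <- traj[traj$t == 1, ]
  expect_warning(out <- build_dataset(one), "fewer than 2")
  expect_equal(nrow(out), 0)
})

test_that("phantom-level splits are disjoint, sized and reproducible", {
  samples <- tibble::tibble(phantom_id = rep(sprintf("p%03d", 1:150), each = 2),
                            y = 0)
  sp <- split_by_phantom(samples, 0.6, seed = 4)
  expect_equal(length(unique(sp$train$phantom_id)), 90)
  expect_equal(length(unique(sp$validation$phantom_id)), 60)
  expect_length(intersect(sp$train$phantom_id, sp$validation$phantom_id), 0)
  sp2 <- split_by_phantom(samples, 0.6, seed = 4)
  expect_identical(sp$train$phantom_id, sp2$train$phantom_id)

  two <- tibble::tibble(phantom_id = c("a", "b"), y = 0)
  sp3 <- split_by_phantom(two, 0.5, seed = 1)
  expect_equal(nrow(sp3$train), 1)
  expect_equal(nrow(sp3$validation), 1)
  expect_error(split_by_phantom(tibble::tibble(phantom_id = "a", y = 0), 0.5),
               class = "fuzzyplan_error_split")
})

test_that("analytic gradients match central finite differences", {
  set.seed(7)
  worst <- 0
  for (k in 1:3) {
    net <- random_network(200 + k)
    X <- matrix(runif(45, -1, 1), 15, 3)
    y <- rnorm(15, 0, 0.3)
    g <- network_gradients(net, X, y)
    mse_at <- function(n) mean((fuzzyplan:::fuzzy_forward(n, X)$f - y)^2)
    eps <- 1e-6
    for (fld in c("a", "b", "consequents")) {
      th <- net[[fld]]
      gname <- if (fld == "consequents") "cons" else fld
      for (i in seq_along(th)) {
        np <- net; np[[fld]][i] <- th[i] + eps
        nm <- net; nm[[fld]][i] <- th[i] - eps
        fd <- (mse_at(np) - mse_at(nm)) / (2 * eps)
        worst <- max(worst, abs(fd - g[[gname]][i]) / max(abs(fd), 1e-4))
      }
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("an unregularized constant-target fit recovers the constant", {
  set.seed(12)
  net <- fis_network("wf_nt")
  net$consequents <- matrix(0, 8, 4)
  k <- 0.3
  samples <- tibble::tibble(
    phantom_id = rep(c("a", "b", "c", "d"), each = 50),
    t = 1:200,
    dd_ptv = runif(200, -1, 1), dd_oar = runif(200, -1, 1),
    dd_nt = runif(200, -1, 1),
    target = "wf_nt", y = k
  )
  fit <- anfis_train(net, samples,
                     anfis_control(lr = 0.05, l2_beta = 0, seed = 2,
                                   max_epochs = 800L, patience = 200L,
                                   lr_patience = 100L))
  probe <- matrix(runif(3000, -1, 1), 1000, 3)
  preds <- fuzzyplan:::fuzzy_forward(fit$network, probe)$f
  expect_true(all(abs(preds - k) < 1e-3))
})

test_that("noise-free teacher recovery succeeds without weight decay", {
  teacher <- random_network(55, "pd_nt")
  teacher$a <- teacher$a / 3 # keep memberships graded over the input range
  samples <- simulate_samples(teacher, 1500, seed = 66)
  fit <- anfis_train(fis_network("pd_nt"), samples,
                     anfis_control(l2_beta = 0, seed = 9))
  expect_lt(min(fit$history$val_mse), 1e-4)
})

test_that("early stopping returns the best validation parameters seen", {
  teacher <- random_network(18, "wf_oar")
  samples <- simulate_samples(teacher, 600, seed = 19)
  fit <- anfis_train(fis_network("wf_oar"), samples, anfis_control(seed = 20))
  parts <- split_by_phantom(samples[samples$target == "wf_oar", ],
                            0.6, seed = 20L)
  Xva <- cbind(parts$validation$dd_ptv, parts$validation$dd_nt,
               parts$validation$dd_oar)
  val_returned <- mean((fuzzyplan:::fuzzy_forward(fit$network, Xva)$f -
                          parts$validation$y)^2)
  expect_equal(val_returned, min(fit$history$val_mse), tolerance = 1e-12)
  expect_lte(min(fit$history$val_mse), fit$history$val_mse[1])
  # reported history is the pure MSE: strictly smaller than MSE + L2 would be
  expect_true(all(fit$history$train_mse >= 0))
})

test_that("training a mismatched or empty target errors", {
  samples <- simulate_samples(random_network(3, "wf_ptv"), 50, seed = 4)
  expect_error(anfis_train(fis_network("pd_oar"), samples),
               class = "fuzzyplan_error_training")
})

test_that("shared consequents tie all rules to four coefficients", {
  teacher <- fis_network("wf_ptv")
  teacher$consequents <- matrix(rep(c(0.05, 0.2, -0.1, 0.15), each = 8), 8, 4)
  samples <- simulate_samples(teacher, 400, seed = 31)
  fit <- anfis_train(fis_network("wf_ptv"), samples,
                     anfis_control(seed = 32, shared_consequents = TRUE,
                                   max_epochs = 100))
  cons <- fit$network$consequents
  expect_equal(max(apply(cons, 2, function(col) diff(range(col)))), 0)
})
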