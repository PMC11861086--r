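# Training-sample construction from recorded planning trajectories and
# gradient training of the six fuzzy networks (Adam on MSE + L2).
#
# A trajectory is a tibble with one row per (snapshot t, channel):
#   phantom_id, t, channel (ptv/oar/nt), pd, wf, mean_dose,
#   dvh (list-column of tibble(volume, dose), volume grid 0,10,...,100 %).

#' Mean dose from a coarse dose-volume record
#'
#' Snapshots store the cumulative DVH as dose-at-volume points on the fixed
#' 0, 10, ..., 100% volume grid; the mean dose is the trapezoidal integral of
#' dose over volume fraction (it agrees with the voxel mean to within one
#' volume-bin width).
#'
#' @param dvh Tibble with columns `volume` (percent, 0..100) and `dose`.
#' @return Scalar mean dose.
#' @export
dvh_mean <- function(dvh) {
  v <- dvh$volume / 100
  d <- dvh$dose
  o <- order(v)
  v <- v[o]; d <- d[o]
  sum(diff(v) * (head(d, -1) + tail(d, -1)) / 2)
}

# dose-at-volume record on the 0..100-by-10 grid from a voxel dose vector
dvh_record <- function(dose) {
  vols <- seq(0, 100, by = 10)
  tibble(volume = vols,
         dose = vapply(vols, function(q) dose_at_volume(dose, q), numeric(1)))
}

snapshot_at <- function(trajectory, t_val) {
  trajectory[trajectory$t == t_val, , drop = FALSE]
}

#' Relative dose deviation of one channel at one snapshot
#'
#' `dd = (D(t) - PD(t)) / PD(t)` with `D(t)` the channel's mean dose derived
#' from the recorded DVH.
#'
#' @param snapshot One snapshot (trajectory rows sharing `t`).
#' @param channel `"ptv"`, `"oar"` or `"nt"`.
#' @return Scalar relative deviation.
#' @export
delta_dose <- function(snapshot, channel) {
  row <- snapshot[snapshot$channel == channel, ]
  if (nrow(row) != 1) abort(sprintf("Channel '%s' missing from snapshot.", channel),
                            class = "fuzzyplan_error_snapshot")
  if (row$pd <= 0) abort("Prescription dose must be positive.",
                         class = "fuzzyplan_error_snapshot")
  d <- dvh_mean(row$dvh[[1]])
  (d - row$pd) / row$pd
}

#' Relative plan-parameter changes between consecutive snapshots
#'
#' @param prev,nxt Snapshots at t and t+1.
#' @return Tibble with one row per channel: `d_pd = (PD(t+1) - PD(t))/PD(t)`
#'   and `d_wf` analogous.
#' @export
delta_tpp <- function(prev, nxt) {
  m <- dplyr::inner_join(
    prev[, c("channel", "pd", "wf")],
    nxt[, c("channel", "pd", "wf")],
    by = "channel", suffix = c("_0", "_1")
  )
  if (any(m$pd_0 <= 0) || any(m$wf_0 <= 0)) {
    abort("Plan parameters must be positive.",
          class = "fuzzyplan_error_snapshot")
  }
  tibble(channel = m$channel,
         d_pd = (m$pd_1 - m$pd_0) / m$pd_0,
         d_wf = (m$wf_1 - m$wf_0) / m$wf_0)
}

#' Build supervised training samples from planning trajectories
#'
#' Each consecutive snapshot pair (t, t+1) yields one input triple (the
#' relative dose deviations at t) and six supervised outputs (the relative
#' prescription-dose and weight changes applied between t and t+1), one per
#' plan-parameter network.
#'
#' @param trajectories A trajectory tibble (possibly covering several
#'   phantoms) or a list of them.
#' @return Tibble with columns `phantom_id`, `t`, `dd_ptv`, `dd_oar`, `dd_nt`,
#'   `target`, `y`. Trajectories with fewer than two snapshots are skipped
#'   with a warning.
#' @export
build_dataset <- function(trajectories) {
  if (is.data.frame(trajectories)) trajectories <- list(trajectories)
  traj <- dplyr::bind_rows(trajectories)
  empty <- tibble(phantom_id = character(), t = integer(),
                  dd_ptv = numeric(), dd_oar = numeric(), dd_nt = numeric(),
                  target = character(), y = numeric())
  if (nrow(traj) == 0) return(empty)
  out <- list()
  for (pid in unique(traj$phantom_id)) {
    tr <- traj[traj$phantom_id == pid, ]
    ts <- sort(unique(tr$t))
    if (length(ts) < 2) {
      warn(sprintf("Trajectory '%s' has fewer than 2 snapshots; skipped.", pid))
      next
    }
    for (j in seq_len(length(ts) - 1)) {
      s0 <- snapshot_at(tr, ts[j])
      s1 <- snapshot_at(tr, ts[j + 1])
      dd <- vapply(c("ptv", "oar", "nt"), function(ch) delta_dose(s0, ch),
                   numeric(1))
      dt <- delta_tpp(s0, s1)
      y <- c(
        pd_ptv = dt$d_pd[dt$channel == "ptv"],
        pd_oar = dt$d_pd[dt$channel == "oar"],
        pd_nt = dt$d_pd[dt$channel == "nt"],
        wf_ptv = dt$d_wf[dt$channel == "ptv"],
        wf_oar = dt$d_wf[dt$channel == "oar"],
        wf_nt = dt$d_wf[dt$channel == "nt"]
      )
      out[[length(out) + 1]] <- tibble(
        phantom_id = pid, t = ts[j],
        dd_ptv = dd[["ptv"]], dd_oar = dd[["oar"]], dd_nt = dd[["nt"]],
        target = names(y), y = unname(y)
      )
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

#' Phantom-level train/validation split
#'
#' Partitions samples so that no phantom contributes to both sides.
#'
#' @param samples Tibble with a `phantom_id` column.
#' @param prop Train fraction of phantoms (default 0.6).
#' @param seed Integer seed; the partition is reproducible.
#' @return List with tibbles `train` and `validation`.
#' @export
split_by_phantom <- function(samples, prop = 0.6, seed = 1L) {
  ids <- unique(samples$phantom_id)
  if (length(ids) < 2) {
    abort("Need at least 2 distinct phantoms to split.",
          class = "fuzzyplan_error_split")
  }
  n_train <- max(1L, min(length(ids) - 1L, round(prop * length(ids))))
  train_ids <- with_seed(seed, sample(ids, n_train))
  list(train = samples[samples$phantom_id %in% train_ids, ],
       validation = samples[!samples$phantom_id %in% train_ids, ])
}

#' Training configuration
#'
#' Defaults follow the study protocol: Adam with initial learning rate 0.01,
#' MSE loss with L2 weight decay beta = 0.015 over all trainable parameters,
#' batch size 16, at most 500 epochs, early stopping after 20 epochs without
#' validation improvement, 60/40 phantom-level split, and learning-rate
#' reduction when the training loss plateaus.
#'
#' @param lr Initial learning rate.
#' @param l2_beta L2 regularization weight (included in the optimized loss,
#'   excluded from the reported MSE history).
#' @param batch Mini-batch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); must be below `max_epochs`.
#' @param split Train fraction of phantoms (0 < split < 1).
#' @param seed RNG seed for the split and batch shuffling.
#' @param lr_factor,lr_patience Learning-rate reduction on training-loss
#'   plateau.
#' @param shared_consequents If `TRUE`, the 32 per-rule consequents are tied
#'   to 4 shared coefficients.
#' @return An `anfis_control` list.
#' @export
anfis_control <- function(lr = 0.01, l2_beta = 0.015, batch = 16L,
                          max_epochs = 500L, patience = 20L, split = 0.6,
                          seed = 1L, lr_factor = 0.5, lr_patience = 10L,
                          shared_consequents = FALSE) {
  stopifnot(split > 0, split < 1, patience < max_epochs)
  list(lr = lr, l2_beta = l2_beta, batch = as.integer(batch),
       max_epochs = as.integer(max_epochs), patience = as.integer(patience),
       split = split, seed = as.integer(seed), lr_factor = lr_factor,
       lr_patience = as.integer(lr_patience),
       shared_consequents = shared_consequents)
}

#' Analytic loss gradients of a fuzzy network
#'
#' Gradients of the batch mean squared error with respect to the 12 premise
#' parameters and the 8 x 4 consequents, derived from the layer structure
#' (sigmoid memberships, product firing, normalization, linear consequents).
#'
#' @param net A [fuzzy_network()].
#' @param X n x 3 input matrix (columns `ptv`, `nt`, `oar`).
#' @param y Length-n target vector.
#' @return List with `mse` and gradient arrays `a`, `b` (3 x 2) and `cons`
#'   (8 x 4).
#' @export
network_gradients <- function(net, X, y) {
  X <- matrix(X, ncol = 3)
  n <- nrow(X)
  fwd <- fuzzy_forward(net, X)
  e <- fwd$f - y
  mse <- mean(e^2)
  r <- 2 * e / n
  ok <- !fwd$degenerate

  g_cons <- crossprod(fwd$wbar * r, fwd$Z) # 8 x 4
  # df/dw_i = (f_i - f) / s
  dfdw <- (fwd$fi - fwd$f) / ifelse(ok, fwd$s, Inf) # n x 8, zero when degenerate
  li <- net$label_idx
  g_a <- matrix(0, 3, 2, dimnames = dimnames(net$a))
  g_b <- matrix(0, 3, 2, dimnames = dimnames(net$b))
  for (k in 1:3) {
    others <- setdiff(1:3, k)
    for (l in 1:2) {
      rules <- which(li[, k] == l)
      if (length(rules) == 0) next
      mu_kl <- fwd$mu[, k, l]
      dmu <- mu_kl * (1 - mu_kl)
      # sum over rules using label l for input k of dL/dw * prod(other mus)
      acc <- numeric(n)
      for (i in rules) {
        p <- fwd$mu[, others[1], li[i, others[1]]] *
          fwd$mu[, others[2], li[i, others[2]]]
        acc <- acc + dfdw[, i] * p
      }
      common <- r * acc * dmu
      g_a[k, l] <- sum(common * (X[, k] - net$b[k, l]))
      g_b[k, l] <- sum(common * (-net$a[k, l]))
    }
  }
  list(mse = mse, a = g_a, b = g_b, cons = g_cons)
}

# Adam state helpers operating on lists of arrays
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

net_params <- function(net) list(a = net$a, b = net$b, cons = net$consequents)

set_net_params <- function(net, params) {
  net$a <- params$a
  net$b <- params$b
  net$consequents <- params$cons
  net
}

net_mse <- function(net, X, y) {
  mean((fuzzy_forward(net, X)$f - y)^2)
}

#' Train a fuzzy network on planning samples
#'
#' Fits the premise and consequent parameters by mini-batch Adam on the mean
#' squared error plus an L2 penalty over all trainable parameters. The samples
#' are split at the phantom level; training stops at the epoch cap or after
#' `patience` epochs without validation improvement, and the returned network
#' carries the best-validation parameters.
#'
#' @param net Starting [fuzzy_network()] (typically the static controller's
#'   network for the same target).
#' @param samples Training-sample tibble from [build_dataset()]; rows are
#'   filtered to the network's target.
#' @param control An [anfis_control()].
#' @return An `anfis_fit`: trained `network`, per-epoch `history`
#'   (train/validation MSE, learning rate), `best_epoch`.
#' @export
anfis_train <- function(net, samples, control = anfis_control()) {
  if (!is.na(net$target)) {
    samples <- samples[samples$target == net$target, ]
  }
  if (nrow(samples) == 0) {
    abort("No training samples for this network's target.",
          class = "fuzzyplan_error_training")
  }
  parts <- split_by_phantom(samples, control$split, control$seed)
  Xtr <- cbind(parts$train$dd_ptv, parts$train$dd_nt, parts$train$dd_oar)
  ytr <- parts$train$y
  Xva <- cbind(parts$validation$dd_ptv, parts$validation$dd_nt,
               parts$validation$dd_oar)
  yva <- parts$validation$y

  params <- net_params(net)
  if (control$shared_consequents) {
    params$cons <- matrix(rep(colMeans(params$cons), each = 8), 8, 4)
  }
  opt <- adam_init(params)
  lr <- control$lr
  beta <- control$l2_beta
  best <- list(val = Inf, params = params, epoch = 0L)
  best_train <- Inf
  stall_val <- 0L; stall_train <- 0L
  hist <- vector("list", control$max_epochs)
  n_tr <- length(ytr)

  with_seed(control$seed + 1L, {
    for (epoch in seq_len(control$max_epochs)) {
      idx <- sample.int(n_tr)
      starts <- seq(1, n_tr, by = control$batch)
      for (s in starts) {
        b_idx <- idx[s:min(s + control$batch - 1, n_tr)]
        cur <- set_net_params(net, params)
        g <- network_gradients(cur, Xtr[b_idx, , drop = FALSE], ytr[b_idx])
        grads <- list(a = g$a + 2 * beta * params$a,
                      b = g$b + 2 * beta * params$b,
                      cons = g$cons + 2 * beta * params$cons)
        if (control$shared_consequents) {
          shared <- matrix(rep(colSums(grads$cons) / 8, each = 8), 8, 4)
          grads$cons <- shared
        }
        upd <- adam_step(opt, params, grads, lr)
        opt <- upd$state
        params <- upd$params
      }
      cur <- set_net_params(net, params)
      tr_mse <- net_mse(cur, Xtr, ytr)
      va_mse <- net_mse(cur, Xva, yva)
      hist[[epoch]] <- tibble(epoch = epoch, train_mse = tr_mse,
                              val_mse = va_mse, lr = lr)
      if (va_mse < best$val - 1e-12) {
        best <- list(val = va_mse, params = params, epoch = epoch)
        stall_val <- 0L
      } else {
        stall_val <- stall_val + 1L
      }
      if (tr_mse < best_train - 1e-12) {
        best_train <- tr_mse
        stall_train <- 0L
      } else {
        stall_train <- stall_train + 1L
        if (stall_train >= control$lr_patience) {
          lr <- lr * control$lr_factor
          stall_train <- 0L
        }
      }
      if (stall_val >= control$patience) break
    }
  })
  structure(
    list(network = set_net_params(net, best$params),
         history = dplyr::bind_rows(hist),
         best_epoch = best$epoch,
         control = control),
    class = "anfis_fit"
  )
}

#' @export
print.anfis_fit <- function(x, ...) {
  cat("<anfis_fit>", x$network$target %||% "", "- best epoch", x$best_epoch,
      "val MSE", format(min(x$history$val_mse), digits = 4), "\n")
  invisible(x)
}

#' @method tidy anfis_fit
#' @export
tidy.anfis_fit <- function(x, ...) {
  net <- x$network
  premise <- tibble(
    term = c(paste0("a_", rep(INPUTS, 2), "_", rep(LABELS, each = 3)),
             paste0("b_", rep(INPUTS, 2), "_", rep(LABELS, each = 3))),
    estimate = c(as.vector(net$a), as.vector(net$b)),
    layer = "premise"
  )
  cons <- tibble(
    term = paste0("c_", rep(1:8, 4), "_", rep(0:3, each = 8)),
    estimate = as.vector(net$consequents),
    layer = "consequent"
  )
  dplyr::bind_rows(premise, cons)
}

#' @method glance anfis_fit
#' @export
glance.anfis_fit <- function(x, ...) {
  tibble(
    target = x$network$target,
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    train_mse = x$history$train_mse[x$best_epoch],
    val_mse = min(x$history$val_mse)
  )
}

#' @method autoplot anfis_fit
#' @export
autoplot.anfis_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_mse", "val_mse"),
                            names_to = "set", values_to = "mse")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$mse,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(y = "MSE", title = object$network$target)
}

#' Simulate supervised samples from a known network
#'
#' Draws input deviations uniformly and labels them with the network's own
#' output (plus optional Gaussian noise). Useful for teacher-student recovery
#' studies.
#'
#' @param net The teacher [fuzzy_network()].
#' @param n Number of samples.
#' @param seed RNG seed.
#' @param range Input range for each deviation channel.
#' @param noise_sd Label noise standard deviation (0 = noise-free).
#' @param n_phantoms Number of synthetic phantom ids to spread samples over
#'   (so phantom-level splits are possible).
#' @return A training-sample tibble as from [build_dataset()].
#' @export
simulate_samples <- function(net, n, seed = 1L, range = c(-1, 1),
                             noise_sd = 0, n_phantoms = 10L) {
  with_seed(seed, {
    X <- matrix(runif(3 * n, range[1], range[2]), n, 3) # ptv, nt, oar
    y <- fuzzy_forward(net, X)$f + rnorm(n, 0, noise_sd)
    tibble(
      phantom_id = paste0("sim", sample.int(n_phantoms, n, replace = TRUE)),
      t = seq_len(n),
      dd_ptv = X[, 1], dd_oar = X[, 3], dd_nt = X[, 2],
      target = net$target %||% NA_character_,
      y = y
    )
  })
}
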