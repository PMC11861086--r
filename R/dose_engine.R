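# Toy pencil-beam dose engine: ray-traced influence matrix (exponential depth
# attenuation x lateral Gaussian penumbra) and projected-gradient minimization
# of the quadratic dose-volume objective over nonnegative fluence.
# All doses are relative (% of the target prescription).

#' Equispaced coplanar beam arrangement
#'
#' @param n_beams Number of beams (>= 1).
#' @param interval_deg Angular spacing in degrees.
#' @param start_deg First gantry angle, degrees clockwise from the anterior
#'   (vertical) axis.
#' @return A `beamset` with angles `start + k * interval (mod 360)`.
#' @examples
#' beamset(9, 40)$angles # 0, 40, ..., 320
#' @export
beamset <- function(n_beams, interval_deg, start_deg = 0) {
  stopifnot(n_beams >= 1)
  angles <- (start_deg + (seq_len(n_beams) - 1) * interval_deg) %% 360
  structure(list(angles = angles), class = "beamset")
}

#' @export
print.beamset <- function(x, ...) {
  cat("<beamset>", length(x$angles), "beams at",
      paste(x$angles, collapse = ", "), "deg\n")
  invisible(x)
}

#' Pencil-beam kernel parameters
#'
#' @param mu Linear attenuation per mm of depth in the body. The default is
#'   milder than a 6 MV depth-dose slope because the single-slice engine has
#'   no scatter buildup to offset attenuation; it keeps the entrance-to-depth
#'   dose ratio in a realistic range over a desk-scale phantom.
#' @param sigma_mm Gaussian penumbra width (mm).
#' @param beamlet_width Beamlet spacing in voxel widths.
#' @param margin_beamlets Extra beamlets on each side of the target projection.
#' @return A named list of kernel parameters.
#' @export
engine_kernel <- function(mu = 0.003, sigma_mm = 4, beamlet_width = 2,
                          margin_beamlets = 2) {
  list(mu = mu, sigma_mm = sigma_mm, beamlet_width = beamlet_width,
       margin_beamlets = margin_beamlets)
}

#' Dose-influence matrix for a phantom and beam arrangement
#'
#' For each beam, parallel beamlets cover the target's lateral projection
#' (plus margin). A beamlet deposits `exp(-mu * depth) *
#' exp(-lateral^2 / (2 sigma^2))` per unit fluence at every body voxel, where
#' depth is measured from the body surface along the beam direction. Dose is
#' linear in fluence and all entries are nonnegative.
#'
#' @param phantom A `phantom`.
#' @param beams A `beamset`.
#' @param kernel Kernel parameters from [engine_kernel()].
#' @return An `influence` object: matrix `A` (body voxels x beamlets), the
#'   body-voxel index, and per-structure voxel index sets.
#' @export
dose_influence <- function(phantom, beams, kernel = engine_kernel()) {
  gs <- phantom$grid_shape
  sp <- phantom$spacing
  body_idx <- which(phantom$masks$body)
  if (length(body_idx) == 0) {
    abort("Body mask is empty; no influence can be computed.",
          class = "fuzzyplan_error_empty_influence")
  }
  xy <- voxel_coords(gs)
  r <- xy$row[body_idx] * sp
  c <- xy$col[body_idx] * sp
  ptv_in_body <- which(phantom$masks$ptv[body_idx])

  cols <- list()
  for (theta in beams$angles) {
    th <- theta * pi / 180
    # propagation direction (row, col), clockwise from anterior
    v <- c(cos(th), -sin(th))
    u <- c(sin(th), cos(th)) # lateral axis
    t_coord <- r * v[1] + c * v[2]
    l_coord <- r * u[1] + c * u[2]
    # body entry depth per lateral strip (one voxel wide)
    strip <- round(l_coord / sp)
    entry <- tapply(t_coord, strip, min)
    depth <- as.numeric(t_coord - entry[as.character(strip)])
    atten <- exp(-kernel$mu * depth)
    # beamlets spanning the target's lateral projection
    bw <- kernel$beamlet_width * sp
    l_ptv <- range(l_coord[ptv_in_body])
    centers <- seq(l_ptv[1] - kernel$margin_beamlets * bw,
                   l_ptv[2] + kernel$margin_beamlets * bw, by = bw)
    lat <- outer(l_coord, centers, `-`)
    cols[[length(cols) + 1]] <- atten * exp(-lat^2 / (2 * kernel$sigma_mm^2))
  }
  A <- do.call(cbind, cols)
  if (max(A) <= 0) {
    abort("Beam geometry misses the body entirely.",
          class = "fuzzyplan_error_empty_influence")
  }
  oar_names <- names(phantom$roles)[phantom$roles == "OAR"]
  omega <- c(
    list(ptv = ptv_in_body),
    setNames(lapply(oar_names,
                    function(nm) which(phantom$masks[[nm]][body_idx])),
             oar_names),
    list(nt = which(phantom$masks$nt[body_idx]))
  )
  structure(
    list(A = A, body_idx = body_idx, omega = omega, grid_shape = gs,
         spacing = sp, kernel = kernel, angles = beams$angles),
    class = "influence"
  )
}

#' @export
print.influence <- function(x, ...) {
  cat("<influence>", nrow(x$A), "body voxels x", ncol(x$A), "beamlets,",
      length(x$angles), "beams\n")
  invisible(x)
}

#' Objective specification for the quadratic dose-volume cost
#'
#' Encodes the tunable plan parameters as the engine's lower/upper dose
#' objectives and penalty weights. The mapping from the six plan parameters
#' is: the target's lower objective is its prescription dose, its upper
#' objective that dose times `1 + ptv_margin`; each OAR and the normal tissue
#' get their prescription dose as upper objective; weights are taken as-is.
#'
#' @param pd Named numeric: prescription doses `c(ptv=, oar=, nt=)` in % units.
#' @param wf Named numeric: penalty weights `c(ptv=, oar=, nt=)`, all >= 0.
#' @param ptv_margin Fractional headroom of the target's upper objective above
#'   its lower objective (default 0.05, motivated by a 107%-of-prescription
#'   maximum-dose style goal).
#' @return An `objective_spec` list.
#' @export
objective_spec <- function(pd, wf, ptv_margin = 0.05) {
  if (any(wf < 0)) {
    abort("Penalty weights must be nonnegative.",
          class = "fuzzyplan_error_spec")
  }
  if (any(pd <= 0)) {
    abort("Prescription doses must be positive.",
          class = "fuzzyplan_error_spec")
  }
  spec <- list(
    d_min_ptv = unname(pd["ptv"]),
    d_max = c(ptv = unname(pd["ptv"]) * (1 + ptv_margin),
              oar = unname(pd["oar"]), nt = unname(pd["nt"])),
    wf_min_ptv = unname(wf["ptv"]),
    wf_max = c(ptv = unname(wf["ptv"]), oar = unname(wf["oar"]),
               nt = unname(wf["nt"]))
  )
  if (spec$d_min_ptv > spec$d_max["ptv"]) {
    abort("Target lower objective exceeds its upper objective.",
          class = "fuzzyplan_error_spec")
  }
  structure(spec, class = "objective_spec")
}

# map the structure-level weights/objectives onto the influence's omega sets
spec_terms <- function(spec, omega) {
  oar_names <- setdiff(names(omega), c("ptv", "nt"))
  upper <- lapply(names(omega), function(nm) {
    key <- if (nm %in% oar_names) "oar" else nm
    list(idx = omega[[nm]], wf = spec$wf_max[[key]], d = spec$d_max[[key]])
  })
  list(lower = list(idx = omega$ptv, wf = spec$wf_min_ptv, d = spec$d_min_ptv),
       upper = upper)
}

#' Quadratic dose-volume objective
#'
#' `F = sum_PTV wf_min * [d_min - d]_+^2 + sum_x sum wf_max_x * [d - d_max_x]_+^2`
#' with `[x]_+ = x * H(x)` the positive operator; underdose is penalized in the
#' target only, overdose in target, OARs and normal tissue.
#'
#' @param dose Numeric vector of per-voxel dose over the body voxels.
#' @param spec An [objective_spec()].
#' @param omega Named list of per-structure voxel index sets (as in an
#'   `influence` object).
#' @return Nonnegative scalar objective value.
#' @export
dose_objective <- function(dose, spec, omega) {
  tm <- spec_terms(spec, omega)
  under <- pmax(tm$lower$d - dose[tm$lower$idx], 0)
  f <- tm$lower$wf * sum(under^2)
  for (term in tm$upper) {
    over <- pmax(dose[term$idx] - term$d, 0)
    f <- f + term$wf * sum(over^2)
  }
  f
}

# gradient of the objective with respect to per-voxel dose
objective_dose_grad <- function(dose, spec, omega) {
  tm <- spec_terms(spec, omega)
  g <- numeric(length(dose))
  li <- tm$lower$idx
  g[li] <- g[li] - 2 * tm$lower$wf * pmax(tm$lower$d - dose[li], 0)
  for (term in tm$upper) {
    ui <- term$idx
    g[ui] <- g[ui] + 2 * term$wf * pmax(dose[ui] - term$d, 0)
  }
  g
}

#' Minimize the quadratic objective over nonnegative fluence
#'
#' Projected-gradient descent with backtracking line search; the objective is
#' non-increasing across accepted iterates by construction. Terminates when
#' the projected step stalls (relative step norm below `tol`) or at the
#' iteration cap (flagged, not fatal).
#'
#' @param influence An `influence` object.
#' @param spec An [objective_spec()].
#' @param init Optional starting fluence (e.g. the previous solution for warm
#'   starts). Default: uniform fluence scaled so the mean target dose equals
#'   the target's lower objective.
#' @param control List: `max_iter` (default 500), `tol` (1e-6), `step0`
#'   (initial step, auto-scaled).
#' @return A `dose_plan`: fluence, per-voxel `dose`, objective `F`, the
#'   accepted-iterate objective `trace`, and a `converged` flag.
#' @export
optimize_fluence <- function(influence, spec, init = NULL,
                             control = list()) {
  ctl <- utils::modifyList(list(max_iter = 500L, tol = 1e-6, step0 = NULL),
                           control)
  A <- influence$A
  omega <- influence$omega
  if (is.null(init)) {
    unif <- rep(1, ncol(A))
    mean_ptv <- mean((A %*% unif)[omega$ptv])
    f <- if (mean_ptv > 0) unif * spec$d_min_ptv / mean_ptv else unif
  } else {
    stopifnot(length(init) == ncol(A))
    f <- pmax(init, 0)
  }
  dose <- as.vector(A %*% f)
  F_cur <- dose_objective(dose, spec, omega)
  trace <- F_cur
  # scale-free initial step from the gradient magnitude
  step <- ctl$step0
  converged <- FALSE
  for (it in seq_len(ctl$max_iter)) {
    g <- as.vector(crossprod(A, objective_dose_grad(dose, spec, omega)))
    gn2 <- sum(g^2)
    if (gn2 == 0) { converged <- TRUE; break }
    if (is.null(step)) step <- 0.1 * (sqrt(sum(f^2)) + 1) / sqrt(gn2)
    accepted <- FALSE
    for (bt in 1:30) {
      f_new <- pmax(f - step * g, 0)
      dose_new <- as.vector(A %*% f_new)
      F_new <- dose_objective(dose_new, spec, omega)
      if (F_new <= F_cur - 1e-4 * sum(g * (f - f_new))) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break } # no descent direction left
    rel_step <- sqrt(sum((f_new - f)^2)) / max(sqrt(sum(f^2)), 1)
    f <- f_new; dose <- dose_new; F_cur <- F_new
    trace <- c(trace, F_cur)
    step <- step * 1.8
    if (rel_step < ctl$tol) { converged <- TRUE; break }
  }
  structure(
    list(fluence = f, dose = dose, F = F_cur, trace = trace,
         converged = converged, n_iter = length(trace) - 1L,
         omega = omega, body_idx = influence$body_idx,
         grid_shape = influence$grid_shape),
    class = "dose_plan"
  )
}

#' @export
print.dose_plan <- function(x, ...) {
  cat("<dose_plan> F =", format(x$F, digits = 5), "after", x$n_iter,
      "iterations", if (x$converged) "(converged)" else "(iteration cap)", "\n")
  print(structure_means(x$dose, x$omega))
  invisible(x)
}

#' Per-structure mean doses
#'
#' @param dose Per-voxel dose over the body voxels.
#' @param omega Named list of structure voxel index sets.
#' @return Named numeric vector of arithmetic mean doses.
#' @export
structure_means <- function(dose, omega) {
  vapply(omega, function(idx) mean(dose[idx]), numeric(1))
}

#' Rescale dose so the mean target dose equals a reference value
#'
#' @param dose Per-voxel dose vector.
#' @param ptv_idx Target voxel indices.
#' @param to Reference mean target dose (default 100).
#' @return The rescaled dose vector.
#' @export
normalize_dose <- function(dose, ptv_idx, to = 100) {
  m <- mean(dose[ptv_idx])
  if (m <= 0) abort("Cannot normalize: mean target dose is zero.")
  dose * to / m
}

#' @method tidy dose_plan
#' @export
tidy.dose_plan <- function(x, ...) {
  m <- structure_means(x$dose, x$omega)
  tibble(structure = names(m), mean_dose = unname(m),
         n_voxels = vapply(x$omega, length, integer(1)))
}

#' @method autoplot dose_plan
#' @export
autoplot.dose_plan <- function(object, ...) {
  gs <- object$grid_shape
  grid <- matrix(NA_real_, gs[1], gs[2])
  grid[object$body_idx] <- object$dose
  df <- tibble(
    row = rep(seq_len(gs[1]), gs[2]),
    col = rep(seq_len(gs[2]), each = gs[1]),
    dose = as.vector(grid)
  )
  df <- df[!is.na(df$dose), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "dose (%)")
}
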