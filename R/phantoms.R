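# Synthetic planning phantoms: voxel masks for PTV, OAR(s) and normal tissue
# on a regular 2D grid, plus randomized geometric variants.

new_phantom <- function(grid_shape, spacing, masks, roles, geometry,
                        nt_includes_all_body = FALSE) {
  structure(
    list(
      grid_shape = as.integer(grid_shape),
      spacing = as.numeric(spacing),
      masks = masks,
      roles = roles,
      geometry = geometry,
      nt_includes_all_body = nt_includes_all_body
    ),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat("<phantom> ", x$geometry$type, " ",
      paste(x$grid_shape, collapse = "x"),
      " grid, ", x$spacing, " mm voxels\n", sep = "")
  for (nm in names(x$masks)) {
    cat(sprintf("  %-8s %-4s %6d voxels\n", nm, x$roles[[nm]],
                sum(x$masks[[nm]])))
  }
  invisible(x)
}

# voxel-center coordinate grids (voxel units, origin at grid centre;
# row axis anterior->posterior, col axis left->right)
voxel_coords <- function(grid_shape) {
  nr <- grid_shape[1]; nc <- grid_shape[2]
  list(
    row = matrix(seq_len(nr) - (nr + 1) / 2, nr, nc),
    col = matrix(rep(seq_len(nc) - (nc + 1) / 2, each = nr), nr, nc)
  )
}

ellipse_mask <- function(grid_shape, center, radii) {
  xy <- voxel_coords(grid_shape)
  ((xy$row - center[1]) / radii[1])^2 + ((xy$col - center[2]) / radii[2])^2 <= 1
}

rect_body_mask <- function(grid_shape, margin) {
  m <- matrix(FALSE, grid_shape[1], grid_shape[2])
  r <- (margin + 1):(grid_shape[1] - margin)
  c <- (margin + 1):(grid_shape[2] - margin)
  m[r, c] <- TRUE
  m
}

abort_geometry <- function(msg) {
  abort(msg, class = "fuzzyplan_error_geometry")
}

# shared finishing step: overlap resolution (PTV > OAR > NT), derived normal
# tissue, and invariant checks
finish_phantom <- function(grid_shape, spacing, ptv, oars, body, geometry,
                           nt_includes_all_body = FALSE) {
  if (!any(ptv)) abort_geometry("PTV mask is empty.")
  # PTV takes priority over OARs, OARs over normal tissue
  oars <- lapply(oars, function(m) m & !ptv)
  if (any(!vapply(oars, any, logical(1)))) {
    abort_geometry("An OAR mask is empty after PTV-priority overlap resolution.")
  }
  oar_union <- Reduce(`|`, oars, matrix(FALSE, grid_shape[1], grid_shape[2]))
  if (any(ptv & !body) || any(oar_union & !body)) {
    abort_geometry("A structure extends outside the body mask.")
  }
  nt <- if (nt_includes_all_body) body else (body & !ptv & !oar_union)
  masks <- c(list(ptv = ptv), oars, list(nt = nt, body = body))
  roles <- c(ptv = "PTV", setNames(rep("OAR", length(oars)), names(oars)),
             nt = "NT", body = "BODY")
  ph <- new_phantom(grid_shape, spacing, masks, roles, geometry,
                    nt_includes_all_body)
  validate_phantom(ph)
  ph
}

#' Validate phantom invariants
#'
#' Checks that every mask matches the grid extent, that the PTV and all OARs
#' are non-empty and pairwise disjoint, and that the body contains every
#' structure.
#'
#' @param phantom A `phantom` object.
#' @return The phantom, invisibly; errors on violation.
#' @export
validate_phantom <- function(phantom) {
  gs <- phantom$grid_shape
  for (nm in names(phantom$masks)) {
    m <- phantom$masks[[nm]]
    if (!is.logical(m) || !identical(dim(m), as.integer(gs))) {
      abort_geometry(sprintf("Mask '%s' does not match the grid extent.", nm))
    }
  }
  oar_names <- names(phantom$roles)[phantom$roles == "OAR"]
  targets <- c("ptv", oar_names)
  for (nm in targets) {
    if (!any(phantom$masks[[nm]])) {
      abort_geometry(sprintf("Mask '%s' is empty.", nm))
    }
  }
  ptv <- phantom$masks$ptv
  for (nm in oar_names) {
    if (any(ptv & phantom$masks[[nm]])) {
      abort_geometry(sprintf("PTV and OAR '%s' overlap.", nm))
    }
  }
  body <- phantom$masks$body
  for (nm in targets) {
    if (any(phantom$masks[[nm]] & !body)) {
      abort_geometry(sprintf("Structure '%s' extends outside the body.", nm))
    }
  }
  invisible(phantom)
}

#' C-shape benchmark phantom
#'
#' A C-shaped target (an elliptical annulus with an angular opening) partially
#' enclosing a circular core OAR, inside a rectangular body. This is the
#' classic commissioning geometry in which target coverage and core sparing
#' pull the optimizer in opposite directions.
#'
#' @param grid_shape Integer vector of voxel counts (rows, cols).
#' @param spacing Voxel size in mm.
#' @param geometry Named list overriding any of the default geometry
#'   parameters (voxel units): `outer_r`, `inner_r` (annulus radii),
#'   `gap_dir_deg`, `gap_half_deg` (direction and half-width of the C opening,
#'   degrees clockwise from anterior), `core_r`, `core_offset`, `center`,
#'   `rx_scale`, `ry_scale` (per-axis target scale factors), `body_margin`.
#' @param nt_includes_all_body If `TRUE`, the normal-tissue mask is the whole
#'   body rather than body minus target and OARs.
#' @return A `phantom` object.
#' @examples
#' ph <- phantom_cshape()
#' sum(ph$masks$ptv & ph$masks$core) # disjoint by construction
#' @export
phantom_cshape <- function(grid_shape = c(64L, 64L), spacing = 4,
                           geometry = list(), nt_includes_all_body = FALSE) {
  m <- min(grid_shape)
  g <- utils::modifyList(list(
    type = "cshape",
    center = c(0, 0), outer_r = 0.172 * m, inner_r = 0.094 * m,
    gap_dir_deg = 180, gap_half_deg = 50,
    core_r = 0.0625 * m, core_offset = c(0, 0),
    rx_scale = 1, ry_scale = 1,
    body_margin = 2
  ), geometry)
  if (any(grid_shape < 8)) abort_geometry("grid_shape must be at least 8 voxels per axis.")
  if (g$inner_r >= g$outer_r) {
    abort_geometry("inner_r must be smaller than outer_r.")
  }
  if (g$outer_r * max(g$ry_scale, g$rx_scale) >= min(grid_shape) / 2 - g$body_margin) {
    abort_geometry("outer radius does not fit inside the body.")
  }
  xy <- voxel_coords(grid_shape)
  dr <- (xy$row - g$center[1]) / g$ry_scale
  dc <- (xy$col - g$center[2]) / g$rx_scale
  rho <- sqrt(dr^2 + dc^2)
  # angle measured clockwise from the anterior (-row) direction
  ang <- (atan2(dc, -dr) * 180 / pi) %% 360
  gap <- pmin(abs(ang - g$gap_dir_deg), 360 - abs(ang - g$gap_dir_deg)) <= g$gap_half_deg
  ptv <- rho >= g$inner_r & rho <= g$outer_r & !gap
  core <- ellipse_mask(grid_shape, g$center + g$core_offset,
                       c(g$core_r, g$core_r))
  body <- rect_body_mask(grid_shape, g$body_margin)
  finish_phantom(grid_shape, spacing, ptv, list(core = core), body, g,
                 nt_includes_all_body)
}

#' Mock prostate phantom
#'
#' An elliptical target with a posterior OAR (rectum) and an anterior OAR
#' (bladder) inside a rectangular body.
#'
#' @inheritParams phantom_cshape
#' @param geometry Named list overriding geometry defaults (voxel units):
#'   `ptv_center`, `ptv_r`, `rectum_center`, `rectum_r`, `bladder_center`,
#'   `bladder_r`, `oar_offset` (shift applied to both OARs), `rx_scale`,
#'   `ry_scale`, `body_margin`.
#' @return A `phantom` object.
#' @export
phantom_prostate <- function(grid_shape = c(64L, 64L), spacing = 4,
                             geometry = list(), nt_includes_all_body = FALSE) {
  m <- min(grid_shape)
  g <- utils::modifyList(list(
    type = "prostate",
    ptv_center = c(0, 0), ptv_r = c(0.141, 0.172) * m,
    rectum_center = c(0.25 * m, 0), rectum_r = c(0.078, 0.109) * m,
    bladder_center = c(-0.266 * m, 0), bladder_r = c(0.094, 0.141) * m,
    oar_offset = c(0, 0),
    rx_scale = 1, ry_scale = 1,
    body_margin = 2
  ), geometry)
  if (any(grid_shape < 8)) abort_geometry("grid_shape must be at least 8 voxels per axis.")
  if (any(c(g$ptv_r, g$rectum_r, g$bladder_r) <= 0)) {
    abort_geometry("all radii must be positive.")
  }
  ptv <- ellipse_mask(grid_shape, g$ptv_center,
                      c(g$ptv_r[1] * g$ry_scale, g$ptv_r[2] * g$rx_scale))
  rectum <- ellipse_mask(grid_shape, g$rectum_center + g$oar_offset, g$rectum_r)
  bladder <- ellipse_mask(grid_shape, g$bladder_center + g$oar_offset, g$bladder_r)
  body <- rect_body_mask(grid_shape, g$body_margin)
  finish_phantom(grid_shape, spacing, ptv,
                 list(rectum = rectum, bladder = bladder), body, g,
                 nt_includes_all_body)
}

# rebuild a phantom from its recorded geometry with a variant transform applied
apply_variant <- function(base, spec) {
  g <- base$geometry
  if (g$type == "cshape") {
    g$core_offset <- g$core_offset + spec$oar_shift
    g$ry_scale <- g$ry_scale * spec$ptv_scale[1] * spec$ptv_stretch
    g$rx_scale <- g$rx_scale * spec$ptv_scale[2] / spec$ptv_stretch
    ph <- phantom_cshape(base$grid_shape, base$spacing, g,
                         base$nt_includes_all_body)
  } else if (g$type == "prostate") {
    g$oar_offset <- g$oar_offset + spec$oar_shift
    g$ry_scale <- g$ry_scale * spec$ptv_scale[1] * spec$ptv_stretch
    g$rx_scale <- g$rx_scale * spec$ptv_scale[2] / spec$ptv_stretch
    ph <- phantom_prostate(base$grid_shape, base$spacing, g,
                           base$nt_includes_all_body)
  } else {
    abort_geometry(sprintf("Unknown phantom type '%s'.", g$type))
  }
  attr(ph, "variant_spec") <- spec
  ph
}

#' Randomized geometric variants of a base phantom
#'
#' Emulates a cohort of modified phantoms by jittering the recorded geometry
#' of a base phantom along three modes: shifting the OAR(s) toward or away
#' from the target, scaling the target's height and width, and stretching the
#' target vertically (taller and narrower). Variants violating the phantom
#' invariants are redrawn a bounded number of times.
#'
#' @param base A `phantom` built by [phantom_cshape()] or [phantom_prostate()].
#' @param n Number of variants (>= 1).
#' @param seed Integer RNG seed; variant generation is a pure function of
#'   `(base, n, seed)` and the ranges.
#' @param shift_frac Maximum OAR displacement as a fraction of the grid extent.
#' @param scale_range Range of per-axis target scale factors.
#' @param stretch_range Range of vertical stretch factors.
#' @param max_retries Redraw budget per variant before erroring.
#' @return A list of `n` phantoms, each carrying its `variant_spec` attribute.
#' @export
phantom_variants <- function(base, n, seed, shift_frac = 0.2,
                             scale_range = c(0.8, 1.3),
                             stretch_range = c(1, 1.3),
                             max_retries = 20L) {
  stopifnot(inherits(base, "phantom"), n >= 1)
  if (any(scale_range <= 0) || any(stretch_range <= 0)) {
    abort_geometry("scale and stretch factors must be positive.")
  }
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      ph <- NULL
      for (try in seq_len(max_retries)) {
        spec <- list(
          oar_shift = round(runif(2, -1, 1) * shift_frac * base$grid_shape),
          ptv_scale = runif(2, scale_range[1], scale_range[2]),
          ptv_stretch = runif(1, stretch_range[1], stretch_range[2])
        )
        ph <- tryCatch(apply_variant(base, spec),
                       fuzzyplan_error_geometry = function(e) NULL)
        if (!is.null(ph)) break
      }
      if (is.null(ph)) {
        abort_geometry(sprintf(
          "Could not draw a valid variant %d within %d retries.", i, max_retries))
      }
      out[[i]] <- ph
    }
    out
  })
}

#' @method as_tibble phantom
#' @export
as_tibble.phantom <- function(x, ...) {
  pri <- c("ptv", names(x$roles)[x$roles == "OAR"], "nt")
  gs <- x$grid_shape
  lab <- matrix(NA_character_, gs[1], gs[2])
  for (nm in rev(pri)) lab[x$masks[[nm]]] <- nm
  tibble(
    row = rep(seq_len(gs[1]), gs[2]),
    col = rep(seq_len(gs[2]), each = gs[1]),
    body = as.vector(x$masks$body),
    structure = as.vector(lab)
  )
}

#' @method autoplot phantom
#' @export
autoplot.phantom <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$body, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$structure)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "structure",
                  title = sprintf("%s phantom", object$geometry$type))
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
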