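# Synthetic image stacks: a demo fixture emulating a two-photon substack of
# one dendrite, for testing detection-adjacent tooling. Not part of the
# quantitative pipeline (which operates on annotation tables).

#' Render a session annotation as a synthetic image stack
#'
#' Draws the dendrite as a fluorescent cylinder along x with
#' Gaussian-blurred spine protrusions at the annotated positions, applies
#' Poisson photon noise, and returns the stack together with a ground-truth
#' label mask of spine voxels. In-plane voxel size defaults to 0.138 um
#' (a typical high-resolution two-photon setting).
#'
#' @param positions_um annotated spine positions along the dendrite (um).
#' @param length_um dendrite length (um).
#' @param cfg list of rendering options: `voxel_um` (in-plane size, default
#'   0.138), `z_step_um` (default 0.5), `width_um` / `depth_um` (field of
#'   view around the dendrite, defaults 8 and 4), `dendrite_radius_um`
#'   (0.4), `spine_length_um` (1.2), `psf_sigma_um` (0.25), `photons`
#'   (peak expected photon count, 50).
#' @param tiff_path optionally write the stack as a multi-page TIFF
#'   (requires the `tiff` package).
#' @return list: `stack` (3-D array x * y * z of photon counts), `mask`
#'   (integer array, 0 = background, `k` = voxels of the k-th spine),
#'   `voxel_um`, `z_step_um`.
#' @export
render_session_stack <- function(positions_um, length_um, cfg = list(),
                                 tiff_path = NULL) {
  stopifnot(all(positions_um >= 0), all(positions_um <= length_um),
            length_um > 0)
  def <- list(voxel_um = 0.138, z_step_um = 0.5, width_um = 8, depth_um = 4,
              dendrite_radius_um = 0.4, spine_length_um = 1.2,
              psf_sigma_um = 0.25, photons = 50)
  cfg <- utils::modifyList(def, cfg)
  nx <- ceiling(length_um / cfg$voxel_um)
  ny <- ceiling(cfg$width_um / cfg$voxel_um)
  nz <- ceiling(cfg$depth_um / cfg$z_step_um) + 1
  if (ny < 5 || nz < 2) {
    stop("voxel grid too small to contain the dendrite; enlarge width_um/depth_um",
         call. = FALSE)
  }
  xs <- (seq_len(nx) - 0.5) * cfg$voxel_um
  ys <- (seq_len(ny) - 0.5) * cfg$voxel_um
  zs <- (seq_len(nz) - 1) * cfg$z_step_um
  y0 <- cfg$width_um / 2
  z0 <- cfg$depth_um / 2

  # radial distance from the dendrite axis, per (y, z)
  r_yz <- sqrt(outer((ys - y0)^2, (zs - z0)^2, `+`))
  tube_yz <- exp(-pmax(r_yz - cfg$dendrite_radius_um, 0)^2 /
                   (2 * cfg$psf_sigma_um^2))
  lambda <- array(rep(tube_yz, each = nx), dim = c(nx, ny, nz))

  mask <- array(0L, dim = c(nx, ny, nz))
  side <- rep_len(c(1, -1), length(positions_um)) # alternate protrusion side
  head_r <- 2 * cfg$psf_sigma_um
  for (k in seq_along(positions_um)) {
    hx <- positions_um[k]
    hy <- y0 + side[k] * (cfg$dendrite_radius_um + cfg$spine_length_um)
    d2 <- outer(outer((xs - hx)^2, (ys - hy)^2, `+`), (zs - z0)^2, `+`)
    # neck: a thin bridge from the tube surface to the head
    neck_y <- y0 + side[k] *
      seq(cfg$dendrite_radius_um, cfg$dendrite_radius_um + cfg$spine_length_um,
          by = cfg$voxel_um / 2)
    for (yy in neck_y) {
      d2n <- outer(outer((xs - hx)^2, (ys - yy)^2, `+`), (zs - z0)^2, `+`)
      lambda <- lambda + 0.6 * exp(-d2n / (2 * cfg$psf_sigma_um^2))
    }
    lambda <- lambda + exp(-d2 / (2 * cfg$psf_sigma_um^2))
    mask[d2 <= head_r^2] <- k
  }
  stack <- array(rpois(length(lambda), cfg$photons * pmin(lambda, 1)),
                 dim = dim(lambda))
  if (!is.null(tiff_path)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("the 'tiff' package is required to write TIFF output", call. = FALSE)
    }
    pages <- lapply(seq_len(nz), function(z) t(stack[, , z]) / max(stack, 1))
    tiff::writeTIFF(pages, tiff_path)
  }
  list(stack = stack, mask = mask, voxel_um = cfg$voxel_um,
       z_step_um = cfg$z_step_um)
}
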