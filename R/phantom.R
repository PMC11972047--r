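#' Voxelized cubic phantom with a displaceable target
#'
#' A water cube (default 10 cm side, 2 mm voxels) holding a cubic target
#' (default 2 cm side) whose center can be displaced from the phantom center.
#'
#' Coordinate convention (right-handed): the beam propagates toward
#' decreasing z and enters through the +z face, so depth in the phantom is
#' `d = z_entry - z`. An "upstream" displacement is +z (toward the nozzle,
#' shallower), "downstream" is -z; transverse displacements are along +x.
#' Voxels are indexed half-open from the phantom corner: voxel `i` along an
#' axis covers `[corner + (i-1) h, corner + i h)` and a voxel belongs to the
#' target iff its center lies inside the displaced target cube.
#'
#' @param extent_cm Phantom cube side (cm).
#' @param voxel_mm Voxel size (mm); must divide the extent exactly.
#' @param target_cm Target cube side (cm).
#' @param target_offset_mm Length-3 displacement of the target center (mm),
#'   `(x, y, z)`.
#' @param body Material of the phantom body (default water).
#' @param target Material filling the target cube (default Dotarem).
#' @return Object of class `phantom_grid`.
#' @export
phantom_grid <- function(extent_cm = 10, voxel_mm = 2, target_cm = 2,
                         target_offset_mm = c(0, 0, 0),
                         body = water_material(),
                         target = dotarem_material()) {
  h <- voxel_mm / 10 # cm
  n <- extent_cm / h
  if (abs(n - round(n)) > 1e-9) {
    stop("voxel size must divide the phantom extent exactly", call. = FALSE)
  }
  n <- as.integer(round(n))
  stopifnot(length(target_offset_mm) == 3)
  half <- extent_cm / 2
  t_half <- target_cm / 2
  off <- target_offset_mm / 10 # cm
  if (any(abs(off) + t_half > half + 1e-9)) {
    stop("displaced target extends outside the phantom", call. = FALSE)
  }
  centers <- -half + (seq_len(n) - 0.5) * h
  structure(list(
    extent = extent_cm, voxel_cm = h, n = n,
    target_extent = target_cm,
    target_offset_mm = target_offset_mm,
    centers = centers, half = half, t_half = t_half,
    body = body, target = target
  ), class = "phantom_grid")
}

#' Displace the target of a phantom
#'
#' @param grid A `phantom_grid`.
#' @param axis `"x"` or `"z"` (+z = upstream).
#' @param mm Signed displacement in mm.
#' @return A new `phantom_grid` with the offset applied.
#' @export
displace_target <- function(grid, axis = c("x", "z"), mm) {
  axis <- match.arg(axis)
  off <- c(0, 0, 0)
  off[if (axis == "x") 1 else 3] <- mm
  phantom_grid(grid$extent, grid$voxel_cm * 10, grid$target_extent,
               target_offset_mm = off, body = grid$body, target = grid$target)
}

# Logical array [n,n,n]: TRUE where the voxel center lies in the target cube.
target_mask <- function(grid) {
  off <- grid$target_offset_mm / 10
  inx <- abs(grid$centers - off[1]) < grid$t_half
  iny <- abs(grid$centers - off[2]) < grid$t_half
  inz <- abs(grid$centers - off[3]) < grid$t_half
  outer(outer(inx, iny, "&"), inz, "&")
}

# Per-voxel geometry tables used by the dose and emission engines.
# Returns arrays indexed [ix, iy, iz] plus the beam-ordered cumulative
# water-equivalent depth at voxel mid-points and voxel WE thickness.
precompute_geometry <- function(grid) {
  n <- grid$n
  mask <- target_mask(grid)
  rsp <- array(grid$body$relative_stopping_power, dim = c(n, n, n))
  rsp[mask] <- grid$target$relative_stopping_power
  rho <- array(grid$body$density, dim = c(n, n, n))
  rho[mask] <- grid$target$density
  h <- grid$voxel_cm
  dwe <- rsp * h
  # beam travels from +z (index n) toward -z (index 1)
  we_exit <- aperm(apply(dwe, c(1, 2), function(col) rev(cumsum(rev(col)))),
                   c(2, 3, 1))
  we_mid <- we_exit - dwe / 2
  depth_phys <- grid$half - grid$centers # physical depth of z-centers (cm)
  list(mask = mask, rsp = rsp, rho = rho, dwe = dwe,
       we_mid = we_mid, depth_phys = depth_phys)
}

#' Water-equivalent path length along a beam-axis ray
#'
#' Cumulative water-equivalent depth at voxel mid-points (and exits) for a
#' ray parallel to the beam axis entering through the +z face at lateral
#' position `(x_mm, y_mm)`.
#'
#' @param grid A `phantom_grid`.
#' @param x_mm,y_mm Lateral ray position in mm (isocenter plane).
#' @return data.frame with columns `z_cm` (voxel center, beam order),
#'   `depth_cm` (physical), `we_mid_cm`, `we_exit_cm`.
#' @export
wepl_along_ray <- function(grid, x_mm, y_mm) {
  x <- x_mm / 10; y <- y_mm / 10
  if (abs(x) >= grid$half || abs(y) >= grid$half) {
    return(data.frame(z_cm = numeric(0), depth_cm = numeric(0),
                      we_mid_cm = numeric(0), we_exit_cm = numeric(0)))
  }
  ix <- findInterval(x, -grid$half + (0:grid$n) * grid$voxel_cm,
                     rightmost.closed = TRUE)
  iy <- findInterval(y, -grid$half + (0:grid$n) * grid$voxel_cm,
                     rightmost.closed = TRUE)
  off <- grid$target_offset_mm / 10
  in_target_col <- abs(grid$centers[ix] - off[1]) < grid$t_half &&
    abs(grid$centers[iy] - off[2]) < grid$t_half
  rsp_col <- rep(grid$body$relative_stopping_power, grid$n)
  if (in_target_col) {
    inz <- abs(grid$centers - off[3]) < grid$t_half
    rsp_col[inz] <- grid$target$relative_stopping_power
  }
  zc <- rev(grid$centers)                 # beam order: +z first
  dwe <- rev(rsp_col) * grid$voxel_cm
  we_exit <- cumsum(dwe)
  data.frame(z_cm = zc, depth_cm = grid$half - zc,
             we_mid_cm = we_exit - dwe / 2, we_exit_cm = we_exit)
}

# Water-equivalent depth at an arbitrary z-plane along the ray (x,y), by
# exact accumulation over whole and partial voxels.
wepl_at_plane <- function(grid, x_mm, y_mm, z_cm) {
  ray <- wepl_along_ray(grid, x_mm, y_mm)
  if (nrow(ray) == 0) return(NA_real_)
  depth <- grid$half - z_cm
  if (depth <= 0) return(0)
  h <- grid$voxel_cm
  dwe <- diff(c(0, ray$we_exit_cm)) # per-voxel WE thickness, beam order
  k <- min(floor(depth / h + 1e-12), grid$n)
  full <- if (k >= 1) ray$we_exit_cm[k] else 0
  if (k >= grid$n) return(full)
  full + (depth - k * h) * dwe[k + 1] / h
}

#' @export
print.phantom_grid <- function(x, ...) {
  cat(sprintf("<phantom_grid> %g cm water cube, %g mm voxels (%d^3)\n",
              x$extent, x$voxel_cm * 10, x$n))
  cat(sprintf("  target: %g cm cube of '%s', offset (%g, %g, %g) mm\n",
              x$target_extent, x$target$name,
              x$target_offset_mm[1], x$target_offset_mm[2],
              x$target_offset_mm[3]))
  invisible(x)
}
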