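#' Maze geometry model
#'
#' Rectangular enclosure with several horizontal floors and wall-mounted
#' reward ports. The origin sits at the lowest south-west corner, axes are
#' x (east), y (north), z (up), units cm. The interior volume is tiled by
#' place bins (per-floor x-y grids); the six inner faces are tiled by view
#' bins on their unwrapped 2D coordinates.
#'
#' The exact real-maze dimensions are not published; these defaults are a
#' configurable stand-in (see the methods vignette).
#'
#' @param extent (x_len, y_len, z_len) in cm.
#' @param n_floors number of horizontal levels.
#' @param floor_heights z of each floor [cm]; default evenly spaced from 0.
#' @param reward_ports matrix (m x 3) of port positions; default 4 per floor.
#' @param place_grid c(nx, ny) place bins per floor (default 7 x 4, giving
#'   84 bins over 3 floors).
#' @param view_bin_cm approximate view-bin edge length on the unwrapped
#'   faces [cm].
#' @return list of class `maze_model`.
#' @export
maze_model <- function(extent = c(100, 50, 120), n_floors = 3,
                       floor_heights = NULL, reward_ports = NULL,
                       place_grid = c(7, 4), view_bin_cm = 25) {
  stopifnot(length(extent) == 3, all(extent > 0), n_floors >= 1)
  if (is.null(floor_heights))
    floor_heights <- seq(0, by = extent[3] / n_floors, length.out = n_floors)
  if (is.null(reward_ports)) {
    xy <- rbind(c(5, 5), c(extent[1] - 5, 5),
                c(5, extent[2] - 5), c(extent[1] - 5, extent[2] - 5))
    reward_ports <- do.call(rbind, lapply(floor_heights, function(h)
      cbind(xy, h + 5)))
  }
  if (any(reward_ports[, 1] < 0 | reward_ports[, 1] > extent[1] |
          reward_ports[, 2] < 0 | reward_ports[, 2] > extent[2] |
          reward_ports[, 3] < 0 | reward_ports[, 3] > extent[3]))
    stop("reward ports outside maze extent")
  m <- list(extent = extent, n_floors = n_floors,
            floor_heights = floor_heights, reward_ports = reward_ports,
            place_grid = place_grid, view_bin_cm = view_bin_cm)
  class(m) <- "maze_model"
  m
}

#' Number of place bins in a maze
#' @param maze a `maze_model`.
#' @export
n_place_bins <- function(maze) maze$n_floors * prod(maze$place_grid)

# Floor slab index for z positions: nearest slab [h_i, h_{i+1}).
floor_index <- function(maze, z) {
  edges <- c(maze$floor_heights[-1], maze$extent[3] + 1e-9)
  findInterval(z, c(-Inf, edges), rightmost.closed = FALSE)
}

#' Place-bin index of 3D positions
#'
#' Bins are numbered floor-major, then row-major in (x, y). Positions outside
#' the extent are clamped to the boundary bin.
#'
#' @param maze a `maze_model`.
#' @param pos matrix (n x 3) of positions [cm].
#' @return integer bin ids in 1..n_place_bins(maze).
#' @export
place_bin_index <- function(maze, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, 1)
  nx <- maze$place_grid[1]; ny <- maze$place_grid[2]
  ix <- pmin(pmax(ceiling(pos[, 1] / maze$extent[1] * nx), 1L), nx)
  iy <- pmin(pmax(ceiling(pos[, 2] / maze$extent[2] * ny), 1L), ny)
  fl <- floor_index(maze, pos[, 3])
  as.integer((fl - 1L) * nx * ny + (iy - 1L) * nx + ix)
}

# Face metadata: each of the six inner faces with its unwrapped 2D size.
maze_faces <- function(maze) {
  e <- maze$extent
  data.frame(face = c("x0", "x1", "y0", "y1", "z0", "z1"),
             u_len = c(e[2], e[2], e[1], e[1], e[1], e[1]),
             v_len = c(e[3], e[3], e[3], e[3], e[2], e[2]),
             stringsAsFactors = FALSE)
}

# View-bin layout: per-face grids of ~view_bin_cm cells, numbered face by face.
view_bin_layout <- function(maze) {
  faces <- maze_faces(maze)
  faces$nu <- pmax(1L, ceiling(faces$u_len / maze$view_bin_cm))
  faces$nv <- pmax(1L, ceiling(faces$v_len / maze$view_bin_cm))
  faces$n_bins <- faces$nu * faces$nv
  faces$offset <- cumsum(c(0L, faces$n_bins[-6]))
  faces
}

#' Number of view bins in a maze
#' @param maze a `maze_model`.
#' @export
n_view_bins <- function(maze) sum(view_bin_layout(maze)$n_bins)

#' View-bin index for face hits
#' @param maze a `maze_model`.
#' @param face face labels ("x0","x1","y0","y1","z0","z1").
#' @param u,v unwrapped face coordinates [cm].
#' @return integer bin ids in 1..n_view_bins(maze); NA where face is NA.
#' @export
view_bin_index <- function(maze, face, u, v) {
  lay <- view_bin_layout(maze)
  idx <- match(face, lay$face)
  out <- rep(NA_integer_, length(face))
  ok <- !is.na(idx)
  if (!any(ok)) return(out)
  i <- idx[ok]
  iu <- pmin(pmax(ceiling(u[ok] / lay$u_len[i] * lay$nu[i]), 1L), lay$nu[i])
  iv <- pmin(pmax(ceiling(v[ok] / lay$v_len[i] * lay$nv[i]), 1L), lay$nv[i])
  out[ok] <- as.integer(lay$offset[i] + (iv - 1L) * lay$nu[i] + iu)
  out
}

#' Six coarse floor-half bins used by the place decoder
#'
#' Each floor is split into two halves along x, giving 6 coarse spatial
#' classes (2 per floor).
#'
#' @param maze a `maze_model`.
#' @param pos matrix (n x 3) of positions.
#' @return integer ids in 1..(2 * n_floors).
#' @export
floor_half_bin <- function(maze, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, 1)
  half <- ifelse(pos[, 1] < maze$extent[1] / 2, 1L, 2L)
  fl <- floor_index(maze, pos[, 3])
  as.integer((fl - 1L) * 2L + half)
}
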