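# Computational slice geometry: the [-10,10]^2 (Y,Z) domain, the rotated
# square graft indicator, initial fields, and the tracer polygon that tracks
# the graft surface area.

#' Sinusoidal ramp
#'
#' The piecewise transition used to build the graft shape: exactly 0 below
#' \code{s1 - s2}, exactly 1 above \code{s1 + s2}, and the sinusoidal blend
#' \code{0.5 [1 + sin((r - s1) pi / (2 s2))]} in between.  Continuous and
#' non-decreasing in \code{r}.
#'
#' @param r evaluation coordinate, cm (vector).
#' @param s1 ramp centre, cm.
#' @param s2 ramp half-width, cm; must be > 0.
#' @return values in [0, 1].
#' @export
ramp <- function(r, s1, s2) {
  if (!(s2 > 0)) stop("s2 must be > 0")
  out <- ifelse(r < s1 - s2, 0,
         ifelse(r > s1 + s2, 1,
                0.5 * (1 + sin((r - s1) * pi / (2 * s2)))))
  out
}

# one-dimensional bump: 1 on |r| < s1 - s2, 0 on |r| > s1 + s2
ramp_bump <- function(r, s1, s2) {
  (1 - ramp(r, s1, s2)) * ramp(r, -s1, s2)
}

#' Graft shape indicator
#'
#' Smooth indicator of unwounded dermis: \code{w = 0} on the grafted core,
#' \code{w = 1} in the far field, blending over a band of width \code{2 s2}
#' around the boundary of a square of half-side \code{s1} rotated by
#' \code{theta_r} about the out-of-plane axis.  Built as
#' \code{w = 1 - B(Y_r) B(Z_r)} with \code{B(r) = [1 - ramp(r, s1, s2)] *
#' ramp(r, -s1, s2)} and \code{(Y_r, Z_r)} the rotated coordinates.
#' Point-symmetric: \code{w(Y, Z) = w(-Y, -Z)}.
#'
#' @param Y,Z Lagrangian coordinates, cm (vectors of equal length).
#' @param params a \code{model_parameters} object (uses \code{s1}, \code{s2},
#'   \code{theta_r}).
#' @return values in [0, 1].
#' @export
graft_indicator <- function(Y, Z, params) {
  ct <- cos(params$theta_r); st <- sin(params$theta_r)
  Yr <- ct * Y - st * Z
  Zr <- st * Y + ct * Z
  1 - ramp_bump(Yr, params$s1, params$s2) * ramp_bump(Zr, params$s1, params$s2)
}

#' Build a structured triangulation of the tissue slice
#'
#' Conforming P1 triangulation of the square \code{[-half_width, half_width]^2}
#' from a uniform grid, each cell split along the same diagonal so the node
#' set and the element set are invariant under the point reflection
#' \code{(Y, Z) -> (-Y, -Z)}.  Reference (Lagrangian) and current (moved)
#' coordinates start identical; boundary nodes are marked.
#'
#' @param half_width half-width of the square domain, cm (default 10).
#' @param target_edge requested grid spacing, cm; the actual spacing is the
#'   nearest exact divisor.
#' @return An object of class \code{graft_mesh}: list with \code{ref} and
#'   \code{cur} (n x 2 coordinate matrices), \code{tri} (m x 3 connectivity),
#'   \code{boundary} (logical per node), \code{level} (integer per element)
#'   and \code{parent_def} (m x 3; the parent's node triple for elements born
#'   by bisection, NA for root elements).
#' @export
build_mesh <- function(half_width = 10, target_edge = 1) {
  if (!(half_width > 0)) stop("degenerate box: half_width must be > 0")
  if (!(target_edge > 0)) stop("target_edge must be > 0")
  ndiv <- max(2L, as.integer(round(2 * half_width / target_edge)))
  xs <- seq(-half_width, half_width, length.out = ndiv + 1L)
  nodes <- cbind(Y = rep(xs, times = ndiv + 1L),
                 Z = rep(xs, each = ndiv + 1L))
  idx <- function(i, j) (j - 1L) * (ndiv + 1L) + i  # i = Y index, j = Z index
  i <- rep(seq_len(ndiv), times = ndiv)
  j <- rep(seq_len(ndiv), each = ndiv)
  # split each cell along the (+1)-slope diagonal: preserved by point reflection
  a <- idx(i, j); b <- idx(i + 1L, j); cc <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
  tri <- rbind(cbind(a, b, cc), cbind(a, cc, d))
  bnd <- nodes[, 1] <= -half_width + 1e-12 | nodes[, 1] >= half_width - 1e-12 |
         nodes[, 2] <= -half_width + 1e-12 | nodes[, 2] >= half_width - 1e-12
  mesh <- list(ref = nodes, cur = nodes, tri = unname(tri), boundary = bnd,
               level = rep(0L, nrow(tri)),
               parent_def = matrix(NA_integer_, nrow(tri), 3L),
               anc = vector("list", nrow(tri)),
               half_width = half_width)
  class(mesh) <- "graft_mesh"
  mesh
}

#' Initial fields after graft placement
#'
#' Fibroblasts reduced to the fraction \code{I_w} of equilibrium inside the
#' graft, myofibroblasts and collagen at equilibrium, signalling molecule at
#' \code{c_w} inside the graft (plus the equilibrium \code{c_bar} outside),
#' and a mechanically unloaded start (\code{u = v = 0}, \code{eps = 0}).
#'
#' @param mesh a \code{graft_mesh}.
#' @param params a \code{model_parameters} object.
#' @return An object of class \code{state_fields}: list with nodal vectors
#'   \code{N}, \code{M}, \code{c}, \code{rho}, n x 2 matrices \code{u} and
#'   \code{v}, and the n x 3 plane tensor \code{eps}.
#' @export
initial_state <- function(mesh, params) {
  w <- graft_indicator(mesh$ref[, 1], mesh$ref[, 2], params)
  n <- nrow(mesh$ref)
  st <- list(
    N   = (params$I_w + (1 - params$I_w) * w) * params$N_bar,
    M   = rep(params$M_bar, n),
    c   = (1 - w) * params$c_w + params$c_bar,
    rho = rep(params$rho_bar, n),
    u   = matrix(0, n, 2),
    v   = matrix(0, n, 2),
    eps = plane_tensor(rep(0, n), 0, 0)
  )
  class(st) <- "state_fields"
  st
}

#' Place tracer material points on the graft boundary
#'
#' Material points on the \code{w = 1/2} level set (the rotated square of
#' half-side \code{s1}), ordered counterclockwise; the displaced polygon
#' through these points measures the graft surface area over time.
#'
#' @param params a \code{model_parameters} object.
#' @param n_per_side points per square side (>= 1); \code{n_per_side = 1}
#'   gives the 4 corners, 2 adds the edge midpoints, and so on.
#' @return An object of class \code{tracer_set}: list with \code{ref}
#'   (k x 2 reference coordinates, counterclockwise).
#' @export
place_tracers <- function(params, n_per_side = 2) {
  if (n_per_side < 1) stop("n_per_side must be >= 1")
  s1 <- params$s1
  # square corners in the rotated frame, counterclockwise
  corners <- rbind(c(s1, s1), c(-s1, s1), c(-s1, -s1), c(s1, -s1))
  pts <- NULL
  for (k in 1:4) {
    a <- corners[k, ]; b <- corners[if (k == 4) 1 else k + 1, ]
    f <- (seq_len(n_per_side) - 1) / n_per_side
    pts <- rbind(pts, cbind(a[1] + f * (b[1] - a[1]), a[2] + f * (b[2] - a[2])))
  }
  # map back from rotated to Lagrangian coordinates (inverse rotation)
  ct <- cos(params$theta_r); st <- sin(params$theta_r)
  ref <- cbind(ct * pts[, 1] + st * pts[, 2],
               -st * pts[, 1] + ct * pts[, 2])
  out <- list(ref = unname(ref))
  class(out) <- "tracer_set"
  out
}

#' Signed polygon area (shoelace formula)
#'
#' @param xy k x 2 matrix of vertices in order.
#' @return signed area; positive for counterclockwise orientation.
#' @export
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

# element reference/current areas and P1 shape gradients on given coordinates
element_geometry <- function(coords, tri) {
  p1 <- coords[tri[, 1], , drop = FALSE]
  p2 <- coords[tri[, 2], , drop = FALSE]
  p3 <- coords[tri[, 3], , drop = FALSE]
  d1 <- p2 - p1; d2 <- p3 - p1
  det <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  area <- 0.5 * det
  # grad phi_i, constant per element: rows of inv([d1; d2])^T assembled directly
  gx <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) / det
  gy <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) / det
  list(area = area, gx = gx, gy = gy)
}

# check for a conforming triangulation: every interior edge shared by exactly
# two elements, boundary edges by one, and no node hangs on another element's
# edge interior (used by tests and the refinement machinery)
mesh_is_conforming <- function(mesh) {
  tri <- mesh$tri
  edges <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  cnt <- table(key)
  if (any(cnt > 2)) return(FALSE)
  # hanging-node check: a node lying strictly inside some element edge
  once <- names(cnt)[cnt == 1]
  used <- sort(unique(as.vector(tri)))
  co <- mesh$ref
  for (k in once) {
    ij <- as.integer(strsplit(k, " ")[[1]])
    a <- co[ij[1], ]; b <- co[ij[2], ]
    ab <- b - a; L2 <- sum(ab^2)
    for (nd in used) {
      if (nd == ij[1] || nd == ij[2]) next
      t <- sum((co[nd, ] - a) * ab) / L2
      if (t > 1e-9 && t < 1 - 1e-9) {
        d <- co[nd, ] - (a + t * ab)
        if (sum(d^2) < 1e-18 * L2) return(FALSE)
      }
    }
  }
  all(element_geometry(mesh$ref, tri)$area > 0)
}
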