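# Mesh generators: structured cylinder tubes, icospheres, flat patches and
# the three-way junction seed.  All fixtures used by the tests are built here
# programmatically; no mesh files ship with the package.

# order a boundary loop by following the directed boundary edges as the
# interior faces traverse them (needed for consistently oriented caps)
order_boundary_loop <- function(faces, loop_verts) {
  he <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  rev_key <- paste(he[, 2], he[, 1])
  bnd <- !(key %in% rev_key)            # directed edges with no opposite
  bhe <- he[bnd, , drop = FALSE]
  sel <- bhe[, 1] %in% loop_verts & bhe[, 2] %in% loop_verts
  bhe <- bhe[sel, , drop = FALSE]
  nxt <- stats::setNames(bhe[, 2], bhe[, 1])
  out <- integer(length(loop_verts))
  out[1] <- loop_verts[1]
  for (i in seq_len(length(loop_verts) - 1)) {
    out[i + 1] <- nxt[[as.character(out[i])]]
  }
  if (anyDuplicated(out) || !setequal(out, loop_verts))
    stop("boundary loop is not a single cycle")
  out
}

# ring descriptor from an ordered circular loop, axis and anchor
make_ring <- function(V, loop, axis, anchor, collar) {
  axis <- axis / sqrt(sum(axis^2))
  # frame: u = projection of z (or x) orthogonal to axis
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  ctr <- colMeans(V[loop, , drop = FALSE])
  d <- sum((ctr - anchor) * axis)
  rel <- sweep(V[loop, , drop = FALSE], 2, anchor + d * axis)
  theta <- atan2(rel %*% v, rel %*% u)[, 1]
  zc <- mean(sweep(V[collar, , drop = FALSE], 2, anchor) %*% axis)
  ring_descriptor(loop, axis, anchor, u, v, theta, d, collar,
                  collar_offset = d - zc)
}

#' Structured cylinder mesh
#'
#' Axis along z, centered at the origin, with boundary rings at both ends
#' and collar rings one row in.  Used as the seed for tether computations.
#'
#' @param radius cylinder radius.
#' @param length total length along the axis.
#' @param edge_target approximate target edge length.
#' @return a [surface_mesh()] with two boundary rings.
#' @export
build_cylinder_mesh <- function(radius, length, edge_target) {
  ntheta <- max(8L, round(2 * pi * radius / edge_target))
  nz <- max(4L, round(length / edge_target))
  th <- 2 * pi * (seq_len(ntheta) - 1) / ntheta
  z <- seq(-length / 2, length / 2, length.out = nz + 1)
  vid <- function(i, j) (i * ntheta) + ((j - 1L) %% ntheta) + 1L  # i = 0..nz
  V <- matrix(0, (nz + 1) * ntheta, 3)
  for (i in 0:nz) {
    V[vid(i, 1:ntheta), ] <- cbind(radius * cos(th), radius * sin(th), z[i + 1])
  }
  Fm <- matrix(0L, 2 * nz * ntheta, 3)
  r <- 1L
  for (i in 0:(nz - 1)) {
    for (j in 1:ntheta) {
      a <- vid(i, j); b <- vid(i, j + 1); cc <- vid(i + 1, j + 1); d <- vid(i + 1, j)
      Fm[r, ] <- c(a, b, cc); Fm[r + 1L, ] <- c(a, cc, d)
      r <- r + 2L
    }
  }
  bottom <- vid(0, 1:ntheta); top <- vid(nz, 1:ntheta)
  bottom <- order_boundary_loop(Fm, bottom)
  top <- order_boundary_loop(Fm, top)
  rings <- list(
    make_ring(V, bottom, c(0, 0, -1), c(0, 0, 0), vid(1, 1:ntheta)),
    make_ring(V, top, c(0, 0, 1), c(0, 0, 0), vid(nz - 1, 1:ntheta)))
  surface_mesh(V, Fm, rings)
}

#' Icosphere mesh
#'
#' Closed triangulated sphere by recursive subdivision of an icosahedron.
#' @param radius sphere radius.
#' @param refine number of subdivision passes.
#' @return a closed [surface_mesh()].
#' @export
build_icosphere <- function(radius = 1, refine = 3) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  Fm <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (pass in seq_len(refine)) {
    nV <- nrow(V)
    ekey <- new.env(hash = TRUE, size = 6L * nrow(Fm))
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      id <- ekey[[k]]
      if (is.null(id)) {
        p <- (V[a, ] + V[b, ]) / 2
        p <- p / sqrt(sum(p^2))
        V <<- rbind(V, p)
        id <- nrow(V)
        ekey[[k]] <- id
      }
      id
    }
    newF <- matrix(0L, 4 * nrow(Fm), 3)
    for (f in seq_len(nrow(Fm))) {
      a <- Fm[f, 1]; b <- Fm[f, 2]; cc <- Fm[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF[(4 * f - 3):(4 * f), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }
    Fm <- newF
  }
  surface_mesh(radius * V, Fm, list())
}

#' Flat triangulated square patch
#'
#' Unit square in the z = 0 plane; used as a zero-curvature reference.
#' @param n grid subdivisions per side.
#' @return an open [surface_mesh()] (no declared rings).
#' @export
build_flat_patch <- function(n = 8) {
  xs <- seq(0, 1, length.out = n + 1)
  V <- as.matrix(expand.grid(x = xs, y = xs))
  V <- cbind(V, 0)
  vid <- function(i, j) (j - 1L) * (n + 1L) + i          # i, j = 1..n+1
  Fm <- matrix(0L, 2 * n * n, 3)
  r <- 1L
  for (j in 1:n) for (i in 1:n) {
    a <- vid(i, j); b <- vid(i + 1, j); cc <- vid(i + 1, j + 1); d <- vid(i, j + 1)
    Fm[r, ] <- c(a, b, cc); Fm[r + 1L, ] <- c(a, cc, d)
    r <- r + 2L
  }
  surface_mesh(V, Fm, list())
}

#' Three-way junction seed mesh
#'
#' Three cylindrical arms of radius `arm_radius` at 120 degree angles in the
#' z = 0 plane, joined at the center by the boundary surface of the union of
#' the three tubes around the ray skeleton (the arm tubes meet pairwise on
#' the bisector planes, their intersection curves running from the in-plane
#' saddle points up to the two poles above and below the junction center).
#' The seed is a feasible pair-of-pants surface; the equilibrium shape is
#' obtained by relaxation.
#'
#' @param arm_radius tube radius of the seed.
#' @param arm_length distance from the junction center to each boundary ring.
#' @param edge_target approximate target edge length.
#' @return a [surface_mesh()] with three boundary rings.
#' @export
build_junction_seed_mesh <- function(arm_radius, arm_length, edge_target) {
  rho <- arm_radius; L <- arm_length
  if (L <= 3 * rho) stop("arm_length must exceed 3 * arm_radius")
  nphi <- max(12L, 2L * round(pi * rho / edge_target))    # even
  nt <- max(6L, round(L / edge_target))
  alph <- c(0, 2, 4) * pi / 3                            # arm planar angles
  ez <- c(0, 0, 1)

  phis <- -pi + 2 * pi * (0:(nphi - 1)) / nphi           # includes -pi and 0
  jtop <- which(abs(phis) < 1e-12)                       # phi = 0 meridian
  jbot <- which(abs(phis + pi) < 1e-12)                  # phi = -pi meridian

  # global vertex table
  Vlist <- list(); nV <- 0L
  addv <- function(p) {
    nV <<- nV + 1L
    Vlist[[nV]] <<- p
    nV
  }
  pole_top <- addv(c(0, 0, rho))
  pole_bot <- addv(c(0, 0, -rho))

  arm_dir <- lapply(alph, function(a) c(cos(a), sin(a), 0))
  lat_dir <- lapply(alph, function(a) c(-sin(a), cos(a), 0))
  pos_on_tube <- function(k, t, phi) {
    t * arm_dir[[k]] + rho * sin(phi) * lat_dir[[k]] + rho * cos(phi) * ez
  }

  # crease vertices between arm k and arm k+1, parameterized by phi in (0, pi)
  # (computed from arm k's + side); index by meridian j of the positive phis
  pos_phis <- phis[phis > 1e-12 & phis < pi - 1e-12]
  crease <- vector("list", 3)
  for (k in 1:3) {
    crease[[k]] <- vapply(pos_phis, function(phi) {
      tc <- rho * abs(sin(phi)) / sqrt(3)
      addv(pos_on_tube(k, tc, phi))
    }, integer(1))
    names(crease[[k]]) <- sprintf("%.12f", pos_phis)
  }
  crease_id <- function(k, phi) crease[[k]][[sprintf("%.12f", abs(phi))]]

  # per-arm grids, rows i = 1..nt (row 0 is the crease / poles)
  grid_id <- array(0L, dim = c(3, nt, nphi))
  for (k in 1:3) {
    for (j in seq_len(nphi)) {
      phi <- phis[j]
      tc <- rho * abs(sin(phi)) / sqrt(3)
      ts <- tc + (L - tc) * (1:nt) / nt
      for (i in 1:nt) grid_id[k, i, j] <- addv(pos_on_tube(k, ts[i], phi))
    }
  }
  row0_id <- function(k, j) {
    phi <- phis[j]
    if (j == jtop) return(pole_top)
    if (j == jbot) return(pole_bot)
    if (phi > 0) crease_id(k, phi) else crease_id(if (k == 1) 3 else k - 1, phi)
  }
  vid <- function(k, i, j) {
    j <- ((j - 1L) %% nphi) + 1L
    if (i == 0L) row0_id(k, j) else grid_id[k, i, j]
  }

  V <- do.call(rbind, Vlist)
  Fs <- vector("list", 3L * nt * nphi * 2L)
  r <- 0L
  for (k in 1:3) {
    for (i in 0:(nt - 1)) {
      for (j in 1:nphi) {
        a <- vid(k, i, j); b <- vid(k, i + 1, j)
        cc <- vid(k, i + 1, j + 1); d <- vid(k, i, j + 1)
        # orientation: +t then +phi is outward
        if (a != d) {
          r <- r + 1L; Fs[[r]] <- c(a, b, cc)
          r <- r + 1L; Fs[[r]] <- c(a, cc, d)
        } else {
          r <- r + 1L; Fs[[r]] <- c(a, b, cc)
        }
      }
    }
  }
  Fm <- do.call(rbind, Fs[seq_len(r)])

  rings <- vector("list", 3)
  for (k in 1:3) {
    loop <- order_boundary_loop(Fm, grid_id[k, nt, ])
    rings[[k]] <- make_ring(V, loop, arm_dir[[k]], c(0, 0, 0),
                            grid_id[k, nt - 1L, ])
  }
  mesh <- surface_mesh(V, Fm, rings)
  if (enclosed_volume(mesh) < 0)
    stop("junction seed has inward orientation")
  mesh
}
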