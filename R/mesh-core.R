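#' Triangulated open membrane surface
#'
#' Container for a triangulated surface with consistently oriented faces and
#' zero or more open boundary rings.  Each boundary ring is an ordered vertex
#' loop lying on a circle in the plane perpendicular to its arm axis; the
#' adjacent interior ring (the "collar") is used to enforce tangency of the
#' membrane to the arm axis at the boundary, the way tether computations pin
#' the tube ends.
#'
#' @param vertices numeric matrix (n x 3) of vertex positions, in units of
#'   the relaxation length.
#' @param faces integer matrix (m x 3) of 1-based vertex triples with
#'   consistent outward orientation.
#' @param rings list of boundary-ring descriptors as built by
#'   [ring_descriptor()]; may be empty for closed surfaces.
#' @param validate logical; run [validate_mesh()] on construction.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, rings = list(), validate = TRUE) {
  storage.mode(vertices) <- "double"
  faces <- matrix(as.integer(faces), ncol = 3)
  mesh <- structure(
    list(vertices = vertices, faces = faces, rings = rings),
    class = "surface_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Boundary-ring descriptor
#'
#' @param verts ordered vertex indices of the boundary loop, following the
#'   direction in which the interior faces traverse the boundary edges.
#' @param axis unit vector of the arm axis, pointing outward (from the
#'   system's center toward the open end).
#' @param anchor point on the axis from which the arm length is measured
#'   (the junction center, or the origin for a plain cylinder).
#' @param frame_u,frame_v orthonormal vectors spanning the boundary plane.
#' @param theta angular position of each boundary vertex in the (u,v) frame.
#' @param d distance from `anchor` to the boundary plane (the arm length).
#' @param collar ordered vertex indices of the adjacent interior ring.
#' @param collar_offset axial distance of the collar plane behind the
#'   boundary plane; the band between them is constrained to a cylinder of
#'   the boundary radius, which realizes the tangency condition.
#' @export
ring_descriptor <- function(verts, axis, anchor, frame_u, frame_v, theta, d,
                            collar, collar_offset = NA_real_) {
  list(verts = as.integer(verts), axis = as.numeric(axis),
       anchor = as.numeric(anchor), frame_u = as.numeric(frame_u),
       frame_v = as.numeric(frame_v), theta = as.numeric(theta),
       d = as.numeric(d), collar = as.integer(collar),
       collar_offset = as.numeric(collar_offset))
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, %d boundary ring(s)\n",
              nrow(x$vertices), nrow(x$faces), length(x$rings)))
  invisible(x)
}

#' Material parameters of the membrane
#'
#' Bending modulus and reference (reservoir) tension.  The derived
#' relaxation length \eqn{\lambda_0 = \sqrt{\kappa/\gamma_0}} is the natural
#' length unit of tether-like shapes; internally the package works in units
#' where \eqn{\kappa = \gamma_0 = \lambda_0 = 1}.
#'
#' @param kappa bending modulus (energy units), > 0.
#' @param gamma0 reference tension (energy / length^2), > 0.
#' @return object of class `material_params` with fields `kappa`, `gamma0`,
#'   `lambda0`.
#' @export
material_params <- function(kappa = 1, gamma0 = 1) {
  stopifnot(is.numeric(kappa), kappa > 0, is.numeric(gamma0), gamma0 > 0)
  structure(list(kappa = kappa, gamma0 = gamma0,
                 lambda0 = sqrt(kappa / gamma0)),
            class = "material_params")
}

# ---- internal helpers -------------------------------------------------------

# vertex indices lying on any boundary edge
boundary_vertices <- function(mesh) {
  et <- edge_table_cpp(mesh$faces - 1L, nrow(mesh$vertices))
  bnd <- is.na(et[, 4])
  unique(c(et[bnd, 1], et[bnd, 2])) + 1L
}

# vertices included in the bending-energy sum: interior vertices that are
# neither on a boundary ring nor on a collar ring (their curvature is fixed
# by the boundary conditions, not by the elastic energy)
bending_vertices <- function(mesh) {
  n <- nrow(mesh$vertices)
  incl <- rep(TRUE, n)
  incl[boundary_vertices(mesh)] <- FALSE
  # ring vertices get their curvature stars completed by mirror ghosts, so
  # they carry bending energy; undeclared open boundaries do not
  for (rg in mesh$rings) incl[rg$verts] <- TRUE
  incl
}

# Static data for the mirror-ghost completion of boundary stars: for each
# boundary ring, the band faces between the ring and its collar are mirrored
# across the boundary plane (reversing the winding), with collar vertices
# mapped to ghost copies.  This realizes the tangency boundary condition in
# the discrete bending energy.
ghost_info <- function(mesh) {
  n <- nrow(mesh$vertices)
  rings <- mesh$rings
  if (length(rings) == 0)
    return(list(n = n, ghost_faces = NULL, map = NULL))
  gmap <- list()
  gfaces <- list()
  nextid <- n
  for (k in seq_along(rings)) {
    rg <- rings[[k]]
    nc <- length(rg$collar)
    gid <- nextid + seq_len(nc)
    nextid <- nextid + nc
    lut <- integer(n)
    lut[rg$collar] <- gid
    inband <- rep(FALSE, n)
    inband[c(rg$verts, rg$collar)] <- TRUE
    sel <- inband[mesh$faces[, 1]] & inband[mesh$faces[, 2]] &
           inband[mesh$faces[, 3]]
    bf <- mesh$faces[sel, , drop = FALSE]
    mf <- bf
    iscol <- matrix(lut[bf] > 0L, nrow(bf), 3)
    mf[iscol] <- lut[bf][iscol]
    mf <- mf[, c(1, 3, 2), drop = FALSE]     # mirror flips orientation
    gmap[[k]] <- list(ring = k, collar = rg$collar, ghosts = gid,
                      bverts = rg$verts, axis = rg$axis, anchor = rg$anchor)
    gfaces[[k]] <- mf
  }
  list(n = n, ghost_faces = do.call(rbind, gfaces), map = gmap)
}

# ghost vertex positions for the current vertex matrix
ghost_positions <- function(V, gi) {
  out <- vector("list", length(gi$map))
  for (k in seq_along(gi$map)) {
    g <- gi$map[[k]]
    a <- g$axis
    d_cur <- mean(V[g$bverts, , drop = FALSE] %*% a) - sum(g$anchor * a)
    Vc <- V[g$collar, , drop = FALSE]
    zc <- as.numeric(Vc %*% a) - sum(g$anchor * a)
    out[[k]] <- Vc + (2 * (d_cur - zc)) %o% a
  }
  do.call(rbind, out)
}

# pull ghost-row gradients back onto the real vertices they depend on
ghost_pullback <- function(G, gi) {
  n <- gi$n
  Gr <- G[seq_len(n), , drop = FALSE]
  for (k in seq_along(gi$map)) {
    g <- gi$map[[k]]
    a <- g$axis
    Gg <- G[g$ghosts, , drop = FALSE]
    proj <- as.numeric(Gg %*% a)
    # d x_ghost / d x_collar = I - 2 a a^T  (mirror)
    Gr[g$collar, ] <- Gr[g$collar, , drop = FALSE] + Gg - (2 * proj) %o% a
    # d x_ghost / d x_boundary = (2/nb) a a^T  (through the plane position)
    nb <- length(g$bverts)
    Gr[g$bverts, ] <- Gr[g$bverts, , drop = FALSE] +
      matrix((2 / nb) * sum(proj) * a, nb, 3, byrow = TRUE)
  }
  Gr
}

# The bending term uses the normal-projected star form at every vertex:
# the projection suppresses the vertex-pairing instability of the raw
# |grad A|^2 star energy (which otherwise drives faces to zero area and
# pins the optimizer against the resulting energy walls).  Tangency at the
# boundary is enforced parametrically by the collar band, not through the
# energy, so the projection loses nothing there.
projected_vertices <- function(mesh) {
  rep(FALSE, nrow(mesh$vertices))
}

# kernel call with ghost completion; gradients returned per real vertex
mesh_terms <- function(mesh, kappa = 1, grad = FALSE, incl = NULL,
                       gi = NULL) {
  if (is.null(incl)) incl <- bending_vertices(mesh)
  if (is.null(gi)) gi <- ghost_info(mesh)
  projv <- projected_vertices(mesh)
  rings0 <- lapply(mesh$rings, function(rg) rg$verts - 1L)
  V <- mesh$vertices
  Fm <- mesh$faces
  n_real <- nrow(Fm)
  if (!is.null(gi$ghost_faces)) {
    V <- rbind(V, ghost_positions(V, gi))
    Fm <- rbind(Fm, gi$ghost_faces)
    incl <- c(incl, rep(FALSE, nrow(V) - gi$n))
    projv <- c(projv, rep(FALSE, nrow(V) - gi$n))
  }
  tr <- mesh_terms_cpp(V, Fm - 1L, incl, projv, rings0, kappa, grad, n_real)
  if (grad && !is.null(gi$ghost_faces)) {
    tr$g_fb <- ghost_pullback(tr$g_fb, gi)
    tr$g_area <- tr$g_area[seq_len(gi$n), , drop = FALSE]
    tr$g_vol <- tr$g_vol[seq_len(gi$n), , drop = FALSE]
  }
  if (!is.null(gi$ghost_faces)) {
    tr$J <- tr$J[seq_len(gi$n)]
    tr$avert <- tr$avert[seq_len(gi$n)]
  }
  tr
}

#' Validate a surface mesh
#'
#' Checks manifoldness (every edge shared by exactly two faces, boundary
#' edges by one), global orientation consistency, non-degenerate faces, and
#' the declared ring structure.
#'
#' @param mesh a [surface_mesh()].
#' @param min_area faces below this area are treated as degenerate.
#' @return invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_mesh <- function(mesh, min_area = 1e-12) {
  V <- mesh$vertices; F <- mesh$faces
  if (any(is.na(V)) || any(!is.finite(V))) stop("non-finite vertex coordinates")
  if (min(F) < 1 || max(F) > nrow(V)) stop("face index out of range")

  # face areas
  a <- V[F[, 1], , drop = FALSE]
  u <- V[F[, 2], , drop = FALSE] - a
  w <- V[F[, 3], , drop = FALSE] - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  fa <- 0.5 * sqrt(rowSums(cr^2))
  if (any(fa <= min_area))
    stop(sprintf("degenerate face(s): min area %.3e", min(fa)))

  # edge manifoldness (errors inside if >2 faces share an edge)
  et <- edge_table_cpp(F - 1L, nrow(V))

  # orientation: each interior edge must be traversed once in each direction
  he <- rbind(F[, c(1, 2)], F[, c(2, 3)], F[, c(3, 1)])
  key <- paste(he[, 1], he[, 2])
  if (anyDuplicated(key))
    stop("inconsistent face orientation: repeated directed edge")

  # ring structure
  nb <- sum(is.na(et[, 4]))
  bverts <- if (nb > 0) unique(c(et[is.na(et[, 4]), 1:2])) + 1L else integer(0)
  declared <- unlist(lapply(mesh$rings, `[[`, "verts"))
  if (length(mesh$rings) > 0) {
    if (!setequal(declared, bverts))
      stop("declared ring vertices do not match mesh boundary")
    for (rg in mesh$rings) {
      ax <- rg$axis
      if (abs(sqrt(sum(ax^2)) - 1) > 1e-8) stop("ring axis must be a unit vector")
    }
  } else if (nb > 0 && length(declared) == 0) {
    # open mesh without declared rings is allowed (e.g. flat patches)
  }
  invisible(TRUE)
}

# ---- public geometry operations --------------------------------------------

#' Total membrane area
#'
#' Sum of triangle areas of the open surface (boundary caps excluded).
#' @param mesh a [surface_mesh()].
#' @return scalar area.
#' @export
surface_area <- function(mesh) {
  mesh_terms(mesh, grad = FALSE)$area
}

#' Enclosed volume
#'
#' Signed volume by the divergence theorem, with each open boundary ring
#' closed by a flat triangle fan to its centroid.  With outward orientation
#' the result is positive and translation invariant.
#' @param mesh a [surface_mesh()].
#' @return scalar volume.
#' @export
enclosed_volume <- function(mesh) {
  mesh_terms(mesh, grad = FALSE)$volume
}

#' Total curvature and vertex areas
#'
#' Per-vertex total curvature \eqn{J_i} (sum of the two principal
#' curvatures, positive for spheres and cylinders with outward normals)
#' from the cotangent mean-curvature normal divided by the mixed Voronoi
#' vertex area, together with those areas.  One-rings dominated by obtuse
#' triangles fall back to the barycentric area with a warning.
#'
#' @param mesh a [surface_mesh()].
#' @return list with `J` (length n, `NA` on boundary vertices where the
#'   one-ring is incomplete) and `A` (vertex areas).
#' @export
mean_curvature <- function(mesh) {
  V <- mesh$vertices; F <- mesh$faces
  n <- nrow(V)
  i1 <- F[, 1]; i2 <- F[, 2]; i3 <- F[, 3]
  e23 <- V[i3, , drop = FALSE] - V[i2, , drop = FALSE]
  e31 <- V[i1, , drop = FALSE] - V[i3, , drop = FALSE]
  e12 <- V[i2, , drop = FALSE] - V[i1, , drop = FALSE]
  # cotangents of the angle at each corner
  cot_at <- function(ea, eb) {         # angle between -ea and eb at shared vertex
    num <- rowSums((-ea) * eb)
    crx <- cbind((-ea)[, 2] * eb[, 3] - (-ea)[, 3] * eb[, 2],
                 (-ea)[, 3] * eb[, 1] - (-ea)[, 1] * eb[, 3],
                 (-ea)[, 1] * eb[, 2] - (-ea)[, 2] * eb[, 1])
    num / sqrt(rowSums(crx^2))
  }
  c1 <- cot_at(e31, e12)  # at vertex 1, between edges to 3 and 2
  c2 <- cot_at(e12, e23)
  c3 <- cot_at(e23, e31)

  # cotan mean-curvature normal: Hn_i = 1/2 sum_j (cot a + cot b)(x_i - x_j),
  # accumulated per half-edge (edge (i,j) weighted by the opposite cotangent)
  acc <- matrix(0, n, 3)
  accum <- function(acc, i, j, cotw) {
    d <- V[i, , drop = FALSE] - V[j, , drop = FALSE]
    contrib <- 0.5 * cotw * d
    for (k in 1:3) {
      s <- rowsum(contrib[, k], i, reorder = FALSE)
      acc[as.integer(rownames(s)), k] <- acc[as.integer(rownames(s)), k] + s
    }
    acc
  }
  acc <- accum(acc, i1, i2, c3); acc <- accum(acc, i2, i1, c3)
  acc <- accum(acc, i2, i3, c1); acc <- accum(acc, i3, i2, c1)
  acc <- accum(acc, i3, i1, c2); acc <- accum(acc, i1, i3, c2)

  # mixed Voronoi areas (Meyer et al. rule)
  l23 <- rowSums(e23^2); l31 <- rowSums(e31^2); l12 <- rowSums(e12^2)
  crx <- cbind(e12[, 2] * (-e31)[, 3] - e12[, 3] * (-e31)[, 2],
               e12[, 3] * (-e31)[, 1] - e12[, 1] * (-e31)[, 3],
               e12[, 1] * (-e31)[, 2] - e12[, 2] * (-e31)[, 1])
  fa <- 0.5 * sqrt(rowSums(crx^2))
  obtuse1 <- c1 < 0; obtuse2 <- c2 < 0; obtuse3 <- c3 < 0
  anyobt <- obtuse1 | obtuse2 | obtuse3
  # non-obtuse triangle: Voronoi corner areas
  w1 <- ifelse(!anyobt, (l12 * c3 + l31 * c2) / 8, ifelse(obtuse1, fa / 2, fa / 4))
  w2 <- ifelse(!anyobt, (l12 * c3 + l23 * c1) / 8, ifelse(obtuse2, fa / 2, fa / 4))
  w3 <- ifelse(!anyobt, (l23 * c1 + l31 * c2) / 8, ifelse(obtuse3, fa / 2, fa / 4))
  Av <- rep(0, n); Ab <- rep(0, n); nobt <- rep(0, n); ninc <- rep(0, n)
  for (co in 1:3) {
    idx <- F[, co]
    wv <- list(w1, w2, w3)[[co]]
    s <- rowsum(wv, idx, reorder = FALSE)
    Av[as.integer(rownames(s))] <- Av[as.integer(rownames(s))] + s
    s <- rowsum(fa / 3, idx, reorder = FALSE)
    Ab[as.integer(rownames(s))] <- Ab[as.integer(rownames(s))] + s
    s <- rowsum(as.numeric(anyobt), idx, reorder = FALSE)
    nobt[as.integer(rownames(s))] <- nobt[as.integer(rownames(s))] + s
    s <- rowsum(rep(1, nrow(F)), idx, reorder = FALSE)
    ninc[as.integer(rownames(s))] <- ninc[as.integer(rownames(s))] + s
  }
  fallback <- nobt > ninc / 2
  if (any(fallback))
    warning(sprintf("%d vertex one-ring(s) dominated by obtuse triangles; using barycentric area there", sum(fallback)))
  A <- ifelse(fallback, Ab, Av)

  # orientation sign from summed face normals
  nsum <- matrix(0, n, 3)
  for (co in 1:3) {
    idx <- F[, co]
    for (k in 1:3) {
      s <- rowsum(crx[, k], idx, reorder = FALSE)
      nsum[as.integer(rownames(s)), k] <- nsum[as.integer(rownames(s)), k] + s
    }
  }
  J <- sqrt(rowSums(acc^2)) / A
  J <- J * sign(rowSums(acc * nsum))
  J[boundary_vertices(mesh)] <- NA_real_
  list(J = J, A = A)
}

#' Helfrich bending energy
#'
#' \eqn{F_B = \sum_i (\kappa/2) J_i^2 a_i} over the interior vertices, with
#' the star discretization used by the energy minimizer (vertex area-gradient
#' magnitude over barycentric vertex area).  Boundary and collar rings are
#' excluded: their shape is dictated by the boundary conditions.
#'
#' @param mesh a [surface_mesh()].
#' @param params a [material_params()].
#' @return scalar energy, >= 0.
#' @export
bending_energy <- function(mesh, params = material_params()) {
  mesh_terms(mesh, kappa = params$kappa, grad = FALSE)$fb
}

#' Gradients of bending energy, area and volume
#'
#' Analytic per-vertex gradients of \eqn{F_B}, total area and enclosed
#' volume with respect to vertex positions; the workhorse of the constrained
#' minimizer, exposed for testing against finite differences.
#'
#' @param mesh a [surface_mesh()].
#' @param params a [material_params()].
#' @return list with `g_fb`, `g_area`, `g_vol` (n x 3 each) plus the scalar
#'   `fb`, `area`, `volume`.
#' @export
shape_gradients <- function(mesh, params = material_params()) {
  tr <- mesh_terms(mesh, kappa = params$kappa, grad = TRUE)
  list(fb = tr$fb, area = tr$area, volume = tr$volume,
       g_fb = tr$g_fb, g_area = tr$g_area, g_vol = tr$g_vol)
}

# mean edge length of a mesh
mean_edge_length <- function(mesh) {
  et <- edge_table_cpp(mesh$faces - 1L, nrow(mesh$vertices))
  d <- mesh$vertices[et[, 1] + 1L, , drop = FALSE] -
       mesh$vertices[et[, 2] + 1L, , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}
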