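# Isotropic remeshing: deterministic edge splits, collapses, equiangulation
# flips and tangential vertex smoothing, in the tradition of finite-element
# surface evolution grooming.  Boundary and collar rings are never touched;
# all other vertices may move tangentially or be created/removed.

# vertices that must not be created/removed/moved by the remesher
protected_vertices <- function(mesh) {
  prot <- rep(FALSE, nrow(mesh$vertices))
  for (rg in mesh$rings) prot[c(rg$verts, rg$collar)] <- TRUE
  prot[boundary_vertices(mesh)] <- TRUE
  prot
}

edge_df <- function(mesh) {
  et <- edge_table_cpp(mesh$faces - 1L, nrow(mesh$vertices))
  v1 <- et[, 1] + 1L; v2 <- et[, 2] + 1L
  d <- mesh$vertices[v1, , drop = FALSE] - mesh$vertices[v2, , drop = FALSE]
  list(v1 = v1, v2 = v2, f1 = et[, 3] + 1L, f2 = et[, 4] + 1L,
       len = sqrt(rowSums(d^2)))
}

# split every edge longer than 4/3 target (longest first, one sweep)
remesh_split <- function(mesh, target) {
  ed <- edge_df(mesh)
  prot <- protected_vertices(mesh)
  long <- which(ed$len > 4 / 3 * target &
                !(prot[ed$v1] & prot[ed$v2]))
  if (length(long) == 0) return(mesh)
  long <- long[order(-ed$len[long])]
  V <- mesh$vertices
  Fm <- mesh$faces
  touched <- rep(FALSE, nrow(Fm))
  newV <- list(); newF <- list()
  for (e in long) {
    fs <- c(ed$f1[e], ed$f2[e]); fs <- fs[!is.na(fs)]
    if (any(touched[fs])) next
    a <- ed$v1[e]; b <- ed$v2[e]
    mid <- (V[a, ] + V[b, ]) / 2
    newV[[length(newV) + 1]] <- mid
    m <- nrow(V) + length(newV)
    for (f in fs) {
      tri <- Fm[f, ]
      # rotate so that tri = (a, b, c) or (b, a, c)
      ia <- which(tri == a); ib <- which(tri == b)
      cc <- tri[-c(ia, ib)]
      # preserve orientation: replace edge a-b with a-m and m-b
      t1 <- tri; t1[t1 == b] <- m
      t2 <- tri; t2[t2 == a] <- m
      Fm[f, ] <- t1
      newF[[length(newF) + 1]] <- t2
      touched[f] <- TRUE
    }
  }
  if (length(newV) > 0) {
    V <- rbind(V, do.call(rbind, newV))
    Fm <- rbind(Fm, do.call(rbind, lapply(newF, as.integer)))
  }
  mesh$vertices <- V
  mesh$faces <- Fm
  mesh
}

# collapse edges shorter than 4/5 target into their midpoint
remesh_collapse <- function(mesh, target) {
  ed <- edge_df(mesh)
  prot <- protected_vertices(mesh)
  # adjacency list of vertex neighbors
  n <- nrow(mesh$vertices)
  short <- which(ed$len < 4 / 5 * target & !prot[ed$v1] & !prot[ed$v2] &
                 !is.na(ed$f2))
  if (length(short) == 0) return(mesh)
  short <- short[order(ed$len[short])]
  V <- mesh$vertices
  Fm <- mesh$faces
  alive_v <- rep(TRUE, n)
  locked <- rep(FALSE, n)
  remap <- seq_len(n)
  drop_face <- rep(FALSE, nrow(Fm))
  nb <- vector("list", n)
  for (e in seq_along(ed$v1)) {
    nb[[ed$v1[e]]] <- c(nb[[ed$v1[e]]], ed$v2[e])
    nb[[ed$v2[e]]] <- c(nb[[ed$v2[e]]], ed$v1[e])
  }
  for (e in short) {
    a <- ed$v1[e]; b <- ed$v2[e]
    if (!alive_v[a] || !alive_v[b] || locked[a] || locked[b]) next
    # link condition: common neighbors must be exactly the two opposite
    # vertices of the two incident faces
    common <- intersect(nb[[a]], nb[[b]])
    common <- common[alive_v[common]]
    if (length(common) != 2) next
    mid <- (V[a, ] + V[b, ]) / 2
    V[a, ] <- mid
    alive_v[b] <- FALSE
    remap[b] <- a
    # freeze the whole neighborhood: further collapses there could break
    # the link condition computed from the stale adjacency
    locked[c(a, nb[[a]], nb[[b]])] <- TRUE
    nb[[a]] <- unique(c(nb[[a]], nb[[b]]))
  }
  Fm2 <- matrix(remap[Fm], ncol = 3)
  degen <- Fm2[, 1] == Fm2[, 2] | Fm2[, 2] == Fm2[, 3] | Fm2[, 1] == Fm2[, 3]
  Fm2 <- Fm2[!degen, , drop = FALSE]
  # renumber
  keep <- which(alive_v | prot)
  newid <- integer(n); newid[keep] <- seq_along(keep)
  mesh$vertices <- V[keep, , drop = FALSE]
  mesh$faces <- matrix(newid[Fm2], ncol = 3)
  for (k in seq_along(mesh$rings)) {
    mesh$rings[[k]]$verts <- newid[mesh$rings[[k]]$verts]
    mesh$rings[[k]]$collar <- newid[mesh$rings[[k]]$collar]
  }
  mesh
}

# Delaunay-style equiangulation flips on unprotected interior edges
remesh_flip <- function(mesh, max_rounds = 6) {
  prot <- protected_vertices(mesh)
  for (round in seq_len(max_rounds)) {
    V <- mesh$vertices
    Fm <- mesh$faces
    ed <- edge_df(mesh)
    cand <- which(!is.na(ed$f2) & !prot[ed$v1] & !prot[ed$v2])
    nflip <- 0L
    touched <- rep(FALSE, nrow(Fm))
    made <- new.env(hash = TRUE, parent = emptyenv())
    for (e in cand) {
      f1 <- ed$f1[e]; f2 <- ed$f2[e]
      if (touched[f1] || touched[f2]) next
      a <- ed$v1[e]; b <- ed$v2[e]
      c1 <- setdiff(Fm[f1, ], c(a, b)); c2 <- setdiff(Fm[f2, ], c(a, b))
      if (length(c1) != 1 || length(c2) != 1 || c1 == c2) next
      # opposite angles at c1, c2
      ang <- function(p, q, r) {       # angle at p in triangle pqr
        u <- V[q, ] - V[p, ]; w <- V[r, ] - V[p, ]
        acos(pmin(1, pmax(-1, sum(u * w) / sqrt(sum(u^2) * sum(w^2)))))
      }
      if (ang(c1, a, b) + ang(c2, a, b) <= pi + 1e-8) next
      # don't create a duplicate edge (existing or made by an earlier flip)
      key <- paste(min(c1, c2), max(c1, c2))
      if (any(ed$v1 == min(c1, c2) & ed$v2 == max(c1, c2)) ||
          !is.null(made[[key]])) next
      made[[key]] <- TRUE
      # flip: faces (a,b,c1),(b,a,c2) -> (a,c2,c1),(b,c1,c2), keeping
      # orientation from the face that traverses a->b
      tri1 <- Fm[f1, ]; tri2 <- Fm[f2, ]
      ab_in_1 <- any(tri1 == a & c(tri1[-1], tri1[1]) == b)
      if (!ab_in_1) {
        tmp <- f1; f1 <- f2; f2 <- tmp
        tmp <- c1; c1 <- c2; c2 <- tmp
      }
      Fm[f1, ] <- c(a, c2[1], c1[1])
      Fm[f2, ] <- c(b, c1[1], c2[1])
      touched[c(f1, f2)] <- TRUE
      nflip <- nflip + 1L
    }
    mesh$faces <- Fm
    if (nflip == 0L) break
  }
  mesh
}

# tangential Laplacian smoothing of unprotected vertices
remesh_smooth <- function(mesh, passes = 2, step = 0.5) {
  prot <- protected_vertices(mesh)
  idx <- which(!prot)
  for (pass in seq_len(passes)) {
    V <- mesh$vertices
    ed <- edge_df(mesh)
    nbsum <- matrix(0, nrow(V), 3); nbn <- numeric(nrow(V))
    for (cc in 1:2) {
      i <- if (cc == 1) ed$v1 else ed$v2
      j <- if (cc == 1) ed$v2 else ed$v1
      for (k in 1:3) {
        s <- rowsum(V[j, k], i, reorder = FALSE)
        nbsum[as.integer(rownames(s)), k] <- nbsum[as.integer(rownames(s)), k] + s
      }
      s <- rowsum(rep(1, length(i)), i, reorder = FALSE)
      nbn[as.integer(rownames(s))] <- nbn[as.integer(rownames(s))] + s
    }
    C <- nbsum / pmax(nbn, 1)
    tr <- mesh_terms(mesh, grad = TRUE)
    N <- tr$g_vol
    nn <- sqrt(rowSums(N^2)); N <- N / pmax(nn, 1e-300)
    d <- C - V
    d <- d - rowSums(d * N) * N
    V[idx, ] <- V[idx, ] + step * d[idx, , drop = FALSE]
    mesh$vertices <- V
  }
  mesh
}

#' Isotropic remesh
#'
#' One or more passes of edge splitting, edge collapsing, equiangulation
#' flips and tangential smoothing toward a target edge length.  Boundary
#' and collar ring vertices are preserved exactly (the declared refinement
#' policy: ring vertex counts never change).  The operation is deterministic.
#'
#' @param mesh a [surface_mesh()].
#' @param target_edge desired edge length.
#' @param passes number of full remeshing passes.
#' @return the remeshed [surface_mesh()].
#' @export
remesh <- function(mesh, target_edge, passes = 3) {
  for (p in seq_len(passes)) {
    mesh <- remesh_split(mesh, target_edge)
    mesh <- remesh_collapse(mesh, target_edge)
    mesh <- remesh_flip(mesh)
    mesh <- remesh_smooth(mesh)
  }
  # flips and smoothing can stretch individual edges past the band; a
  # final split pass restores the upper bound
  mesh <- remesh_split(mesh, target_edge)
  mesh <- remesh_smooth(mesh, passes = 1)
  q <- mesh_quality(mesh)
  if (q$min_angle < 15 * pi / 180)
    warning(sprintf("remesh: minimum triangle angle %.1f deg below 15 deg",
                    q$min_angle * 180 / pi))
  validate_mesh(mesh)
  mesh
}

#' Mesh quality summary
#'
#' @param mesh a [surface_mesh()].
#' @return list with `min_angle` (radians), `edge_range`, `mean_edge`.
#' @export
mesh_quality <- function(mesh) {
  V <- mesh$vertices; Fm <- mesh$faces
  angs <- sapply(1:3, function(co) {
    p <- V[Fm[, co], , drop = FALSE]
    q <- V[Fm[, co %% 3 + 1], , drop = FALSE]
    r <- V[Fm[, (co + 1) %% 3 + 1], , drop = FALSE]
    u <- q - p; w <- r - p
    acos(pmin(1, pmax(-1, rowSums(u * w) / sqrt(rowSums(u^2) * rowSums(w^2)))))
  })
  ed <- edge_df(mesh)
  list(min_angle = min(angs), edge_range = range(ed$len),
       mean_edge = mean(ed$len))
}


# surgical sliver removal: collapse the shortest edge of any face whose
# minimum angle is below the threshold (protected vertices untouched)
collapse_slivers <- function(mesh, min_angle_deg = 10) {
  V <- mesh$vertices; Fm <- mesh$faces
  angs <- sapply(1:3, function(co) {
    p <- V[Fm[, co], , drop = FALSE]
    q <- V[Fm[, co %% 3 + 1], , drop = FALSE]
    r <- V[Fm[, (co + 1) %% 3 + 1], , drop = FALSE]
    u <- q - p; w <- r - p
    acos(pmin(1, pmax(-1, rowSums(u * w) / sqrt(rowSums(u^2) * rowSums(w^2)))))
  })
  bad <- which(apply(angs, 1, min) < min_angle_deg * pi / 180)
  if (length(bad) == 0) return(mesh)
  prot <- protected_vertices(mesh)
  n <- nrow(V)
  ed <- edge_df(mesh)
  nb <- vector("list", n)
  for (e in seq_along(ed$v1)) {
    nb[[ed$v1[e]]] <- c(nb[[ed$v1[e]]], ed$v2[e])
    nb[[ed$v2[e]]] <- c(nb[[ed$v2[e]]], ed$v1[e])
  }
  alive_v <- rep(TRUE, n); locked <- rep(FALSE, n); remap <- seq_len(n)
  ncol_done <- 0L
  for (f in bad) {
    tri <- Fm[f, ]
    epairs <- rbind(tri[1:2], tri[2:3], tri[c(3, 1)])
    len <- sqrt(rowSums((V[epairs[, 1], , drop = FALSE] -
                         V[epairs[, 2], , drop = FALSE])^2))
    for (ei in order(len)) {
      a <- epairs[ei, 1]; b <- epairs[ei, 2]
      if (prot[a] || prot[b] || !alive_v[a] || !alive_v[b] ||
          locked[a] || locked[b]) next
      common <- intersect(nb[[a]], nb[[b]])
      common <- common[alive_v[common]]
      if (length(common) != 2) next
      V[a, ] <- (V[a, ] + V[b, ]) / 2
      alive_v[b] <- FALSE
      remap[b] <- a
      locked[c(a, nb[[a]], nb[[b]])] <- TRUE
      nb[[a]] <- unique(c(nb[[a]], nb[[b]]))
      ncol_done <- ncol_done + 1L
      break
    }
  }
  if (ncol_done == 0L) return(mesh)
  Fm2 <- matrix(remap[Fm], ncol = 3)
  degen <- Fm2[, 1] == Fm2[, 2] | Fm2[, 2] == Fm2[, 3] | Fm2[, 1] == Fm2[, 3]
  Fm2 <- Fm2[!degen, , drop = FALSE]
  keep <- which(alive_v)
  newid <- integer(n); newid[keep] <- seq_along(keep)
  mesh$vertices <- V[keep, , drop = FALSE]
  mesh$faces <- matrix(newid[Fm2], ncol = 3)
  for (k in seq_along(mesh$rings)) {
    mesh$rings[[k]]$verts <- newid[mesh$rings[[k]]$verts]
    mesh$rings[[k]]$collar <- newid[mesh$rings[[k]]$collar]
  }
  remesh_flip(mesh, max_rounds = 2)
}
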