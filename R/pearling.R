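# The two bulging experiments as continuation sweeps, pearling-onset
# detection from the stress-parameter maximum, cross-section contour
# classification and the junction-versus-arm bulge comparison.

sweep_row <- function(st, control) {
  ex <- tryCatch(excess_quantities(st), error = function(e)
    list(Vexc = NA_real_, Aexc = NA_real_))
  data.frame(control = control, gamma = st$gamma, P = st$P, f_arm = st$f,
             p = st$p, R = st$R, L_arm = mean(st$L), F_B = st$F_B,
             Vexc = ex$Vexc, Aexc = ex$Aexc,
             contour = NA_character_, converged = st$converged,
             stringsAsFactors = FALSE)
}

run_sweep <- function(initial, controls, make_spec, schedule, classify) {
  rows <- list(); states <- list()
  mesh <- initial$state$mesh
  # seed the multipliers from the known initial-state tension and pressure
  warm <- list(muA = initial$gamma0 * initial$A0, muV = 0)
  nstep <- 0L
  for (ctl in controls) {
    spec <- make_spec(ctl)
    st <- tryCatch(minimize_state(mesh, initial$params, spec, schedule,
                                  warm = warm),
                   error = function(e) e)
    if (inherits(st, "error")) {
      warning(sprintf("sweep step %.4g failed: %s", ctl,
                      conditionMessage(st)))
      break
    }
    nstep <- nstep + 1L
    if (schedule$remesh_every > 0 && nstep %% schedule$remesh_every == 0) {
      st <- tryCatch(groom_state(st, initial$params, spec, schedule,
                                 initial$edge_target, full = FALSE),
                     error = function(e) st)
    }
    # a continuation step that did not move the shape at all is stuck
    # against a discrete barrier: its multiplier retrieval is stale and it
    # is excluded from the onset analysis
    if (nstep > 1 &&
        nrow(st$mesh$vertices) == nrow(mesh$vertices) &&
        max(abs(st$mesh$vertices - mesh$vertices)) < 1e-9) {
      st$converged <- FALSE
    }
    mesh <- st$mesh; warm <- st$warm
    row <- sweep_row(st, ctl)
    if (classify && initial$geometry == "junction")
      row$contour <- tryCatch(junction_contour_class(st$mesh),
                              error = function(e) NA_character_)
    rows[[length(rows) + 1]] <- row
    states[[length(states) + 1]] <- st
  }
  if (length(rows) == 0) stop("sweep produced no states")
  tab <- do.call(rbind, rows)
  structure(list(table = tab, states = states,
                 onset = detect_pearling_onset(tab),
                 initial = initial, seed = schedule$seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %d states, controls [%g, %g]\n",
              nrow(x$table), min(x$table$control), max(x$table$control)))
  if (!is.null(x$onset) && !is.na(x$onset$control)) {
    cat(sprintf("  onset: control=%.4g p*=%.4g gamma*/gamma0=%.4g\n",
                x$onset$control, x$onset$p_star, x$onset$gamma_star /
                  x$initial$gamma0))
  } else cat("  onset: none detected\n")
  invisible(x)
}

#' Osmotic-swelling sweep
#'
#' Continuation in luminal volume at fixed membrane area and arm lengths
#' (the live-cell swelling protocol): for each relative volume increment
#' the state is re-minimized in the (A, V, L) ensemble, warm-started from
#' its predecessor, and the retrieved tension, pressure and stress
#' parameter are recorded.
#'
#' @param initial an `initial_state`.
#' @param dv_over_v0_grid increasing grid of relative volume increments,
#'   starting at 0.
#' @param schedule a [solver_schedule()].
#' @param classify_contours classify the junction cross-section contour at
#'   each step.
#' @return a `sweep_result` with the state table and detected onset.
#' @export
volume_sweep <- function(initial, dv_over_v0_grid,
                         schedule = solver_schedule(remesh_every = 5),
                         classify_contours = TRUE) {
  stopifnot(dv_over_v0_grid[1] == 0, !is.unsorted(dv_over_v0_grid))
  A0 <- initial$A0; V0 <- initial$V0; L0 <- initial$L0
  run_sweep(initial, dv_over_v0_grid,
            function(dv) ensemble_spec(L = L0, A = A0, V = V0 * (1 + dv)),
            schedule, classify_contours)
}

#' Force-jump sweep
#'
#' Continuation in the pulling force at fixed membrane area and volume
#' (the biomimetic tension-jump protocol): the arm lengths and the boundary
#' radius are free; the functional includes the work term `-f` times the
#' total arm length.
#'
#' @param initial an `initial_state`.
#' @param f_over_f0_grid increasing grid of relative forces, starting at 1.
#' @param schedule a [solver_schedule()].
#' @param classify_contours classify junction contours along the sweep.
#' @return a `sweep_result`.
#' @export
force_sweep <- function(initial, f_over_f0_grid,
                        schedule = solver_schedule(rho0 = 100,
                                                   remesh_every = 3),
                        classify_contours = TRUE) {
  stopifnot(abs(f_over_f0_grid[1] - 1) < 1e-12,
            !is.unsorted(f_over_f0_grid))
  A0 <- initial$A0; V0 <- initial$V0; f0 <- initial$f0
  run_sweep(initial, f_over_f0_grid,
            function(fr) ensemble_spec(f = fr * f0, A = A0, V = V0),
            schedule, classify_contours)
}

#' Detect the pearling onset from a sweep
#'
#' The critical point is the interior maximum of the stress parameter
#' along the sweep, refined by a three-point quadratic fit; the critical
#' tension is interpolated at the refined control value.  A monotone p
#' series yields no onset.
#'
#' @param sweep a `sweep_result` or its `table` data frame (needs at least
#'   5 converged records).
#' @return list with `control` (NA when none detected), `p_star`,
#'   `gamma_star`, `index`.
#' @export
detect_pearling_onset <- function(sweep) {
  tab <- if (inherits(sweep, "sweep_result")) sweep$table else sweep
  tab <- tab[tab$converged & is.finite(tab$p), ]
  none <- list(control = NA_real_, p_star = NA_real_,
               gamma_star = NA_real_, index = NA_integer_)
  if (nrow(tab) < 5) return(none)
  if (nrow(tab) >= 10) {
    # robust smooth of the (noisy) multiplier retrievals, then read the
    # interior maximum off the fitted curve
    fit <- stats::loess(p ~ control, data = tab, span = 0.75,
                        family = "symmetric", degree = 2)
    grid <- seq(min(tab$control), max(tab$control), length.out = 400)
    ps <- stats::predict(fit, data.frame(control = grid))
    i <- which.max(ps)
    if (i <= 2 || i >= length(grid) - 1) return(none)
    xstar <- grid[i]
    p_star <- ps[i]
    gfit <- stats::loess(gamma ~ control, data = tab, span = 0.75,
                         family = "symmetric", degree = 2)
    gamma_star <- unname(stats::predict(gfit, data.frame(control = xstar)))
    return(list(control = xstar, p_star = p_star, gamma_star = gamma_star,
                index = which.min(abs(tab$control - xstar))))
  }
  i <- which.max(tab$p)
  if (i == 1 || i == nrow(tab)) return(none)
  # quadratic refinement over a window around the maximum
  win <- max(1, i - 2):min(nrow(tab), i + 2)
  x <- tab$control[win]; y <- tab$p[win]
  fit <- stats::lm(y ~ x + I(x^2))
  co <- stats::coef(fit)
  xstar <- if (is.finite(co[3]) && co[3] < 0) -co[2] / (2 * co[3]) else
    tab$control[i]
  xstar <- min(max(xstar, min(x)), max(x))
  p_star <- unname(stats::predict(fit, data.frame(x = xstar)))
  gamma_star <- stats::approx(tab$control, tab$gamma, xout = xstar)$y
  list(control = xstar, p_star = p_star, gamma_star = gamma_star, index = i)
}

#' Classify the junction cross-section contour
#'
#' Intersects the surface with the system plane (z = 0), extracts the
#' closed outer silhouette and measures the signed turning of the three
#' contour sides between adjacent arms (counter-clockwise loop): turning
#' toward the junction center means concave sides (the tether-like initial
#' shape); outward turning means convex sides (the bulged, sphere-like
#' junction).
#'
#' @param mesh a junction [surface_mesh()] straddling z = 0.
#' @param transitional_deg absolute mean side-turning (degrees) below which
#'   the contour is called transitional.
#' @return `"concave"`, `"transitional"` or `"convex"`.
#' @export
junction_contour_class <- function(mesh, transitional_deg = 4) {
  seg <- cross_section_segments(mesh, z = 0)
  pts <- unique(round(rbind(seg[, 1:2, drop = FALSE],
                            seg[, 3:4, drop = FALSE]), 9))
  ang <- atan2(pts[, 2], pts[, 1]) %% (2 * pi)
  arms <- c(0, 2, 4) * pi / 3
  turn <- numeric(3)
  for (k in 1:3) {
    lo <- arms[k] + 25 * pi / 180
    hi <- arms[k] + 2 * pi / 3 - 25 * pi / 180
    a_shift <- (ang - arms[k]) %% (2 * pi)
    inside <- a_shift >= 25 * pi / 180 & a_shift <= (120 - 25) * pi / 180
    idx <- which(inside)
    if (length(idx) < 4) { turn[k] <- NA_real_; next }
    # the section of the junction between two arms is a single contour arc;
    # order its points by planar angle (counter-clockwise)
    P <- pts[idx[order(a_shift[idx])], , drop = FALSE]
    d <- diff(P)
    keep <- rowSums(d^2) > 1e-16
    d <- d[keep, , drop = FALSE]
    if (nrow(d) < 3) { turn[k] <- NA_real_; next }
    cr <- d[-nrow(d), 1] * d[-1, 2] - d[-nrow(d), 2] * d[-1, 1]
    dt <- asin(pmin(1, pmax(-1, cr / (sqrt(rowSums(d[-nrow(d), , drop = FALSE]^2)) *
                                      sqrt(rowSums(d[-1, , drop = FALSE]^2))))))
    turn[k] <- sum(dt)
  }
  mt <- mean(turn, na.rm = TRUE) * 180 / pi
  if (!is.finite(mt)) stop("contour classification failed: empty sides")
  if (abs(mt) < transitional_deg) "transitional"
  else if (mt > 0) "convex" else "concave"
}

# segments of the z = zc cross-section, one per straddling face
cross_section_segments <- function(mesh, z = 0) {
  V <- mesh$vertices; Fm <- mesh$faces
  zs <- V[, 3] - z
  s1 <- zs[Fm[, 1]]; s2 <- zs[Fm[, 2]]; s3 <- zs[Fm[, 3]]
  straddle <- (pmin(s1, s2, s3) < 0) & (pmax(s1, s2, s3) > 0)
  if (!any(straddle)) stop("mesh does not straddle the section plane")
  segs <- list()
  for (f in which(straddle)) {
    tri <- Fm[f, ]; sz <- zs[tri]
    pts <- list()
    for (e in 1:3) {
      i <- tri[e]; j <- tri[e %% 3 + 1]
      if (zs[i] * zs[j] < 0) {
        t <- zs[i] / (zs[i] - zs[j])
        pts[[length(pts) + 1]] <- V[i, 1:2] + t * (V[j, 1:2] - V[i, 1:2])
      } else if (zs[i] == 0) pts[[length(pts) + 1]] <- V[i, 1:2]
    }
    if (length(pts) >= 2)
      segs[[length(segs) + 1]] <- c(pts[[1]], pts[[2]])
  }
  do.call(rbind, segs)
}

#' Compare junction-seeded and arm-seeded bulges
#'
#' At matched clamped (A, V, L) beyond the onset, minimizes two states:
#' one continued from the junction-bulged branch and one seeded with a
#' Gaussian radial bulge at an arm midpoint, and reports which carries the
#' lower bending energy.  The arm-seeded state frequently relaxes into the
#' junction branch; this is reported as `"merged"`.
#'
#' @param initial an `initial_state` (junction geometry).
#' @param total_excess_volume relative excess volume dV/V0 at which to
#'   compare.
#' @param schedule a [solver_schedule()].
#' @param steps continuation steps from 0 to the target excess volume.
#' @return list with `F_B_junction`, `F_B_arm`, `favored`
#'   (`"junction"`, `"arm"` or `"merged"`), and the two states.
#' @export
compare_bulge_placement <- function(initial, total_excess_volume,
                                    schedule = solver_schedule(),
                                    steps = 8) {
  stopifnot(initial$geometry == "junction")
  A0 <- initial$A0; V0 <- initial$V0; L0 <- initial$L0
  grid <- seq(0, total_excess_volume, length.out = steps + 1)
  # junction branch: plain continuation
  swJ <- volume_sweep(initial, grid, schedule, classify_contours = FALSE)
  stJ <- swJ$states[[length(swJ$states)]]
  # arm branch: seed a mid-arm bulge, then the same continuation
  seeded <- initial
  seeded$state$mesh <- seed_arm_bulge(initial$state$mesh,
                                      sigma = 2 * initial$params$lambda0,
                                      amplitude = 0.6 * initial$R0)
  swA <- volume_sweep(seeded, grid, schedule, classify_contours = FALSE)
  stA <- swA$states[[length(swA$states)]]
  # where does the arm state's excess radius live?
  merged <- arm_bulge_position(stA$mesh) < 2 * initial$params$lambda0
  favored <- if (merged) "merged"
  else if (stJ$F_B <= stA$F_B) "junction" else "arm"
  list(F_B_junction = stJ$F_B, F_B_arm = stA$F_B, favored = favored,
       state_junction = stJ, state_arm = stA)
}

# radial Gaussian inflation centered at the midpoint of arm 1
seed_arm_bulge <- function(mesh, sigma, amplitude) {
  rg <- mesh$rings[[1]]
  center <- rg$anchor + 0.5 * rg$d * rg$axis
  V <- mesh$vertices
  prot <- protected_vertices(mesh)
  t_axis <- as.numeric(sweep(V, 2, rg$anchor) %*% rg$axis)
  radial <- V - (t_axis %o% rg$axis) -
    matrix(rg$anchor, nrow(V), 3, byrow = TRUE)
  rr <- sqrt(rowSums(radial^2))
  along <- as.numeric(sweep(V, 2, center) %*% rg$axis)
  w <- exp(-along^2 / (2 * sigma^2)) * (t_axis > 0.2 * rg$d)
  fac <- 1 + amplitude * w / pmax(rr, 1e-9)
  idx <- which(!prot)
  V[idx, ] <- V[idx, ] - radial[idx, ] + radial[idx, ] * fac[idx]
  mesh$vertices <- V
  mesh
}

# distance from the junction center of the fattest cross-section
arm_bulge_position <- function(mesh) {
  V <- mesh$vertices
  rr <- sqrt(V[, 1]^2 + V[, 2]^2 + V[, 3]^2)
  d_skel <- sqrt(V[, 3]^2 + 0 * rr)   # placeholder refined below
  # distance from skeleton: min over the three rays
  alph <- c(0, 2, 4) * pi / 3
  dmin <- rep(Inf, nrow(V))
  tbest <- rep(0, nrow(V))
  for (a in alph) {
    e <- c(cos(a), sin(a), 0)
    t <- pmax(0, as.numeric(V %*% e))
    dd <- sqrt(rowSums((V - t %o% e)^2))
    upd <- dd < dmin
    dmin[upd] <- dd[upd]; tbest[upd] <- t[upd]
  }
  tbest[which.max(dmin)]
}
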