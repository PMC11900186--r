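# Serialization: ASCII OFF/PLY meshes with a YAML sidecar holding the
# boundary-ring structure, state tables as CSV with reproducibility
# headers, YAML run configuration.

#' Write a mesh to OFF or PLY (ASCII)
#'
#' The triangulation goes into the OFF/PLY file; the boundary-ring
#' structure (vertex loops, axes, anchors, frames) goes into a YAML sidecar
#' `<path>.rings.yaml` so the mesh round-trips losslessly.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file; format from the extension (`.off` or `.ply`).
#' @param digits coordinate precision.
#' @return invisibly `path`.
#' @export
write_mesh <- function(mesh, path, digits = 12) {
  fmt <- tolower(tools::file_ext(path))
  V <- mesh$vertices; Fm <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  vtxt <- apply(signif(V, digits), 1, paste, collapse = " ")
  ftxt <- paste(3, Fm[, 1] - 1L, Fm[, 2] - 1L, Fm[, 3] - 1L)
  if (fmt == "off") {
    writeLines(c("OFF", paste(nrow(V), nrow(Fm), 0), vtxt, ftxt), con)
  } else if (fmt == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(V)),
                 "property double x", "property double y", "property double z",
                 paste("element face", nrow(Fm)),
                 "property list uchar int vertex_indices",
                 "end_header", vtxt, ftxt), con)
  } else stop("unsupported mesh format: ", fmt)
  rings <- lapply(mesh$rings, function(rg)
    list(verts = rg$verts, axis = rg$axis, anchor = rg$anchor,
         frame_u = rg$frame_u, frame_v = rg$frame_v, theta = rg$theta,
         d = rg$d, collar = rg$collar))
  yaml::write_yaml(list(rings = rings), paste0(path, ".rings.yaml"))
  invisible(path)
}

#' Read a mesh written by [write_mesh()]
#'
#' @param path an `.off` or `.ply` file; the `.rings.yaml` sidecar is read
#'   when present.
#' @return a [surface_mesh()].
#' @export
read_mesh <- function(path) {
  fmt <- tolower(tools::file_ext(path))
  ln <- readLines(path)
  if (fmt == "off") {
    stopifnot(trimws(ln[1]) == "OFF")
    hdr <- scan(text = ln[2], quiet = TRUE)
    nv <- hdr[1]; nf <- hdr[2]
    V <- matrix(scan(text = ln[3:(2 + nv)], quiet = TRUE), ncol = 3,
                byrow = TRUE)
    Fm <- matrix(scan(text = ln[(3 + nv):(2 + nv + nf)], quiet = TRUE),
                 ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  } else if (fmt == "ply") {
    endh <- which(trimws(ln) == "end_header")[1]
    nv <- as.integer(sub("element vertex ", "",
                         grep("^element vertex", ln, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "",
                         grep("^element face", ln, value = TRUE)[1]))
    V <- matrix(scan(text = ln[endh + (1:nv)], quiet = TRUE), ncol = 3,
                byrow = TRUE)
    Fm <- matrix(scan(text = ln[endh + nv + (1:nf)], quiet = TRUE),
                 ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  } else stop("unsupported mesh format: ", fmt)
  side <- paste0(path, ".rings.yaml")
  rings <- list()
  if (file.exists(side)) {
    ry <- yaml::read_yaml(side)
    rings <- lapply(ry$rings, function(rg)
      ring_descriptor(rg$verts, rg$axis, rg$anchor, rg$frame_u, rg$frame_v,
                      rg$theta, rg$d, rg$collar))
  }
  surface_mesh(V, Fm, rings)
}

#' Export per-vertex total curvature as CSV
#' @param mesh a [surface_mesh()].
#' @param path output CSV.
#' @return invisibly `path`.
#' @export
write_curvature_csv <- function(mesh, path) {
  mc <- mean_curvature(mesh)
  df <- data.frame(vertex = seq_len(nrow(mesh$vertices)),
                   x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                   z = mesh$vertices[, 3], J = mc$J, A = mc$A)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- run configuration ------------------------------------------------------

#' Read and validate a run configuration
#'
#' YAML configuration with sections `geometry` (kind, L0, edge_target),
#' `material` (kappa, gamma0), `ensemble` (length_mode/area_mode/volume_mode
#' with values), `sweep` (mode, from, to, steps) and `solver` (optional
#' overrides of [solver_schedule()] fields, including `seed`).
#'
#' @param path YAML file.
#' @return a validated `run_config` list, with `hash` (md5 of the
#'   canonicalized config) attached.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  need <- function(x, key, where) {
    if (is.null(x)) stop(sprintf("config key missing: %s.%s", where, key))
    x
  }
  geom <- need(cfg$geometry, "geometry", "")
  kind <- need(geom$kind, "kind", "geometry")
  if (!kind %in% c("cylinder", "junction"))
    stop("config geometry.kind must be 'cylinder' or 'junction'")
  mat <- cfg$material %||% list()
  kappa <- mat$kappa %||% 1
  gamma0 <- mat$gamma0 %||% 1
  ens <- cfg$ensemble %||% list()
  modes <- list(length_mode = ens$length_mode %||% "fixed_length",
                area_mode = ens$area_mode %||% "fixed_area",
                volume_mode = ens$volume_mode %||% "fixed_volume")
  ok <- list(length_mode = c("fixed_length", "fixed_force"),
             area_mode = c("fixed_area", "fixed_tension"),
             volume_mode = c("fixed_volume", "fixed_pressure"))
  for (k in names(modes)) {
    if (!modes[[k]] %in% ok[[k]])
      stop(sprintf("config key ensemble.%s: '%s' not one of %s", k,
                   modes[[k]], paste(ok[[k]], collapse = "/")))
  }
  if (modes$area_mode == "fixed_tension" && modes$volume_mode == "fixed_pressure")
    stop("config ensemble: clamping both tension and pressure is refused ",
         "(divergent ensemble)")
  sweep <- cfg$sweep %||% list(mode = "volume", from = 0, to = 0.2, steps = 10)
  if (!(sweep$mode %||% "volume") %in% c("volume", "force"))
    stop("config key sweep.mode must be 'volume' or 'force'")
  solver <- cfg$solver %||% list()
  out <- list(geometry = list(kind = kind,
                              L0 = need(geom$L0, "L0", "geometry"),
                              edge_target = geom$edge_target %||% (sqrt(kappa / gamma0) / 3)),
              material = list(kappa = kappa, gamma0 = gamma0),
              ensemble = modes, sweep = sweep, solver = solver,
              seed = solver$seed %||% 1L)
  out$hash <- config_hash(out)
  class(out) <- "run_config"
  out
}

config_hash <- function(cfg) {
  cfg$hash <- NULL
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

# reproducibility header lines for CSV outputs
output_header <- function(cfg_hash, seed, resolution) {
  c(sprintf("# junctionmech %s", as.character(utils::packageVersion("junctionmech"))),
    sprintf("# config_hash: %s", cfg_hash %||% "none"),
    sprintf("# seed: %d", as.integer(seed)),
    sprintf("# edge_target: %g", resolution))
}

#' Write a sweep state table as CSV with a reproducibility header
#'
#' @param sweep a `sweep_result`.
#' @param path output CSV path.
#' @param cfg_hash configuration hash to embed (optional).
#' @return invisibly `path`.
#' @export
write_state_csv <- function(sweep, path, cfg_hash = NULL) {
  hdr <- output_header(cfg_hash, sweep$seed, sweep$initial$edge_target)
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  utils::write.csv(sweep$table, con, row.names = FALSE)
  invisible(path)
}

#' Read a state table written by [write_state_csv()]
#' @param path CSV path.
#' @return data frame with attributes `header` (the comment lines).
#' @export
read_state_csv <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#")]
  if (length(hdr) == 0)
    warning("state table has no reproducibility header (legacy file)")
  df <- utils::read.csv(text = ln[!startsWith(ln, "#")])
  attr(df, "header") <- hdr
  df
}
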