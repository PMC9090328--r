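#' Triangulated cortical surface mesh
#'
#' Stores node coordinates (mm) and triangular faces, and derives the
#' quantities the topographic metrics need: per-node area (one third of the
#' area of each incident triangle, i.e. barycentric lumping) and node
#' adjacency. Two adjacencies are kept: \code{adjacency} (nodes sharing a
#' face edge, the default for region growing) and \code{face_adjacency}
#' (nodes sharing any face).
#'
#' @param nodes numeric matrix n x 3 (mm)
#' @param faces integer matrix m x 3 of 1-based node indices
#' @return object of class \code{cortical_mesh} with elements \code{nodes},
#'   \code{faces}, \code{node_area} (mm^2), \code{adjacency},
#'   \code{face_adjacency}
#' @export
cortical_mesh <- function(nodes, faces) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  if (ncol(nodes) != 3 || ncol(faces) != 3) stop("nodes and faces must have 3 columns")
  n <- nrow(nodes)
  if (any(faces < 1) || any(faces > n)) stop("faces reference invalid node indices")
  a <- nodes[faces[, 1], , drop = FALSE]
  b <- nodes[faces[, 2], , drop = FALSE]
  cc <- nodes[faces[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  tri_area <- 0.5 * sqrt(rowSums(cr^2))
  node_area <- numeric(n)
  for (k in 1:3) {
    s <- tapply(tri_area, faces[, k], sum)
    node_area[as.integer(names(s))] <- node_area[as.integer(names(s))] + s
  }
  node_area <- node_area / 3
  if (any(node_area <= 0)) stop("every node must belong to at least one face (positive area)")
  edges <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(1, 3)])
  edges <- unique(rbind(edges, edges[, c(2, 1)]))
  adjacency <- split(edges[, 2], factor(edges[, 1], levels = seq_len(n)))
  adjacency <- lapply(adjacency, function(x) sort(unique(x)))
  # face adjacency: on a pure triangle mesh every pair of nodes in a face
  # also shares an edge, so the two coincide; kept separately for clarity
  # and for meshes where faces may be stored with repeated vertices.
  structure(list(nodes = nodes, faces = faces, node_area = node_area,
                 adjacency = adjacency, face_adjacency = adjacency),
            class = "cortical_mesh")
}

#' @export
print.cortical_mesh <- function(x, ...) {
  cat("cortical mesh:", nrow(x$nodes), "nodes,", nrow(x$faces), "faces, total area",
      round(sum(x$node_area), 1), "mm^2\n")
  invisible(x)
}

#' Curved rectangular patch mesh
#'
#' Generates a regular triangulated patch standing in for peri-rolandic
#' cortex: an nx x ny grid over \code{width_mm} x \code{height_mm}, with the
#' z coordinate following a spherical cap of radius \code{curvature_mm}
#' (0 or \code{Inf} gives a planar patch).
#'
#' @param nx,ny grid resolution (nodes per side)
#' @param width_mm,height_mm patch extent
#' @param curvature_mm radius of curvature; \code{Inf} for planar
#' @return a \code{cortical_mesh} with \code{nx * ny} nodes
#' @export
make_patch_mesh <- function(nx = 45, ny = 45, width_mm = 90, height_mm = 90,
                            curvature_mm = 120) {
  xs <- seq(-width_mm / 2, width_mm / 2, length.out = nx)
  ys <- seq(-height_mm / 2, height_mm / 2, length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  r2 <- g$x^2 + g$y^2
  z <- if (is.finite(curvature_mm) && curvature_mm > 0) {
    sqrt(pmax(curvature_mm^2 - r2, 0)) - curvature_mm
  } else rep(0, nrow(g))
  nodes <- unname(cbind(g$x, g$y, unname(z)))
  idx <- function(ix, iy) (iy - 1L) * nx + ix
  fa <- vector("list", (nx - 1) * (ny - 1))
  k <- 0L
  for (iy in seq_len(ny - 1)) for (ix in seq_len(nx - 1)) {
    k <- k + 1L
    n00 <- idx(ix, iy); n10 <- idx(ix + 1L, iy)
    n01 <- idx(ix, iy + 1L); n11 <- idx(ix + 1L, iy + 1L)
    fa[[k]] <- rbind(c(n00, n10, n11), c(n00, n11, n01))
  }
  cortical_mesh(nodes, do.call(rbind, fa))
}

#' Median edge length of a mesh (mm)
#' @param mesh a \code{cortical_mesh}
#' @export
mesh_edge_length <- function(mesh) {
  e <- rbind(mesh$faces[, c(1, 2)], mesh$faces[, c(2, 3)], mesh$faces[, c(1, 3)])
  e <- unique(t(apply(e, 1, sort)))
  stats::median(sqrt(rowSums((mesh$nodes[e[, 1], ] - mesh$nodes[e[, 2], ])^2)))
}

#' Write / read a mesh in OFF format (plain text)
#' @param mesh a \code{cortical_mesh}
#' @param path file path
#' @return \code{path} invisibly / a \code{cortical_mesh}
#' @export
write_mesh_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(mesh$nodes), nrow(mesh$faces), 0), con)
  utils::write.table(format(mesh$nodes, digits = 15, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh_off
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (trimws(lines[1]) != "OFF") stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  vtx <- matrix(as.numeric(unlist(strsplit(trimws(lines[3:(2 + nv)]), "\\s+"))),
                ncol = 3, byrow = TRUE)
  fc <- matrix(as.integer(unlist(strsplit(trimws(lines[(3 + nv):(2 + nv + nf)]), "\\s+"))),
               ncol = 4, byrow = TRUE)
  if (any(fc[, 1] != 3L)) stop("only triangular faces supported")
  cortical_mesh(vtx, fc[, 2:4] + 1L)
}
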