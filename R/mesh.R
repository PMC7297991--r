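# Triangle-mesh container, synthetic test meshes (icosphere, ellipsoid,
# angular-sector labels) and ASCII OFF/PLY + label-CSV I/O.

#' Labelled triangle-mesh container
#'
#' @param vertices n x 3 numeric matrix, mm.
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @param labels Optional per-vertex label vector (length n); defaults to 1.
#' @return A `surface_mesh` object.
#' @export
surface_mesh <- function(vertices, triangles, labels = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  stopifnot(ncol(vertices) == 3)
  if (any(triangles < 1) || any(triangles > nrow(vertices))) {
    stop("triangle indices out of range.", call. = FALSE)
  }
  if (is.null(labels)) labels <- rep(1L, nrow(vertices))
  if (length(labels) != nrow(vertices)) {
    stop("one label per vertex required.", call. = FALSE)
  }
  structure(list(vertices = vertices, triangles = triangles,
                 labels = labels),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh>", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles,",
      length(unique(x$labels)), "label(s)\n")
  invisible(x)
}

# Edge table: each row one undirected edge with incidence count.
mesh_edges <- function(mesh) {
  tri <- mesh$triangles
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Mesh validity checks
#'
#' @param mesh A [surface_mesh()].
#' @return `is_edge_manifold()`: every edge in at most 2 triangles.
#'   `is_watertight()`: every edge in exactly 2.
#' @export
is_edge_manifold <- function(mesh) all(mesh_edges(mesh) <= 2)

#' @rdname is_edge_manifold
#' @export
is_watertight <- function(mesh) all(mesh_edges(mesh) == 2)

# Unit icosahedron.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(v = v, f = f)
}

# One loop-style midpoint subdivision, projecting new vertices to the sphere.
subdivide_sphere <- function(v, f) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  cache <- new.env(parent = emptyenv())
  verts <- v
  midpoint <- function(a, b) {
    k <- key(a, b)
    if (!is.null(cache[[k]])) return(cache[[k]])
    m <- (verts[a, ] + verts[b, ]) / 2
    m <- m / sqrt(sum(m^2))
    verts <<- rbind(verts, m)
    cache[[k]] <- nrow(verts)
    nrow(verts)
  }
  nf <- matrix(0L, nrow(f) * 4, 3)
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    nf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                     c(c, ca, bc), c(ab, bc, ca))
  }
  list(v = verts, f = nf)
}

#' Generate a synthetic test mesh
#'
#' Shapes: `icosphere(radius, subdivisions)` — watertight geodesic sphere;
#' `ellipsoid(a, b, c)` — icosphere scaled anisotropically; optional
#' `n_sectors` angular-sector labels partition the vertices by azimuth.
#'
#' @param shape `"icosphere"` or `"ellipsoid"`.
#' @param radius Sphere radius, mm.
#' @param subdivisions Number of subdivision rounds (>= 0).
#' @param axes Semi-axes `c(a, b, c)` for the ellipsoid.
#' @param n_sectors If > 1, label vertices into this many azimuthal sectors.
#' @return A [surface_mesh()].
#' @export
#' @examples
#' m <- generate_test_mesh("icosphere", radius = 1, subdivisions = 3)
#' is_watertight(m)
generate_test_mesh <- function(shape = c("icosphere", "ellipsoid"),
                               radius = 1, subdivisions = 3,
                               axes = c(2, 1, 1), n_sectors = 1) {
  shape <- match.arg(shape)
  if (subdivisions < 0) stop("subdivisions must be >= 0.", call. = FALSE)
  ico <- icosahedron()
  for (i in seq_len(subdivisions)) ico <- subdivide_sphere(ico$v, ico$f)
  v <- ico$v
  v <- if (shape == "icosphere") v * radius else sweep(v, 2, axes, "*")
  labels <- if (n_sectors > 1) {
    az <- atan2(v[, 2], v[, 1])
    as.integer(pmin(floor((az + pi) / (2 * pi) * n_sectors) + 1, n_sectors))
  } else {
    rep(1L, nrow(v))
  }
  surface_mesh(v, ico$f, labels)
}

#' Write/read a mesh as ASCII OFF or PLY with a label sidecar CSV
#'
#' Format is chosen from the file extension (`.off` or `.ply`). Vertex
#' labels travel in a sidecar CSV (`vertex_index,label`, 1-based) at
#' `labels_path`.
#'
#' @param mesh A [surface_mesh()].
#' @param path Mesh file path.
#' @param labels_path Optional sidecar CSV path; defaults to
#'   `<path>.labels.csv`.
#' @return `read_mesh()` returns a [surface_mesh()].
#' @export
write_mesh <- function(mesh, path, labels_path = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  vt <- apply(mesh$vertices, 1, paste, collapse = " ")
  ft <- apply(mesh$triangles - 1L, 1, function(r) paste(c(3, r), collapse = " "))
  if (ext == "off") {
    writeLines(c("OFF", paste(nv, nf, 0), vt, ft), path)
  } else if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nv),
             "property float x", "property float y", "property float z",
             paste("element face", nf),
             "property list uchar int vertex_indices", "end_header")
    writeLines(c(hdr, vt, ft), path)
  } else {
    stop("unsupported mesh format: ", ext, call. = FALSE)
  }
  labels_path <- labels_path %||% paste0(path, ".labels.csv")
  write.csv(data.frame(vertex_index = seq_len(nv), label = mesh$labels),
            labels_path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, labels_path = NULL) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "off") {
    stopifnot(trimws(lines[1]) == "OFF")
    counts <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    nv <- counts[1]; nf <- counts[2]
    body <- lines[-(1:2)]
  } else if (ext == "ply") {
    hend <- which(trimws(lines) == "end_header")
    hdr <- lines[1:hend]
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
    body <- lines[-(1:hend)]
  } else {
    stop("unsupported mesh format: ", ext, call. = FALSE)
  }
  v <- do.call(rbind, lapply(body[1:nv],
                             function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  f <- do.call(rbind, lapply(body[nv + 1:nf], function(l) {
    x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    stopifnot(x[1] == 3)
    x[2:4] + 1L
  }))
  labels_path <- labels_path %||% paste0(path, ".labels.csv")
  labels <- if (file.exists(labels_path)) {
    lab <- read.csv(labels_path)
    lab$label[order(lab$vertex_index)]
  } else {
    NULL
  }
  surface_mesh(v, f, labels)
}
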