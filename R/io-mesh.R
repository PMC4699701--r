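#' Construct and validate a nucleus boundary mesh
#'
#' A `nucleus_mesh` is a closed, manifold, consistently oriented triangle mesh
#' delimiting the nucleus in standardized space (micrometres), with a
#' non-empty proper subset of faces labelled as the pial surface. Face
#' orientation is normalized so that normals point outward (faces are flipped
#' as a whole if the signed volume is negative).
#'
#' @param vertices Numeric matrix, n x 3, vertex coordinates in micrometres.
#' @param faces Integer matrix, m x 3, 1-based vertex indices per triangle.
#' @param pial_faces Integer vector of 1-based face indices forming the pial
#'   cap.
#' @return An object of class `nucleus_mesh`: a list with elements
#'   `vertices`, `faces`, `pial_faces`.
#' @export
nucleus_mesh <- function(vertices, faces, pial_faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  pial_faces <- as.integer(pial_faces)
  if (ncol(vertices) != 3L) abort("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) abort("faces must be an m x 3 matrix of vertex indices")
  if (!all(is.finite(vertices))) abort("mesh has non-finite vertex coordinates")
  if (any(faces < 1L) || any(faces > nrow(vertices))) {
    abort("face indices out of vertex range")
  }

  # Manifold + closed + orientable: every directed edge appears exactly once,
  # so every undirected edge is shared by exactly two consistently wound faces.
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  dir_key <- paste(e[, 1], e[, 2])
  if (anyDuplicated(dir_key)) {
    abort("mesh is not consistently oriented or not manifold: repeated directed edge")
  }
  rev_key <- paste(e[, 2], e[, 1])
  open_edges <- setdiff(dir_key, rev_key)
  if (length(open_edges)) {
    abort(paste0("mesh not closed: ", length(open_edges), " boundary edge(s)"))
  }

  if (length(pial_faces) == 0L) abort("pial face set is empty")
  if (any(pial_faces < 1L) || any(pial_faces > nrow(faces))) {
    abort("pial face indices out of range")
  }
  pial_faces <- sort(unique(pial_faces))
  if (length(pial_faces) >= nrow(faces)) {
    abort("pial face set must be a proper subset of the faces")
  }

  m <- structure(list(vertices = vertices, faces = faces, pial_faces = pial_faces),
                 class = "nucleus_mesh")
  if (mesh_volume(m) < 0) {
    m$faces <- faces[, c(1L, 3L, 2L)]
  }
  m
}

#' @export
print.nucleus_mesh <- function(x, ...) {
  cat("<nucleus_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces (", length(x$pial_faces), " pial), volume ",
      format(mesh_volume(x), digits = 6), " um^3\n", sep = "")
  invisible(x)
}

#' Enclosed volume of a nucleus mesh
#'
#' Signed sum of origin-anchored tetrahedra; positive for an outward-oriented
#' closed surface.
#'
#' @param mesh A [nucleus_mesh()].
#' @return Volume in cubic micrometres.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Read a nucleus mesh from OFF or PLY
#'
#' Accepts ASCII OFF or binary little-endian PLY triangle meshes. The pial
#' cap is listed in a sidecar text file with one 0-based face index per line
#' (default `<path>.pial`). The mesh is validated on read (closed, manifold,
#' consistent orientation) and normals are normalized outward.
#'
#' @param path Mesh file path (`.off` or `.ply`).
#' @param pial_path Sidecar path; defaults to `paste0(path, ".pial")`.
#' @return A [nucleus_mesh()].
#' @export
read_mesh <- function(path, pial_path = paste0(path, ".pial")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  head1 <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^OFF", head1)) {
    vf <- read_off(path)
  } else if (grepl("^ply", head1)) {
    vf <- read_ply_binary(path)
  } else {
    abort(paste0("unrecognized mesh format in ", path, " (expected OFF or PLY)"))
  }
  if (!file.exists(pial_path)) {
    abort(paste0("pial sidecar not found: ", pial_path))
  }
  pial0 <- scan(pial_path, what = integer(), quiet = TRUE)
  nucleus_mesh(vf$vertices, vf$faces, pial0 + 1L)
}

#' Write a nucleus mesh to OFF plus pial sidecar
#'
#' @param mesh A [nucleus_mesh()].
#' @param path Output `.off` path.
#' @param pial_path Sidecar path; defaults to `paste0(path, ".pial")`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, pial_path = paste0(path, ".pial")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nrow(mesh$vertices), nrow(mesh$faces), 0L), con)
  writeLines(apply(format(mesh$vertices, digits = 17, trim = TRUE,
                          scientific = FALSE), 1, paste, collapse = " "), con)
  writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
  writeLines(as.character(mesh$pial_faces - 1L), pial_path)
  invisible(path)
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!grepl("^OFF", lines[1])) abort("not an OFF file")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf) abort("truncated OFF file")
  verts <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE), ncol = 3, byrow = TRUE)
  fdat <- lapply(lines[(3 + nv):(2 + nv + nf)], function(l) scan(text = l, quiet = TRUE))
  if (any(vapply(fdat, function(x) x[1], 0) != 3)) {
    abort("OFF file contains non-triangular faces")
  }
  faces <- do.call(rbind, lapply(fdat, function(x) x[2:4])) + 1L
  list(vertices = verts, faces = faces)
}

# Minimal binary little-endian PLY reader: float/double vertex x,y,z and
# triangular faces with a uchar/int count prefix.
read_ply_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (!length(ln)) abort("truncated PLY header")
    header <- c(header, ln)
    if (ln == "end_header") break
  }
  if (!any(grepl("^format binary_little_endian", header))) {
    abort("PLY must be binary little-endian")
  }
  elem <- grep("^element ", header, value = TRUE)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex", elem, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face", elem, value = TRUE)))
  if (!length(nv) || !length(nf)) abort("PLY header missing vertex or face element")
  # vertex property types (assume x, y, z first and only, as written by write)
  vprops <- header[seq(grep("^element vertex", header) + 1L, length(header))]
  vprops <- vprops[cumsum(grepl("^element|^end_header", vprops)) == 0]
  vtypes <- vapply(strsplit(vprops, " "), `[`, "", 2L)
  vsize <- c(float = 4L, double = 8L)[vtypes]
  if (anyNA(vsize)) abort("unsupported PLY vertex property type")
  verts <- matrix(NA_real_, nv, length(vtypes))
  for (i in seq_len(nv)) {
    for (j in seq_along(vtypes)) {
      verts[i, j] <- readBin(con, "double", 1L, size = vsize[j], endian = "little")
    }
  }
  faces <- matrix(NA_integer_, nf, 3L)
  for (i in seq_len(nf)) {
    k <- readBin(con, "integer", 1L, size = 1L, signed = FALSE, endian = "little")
    if (k != 3L) abort("PLY contains non-triangular faces")
    faces[i, ] <- readBin(con, "integer", 3L, size = 4L, endian = "little")
  }
  list(vertices = verts[, 1:3, drop = FALSE], faces = faces + 1L)
}

#' Write a nucleus mesh as binary little-endian PLY
#'
#' @inheritParams write_mesh
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, pial_path = paste0(path, ".pial")) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           paste("element vertex", nrow(mesh$vertices)),
           "property double x", "property double y", "property double z",
           paste("element face", nrow(mesh$faces)),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.vector(t(mesh$vertices)), con, size = 8L, endian = "little")
  for (i in seq_len(nrow(mesh$faces))) {
    writeBin(as.raw(3L), con)
    writeBin(as.integer(mesh$faces[i, ] - 1L), con, size = 4L, endian = "little")
  }
  writeLines(as.character(mesh$pial_faces - 1L), pial_path)
  invisible(path)
}
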