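#' Construct a surface mesh
#'
#' Container for a triangulated surface in world millimetres (LPS frame).
#' Validation enforces the contract every downstream stage relies on: finite
#' coordinates, valid face indices, and a closed orientable 2-manifold
#' (every undirected edge shared by exactly two faces, traversed once in each
#' direction). Meshes may contain several connected components (e.g. aortic
#' root and left ventricle as separate shells); the manifold conditions apply
#' per component.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm, LPS).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @param validate Run full validation (default `TRUE`).
#' @return Object of class `surface_mesh` with fields `vertices` and `faces`.
#' @export
surface_mesh <- function(vertices, faces, validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  dimnames(vertices) <- NULL; dimnames(faces) <- NULL
  mesh <- structure(list(vertices = vertices, faces = faces),
                    class = "surface_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' Validate a surface mesh
#'
#' @param mesh A `surface_mesh`.
#' @return The mesh, invisibly; errors on violation.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (!all(is.finite(v))) stop("mesh validation: non-finite vertex coordinates", call. = FALSE)
  if (nrow(f) < 4) stop("mesh validation: fewer than 4 faces cannot close a surface", call. = FALSE)
  if (min(f) < 1 || max(f) > nrow(v)) {
    stop("mesh validation: face indices outside 1..", nrow(v), call. = FALSE)
  }
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3])) {
    stop("mesh validation: degenerate faces with repeated vertex indices", call. = FALSE)
  }
  # directed half-edges of every face
  he_from <- c(f[, 1], f[, 2], f[, 3])
  he_to   <- c(f[, 2], f[, 3], f[, 1])
  nv <- nrow(v)
  dir_key <- (he_from - 1) * nv + he_to           # directed edge id
  und_key <- (pmin(he_from, he_to) - 1) * nv + pmax(he_from, he_to)
  if (anyDuplicated(dir_key)) {
    stop("mesh validation: non-orientable or duplicated faces (repeated directed edge)", call. = FALSE)
  }
  cnt <- table(und_key)
  bad <- sum(cnt != 2L)
  if (bad > 0) {
    stop("mesh validation: surface is not closed/manifold; ", bad,
         " edge(s) not shared by exactly 2 faces", call. = FALSE)
  }
  invisible(mesh)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces (mm, LPS)\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# Undirected unique edge matrix (2 columns of vertex indices).
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(cbind(f[, 1], f[, 2]), cbind(f[, 2], f[, 3]), cbind(f[, 3], f[, 1]))
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Transform a mesh rigidly
#'
#' @param mesh A `surface_mesh`.
#' @param transform List with `R` and `t` (see [random_rigid_transform()]).
#' @return Transformed `surface_mesh`.
#' @export
transform_mesh <- function(mesh, transform) {
  surface_mesh(apply_rigid(mesh$vertices, transform), mesh$faces, validate = FALSE)
}
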