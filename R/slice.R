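# Plane-mesh intersection. A plane cutting a closed manifold mesh yields one
# or more closed polyline loops; each crossed triangle contributes a segment
# whose endpoints lie on the two crossed mesh edges, and loops are stitched
# by following shared mesh edges (every crossed edge joins exactly 2 faces).

# All intersection loops of a plane with a mesh, as a list of n x 3 matrices
# of ordered 3D points (open representation: last point connects to first).
slice_mesh_loops <- function(mesh, pl) {
  v <- mesh$vertices
  f <- mesh$faces
  d <- plane_signed_distance(pl, v)
  # deterministic nudge: vertices exactly on the plane are treated as positive
  d[d == 0] <- 1e-12
  s1 <- d[f[, 1]] > 0; s2 <- d[f[, 2]] > 0; s3 <- d[f[, 3]] > 0
  crossed <- (s1 != s2) | (s2 != s3)
  if (!any(crossed)) return(list())
  fc <- f[crossed, , drop = FALSE]
  nv <- nrow(v)
  edge_key <- function(i, j) (pmin(i, j) - 1) * nv + pmax(i, j)
  # per crossed face, the two crossed edges among (1,2),(2,3),(3,1)
  pairs <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  ek <- matrix(NA_real_, nrow(fc), 2)
  for (p in pairs) {
    i <- fc[, p[1]]; j <- fc[, p[2]]
    cr <- (d[i] > 0) != (d[j] > 0)
    k <- edge_key(i, j)
    slot1 <- is.na(ek[, 1])
    put1 <- cr & slot1
    ek[put1, 1] <- k[put1]
    put2 <- cr & !slot1 & is.na(ek[, 2])
    ek[put2, 2] <- k[put2]
  }
  keys <- unique(as.numeric(ek))
  # intersection point per unique crossed edge; key = (min-1)*nv + max
  kmin <- floor((keys - 1) / nv) + 1
  kmax <- keys - (kmin - 1) * nv
  tt <- d[kmin] / (d[kmin] - d[kmax])
  pts <- v[kmin, , drop = FALSE] + tt * (v[kmax, , drop = FALSE] - v[kmin, , drop = FALSE])
  seg <- cbind(match(ek[, 1], keys), match(ek[, 2], keys))
  # stitch segments into loops: nodes = crossed edges, links = segments
  nseg <- nrow(seg)
  nkey <- length(keys)
  inc <- vector("list", nkey)           # segments incident to each node
  for (sidx in seq_len(nseg)) {
    inc[[seg[sidx, 1]]] <- c(inc[[seg[sidx, 1]]], sidx)
    inc[[seg[sidx, 2]]] <- c(inc[[seg[sidx, 2]]], sidx)
  }
  used <- logical(nseg)
  loops <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    path_nodes <- integer(0)
    cur_seg <- start
    cur_node <- seg[start, 1]
    repeat {
      used[cur_seg] <- TRUE
      path_nodes <- c(path_nodes, cur_node)
      nxt_node <- setdiff(seg[cur_seg, ], cur_node)
      if (length(nxt_node) != 1) break  # degenerate (should not occur on manifold)
      cand <- inc[[nxt_node]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) {
        path_nodes <- c(path_nodes, nxt_node)
        break
      }
      cur_seg <- cand[1]
      cur_node <- nxt_node
    }
    # closed loop: first node reachable from last -> drop duplicate endpoint
    if (length(path_nodes) >= 3) {
      if (path_nodes[length(path_nodes)] == path_nodes[1]) {
        path_nodes <- path_nodes[-length(path_nodes)]
      }
      loops[[length(loops) + 1]] <- pts[path_nodes, , drop = FALSE]
    }
  }
  loops
}

#' Intersect a plane with a mesh and select the relevant lumen contour
#'
#' Computes all closed intersection loops of `pl` with `mesh` and keeps the
#' single loop whose interior (in-plane) contains the projection of `anchor`
#' — the expected lumen-interior point, normally the centerline point of the
#' plane. If no loop contains it, the loop whose in-plane centroid is nearest
#' the anchor is taken. The contour is ordered counter-clockwise about the
#' plane normal; area uses the planar shoelace formula, the centroid is the
#' area centroid.
#'
#' @param mesh A [surface_mesh()].
#' @param pl A [plane()].
#' @param anchor Length-3 interior witness point (mm).
#' @param basis_reference Optional direction anchoring the in-plane basis
#'   (see [plane_basis()]); in-plane angles (hence chord-scan diameters at a
#'   finite angular step) follow this reference.
#' @param min_area Loops below this area (mm^2) are discarded as degenerate.
#' @return Object of class `cross_section` with fields `contour` (n x 3,
#'   closed, CCW), `contour2d` (n x 2 in-plane coordinates), `plane`,
#'   `basis`, `area` (mm^2), `perimeter` (mm), `centroid` (3D mm) and
#'   `centroid2d`.
#' @export
slice_mesh <- function(mesh, pl, anchor, basis_reference = NULL, min_area = 1) {
  loops <- slice_mesh_loops(mesh, pl)
  if (length(loops) == 0) {
    stop("empty section: the plane does not intersect the mesh", call. = FALSE)
  }
  basis <- plane_basis(pl, basis_reference)
  a2 <- plane_to_2d(pl, anchor, basis)[1, ]
  loops2d <- lapply(loops, function(L) plane_to_2d(pl, L, basis))
  areas <- vapply(loops2d, function(xy) abs(polygon_signed_area(xy)), 0)
  keep <- areas >= min_area
  if (!any(keep)) {
    stop("degenerate section: all intersection loops have area < ",
         min_area, " mm^2", call. = FALSE)
  }
  loops <- loops[keep]; loops2d <- loops2d[keep]
  contains <- vapply(loops2d, function(xy) point_in_polygon(a2, xy), FALSE)
  if (any(contains)) {
    # smallest containing loop = innermost boundary around the anchor
    cand <- which(contains)
    sel <- cand[which.min(vapply(loops2d[cand],
                                 function(xy) abs(polygon_signed_area(xy)), 0))]
  } else {
    cent <- t(vapply(loops2d, polygon_centroid, numeric(2)))
    sel <- which.min((cent[, 1] - a2[1])^2 + (cent[, 2] - a2[2])^2)
  }
  xy <- loops2d[[sel]]
  contour <- loops[[sel]]
  if (polygon_signed_area(xy) < 0) {            # enforce CCW about the normal
    xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
    contour <- contour[rev(seq_len(nrow(contour))), , drop = FALSE]
  }
  cross_section(contour, pl, basis, xy)
}

# Internal constructor computing the planar metrics from an ordered contour.
cross_section <- function(contour, pl, basis, xy = NULL) {
  if (is.null(xy)) xy <- plane_to_2d(pl, contour, basis)
  area <- polygon_signed_area(xy)
  per <- polygon_perimeter(xy)
  c2 <- polygon_centroid(xy)
  structure(list(contour = contour, contour2d = xy, plane = pl, basis = basis,
                 area = area, perimeter = per,
                 centroid = as.numeric(plane_from_2d(pl, c2, basis)),
                 centroid2d = c2),
            class = "cross_section")
}

#' @export
print.cross_section <- function(x, ...) {
  cat(sprintf("<cross_section> %d points, area %.3f mm^2, perimeter %.3f mm\n",
              nrow(x$contour), x$area, x$perimeter))
  invisible(x)
}
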