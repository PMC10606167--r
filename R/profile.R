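#' Cross-sectional area profile along a centerline
#'
#' Slices the mesh at evenly spaced stations along the centerline and records
#' the lumen cross-section area at each, enabling area profiling of the
#' aortic root. Stations where the section is empty or degenerate are
#' recorded as missing, never fabricated.
#'
#' @param mesh A [surface_mesh()].
#' @param cl A [centerline()].
#' @param s_start,s_end Arc-length range (mm) within the centerline.
#' @param spacing Station spacing (mm), default 1.
#' @param orientation_mode `"tangent"` (planes perpendicular to the local
#'   centerline tangent) or `"annulus_parallel"` (all planes share
#'   `fixed_normal`).
#' @param fixed_normal Normal used when `orientation_mode = "annulus_parallel"`.
#' @param basis_reference Optional in-plane reference direction passed to
#'   [slice_mesh()].
#' @param max_missing_frac Error when more than this fraction of stations is
#'   missing (signals an upstream segmentation/centerline failure).
#' @return Object of class `area_profile`: list with `s` (stations, mm),
#'   `area` (mm^2, `NA` where missing) and `sections` (list of
#'   `cross_section` or `NULL`).
#' @export
area_profile <- function(mesh, cl, s_start, s_end, spacing = 1,
                         orientation_mode = c("tangent", "annulus_parallel"),
                         fixed_normal = NULL, basis_reference = NULL,
                         max_missing_frac = 0.5) {
  orientation_mode <- match.arg(orientation_mode)
  stopifnot(spacing > 0)
  L <- centerline_length(cl)
  if (s_start < -1e-9 || s_end > L + 1e-9 || s_end <= s_start) {
    stop("profile range [", s_start, ", ", s_end,
         "] outside the centerline [0, ", sprintf("%.2f", L), "]", call. = FALSE)
  }
  if (orientation_mode == "annulus_parallel" && is.null(fixed_normal)) {
    stop("annulus_parallel orientation requires fixed_normal", call. = FALSE)
  }
  s <- seq(s_start, s_end, by = spacing)
  pts <- centerline_point_at(cl, s)
  sections <- vector("list", length(s))
  areas <- rep(NA_real_, length(s))
  for (i in seq_along(s)) {
    normal <- if (orientation_mode == "tangent") tangent_at(cl, s[i]) else fixed_normal
    sec <- tryCatch(
      slice_mesh(mesh, plane(pts[i, ], normal), anchor = pts[i, ],
                 basis_reference = basis_reference),
      error = function(e) NULL)
    if (!is.null(sec)) {
      sections[[i]] <- sec
      areas[i] <- sec$area
    }
  }
  frac_missing <- mean(is.na(areas))
  if (frac_missing > max_missing_frac) {
    stop(sprintf(
      "profile error: %.0f%% of stations have no usable cross-section",
      100 * frac_missing), call. = FALSE)
  }
  structure(list(s = s, area = areas, sections = sections,
                 orientation_mode = orientation_mode),
            class = "area_profile")
}

#' @export
print.area_profile <- function(x, ...) {
  cat(sprintf("<area_profile> %d stations over [%.1f, %.1f] mm, %d missing\n",
              length(x$s), min(x$s), max(x$s), sum(is.na(x$area))))
  invisible(x)
}

#' @export
as.data.frame.area_profile <- function(x, ...) {
  data.frame(s_mm = x$s, area_mm2 = x$area)
}
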