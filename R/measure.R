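# Anatomical plane construction and the full measurement pipeline:
# centerline -> annulus plane (3 nadirs) -> annulus section -> LVOT plane
# (4 mm below along the centerline, same normal) -> area profile -> SOV
# (area maximum) and SNTJ (area stabilization) -> per-sinus diameters
# (nadir projections) -> coronary heights -> 22-measurement report.

#' Pipeline configuration
#'
#' @param plane_spacing_mm Station spacing of the area profile (mm).
#' @param lvot_offset_mm Distance below the annulus, along the centerline, of
#'   the LVOT plane (mm).
#' @param angular_step_deg Angular step of the centroid-chord diameter scan.
#' @param sntj_rel_tol Relative area change per station below which the
#'   profile counts as stable.
#' @param sntj_window Number of consecutive stable station-to-station changes
#'   required to call the junction.
#' @param sov_search_max_mm Upper bound of the SOV/SNTJ search above the
#'   annulus (mm); guards against latching onto a dilated ascending aorta.
#' @param orientation_mode Orientation of the profile planes: `"tangent"`
#'   (perpendicular to the centerline) or `"annulus_parallel"`.
#' @param centerline_method `"lbc"` (Laplacian-based contraction) or
#'   `"marching"` (cross-section centroid tracking).
#' @param lbc Parameters for [extract_centerline_lbc()].
#' @param allow_partial Emit a partial report (missing fields `NA`, QC
#'   flagged) instead of failing when a stage errors.
#' @return Named list of class `measure_config`.
#' @export
measure_config <- function(plane_spacing_mm = 1.0,
                           lvot_offset_mm = 4.0,
                           angular_step_deg = 0.5,
                           sntj_rel_tol = 0.02,
                           sntj_window = 3,
                           sov_search_max_mm = 40,
                           orientation_mode = c("tangent", "annulus_parallel"),
                           centerline_method = c("lbc", "marching"),
                           lbc = lbc_params(),
                           allow_partial = FALSE) {
  orientation_mode <- match.arg(orientation_mode)
  centerline_method <- match.arg(centerline_method)
  structure(list(plane_spacing_mm = plane_spacing_mm,
                 lvot_offset_mm = lvot_offset_mm,
                 angular_step_deg = angular_step_deg,
                 sntj_rel_tol = sntj_rel_tol,
                 sntj_window = sntj_window,
                 sov_search_max_mm = sov_search_max_mm,
                 orientation_mode = orientation_mode,
                 centerline_method = centerline_method,
                 lbc = lbc,
                 allow_partial = allow_partial),
            class = "measure_config")
}

# Build a measure_config from a named list (e.g. parsed YAML/JSON),
# rejecting unknown keys.
config_from_list <- function(x) {
  known <- names(formals(measure_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!is.null(x$lbc)) x$lbc <- do.call(lbc_params, x$lbc)
  do.call(measure_config, x)
}

#' Annulus plane from the three nadirs
#'
#' The plane through the left-coronary, right-coronary and non-coronary
#' nadirs, with origin at their centroid and the normal signed to point
#' toward increasing centerline arc length (toward the aorta).
#'
#' @param nadirs 3 x 3 matrix of the nadir points (rows LC, RC, NC) or a
#'   [landmark_set()].
#' @param cl A [centerline()] fixing the normal sign.
#' @param min_area Minimum nadir-triangle area (mm^2) below which the nadir
#'   geometry is rejected as implausible.
#' @return A [plane()].
#' @export
annulus_plane <- function(nadirs, cl, min_area = 1e-6) {
  if (inherits(nadirs, "landmark_set")) nadirs <- nadir_matrix(nadirs)
  pl <- tryCatch(plane_from_points(nadirs[1, ], nadirs[2, ], nadirs[3, ],
                                   min_area = min_area),
                 error = function(e) {
                   stop("nadir geometry implausible: ", conditionMessage(e),
                        call. = FALSE)
                 })
  s_cross <- centerline_plane_crossing(cl, pl)
  tg <- tangent_at(cl, s_cross)
  if (sum(pl$normal * tg) < 0) pl <- plane(pl$origin, -pl$normal)
  pl
}

# Arc length at which the centerline crosses a plane (nearest crossing to
# the plane origin; falls back to the closest point when no sign change).
centerline_plane_crossing <- function(cl, pl) {
  d <- plane_signed_distance(pl, cl$points)
  sgn <- d > 0
  cross_idx <- which(sgn[-1] != sgn[-length(sgn)])
  if (length(cross_idx) == 0) return(cl$arclength[which.min(abs(d))])
  s0 <- cl$arclength[cross_idx]
  s1 <- cl$arclength[cross_idx + 1]
  frac <- d[cross_idx] / (d[cross_idx] - d[cross_idx + 1])
  s_cross <- s0 + frac * (s1 - s0)
  # nearest to the plane origin's own station
  p0 <- cl$points[which.min(rowSums(sweep(cl$points, 2, pl$origin)^2)), ]
  s_near <- cl$arclength[which.min(rowSums(sweep(cl$points, 2, p0)^2))]
  s_cross[which.min(abs(s_cross - s_near))]
}

#' LVOT plane
#'
#' The annulus plane translated down the centerline by `offset` mm: the
#' origin moves to the centerline point at `s_annulus - offset`, the normal
#' is kept (pure translation, so nadir errors propagate identically to LVOT
#' measurements).
#'
#' @param annulus A [plane()] from [annulus_plane()].
#' @param cl A [centerline()].
#' @param offset Offset below the annulus (mm), default 4.
#' @return A [plane()].
#' @export
lvot_plane <- function(annulus, cl, offset = 4) {
  s_ann <- centerline_plane_crossing(cl, annulus)
  s_lvot <- s_ann - offset
  if (s_lvot < 0) {
    stop("centerline too short below the annulus: annulus at ",
         sprintf("%.2f", s_ann), " mm, offset ", offset, " mm", call. = FALSE)
  }
  out <- plane(as.numeric(centerline_point_at(cl, s_lvot)), annulus$normal)
  out$normal <- annulus$normal    # bitwise-identical normal (pure translation)
  out
}

#' Locate the sinus-of-Valsalva and sinotubular-junction stations
#'
#' The SOV is the station of greatest cross-sectional area above the annulus
#' (ties break toward the smaller arc length). The SNTJ is the smallest
#' station above the SOV from which the relative area change per station
#' stays below `sntj_rel_tol` for `sntj_window` consecutive station pairs;
#' when no station qualifies, the station minimizing `|dA/ds|` above the SOV
#' is used and a QC flag is raised.
#'
#' @param profile An [area_profile()] covering the root above the annulus.
#' @param s_annulus Annulus arc length (mm).
#' @param sntj_rel_tol,sntj_window Stabilization criterion (see
#'   [measure_config()]).
#' @param min_valid Minimum number of valid stations required.
#' @return List with `s_sov`, `s_sntj`, `sov_index`, `sntj_index`,
#'   `qc_flags` (character vector).
#' @export
find_sov_sntj <- function(profile, s_annulus, sntj_rel_tol = 0.02,
                          sntj_window = 3, min_valid = 10) {
  qc <- character()
  valid <- which(!is.na(profile$area) & profile$s > s_annulus + 1e-9)
  if (length(valid) < min_valid) {
    stop("SOV/SNTJ search: only ", length(valid),
         " valid stations above the annulus (need >= ", min_valid, ")",
         call. = FALSE)
  }
  a <- profile$area[valid]
  s <- profile$s[valid]
  i_max <- which(a == max(a))[1]
  if (i_max == 1 || i_max == length(valid)) {
    qc <- c(qc, "SOV at search boundary")
  }
  s_sov <- s[i_max]
  above <- i_max:length(valid)      # positions (within `valid`) at/above SOV
  if (length(above) < 2) {
    # degenerate anatomy (e.g. monotone root): no stations above the SOV;
    # report the boundary station for both planes, QC-flagged above
    qc <- c(qc, "SNTJ stabilization fallback")
    return(list(s_sov = s_sov, s_sntj = s_sov,
                sov_index = valid[i_max], sntj_index = valid[i_max],
                qc_flags = qc))
  }
  # rel[j]: relative area change from station above[j] to above[j+1]
  rel <- abs(diff(a[above])) / a[above][-length(above)]
  sntj_pos <- NA_integer_
  if (length(rel) >= sntj_window) {
    stable <- rel < sntj_rel_tol
    run <- stats::filter(as.numeric(stable), rep(1, sntj_window), sides = 1)
    hit <- which(!is.na(run) & run == sntj_window)
    # run[j] counts the window ending at change j; stability begins at the
    # first change of that window
    if (length(hit) > 0) sntj_pos <- above[hit[1] - sntj_window + 1]
  }
  if (is.na(sntj_pos)) {
    # fallback: first local minimum of |dA/ds| above the SOV
    qc <- c(qc, "SNTJ stabilization fallback")
    if (length(rel) == 1) {
      sntj_pos <- above[2]
    } else {
      locmin <- which(diff(sign(diff(c(Inf, rel, Inf)))) > 0)
      sntj_pos <- above[min(locmin[1] + 1, length(above))]
    }
  }
  if (s[sntj_pos] <= s_sov) sntj_pos <- above[2]
  list(s_sov = s_sov, s_sntj = s[sntj_pos],
       sov_index = valid[i_max], sntj_index = valid[sntj_pos], qc_flags = qc)
}

#' Per-sinus diameters on the SOV section
#'
#' Each nadir is orthogonally projected onto the SOV plane; the full line
#' through the projection and the section centroid is intersected with the
#' contour, and the sinus diameter is the distance between the two boundary
#' crossings (the farthest pair on opposite sides of the centroid when the
#' contour is crossed more than twice, with a QC flag).
#'
#' @param sov_section A `cross_section` at the SOV plane.
#' @param landmarks A [landmark_set()] (the three nadirs are used).
#' @param min_offset Minimum distance (mm) between a projected nadir and the
#'   centroid for the line direction to be defined.
#' @return List with `diameters` (named `diameter_lcc`, `diameter_rcc`,
#'   `diameter_ncc`, mm), `endpoints` (per sinus, 2 x 3 world points for QC)
#'   and `qc_flags`.
#' @export
sinus_diameters <- function(sov_section, landmarks, min_offset = 0.1) {
  nad <- nadir_matrix(landmarks)
  labels <- c("diameter_lcc", "diameter_rcc", "diameter_ncc")
  pl <- sov_section$plane
  basis <- sov_section$basis
  p2 <- plane_to_2d(pl, plane_project(pl, nad), basis)
  cen <- sov_section$centroid2d
  qc <- character()
  d <- numeric(3)
  endpoints <- vector("list", 3)
  for (k in 1:3) {
    off <- p2[k, ] - cen
    if (vnorm(c(off, 0)) < min_offset) {
      stop("sinus line direction undefined: projected nadir within ",
           min_offset, " mm of the section centroid", call. = FALSE)
    }
    u <- off / sqrt(sum(off^2))
    ch <- chord_through(sov_section$contour2d, cen, u)
    if (is.null(ch)) {
      stop("sinus line misses the SOV contour on one side", call. = FALSE)
    }
    if (ch$n_crossings != 2) {
      qc <- c(qc, paste0("non-convex sinus contour (", labels[k], ")"))
    }
    d[k] <- ch$length
    endpoints[[k]] <- plane_from_2d(pl, rbind(ch$p_lo, ch$p_hi), basis)
  }
  names(d) <- labels
  names(endpoints) <- labels
  list(diameters = d, endpoints = endpoints, qc_flags = unique(qc))
}

#' Perpendicular coronary ostium height above the annulus plane
#'
#' Signed distance of the ostium to the annulus plane, positive on the aortic
#' side (the side the annulus normal points to). A non-positive value
#' indicates a landmark or plane failure, not anatomy; the pipeline reports
#' the unsigned value with a QC flag.
#'
#' @param ostium Length-3 ostium point (mm).
#' @param annulus The annulus [plane()].
#' @return Signed height (mm).
#' @export
coronary_height <- function(ostium, annulus) {
  plane_signed_distance(annulus, as.numeric(ostium))
}

#' Run the full measurement pipeline
#'
#' Executes centerline extraction, annulus/LVOT plane construction and
#' sectioning, the area profile, SOV/SNTJ detection, sinus diameters and
#' coronary heights, and assembles the 22-measurement report. Deterministic
#' for fixed inputs and configuration. On a stage failure the error is
#' re-signalled with the stage name (condition class
#' `pipeline_stage_error`), or, with `config$allow_partial`, the affected
#' fields are set to `NA` and QC-flagged.
#'
#' @param mesh A [surface_mesh()].
#' @param landmarks A [landmark_set()].
#' @param config A [measure_config()].
#' @param centerline Optional precomputed [centerline()]; skips extraction
#'   (useful for landmark sensitivity studies on a fixed mesh).
#' @return A [measurement_report()]; attribute `"detail"` carries the
#'   centerline, planes, sections, profile and stations.
#' @export
run_pipeline <- function(mesh, landmarks, config = measure_config(),
                         centerline = NULL) {
  stopifnot(inherits(config, "measure_config"))
  qc <- character()
  partial <- FALSE
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(paste0("stage ", name, ": ", conditionMessage(e)),
                          class = c("pipeline_stage_error", "error"),
                          stage = name))
    })
  }
  # like stage(), but under allow_partial a failure yields NULL + QC flag
  soft_stage <- function(name, expr) {
    if (!config$allow_partial) return(stage(name, expr))
    tryCatch(expr, error = function(e) {
      qc <<- c(qc, paste0("partial: stage ", name, " failed (",
                          conditionMessage(e), ")"))
      partial <<- TRUE
      NULL
    })
  }
  na_metrics <- function(fields) stats::setNames(rep(NA_real_, length(fields)), fields)
  stage("validate_inputs", {
    validate_mesh(mesh)
    stopifnot(inherits(landmarks, "landmark_set"))
  })
  cl <- centerline
  if (is.null(cl)) {
    cl <- stage("centerline", {
      if (config$centerline_method == "lbc") {
        extract_centerline_lbc(mesh, config$lbc, landmarks = landmarks)
      } else {
        nad <- nadir_matrix(landmarks)
        seed <- plane_from_points(nad[1, ], nad[2, ], nad[3, ])
        orient_centerline(
          extract_centerline_marching(mesh, seed,
                                      step = min(1, config$plane_spacing_mm)),
          landmarks)
      }
    })
  }
  # in-plane reference direction anchored to the anatomy (NC nadir), so
  # chord-scan angles rotate with the data and the report is rigidly
  # equivariant even at a finite angular step
  ref_dir <- landmarks$nadir_noncoronary - colMeans(nadir_matrix(landmarks))
  ann_pl <- stage("annulus_plane", annulus_plane(landmarks, cl))
  s_ann <- centerline_plane_crossing(cl, ann_pl)
  ann_sec <- stage("annulus_section",
    slice_mesh(mesh, ann_pl, anchor = as.numeric(centerline_point_at(cl, s_ann)),
               basis_reference = ref_dir))
  annulus <- stage("annulus_metrics", section_metrics(ann_sec, config$angular_step_deg))
  lvot <- soft_stage("lvot", {
    lv_pl <- lvot_plane(ann_pl, cl, config$lvot_offset_mm)
    lv_sec <- slice_mesh(mesh, lv_pl, anchor = lv_pl$origin,
                         basis_reference = ref_dir)
    section_metrics(lv_sec, config$angular_step_deg)
  })
  if (is.null(lvot)) { lv_pl <- NULL; lv_sec <- NULL; lvot <- na_metrics(SECTION_METRICS) }
  root <- soft_stage("sov_sntj", {
    s_end <- min(s_ann + config$sov_search_max_mm, centerline_length(cl))
    prof <- area_profile(mesh, cl, s_ann, s_end, config$plane_spacing_mm,
                         orientation_mode = config$orientation_mode,
                         fixed_normal = ann_pl$normal, basis_reference = ref_dir)
    stations <- find_sov_sntj(prof, s_ann, config$sntj_rel_tol, config$sntj_window)
    sov_sec <- prof$sections[[stations$sov_index]]
    sntj_sec <- prof$sections[[stations$sntj_index]]
    mm <- min_max_diameters(sntj_sec, config$angular_step_deg)
    sinus <- sinus_diameters(sov_sec, landmarks)
    list(profile = prof, stations = stations, sov_section = sov_sec,
         sntj_section = sntj_sec, sinus = sinus,
         sntj = c(diameter_min = mm$d_min, diameter_max = mm$d_max,
                  diameter_avg = (mm$d_min + mm$d_max) / 2))
  })
  if (is.null(root)) {
    sntj <- na_metrics(REPORT_FIELDS$sntj)
    sinus <- list(diameters = na_metrics(REPORT_FIELDS$sov), qc_flags = character())
    stations <- list(s_sov = NA_real_, s_sntj = NA_real_)
  } else {
    sntj <- root$sntj
    sinus <- root$sinus
    stations <- root$stations
    qc <- c(qc, stations$qc_flags, sinus$qc_flags)
  }
  coronary <- stage("coronary_heights", {
    hl <- coronary_height(landmarks$left_coronary_ostium, ann_pl)
    hr <- coronary_height(landmarks$right_coronary_ostium, ann_pl)
    if (hl <= 0) qc <<- c(qc, "non-positive left coronary height")
    if (hr <= 0) qc <<- c(qc, "non-positive right coronary height")
    c(height_left = abs(hl), height_right = abs(hr))
  })
  meta <- list(config = unclass(config),
               n_vertices = nrow(mesh$vertices), n_faces = nrow(mesh$faces),
               s_annulus = s_ann, s_sov = stations$s_sov,
               s_sntj = stations$s_sntj, qc_flags = unique(qc))
  report <- measurement_report(annulus, lvot, sntj, sinus$diameters, coronary,
                               metadata = meta, validate = !partial)
  attr(report, "detail") <- list(
    centerline = cl, annulus_plane = ann_pl, annulus_section = ann_sec,
    lvot_plane = if (exists("lv_pl", inherits = FALSE)) lv_pl else NULL,
    lvot_section = if (exists("lv_sec", inherits = FALSE)) lv_sec else NULL,
    profile = root$profile, stations = stations,
    sov_section = root$sov_section, sntj_section = root$sntj_section,
    sinus = sinus)
  report
}
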