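LANDMARK_NAMES <- c("left_coronary_ostium", "right_coronary_ostium",
                    "nadir_left", "nadir_right", "nadir_noncoronary")

#' Construct a landmark set
#'
#' The five anatomical points that drive every plane in the pipeline: the two
#' coronary ostia and the three leaflet nadirs (left-coronary, right-coronary
#' and non-coronary). All points are mm in the LPS world frame.
#'
#' @param left_coronary_ostium,right_coronary_ostium,nadir_left,nadir_right,nadir_noncoronary
#'   Length-3 numeric points (mm, LPS).
#' @param min_nadir_area Minimum area (mm^2) of the nadir triangle; below it
#'   the nadirs are rejected as collinear (no annulus plane exists). The
#'   default is a strict geometric tolerance; anatomical plausibility is
#'   checked downstream by [annulus_plane()].
#' @return Object of class `landmark_set`: a named list of length-3 points.
#' @export
landmark_set <- function(left_coronary_ostium, right_coronary_ostium,
                         nadir_left, nadir_right, nadir_noncoronary,
                         min_nadir_area = 1e-6) {
  lm <- list(left_coronary_ostium = as.numeric(left_coronary_ostium),
             right_coronary_ostium = as.numeric(right_coronary_ostium),
             nadir_left = as.numeric(nadir_left),
             nadir_right = as.numeric(nadir_right),
             nadir_noncoronary = as.numeric(nadir_noncoronary))
  for (nm in LANDMARK_NAMES) {
    p <- lm[[nm]]
    if (length(p) != 3 || !all(is.finite(p))) {
      stop("landmark '", nm, "' must be a finite 3D point", call. = FALSE)
    }
  }
  a <- 0.5 * vnorm(cross3(lm$nadir_right - lm$nadir_left,
                          lm$nadir_noncoronary - lm$nadir_left))
  if (a < min_nadir_area) {
    stop("collinear nadirs: nadir triangle area ",
         sprintf("%.4g mm^2 < %g mm^2; no annulus plane exists", a, min_nadir_area),
         call. = FALSE)
  }
  structure(lm, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> (mm, LPS)\n")
  for (nm in LANDMARK_NAMES) {
    cat(sprintf("  %-22s (%.3f, %.3f, %.3f)\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  }
  invisible(x)
}

# 3 x 3 matrix of the nadirs in LC, RC, NC row order.
nadir_matrix <- function(lm) {
  rbind(lm$nadir_left, lm$nadir_right, lm$nadir_noncoronary)
}

#' Read a landmark JSON file
#'
#' Schema: a JSON object with exactly the five landmark keys, each an
#' `[x, y, z]` array in mm LPS. An optional `"frame"` field must equal
#' `"LPS"` when present.
#'
#' @param path Path to the JSON file.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.null(obj$frame) && !identical(obj$frame, "LPS")) {
    stop("landmark schema error: frame must be \"LPS\", got \"", obj$frame, "\"",
         call. = FALSE)
  }
  missing <- setdiff(LANDMARK_NAMES, names(obj))
  if (length(missing) > 0) {
    stop("landmark schema error: missing key(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(landmark_set, obj[LANDMARK_NAMES])
}

#' Write a landmark set to JSON
#'
#' @param lm A [landmark_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(lm, path) {
  obj <- c(lapply(unclass(lm)[LANDMARK_NAMES], as.numeric), list(frame = "LPS"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Transform a landmark set rigidly
#'
#' @param lm A [landmark_set()].
#' @param transform List with `R` and `t` (see [random_rigid_transform()]).
#' @return Transformed `landmark_set`.
#' @export
transform_landmarks <- function(lm, transform) {
  out <- lapply(unclass(lm)[LANDMARK_NAMES], apply_rigid, transform = transform)
  do.call(landmark_set, out)
}

#' Mean absolute landmark error
#'
#' Mean over the five landmarks of the Euclidean distance between a predicted
#' and a reference landmark set.
#'
#' @param predicted,truth [landmark_set()] objects.
#' @return Mean absolute error in mm.
#' @export
landmark_mae <- function(predicted, truth) {
  d <- vapply(LANDMARK_NAMES,
              function(nm) vnorm(predicted[[nm]] - truth[[nm]]), 0)
  mean(d)
}
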