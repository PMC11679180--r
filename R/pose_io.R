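# BODY_25 keypoint I/O and pixel->metric calibration.
#
# Keypoint files follow the dialect of common markerless pose estimators:
# {"version": .., "people": [{"pose_keypoints_2d": [x0,y0,c0, ... 75 numbers]}]}
# Pixel coordinates are y-down; the world frame is y-up with the ground at
# y = 0 and x along the facing direction.

# 0-based BODY_25 indices for the keypoints this package consumes
.body25 <- c(
  nose = 0L, neck = 1L, rshoulder = 2L, relbow = 3L, rwrist = 4L,
  lshoulder = 5L, lelbow = 6L, lwrist = 7L, midhip = 8L,
  rhip = 9L, rknee = 10L, rankle = 11L,
  lhip = 12L, lknee = 13L, lankle = 14L,
  reye = 15L, leye = 16L, rear = 17L, lear = 18L,
  lbigtoe = 19L, lsmalltoe = 20L, lheel = 21L,
  rbigtoe = 22L, rsmalltoe = 23L, rheel = 24L
)

kp_row <- function(name) .body25[[name]] + 1L

#' Construct a raw pose
#'
#' @param keypoints A 25 x 3 numeric matrix of (x, y, confidence) rows in
#'   BODY_25 index order (0-based indices nose = 0 ... rheel = 24). A
#'   keypoint with confidence 0 is treated as missing.
#' @param source_id Free-text identifier of the pose's origin.
#' @return An object of class `raw_pose`.
#' @export
raw_pose <- function(keypoints, source_id = "unknown") {
  keypoints <- as.matrix(keypoints)
  if (!is.numeric(keypoints) || !identical(dim(keypoints), c(25L, 3L)))
    ls_abort("keypoints must be a numeric 25 x 3 matrix", "validation")
  conf <- keypoints[, 3L]
  if (anyNA(conf) || any(conf < 0 | conf > 1))
    ls_abort("keypoint confidences must lie in [0, 1]", "validation")
  dimnames(keypoints) <- list(names(.body25), c("x", "y", "confidence"))
  structure(list(keypoints = keypoints, source_id = as.character(source_id)),
            class = "raw_pose")
}

#' Read a BODY_25 keypoint file
#'
#' Parses the JSON dialect written by common pose estimators (a `people`
#' array whose entries carry a flat `pose_keypoints_2d` vector of 75
#' numbers). A file with zero detected people yields an empty list, not an
#' error.
#'
#' @param path Path to the keypoint JSON file.
#' @return A list of [raw_pose()] objects, one per person, in file order.
#' @export
read_pose_file <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    ls_abort(sprintf("pose file not found: '%s'", paste(path, collapse = ",")),
             "io")
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    ls_abort(sprintf("cannot parse pose file '%s': %s", path,
                                     conditionMessage(e)), "parse"))
  if (!is.list(doc) || is.null(doc$people))
    ls_abort(sprintf("pose file '%s' has no 'people' array", path), "parse")
  people <- doc$people
  out <- vector("list", length(people))
  for (i in seq_along(people)) {
    kp <- unlist(people[[i]]$pose_keypoints_2d, use.names = FALSE)
    if (!is.numeric(kp) || length(kp) != 75L)
      ls_abort(sprintf(
        "pose file '%s': person %d has %d numbers in pose_keypoints_2d (need 75)",
        path, i, length(kp)), "parse")
    out[[i]] <- raw_pose(matrix(kp, ncol = 3L, byrow = TRUE),
                         source_id = sprintf("%s#%d", path, i))
  }
  out
}

#' Calibration configuration
#'
#' @param min_confidence Minimum keypoint confidence for a keypoint to count
#'   as detected (default 0.3).
#' @param ground_tolerance Vertical tolerance in meters within which a heel
#'   or toe counts as touching the ground (default 0.02 m).
#' @param scale Explicit meters-per-pixel scale; `NULL` (default) estimates
#'   it from shank length via [estimate_scale()].
#' @param flip_y Whether pixel y (down) must be negated into world y (up);
#'   default `TRUE`. Set `FALSE` for coordinates that are already y-up.
#' @param support Support-state handling: `"auto"` infers it from foot
#'   heights; `"double"`, `"single_hind"`, `"single_front"` force the stated
#'   interpretation (double support tolerates foot-height discrepancies up to
#'   a relaxed tolerance).
#' @param facing Facing sign `+1`/`-1`, or `NULL` to infer it from the
#'   heel-to-toe direction of the grounded feet.
#' @return A list of class `calibration_config`.
#' @export
calibration_config <- function(min_confidence = 0.3, ground_tolerance = 0.02,
                               scale = NULL, flip_y = TRUE,
                               support = c("auto", "double", "single_hind",
                                           "single_front"),
                               facing = NULL) {
  support <- match.arg(support)
  if (!is_number(min_confidence) || min_confidence < 0 || min_confidence > 1)
    ls_abort("min_confidence must be in [0, 1]", "validation")
  if (!is_number(ground_tolerance) || ground_tolerance <= 0)
    ls_abort("ground_tolerance must be > 0", "validation")
  if (!is.null(scale) && (!is_number(scale) || scale <= 0))
    ls_abort("scale must be NULL or a positive number (m/px)", "validation")
  if (!is.null(facing) && !(is_number(facing) && facing %in% c(-1, 1)))
    ls_abort("facing must be NULL, +1 or -1", "validation")
  structure(list(min_confidence = min_confidence,
                 ground_tolerance = ground_tolerance, scale = scale,
                 flip_y = isTRUE(flip_y), support = support, facing = facing),
            class = "calibration_config")
}

kp_valid <- function(raw, name, min_confidence) {
  raw$keypoints[kp_row(name), "confidence"] >= min_confidence &&
    raw$keypoints[kp_row(name), "confidence"] > 0
}

kp_xy <- function(raw, name) as.numeric(raw$keypoints[kp_row(name), 1:2])

#' Estimate the meters-per-pixel scale of a raw pose
#'
#' Uses the model shank length divided by the pixel knee-to-ankle distance,
#' averaged over the legs whose knee and ankle keypoints are detected. The
#' shank is preferred over stature because head keypoints on stylized
#' figures are unreliable.
#'
#' @param raw A [raw_pose()].
#' @param model An [build_model()] result.
#' @param min_confidence Minimum confidence for a keypoint to count.
#' @return Scalar scale in meters per pixel.
#' @export
estimate_scale <- function(raw, model, min_confidence = 0.3) {
  stopifnot(inherits(raw, "raw_pose"), inherits(model, "anthropometric_model"))
  shank <- model$segments$shank$length
  scales <- numeric(0)
  for (leg in list(c("rknee", "rankle"), c("lknee", "lankle"))) {
    if (kp_valid(raw, leg[1L], min_confidence) &&
        kp_valid(raw, leg[2L], min_confidence)) {
      d <- vnorm(kp_xy(raw, leg[1L]) - kp_xy(raw, leg[2L]))
      if (d == 0)
        ls_abort(sprintf("degenerate pose: %s and %s coincide",
                         leg[1L], leg[2L]), "degenerate_pose")
      scales <- c(scales, shank / d)
    }
  }
  if (!length(scales))
    ls_abort("no leg with detected knee and ankle keypoints; cannot estimate scale",
             "insufficient_keypoints")
  mean(scales)
}

#' Construct a calibrated posture
#'
#' Low-level constructor for a metric sagittal posture. Usually produced by
#' [calibrate()] or [generate_scene()] rather than called directly.
#'
#' @param hind,front Per-leg lists with points `hip`, `knee`, `ankle`,
#'   `heel`, `toe` (numeric length-2, meters, world frame).
#' @param trunk_anchor Representative head-arms-trunk point (length-2).
#' @param support_state `"double"`, `"single_hind"` or `"single_front"`.
#' @param facing_sign `+1` if the figure faces +x, `-1` otherwise.
#' @param ground_tolerance Tolerance used by the ground-contact invariants.
#' @param check_ground If `FALSE`, skip the ground-contact invariants (used
#'   when a support state is forced by configuration).
#' @return An object of class `posture`.
#' @export
posture <- function(hind, front, trunk_anchor,
                    support_state = c("double", "single_hind", "single_front"),
                    facing_sign = 1, ground_tolerance = 0.02,
                    check_ground = TRUE) {
  support_state <- match.arg(support_state)
  chk_leg <- function(leg, which) {
    need <- c("hip", "knee", "ankle", "heel", "toe")
    if (!is.list(leg) || !all(need %in% names(leg)))
      ls_abort(sprintf("%s leg must list points %s", which,
                       paste(need, collapse = ", ")), "validation")
    leg <- lapply(leg[need], as_point)
    for (seg in list(c("hip", "knee"), c("knee", "ankle"), c("ankle", "toe"),
                     c("heel", "toe")))
      if (vnorm(leg[[seg[1L]]] - leg[[seg[2L]]]) == 0)
        ls_abort(sprintf("%s leg: %s and %s coincide (zero-length segment)",
                         which, seg[1L], seg[2L]), "degenerate_segment")
    leg
  }
  hind <- chk_leg(hind, "hind")
  front <- chk_leg(front, "front")
  trunk_anchor <- as_point(trunk_anchor, "trunk_anchor")
  if (!facing_sign %in% c(-1, 1))
    ls_abort("facing_sign must be +1 or -1", "validation")

  p <- structure(list(hind = hind, front = front,
                      trunk_anchor = trunk_anchor,
                      support_state = support_state,
                      facing_sign = facing_sign),
                 class = "posture")
  if (check_ground) {
    grounded <- function(leg)
      abs(leg$heel[2L]) <= ground_tolerance && abs(leg$toe[2L]) <= ground_tolerance
    ok <- switch(support_state,
      double = grounded(hind) && grounded(front),
      single_hind = grounded(hind) && !grounded(front),
      single_front = grounded(front) && !grounded(hind))
    if (!ok)
      ls_abort(sprintf(
        "foot heights are inconsistent with support state '%s' (tolerance %g m)",
        support_state, ground_tolerance), "validation")
  }
  p
}

#' @export
print.posture <- function(x, ...) {
  cat(sprintf("Posture: support %s, facing %+d\n", x$support_state,
              x$facing_sign))
  for (side in c("hind", "front")) {
    leg <- x[[side]]
    cat(sprintf("  %-5s hip (%.3f, %.3f)  knee (%.3f, %.3f)  ankle (%.3f, %.3f)\n",
                side, leg$hip[1], leg$hip[2], leg$knee[1], leg$knee[2],
                leg$ankle[1], leg$ankle[2]))
  }
  cat(sprintf("  trunk anchor (%.3f, %.3f)\n", x$trunk_anchor[1],
              x$trunk_anchor[2]))
  invisible(x)
}

#' Calibrate a raw pose into a metric posture
#'
#' Flips the pixel y-axis to y-up (unless disabled), applies a single
#' isotropic meters-per-pixel scale (explicit or estimated from shank
#' length), sets the ground line so the lowest heel/toe point maps to
#' y = 0, infers or enforces the support state, and assigns the hind/front
#' legs by x-order against the facing direction.
#'
#' @param raw A [raw_pose()].
#' @param model An [build_model()] result.
#' @param config A [calibration_config()].
#' @return A [posture()].
#' @export
calibrate <- function(raw, model, config = calibration_config()) {
  stopifnot(inherits(raw, "raw_pose"), inherits(model, "anthropometric_model"))
  if (!inherits(config, "calibration_config"))
    ls_abort("config must be a calibration_config()", "validation")

  required <- c("rhip", "rknee", "rankle", "rheel", "rbigtoe",
                "lhip", "lknee", "lankle", "lheel", "lbigtoe",
                "neck", "midhip")
  missing <- required[!vapply(required, kp_valid, logical(1), raw = raw,
                              min_confidence = config$min_confidence)]
  if (length(missing))
    ls_abort(sprintf("insufficient keypoints (below confidence %.2f): %s",
                     config$min_confidence, paste(missing, collapse = ", ")),
             "insufficient_keypoints")

  s <- if (!is.null(config$scale)) config$scale
       else estimate_scale(raw, model, config$min_confidence)
  ysign <- if (config$flip_y) -1 else 1
  w <- function(name) {
    p <- kp_xy(raw, name)
    c(p[1L] * s, ysign * p[2L] * s)
  }

  legs <- list(
    r = list(hip = w("rhip"), knee = w("rknee"), ankle = w("rankle"),
             heel = w("rheel"), toe = w("rbigtoe")),
    l = list(hip = w("lhip"), knee = w("lknee"), ankle = w("lankle"),
             heel = w("lheel"), toe = w("lbigtoe")))
  trunk <- (w("neck") + w("midhip")) / 2

  # ground line: lowest heel/toe maps to y = 0
  foot_ys <- unlist(lapply(legs, function(L) c(L$heel[2L], L$toe[2L])))
  ground <- min(foot_ys)
  shift <- function(p) c(p[1L], p[2L] - ground)
  legs <- lapply(legs, function(L) lapply(L, shift))
  trunk <- shift(trunk)

  tol <- config$ground_tolerance
  grounded <- vapply(legs, function(L)
    L$heel[2L] <= tol && L$toe[2L] <= tol, logical(1))

  forced <- config$support != "auto"
  if (config$support == "auto") {
    support <- if (all(grounded)) "double"
      else if (!any(grounded))
        ls_abort("no foot is in ground contact; cannot analyze support",
                 "no_support")
      else "single" # resolved to hind/front after leg assignment
  } else {
    # forcing a support state tolerates larger foot-height discrepancies,
    # but a clearly airborne foot still refuses the interpretation
    relaxed <- max(0.1, 5 * tol)
    near <- vapply(legs, function(L)
      L$heel[2L] <= relaxed && L$toe[2L] <= relaxed, logical(1))
    if (config$support == "double" && !all(near))
      ls_abort(sprintf(
        "support forced to 'double' but a foot is %.2f m above the ground",
        max(unlist(lapply(legs, function(L) min(L$heel[2L], L$toe[2L]))))),
        "no_support")
    support <- config$support
  }

  # facing: heel -> toe direction of grounded feet (or both if forced)
  facing <- config$facing
  if (is.null(facing)) {
    use <- if (any(grounded)) legs[grounded] else legs
    dx <- mean(vapply(use, function(L) L$toe[1L] - L$heel[1L], numeric(1)))
    if (dx == 0)
      ls_abort("cannot infer facing direction from foot orientation",
               "degenerate_pose")
    facing <- sign(dx)
  }

  # hind/front assignment: hind is the leg whose midfoot trails along facing
  midfoot_x <- vapply(legs, function(L) mean(c(L$heel[1L], L$toe[1L])),
                      numeric(1))
  hind_key <- names(which.min(facing * midfoot_x))
  front_key <- setdiff(names(legs), hind_key)
  if (support == "single")
    support <- if (grounded[[hind_key]]) "single_hind" else "single_front"

  posture(hind = legs[[hind_key]], front = legs[[front_key]],
          trunk_anchor = trunk, support_state = support,
          facing_sign = facing, ground_tolerance = tol,
          check_ground = !forced)
}

#' Select the best-detected person in a pose file
#'
#' @param poses List of [raw_pose()] as returned by [read_pose_file()].
#' @return The `raw_pose` with the highest mean keypoint confidence.
#' @export
select_person <- function(poses) {
  if (!length(poses))
    ls_abort("pose file contains no people", "no_people")
  conf <- vapply(poses, function(p) mean(p$keypoints[, "confidence"]),
                 numeric(1))
  best <- which.max(conf)
  if (length(poses) > 1L)
    message(sprintf("pose file contains %d people; using person %d (mean confidence %.2f)",
                    length(poses), best, conf[best]))
  poses[[best]]
}
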