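# Synthetic sagittal scenes with analytically known ground truth: the
# stand-in for artwork-derived keypoints. Geometry is built by forward
# kinematics from the ground up (stance legs) or from the hip down (swing
# leg); the trunk anchor is then placed in closed form so the whole-body CoM
# achieves the requested hind-leg weight share. Ground-truth joint loads are
# computed by distal-chain aggregation with moments taken about the joint —
# a formulation independent of the per-segment CoM-referenced recursion in
# solve_limb() — and verified by the equilibrium oracle before the scene is
# returned.

# hind vertical GRF share that reproduces the reference double-support split
# (674.5038 N of a 981 N body weight)
.ls_reference_hind_share <- 674.5038 / 981

# Preset tilt angles (degrees from vertical, + toward +x), chosen once so
# the presets emulate the two stance families: readiness with the hind knee
# flexed ~33 deg and the front leg nearly straight, kick with a near-vertical
# stance leg. The stance knee-moment magnitudes they induce sit near the
# reference values for these posture families (readiness knee ~47 N m, kick
# stance knee ~66 N m).
.ls_preset_angles <- list(
  readiness = list(hind = c(shank = 23, thigh = -10),
                   front = c(shank = -25, thigh = -21)),
  kick = list(hind = c(shank = 3, thigh = -3),
              front = c(thigh = 85, shank = 100)))

#' Scene generation parameters
#'
#' @param preset `"readiness"` (double support, CoM biased toward the hind
#'   foot), `"kick"` (single support on the hind leg, front leg extended in
#'   a heel-leading kick) or `"custom"` (double support with caller-supplied
#'   joint angles).
#' @param stance_width Horizontal distance between the heels in meters
#'   (double support only).
#' @param com_bias Target hind-leg share of the vertical load, in (0, 1)
#'   (double support only). Defaults to `674.5038 / 981`, the reference
#'   double-support split.
#' @param joint_angles Optional per-leg tilt angles in degrees from the
#'   vertical (positive toward +x): a list with entries `hind` and `front`,
#'   each a named vector with `shank` and `thigh`.
#' @param seed Integer seed driving any pixel noise (see `noise_sigma`).
#' @param noise_sigma Standard deviation, in pixels, of i.i.d. Gaussian
#'   jitter applied to rendered keypoints by [write_pose_file()]; 0 renders
#'   exact coordinates.
#' @return A list of class `scene_params`.
#' @export
scene_params <- function(preset = c("readiness", "kick", "custom"),
                         stance_width = 0.55,
                         com_bias = .ls_reference_hind_share,
                         joint_angles = NULL, seed = 1L, noise_sigma = 0) {
  preset <- match.arg(preset)
  if (!is_number(stance_width) || stance_width <= 0)
    ls_abort("stance_width must be > 0", "validation")
  if (!is_number(com_bias) || com_bias <= 0 || com_bias >= 1)
    ls_abort("com_bias must be in (0, 1)", "validation")
  if (!is_number(noise_sigma) || noise_sigma < 0)
    ls_abort("noise_sigma must be >= 0", "validation")
  if (preset == "custom" && is.null(joint_angles))
    ls_abort("preset 'custom' requires joint_angles", "validation")
  if (is.null(joint_angles)) joint_angles <- .ls_preset_angles[[preset]]
  structure(list(preset = preset, stance_width = stance_width,
                 com_bias = com_bias, joint_angles = joint_angles,
                 seed = as.integer(seed), noise_sigma = noise_sigma),
            class = "scene_params")
}

# A grounded leg built from the heel up: flat foot (heel and toe on the
# ground, ankle raised), then shank and thigh by tilt angles from vertical.
flat_foot_leg <- function(heel_x, shank_tilt, thigh_tilt, model) {
  r <- model$stature / .ls_reference_stature
  Lf <- model$segments$foot$length
  Ls <- model$segments$shank$length
  Lt <- model$segments$thigh$length
  ankle <- c(heel_x + 0.04 * r, 0.08 * r)
  toe <- c(ankle[1L] + sqrt(Lf^2 - ankle[2L]^2), 0)
  ts <- shank_tilt * pi / 180
  tt <- thigh_tilt * pi / 180
  knee <- ankle + Ls * c(sin(ts), cos(ts))
  hip <- knee + Lt * c(sin(tt), cos(tt))
  list(hip = hip, knee = knee, ankle = ankle, heel = c(heel_x, 0), toe = toe)
}

# The swing (kicking) leg built from the hip down, foot dorsiflexed with the
# heel as the leading edge.
swing_leg <- function(hip, thigh_tilt, shank_tilt, model) {
  r <- model$stature / .ls_reference_stature
  Lf <- model$segments$foot$length
  Ls <- model$segments$shank$length
  Lt <- model$segments$thigh$length
  tt <- thigh_tilt * pi / 180
  ts <- shank_tilt * pi / 180
  knee <- hip + Lt * c(sin(tt), cos(tt))
  ankle <- knee + Ls * c(sin(ts), cos(ts))
  toe_dir <- c(-0.2, -0.98)
  toe <- ankle + Lf * toe_dir / vnorm(toe_dir)
  heel <- ankle + c(0.07, 0.04) * r
  list(hip = hip, knee = knee, ankle = ankle, heel = heel, toe = toe)
}

# Place the HAT lump so the whole-body CoM x hits target_cx (closed form
# from the mass-point linear system).
solve_trunk_anchor <- function(legs, target_cx, model) {
  axes <- list(foot = c("ankle", "toe"), shank = c("knee", "ankle"),
               thigh = c("hip", "knee"))
  mx <- 0
  for (leg in legs) {
    for (seg in names(axes)) {
      sp <- model$segments[[seg]]
      p <- segment_com_point(leg[[axes[[seg]][1L]]], leg[[axes[[seg]][2L]]],
                             sp$com_fraction)
      mx <- mx + sp$mass_fraction * model$total_mass * p[1L]
    }
  }
  m_hat <- model$residual_mass_fraction * model$total_mass
  tx <- (model$total_mass * target_cx - mx) / m_hat
  hip_x <- mean(vapply(legs, function(l) l$hip[1L], numeric(1)))
  if (abs(tx - hip_x) > 0.6)
    ls_abort(sprintf(
      "infeasible scene: com_bias requires the trunk anchor at x = %.3f m, %.2f m away from the hips",
      tx, abs(tx - hip_x)), "infeasible_scene")
  hip_y <- mean(vapply(legs, function(l) l$hip[2L], numeric(1)))
  c(tx, hip_y + 0.30 * model$stature / .ls_reference_stature)
}

# ground-truth joint loads of one limb by distal-chain aggregation: the
# joint force balances every external load distal to the joint, and the
# joint moment is minus the net moment of those loads about the joint point
direct_limb_truth <- function(posture, side, contact, model) {
  leg <- posture[[side]]
  sp <- model$segments
  W <- function(seg) sp[[seg]]$mass_fraction * model$total_mass * model$g
  ext <- list(
    foot = list(force = c(0, -W("foot")),
                point = segment_com_point(leg$ankle, leg$toe,
                                          sp$foot$com_fraction)),
    shank = list(force = c(0, -W("shank")),
                 point = segment_com_point(leg$knee, leg$ankle,
                                           sp$shank$com_fraction)),
    thigh = list(force = c(0, -W("thigh")),
                 point = segment_com_point(leg$hip, leg$knee,
                                           sp$thigh$com_fraction)))
  if (!is.null(contact))
    ext$grf <- list(force = contact$grf, point = contact$point)

  agg <- function(names, joint_point) {
    f <- c(0, 0); m <- 0
    for (nm in names) {
      f <- f + ext[[nm]]$force
      m <- m + cross2(ext[[nm]]$point - joint_point, ext[[nm]]$force)
    }
    list(force = -f, moment = -m)
  }
  foot_set <- intersect(c("foot", "grf"), names(ext))
  a <- agg(foot_set, leg$ankle)
  k <- agg(c(foot_set, "shank"), leg$knee)
  h <- agg(c(foot_set, "shank", "thigh"), leg$hip)
  structure(list(
    side = side,
    ankle = joint_load("ankle", a$force, a$moment, side = side),
    knee = joint_load("knee", k$force, k$moment, side = side),
    hip = joint_load("hip", h$force, h$moment, side = side),
    equilibrium_residuals = NULL), class = "limb_solution")
}

# truth loads + oracle verification for any consistent posture
scene_truth <- function(posture, model, contact = "midfoot") {
  com <- total_com(body_mass_points(posture, model))
  Pt <- model$total_mass * model$g
  if (posture$support_state == "double") {
    xh <- contact_x(posture$hind, contact)
    xf <- contact_x(posture$front, contact)
    cx <- com$com[1L]
    if (cx < min(xh, xf) - 1e-12 || cx > max(xh, xf) + 1e-12)
      ls_abort("scene CoM falls outside the base of support", "out_of_base")
    L1 <- abs(cx - xh); L2 <- abs(xf - cx)
    gy1 <- Pt * L2 / (L1 + L2)
    gx1 <- posture$facing_sign * model$friction_coefficient * gy1
    grf <- new_grf_solution(
      hind = ground_contact(c(xh, 0), c(gx1, gy1)),
      front = ground_contact(c(xf, 0), c(-gx1, Pt - gy1)),
      L1 = L1, L2 = L2, Ptotal = Pt, hind_share = gy1 / Pt,
      contact = contact)
  } else {
    stance <- if (posture$support_state == "single_hind") "hind" else "front"
    leg <- posture[[stance]]
    cx <- com$com[1L]
    ext <- range(leg$heel[1L], leg$toe[1L])
    if (cx < ext[1L] - 1e-12 || cx > ext[2L] + 1e-12)
      ls_abort("scene CoM falls outside the stance foot", "out_of_base")
    gc <- ground_contact(c(cx, 0), c(0, Pt))
    grf <- if (stance == "hind")
      new_grf_solution(gc, NULL, 0, 0, Pt, 1, "cop")
    else new_grf_solution(NULL, gc, 0, 0, Pt, 0, "cop")
  }
  limbs <- list(
    hind = direct_limb_truth(posture, "hind", grf$hind, model),
    front = direct_limb_truth(posture, "front", grf$front, model))
  reports <- check_scene(posture, model, grf, limbs)
  # fill per-segment residuals from the oracle reports
  for (side in names(limbs)) {
    res <- t(vapply(c("foot", "shank", "thigh"), function(seg) {
      r <- Filter(function(x) x$body_id == sprintf("%s_%s", side, seg),
                  reports)[[1L]]
      c(force = vnorm(r$net_force), moment = abs(r$net_moment))
    }, numeric(2)))
    limbs[[side]]$equilibrium_residuals <- res
  }
  if (!all_balanced(reports))
    ls_abort("internal error: generated scene failed its own equilibrium check",
             "validation")
  list(com = com, grf = grf, limbs = limbs, oracle = reports)
}

#' Generate a synthetic scene with known ground truth
#'
#' Deterministic for given parameters (randomness only enters later, through
#' pixel noise in [write_pose_file()] / [perturb_scene()]). The returned
#' truth loads have passed the full equilibrium oracle.
#'
#' @param params A [scene_params()].
#' @param model An [build_model()] result.
#' @return An object of class `synthetic_scene` with fields `params`,
#'   `model`, `posture`, `com`, `truth_grf`, `truth_limbs` and `oracle`.
#' @export
generate_scene <- function(params = scene_params(), model = build_model()) {
  stopifnot(inherits(params, "scene_params"),
            inherits(model, "anthropometric_model"))
  ja <- params$joint_angles
  if (params$preset %in% c("readiness", "custom")) {
    hind <- flat_foot_leg(0, ja$hind[["shank"]], ja$hind[["thigh"]], model)
    front <- flat_foot_leg(params$stance_width, ja$front[["shank"]],
                           ja$front[["thigh"]], model)
    xh <- contact_x(hind, "midfoot")
    xf <- contact_x(front, "midfoot")
    target_cx <- xf - params$com_bias * (xf - xh)
    trunk <- solve_trunk_anchor(list(hind, front), target_cx, model)
    pos <- posture(hind, front, trunk, "double", facing_sign = 1)
  } else { # kick: single support on the hind (stance) leg
    stance <- flat_foot_leg(0, ja$hind[["shank"]], ja$hind[["thigh"]], model)
    swing_hip <- stance$hip + c(0.03, 0.02) * model$stature /
      .ls_reference_stature
    swing <- swing_leg(swing_hip, ja$front[["thigh"]], ja$front[["shank"]],
                       model)
    target_cx <- contact_x(stance, "midfoot")
    trunk <- solve_trunk_anchor(list(stance, swing), target_cx, model)
    pos <- posture(stance, swing, trunk, "single_hind", facing_sign = 1)
  }
  truth <- scene_truth(pos, model)
  structure(list(params = params, model = model, posture = pos,
                 com = truth$com, truth_grf = truth$grf,
                 truth_limbs = truth$limbs, oracle = truth$oracle),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: preset '%s', support %s, hind share %.4f\n",
              x$params$preset, x$posture$support_state,
              x$truth_grf$hind_share))
  invisible(x)
}

#' Write a scene as a BODY_25 keypoint file
#'
#' Renders the posture into y-down pixel coordinates at `render` pixels per
#' meter (with `y_px = image_height - y_world * render`) and writes the
#' standard keypoint JSON dialect. Rendered keypoints get confidence 0.95;
#' keypoints the scene does not model (head, arms, small toes) get 0.
#' Gaussian pixel noise of `params$noise_sigma` is applied under the scene's
#' seed, so the writer is deterministic for a given scene.
#'
#' @param scene A [generate_scene()] result.
#' @param path Output file path.
#' @param render Pixels per meter (> 0).
#' @param image_height Image height in pixels used for the y-axis flip.
#' @return `path`, invisibly.
#' @export
write_pose_file <- function(scene, path, render = 100,
                            image_height = round(2.2 * render)) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!is_number(render) || render <= 0)
    ls_abort("render must be > 0 (pixels per meter)", "validation")
  pos <- scene$posture
  px <- function(p) c(p[1L] * render, image_height - p[2L] * render)

  # hind leg rendered as the anatomical right, front as the left
  midhip <- (pos$hind$hip + pos$front$hip) / 2
  neck <- 2 * pos$trunk_anchor - midhip
  pts <- list(
    neck = neck, midhip = midhip,
    rhip = pos$hind$hip, rknee = pos$hind$knee, rankle = pos$hind$ankle,
    rheel = pos$hind$heel, rbigtoe = pos$hind$toe,
    lhip = pos$front$hip, lknee = pos$front$knee, lankle = pos$front$ankle,
    lheel = pos$front$heel, lbigtoe = pos$front$toe)

  kp <- matrix(0, nrow = 25L, ncol = 3L)
  for (nm in names(pts)) {
    kp[kp_row(nm), 1:2] <- px(pts[[nm]])
    kp[kp_row(nm), 3L] <- 0.95
  }
  if (scene$params$noise_sigma > 0) {
    rows <- vapply(names(pts), kp_row, integer(1))
    noise <- with_private_seed(scene$params$seed,
      matrix(rnorm(2L * length(rows), sd = scene$params$noise_sigma),
             ncol = 2L))
    kp[rows, 1:2] <- kp[rows, 1:2] + noise
  }
  doc <- list(version = 1.3,
              people = list(list(pose_keypoints_2d = as.vector(t(kp)))))
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    ls_abort(sprintf("cannot write pose file '%s': %s", path,
                     conditionMessage(ok)), "io")
  invisible(path)
}

#' Perturb a scene with keypoint noise
#'
#' Applies i.i.d. Gaussian jitter (standard deviation `sigma` pixels) to the
#' rendered keypoints, re-calibrates the jittered pose, and recomputes the
#' ground-truth loads for the perturbed geometry. `sigma = 0` returns the
#' scene unchanged.
#'
#' @param scene A [generate_scene()] result.
#' @param sigma Noise standard deviation in pixels (>= 0).
#' @param seed Integer seed for the jitter.
#' @param render Pixels per meter used for the intermediate rendering.
#' @return A new `synthetic_scene` with jittered posture and fresh truth.
#' @export
perturb_scene <- function(scene, sigma, seed = scene$params$seed,
                          render = 100) {
  stopifnot(inherits(scene, "synthetic_scene"))
  if (!is_number(sigma) || sigma < 0)
    ls_abort("sigma must be >= 0", "validation")
  if (sigma == 0) return(scene)
  params <- scene$params
  params$noise_sigma <- sigma
  params$seed <- as.integer(seed)
  noisy <- scene
  noisy$params <- params
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_pose_file(noisy, path, render = render)
  raw <- read_pose_file(path)[[1L]]
  support <- if (scene$posture$support_state == "double") "double"
             else scene$posture$support_state
  pos <- calibrate(raw, scene$model, calibration_config(
    support = support, facing = scene$posture$facing_sign))
  truth <- scene_truth(pos, scene$model,
                       contact = if (identical(scene$truth_grf$contact, "cop"))
                         "midfoot" else scene$truth_grf$contact)
  structure(list(params = params, model = scene$model, posture = pos,
                 com = truth$com, truth_grf = truth$grf,
                 truth_limbs = truth$limbs, oracle = truth$oracle),
            class = "synthetic_scene")
}
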