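# Segment-by-segment static recursion over one lower limb. Each segment is
# isolated as a free body; the unknown proximal joint force and moment are
# the unique loads closing its force and moment balances. Moments are taken
# about the segment CoM with a single CCW-positive r x F convention; the
# reaction transmitted to the next segment enters with flipped sign.

#' Joint load constructor
#'
#' The force and free moment exerted *on the distal segment* at a joint, in
#' the world frame, CCW-positive. Reporting the same load on the adjacent
#' proximal segment negates both (action-reaction).
#'
#' @param joint `"ankle"`, `"knee"` or `"hip"`.
#' @param force Length-2 force vector in newtons.
#' @param moment Scalar moment in newton-meters, CCW-positive.
#' @param side `"hind"` or `"front"` (used for wiring checks).
#' @return An object of class `joint_load`.
#' @export
joint_load <- function(joint = c("ankle", "knee", "hip"), force, moment,
                       side = NA_character_) {
  joint <- match.arg(joint)
  force <- as_point(force, "force")
  if (!is_number(moment))
    ls_abort("moment must be a finite number", "validation")
  structure(list(joint = joint, force = force, moment = moment, side = side),
            class = "joint_load")
}

#' Segment free body constructor
#'
#' @param name `"foot"`, `"shank"` or `"thigh"`.
#' @param proximal_joint,distal_joint Length-2 joint points (for the foot the
#'   distal point is the toe; for the swing foot there is no distal joint
#'   proper, the toe still defines the segment axis).
#' @param com Length-2 segment CoM point; if `NULL` it is placed on the
#'   proximal-to-distal axis at `com_fraction`.
#' @param weight Scalar segment weight in newtons (>= 0; zero is allowed for
#'   constructed test bodies).
#' @param external Optional [ground_contact()] acting on the segment.
#' @param side `"hind"` or `"front"`.
#' @param com_fraction CoM fraction used when `com` is `NULL`.
#' @return An object of class `segment_free_body`.
#' @export
segment_free_body <- function(name = c("foot", "shank", "thigh"),
                              proximal_joint, distal_joint, com = NULL,
                              weight, external = NULL,
                              side = NA_character_, com_fraction = 0.5) {
  name <- match.arg(name)
  proximal_joint <- as_point(proximal_joint, "proximal_joint")
  distal_joint <- as_point(distal_joint, "distal_joint")
  if (!is_number(weight) || weight < 0)
    ls_abort("weight must be a non-negative number", "validation")
  if (is.null(com))
    com <- segment_com_point(proximal_joint, distal_joint, com_fraction)
  com <- as_point(com, "com")
  if (!is.null(external) && !inherits(external, "ground_contact"))
    ls_abort("external must be NULL or a ground_contact", "validation")
  structure(list(name = name, proximal_joint = proximal_joint,
                 distal_joint = distal_joint, com = com, weight = weight,
                 external = external, side = side),
            class = "segment_free_body")
}

# Close the force and moment balance of one free body. `known` is a list of
# list(force =, point =) loads; `free_moments` a numeric vector of couples
# already acting on the body. Returns the joint_load at `joint_point` that
# makes net force and net moment (about `ref`) vanish.
close_free_body <- function(joint, joint_point, known, free_moments, ref,
                            side = NA_character_) {
  fsum <- c(0, 0)
  msum <- sum(free_moments)
  for (ld in known) {
    fsum <- fsum + ld$force
    msum <- msum + cross2(ld$point - ref, ld$force)
  }
  force <- -fsum
  moment <- -(msum + cross2(joint_point - ref, force))
  joint_load(joint, force, moment, side = side)
}

#' Solve the foot free body for the ankle load
#'
#' Balances the foot under its weight `P1` and the ground reaction (if
#' grounded): the ankle force closes the force sums and the ankle moment is
#' the unique couple closing the moment balance about the foot CoM.
#'
#' @param fb A [segment_free_body()] with `name = "foot"`; `external` must be
#'   present iff the foot is grounded.
#' @return A [joint_load()] at the ankle, acting on the foot.
#' @export
solve_foot <- function(fb) {
  stopifnot(inherits(fb, "segment_free_body"))
  if (fb$name != "foot")
    ls_abort("solve_foot expects a foot free body", "wiring")
  known <- list(list(force = c(0, -fb$weight), point = fb$com))
  if (!is.null(fb$external))
    known <- c(known, list(list(force = fb$external$grf,
                                point = fb$external$point)))
  close_free_body("ankle", fb$proximal_joint, known, numeric(0), fb$com,
                  side = fb$side)
}

# shared logic of shank (ankle load in, knee out) and thigh (knee in, hip out)
solve_intermediate <- function(fb, distal_load, expect_name, expect_joint,
                               out_joint) {
  stopifnot(inherits(fb, "segment_free_body"),
            inherits(distal_load, "joint_load"))
  if (fb$name != expect_name || distal_load$joint != expect_joint)
    ls_abort(sprintf("expected a %s free body with an %s load", expect_name,
                     expect_joint), "wiring")
  if (!is.na(fb$side) && !is.na(distal_load$side) &&
      fb$side != distal_load$side)
    ls_abort(sprintf("limb sides do not match: free body '%s' vs load '%s'",
                     fb$side, distal_load$side), "wiring")
  # reaction of the distal segment on this one: negated force and moment,
  # applied at the shared (distal) joint
  known <- list(
    list(force = c(0, -fb$weight), point = fb$com),
    list(force = -distal_load$force, point = fb$distal_joint))
  close_free_body(out_joint, fb$proximal_joint, known, -distal_load$moment,
                  fb$com, side = fb$side)
}

#' Solve the shank free body for the knee load
#'
#' The ankle load enters negated (reaction on the shank) together with the
#' transferred ankle couple; the knee force and moment close the balance
#' with the shank weight `P2`.
#'
#' @param fb A [segment_free_body()] with `name = "shank"` (proximal = knee,
#'   distal = ankle).
#' @param ankle_load The [joint_load()] from [solve_foot()] of the same limb.
#' @return A [joint_load()] at the knee, acting on the shank.
#' @export
solve_shank <- function(fb, ankle_load)
  solve_intermediate(fb, ankle_load, "shank", "ankle", "knee")

#' Solve the thigh free body for the hip load
#'
#' Exactly analogous to [solve_shank()] with the thigh weight `P3` and the
#' hip joint.
#'
#' @param fb A [segment_free_body()] with `name = "thigh"` (proximal = hip,
#'   distal = knee).
#' @param knee_load The [joint_load()] from [solve_shank()] of the same limb.
#' @return A [joint_load()] at the hip, acting on the thigh.
#' @export
solve_thigh <- function(fb, knee_load)
  solve_intermediate(fb, knee_load, "thigh", "knee", "hip")

# Build the three free bodies of one limb from a posture + model.
limb_free_bodies <- function(posture, side, model, external = NULL) {
  leg <- posture[[side]]
  sp <- model$segments
  list(
    foot = segment_free_body(
      "foot", leg$ankle, leg$toe,
      com = segment_com_point(leg$ankle, leg$toe, sp$foot$com_fraction),
      weight = segment_weight(model, "foot"), external = external,
      side = side),
    shank = segment_free_body(
      "shank", leg$knee, leg$ankle,
      com = segment_com_point(leg$knee, leg$ankle, sp$shank$com_fraction),
      weight = segment_weight(model, "shank"), side = side),
    thigh = segment_free_body(
      "thigh", leg$hip, leg$knee,
      com = segment_com_point(leg$hip, leg$knee, sp$thigh$com_fraction),
      weight = segment_weight(model, "thigh"), side = side))
}

# residual of one solved free body: net force and net moment about its CoM
free_body_residual <- function(fb, proximal_load, distal_load = NULL) {
  loads <- list(list(force = c(0, -fb$weight), point = fb$com),
                list(force = proximal_load$force, point = fb$proximal_joint))
  moments <- proximal_load$moment
  if (!is.null(fb$external))
    loads <- c(loads, list(list(force = fb$external$grf,
                                point = fb$external$point)))
  if (!is.null(distal_load)) {
    loads <- c(loads, list(list(force = -distal_load$force,
                                point = fb$distal_joint)))
    moments <- c(moments, -distal_load$moment)
  }
  f <- Reduce(`+`, lapply(loads, `[[`, "force"))
  m <- sum(moments) +
    sum(vapply(loads, function(l) cross2(l$point - fb$com, l$force),
               numeric(1)))
  c(force = vnorm(f), moment = abs(m))
}

#' Solve one limb distal-to-proximal
#'
#' Chains [solve_foot()], [solve_shank()] and [solve_thigh()] with
#' action-reaction sign flips between segments, and records per-segment
#' equilibrium residuals.
#'
#' @param posture A [posture()].
#' @param side `"hind"` or `"front"`.
#' @param grf A [ground_contact()] for this limb's foot, or `NULL` when the
#'   foot is off the ground (swing limb).
#' @param model An [build_model()] result.
#' @return An object of class `limb_solution` with [joint_load()]s `ankle`,
#'   `knee`, `hip` and a residual matrix `equilibrium_residuals`.
#' @export
solve_limb <- function(posture, side = c("hind", "front"), grf = NULL,
                       model = build_model()) {
  side <- match.arg(side)
  stopifnot(inherits(posture, "posture"),
            inherits(model, "anthropometric_model"))
  if (!is.null(grf) && !inherits(grf, "ground_contact"))
    ls_abort("grf must be NULL or a ground_contact", "validation")
  fbs <- limb_free_bodies(posture, side, model, external = grf)
  ankle <- solve_foot(fbs$foot)
  knee <- solve_shank(fbs$shank, ankle)
  hip <- solve_thigh(fbs$thigh, knee)
  res <- rbind(foot = free_body_residual(fbs$foot, ankle),
               shank = free_body_residual(fbs$shank, knee, ankle),
               thigh = free_body_residual(fbs$thigh, hip, knee))
  structure(list(side = side, ankle = ankle, knee = knee, hip = hip,
                 equilibrium_residuals = res),
            class = "limb_solution")
}

#' @export
print.limb_solution <- function(x, ...) {
  cat(sprintf("Limb solution (%s leg):\n", x$side))
  for (j in c("ankle", "knee", "hip")) {
    jl <- x[[j]]
    cat(sprintf("  %-5s F = (%8.3f, %8.3f) N   M = %8.4f N m\n",
                j, jl$force[1], jl$force[2], jl$moment))
  }
  cat(sprintf("  max residuals: force %.2e N, moment %.2e N m\n",
              max(x$equilibrium_residuals[, "force"]),
              max(x$equilibrium_residuals[, "moment"])))
  invisible(x)
}
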