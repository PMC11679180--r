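# Whole-body static equilibrium: distribution of the ground reaction force
# between the feet. In double support the vertical split follows from moment
# equilibrium about one contact, GRFy1 = Ptotal * L2 / (L1 + L2), and the
# horizontal components are friction-coupled, GRFx1 = Co * GRFy1 = -GRFx2.
# In single support the centre of pressure sits directly under the CoM.

#' Ground contact constructor
#'
#' @param point Length-2 contact point on the ground (y = 0).
#' @param grf Length-2 ground reaction force vector (newtons); the vertical
#'   component must be non-negative (the ground only pushes).
#' @return An object of class `ground_contact`.
#' @export
ground_contact <- function(point, grf) {
  point <- as_point(point, "contact point")
  grf <- as_point(grf, "grf")
  if (abs(point[2L]) > 1e-6)
    ls_abort("ground contact point must lie on the ground (y = 0)",
             "validation")
  if (grf[2L] < 0)
    ls_abort("vertical GRF must be non-negative", "validation")
  structure(list(point = point, grf = grf), class = "ground_contact")
}

contact_x <- function(leg, contact = c("midfoot", "heel", "toe")) {
  contact <- match.arg(contact)
  switch(contact,
         heel = leg$heel[1L],
         toe = leg$toe[1L],
         midfoot = mean(c(leg$heel[1L], leg$toe[1L])))
}

new_grf_solution <- function(hind, front, L1, L2, Ptotal, hind_share,
                             contact) {
  structure(list(hind = hind, front = front, L1 = L1, L2 = L2,
                 Ptotal = Ptotal, hind_share = hind_share,
                 contact = contact),
            class = "grf_solution")
}

#' Solve double-support ground reaction forces
#'
#' Distributes total body weight between the two feet from moment
#' equilibrium about one contact point: with `L1` the horizontal distance
#' from the hind contact to the CoM and `L2` from the CoM to the front
#' contact, the hind vertical GRF is `Ptotal * L2 / (L1 + L2)` and the front
#' carries the remainder. Horizontal components are friction-coupled: the
#' hind foot pushes along the facing direction with `Co` times its vertical
#' load, mirrored on the front foot so the net horizontal force is zero.
#'
#' @param posture A [posture()] in double support.
#' @param com A [total_com()] result (or any list with a `com` point).
#' @param model An [build_model()] result.
#' @param contact Where each foot's contact point sits: `"midfoot"`
#'   (default, midpoint of heel and toe), `"heel"` or `"toe"`.
#' @return A `grf_solution` with per-foot [ground_contact()]s, lever arms
#'   `L1`/`L2`, total load `Ptotal` and the hind weight share.
#' @export
solve_double_support <- function(posture, com, model,
                                 contact = c("midfoot", "heel", "toe")) {
  stopifnot(inherits(posture, "posture"),
            inherits(model, "anthropometric_model"))
  contact <- match.arg(contact)
  if (posture$support_state != "double")
    ls_abort("solve_double_support requires a double-support posture",
             "validation")
  xh <- contact_x(posture$hind, contact)
  xf <- contact_x(posture$front, contact)
  if (abs(xf - xh) < 1e-9)
    ls_abort("degenerate stance: hind and front contact points coincide",
             "degenerate_stance")
  cx <- as_point(com$com, "com")[1L]
  lo <- min(xh, xf); hi <- max(xh, xf)
  if (cx < lo - 1e-12 || cx > hi + 1e-12)
    ls_abort(sprintf(
      "CoM x = %.4f lies outside the base of support [%.4f, %.4f]; %s",
      cx, lo, hi,
      "static balance is impossible with unilateral ground contact"),
      "out_of_base")
  L1 <- abs(cx - xh)
  L2 <- abs(xf - cx)
  Pt <- body_weight(model)
  gy1 <- Pt * L2 / (L1 + L2)
  gy2 <- Pt - gy1
  gx1 <- posture$facing_sign * model$friction_coefficient * gy1
  new_grf_solution(
    hind = ground_contact(c(xh, 0), c(gx1, gy1)),
    front = ground_contact(c(xf, 0), c(-gx1, gy2)),
    L1 = L1, L2 = L2, Ptotal = Pt, hind_share = gy1 / Pt,
    contact = contact)
}

#' Solve single-support ground reaction forces
#'
#' With one foot on the ground the whole body weight passes through a single
#' contact; statics admits exactly one solution, with the centre of pressure
#' directly under the whole-body CoM and zero horizontal GRF. The CoP must
#' fall within the stance foot's heel-to-toe extent.
#'
#' @inheritParams solve_double_support
#' @return A `grf_solution` whose stance-side contact carries
#'   `(0, Ptotal)`; the swing side contact is `NULL`.
#' @export
solve_single_support <- function(posture, com, model) {
  stopifnot(inherits(posture, "posture"),
            inherits(model, "anthropometric_model"))
  if (!posture$support_state %in% c("single_hind", "single_front"))
    ls_abort("solve_single_support requires a single-support posture",
             "validation")
  stance <- if (posture$support_state == "single_hind") "hind" else "front"
  leg <- posture[[stance]]
  cx <- as_point(com$com, "com")[1L]
  ext <- range(leg$heel[1L], leg$toe[1L])
  if (cx < ext[1L] - 1e-12 || cx > ext[2L] + 1e-12)
    ls_abort(sprintf(
      "CoM x = %.4f lies outside the stance foot extent [%.4f, %.4f]",
      cx, ext[1L], ext[2L]), "out_of_base")
  Pt <- body_weight(model)
  gc <- ground_contact(c(cx, 0), c(0, Pt))
  sol <- if (stance == "hind")
    new_grf_solution(hind = gc, front = NULL, L1 = 0, L2 = 0, Ptotal = Pt,
                     hind_share = 1, contact = "cop")
  else
    new_grf_solution(hind = NULL, front = gc, L1 = 0, L2 = 0, Ptotal = Pt,
                     hind_share = 0, contact = "cop")
  sol
}

#' Coulomb friction component of a ground reaction force
#'
#' @param grf_y Vertical GRF in newtons (non-negative).
#' @param model An [build_model()] result supplying the friction coefficient.
#' @param sign Direction sign, `+1` or `-1`.
#' @return `sign * Co * grf_y` in newtons.
#' @export
friction_components <- function(grf_y, model, sign = 1) {
  stopifnot(inherits(model, "anthropometric_model"))
  if (!is_number(grf_y) || grf_y < 0)
    ls_abort("grf_y must be a non-negative number", "validation")
  if (!sign %in% c(-1, 1))
    ls_abort("sign must be +1 or -1", "validation")
  sign * model$friction_coefficient * grf_y
}

#' @export
print.grf_solution <- function(x, ...) {
  cat(sprintf("GRF solution (Ptotal %.2f N, hind share %.2f%%)\n",
              x$Ptotal, 100 * x$hind_share))
  for (side in c("hind", "front")) {
    gc <- x[[side]]
    if (is.null(gc)) next
    cat(sprintf("  %-5s contact x %.4f m: GRF (%.3f, %.3f) N\n",
                side, gc$point[1], gc$grf[1], gc$grf[2]))
  }
  invisible(x)
}
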