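# Independent brute-force equilibrium validation. This module deliberately
# re-derives every quantity it needs by direct summation (no calls into the
# GRF or limb solvers' helper paths), so that a defect in the solvers cannot
# hide in the check.

#' Net force and net moment of a load set
#'
#' Sums forces, the moments of those forces about a reference point
#' (`(p - about) x F`, CCW-positive) and any free couples.
#'
#' @param loads Non-empty list; each element is a list with either
#'   `force` (length-2) and `point` (length-2), or a scalar `moment`
#'   (a free couple), or both.
#' @param about Length-2 reference point for the moment sum.
#' @return A list with `force` (length-2 newtons) and `moment` (scalar
#'   newton-meters).
#' @export
net_load <- function(loads, about = c(0, 0)) {
  if (!is.list(loads) || !length(loads))
    ls_abort("loads must be a non-empty list", "validation")
  about <- as_point(about, "about")
  f <- c(0, 0)
  m <- 0
  for (ld in loads) {
    if (!is.null(ld$force)) {
      fo <- as_point(ld$force, "force")
      p <- as_point(ld$point, "point")
      f <- f + fo
      m <- m + cross2(p - about, fo)
    }
    if (!is.null(ld$moment)) {
      if (!is_number(ld$moment))
        ls_abort("free moment must be a finite number", "validation")
      m <- m + ld$moment
    }
  }
  list(force = f, moment = m)
}

equilibrium_report <- function(body_id, nl, about, tol_F, tol_M) {
  passed <- vnorm(nl$force) < tol_F && abs(nl$moment) < tol_M
  structure(list(body_id = body_id, net_force = nl$force,
                 about = about, net_moment = nl$moment, passed = passed),
            class = "equilibrium_report")
}

# interpolation along a segment axis, kept local so the oracle does not
# share code with segment_com_point
.oracle_lerp <- function(a, b, f) a + f * (b - a)

#' Check a full scene for static equilibrium
#'
#' Builds one equilibrium report per solved segment free body (foot, shank,
#' thigh of each limb present in `limbs`) plus one whole-body report (all
#' ground reactions plus the gravity of every mass point), each by direct
#' summation of the external loads. Failures are reported, never raised.
#'
#' @param posture A [posture()].
#' @param model An [build_model()] result.
#' @param grf A `grf_solution` (or `NULL` to skip ground reactions).
#' @param limbs Named list of `limb_solution`s keyed `"hind"`/`"front"`
#'   (may be empty: then only the whole-body report is produced).
#' @param tol_F,tol_M Absolute tolerances in newtons / newton-meters.
#' @return A list of `equilibrium_report`s.
#' @export
check_scene <- function(posture, model, grf = NULL, limbs = list(),
                        tol_F = 1e-8, tol_M = 1e-8) {
  stopifnot(inherits(posture, "posture"),
            inherits(model, "anthropometric_model"))
  reports <- list()
  Mtot <- model$total_mass
  gg <- model$g

  axes <- list(foot = c("ankle", "toe"), shank = c("knee", "ankle"),
               thigh = c("hip", "knee"))
  joints <- list(foot = "ankle", shank = "knee", thigh = "hip")

  for (side in names(limbs)) {
    sol <- limbs[[side]]
    leg <- posture[[side]]
    contact <- if (!is.null(grf)) grf[[side]] else NULL
    prev <- NULL # distal joint load transmitted into the current segment
    for (seg in c("foot", "shank", "thigh")) {
      sp <- model$segments[[seg]]
      prox <- leg[[axes[[seg]][1L]]]
      dist <- leg[[axes[[seg]][2L]]]
      comp <- .oracle_lerp(prox, dist, sp$com_fraction)
      w <- sp$mass_fraction * Mtot * gg
      jl <- sol[[joints[[seg]]]]
      loads <- list(
        list(force = c(0, -w), point = comp),
        list(force = jl$force, point = prox, moment = jl$moment))
      if (seg == "foot" && !is.null(contact))
        loads <- c(loads, list(list(force = contact$grf,
                                    point = contact$point)))
      if (!is.null(prev))
        loads <- c(loads, list(list(force = -prev$force, point = dist,
                                    moment = -prev$moment)))
      nl <- net_load(loads, about = prox)
      reports[[length(reports) + 1L]] <- equilibrium_report(
        sprintf("%s_%s", side, seg), nl, prox, tol_F, tol_M)
      prev <- jl
    }
  }

  # whole body: ground reactions + per-mass-point gravity (no CoM shortcut)
  wb <- list()
  if (!is.null(grf)) {
    for (side in c("hind", "front")) {
      gc <- grf[[side]]
      if (!is.null(gc))
        wb <- c(wb, list(list(force = gc$grf, point = gc$point)))
    }
  }
  for (side in c("hind", "front")) {
    leg <- posture[[side]]
    for (seg in names(axes)) {
      sp <- model$segments[[seg]]
      p <- .oracle_lerp(leg[[axes[[seg]][1L]]], leg[[axes[[seg]][2L]]],
                        sp$com_fraction)
      wb <- c(wb, list(list(force = c(0, -sp$mass_fraction * Mtot * gg),
                            point = p)))
    }
  }
  wb <- c(wb, list(list(
    force = c(0, -model$residual_mass_fraction * Mtot * gg),
    point = posture$trunk_anchor)))
  nl <- net_load(wb, about = c(0, 0))
  reports[[length(reports) + 1L]] <- equilibrium_report(
    "whole_body", nl, c(0, 0), tol_F, tol_M)
  reports
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat(sprintf("%-12s |F| = %.3e N, M = %+.3e N m about (%.3f, %.3f): %s\n",
              x$body_id, vnorm(x$net_force), x$net_moment, x$about[1],
              x$about[2], if (x$passed) "ok" else "FAIL"))
  invisible(x)
}

#' Did every equilibrium report pass?
#'
#' @param reports List of reports from [check_scene()].
#' @return Single logical.
#' @export
all_balanced <- function(reports)
  all(vapply(reports, function(r) isTRUE(r$passed), logical(1)))
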