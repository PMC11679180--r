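# Segmental and whole-body centre of mass: the mass-weighted mean of the
# segment CoM points, CoM = sum(m_i p_i) / sum(m_i), evaluated per component.

#' Mass points of a posture
#'
#' Decomposes the body into 7 point masses: foot, shank and thigh of each
#' leg, placed at their segment centre-of-mass points (foot axis ankle->toe,
#' shank knee->ankle, thigh hip->knee, each at the model's CoM fraction from
#' the proximal end), plus the lumped head-arms-trunk (HAT) residual mass at
#' the posture's trunk anchor. The masses sum to the model's total mass by
#' construction.
#'
#' @param posture A [posture()].
#' @param model An [build_model()] result.
#' @return A data frame with columns `label`, `side`, `x`, `y`, `mass`.
#' @export
body_mass_points <- function(posture, model) {
  stopifnot(inherits(posture, "posture"),
            inherits(model, "anthropometric_model"))
  rows <- list()
  for (side in c("hind", "front")) {
    leg <- posture[[side]]
    axes <- list(foot = c("ankle", "toe"), shank = c("knee", "ankle"),
                 thigh = c("hip", "knee"))
    for (seg in names(axes)) {
      sp <- model$segments[[seg]]
      p <- segment_com_point(leg[[axes[[seg]][1L]]], leg[[axes[[seg]][2L]]],
                             sp$com_fraction)
      rows[[length(rows) + 1L]] <- data.frame(
        label = seg, side = side, x = p[1L], y = p[2L],
        mass = sp$mass_fraction * model$total_mass)
    }
  }
  rows[[length(rows) + 1L]] <- data.frame(
    label = "hat", side = "trunk",
    x = posture$trunk_anchor[1L], y = posture$trunk_anchor[2L],
    mass = model$residual_mass_fraction * model$total_mass)
  do.call(rbind, rows)
}

#' Whole-body centre of mass
#'
#' @param points A data frame with columns `x`, `y`, `mass` (e.g. from
#'   [body_mass_points()]); all masses must be positive.
#' @return An object of class `com_result` with fields `com` (length-2
#'   point), `total_mass`, and `contributions` (the input data frame).
#' @export
total_com <- function(points) {
  if (!is.data.frame(points) || nrow(points) == 0L ||
      !all(c("x", "y", "mass") %in% names(points)))
    ls_abort("points must be a non-empty data frame with columns x, y, mass",
             "validation")
  if (anyNA(points[c("x", "y", "mass")]) || any(points$mass <= 0))
    ls_abort("all mass-point masses must be positive and coordinates finite",
             "validation")
  m <- sum(points$mass)
  com <- c(sum(points$mass * points$x), sum(points$mass * points$y)) / m
  structure(list(com = com, total_mass = m, contributions = points),
            class = "com_result")
}

#' @export
print.com_result <- function(x, ...) {
  cat(sprintf("CoM: (%.4f, %.4f) m over %.1f kg in %d mass points\n",
              x$com[1], x$com[2], x$total_mass, nrow(x$contributions)))
  invisible(x)
}
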