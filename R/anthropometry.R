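# Anthropometric model of the hypothetical athlete: segment lengths from the
# simulation table (foot 24 cm, shank 48 cm, thigh 50 cm at 1.85 m stature)
# and normative relative masses / CoM locations (Winter-style tables).

.ls_reference_stature <- 1.85
.ls_default_lengths <- c(foot = 0.24, shank = 0.48, thigh = 0.50)
.ls_default_mass_fractions <- c(foot = 0.017, shank = 0.047, thigh = 0.107)
.ls_default_com_fractions <- c(foot = 0.434, shank = 0.420, thigh = 0.439)

.ls_segment_names <- c("foot", "shank", "thigh")

#' Specification of one lower-limb segment
#'
#' A `segment_spec` bundles the metric length of a segment with its mass as a
#' fraction of total body mass and the location of its centre of mass as a
#' fraction of segment length measured from the proximal end.
#'
#' @param name One of `"foot"`, `"shank"`, `"thigh"`.
#' @param length Segment length in meters; must be positive.
#' @param mass_fraction Fraction of total body mass, in (0, 1).
#' @param com_fraction CoM location as a fraction of segment length from the
#'   proximal end, in (0, 1).
#' @return An object of class `segment_spec`.
#' @export
segment_spec <- function(name, length, mass_fraction, com_fraction) {
  name <- match.arg(name, .ls_segment_names)
  if (!is_number(length) || length <= 0)
    ls_abort(sprintf("segment '%s': length must be > 0", name), "validation")
  if (!is_number(mass_fraction) || mass_fraction <= 0 || mass_fraction >= 1)
    ls_abort(sprintf("segment '%s': mass_fraction must be in (0, 1)", name),
             "validation")
  if (!is_number(com_fraction) || com_fraction <= 0 || com_fraction >= 1)
    ls_abort(sprintf("segment '%s': com_fraction must be in (0, 1)", name),
             "validation")
  structure(list(name = name, length = length,
                 mass_fraction = mass_fraction, com_fraction = com_fraction),
            class = "segment_spec")
}

#' Build the scaled anthropometric model
#'
#' Constructs the bilaterally symmetric lower-limb anthropometric model used
#' throughout the package: per-segment lengths, mass fractions and CoM
#' fractions for foot, shank and thigh, plus a single lumped head-arms-trunk
#' (HAT) residual mass carrying the remainder of body mass. Default segment
#' lengths correspond to a 1.85 m stature (foot 0.24 m, shank 0.48 m, thigh
#' 0.50 m) and scale linearly with `stature`; mass and CoM fractions are
#' normative and stature-independent.
#'
#' @param stature Body height in meters (> 0).
#' @param total_mass Total body mass in kilograms (> 0).
#' @param overrides Optional named list of parameter overrides. Recognized
#'   top-level keys: `mu` (or `friction_coefficient`), `g`, and one list per
#'   segment name (`foot`, `shank`, `thigh`) with any of `length`,
#'   `mass_fraction`, `com_fraction`.
#' @return An object of class `anthropometric_model` with fields `stature`,
#'   `total_mass`, `g`, `friction_coefficient`, `segments` (named list of
#'   [segment_spec()]s shared by both sides) and `residual_mass_fraction`.
#' @examples
#' m <- build_model(1.85, 100)
#' m$segments$thigh$length          # 0.50 m
#' segment_weight(m, "foot")        # 16.677 N
#' @export
build_model <- function(stature = 1.85, total_mass = 100, overrides = NULL) {
  if (!is_number(stature) || stature <= 0)
    ls_abort("stature must be a positive number (meters)", "validation")
  if (!is_number(total_mass) || total_mass <= 0)
    ls_abort("total_mass must be a positive number (kilograms)", "validation")
  if (!is.null(overrides) && !is.list(overrides))
    ls_abort("overrides must be a named list", "validation")

  mu <- 0.3
  g <- 9.81
  if (!is.null(overrides$mu)) mu <- overrides$mu
  if (!is.null(overrides$friction_coefficient))
    mu <- overrides$friction_coefficient
  if (!is.null(overrides$g)) g <- overrides$g
  if (!is_number(mu) || mu < 0)
    ls_abort("friction coefficient must be a non-negative number",
             "validation")
  if (mu > 1)
    warning("friction coefficient ", mu, " lies outside [0, 1]",
            call. = FALSE)
  if (!is_number(g) || g <= 0)
    ls_abort("g must be a positive number (m/s^2)", "validation")

  scale <- stature / .ls_reference_stature
  segs <- lapply(.ls_segment_names, function(nm) {
    ov <- overrides[[nm]]
    len <- if (!is.null(ov$length)) ov$length
           else .ls_default_lengths[[nm]] * scale
    mf <- if (!is.null(ov$mass_fraction)) ov$mass_fraction
          else .ls_default_mass_fractions[[nm]]
    cf <- if (!is.null(ov$com_fraction)) ov$com_fraction
          else .ls_default_com_fractions[[nm]]
    segment_spec(nm, len, mf, cf)
  })
  names(segs) <- .ls_segment_names

  leg_fraction <- sum(vapply(segs, function(s) s$mass_fraction, numeric(1)))
  residual <- 1 - 2 * leg_fraction
  if (residual <= 0 || residual >= 1)
    ls_abort(sprintf(
      "residual (head-arms-trunk) mass fraction %.4f is outside (0, 1); %s",
      residual, "segment mass fractions are too large"), "validation")

  structure(list(
    stature = stature, total_mass = total_mass, g = g,
    friction_coefficient = mu, segments = segs,
    residual_mass_fraction = residual
  ), class = "anthropometric_model")
}

#' @export
print.anthropometric_model <- function(x, ...) {
  cat(sprintf("Anthropometric model: stature %.2f m, mass %.1f kg, g %.2f, mu %.2f\n",
              x$stature, x$total_mass, x$g, x$friction_coefficient))
  for (s in x$segments)
    cat(sprintf("  %-5s length %.3f m, mass %.1f kg, CoM %.1f%% from proximal\n",
                s$name, s$length, s$mass_fraction * x$total_mass,
                100 * s$com_fraction))
  cat(sprintf("  HAT lump: %.1f kg (fraction %.3f)\n",
              x$residual_mass_fraction * x$total_mass,
              x$residual_mass_fraction))
  invisible(x)
}

#' Total body weight of a model
#'
#' @param model An [build_model()] result.
#' @return Scalar weight in newtons (`total_mass * g`).
#' @export
body_weight <- function(model) {
  stopifnot(inherits(model, "anthropometric_model"))
  model$total_mass * model$g
}

#' Weight of one segment
#'
#' The gravitational force on a single segment: mass fraction times total
#' body mass times g. These are the per-segment loads P1 (foot), P2 (shank)
#' and P3 (thigh) entering the free-body balances.
#'
#' @inheritParams body_weight
#' @param name Segment name: `"foot"`, `"shank"` or `"thigh"`.
#' @return Scalar force in newtons, strictly positive.
#' @export
segment_weight <- function(model, name) {
  stopifnot(inherits(model, "anthropometric_model"))
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% names(model$segments)))
    ls_abort(sprintf("unknown segment '%s'", paste(name, collapse = ",")),
             "lookup")
  s <- model$segments[[name]]
  s$mass_fraction * model$total_mass * model$g
}

#' Centre-of-mass point of a segment
#'
#' Linear interpolation between segment endpoints: the CoM lies at
#' `com_fraction` of the way from the proximal to the distal end.
#'
#' @param proximal,distal Numeric length-2 points (meters). Must differ.
#' @param com_fraction Fraction in (0, 1) from the proximal end.
#' @return A numeric length-2 point.
#' @export
segment_com_point <- function(proximal, distal, com_fraction) {
  proximal <- as_point(proximal, "proximal")
  distal <- as_point(distal, "distal")
  if (!is_number(com_fraction) || com_fraction <= 0 || com_fraction >= 1)
    ls_abort("com_fraction must be in (0, 1)", "validation")
  if (vnorm(distal - proximal) == 0)
    ls_abort("degenerate segment: proximal and distal endpoints coincide",
             "degenerate_segment")
  proximal + com_fraction * (distal - proximal)
}

#' Read an anthropometric configuration file
#'
#' Flat JSON with keys `stature_m`, `mass_kg` and optionally `mu`, `g` and a
#' `segments` object holding per-segment overrides (`length`,
#' `mass_fraction`, `com_fraction`).
#'
#' @param path Path to a JSON configuration file.
#' @return An `anthropometric_model`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path))
    ls_abort(sprintf("model config file not found: '%s'", path), "io")
  cfg <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    ls_abort(sprintf("cannot parse model config '%s': %s",
                                     path, conditionMessage(e)), "parse"))
  if (!is.list(cfg) || !is_number(cfg$stature_m) || !is_number(cfg$mass_kg))
    ls_abort(sprintf(
      "model config '%s' must supply numeric stature_m and mass_kg", path),
      "parse")
  overrides <- list()
  if (!is.null(cfg$mu)) overrides$mu <- cfg$mu
  if (!is.null(cfg$g)) overrides$g <- cfg$g
  for (nm in intersect(names(cfg$segments), .ls_segment_names))
    overrides[[nm]] <- as.list(cfg$segments[[nm]])
  build_model(cfg$stature_m, cfg$mass_kg,
              overrides = if (length(overrides)) overrides else NULL)
}
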