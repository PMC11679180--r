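# Full-pipeline analysis and structured reporting.

stage <- function(name, expr) {
  withCallingHandlers(expr, limbstat_error = function(e) {
    e$message <- sprintf("[stage %s] %s", name, conditionMessage(e))
    stop(e)
  })
}

#' Analyze a pose file end to end
#'
#' Runs the complete chain: read the keypoint file, select the
#' best-detected person, calibrate to the metric world frame, locate the
#' whole-body centre of mass, solve the ground reaction forces (double or
#' single support), solve both limbs distal-to-proximal, and validate every
#' free body with the independent equilibrium oracle. Oracle failures mark
#' the report as failed rather than raising.
#'
#' @param pose_path Path to a BODY_25 keypoint JSON file.
#' @param model An [build_model()] result, or a path to a JSON model
#'   configuration (see [read_model_config()]), or `NULL` for the default
#'   1.85 m / 100 kg model.
#' @param config A [calibration_config()].
#' @param contact Contact-point convention for double support: `"midfoot"`,
#'   `"heel"` or `"toe"`.
#' @return An object of class `analysis_report`.
#' @export
analyze <- function(pose_path, model = NULL,
                    config = calibration_config(),
                    contact = c("midfoot", "heel", "toe")) {
  contact <- match.arg(contact)
  if (is.null(model)) model <- build_model()
  else if (is.character(model)) model <- stage("model-config",
                                               read_model_config(model))
  stopifnot(inherits(model, "anthropometric_model"))

  poses <- stage("read", read_pose_file(pose_path))
  raw <- stage("select", select_person(poses))
  pos <- stage("calibrate", calibrate(raw, model, config))
  com <- stage("com", total_com(body_mass_points(pos, model)))
  grf <- stage("grf", if (pos$support_state == "double")
    solve_double_support(pos, com, model, contact = contact)
  else solve_single_support(pos, com, model))
  limbs <- stage("limbs", list(
    hind = solve_limb(pos, "hind", grf = grf$hind, model = model),
    front = solve_limb(pos, "front", grf = grf$front, model = model)))
  oracle <- check_scene(pos, model, grf, limbs)

  stance_width <- if (pos$support_state == "double")
    abs(contact_x(pos$front, contact) - contact_x(pos$hind, contact))
  else NA_real_

  structure(list(
    package_version = as.character(packageVersion("limbstat")),
    provenance = list(input = pose_path, contact = contact,
                      support = config$support,
                      min_confidence = config$min_confidence),
    model = list(stature_m = model$stature, mass_kg = model$total_mass,
                 g = model$g, mu = model$friction_coefficient),
    posture = list(support_state = pos$support_state,
                   facing_sign = pos$facing_sign,
                   stance_width_m = stance_width,
                   com = com$com),
    grf = grf,
    hind_share_pct = round(100 * grf$hind_share, 2),
    limbs = limbs,
    equilibrium = oracle,
    passed = all_balanced(oracle)
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("limbstat analysis of %s\n", x$provenance$input))
  cat(sprintf("  support: %s, facing %+d\n", x$posture$support_state,
              x$posture$facing_sign))
  cat(sprintf("  CoM: (%.4f, %.4f) m\n", x$posture$com[1], x$posture$com[2]))
  cat(sprintf("  hind-leg share of vertical load: %.2f%%\n",
              x$hind_share_pct))
  print(x$grf)
  for (side in c("hind", "front")) print(x$limbs[[side]])
  cat(sprintf("  equilibrium check: %s\n",
              if (x$passed) "all free bodies balanced" else "FAILED"))
  invisible(x)
}

# recursive serializer: strip classes, keep full-precision numbers
serialize_node <- function(x) {
  if (inherits(x, "ground_contact"))
    return(list(point = x$point, grf = x$grf))
  if (inherits(x, "joint_load"))
    return(list(joint = x$joint, side = x$side, force = x$force,
                moment = x$moment))
  if (inherits(x, "equilibrium_report"))
    return(list(body_id = x$body_id, net_force = x$net_force,
                about = x$about, net_moment = x$net_moment,
                passed = x$passed))
  if (is.data.frame(x)) return(x)
  if (is.matrix(x)) {
    out <- as.data.frame(x)
    out$body <- rownames(x)
    return(out)
  }
  if (is.list(x)) return(lapply(unclass(x), serialize_node))
  x
}

#' Write an analysis report as JSON
#'
#' Numbers are written at full precision so the report round-trips
#' losslessly.
#'
#' @param report An [analyze()] result (or a `synthetic_scene` truth report).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  # digits = I(17): 17 significant digits, enough for a bit-exact
  # double-precision round trip
  jsonlite::write_json(serialize_node(report), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null")
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Path written by [write_report()].
#' @return A nested list mirroring the report structure.
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    ls_abort(sprintf("report file not found: '%s'", path), "io")
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}

#' Validate a serialized analysis report
#'
#' Checks structural completeness, that every numeric field is finite, that
#' the per-foot vertical GRFs sum to the total load and the horizontal GRFs
#' cancel, and that the stored equilibrium flags passed.
#'
#' @param path Path to a JSON report.
#' @return `TRUE` invisibly; raises a classed error describing the first
#'   violation otherwise.
#' @export
validate_report <- function(path) {
  rep <- read_report(path)
  need <- c("model", "posture", "grf", "limbs", "passed")
  miss <- setdiff(need, names(rep))
  if (length(miss))
    ls_abort(sprintf("report is missing fields: %s",
                     paste(miss, collapse = ", ")), "invalid_report")
  nums <- unlist(rep[c("model", "grf", "limbs")], use.names = FALSE)
  nums <- suppressWarnings(as.numeric(nums[!is.na(suppressWarnings(
    as.numeric(nums)))]))
  if (any(!is.finite(nums)))
    ls_abort("report contains non-finite numbers", "invalid_report")
  gy <- 0; gx <- 0
  for (side in c("hind", "front")) {
    gc <- rep$grf[[side]]
    if (!is.null(gc) && !is.null(gc$grf)) {
      gy <- gy + gc$grf[2L]; gx <- gx + gc$grf[1L]
    }
  }
  if (abs(gy - rep$grf$Ptotal) > 1e-6 || abs(gx) > 1e-6)
    ls_abort("ground reactions do not balance the total load",
             "invalid_report")
  if (!isTRUE(rep$passed))
    ls_abort("report records a failed equilibrium check", "invalid_report")
  invisible(TRUE)
}

#' Flat table of joint loads
#'
#' @param x An [analyze()] result or a named list of `limb_solution`s.
#' @return A data frame with columns `side`, `joint`, `Fx_N`, `Fy_N`,
#'   `M_Nm`.
#' @export
joint_loads_df <- function(x) {
  limbs <- if (inherits(x, "analysis_report")) x$limbs else x
  rows <- list()
  for (side in names(limbs)) {
    for (j in c("ankle", "knee", "hip")) {
      jl <- limbs[[side]][[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        side = side, joint = j, Fx_N = jl$force[1L], Fy_N = jl$force[2L],
        M_Nm = jl$moment)
    }
  }
  do.call(rbind, rows)
}
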