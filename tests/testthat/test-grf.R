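scene <- generate_scene(scene_params("readiness"))
kick <- generate_scene(scene_params("kick"))

fake_com <- function(x, y = 1) structure(list(com = c(x, y)),
                                         class = "com_result")
hind_x <- mean(c(scene$posture$hind$heel[1], scene$posture$hind$toe[1]))
front_x <- mean(c(scene$posture$front$heel[1], scene$posture$front$toe[1]))

test_that("double support splits the load by lever arms", {
  mid <- solve_double_support(scene$posture, fake_com((hind_x + front_x) / 2),
                              default_model)
  expect_equal(mid$hind$grf[2], 490.5, tolerance = 1e-9)
  expect_equal(mid$front$grf[2], 490.5, tolerance = 1e-9)

  lim <- solve_double_support(scene$posture, fake_com(hind_x), default_model)
  expect_equal(lim$hind$grf[2], 981, tolerance = 1e-9)
  expect_equal(lim$front$grf[2], 0, tolerance = 1e-9)
  expect_equal(lim$hind_share, 1)
})

test_that("the friction relation reproduces the reference values", {
  # a stance whose hind vertical GRF is 674.5038 N yields 202.35 N of
  # horizontal GRF at Co = 0.3, mirrored on the front leg
  sol <- scene$truth_grf
  expect_equal(sol$hind$grf[2], 674.5038, tolerance = 1e-6)
  expect_equal(sol$hind$grf[1], 0.3 * 674.5038, tolerance = 1e-6)
  expect_equal(round(sol$hind$grf[1], 2), 202.35)
  expect_equal(sol$front$grf[1], -sol$hind$grf[1])

  expect_equal(friction_components(674.5038, default_model, +1), 202.35114)
  expect_equal(friction_components(0, default_model, -1), 0)
  m0 <- build_model(overrides = list(mu = 0))
  expect_equal(friction_components(100, m0, +1), 0)
  expect_error(friction_components(-1, default_model),
               class = "limbstat_error_validation")
})

test_that("double support rejects degenerate and unbalanced stances", {
  expect_error(solve_double_support(scene$posture, fake_com(hind_x - 0.05),
                                    default_model),
               class = "limbstat_error_out_of_base")
  expect_error(solve_double_support(scene$posture, fake_com(front_x + 0.01),
                                    default_model),
               class = "limbstat_error_out_of_base")
  expect_error(solve_double_support(kick$posture, fake_com(0.1),
                                    default_model),
               class = "limbstat_error_validation")
  squeezed <- generate_scene(scene_params("custom", stance_width = 1e-3,
                                          com_bias = 0.5,
                                          joint_angles = scene$params$joint_angles))
  # near-coincident contacts stay bounded and shares sum to one
  g <- squeezed$truth_grf
  expect_true(all(is.finite(c(g$hind$grf, g$front$grf))))
  expect_equal(g$hind$grf[2] + g$front$grf[2], g$Ptotal, tolerance = 1e-9)
})

test_that("whole-body equilibrium residuals vanish at the solution", {
  for (seed in 1:20) {
    s <- random_scene(seed)
    com <- total_com(body_mass_points(s$posture, default_model))
    sol <- solve_double_support(s$posture, com, default_model)
    # horizontal, vertical and moment balances (about the front contact)
    expect_lt(abs(sol$hind$grf[1] + sol$front$grf[1]), 1e-9)
    expect_lt(abs(sol$hind$grf[2] + sol$front$grf[2] - sol$Ptotal), 1e-9)
    expect_lt(abs(sol$Ptotal * sol$L2 - sol$hind$grf[2] * (sol$L1 + sol$L2)),
              1e-9)
    # cross-check: moments about the hind contact
    expect_lt(abs(sol$Ptotal * sol$L1 - sol$front$grf[2] * (sol$L1 + sol$L2)),
              1e-9)
  }
})

test_that("hind share decreases strictly as the CoM moves forward", {
  xs <- seq(hind_x + 1e-4, front_x - 1e-4, length.out = 50)
  shares <- vapply(xs, function(x)
    solve_double_support(scene$posture, fake_com(x),
                         default_model)$hind_share, numeric(1))
  expect_true(all(diff(shares) < 0))
  expect_true(all(shares >= 0 & shares <= 1))
})

test_that("the solution is invariant to translating the scene along x", {
  com <- total_com(body_mass_points(scene$posture, default_model))
  base <- solve_double_support(scene$posture, com, default_model)
  shift <- 3.7
  moved <- scene$posture
  for (side in c("hind", "front"))
    for (pt in names(moved[[side]]))
      moved[[side]][[pt]] <- moved[[side]][[pt]] + c(shift, 0)
  moved$trunk_anchor <- moved$trunk_anchor + c(shift, 0)
  mcom <- total_com(body_mass_points(moved, default_model))
  msol <- solve_double_support(moved, mcom, default_model)
  expect_equal(msol$hind$grf, base$hind$grf, tolerance = 1e-9)
  expect_equal(msol$hind_share, base$hind_share, tolerance = 1e-12)
  expect_equal(msol$hind$point[1], base$hind$point[1] + shift,
               tolerance = 1e-9)
})

test_that("single support places the full load under the CoM", {
  com <- total_com(body_mass_points(kick$posture, default_model))
  sol <- solve_single_support(kick$posture, com, default_model)
  expect_equal(sol$hind$grf, c(0, 981), tolerance = 1e-9)
  expect_null(sol$front)
  expect_equal(sol$hind$point[1], com$com[1])
  expect_equal(sol$hind_share, 1)
  # CoM beyond the toe cannot be balanced
  toe_x <- max(kick$posture$hind$heel[1], kick$posture$hind$toe[1])
  expect_error(solve_single_support(kick$posture, fake_com(toe_x + 0.05),
                                    default_model),
               class = "limbstat_error_out_of_base")
  expect_error(solve_single_support(scene$posture, com, default_model),
               class = "limbstat_error_validation")
})
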