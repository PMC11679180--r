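scene <- generate_scene(scene_params("readiness"))
kick <- generate_scene(scene_params("kick"))

test_that("a swing foot's ankle carries exactly the foot weight", {
  sol <- solve_limb(kick$posture, "front", grf = NULL, model = default_model)
  expect_equal(sol$ankle$force, c(0, 16.677), tolerance = 1e-12)
})

test_that("zero loads propagate through weightless segments", {
  fb <- segment_free_body("shank", proximal_joint = c(0, 1),
                          distal_joint = c(0, 0), weight = 0, side = "hind")
  zero <- joint_load("ankle", c(0, 0), 0, side = "hind")
  knee <- solve_shank(fb, zero)
  expect_equal(knee$force, c(0, 0))
  expect_equal(knee$moment, 0)
  thigh <- segment_free_body("thigh", proximal_joint = c(0, 2),
                             distal_joint = c(0, 1), weight = 0,
                             side = "hind")
  hip <- solve_thigh(thigh, joint_load("knee", c(0, 0), 0, side = "hind"))
  expect_equal(hip$force, c(0, 0))
  expect_equal(hip$moment, 0)
})

test_that("a fully collinear vertical stack has zero joint moments", {
  # foot axis, joints, CoMs and the GRF line all share x = 0
  G <- 500
  foot <- segment_free_body("foot", proximal_joint = c(0, 0.1),
                            distal_joint = c(0, 0), weight = 10,
                            external = ground_contact(c(0, 0), c(0, G)),
                            side = "hind")
  ankle <- solve_foot(foot)
  expect_equal(ankle$force, c(0, 10 - G))
  expect_equal(ankle$moment, 0, tolerance = 1e-12)
  shank <- segment_free_body("shank", proximal_joint = c(0, 0.58),
                             distal_joint = c(0, 0.1), weight = 40,
                             side = "hind")
  knee <- solve_shank(shank, ankle)
  expect_equal(knee$force, c(0, 50 - G))
  expect_equal(knee$moment, 0, tolerance = 1e-12)
  thigh <- segment_free_body("thigh", proximal_joint = c(0, 1.08),
                             distal_joint = c(0, 0.58), weight = 100,
                             side = "hind")
  hip <- solve_thigh(thigh, knee)
  expect_equal(hip$force, c(0, 150 - G))
  expect_equal(hip$moment, 0, tolerance = 1e-12)
})

test_that("mismatched limb sides are a wiring error", {
  fb <- segment_free_body("shank", proximal_joint = c(0, 1),
                          distal_joint = c(0, 0.2), weight = 40,
                          side = "front")
  expect_error(solve_shank(fb, joint_load("ankle", c(1, 1), 0.5,
                                          side = "hind")),
               class = "limbstat_error_wiring")
  expect_error(solve_shank(fb, joint_load("knee", c(1, 1), 0.5,
                                          side = "front")),
               class = "limbstat_error_wiring")
})

test_that("per-segment residuals vanish on the presets", {
  for (sc in list(scene, kick)) {
    for (side in c("hind", "front")) {
      sol <- solve_limb(sc$posture, side, grf = sc$truth_grf[[side]],
                        model = default_model)
      expect_lt(max(sol$equilibrium_residuals), 1e-9)
    }
  }
})

test_that("solve_limb reproduces generator ground truth", {
  for (seed in 1:15) {
    s <- random_scene(seed)
    for (side in c("hind", "front")) {
      sol <- solve_limb(s$posture, side, grf = s$truth_grf[[side]],
                        model = default_model)
      for (j in c("ankle", "knee", "hip"))
        expect_joint_equal(sol[[j]], s$truth_limbs[[side]][[j]], tol = 1e-8)
    }
  }
})

test_that("moments about proximal joints give identical joint loads", {
  # independent recursion (helper) referenced at the joints, not the CoMs
  for (sc in list(scene, kick)) {
    for (side in c("hind", "front")) {
      sol <- solve_limb(sc$posture, side, grf = sc$truth_grf[[side]],
                        model = default_model)
      alt <- oracle_limb_recursion(sc$posture, side, sc$truth_grf[[side]],
                                   default_model)
      for (j in c("ankle", "knee", "hip"))
        expect_joint_equal(sol[[j]], alt[[j]], tol = 1e-9)
    }
  }
})

test_that("doubling all masses doubles every joint load", {
  heavy <- build_model(1.85, 200)
  params <- scene_params("readiness")
  s2 <- generate_scene(params, model = heavy)
  for (side in c("hind", "front")) {
    a <- solve_limb(scene$posture, side, grf = scene$truth_grf[[side]],
                    model = default_model)
    b <- solve_limb(s2$posture, side, grf = s2$truth_grf[[side]],
                    model = heavy)
    for (j in c("ankle", "knee", "hip")) {
      expect_equal(b[[j]]$force, 2 * a[[j]]$force, tolerance = 1e-9)
      expect_equal(b[[j]]$moment, 2 * a[[j]]$moment, tolerance = 1e-9)
    }
  }
})

test_that("hip reactions of both limbs balance the HAT weight", {
  hind <- solve_limb(scene$posture, "hind", grf = scene$truth_grf$hind,
                     model = default_model)
  front <- solve_limb(scene$posture, "front", grf = scene$truth_grf$front,
                      model = default_model)
  w_hat <- default_model$residual_mass_fraction * 100 * 9.81
  net <- -hind$hip$force - front$hip$force + c(0, -w_hat)
  expect_lt(max(abs(net)), 1e-8)
})

test_that("the kick swing limb shows a near-negligible ankle moment", {
  sol <- solve_limb(kick$posture, "front", grf = NULL, model = default_model)
  m <- abs(c(ankle = sol$ankle$moment, knee = sol$knee$moment,
             hip = sol$hip$moment))
  expect_lt(m["ankle"], min(m["knee"], m["hip"]))
})
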