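# Shared fixtures and independent oracles for the limbstat test suite.
# Everything here is built in code at test time; nothing is read from disk.

default_model <- build_model()

cross2_test <- function(r, f) r[1] * f[2] - r[2] * f[1]

# Random double-support scene parameters with the CoM comfortably inside
# the base of support. Ranges are fixed once; seeds make draws reproducible.
random_scene_params <- function(seed) {
  set.seed(seed)
  scene_params(
    preset = "custom",
    stance_width = runif(1, 0.40, 0.75),
    com_bias = runif(1, 0.25, 0.80),
    joint_angles = list(
      hind = c(shank = runif(1, 12, 27), thigh = runif(1, -16, -4)),
      front = c(shank = runif(1, -28, -14), thigh = runif(1, -26, -10))))
}

random_scene <- function(seed, model = default_model)
  generate_scene(random_scene_params(seed), model = model)

# Independent limb recursion used as a reference-point oracle: per-segment
# free bodies exactly as in the solver, but with every moment balance taken
# about the segment's PROXIMAL JOINT instead of its CoM. Shares no code
# with solve_limb() or with the generator's distal-chain truth.
oracle_limb_recursion <- function(posture, side, contact, model) {
  leg <- posture[[side]]
  sp <- model$segments
  lerp <- function(a, b, f) a + f * (b - a)
  W <- function(seg) sp[[seg]]$mass_fraction * model$total_mass * model$g

  coms <- list(foot = lerp(leg$ankle, leg$toe, sp$foot$com_fraction),
               shank = lerp(leg$knee, leg$ankle, sp$shank$com_fraction),
               thigh = lerp(leg$hip, leg$knee, sp$thigh$com_fraction))

  # foot, moments about the ankle
  fsum <- c(0, -W("foot"))
  msum <- cross2_test(coms$foot - leg$ankle, c(0, -W("foot")))
  if (!is.null(contact)) {
    fsum <- fsum + contact$grf
    msum <- msum + cross2_test(contact$point - leg$ankle, contact$grf)
  }
  Fa <- -fsum
  Ma <- -msum # ankle force has zero arm about the ankle

  # shank, moments about the knee
  fsum <- c(0, -W("shank")) - Fa
  msum <- cross2_test(coms$shank - leg$knee, c(0, -W("shank"))) +
    cross2_test(leg$ankle - leg$knee, -Fa) - Ma
  Fk <- -fsum
  Mk <- -msum

  # thigh, moments about the hip
  fsum <- c(0, -W("thigh")) - Fk
  msum <- cross2_test(coms$thigh - leg$hip, c(0, -W("thigh"))) +
    cross2_test(leg$knee - leg$hip, -Fk) - Mk
  Fh <- -fsum
  Mh <- -msum

  list(ankle = list(force = Fa, moment = Ma),
       knee = list(force = Fk, moment = Mk),
       hip = list(force = Fh, moment = Mh))
}

expect_joint_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(a$force - b$force)), tol)
  expect_lt(abs(a$moment - b$moment), tol)
}
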