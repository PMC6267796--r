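test_that("cosine kinematics have zero angular velocity at both endpoints", {
  mov <- default_movements()
  kin <- movement_kinematics(mov, which = adopted_idx()[1:3])
  nf <- mov$n_frames
  for (th in list(kin$thetad_s, kin$thetad_th, kin$thetad_tr)) {
    expect_equal(th[, 1], rep(0, 3), tolerance = 1e-12)
    expect_equal(abs(th[, nf]), rep(0, 3), tolerance = 1e-12)
  }
  # angular acceleration vanishes at the waveform inflection (t = T/2)
  mid <- (nf + 1) / 2
  expect_equal(kin$alpha_tr[, mid], rep(0, 3), tolerance = 1e-12)
})

test_that("analytic COM accelerations match a finite-difference oracle", {
  body <- default_body()
  grid <- default_movements()$postures[adopted_idx()[10], ]
  mov <- generate_movements(body, grid, n_frames = 2001)
  kin <- movement_kinematics(mov)
  dt <- mov$t[2] - mov$t[1]
  fd2 <- function(x) (x[, -c(1, 2)] - 2 * x[, -c(1, ncol(x))] +
                        x[, -c(ncol(x) - 1, ncol(x))]) / dt^2
  for (pair in list(c("hat_com_x", "hat_com_acc_x"),
                    c("hat_com_y", "hat_com_acc_y"),
                    c("thigh_com_x", "thigh_com_acc_x"),
                    c("shank_com_y", "shank_com_acc_y"))) {
    num <- fd2(kin[[pair[1]]])
    ana <- kin[[pair[2]]][, 2:(ncol(kin[[pair[1]]]) - 1), drop = FALSE]
    expect_lt(max(abs(num - ana)), 1e-4)
  }
})

test_that("moments vanish without gravity in the static case and scale with mass", {
  mov <- default_movements()
  idx <- adopted_idx()[1:5]
  k0 <- compute_joint_moments(mov, which = idx, static = TRUE, gravity = 0)
  expect_equal(max(abs(k0$hip_moment)), 0, tolerance = 1e-12)
  expect_equal(max(abs(k0$knee_moment)), 0, tolerance = 1e-12)
  expect_equal(max(abs(k0$hjf_x)) + max(abs(k0$hjf_y)), 0, tolerance = 1e-12)
  # mass-normalized moments are invariant to body mass at fixed kinematics
  b2 <- build_body_model(1.74, 2 * 73.8)
  mov2 <- apply_adoption_filters(generate_movements(b2))
  k1 <- compute_joint_moments(mov, which = idx)
  k2 <- compute_joint_moments(mov2, which = idx)
  expect_equal(k1$hip_moment, k2$hip_moment, tolerance = 1e-12)
  expect_equal(k1$ankle_moment, k2$ankle_moment, tolerance = 1e-12)
})

test_that("a massless-leg body reduces to the inverted-pendulum closed form", {
  body <- pendulum_body()
  grid <- generate_posture_grid(body)
  mov <- generate_movements(body, grid)
  i <- which(grid$valid & grid$hip_dx == -0.15 & grid$trunk_angle_deg == 40)
  ks <- compute_joint_moments(mov, which = i, static = TRUE)
  # static hip moment per leg: half the HAT weight times the horizontal
  # COM offset, m g L_com sin(theta)
  L_com <- body$hat$com_ratio * body$hat$length
  theta <- outer(40 * pi / 180, mov$w)
  closed <- (body$hat$mass / 2) * 9.8 * L_com * sin(theta) / body$mass
  expect_equal(ks$hip_moment, closed, tolerance = 1e-10)
})

test_that("static moments match a hand summation of gravity lever arms", {
  body <- default_body()
  mov <- default_movements()
  i <- adopted_idx()[30]
  fr <- 25
  ks <- static_moment_component(mov, which = i)
  kin <- movement_kinematics(mov, which = i, derivatives = FALSE)
  g <- 9.8
  # per leg: knee extension moment balances half the HAT weight plus the
  # thigh weight acting at their horizontal offsets from the knee
  hand_knee <- g * (body$hat$mass / 2 *
                      (kin$knee_x[1, fr] - kin$hat_com_x[1, fr]) +
                    body$thigh$mass *
                      (kin$knee_x[1, fr] - kin$thigh_com_x[1, fr])) / body$mass
  expect_equal(ks$knee_moment[1, fr], hand_knee, tolerance = 1e-10)
  hand_hip <- g * body$hat$mass / 2 *
    (kin$hat_com_x[1, fr] - kin$hip_x[1, fr]) / body$mass
  expect_equal(ks$hip_moment[1, fr], hand_hip, tolerance = 1e-10)
})

test_that("top-down and bottom-up inverse dynamics agree on every frame", {
  mov <- default_movements()
  idx <- adopted_idx()[seq(1, length(adopted_idx()), by = 37)]
  top <- compute_joint_moments(mov, which = idx)
  bot <- bottom_up_kinetics(mov, default_body(), idx)
  for (q in c("hip_moment", "knee_moment", "ankle_moment", "hjf_x", "hjf_y")) {
    expect_lt(max(abs(top[[q]] - bot[[q]])), 1e-6)
  }
})

test_that("the static component is the infinite-duration limit of the moments", {
  body <- default_body()
  grid <- default_movements()$postures[adopted_idx()[20], ]
  slow <- generate_movements(body, grid, duration = 100, n_frames = 101)
  k_slow <- compute_joint_moments(slow)
  k_stat <- static_moment_component(slow)
  expect_lt(max(abs(k_slow$hip_moment - k_stat$hip_moment)), 1e-3)
  expect_lt(max(abs(k_slow$knee_moment - k_stat$knee_moment)), 1e-3)
})

test_that("the standing hip intersegmental force carries half the HAT weight", {
  body <- default_body()
  grid <- data.frame(posture_id = 1, hip_dx = 0, trunk_angle_deg = 0,
                     hip_deg = 0, knee_deg = 0, ankle_deg = 0, valid = TRUE)
  mov <- generate_movements(body, grid, n_frames = 3)
  hjf <- hip_joint_force(mov)
  k <- length(mov$w)
  expect_equal(hjf$y[1, 1], -(body$hat$mass / 2) * 9.8 / body$mass,
               tolerance = 1e-9)
  expect_equal(hjf$x[1, 1], 0, tolerance = 1e-9)
})
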