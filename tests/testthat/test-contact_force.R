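test_that("muscle line-of-action vectors are unit and frame-equivariant", {
  th_th <- matrix(c(-1.3, -0.4, 0), 1)
  th_tr <- matrix(c(0.8, 0.3, 0), 1)
  for (mu in hip_muscles()) {
    e <- muscle_line_unit_vector(mu, th_th, th_tr)
    expect_equal(sqrt(e$x^2 + e$y^2), matrix(1, 1, 3), tolerance = 1e-9)
    # rotating the whole body by phi rotates every unit vector by phi
    phi <- 0.37  # radians, clockwise orientation shift
    e2 <- muscle_line_unit_vector(mu, th_th + phi, th_tr + phi)
    rot_x <- e$x * cos(phi) + e$y * sin(phi)   # clockwise rotation by phi
    rot_y <- -e$x * sin(phi) + e$y * cos(phi)
    expect_equal(e2$x, rot_x, tolerance = 1e-9)
    expect_equal(e2$y, rot_y, tolerance = 1e-9)
  }
  expect_error(muscle_line_unit_vector("soleus", 0, 0), "soleus")
})

test_that("the gluteus maximus direction matches hand trigonometry", {
  # mean seat-off posture: thigh at -74 deg, trunk at +46 deg from vertical
  th_th <- -74 * pi / 180
  th_tr <- 46 * pi / 180
  att <- muscle_attachments()
  row <- att[att$muscle == "gluteus_maximus", ]
  rot_cw <- function(p, th) {
    # local (x anterior, y up) frame tilted th clockwise from vertical
    c(p[1] * cos(th) + p[2] * sin(th), -p[1] * sin(th) + p[2] * cos(th))
  }
  pel <- rot_cw(c(row$pelvis_x, row$pelvis_y), th_tr)
  # femur frame y is distal: global = rotate (x, -y) by the thigh angle of
  # the hip->knee direction, which is th_th + pi
  fem <- rot_cw(c(row$femur_x, -row$femur_y), th_th)
  d <- pel - fem
  hand <- d / sqrt(sum(d^2))
  e <- muscle_line_unit_vector("gluteus_maximus", th_th, th_tr)
  expect_equal(c(e$x, e$y), hand, tolerance = 1e-9)
})

test_that("the contact force norm follows the defining vector arithmetic", {
  body <- default_body()
  # synthetic one-movement kinetics: constant intersegmental force
  nf <- 5
  kin <- list(hjf_x = matrix(0, 1, nf), hjf_y = matrix(-3, 1, nf),
              kin = list(theta_th = matrix(0, 1, nf),
                         theta_tr = matrix(0, 1, nf)))
  zero_F <- array(0, dim = c(8, 1, nf),
                  dimnames = list(muscle_params()$muscle, NULL, NULL))
  forces <- list(F = zero_F, feasible = matrix(TRUE, 1, nf),
                 movement_feasible = TRUE, which = 1)
  # all muscle forces zero: HJCF = |v_HJF|
  cf0 <- hip_contact_force(kin, forces, body)
  expect_equal(cf0$hjcf, matrix(3, 1, nf))
  expect_equal(cf0$peak, 3)
  # one muscle pulling antiparallel to v_HJF with force |v_HJF| doubles it
  e <- muscle_line_unit_vector("gluteus_maximus", matrix(0, 1, nf),
                               matrix(0, 1, nf))
  f_anti <- forces
  f_anti$F["gluteus_maximus", 1, ] <- 3 * body$mass  # N, = 3 N/kg
  kin_anti <- kin
  kin_anti$hjf_x <- -3 * e$x
  kin_anti$hjf_y <- -3 * e$y
  cf1 <- hip_contact_force(kin_anti, f_anti, body)
  expect_equal(cf1$hjcf, matrix(6, 1, nf), tolerance = 1e-9)
  # scaling all forces and the intersegmental force by c scales HJCF by c
  f_sc <- f_anti
  f_sc$F <- f_anti$F * 2.5
  kin_sc <- kin_anti
  kin_sc$hjf_x <- kin_anti$hjf_x * 2.5
  kin_sc$hjf_y <- kin_anti$hjf_y * 2.5
  cf2 <- hip_contact_force(kin_sc, f_sc, body)
  expect_equal(cf2$hjcf, 2.5 * cf1$hjcf, tolerance = 1e-9)
  # mismatched series lengths error out
  kin_bad <- kin
  kin_bad$hjf_x <- matrix(0, 1, nf + 1)
  expect_error(hip_contact_force(kin_bad, forces, body), "mismatch")
})

test_that("peak contact force rises with seat-off hip flexion angle", {
  cf <- adopted_contact()
  mov <- default_movements()
  ok <- cf$movement_feasible
  hip <- mov$postures$hip_deg[adopted_idx()][ok]
  expect_gt(cor(hip, cf$peak[ok], method = "spearman"), 0.9)
})

test_that("the gluteus medius adjustment reproduces the published arithmetic", {
  expect_equal(gluteus_medius_adjustment(45.6, 0.11, 60, 73.8),
               45.6 * 0.11 * 60 / 73.8)
  expect_equal(round(gluteus_medius_adjustment(), 1), 4.1)
  expect_equal(gluteus_medius_adjustment(activation_fraction = 0), 0)
  expect_equal(gluteus_medius_adjustment(activation_fraction = 0.22),
               2 * gluteus_medius_adjustment(activation_fraction = 0.11))
})
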