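# Shared fixtures, built once per test run and cached.

.study_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .study_cache)) {
    assign(name, build(), envir = .study_cache)
  }
  get(name, envir = .study_cache)
}

default_body <- function() cached("body", function() build_body_model())

# full grid with adoption filters applied (101 frames)
default_movements <- function() cached("mov", function() {
  mov <- generate_movements(default_body())
  apply_adoption_filters(mov)
})

adopted_idx <- function() which(default_movements()$adopted)

adopted_kinetics <- function() cached("kin", function() {
  compute_joint_moments(default_movements(), which = adopted_idx())
})

adopted_static_kinetics <- function() cached("kin_s", function() {
  static_moment_component(default_movements(), which = adopted_idx())
})

adopted_forces <- function() cached("forces", function() {
  solve_movement_forces(default_movements(), kinetics = adopted_kinetics(),
                        which = adopted_idx(), objective = "activation")
})

adopted_contact <- function() cached("contact", function() {
  hip_contact_force(adopted_kinetics(), adopted_forces(), default_body())
})

# a body whose whole mass sits in the HAT segment (legs massless): reduces
# the linked chain to a single inverted pendulum over the hip
pendulum_body <- function() {
  tab <- default_anthropometry()
  tab$mass_fraction <- c(1, 0, 0, 0)[match(tab$segment,
                                           c("hat", "thigh", "shank", "foot"))]
  build_body_model(fraction_table = tab)
}

# independent bottom-up inverse dynamics oracle: aggregate momentum balance
# of the subsystem above each joint, per leg (half HAT), about the joint
# point. Returns the same per-leg, mass-normalized conventions as
# compute_joint_moments().
bottom_up_kinetics <- function(mov, body, which) {
  kin <- movement_kinematics(mov, body, which = which, derivatives = TRUE)
  g <- 9.8
  m_h2 <- body$hat$mass / 2
  I_h2 <- segment_inertia(body$hat) / 2
  m_th <- body$thigh$mass
  I_th <- segment_inertia(body$thigh)
  m_sh <- body$shank$mass
  I_sh <- segment_inertia(body$shank)
  crossz <- function(ax, ay, bx, by) ax * by - ay * bx
  # net moment applied at point (px, py) to hold the listed particles+inertias
  agg_moment <- function(px, py, parts) {
    M <- 0
    for (p in parts) {
      M <- M + crossz(p$x - px, p$y - py, p$m * p$ax, p$m * (p$ay + g)) +
        p$I * p$alpha
    }
    M
  }
  agg_force <- function(parts, comp) {
    Reduce(`+`, lapply(parts, function(p) {
      if (comp == "x") p$m * p$ax else p$m * (p$ay + g)
    }))
  }
  hat <- list(m = m_h2, I = I_h2, x = kin$hat_com_x, y = kin$hat_com_y,
              ax = kin$hat_com_acc_x, ay = kin$hat_com_acc_y,
              alpha = kin$alpha_tr)
  thigh <- list(m = m_th, I = I_th, x = kin$thigh_com_x, y = kin$thigh_com_y,
                ax = kin$thigh_com_acc_x, ay = kin$thigh_com_acc_y,
                alpha = kin$alpha_th)
  shank <- list(m = m_sh, I = I_sh, x = kin$shank_com_x, y = kin$shank_com_y,
                ax = kin$shank_com_acc_x, ay = kin$shank_com_acc_y,
                alpha = kin$alpha_s)
  Mb <- body$mass
  list(
    hip_moment = agg_moment(kin$hip_x, kin$hip_y, list(hat)) / Mb,
    knee_moment = -agg_moment(kin$knee_x, kin$knee_y, list(hat, thigh)) / Mb,
    ankle_moment = agg_moment(0, body$ankle_height,
                              list(hat, thigh, shank)) / Mb,
    hjf_x = -agg_force(list(hat), "x") / Mb,
    hjf_y = -agg_force(list(hat), "y") / Mb
  )
}

# dense brute-force oracle for small muscle-redundancy problems:
# minimize sum((F/w)^2) s.t. r' F = M (single joint), 0 <= F <= u.
# The last variable is eliminated through the constraint; the remaining
# variables are gridded over their exactly-computed feasible intervals
# (so box boundaries and the constraint edges are sampled exactly, and an
# empty interval is an exact infeasibility certificate), with refinement
# around the incumbent.
brute_force_qp <- function(r, M, u, w, n_grid = 401) {
  k <- length(r)
  stopifnot(k %in% c(2, 3))
  # exact interval of t such that t = r_i F_i is reachable with F_i in [0, u_i]
  term_range <- function(i) sort(c(0, r[i] * u[i]))
  # interval of F1 for which the rest of the chain stays feasible
  rest_lo <- sum(vapply((2:k), function(i) term_range(i)[1], 0))
  rest_hi <- sum(vapply((2:k), function(i) term_range(i)[2], 0))
  f1_bounds <- sort(c((M - rest_lo) / r[1], (M - rest_hi) / r[1]))
  f1_lo <- max(0, f1_bounds[1])
  f1_hi <- min(u[1], f1_bounds[2])
  if (f1_lo > f1_hi + 1e-15) return(NULL)

  # best point for a fixed F1 (grids F2 over its exact interval; F_k exact)
  best_for_f1 <- function(F1) {
    rem <- M - r[1] * F1
    if (k == 2) {
      F2 <- rem / r[2]
      if (F2 < -1e-12 || F2 > u[2] + 1e-12) return(NULL)
      F2 <- min(max(F2, 0), u[2])
      return(list(F = c(F1, F2), value = sum((c(F1, F2) / w)^2)))
    }
    t3 <- term_range(3)
    f2b <- sort(c((rem - t3[1]) / r[2], (rem - t3[2]) / r[2]))
    lo <- max(0, f2b[1]); hi <- min(u[2], f2b[2])
    if (lo > hi + 1e-15) return(NULL)
    # minimize (F2/w2)^2 + (F3/w3)^2 with F3 = (rem - r2 F2)/r3 exactly:
    # the 1-D quadratic stationary point clipped to the feasible interval,
    # plus the interval endpoints (where a box bound becomes active)
    F2_star <- (r[2] * rem / (r[3]^2 * w[3]^2)) /
      (1 / w[2]^2 + r[2]^2 / (r[3]^2 * w[3]^2))
    F2 <- unique(c(min(max(F2_star, lo), hi), lo, hi))
    F3 <- pmin(pmax((rem - r[2] * F2) / r[3], 0), u[3])
    vals <- (F1 / w[1])^2 + (F2 / w[2])^2 + (F3 / w[3])^2
    i <- which.min(vals)
    list(F = c(F1, F2[i], F3[i]), value = vals[i])
  }

  scan <- function(lo, hi) {
    F1s <- seq(lo, hi, length.out = n_grid)
    best <- NULL
    for (F1 in F1s) {
      cand <- best_for_f1(F1)
      if (!is.null(cand) && (is.null(best) || cand$value < best$value)) {
        best <- cand
      }
    }
    best
  }
  best <- scan(f1_lo, f1_hi)
  if (is.null(best)) return(NULL)
  h <- (f1_hi - f1_lo) / (n_grid - 1)
  for (rep in 1:2) {
    lo <- max(f1_lo, best$F[1] - 2 * h)
    hi <- min(f1_hi, best$F[1] + 2 * h)
    ref <- scan(lo, hi)
    if (!is.null(ref) && ref$value < best$value) best <- ref
    h <- (hi - lo) / (n_grid - 1)
  }
  best
}
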