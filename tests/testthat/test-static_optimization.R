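test_that("the moment-arm matrix has the Table-1 sparsity and anatomy signs", {
  A <- moment_arm_matrix()
  expect_equal(dim(A), c(3, 8))
  expect_equal(sum(A["ankle", ] != 0), 3)
  expect_setequal(colnames(A)[A["ankle", ] != 0],
                  c("tibialis_anterior", "soleus", "gastrocnemius"))
  expect_gt(A["hip", "gluteus_maximus"], 0)
  expect_gt(A["hip", "hamstrings"], 0)
  expect_lt(A["hip", "iliopsoas"], 0)
  expect_lt(A["hip", "rectus_femoris"], 0)
  expect_gt(A["knee", "vastus"], 0)
  expect_lt(A["knee", "hamstrings"], 0)
  expect_lt(A["ankle", "tibialis_anterior"], 0)
})

test_that("zero target moments give the all-zero optimum", {
  mus <- muscle_params()
  pr <- build_problem(c(0, 0, 0), 73.8, rep(1000, 8), mus, "activation")
  sol <- solve_frame(pr)
  expect_true(sol$feasible)
  expect_equal(unname(sol$F_ce), rep(0, 8))
  expect_equal(sol$objective_value, 0)
})

test_that("two unbounded agonists follow the weighted closed-form split", {
  # minimize (F1/w1)^2 + (F2/w2)^2 s.t. r1 F1 + r2 F2 = M:
  # F_i = M r_i w_i^2 / sum(r_j^2 w_j^2)
  set.seed(42)
  for (rep in 1:20) {
    r <- runif(2, 0.2, 1.5)
    w <- runif(2, 0.5, 2)
    M <- runif(1, 0.1, 0.5)
    pr <- structure(list(A = matrix(r, 1, 2), b = M,
                         u = c(1e9, 1e9), w = w), class = "sts_qp")
    sol <- solve_frame(pr)
    closed <- M * r * w^2 / sum(r^2 * w^2)
    expect_true(sol$feasible)
    expect_equal(unname(sol$F_ce), closed, tolerance = 1e-8)
  }
})

test_that("the solver matches a dense brute-force oracle on 1000 problems", {
  set.seed(7)
  n_cases <- 1000
  worst <- 0
  n_infeasible <- 0
  for (case in seq_len(n_cases)) {
    k <- sample(2:3, 1)
    r <- runif(k, 0.3, 1.5) * sample(c(-1, 1), k, replace = TRUE)
    u <- runif(k, 0.5, 2)
    w <- runif(k, 0.5, 2)
    # target between the extremes of what the box can produce, sometimes out
    reach <- sum(pmax(r, 0) * u)
    M <- runif(1, -0.2, reach * 1.1)
    pr <- structure(list(A = matrix(r, 1, k), b = M, u = u, w = w),
                    class = "sts_qp")
    sol <- solve_frame(pr)
    oracle <- brute_force_qp(r, M, u, w)
    if (is.null(oracle)) {
      # grid found no feasible point; solver must agree (up to grid slack)
      n_infeasible <- n_infeasible + 1
      expect_false(sol$feasible)
    } else if (sol$feasible) {
      worst <- max(worst, abs(sol$objective_value - oracle$value))
    } else {
      # solver says infeasible but a grid point satisfied the constraint to
      # grid precision: must not happen
      fail(sprintf("case %d: solver infeasible, oracle found %.6f",
                   case, oracle$value))
    }
  }
  expect_lt(worst, 1e-6)
  expect_gt(n_infeasible, 10)  # the case mix really exercises infeasibility
})

test_that("the solver agrees with an independent QP implementation", {
  kin <- adopted_kinetics()
  mus <- muscle_params()
  mov <- default_movements()
  st <- muscle_states(mov, mus, which = adopted_idx())
  A <- moment_arm_matrix(mus)
  body <- default_body()
  set.seed(11)
  frames <- cbind(sample(nrow(kin$hip_moment), 25), sample(101, 25))
  for (i in seq_len(nrow(frames))) {
    mvt <- frames[i, 1]; fr <- frames[i, 2]
    b <- c(kin$hip_moment[mvt, fr], kin$knee_moment[mvt, fr],
           kin$ankle_moment[mvt, fr]) * body$mass
    u <- vapply(mus$muscle, function(m) st[[m]]$F_max[mvt, fr], 0)
    if (any(u <= 0)) next
    pr <- structure(list(A = A, b = b, u = u, w = u), class = "sts_qp")
    sol <- solve_frame(pr)
    ref <- tryCatch(
      pracma::quadprog(C = diag(2 / u^2), d = rep(0, 8),
                       Aeq = A, beq = b, lb = rep(0, 8), ub = u),
      error = function(e) NULL)
    if (is.null(ref) || ref$eflag != 1) {
      next
    }
    expect_true(sol$feasible)
    expect_equal(sol$objective_value, sum((ref$xmin / u)^2), tolerance = 1e-6)
  }
})

test_that("feasible frames satisfy the moment constraints to 1e-6 Nm", {
  forces <- adopted_forces()
  kin <- adopted_kinetics()
  body <- default_body()
  mov <- default_movements()
  mus <- muscle_params()
  st <- muscle_states(mov, mus, which = adopted_idx())
  A <- forces$arm_matrix
  set.seed(3)
  sel <- sample(which(forces$feasible), 200)
  worst_res <- 0
  worst_obj <- 0
  for (s in sel) {
    mvt <- (s - 1) %% nrow(forces$feasible) + 1
    fr <- (s - 1) %/% nrow(forces$feasible) + 1
    F <- forces$F[, mvt, fr]
    b <- c(kin$hip_moment[mvt, fr], kin$knee_moment[mvt, fr],
           kin$ankle_moment[mvt, fr]) * body$mass
    worst_res <- max(worst_res, max(abs(A %*% F - b)))
    # reported objective equals its recomputation from the returned forces
    u <- vapply(mus$muscle, function(m) st[[m]]$F_max[mvt, fr], 0)
    act <- ifelse(u > 0, F / u, 0)
    worst_obj <- max(worst_obj,
                     abs(forces$objective_value[mvt, fr] - sum(act^2)))
    expect_true(all(F >= 0 & F <= u + 1e-9))
  }
  expect_lt(worst_res, 1e-6)
  expect_lt(worst_obj, 1e-9)
})

test_that("the two objectives generally choose different force distributions", {
  kin <- adopted_kinetics()
  mov <- default_movements()
  idx <- adopted_idx()[50]
  f1 <- solve_movement_forces(mov, which = idx, objective = "activation")
  f2 <- solve_movement_forces(mov, which = idx, objective = "stress")
  mid <- 30
  expect_gt(max(abs(f1$F[, 1, mid] - f2$F[, 1, mid])), 1)
})

test_that("overwhelming moment demands are flagged infeasible, not errored", {
  mus <- muscle_params()
  pr <- build_problem(c(50, 50, 50), 73.8, rep(100, 8), mus, "activation")
  sol <- solve_frame(pr)
  expect_false(sol$feasible)
  expect_true(all(is.na(sol$F_ce)))
})

test_that("frames are solved independently of batch order", {
  mov <- default_movements()
  idx <- adopted_idx()[c(2, 40, 200)]
  f_all <- solve_movement_forces(mov, which = idx)
  f_rev <- solve_movement_forces(mov, which = rev(idx))
  expect_equal(f_all$F[, 1, ], f_rev$F[, 3, ])
  expect_equal(f_all$F[, 3, ], f_rev$F[, 1, ])
})
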