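# Per-frame muscle redundancy problem: distribute the hip/knee/ankle joint
# moments over the eight muscles by minimizing either the sum of squared
# activations (F/F_MAX)^2 or the sum of squared stresses (F/PCSA)^2 subject
# to the moment equality constraints and 0 <= F <= F_MAX.

#' Signed moment-arm matrix
#'
#' Builds the 3 x 8 matrix `R` with `R[j, m] = sign * arm` (m), rows hip,
#' knee, ankle (extension / plantarflexion positive), columns in the order
#' of the muscle table; entries are zero where a muscle does not span a
#' joint.
#'
#' @param muscles a [muscle_params()] table
#' @return numeric matrix with dimnames
#' @export
moment_arm_matrix <- function(muscles = muscle_params()) {
  R <- rbind(hip = muscles$s_hip * muscles$r_hip,
             knee = muscles$s_knee * muscles$r_knee,
             ankle = muscles$s_ankle * muscles$r_ankle)
  colnames(R) <- muscles$muscle
  R
}

#' Assemble a single-frame optimization problem
#'
#' De-normalizes the mass-normalized joint moments by body mass and collects
#' the signed moment-arm matrix, force bounds and objective weights.
#'
#' @param moments_nmkg length-3 vector of hip/knee/ankle moments (Nm/kg,
#'   extension/plantarflexion positive)
#' @param body_mass body mass in kg
#' @param f_max length-8 vector of maximum muscle forces (N)
#' @param muscles a [muscle_params()] table
#' @param objective `"activation"` (weights F_MAX) or `"stress"` (weights PCSA)
#' @param arm_matrix optional signed moment-arm matrix override
#' @return list of class `sts_qp` with elements `A`, `b`, `u`, `w`
#' @export
build_problem <- function(moments_nmkg, body_mass, f_max,
                          muscles = muscle_params(),
                          objective = c("activation", "stress"),
                          arm_matrix = NULL) {
  objective <- match.arg(objective)
  A <- if (is.null(arm_matrix)) moment_arm_matrix(muscles) else arm_matrix
  stopifnot(length(moments_nmkg) == nrow(A), length(f_max) == ncol(A))
  w <- if (objective == "activation") f_max else muscles$pcsa_mean
  structure(list(A = A, b = moments_nmkg * body_mass,
                 u = pmax(f_max, 0), w = w, objective = objective),
            class = "sts_qp")
}

#' Solve a single-frame muscle force problem
#'
#' Finds the global optimum of the convex quadratic program assembled by
#' [build_problem()]. Infeasibility (no force vector within the bounds can
#' reproduce the moments) is reported via `feasible = FALSE`, not an error.
#'
#' @param problem an `sts_qp` object
#' @return list with `F_ce` (N, named), `feasible`, `objective_value`,
#'   `residuals` (Nm per joint)
#' @export
solve_frame <- function(problem) {
  sol <- qp_solve_batch(problem$A, matrix(problem$b, ncol = 1),
                        matrix(problem$u, ncol = 1),
                        matrix(problem$w, ncol = 1))
  F_ce <- drop(sol$F)
  names(F_ce) <- colnames(problem$A)
  list(F_ce = F_ce,
       feasible = sol$feasible[1],
       objective_value = sol$objective[1],
       residuals = if (sol$feasible[1]) problem$b - drop(problem$A %*% F_ce)
                   else rep(NA_real_, length(problem$b)))
}

#' Solve the muscle redundancy problem for whole movements
#'
#' Runs the per-frame static optimization independently for every frame of
#' the selected movements. A movement is "non-optimal" when any of its
#' frames is infeasible (the required moments exceed what the bounded
#' muscle forces can produce).
#'
#' @param mov an `sts_movements` object
#' @param kinetics an `sts_kinetics` object for the same `which` (computed
#'   if `NULL`)
#' @param muscles a [muscle_params()] table (possibly perturbed)
#' @param which movement indices
#' @param objective `"activation"` or `"stress"`
#' @param sigma specific tension N/cm^2
#' @param k force-length ability scaling
#' @param arm_matrix optional signed moment-arm matrix override (perturbed
#'   arms)
#' @param states precomputed [muscle_states()] (recomputed if `NULL`)
#' @return object of class `sts_muscle_forces`: `F` array (muscle x movement
#'   x frame, N), `feasible` and `objective_value` matrices (movement x
#'   frame), `infeasible_frames` per movement, `movement_feasible` flags
#' @export
solve_movement_forces <- function(mov, kinetics = NULL,
                                  muscles = muscle_params(),
                                  which = seq_len(nrow(mov$postures)),
                                  objective = c("activation", "stress"),
                                  sigma = 60, k = 1,
                                  arm_matrix = NULL, states = NULL) {
  objective <- match.arg(objective)
  body <- mov$body
  if (is.null(kinetics)) kinetics <- compute_joint_moments(mov, which = which)
  if (is.null(states)) states <- muscle_states(mov, muscles, which = which,
                                               sigma = sigma, k = k)
  A <- if (is.null(arm_matrix)) moment_arm_matrix(muscles) else arm_matrix
  n_mov <- length(which)
  n_fr <- mov$n_frames
  n_mu <- nrow(muscles)
  N <- n_mov * n_fr

  # frames stacked movement-major: column index = (movement - 1) * n_fr + frame
  bmat <- matrix(0, 3, N)
  bmat[1, ] <- as.vector(t(kinetics$hip_moment)) * body$mass
  bmat[2, ] <- as.vector(t(kinetics$knee_moment)) * body$mass
  bmat[3, ] <- as.vector(t(kinetics$ankle_moment)) * body$mass
  umat <- matrix(0, n_mu, N)
  for (i in seq_len(n_mu)) {
    umat[i, ] <- as.vector(t(states[[muscles$muscle[i]]]$F_max))
  }
  wmat <- if (objective == "activation") umat else
    matrix(muscles$pcsa_mean, n_mu, N)

  sol <- qp_solve_batch(A, bmat, umat, wmat)

  Farr <- array(sol$F, dim = c(n_mu, n_fr, n_mov),
                dimnames = list(muscles$muscle, NULL, NULL))
  Farr <- aperm(Farr, c(1, 3, 2))  # muscle x movement x frame
  feas <- matrix(sol$feasible, n_fr, n_mov)
  objv <- matrix(sol$objective, n_fr, n_mov)
  out <- list(
    F = Farr,
    feasible = t(feas),
    objective_value = t(objv),
    infeasible_frames = colSums(!feas),
    movement_feasible = colSums(!feas) == 0,
    which = which, objective = objective,
    muscles = muscles, arm_matrix = A
  )
  class(out) <- "sts_muscle_forces"
  out
}

#' @export
print.sts_muscle_forces <- function(x, ...) {
  cat(sprintf("Muscle force solutions (%s objective): %d movements x %d frames\n",
              x$objective, dim(x$F)[2], dim(x$F)[3]))
  cat(sprintf("  movements with all frames optimal: %d / %d\n",
              sum(x$movement_feasible), length(x$movement_feasible)))
  invisible(x)
}
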