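# Four-parameter sensitivity analysis: objective function, PCSA, muscle
# moment arm length, and force-length ability. For each of the two
# objectives, n_draws random parameter sets are drawn (uniform within the
# stated ranges) and the whole muscle-force / contact-force pipeline is
# re-run over the adopted movements with the perturbed parameters; one draw
# is shared by all movements of a run.

#' Draw one random parameter perturbation
#'
#' Adds, to the base muscle table, one uniform draw per muscle within
#' +/- SD of its PCSA, one uniform draw per nonzero muscle-joint moment arm
#' within +/- 1 cm, and one global force-length ability factor `k` uniform
#' in 0.5-1.5. Draws violating positivity (a perturbed PCSA or moment arm
#' <= 0) are redrawn for the offending entry.
#'
#' @param muscles base [muscle_params()] table
#' @param arm_delta_max moment arm perturbation half-range in m (default 0.01)
#' @param k_range range of the force-length ability factor
#' @return list with `muscles` (perturbed table), `arm_matrix` (perturbed
#'   signed moment arms), `k`, and the raw `pcsa_delta` / `arm_delta` draws
#' @export
draw_perturbation <- function(muscles = muscle_params(),
                              arm_delta_max = 0.01,
                              k_range = c(0.5, 1.5)) {
  n <- nrow(muscles)
  pcsa_delta <- runif(n, -muscles$pcsa_sd, muscles$pcsa_sd)
  pcsa <- muscles$pcsa_mean + pcsa_delta
  bad <- which(pcsa <= 0)
  while (length(bad) > 0) {
    pcsa_delta[bad] <- runif(length(bad), -muscles$pcsa_sd[bad],
                             muscles$pcsa_sd[bad])
    pcsa <- muscles$pcsa_mean + pcsa_delta
    bad <- which(pcsa <= 0)
  }
  arm_delta <- matrix(0, n, 3, dimnames = list(muscles$muscle,
                                               c("hip", "knee", "ankle")))
  arms <- cbind(muscles$r_hip, muscles$r_knee, muscles$r_ankle)
  for (j in 1:3) {
    span <- which(arms[, j] > 0)
    if (length(span) == 0) next
    d <- runif(length(span), -arm_delta_max, arm_delta_max)
    bad <- which(arms[span, j] + d <= 0)
    while (length(bad) > 0) {
      d[bad] <- runif(length(bad), -arm_delta_max, arm_delta_max)
      bad <- which(arms[span, j] + d <= 0)
    }
    arm_delta[span, j] <- d
  }
  k <- runif(1, k_range[1], k_range[2])

  pm <- muscles
  pm$pcsa_mean <- pcsa
  pm$r_hip <- arms[, 1] + arm_delta[, "hip"]
  pm$r_knee <- arms[, 2] + arm_delta[, "knee"]
  pm$r_ankle <- arms[, 3] + arm_delta[, "ankle"]
  list(muscles = pm, arm_matrix = moment_arm_matrix(pm), k = k,
       pcsa_delta = pcsa_delta, arm_delta = arm_delta)
}

#' Run the sensitivity analysis
#'
#' For each objective function and each of `n_draws_per_objective` parameter
#' draws (2 x 10 = 20 runs by default), re-estimates the muscle forces and
#' the hip joint contact force for every adopted movement with the perturbed
#' parameters. One parameter draw is shared across all movements of a run.
#'
#' @param mov an `sts_movements` object with adoption flags set
#' @param muscles base muscle table
#' @param n_draws_per_objective draws per objective (default 10)
#' @param seed RNG seed for reproducibility
#' @param which movement indices (`NULL` = the adopted set)
#' @param sigma specific tension N/cm^2
#' @return object of class `sts_sensitivity`: `runs` data.frame (one row per
#'   run: objective, draw, k, feasible movement count), `peak_hjcf` matrix
#'   (run x movement, N/kg, NA where any frame was infeasible),
#'   `movement_feasible` matrix, `seatoff_hip_deg`, and per-run draws
#' @export
run_sensitivity <- function(mov, muscles = muscle_params(),
                            n_draws_per_objective = 10, seed = 1,
                            which = NULL, sigma = 60) {
  if (is.null(which)) which <- base::which(mov$adopted)
  set.seed(seed)
  body <- mov$body
  kin <- compute_joint_moments(mov, which = which)
  attach_tab <- muscle_attachments()
  objectives <- c("activation", "stress")
  n_runs <- length(objectives) * n_draws_per_objective
  n_mov <- length(which)
  peak_hjcf <- matrix(NA_real_, n_runs, n_mov)
  mfeas <- matrix(NA, n_runs, n_mov)
  runs <- data.frame(run = seq_len(n_runs),
                     objective = rep(objectives, each = n_draws_per_objective),
                     draw = rep(seq_len(n_draws_per_objective), 2),
                     k = NA_real_, feasible_movements = NA_integer_,
                     infeasible_frames = NA_integer_)
  draws <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    pert <- draw_perturbation(muscles)
    draws[[r]] <- pert
    runs$k[r] <- pert$k
    fr <- solve_movement_forces(mov, kinetics = kin, muscles = pert$muscles,
                                which = which, objective = runs$objective[r],
                                sigma = sigma, k = pert$k,
                                arm_matrix = pert$arm_matrix)
    cf <- hip_contact_force(kin, fr, body, attachments = attach_tab)
    pk <- cf$peak
    pk[!fr$movement_feasible] <- NA_real_
    peak_hjcf[r, ] <- pk
    mfeas[r, ] <- fr$movement_feasible
    runs$feasible_movements[r] <- sum(fr$movement_feasible)
    runs$infeasible_frames[r] <- sum(fr$infeasible_frames)
  }
  out <- list(runs = runs, peak_hjcf = peak_hjcf,
              movement_feasible = mfeas,
              seatoff_hip_deg = mov$postures$hip_deg[which],
              which = which, seed = seed, draws = draws)
  class(out) <- "sts_sensitivity"
  out
}

#' @export
print.sts_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: %d runs x %d movements (seed %d)\n",
              nrow(x$runs), ncol(x$peak_hjcf), x$seed))
  for (obj in unique(x$runs$objective)) {
    sel <- x$runs$objective == obj
    cat(sprintf("  %s objective: %d / %d movement solutions optimal\n",
                obj, sum(x$runs$feasible_movements[sel]),
                sum(sel) * ncol(x$peak_hjcf)))
  }
  invisible(x)
}

#' Correlation between seat-off hip angle and peak contact force per run
#'
#' @param sens an `sts_sensitivity` object
#' @param method correlation type (default Pearson)
#' @return numeric vector, one correlation per run (feasible movements only)
#' @export
sensitivity_correlations <- function(sens, method = "pearson") {
  apply(sens$peak_hjcf, 1, function(pk) {
    ok <- !is.na(pk)
    cor(sens$seatoff_hip_deg[ok], pk[ok], method = method)
  })
}
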