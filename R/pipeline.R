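# Study orchestration: run every stage (grid -> trajectories -> filters ->
# inverse dynamics -> static optimization -> contact force -> sensitivity),
# collect a per-movement summary table and the aggregate comparisons.

#' Study configuration
#'
#' Collects and validates every tunable of the simulation with the study
#' defaults: 1.74 m / 73.8 kg body, hip height 0.513 m at seat-off, 41 x 71
#' seat-off grid, 1.55 s movement over 101 frames, adoption ranges
#' hip 85-145 / knee 95-120 / ankle 15-45 degrees, specific tension
#' 60 N/cm^2, activation-squared objective, 10 sensitivity draws per
#' objective.
#'
#' @param height,mass body dimensions (m, kg)
#' @param hip_height_seatoff hip height at seat-off (m)
#' @param heel_to_ankle_x horizontal heel-to-ankle offset (m)
#' @param duration movement duration (s)
#' @param n_frames time samples per movement
#' @param hip_dx_values,trunk_angles_deg seat-off grid
#' @param hip_range,knee_range,ankle_range adoption intervals (deg)
#' @param sigma specific tension (N/cm^2)
#' @param objective `"activation"` or `"stress"`
#' @param n_draws_per_objective sensitivity draws per objective
#' @param seed RNG seed
#' @param out_dir output directory (`NULL` = no files written)
#' @param verbose print per-stage progress
#' @return a validated list of class `study_config`
#' @export
study_config <- function(height = 1.74, mass = 73.8,
                         hip_height_seatoff = 0.513,
                         heel_to_ankle_x = 0.06,
                         duration = 1.55, n_frames = 101,
                         hip_dx_values = -(0:40) / 100,
                         trunk_angles_deg = 0:70,
                         hip_range = c(85, 145), knee_range = c(95, 120),
                         ankle_range = c(15, 45),
                         sigma = 60,
                         objective = c("activation", "stress"),
                         n_draws_per_objective = 10,
                         seed = 1, out_dir = NULL, verbose = FALSE) {
  objective <- match.arg(objective)
  stopifnot(height > 0, mass > 0, duration > 0, n_frames >= 3, sigma > 0,
            n_draws_per_objective >= 0)
  cfg <- list(height = height, mass = mass,
              hip_height_seatoff = hip_height_seatoff,
              heel_to_ankle_x = heel_to_ankle_x,
              duration = duration, n_frames = n_frames,
              hip_dx_values = hip_dx_values,
              trunk_angles_deg = trunk_angles_deg,
              hip_range = hip_range, knee_range = knee_range,
              ankle_range = ankle_range, sigma = sigma,
              objective = objective,
              n_draws_per_objective = n_draws_per_objective,
              seed = seed, out_dir = out_dir, verbose = verbose)
  class(cfg) <- "study_config"
  cfg
}

write_config_copy <- function(cfg, path) {
  fmt <- function(v) paste(format(v, digits = 15), collapse = ", ")
  lines <- vapply(setdiff(names(cfg), c("out_dir", "verbose")),
                  function(nm) sprintf("%s: %s", nm, fmt(cfg[[nm]])),
                  character(1))
  writeLines(lines, path)
}

#' Run the full study
#'
#' Executes every stage of the simulation under one configuration and
#' returns the per-movement summary table, the aggregate summary (see
#' [summarize_study()]) and, when `n_draws_per_objective > 0`, the
#' sensitivity result. When `cfg$out_dir` is set, writes `movements.csv`,
#' `summary_per_movement.csv`, `summary.csv`, `correlations.csv`,
#' `sensitivity.csv`, a config copy and a plain-text log.
#'
#' @param cfg a [study_config()]
#' @return list of class `sts_study` with elements `config`, `body`,
#'   `movements`, `per_movement`, `summary`, `sensitivity`
#' @export
run_full_study <- function(cfg = study_config()) {
  t_start <- Sys.time()
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, sprintf("[%6.1f s] %s",
                           as.numeric(Sys.time() - t_start, units = "secs"),
                           msg))
    if (cfg$verbose) message(msg)
  }

  say("building body model (%.2f m, %.1f kg)", cfg$height, cfg$mass)
  body <- build_body_model(cfg$height, cfg$mass,
                           hip_height_seatoff = cfg$hip_height_seatoff,
                           heel_to_ankle_x = cfg$heel_to_ankle_x)
  grid <- generate_posture_grid(body, cfg$hip_dx_values, cfg$trunk_angles_deg)
  say("generated %d seat-off postures", nrow(grid))
  mov <- generate_movements(body, grid, duration = cfg$duration,
                            n_frames = cfg$n_frames)
  mov <- apply_adoption_filters(mov, cfg$hip_range, cfg$knee_range,
                                cfg$ankle_range)
  say("adopted %d movements, %d normal", sum(mov$adopted), sum(mov$normal))
  if (sum(mov$adopted) == 0) stop("stage adoption: no movements adopted")

  idx <- which(mov$adopted)
  kin <- compute_joint_moments(mov, which = idx)
  kin_s <- static_moment_component(mov, which = idx)
  say("inverse dynamics done for %d movements", length(idx))

  muscles <- muscle_params()
  forces <- solve_movement_forces(mov, kinetics = kin, muscles = muscles,
                                  which = idx, objective = cfg$objective,
                                  sigma = cfg$sigma)
  say("static optimization (%s): %d/%d movements optimal, %d infeasible frames",
      cfg$objective, sum(forces$movement_feasible), length(idx),
      sum(forces$infeasible_frames))
  contact <- hip_contact_force(kin, forces, body)
  say("contact force done")

  per_movement <- per_movement_table(mov, idx, kin, kin_s, forces, contact,
                                     body)
  summary <- summarize_study(per_movement)

  sens <- NULL
  if (cfg$n_draws_per_objective > 0) {
    sens <- run_sensitivity(mov, muscles,
                            n_draws_per_objective = cfg$n_draws_per_objective,
                            seed = cfg$seed, which = idx, sigma = cfg$sigma)
    say("sensitivity: %d runs", nrow(sens$runs))
  }

  out <- list(config = cfg, body = body, movements = mov,
              per_movement = per_movement, summary = summary,
              sensitivity = sens, log = log)
  class(out) <- "sts_study"

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(cfg$out_dir, f)
    mtab <- mov$postures
    mtab$adopted <- mov$adopted
    mtab$normal <- mov$normal
    mtab$exclusion_reason <- mov$exclusion_reason
    write.csv(mtab, p("movements.csv"), row.names = FALSE)
    write.csv(per_movement, p("summary_per_movement.csv"), row.names = FALSE)
    write.csv(summary$aggregates, p("summary.csv"), row.names = FALSE)
    write.csv(summary$correlations, p("correlations.csv"), row.names = FALSE)
    if (!is.null(sens)) {
      write.csv(sens$runs, p("sensitivity.csv"), row.names = FALSE)
    }
    write_config_copy(cfg, p("config.txt"))
    writeLines(log, p("log.txt"))
  }
  out
}

#' @export
print.sts_study <- function(x, ...) {
  cat("STS study run\n")
  cat(sprintf("  adopted %d movements (%d normal)\n",
              nrow(x$per_movement), sum(x$per_movement$normal)))
  print(x$summary$aggregates, row.names = FALSE)
  invisible(x)
}

per_movement_table <- function(mov, idx, kin, kin_s, forces, contact, body) {
  p <- mov$postures[idx, ]
  # per-movement signed peak (value of largest magnitude over frames)
  signed_peak <- function(m) {
    m[cbind(seq_len(nrow(m)), max.col(abs(m), ties.method = "first"))]
  }
  pkF <- function(mu) apply(forces$F[mu, , , drop = FALSE], 2, max) / body$mass
  data.frame(
    posture_id = p$posture_id,
    hip_deg = p$hip_deg, knee_deg = p$knee_deg, ankle_deg = p$ankle_deg,
    normal = mov$normal[idx],
    peak_hip_moment = apply(kin$hip_moment, 1, max),
    peak_knee_moment = apply(kin$knee_moment, 1, max),
    peak_ankle_moment = signed_peak(kin$ankle_moment),
    peak_static_hip_moment = signed_peak(kin_s$hip_moment),
    peak_static_knee_moment = signed_peak(kin_s$knee_moment),
    peak_static_ankle_moment = signed_peak(kin_s$ankle_moment),
    peak_f_gluteus_maximus = pkF("gluteus_maximus"),
    peak_f_hamstrings = pkF("hamstrings"),
    peak_f_vastus = pkF("vastus"),
    peak_f_rectus_femoris = pkF("rectus_femoris"),
    peak_hjcf = contact$peak,
    feasible = forces$movement_feasible
  )
}

#' Aggregate summary of a study
#'
#' Computes, from the per-movement table, the study-level comparison rows:
#' the minimum over adopted movements of the absolute peak static hip, knee
#' and ankle moments; the minimum sum of the peak hip and knee moments; the
#' mean (SD) peak hip extension moment and mean peak hip joint contact
#' force over the normal movements; the mean peak muscle forces over the
#' adopted and the normal movements; and Pearson/Spearman correlations for
#' the relationships between seat-off hip angle, peak contact force, peak
#' hip extensor muscle force and peak hip extension moment.
#'
#' @param per_movement the per-movement table of an [run_full_study()] result
#' @return list with data.frames `aggregates` and `correlations`
#' @export
summarize_study <- function(per_movement) {
  pm <- per_movement
  if (!any(pm$normal)) stop("no normal movements in the summary table")
  no <- pm[pm$normal & pm$feasible, ]
  ad <- pm[pm$feasible, ]
  min_abs <- function(x) x[which.min(abs(x))]
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  quad_ad <- ad$peak_f_vastus + ad$peak_f_rectus_femoris
  quad_no <- no$peak_f_vastus + no$peak_f_rectus_femoris
  ext_ad <- ad$peak_f_gluteus_maximus + ad$peak_f_hamstrings
  aggregates <- data.frame(
    quantity = c(
      "min_abs_peak_static_hip_moment_nmkg",
      "min_abs_peak_static_knee_moment_nmkg",
      "static_ankle_moment_at_min_abs_nmkg",
      "min_sum_peak_hip_knee_moment_nmkg",
      "mean_peak_hip_moment_normal_nmkg",
      "sd_peak_hip_moment_normal_nmkg",
      "mean_peak_gmax_force_adopted_nkg",
      "mean_peak_hamstrings_force_adopted_nkg",
      "mean_peak_quadriceps_force_adopted_nkg",
      "mean_peak_extensor_sum_adopted_nkg",
      "mean_peak_gmax_force_normal_nkg",
      "mean_peak_hamstrings_force_normal_nkg",
      "mean_peak_quadriceps_force_normal_nkg",
      "mean_peak_hjcf_normal_nkg",
      "n_adopted", "n_normal"),
    value = c(
      abs(min_abs(pm$peak_static_hip_moment)),
      abs(min_abs(pm$peak_static_knee_moment)),
      min_abs(pm$peak_static_ankle_moment),
      min(pm$peak_hip_moment + pm$peak_knee_moment),
      mean(no$peak_hip_moment), sd0(no$peak_hip_moment),
      mean(ad$peak_f_gluteus_maximus), mean(ad$peak_f_hamstrings),
      mean(quad_ad), mean(ext_ad + quad_ad),
      mean(no$peak_f_gluteus_maximus), mean(no$peak_f_hamstrings),
      mean(quad_no),
      mean(no$peak_hjcf),
      nrow(pm), sum(pm$normal))
  )
  ext_force <- ad$peak_f_gluteus_maximus + ad$peak_f_hamstrings
  pairs <- list(
    c("hip_deg", "peak_hjcf"),
    c("hip_deg", "peak_hip_moment"),
    c("hip_deg", "extensor_force"),
    c("peak_hjcf", "peak_hip_moment"),
    c("peak_hjcf", "extensor_force")
  )
  tab <- cbind(ad, extensor_force = ext_force)
  correlations <- do.call(rbind, lapply(pairs, function(pr) {
    data.frame(x = pr[1], y = pr[2],
               pearson = cor(tab[[pr[1]]], tab[[pr[2]]]),
               spearman = cor(tab[[pr[1]]], tab[[pr[2]]], method = "spearman"))
  }))
  list(aggregates = aggregates, correlations = correlations)
}

#' Seat-height scaling comparison value
#'
#' Scales a peak contact force obtained at a 0.4 m seat height to its
#' 0.5 m-seat-height equivalent by dividing by the reported ratio of peak
#' hip moments between the two heights (1.3 by default): 26.3 / 1.3 = 20.2
#' N/kg.
#'
#' @param mean_peak_hjcf mean peak hip joint contact force, N/kg
#' @param factor seat-height moment ratio
#' @return scaled value in N/kg
#' @export
seat_height_scaling_note <- function(mean_peak_hjcf, factor = 1.3) {
  stopifnot(factor > 0)
  mean_peak_hjcf / factor
}
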