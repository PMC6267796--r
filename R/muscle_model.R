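#' Muscle parameter table
#'
#' Reads the eight-muscle parameter fixture shipped with the package:
#' physiological cross-sectional areas (mean and SD, cm^2), constant muscle
#' moment arm lengths per spanned joint (m, evaluated at the mean seat-off
#' posture of 120/109/35 degrees), the action sign per joint (+1 for
#' extensors/plantarflexors, -1 for flexors/dorsiflexors, 0 when the joint
#' is not spanned), and the quadratic fiber-length-ratio coefficients
#' (`b`, `a`) per joint such that the contribution of joint angle theta
#' (radians, flexion positive) to the fiber length ratio is
#' `b * (theta - theta_ref) + a * (theta - theta_ref)^2` around the
#' reference posture where the ratio is 1. The quadratic coefficients are a
#' synthetic, documented fixture with slopes signed by anatomical action.
#'
#' @param path CSV file; defaults to the shipped fixture
#' @return a data.frame of class `muscle_params`, one row per muscle
#' @export
muscle_params <- function(path = system.file("extdata", "muscles.csv",
                                             package = "sitstand",
                                             mustWork = TRUE)) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(m$pcsa_mean > 0), all(m$pcsa_sd >= 0))
  class(m) <- c("muscle_params", "data.frame")
  m
}

#' Hip-spanning muscle names
#' @return character vector of the four muscles crossing the hip joint
#' @export
hip_muscles <- function() {
  c("iliopsoas", "gluteus_maximus", "rectus_femoris", "hamstrings")
}

# reference posture (deg) at which the fiber-length ratio is 1 and the
# moment arms of the parameter table are defined
REF_POSTURE_DEG <- c(hip = 120, knee = 109, ankle = 35)

#' Muscle fiber length ratio
#'
#' Quadratic approximation of the normalized fiber length as a function of
#' the spanned joint angles; biarticular muscles sum the contributions of
#' both joints around a reference ratio of 1 (taken at the mean seat-off
#' posture).
#'
#' @param muscle one row of [muscle_params()] (or the full table with
#'   `name` given)
#' @param hip_deg,knee_deg,ankle_deg joint angles (degrees, flexion /
#'   dorsiflexion positive); scalars, vectors or matrices of equal shape
#' @return fiber length ratio, same shape as the angle input
#' @export
fiber_length_ratio <- function(muscle, hip_deg, knee_deg, ankle_deg) {
  d2r <- pi / 180
  dh <- (hip_deg - REF_POSTURE_DEG[["hip"]]) * d2r
  dk <- (knee_deg - REF_POSTURE_DEG[["knee"]]) * d2r
  da <- (ankle_deg - REF_POSTURE_DEG[["ankle"]]) * d2r
  1 +
    muscle$b_hip * dh + muscle$a_hip * dh^2 +
    muscle$b_knee * dk + muscle$a_knee * dk^2 +
    muscle$b_ankle * da + muscle$a_ankle * da^2
}

# analytic time derivative of the fiber length ratio given joint angles and
# their time derivatives (deg, deg/s); returns ratio/s
fiber_length_rate <- function(muscle, hip_deg, knee_deg, ankle_deg,
                              hip_dps, knee_dps, ankle_dps) {
  d2r <- pi / 180
  dh <- (hip_deg - REF_POSTURE_DEG[["hip"]]) * d2r
  dk <- (knee_deg - REF_POSTURE_DEG[["knee"]]) * d2r
  da <- (ankle_deg - REF_POSTURE_DEG[["ankle"]]) * d2r
  (muscle$b_hip + 2 * muscle$a_hip * dh) * hip_dps * d2r +
    (muscle$b_knee + 2 * muscle$a_knee * dk) * knee_dps * d2r +
    (muscle$b_ankle + 2 * muscle$a_ankle * da) * ankle_dps * d2r
}

#' Normalized force-length curve
#'
#' Bell-shaped (Gaussian) active force-length scaling: maximum 1 at a fiber
#' length ratio of 1, width 0.45, truncated to zero at and beyond ratios of
#' 0.5 and 1.5.
#'
#' @param L fiber length ratio
#' @param width Gaussian width parameter
#' @param support half-width of the truncation interval around 1
#' @return normalized force in `[0, 1]`
#' @export
force_length <- function(L, width = 0.45, support = 0.5) {
  f <- exp(-((L - 1) / width)^2)
  f[L <= 1 - support | L >= 1 + support] <- 0
  f
}

#' Normalized force-velocity curve
#'
#' Hill hyperbola for shortening (`f_v(-1) = 0`, `f_v(0) = 1`, shape
#' parameter a/F0 = 0.25) and a slope-continuous saturating branch for
#' lengthening with an eccentric plateau below 1.5.
#'
#' @param V normalized fiber velocity (optimal lengths per second divided by
#'   the maximum shortening velocity; shortening negative)
#' @param a_f0 Hill shape parameter a/F0
#' @param ecc_gain eccentric force gain above isometric (plateau = 1 + gain)
#' @return normalized force in `[0, 1 + ecc_gain)`
#' @export
force_velocity <- function(V, a_f0 = 0.25, ecc_gain = 0.5) {
  f <- numeric(length(V))
  dim(f) <- dim(V)
  sh <- V < 0
  v <- pmax(V, -1)
  # concentric: (1 + v) / (1 - v / a_f0); slope at 0 is 1 + 1/a_f0
  f[sh] <- (1 + v[sh]) / (1 - v[sh] / a_f0)
  # eccentric: 1 + g * v / (v + c), slope-matched at v = 0 via c = g / (1 + 1/a_f0)
  cc <- ecc_gain / (1 + 1 / a_f0)
  f[!sh] <- 1 + ecc_gain * v[!sh] / (v[!sh] + cc)
  f
}

#' Per-frame muscle states and maximum forces for a movement set
#'
#' For each muscle, evaluates the fiber length ratio, the normalized fiber
#' velocity (analytic differentiation of the quadratic ratio composed with
#' the cosine trajectories, divided by `vmax`), the force-length and
#' force-velocity scalings, and the maximum contractile-element force
#' `F_MAX = k * f_ce * f_v * PCSA * sigma`.
#'
#' @param mov an `sts_movements` object
#' @param muscles a [muscle_params()] table
#' @param which movement indices
#' @param sigma specific muscle tension, N/cm^2 (default 60)
#' @param k force-length ability scaling (default 1; perturbed by the
#'   sensitivity analysis)
#' @param vmax maximum fiber shortening velocity, optimal lengths/s
#' @return list with, per muscle name, a list of movements x frames matrices
#'   `L` (ratio), `V` (normalized velocity), `f_ce`, `f_v`, `F_max` (N)
#' @export
muscle_states <- function(mov, muscles = muscle_params(),
                          which = seq_len(nrow(mov$postures)),
                          sigma = 60, k = 1, vmax = 10) {
  p <- mov$postures[which, ]
  hip <- outer(p$hip_deg, mov$w)
  knee <- outer(p$knee_deg, mov$w)
  ankle <- outer(p$ankle_deg, mov$w)
  hip_d <- outer(p$hip_deg, mov$wd)
  knee_d <- outer(p$knee_deg, mov$wd)
  ankle_d <- outer(p$ankle_deg, mov$wd)
  out <- list()
  for (i in seq_len(nrow(muscles))) {
    mu <- muscles[i, ]
    L <- fiber_length_ratio(mu, hip, knee, ankle)
    V <- fiber_length_rate(mu, hip, knee, ankle, hip_d, knee_d, ankle_d) / vmax
    f_ce <- force_length(L)
    f_v <- force_velocity(V)
    F_max <- pmax(k * f_ce * f_v * mu$pcsa_mean * sigma, 0)
    out[[mu$muscle]] <- list(L = L, V = V, f_ce = f_ce, f_v = f_v,
                             F_max = F_max)
  }
  attr(out, "muscles") <- muscles
  out
}

#' Maximum muscle force from a muscle state
#'
#' `F_MAX = k * f_ce(L) * f_v(V) * PCSA * sigma`, clipped at zero.
#'
#' @param pcsa physiological cross-sectional area, cm^2
#' @param f_ce,f_v normalized force-length and force-velocity factors
#' @param sigma specific tension, N/cm^2
#' @param k force-length ability scaling
#' @return maximum contractile-element force in N
#' @export
max_muscle_force <- function(pcsa, f_ce, f_v, sigma = 60, k = 1) {
  pmax(k * f_ce * f_v * pcsa * sigma, 0)
}
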