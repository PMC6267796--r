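# Hip joint contact force: the norm of the hip intersegmental force minus
# the force-weighted sum of the hip-spanning muscle line-of-action unit
# vectors (iliopsoas, gluteus maximus, rectus femoris, hamstrings).

#' Muscle attachment table
#'
#' Reads the sagittal attachment fixture for the four hip-spanning muscles:
#' one point in the pelvis frame (origin at the hip joint, +y along the
#' trunk toward the shoulder, +x anterior; for the gluteus maximus this is
#' its ischial-tuberosity via point) and one point in the femur frame
#' (origin at the hip joint, +y distal along the thigh, +x anterior). The
#' coordinates are a synthetic, documented stand-in for unpublished
#' cadaver-based lines of action; only the unit directions enter the
#' contact-force computation.
#'
#' @param path CSV file; defaults to the shipped fixture
#' @return data.frame with columns `muscle`, `pelvis_x`, `pelvis_y`,
#'   `femur_x`, `femur_y`, `note`
#' @export
muscle_attachments <- function(path = system.file("extdata", "attachments.csv",
                                                  package = "sitstand",
                                                  mustWork = TRUE)) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Muscle line-of-action unit vectors
#'
#' For each hip-spanning muscle, the global-frame unit vector pointing from
#' its femoral attachment toward its pelvic attachment (or via point), i.e.
#' the direction of the muscle pull on the femur-side free body, for every
#' movement and frame.
#'
#' @param muscle muscle name (must span the hip)
#' @param theta_th,theta_tr thigh (knee to hip) and trunk orientation angles
#'   in radians, clockwise from vertical; matrices or scalars of equal shape
#' @param attachments attachment table from [muscle_attachments()]
#' @return list with components `x`, `y` (same shape as the inputs); the
#'   vector norm is 1 everywhere
#' @export
muscle_line_unit_vector <- function(muscle, theta_th, theta_tr,
                                    attachments = muscle_attachments()) {
  row <- attachments[attachments$muscle == muscle, ]
  if (nrow(row) != 1) {
    stop("'", muscle, "' does not span the hip joint (no attachment entry)")
  }
  # pelvis frame axes in the global frame
  pel_x <- row$pelvis_x * cos(theta_tr) + row$pelvis_y * sin(theta_tr)
  pel_y <- -row$pelvis_x * sin(theta_tr) + row$pelvis_y * cos(theta_tr)
  # femur frame: +y distal along the thigh (opposite the knee->hip direction)
  fem_x <- row$femur_x * cos(theta_th) - row$femur_y * sin(theta_th)
  fem_y <- -row$femur_x * sin(theta_th) - row$femur_y * cos(theta_th)
  dx <- pel_x - fem_x
  dy <- pel_y - fem_y
  nrm <- sqrt(dx^2 + dy^2)
  list(x = dx / nrm, y = dy / nrm)
}

#' Hip joint contact force
#'
#' `HJCF = || v_HJF - sum_n (F_n / M) e_n ||` per frame: the Euclidean norm
#' of the hip intersegmental force minus the mass-normalized muscle forces
#' of the four hip-spanning muscles along their line-of-action unit
#' vectors. All quantities are per leg and normalized by body mass (N/kg).
#'
#' @param kinetics an `sts_kinetics` object (provides `hjf_x`, `hjf_y` and
#'   the kinematics for the segment orientations)
#' @param forces an `sts_muscle_forces` object for the same movements
#' @param body body model (for the mass normalization)
#' @param attachments attachment table
#' @return object of class `sts_contact`: `hjcf` matrix (movement x frame,
#'   N/kg), `peak` (per movement), `feasible` flags carried over from the
#'   force solutions
#' @export
hip_contact_force <- function(kinetics, forces, body,
                              attachments = muscle_attachments()) {
  if (!identical(dim(kinetics$hjf_x), dim(forces$feasible))) {
    stop("kinetics and muscle force series have mismatched dimensions")
  }
  rx <- kinetics$hjf_x
  ry <- kinetics$hjf_y
  for (mu in hip_muscles()) {
    e <- muscle_line_unit_vector(mu, kinetics$kin$theta_th,
                                 kinetics$kin$theta_tr, attachments)
    Fm <- forces$F[mu, , , drop = TRUE] / body$mass
    if (is.null(dim(Fm))) Fm <- matrix(Fm, nrow = nrow(rx))
    rx <- rx - Fm * e$x
    ry <- ry - Fm * e$y
  }
  hjcf <- sqrt(rx^2 + ry^2)
  peak <- apply(hjcf, 1, max)
  out <- list(hjcf = hjcf, peak = peak,
              movement_feasible = forces$movement_feasible,
              which = forces$which)
  class(out) <- "sts_contact"
  out
}

#' @export
print.sts_contact <- function(x, ...) {
  cat(sprintf("Hip joint contact force: %d movements x %d frames\n",
              nrow(x$hjcf), ncol(x$hjcf)))
  ok <- x$movement_feasible
  cat(sprintf("  mean peak over optimal movements: %.1f N/kg\n",
              mean(x$peak[ok])))
  invisible(x)
}

#' Frontal-plane gluteus medius adjustment
#'
#' The sagittal model omits the gluteus medius; an order-of-magnitude
#' correction to the hip joint contact force is its PCSA times a submaximal
#' activation fraction times the specific tension, divided by body mass:
#' with the defaults, (45.6 cm^2 x 0.11 x 60 N/cm^2) / 73.8 kg = 4.1 N/kg.
#'
#' @param pcsa gluteus medius PCSA in cm^2
#' @param activation_fraction activation relative to maximum (0-1)
#' @param sigma specific tension, N/cm^2
#' @param body_mass body mass, kg
#' @return adjustment in N/kg
#' @export
gluteus_medius_adjustment <- function(pcsa = 45.6, activation_fraction = 0.11,
                                      sigma = 60, body_mass = 73.8) {
  stopifnot(pcsa > 0, sigma > 0, body_mass > 0)
  pcsa * activation_fraction * sigma / body_mass
}
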