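#' Two-link inverse kinematics for the leg
#'
#' Given hip and ankle positions and the thigh and shank lengths, returns the
#' knee position as the anterior (larger X) of the two circle intersections,
#' i.e. the solution with the knee flexed forward. Vectorized over postures.
#'
#' @param hip_x,hip_y,ankle_x,ankle_y joint coordinates in m
#' @param thigh_length,shank_length segment lengths in m
#' @return a data.frame with columns `knee_x`, `knee_y`, `valid`; unreachable
#'   configurations have `valid = FALSE` and `NA` knee coordinates
#' @export
solve_leg_configuration <- function(hip_x, hip_y, ankle_x, ankle_y,
                                    thigh_length, shank_length) {
  dx <- ankle_x - hip_x
  dy <- ankle_y - hip_y
  d <- sqrt(dx^2 + dy^2)
  tol <- 1e-12
  valid <- d <= thigh_length + shank_length + tol &
    d >= abs(thigh_length - shank_length) - tol & d > tol
  # distance from hip along the hip->ankle axis to the foot of the knee
  a <- (thigh_length^2 - shank_length^2 + d^2) / (2 * d)
  h2 <- pmax(thigh_length^2 - a^2, 0)
  h <- sqrt(h2)
  ux <- dx / d
  uy <- dy / d
  bx <- hip_x + a * ux
  by <- hip_y + a * uy
  # two intersections: base +/- h * perpendicular; take the anterior one
  k1x <- bx - h * uy; k1y <- by + h * ux
  k2x <- bx + h * uy; k2y <- by - h * ux
  anterior <- k1x >= k2x
  knee_x <- ifelse(anterior, k1x, k2x)
  knee_y <- ifelse(anterior, k1y, k2y)
  knee_x[!valid] <- NA_real_
  knee_y[!valid] <- NA_real_
  data.frame(knee_x = knee_x, knee_y = knee_y, valid = valid)
}

# orientation angle of a direction vector, measured from vertical (+Y),
# positive clockwise toward +X (anterior); returns degrees
orient_deg <- function(dx, dy) atan2(dx, dy) * 180 / pi

#' Joint angles of a seat-off posture
#'
#' Computes hip flexion, knee flexion and ankle dorsiflexion (degrees,
#' flexion/dorsiflexion positive) from joint positions and the trunk
#' orientation. Conventions: all three angles are zero in the upright
#' standing posture (segments stacked vertically); hip flexion is the angle
#' between the trunk and the thigh prolongation, knee flexion the angle
#' between thigh and shank, ankle dorsiflexion the forward inclination of
#' the shank with the foot flat.
#'
#' @param hip_x,hip_y,knee_x,knee_y,ankle_x,ankle_y joint positions in m
#' @param trunk_angle_deg trunk inclination, degrees clockwise from vertical
#' @return data.frame with `hip_deg`, `knee_deg`, `ankle_deg`
#' @export
compute_joint_angles <- function(hip_x, hip_y, knee_x, knee_y,
                                 ankle_x, ankle_y, trunk_angle_deg) {
  theta_s <- orient_deg(knee_x - ankle_x, knee_y - ankle_y)   # shank, ankle->knee
  theta_th <- orient_deg(hip_x - knee_x, hip_y - knee_y)      # thigh, knee->hip
  theta_tr <- trunk_angle_deg                                  # trunk, hip->top
  data.frame(hip_deg = theta_tr - theta_th,
             knee_deg = theta_s - theta_th,
             ankle_deg = theta_s)
}

#' Generate the seat-off posture grid
#'
#' Builds the full grid of candidate seat-off postures: the hip X position is
#' placed 0 to 40 cm posterior to the ankle in 1 cm steps (41 values) and the
#' trunk is inclined 0 to 70 degrees clockwise from vertical in 1 degree
#' steps (71 values), giving 41 x 71 = 2911 postures by default. The hip
#' height is fixed at the seat-off hip height of the body model. Knee
#' position is resolved by two-link inverse kinematics; geometrically
#' impossible postures are retained with `valid = FALSE`.
#'
#' @param body a [build_body_model()] object
#' @param hip_dx_values hip X positions relative to the ankle (m)
#' @param trunk_angles_deg trunk inclination values (degrees)
#' @return a data.frame of class `sts_grid`, one row per posture, with joint
#'   positions and seat-off joint angles
#' @examples
#' grid <- generate_posture_grid(build_body_model())
#' nrow(grid)  # 2911
#' @export
generate_posture_grid <- function(body,
                                  hip_dx_values = -(0:40) / 100,
                                  trunk_angles_deg = 0:70) {
  g <- expand.grid(trunk_angle_deg = trunk_angles_deg,
                   hip_dx = hip_dx_values,
                   KEEP.OUT.ATTRS = FALSE)
  # order: hip position varies slowest, trunk angle fastest
  g <- g[order(match(g$hip_dx, hip_dx_values), g$trunk_angle_deg), ]
  rownames(g) <- NULL
  hip_x <- g$hip_dx
  hip_y <- rep(body$hip_height_seatoff, nrow(g))
  ankle_x <- rep(0, nrow(g))
  ankle_y <- rep(body$ankle_height, nrow(g))
  knee <- solve_leg_configuration(hip_x, hip_y, ankle_x, ankle_y,
                                  body$thigh$length, body$shank$length)
  ang <- compute_joint_angles(hip_x, hip_y, knee$knee_x, knee$knee_y,
                              ankle_x, ankle_y, g$trunk_angle_deg)
  out <- data.frame(
    posture_id = seq_len(nrow(g)),
    hip_dx = g$hip_dx,
    trunk_angle_deg = g$trunk_angle_deg,
    hip_x = hip_x, hip_y = hip_y,
    knee_x = knee$knee_x, knee_y = knee$knee_y,
    ankle_x = ankle_x, ankle_y = ankle_y,
    valid = knee$valid,
    hip_deg = ang$hip_deg,
    knee_deg = ang$knee_deg,
    ankle_deg = ang$ankle_deg
  )
  class(out) <- c("sts_grid", "data.frame")
  out
}
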