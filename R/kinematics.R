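# Batch segment kinematics for a movement set.
#
# Segment orientation angles are measured from vertical (+Y), positive
# clockwise toward +X (anterior). With the foot flat and the ankle fixed,
# the joint angles (ankle dorsiflexion phi_a, knee flexion phi_k, hip
# flexion phi_h) determine the segment orientations:
#   shank theta_s  = phi_a
#   thigh theta_th = phi_a - phi_k          (direction knee -> hip)
#   trunk theta_tr = phi_a - phi_k + phi_h  (direction hip -> top)
# Because every joint angle is its seat-off value times the common cosine
# weight w(t), each orientation angle is its seat-off value times w(t), and
# velocities/accelerations follow analytically from the derivatives of w.

#' Segment kinematics of a movement set
#'
#' Computes, for the selected movements and every frame, the segment
#' orientation angles, joint positions, segment COM positions and (when
#' `derivatives = TRUE`) their analytic accelerations and the segment
#' angular accelerations. All returned elements are movements x frames
#' matrices. Physical angular quantities (`alpha_*`) use the right-handed
#' z-convention (counterclockwise positive in the X-right, Y-up plane).
#'
#' @param mov an `sts_movements` object
#' @param body body model (defaults to the one inside `mov`)
#' @param which movement indices
#' @param derivatives compute accelerations as well as positions
#' @return a list of matrices; see source for element names
#' @export
movement_kinematics <- function(mov, body = mov$body,
                                which = seq_len(nrow(mov$postures)),
                                derivatives = TRUE) {
  p <- mov$postures[which, ]
  d2r <- pi / 180
  phi_a <- p$ankle_deg * d2r
  phi_k <- p$knee_deg * d2r
  phi_h <- p$hip_deg * d2r
  th_s0 <- phi_a
  th_th0 <- phi_a - phi_k
  th_tr0 <- phi_a - phi_k + phi_h

  w <- mov$w; wd <- mov$wd; wdd <- mov$wdd
  Th_s <- outer(th_s0, w)
  Th_th <- outer(th_th0, w)
  Th_tr <- outer(th_tr0, w)

  L_sh <- body$shank$length
  L_th <- body$thigh$length
  L_hat <- body$hat$length
  A <- c(0, body$ankle_height)

  K_x <- A[1] + L_sh * sin(Th_s);  K_y <- A[2] + L_sh * cos(Th_s)
  H_x <- K_x + L_th * sin(Th_th);  H_y <- K_y + L_th * cos(Th_th)

  c_sh <- body$shank$com_ratio
  c_th <- body$thigh$com_ratio
  c_hat <- body$hat$com_ratio

  out <- list(
    which = which,
    theta_s = Th_s, theta_th = Th_th, theta_tr = Th_tr,
    knee_x = K_x, knee_y = K_y, hip_x = H_x, hip_y = H_y,
    shank_com_x = (1 - c_sh) * K_x + c_sh * A[1],
    shank_com_y = (1 - c_sh) * K_y + c_sh * A[2],
    thigh_com_x = (1 - c_th) * H_x + c_th * K_x,
    thigh_com_y = (1 - c_th) * H_y + c_th * K_y,
    hat_com_x = H_x + c_hat * L_hat * sin(Th_tr),
    hat_com_y = H_y + c_hat * L_hat * cos(Th_tr)
  )

  if (derivatives) {
    Thd_s <- outer(th_s0, wd);  Thdd_s <- outer(th_s0, wdd)
    Thd_th <- outer(th_th0, wd); Thdd_th <- outer(th_th0, wdd)
    Thd_tr <- outer(th_tr0, wd); Thdd_tr <- outer(th_tr0, wdd)

    # second time derivative of L * (sin theta, cos theta)
    acc_x <- function(Th, Thd, Thdd, L) L * (cos(Th) * Thdd - sin(Th) * Thd^2)
    acc_y <- function(Th, Thd, Thdd, L) L * (-sin(Th) * Thdd - cos(Th) * Thd^2)

    Ka_x <- acc_x(Th_s, Thd_s, Thdd_s, L_sh)
    Ka_y <- acc_y(Th_s, Thd_s, Thdd_s, L_sh)
    Ha_x <- Ka_x + acc_x(Th_th, Thd_th, Thdd_th, L_th)
    Ha_y <- Ka_y + acc_y(Th_th, Thd_th, Thdd_th, L_th)

    out$knee_acc_x <- Ka_x; out$knee_acc_y <- Ka_y
    out$hip_acc_x <- Ha_x;  out$hip_acc_y <- Ha_y
    out$shank_com_acc_x <- (1 - c_sh) * Ka_x
    out$shank_com_acc_y <- (1 - c_sh) * Ka_y
    out$thigh_com_acc_x <- (1 - c_th) * Ha_x + c_th * Ka_x
    out$thigh_com_acc_y <- (1 - c_th) * Ha_y + c_th * Ka_y
    out$hat_com_acc_x <- Ha_x + acc_x(Th_tr, Thd_tr, Thdd_tr, c_hat * L_hat)
    out$hat_com_acc_y <- Ha_y + acc_y(Th_tr, Thd_tr, Thdd_tr, c_hat * L_hat)

    # physical angular accelerations, CCW-positive z
    out$alpha_s <- -Thdd_s
    out$alpha_th <- -Thdd_th
    out$alpha_tr <- -Thdd_tr
    out$thetad_s <- Thd_s; out$thetad_th <- Thd_th; out$thetad_tr <- Thd_tr
  }
  out
}
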