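#' Default anthropometric fraction table
#'
#' Reads the segment fraction table shipped with the package
#' (`inst/extdata/anthropometry.csv`): for each of the four sagittal segments
#' (HAT = head-arms-trunk, thigh, shank, foot) the segment length as a
#' fraction of body height, the segment mass as a fraction of body mass
#' (per-side for the leg segments, so HAT + 2 x legs sums to 1), the
#' centre-of-mass position as a fraction of segment length from the proximal
#' joint, and the radius of gyration about the COM as a fraction of segment
#' length. The values are the classical Dempster-derived fractions with the
#' arms folded into the HAT segment.
#'
#' @return A data.frame with columns `segment`, `length_fraction`,
#'   `mass_fraction`, `com_ratio`, `gyration_ratio`.
#' @export
default_anthropometry <- function() {
  path <- system.file("extdata", "anthropometry.csv", package = "sitstand",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

segment_params <- function(name, length, mass, com_ratio, gyration_ratio) {
  stopifnot(length > 0, mass >= 0,
            com_ratio >= 0, com_ratio <= 1,
            gyration_ratio >= 0, gyration_ratio <= 1)
  list(name = name, length = length, mass = mass,
       com_ratio = com_ratio, gyration_ratio = gyration_ratio)
}

#' Moment of inertia of a segment about its centre of mass
#'
#' @param seg a segment parameter list as stored in a body model
#' @return inertia in kg m^2
#' @export
segment_inertia <- function(seg) {
  seg$mass * (seg$gyration_ratio * seg$length)^2
}

#' Build the sagittal-plane anthropometric body model
#'
#' Constructs the four-segment (HAT, thigh, shank, foot) planar model from
#' body height and mass using an anthropometric fraction table. Leg segments
#' are bilateral; the invariant `hat + 2 * (thigh + shank + foot) == mass`
#' holds exactly. The coordinate frame is X positive anterior, Y positive up,
#' origin at the ground projection of the ankle joint; the foot is flat on
#' the floor throughout.
#'
#' @param height body height in m (default 1.74)
#' @param mass body mass in kg (default 73.8)
#' @param fraction_table anthropometric fractions, see [default_anthropometry()]
#' @param hip_height_seatoff hip joint height (Y) at seat-off in m (default 0.513)
#' @param heel_to_ankle_x horizontal heel-to-ankle offset in m (default 0.06)
#' @param ankle_height_fraction ankle joint height as a fraction of body height
#' @return an object of class `body_model`
#' @examples
#' body <- build_body_model()
#' body$hat$mass / body$mass   # HAT mass fraction
#' @export
build_body_model <- function(height = 1.74, mass = 73.8,
                             fraction_table = default_anthropometry(),
                             hip_height_seatoff = 0.513,
                             heel_to_ankle_x = 0.06,
                             ankle_height_fraction = 0.039) {
  stopifnot(height > 0, mass >= 0, hip_height_seatoff > 0)
  needed <- c("hat", "thigh", "shank", "foot")
  missing <- setdiff(needed, fraction_table$segment)
  if (length(missing) > 0) {
    stop("anthropometric fraction table is missing segment(s): ",
         paste(missing, collapse = ", "))
  }
  row_of <- function(s) fraction_table[fraction_table$segment == s, , drop = FALSE][1, ]
  mk <- function(s) {
    r <- row_of(s)
    segment_params(s,
                   length = r$length_fraction * height,
                   mass = r$mass_fraction * mass,
                   com_ratio = r$com_ratio,
                   gyration_ratio = r$gyration_ratio)
  }
  model <- list(
    height = height, mass = mass,
    hat = mk("hat"), thigh = mk("thigh"),
    shank = mk("shank"), foot = mk("foot"),
    heel_to_ankle_x = heel_to_ankle_x,
    foot_length = row_of("foot")$length_fraction * height,
    ankle_height = ankle_height_fraction * height,
    hip_height_seatoff = hip_height_seatoff
  )
  total <- model$hat$mass + 2 * (model$thigh$mass + model$shank$mass + model$foot$mass)
  if (abs(total - mass) > 1e-9) {
    stop(sprintf("segment masses sum to %.12f kg, expected %.12f kg", total, mass))
  }
  class(model) <- "body_model"
  model
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("Sagittal body model: height %.3f m, mass %.2f kg\n",
              x$height, x$mass))
  for (s in c("hat", "thigh", "shank", "foot")) {
    seg <- x[[s]]
    cat(sprintf("  %-6s length %.4f m  mass %7.3f kg  com %.3f  gyr %.3f\n",
                seg$name, seg$length, seg$mass, seg$com_ratio,
                seg$gyration_ratio))
  }
  cat(sprintf("  foot flat on floor: heel at x = %.3f m, toe at x = %.3f m, ankle height %.4f m\n",
              -x$heel_to_ankle_x, -x$heel_to_ankle_x + x$foot_length,
              x$ankle_height))
  cat(sprintf("  hip height at seat-off %.3f m\n", x$hip_height_seatoff))
  invisible(x)
}

# support base of the flat foot: [heel_x, heel_x + foot_length]
support_base <- function(body) {
  c(-body$heel_to_ankle_x, -body$heel_to_ankle_x + body$foot_length)
}

# fixed foot COM (foot is static, flat on the floor)
foot_com <- function(body) {
  c(-body$heel_to_ankle_x + body$foot$com_ratio * body$foot_length,
    0.5 * body$ankle_height)
}
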