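#' Zonal interaction parameters
#'
#' Parameters of the canonical zonal (repulsion / orientation / attraction)
#' schooling model with a rear blind zone, a maximum turning rate, and a
#' small Gaussian heading error.  Defaults are the golden-shiner fit used
#' throughout: zones 0.5 / 3.0 / 5.5 body lengths, 270 degree field of
#' perception, 100 degrees/s turning rate, 0.01 rad social error, and a
#' 0.125 s time step.
#'
#' @param r_repulsion_bl,r_orientation_bl,r_attraction_bl zone radii in body
#'   lengths; must be strictly increasing.
#' @param perception_deg total field of perception in degrees (the rear
#'   `360 - perception_deg` wedge is invisible).
#' @param turn_rate_deg_s maximum turning rate, degrees per second.
#' @param social_error_sd sd of the Gaussian heading rotation applied after
#'   the turn limit, radians.
#' @param dt_s time step, seconds.
#' @return a `social_params` list.
#' @export
social_params <- function(r_repulsion_bl = 0.5, r_orientation_bl = 3.0,
                          r_attraction_bl = 5.5, perception_deg = 270,
                          turn_rate_deg_s = 100, social_error_sd = 0.01,
                          dt_s = 0.125) {
  p <- list(r_repulsion_bl = r_repulsion_bl,
            r_orientation_bl = r_orientation_bl,
            r_attraction_bl = r_attraction_bl,
            perception_deg = perception_deg,
            turn_rate_deg_s = turn_rate_deg_s,
            social_error_sd = social_error_sd, dt_s = dt_s)
  class(p) <- "social_params"
  validate_social_params(p)
  p
}

validate_social_params <- function(p) {
  if (!(p$r_repulsion_bl > 0 && p$r_repulsion_bl < p$r_orientation_bl &&
        p$r_orientation_bl < p$r_attraction_bl))
    stop("social params: need 0 < r_repulsion < r_orientation < r_attraction")
  if (p$perception_deg <= 0 || p$perception_deg > 360)
    stop("social params: perception must lie in (0, 360] degrees")
  if (p$turn_rate_deg_s <= 0 || p$dt_s <= 0)
    stop("social params: turn rate and dt must be positive")
  if (p$social_error_sd < 0)
    stop("social params: social error sd must be >= 0")
  invisible(p)
}

max_turn_rad <- function(params) {
  params$turn_rate_deg_s * pi / 180 * params$dt_s
}

cos_half_perception <- function(params) {
  cos(params$perception_deg / 2 * pi / 180)
}

#' Social desired direction of a focal agent
#'
#' The zonal rule: neighbours in the rear blind wedge are ignored; if any
#' visible neighbour lies within the repulsion radius, the output is the
#' normalised sum of unit vectors pointing away from those neighbours
#' (repulsion overrides everything); otherwise the normalised orientation
#' term (mean heading of neighbours in the orientation shell) and the
#' normalised attraction term (sum of unit vectors toward neighbours in the
#' attraction shell) are summed with equal weight and renormalised.  Returns
#' the zero vector when no neighbour is visible, in which case the caller
#' keeps the current heading.
#'
#' @param focal_pos,focal_heading focal position (cm) and unit heading.
#' @param nb_pos,nb_heading neighbour positions (n x 2, cm) and unit headings
#'   (n x 2); must not include the focal agent.
#' @param params a [social_params()].
#' @param body_length_cm body length used to convert zone radii to cm.
#' @return a 2-vector (unit length or zero).
#' @export
social_direction <- function(focal_pos, focal_heading, nb_pos, nb_heading,
                             params = social_params(), body_length_cm = 3.4) {
  nb_pos <- as_xy_matrix(nb_pos)
  nb_heading <- as_xy_matrix(nb_heading)
  stopifnot(nrow(nb_pos) == nrow(nb_heading))
  cpp_social_direction(as.numeric(focal_pos), as.numeric(focal_heading),
                       nb_pos, nb_heading,
                       params$r_repulsion_bl * body_length_cm,
                       params$r_orientation_bl * body_length_cm,
                       params$r_attraction_bl * body_length_cm,
                       cos_half_perception(params), TRUE)
}

#' Limit the turn toward a desired direction
#'
#' If the angle between `current` and `desired` is at most
#' `turn_rate * dt`, returns `desired`; otherwise rotates `current` by
#' exactly `turn_rate * dt` toward `desired`.  An exactly antiparallel
#' `desired` is resolved counter-clockwise; a zero-length `desired` returns
#' `current` unchanged.
#'
#' @param current,desired unit 2-vectors.
#' @param params a [social_params()].
#' @return a unit 2-vector.
#' @export
limit_turn <- function(current, desired, params = social_params()) {
  cpp_limit_turn(as.numeric(current), as.numeric(desired),
                 max_turn_rad(params))
}

#' Rotate a heading by a Gaussian angular error
#'
#' @param direction unit 2-vector.
#' @param sd error sd in radians; 0 is the identity.
#' @return a unit 2-vector.  Uses R's global RNG.
#' @export
apply_social_error <- function(direction, sd) {
  if (sd <= 0) return(as.numeric(direction))
  rotate_vec(as.numeric(direction), stats::rnorm(1, 0, sd))
}
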