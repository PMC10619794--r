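#' Moment of the vertical ground reaction force about the CoM
#'
#' With the center-of-mass as pivot, the vertical ground reaction force
#' generates a frontal-plane moment
#' \deqn{M = F_{grf,vert} (CoP_{ML} - CoM_{ML})}
#' where the moment arm is the mediolateral distance between the
#' center-of-pressure and the projection of the center-of-mass on the floor.
#' This moment accelerates the CoM mediolaterally and is the mechanical
#' route by which foot placement (which largely determines the CoP) controls
#' lateral balance.
#'
#' @param f_grf_vert vertical ground reaction force, N (positive).
#' @param cop_ml mediolateral center-of-pressure position, m.
#' @param com_ml mediolateral center-of-mass position, m (same frame).
#' @return Moment, N·m.
#' @export
#' @examples
#' ground_reaction_moment(750, 0.05, 0) # 37.5 N·m
ground_reaction_moment <- function(f_grf_vert, cop_ml, com_ml) {
  if (any(f_grf_vert <= 0)) {
    abort("`f_grf_vert` must be positive.")
  }
  f_grf_vert * (cop_ml - com_ml)
}

#' Corrective moment implied by a foot placement error
#'
#' Assuming the center-of-mass is positioned midway between the feet, the
#' nominal moment arm is half the step width. A foot placement error of
#' `fp_error` meters (too medial) shortens the arm by that amount, and the
#' corrective moment needed to make up the difference is
#' `f_grf_vert * fp_error`:
#' at 750 N and 0.10 m step width, a 2 mm error costs 1.5 N·m.
#'
#' @param f_grf_vert vertical ground reaction force, N (positive).
#' @param step_width step width, m (positive).
#' @param fp_error foot placement error, m, in `[0, step_width / 2)`.
#' @return Corrective moment, N·m.
#' @export
#' @examples
#' corrective_moment_for_error(750, 0.10, 0.002) # 1.5 N·m
corrective_moment_for_error <- function(f_grf_vert, step_width, fp_error) {
  if (any(step_width <= 0)) abort("`step_width` must be positive.")
  if (any(fp_error < 0)) abort("`fp_error` must be non-negative.")
  if (any(fp_error >= step_width / 2)) {
    abort("`fp_error` must be smaller than half the step width.")
  }
  arm <- step_width / 2
  ground_reaction_moment(f_grf_vert, arm, 0) -
    ground_reaction_moment(f_grf_vert, arm - fp_error, 0)
}
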