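#' Search-array geometry
#'
#' Describes the circular six-item search array: screen center, eccentricity
#' of the stimulus centers, their polar angles, and which meridian
#' (horizontal or vertical) holds two of the six stimuli. Polar angles are
#' measured counterclockwise from the positive x-axis in a conventional
#' mathematical frame; because screen pixel coordinates grow downward, the
#' y-component of a location is `center_y - eccentricity * sin(angle)`.
#'
#' Location indices 0-5 are assigned counterclockwise starting from the
#' location with the smallest angle >= 0 degrees, so index `i` sits at
#' `location_angles[i + 1]`.
#'
#' @param center_x,center_y Screen center in pixels.
#' @param eccentricity Distance from fixation to each stimulus center, pixels.
#' @param location_angles Six polar angles in degrees, 60 degrees apart.
#' @param stimulus_radius Radius of each stimulus disc, pixels (used only for
#'   plotting overlays; classification never depends on it).
#' @param meridian `"horizontal"` or `"vertical"`.
#' @return An object of class `array_geometry`.
#' @export
array_geometry <- function(center_x, center_y, eccentricity, location_angles,
                           stimulus_radius = 75, meridian = c("horizontal", "vertical")) {
  meridian <- match.arg(meridian)
  stopifnot(is.numeric(location_angles), eccentricity > 0, stimulus_radius > 0)
  if (length(location_angles) != 6L)
    stop("geometry must have exactly 6 location angles")
  a <- sort(location_angles %% 360)
  if (anyDuplicated(a))
    stop("location angles must be pairwise distinct modulo 360")
  gaps <- diff(c(a, a[1] + 360))
  if (any(abs(gaps - 60) > 1e-8))
    stop("adjacent location angles must be 60 degrees apart")
  structure(list(center_x = center_x, center_y = center_y,
                 eccentricity = eccentricity, location_angles = a,
                 stimulus_radius = stimulus_radius, meridian = meridian),
            class = "array_geometry")
}

#' Default geometry for a given screen
#'
#' Places six equally spaced stimulus locations around the screen center.
#' The center is `((screen_w - 1) / 2, (screen_h - 1) / 2)` -- for a
#' 2560 x 1440 display this is (1279.5, 719.5), the coordinate pair used to
#' stand in for central fixation throughout preprocessing. The horizontal
#' variant has stimuli at 0 and 180 degrees (angles 0, 60, ..., 300); the
#' vertical variant at 90 and 270 (angles 30, 90, ..., 330).
#'
#' @param screen_w,screen_h Screen size in pixels.
#' @param meridian Which meridian holds two stimuli.
#' @param eccentricity_px Fixation-to-stimulus distance in pixels. Not a
#'   quantity the analyses estimate; it only anchors synthetic saccade
#'   endpoints and plotting overlays.
#' @param stimulus_radius_px Stimulus radius in pixels.
#' @return An `array_geometry`.
#' @export
default_geometry <- function(screen_w = 2560, screen_h = 1440,
                             meridian = c("horizontal", "vertical"),
                             eccentricity_px = 400, stimulus_radius_px = 75) {
  meridian <- match.arg(meridian)
  stopifnot(screen_w > 0, screen_h > 0)
  angles <- if (meridian == "horizontal") seq(0, 300, by = 60) else seq(30, 330, by = 60)
  g <- array_geometry((screen_w - 1) / 2, (screen_h - 1) / 2,
                      eccentricity_px, angles, stimulus_radius_px, meridian)
  g$screen_w <- screen_w
  g$screen_h <- screen_h
  g
}

#' Pixel coordinates of the six stimulus locations
#'
#' @param g An `array_geometry`.
#' @return A 6 x 2 matrix (columns `x`, `y`); row `i` is location index `i - 1`.
#' @export
location_coords <- function(g) {
  th <- g$location_angles * pi / 180
  cbind(x = g$center_x + g$eccentricity * cos(th),
        y = g$center_y - g$eccentricity * sin(th))
}
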