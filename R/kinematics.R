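#' Morphological and air properties of the model insect
#'
#' Defaults describe a hovering fruit fly: body length 2.78 mm, mean chord
#' 0.78 mm, wing length 2.39 mm, mean wing-tip speed 2.58 m/s, wingbeat
#' frequency 218 Hz, in air (`nu = 1.5e-5` m^2/s, `rho = 1.2` kg/m^3), giving
#' a wing-tip Reynolds number of about 134.
#'
#' @param body_length,mean_chord,wing_length metres.
#' @param mean_tip_speed cycle-mean wing-tip speed, m/s.
#' @param frequency wingbeat frequency, Hz.
#' @param air_kinematic_viscosity m^2/s.
#' @param air_density kg/m^3.
#' @return list of class `physical_wing`, with the derived Reynolds number
#'   `re` and the combined two-wing reference area `area_ref = 2 Cm R`.
#' @export
physical_wing <- function(body_length = 2.78e-3,
                          mean_chord = 0.78e-3,
                          wing_length = 2.39e-3,
                          mean_tip_speed = 2.58,
                          frequency = 218,
                          air_kinematic_viscosity = 1.5e-5,
                          air_density = 1.2) {
  vals <- c(body_length, mean_chord, wing_length, mean_tip_speed, frequency,
            air_kinematic_viscosity, air_density)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physical wing properties must be positive and finite")
  structure(list(
    body_length = body_length, mean_chord = mean_chord,
    wing_length = wing_length, mean_tip_speed = mean_tip_speed,
    frequency = frequency,
    air_kinematic_viscosity = air_kinematic_viscosity,
    air_density = air_density,
    re = reynolds_number(mean_tip_speed, mean_chord, air_kinematic_viscosity),
    area_ref = 2 * mean_chord * wing_length
  ), class = "physical_wing")
}

#' Wing-tip Reynolds number
#'
#' `Re = utip_bar * Cm / nu`: mean tip speed times mean chord over the air
#' kinematic viscosity.
#'
#' @param utip_bar cycle-mean wing-tip speed (m/s).
#' @param cm mean chord (m).
#' @param nu kinematic viscosity (m^2/s).
#' @export
reynolds_number <- function(utip_bar, cm, nu) {
  if (any(c(utip_bar, cm, nu) <= 0)) stop("inputs must be positive")
  utip_bar * cm / nu
}

#' Three-angle flapping kinematics
#'
#' The wing motion combines a positional (stroke) angle about the vertical
#' axis, a feathering (pitch) rotation about the spanwise wing axis, and an
#' elevation (out-of-stroke-plane) angle oscillating at twice the wingbeat
#' frequency:
#' \deqn{\theta_p = \theta_{p,amp} \cos(2\pi f t + \varphi_p)}
#' \deqn{\theta_f = \theta_{f,amp} \sin(2\pi f t + \varphi_f)}
#' \deqn{\theta_e = \theta_{e,amp} \cos(2\pi (2f) t - \varphi_{e0}) + \varphi_e}
#' The elevation initial phase `phase_elevation_initial` (\eqn{\varphi_{e0}})
#' selects the figure-eight shape of the wing-tip path; zero elevation
#' amplitude gives the planar "without figure-eight" motion.
#'
#' @param amp_positional,amp_feathering,amp_elevation amplitudes, degrees.
#' @param phase_positional,phase_feathering,phase_elevation offsets, degrees.
#' @param phase_elevation_initial \eqn{\varphi_{e0}}, degrees.
#' @param frequency wingbeat frequency f, Hz.
#' @return list of class `wing_kinematics`.
#' @export
wing_kinematics <- function(amp_positional = 70, amp_feathering = 70,
                            amp_elevation = 10, phase_positional = 10,
                            phase_feathering = 0, phase_elevation = 10,
                            phase_elevation_initial = 10, frequency = 218) {
  if (any(c(amp_positional, amp_feathering, amp_elevation) < 0))
    stop("amplitudes must be >= 0")
  stopifnot(frequency > 0)
  structure(list(
    amp_positional = amp_positional, amp_feathering = amp_feathering,
    amp_elevation = amp_elevation, phase_positional = phase_positional,
    phase_feathering = phase_feathering, phase_elevation = phase_elevation,
    phase_elevation_initial = phase_elevation_initial,
    frequency = frequency,
    figure_eight = amp_elevation != 0
  ), class = "wing_kinematics")
}

#' Instantaneous flapping angles
#'
#' @param kin a [wing_kinematics()].
#' @param t time in seconds (vector allowed), `t >= 0`.
#' @return tibble with columns `t`, `positional`, `feathering`, `elevation`
#'   (degrees).
#' @export
euler_angles <- function(kin, t) {
  stopifnot(all(t >= 0))
  f <- kin$frequency
  d2r <- pi / 180
  tibble::tibble(
    t = t,
    positional = kin$amp_positional *
      cos(2 * pi * f * t + kin$phase_positional * d2r),
    feathering = kin$amp_feathering *
      sin(2 * pi * f * t + kin$phase_feathering * d2r),
    elevation = kin$amp_elevation *
      cos(2 * pi * (2 * f) * t - kin$phase_elevation_initial * d2r) +
      kin$phase_elevation
  )
}

#' Rectangular zero-thickness plate geometry
#'
#' The wing is a rigid rectangle: span along the wing axis from the root,
#' chord centred on the feathering (mid-chord) line.  Lengths are in lab
#' units (reference chords).
#'
#' @param chord,span side lengths.
#' @param root_offset lab-frame position of the wing root at zero angles.
#' @param side `"right"` (reference span along +x) or `"left"` (mirror image
#'   through the y-z plane).
#' @export
plate_geometry <- function(chord = 1, span = 2.39 / 0.78,
                           root_offset = c(0, 0, 0),
                           side = c("right", "left")) {
  side <- match.arg(side)
  stopifnot(chord > 0, span > 0, length(root_offset) == 3)
  structure(list(chord = chord, span = span, root_offset = root_offset,
                 side = side, area = chord * span),
            class = "plate_geometry")
}

# rotation matrices (angles in radians)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
rot_y <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)

#' Rigid transform from the wing frame to the lab frame
#'
#' Wing-frame points are `(s, c)` with span coordinate `s` in `[0, span]` and
#' chord coordinate `c` in `[-chord/2, chord/2]`; they embed as
#' `s x_hat + c z_hat` (chord reference vertical, so the plate is pitched
#' fully up at stroke reversal).  The lab pose composes positional (about z),
#' elevation (about y) and feathering (about the spanwise axis), in that
#' order from lab to wing; the left wing is the mirror image through the
#' y-z plane.
#'
#' @param kin a [wing_kinematics()].
#' @param t time (s), scalar.
#' @param side `"right"` or `"left"`.
#' @param geom a [plate_geometry()] supplying the root offset.
#' @return list with rotation `R` (3 x 3, orthonormal, det +1), translation
#'   `origin`, and `mirror` (+1/-1).
#' @export
wing_transform <- function(kin, t, side = c("right", "left"),
                           geom = plate_geometry()) {
  side <- match.arg(side)
  ang <- euler_angles(kin, t)
  d2r <- pi / 180
  R <- rot_z(ang$positional * d2r) %*% rot_y(-ang$elevation * d2r) %*%
    rot_x(ang$feathering * d2r)
  m <- if (side == "left") -1 else 1
  M <- diag(c(m, 1, 1))
  # the left wing pose is conjugated by the y-z mirror and applied to the
  # mirrored reference span (-x), keeping R a proper rotation (det +1)
  list(R = M %*% R %*% M, origin = as.numeric(M %*% geom$root_offset),
       mirror = m)
}

# lab positions of wing-frame points (n x 2 matrix of (s, c))
wing_points_lab <- function(kin, t, geom, pts) {
  tr <- wing_transform(kin, t, geom$side, geom)
  ref <- cbind(tr$mirror * pts[, 1], 0, pts[, 2])   # s x_hat + c z_hat
  t(tr$R %*% t(ref)) + matrix(tr$origin, nrow(ref), 3, byrow = TRUE)
}

#' Wall velocity of material points on the plate
#'
#' Rigid-body velocity `u = dX/dt` of the lab-frame position, evaluated by
#' central differencing of the pose with a step `dt/10` of the supplied
#' reference step (the motion is smooth, so this matches the analytic
#' derivative to high order).
#'
#' @param kin a [wing_kinematics()].
#' @param geom a [plate_geometry()].
#' @param t time (s).
#' @param points n x 2 matrix of wing-frame `(s, c)` coordinates.
#' @param dt_ref reference time step (defaults to `1e-3 / f`).
#' @return n x 3 matrix of lab-frame velocities (lab length units per second).
#' @export
wall_velocity <- function(kin, geom, t, points, dt_ref = NULL) {
  if (is.null(dt_ref)) dt_ref <- 1e-3 / kin$frequency
  h <- dt_ref / 10
  tm <- max(t - h, 0)
  (wing_points_lab(kin, t + h, geom, points) -
     wing_points_lab(kin, tm, geom, points)) / (t + h - tm)
}

#' Wing-tip trajectory over one flapping period
#'
#' @param kin a [wing_kinematics()].
#' @param geom a [plate_geometry()].
#' @param n number of samples (>= 8); the curve closes on itself.
#' @return tibble `t`, `x`, `y`, `z` (lab units) plus the projected stroke
#'   coordinates `positional`, `elevation` (degrees, offsets removed).
#' @export
tip_trajectory <- function(kin, geom = plate_geometry(), n = 256) {
  if (n < 8) stop("n < 8 gives too coarse a trajectory")
  T <- 1 / kin$frequency
  tt <- seq(0, T, length.out = n + 1)
  xyz <- t(vapply(tt, function(ti)
    wing_points_lab(kin, ti, geom, cbind(geom$span, 0))[1, ], numeric(3)))
  ang <- euler_angles(kin, tt)
  tibble::tibble(t = tt, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 positional = ang$positional,
                 elevation = ang$elevation - kin$phase_elevation)
}

#' Count self-intersections of a closed planar curve
#'
#' Brute-force segment pair test on the sampled polyline; used to classify
#' wing-tip paths (0 crossings: U-shaped or line-shaped; 1 crossing:
#' figure-eight).  Because the positional phase offset does not cancel from
#' the elevation argument, nominally U-shaped paths carry a vestigial very
#' shallow crossing at the stroke reversal; passing a nonzero `min_angle`
#' (radians) ignores crossings shallower than that, which separates the
#' vestigial reversal loops (about 0.2 rad here) from genuine figure-eight
#' crossings (0.3 rad and above).
#'
#' @param x,y coordinates of the sampled closed curve (first point not
#'   repeated at the end, or repeated -- both accepted).
#' @param min_angle minimum crossing angle counted as a true intersection
#'   (0: count every transversal crossing).
#' @export
count_self_intersections <- function(x, y, min_angle = 0) {
  n <- length(x)
  if (n > 1 && x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  nxt <- c(2:n, 1)
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  cnt <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent segments (shared endpoint)
      if (j == i || nxt[i] == j || nxt[j] == i) next
      p1x <- x[i]; p1y <- y[i]; p2x <- x[nxt[i]]; p2y <- y[nxt[i]]
      q1x <- x[j]; q1y <- y[j]; q2x <- x[nxt[j]]; q2y <- y[nxt[j]]
      d1 <- cross2(p2x - p1x, p2y - p1y, q1x - p1x, q1y - p1y)
      d2 <- cross2(p2x - p1x, p2y - p1y, q2x - p1x, q2y - p1y)
      d3 <- cross2(q2x - q1x, q2y - q1y, p1x - q1x, p1y - q1y)
      d4 <- cross2(q2x - q1x, q2y - q1y, p2x - q1x, p2y - q1y)
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        ux <- p2x - p1x; uy <- p2y - p1y
        vx <- q2x - q1x; vy <- q2y - q1y
        sin_ang <- abs(cross2(ux, uy, vx, vy)) /
          (sqrt(ux^2 + uy^2) * sqrt(vx^2 + vy^2))
        if (min_angle <= 0 || sin_ang > sin(min_angle)) cnt <- cnt + 1
      }
    }
  }
  cnt
}

#' Cycle-mean wing-tip speed
#'
#' Trapezoidal quadrature of `|tip velocity|` over one period; reported as a
#' cross-check against the configured mean tip speed rather than used to
#' rescale the kinematics.
#'
#' @param kin a [wing_kinematics()].
#' @param geom a [plate_geometry()].
#' @param n quadrature points.
#' @return mean speed in lab length units per second.
#' @export
tip_speed_mean <- function(kin, geom = plate_geometry(), n = 2048) {
  T <- 1 / kin$frequency
  tt <- seq(0, T, length.out = n + 1)
  sp <- vapply(tt, function(ti) {
    v <- wall_velocity(kin, geom, ti, cbind(geom$span, 0))
    sqrt(sum(v^2))
  }, numeric(1))
  mean(sp[-1] + sp[-length(sp)]) / 2
}
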