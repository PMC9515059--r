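#' Transducer pose at a viewport
#'
#' The probe sits on the skin point with its axial axis directed at the
#' target centroid; the last rotational degree of freedom (mounting roll)
#' is fixed so the mounting faces the robot base: the roll vector is the
#' projection of `base - position` onto the plane normal to the axial
#' axis. When the base is (nearly) collinear with the axial axis, the roll
#' falls back to the patient-superior direction and the pose is flagged.
#'
#' @param skin_point numeric(3), the viewport skin point, mm.
#' @param centroid numeric(3), target centroid, mm.
#' @param base_position numeric(3), robot base, mm.
#' @return A `transducer_pose`: `position`, `axial` (unit), `roll` (unit,
#'   perpendicular to axial), `degenerate` flag.
#' @export
transducer_pose_from_viewport <- function(skin_point, centroid,
                                          base_position) {
  position <- as.numeric(skin_point)
  axial <- unitize(as.numeric(centroid) - position)
  v <- as.numeric(base_position) - position
  roll <- v - sum(v * axial) * axial
  degenerate <- vnorm(roll) < 1e-6
  if (degenerate) {
    up <- c(0, 0, 1)
    roll <- up - sum(up * axial) * axial
    if (vnorm(roll) < 1e-6) roll <- c(1, 0, 0) - axial[1] * axial
  }
  structure(list(position = position, axial = axial,
                 roll = unitize(roll), degenerate = degenerate),
            class = "transducer_pose")
}

#' Robot arm configuration as a capsule chain
#'
#' Minimal kinematic proxy for the transducer-carrying 7-DoF arm: a
#' capsule chain base -> elbow -> wrist -> mount with link lengths 400,
#' 400 and 120 mm, the forearm (elbow -> wrist -> mount) held straight, so
#' the elbow moves on the self-motion circle of a two-bar (400, 520 mm)
#' linkage — the redundant degree of freedom parameterized by the LIFT
#' angle. The transducer body (24 x 26 mm footprint) is a 16 mm-radius
#' capsule from the mount to the skin.
#'
#' @param base numeric(3), base position, mm.
#' @param pose a `transducer_pose`.
#' @param lift LIFT angle, radians (elbow position on its circle).
#' @param link_radii capsule radii for upper arm, forearm, wrist link, mm.
#' @param probe_radius,probe_length transducer capsule radius / length, mm.
#' @param reach,min_reach feasibility band for the base-to-mount distance,
#'   mm: beyond `reach` (920 = 400 + 400 + 120) or under `min_reach` (150)
#'   no configuration exists and `NULL` is returned.
#' @return A `capsule_set` (list with matrices `a`, `b` and vector `r`), or
#'   `NULL` when the pose is out of reach.
#' @export
solve_configuration <- function(base, pose, lift,
                                link_radii = c(60, 50, 45),
                                probe_radius = 16, probe_length = 80,
                                reach = 920, min_reach = 150) {
  base <- as.numeric(base)
  mount <- pose$position - probe_length * pose$axial
  v <- mount - base
  d <- vnorm(v)
  if (d > reach || d < min_reach) return(NULL)
  e <- v / d
  L1 <- 400
  L2 <- 520  # straight forearm: elbow->wrist (400) + wrist->mount (120)
  proj <- (d^2 + L1^2 - L2^2) / (2 * d)
  r2 <- L1^2 - proj^2
  r <- sqrt(max(r2, 0))
  # orthonormal basis of the elbow circle plane
  ref <- if (abs(e[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u1 <- unitize(cross3(e, ref))
  u2 <- cross3(e, u1)
  elbow <- base + proj * e + r * (cos(lift) * u1 + sin(lift) * u2)
  wrist <- elbow + 400 * unitize(mount - elbow)
  caps_a <- rbind(base, elbow, wrist, mount)
  caps_b <- rbind(elbow, wrist, mount, pose$position)
  structure(list(a = caps_a, b = caps_b,
                 r = c(link_radii, probe_radius),
                 lift = lift),
            class = "capsule_set")
}

#' Is a beam blocked by a capsule set?
#'
#' A beam is blocked when some capsule comes closer to the beam axis
#' segment (source to target) than the capsule radius plus the local beam
#' cone radius plus the motion safety margin (20 mm, accounting for
#' breathing motion of transducer and target).
#'
#' @param beams `candidate_beams` tibble (or a one-row beam).
#' @param capsules a `capsule_set`.
#' @param margin safety margin, mm.
#' @param sad source-axis distance used by the cone radius, mm.
#' @return Logical vector, one entry per beam.
#' @export
beam_blocked <- function(beams, capsules, margin = 20, sad = 800) {
  beam_clearance(beams, capsules, margin, sad) < 0
}

#' @rdname beam_blocked
#' @return `beam_clearance()` returns the signed clearance slack in mm
#'   (negative = blocked).
#' @export
beam_clearance <- function(beams, capsules, margin = 20, sad = 800) {
  .beam_clearance_cpp(cbind(beams$sx, beams$sy, beams$sz),
                      cbind(beams$tx, beams$ty, beams$tz),
                      beams$diameter_mm,
                      capsules$a, capsules$b, capsules$r, margin, sad)
}

#' Robot setup
#'
#' The search state of the setup optimization: a base position inside one
#' of the allowed boxes, a viewport index into a [viewport_map()], and the
#' base LIFT angle.
#'
#' @param base_position numeric(3), mm.
#' @param box name of the containing base box.
#' @param viewport_index row index into the viewport map.
#' @param lift base LIFT angle, radians.
#' @return A `robot_setup` list.
#' @export
robot_setup <- function(base_position, box, viewport_index, lift = 0) {
  structure(list(base_position = as.numeric(base_position), box = box,
                 viewport_index = as.integer(viewport_index),
                 lift = lift),
            class = "robot_setup")
}

#' Allowed base-position boxes
#'
#' Axis-aligned boxes beside the patient (left/right of the torso) and
#' between the patient's legs (inferior), with a fixed base rotation.
#' Defaults are sized to the default phantom; each element is
#' `list(lo =, hi =)` in mm.
#' @return Named list of boxes.
#' @export
default_base_boxes <- function() {
  list(
    left = list(lo = c(250, -150, -250), hi = c(450, 150, 150)),
    right = list(lo = c(-450, -150, -250), hi = c(-250, 150, 150)),
    legs = list(lo = c(-120, -120, -500), hi = c(120, 120, -280)))
}

#' Beams blocked under a robot setup
#'
#' Realizes the transducer pose at the setup's viewport and one robot
#' configuration per LIFT angle; with `k` LIFT angles a beam counts as
#' blocked only when it is blocked under *all* solvable configurations
#' (the robot can move its elbow out of the way during treatment without
#' moving the probe). Unsolvable LIFT configurations are skipped; when no
#' configuration is solvable the setup is infeasible and an error is
#' raised.
#'
#' @param beams `candidate_beams`.
#' @param setup a `robot_setup`.
#' @param viewports a [viewport_map()].
#' @param centroid target centroid, mm (defaults to the map's attribute).
#' @param lift_offsets offsets (radians) added to the setup's base LIFT
#'   angle; `0` for the single-angle setting, `c(-pi/6, 0, pi/6)` for the
#'   three-angle setting.
#' @param margin blocking margin, mm.
#' @return Integer vector of blocked beam indices.
#' @export
blocked_set <- function(beams, setup, viewports,
                        centroid = attr(viewports, "centroid"),
                        lift_offsets = 0, margin = 20) {
  vp <- viewports[setup$viewport_index, ]
  pose <- transducer_pose_from_viewport(c(vp$x, vp$y, vp$z), centroid,
                                        setup$base_position)
  blocked <- NULL
  solvable <- 0L
  for (off in lift_offsets) {
    caps <- solve_configuration(setup$base_position, pose, setup$lift + off)
    if (is.null(caps)) next
    solvable <- solvable + 1L
    bl <- which(beam_blocked(beams, caps, margin = margin))
    blocked <- if (is.null(blocked)) bl else intersect(blocked, bl)
  }
  if (solvable == 0L) {
    abort("setup infeasible: no LIFT configuration is solvable")
  }
  sort(blocked)
}
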