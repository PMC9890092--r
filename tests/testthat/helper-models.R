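# Fixture builders shared across the suite. Everything is generated in code;
# no binary fixtures.

# A minimal two-segment, one-hinge model: proximal axis +z, floating +y,
# distal +x, all through the origin. The hinge DOF is "flex" about +z.
hinge_model <- function(centre = c(0, 0, 0), landmarks = list(tip = c(0.1, 0, 0)),
                        cylinders = list(), muscles = list()) {
  segs <- list(
    segment("root"),
    segment("arm", parent = "root", landmarks = landmarks))
  j <- joint_axis_system("hinge", "root", "arm", centre, list(
    list(action_pair = c("flex", "ext"), axis_parent = "proximal",
         axis_direction = c(0, 0, 1)),
    list(action_pair = c("dev", "undev"), axis_parent = "floating",
         axis_direction = c(0, 1, 0)),
    list(action_pair = c("mrot", "lrot"), axis_parent = "distal",
         axis_direction = c(1, 0, 0))))
  limb_model("hinge_fixture", segs, list(j), muscles = muscles,
             cylinders = cylinders, norm_circumference = 0.1)
}

# A shoulder+elbow toy with non-trivial rest offsets, used where two joints
# in series matter.
two_joint_model <- function() {
  segs <- list(
    segment("scapulocoracoid",
            landmarks = list(acromion = c(0.02, 0.05, 0))),
    segment("humerus", parent = "scapulocoracoid",
            landmarks = list(
              dpc = c(0.03, -0.12, 0.02),
              lateral_epicondyle = c(0, -0.30, 0.03),
              medial_epicondyle = c(0, -0.30, -0.03))),
    segment("antebrachium", parent = "humerus",
            landmarks = list(olecranon = c(-0.03, -0.28, 0))))
  gh <- joint_axis_system("glenohumeral", "scapulocoracoid", "humerus",
                          c(0, 0, 0), list(
    list(action_pair = c("adduction", "abduction"), axis_parent = "proximal",
         axis_direction = c(1, 0, 0)),
    list(action_pair = c("protraction", "retraction"),
         axis_parent = "floating", axis_direction = c(0, 0, 1)),
    list(action_pair = c("medial_rotation", "lateral_rotation"),
         axis_parent = "distal", axis_direction = c(0, 1, 0))))
  el <- joint_axis_system("elbow", "humerus", "antebrachium",
                          c(0, -0.30, 0), list(
    list(action_pair = c("flexion", "extension"), axis_parent = "proximal",
         axis_direction = c(0, 0, 1)),
    list(action_pair = c("adduction", "abduction"), axis_parent = "floating",
         axis_direction = c(1, 0, 0)),
    list(action_pair = c("medial_rotation", "lateral_rotation"),
         axis_parent = "distal", axis_direction = c(0, 1, 0))))
  limb_model("two_joint_fixture", segs, list(gh, el),
             norm_circumference = 0.1,
             meta = list(scapular_slope_deg = 50))
}

# World-frame cylinder for direct solve_wrap_single calls: axis = z through
# the origin unless overridden.
world_cylinder <- function(radius = 1, half_length = 10, side = c(0, 1, 0),
                           frame = diag(4)) {
  list(name = "wcyl", frame = frame, radius = radius,
       half_length = half_length, side = side)
}

# Independent sphere-fit oracle: full nonlinear least squares on (centre,
# radius) started from the centroid, never sharing code with the package fit.
sphere_fit_oracle <- function(points) {
  obj <- function(par) {
    r <- sqrt(colSums((t(points) - par[1:3])^2))
    sum((r - par[4L])^2)
  }
  start <- c(colMeans(points), mean(sqrt(colSums(
    (t(points) - colMeans(points))^2))))
  stats::optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))$par
}

# Points on a circle/sphere with optional noise
circle_points <- function(n, radius, centre = c(0, 0, 0), noise = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  pts <- cbind(radius * cos(th), radius * sin(th), 0)
  sweep(pts + matrix(stats::rnorm(3 * n, sd = noise), n, 3), 2, centre, "+")
}

sphere_points <- function(n, radius, centre = c(0, 0, 0), noise = 0) {
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  sweep(radius * u + matrix(stats::rnorm(3 * n, sd = noise), n, 3),
        2, centre, "+")
}

# A symmetric synthetic elbow: humerus hangs along -y, two single-strand
# elbow muscles inserted mirror-symmetrically about the condyle midplane
# (z = 0). Translating the abduction-adduction centre along the condyle
# chord breaks the symmetry in a known direction.
symmetric_elbow_model <- function() {
  a <- 0.025
  segs <- list(
    segment("scapulocoracoid"),
    segment("humerus", parent = "scapulocoracoid",
            landmarks = list(
              lateral_epicondyle = c(0, -0.30, 0.03),
              medial_epicondyle = c(0, -0.30, -0.03))),
    segment("antebrachium", parent = "humerus"))
  gh <- joint_axis_system("glenohumeral", "scapulocoracoid", "humerus",
                          c(0, 0, 0), list(
    list(action_pair = c("adduction", "abduction"), axis_parent = "proximal",
         axis_direction = c(1, 0, 0)),
    list(action_pair = c("protraction", "retraction"),
         axis_parent = "floating", axis_direction = c(0, 0, 1)),
    list(action_pair = c("medial_rotation", "lateral_rotation"),
         axis_parent = "distal", axis_direction = c(0, 1, 0))))
  # floating axis oriented so that positive "adduction" swings the hanging
  # antebrachium laterally; with this (data-declared) sense, translating the
  # rotational centre laterally raises summed abduction, the direction the
  # study reports
  el <- joint_axis_system("elbow", "humerus", "antebrachium",
                          c(0, -0.30, 0), list(
    list(action_pair = c("flexion", "extension"), axis_parent = "proximal",
         axis_direction = c(0, 0, 1)),
    list(action_pair = c("adduction", "abduction"), axis_parent = "floating",
         axis_direction = c(-1, 0, 0)),
    list(action_pair = c("medial_rotation", "lateral_rotation"),
         axis_parent = "distal", axis_direction = c(0, 1, 0))))
  mk <- function(name, z) muscle(name, list(muscle_strand(
    "single",
    origin = list(segment = "humerus", point = c(0.02, -0.20, z)),
    insertion = list(segment = "antebrachium", point = c(0.02, -0.36, z)))),
    spanned_joints = "elbow")
  limb_model("symmetric_elbow", segs, list(gh, el),
             muscles = list(mk("MED", -a), mk("LAT", a)),
             norm_circumference = 0.1)
}

# Closed triangulated tube around the z axis (prism approximating a
# cylinder), with end caps, for the circumference helper.
tube_mesh <- function(radius = 0.02, z0 = -0.1, z1 = 0.1, n = 128L,
                      ry = radius) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  ring0 <- cbind(radius * cos(th), ry * sin(th), z0)
  ring1 <- cbind(radius * cos(th), ry * sin(th), z1)
  V <- rbind(ring0, ring1, c(0, 0, z0), c(0, 0, z1))
  c0 <- 2L * n + 1L; c1 <- 2L * n + 2L
  F_ <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    F_ <- rbind(F_,
                c(i, j, n + i), c(j, n + j, n + i),   # side quads
                c(j, i, c0),                          # bottom cap
                c(n + i, n + j, c1))                  # top cap
  }
  list(vertices = V, faces = F_)
}
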