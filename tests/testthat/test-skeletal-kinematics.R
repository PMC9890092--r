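test_that("circle fit recovers exact circles and circumscribed triangles", {
  pts <- circle_points(8L, 0.025)
  fit <- fit_joint_centre(pts, "circle")
  expect_equal(fit$centre, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(fit$radius, 0.025, tolerance = 1e-9)
  expect_lt(fit$rms_residual, 1e-12)

  # three non-collinear points: the unique circumscribed circle
  tri <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0))
  fit3 <- fit_joint_centre(tri, "circle")
  expect_equal(fit3$centre, c(0, 0, 0), tolerance = 1e-8)
  expect_equal(fit3$radius, 1, tolerance = 1e-8)

  # in-plane fit works for tilted planes too
  R <- ossomech:::rot_axis_angle(c(1, 1, 0), 0.7)
  tilted <- circle_points(12L, 0.04, centre = c(0, 0, 0)) %*% t(R)
  tilted <- sweep(tilted, 2, c(0.1, -0.2, 0.3), "+")
  fitt <- fit_joint_centre(tilted, "circle")
  expect_equal(fitt$centre, c(0.1, -0.2, 0.3), tolerance = 1e-8)
  expect_equal(fitt$radius, 0.04, tolerance = 1e-8)
})

test_that("noisy sphere fit matches an independent optimizer from the centroid", {
  set.seed(81)
  truth <- c(0.01, -0.02, 0.03)
  pts <- sphere_points(40L, 0.04, centre = truth, noise = 0.001)
  fit <- fit_joint_centre(pts, "sphere")
  expect_lt(sqrt(sum((fit$centre - truth)^2)), 0.001)
  oracle <- sphere_fit_oracle(pts)
  expect_equal(fit$centre, oracle[1:3], tolerance = 1e-4)
  expect_equal(fit$radius, oracle[4L], tolerance = 1e-4)
})

test_that("degenerate joint-centre inputs error", {
  expect_error(fit_joint_centre(rbind(c(0, 0, 0), c(1, 0, 0)), "circle"),
               "at least 3")
  line <- cbind(seq_len(5L), 0, 0)
  expect_error(fit_joint_centre(line, "circle"), "collinear")
  planar <- circle_points(10L, 1)
  expect_error(fit_joint_centre(planar, "sphere"), "coplanar")
})

test_that("reference pose reproduces rest transforms and a hinge rotates landmarks", {
  m <- two_joint_model()
  W <- apply_pose(m, make_pose(m))
  ref <- ossomech:::reference_transforms(m)
  for (nm in names(W)) expect_equal(W[[nm]], ref[[nm]])

  hm <- hinge_model()
  Wr <- apply_pose(hm, make_pose(hm, c(hinge.flex = 90)))
  expect_equal(ossomech:::tf_point(Wr$arm, c(0.1, 0, 0)), c(0, 0.1, 0),
               tolerance = 1e-12)
})

test_that("two rotations compose as the product of axis-angle matrices", {
  m <- two_joint_model()
  pose <- make_pose(m, c(glenohumeral.protraction = 20,
                         glenohumeral.adduction = 90))
  W <- apply_pose(m, pose)
  # brute-force oracle: R = R_prox(adduction) %*% R_float(protraction)
  # about the pre-rotation axis directions (+x and +z at reference)
  d2r <- pi / 180
  R_oracle <- ossomech:::rot_axis_angle(c(1, 0, 0), 90 * d2r) %*%
    ossomech:::rot_axis_angle(c(0, 0, 1), 20 * d2r)
  expect_equal(ossomech:::tf_rotation(W$humerus), R_oracle,
               tolerance = 1e-12)
})

test_that("joint axes stay parented to their segments as the pose changes", {
  m <- two_joint_model()
  p0 <- make_pose(m)
  ax0 <- joint_axis_world(m, p0, "glenohumeral", "medial_rotation")
  expect_equal(ax0$direction, c(0, 1, 0), tolerance = 1e-12)

  # rotating 30 deg about the proximal axis carries the distal axis with it
  p30 <- make_pose(m, c(glenohumeral.adduction = 30))
  ax30 <- joint_axis_world(m, p30, "glenohumeral", "medial_rotation")
  R30 <- ossomech:::rot_axis_angle(c(1, 0, 0), 30 * pi / 180)
  expect_equal(ax30$direction, as.numeric(R30 %*% c(0, 1, 0)),
               tolerance = 1e-12)

  # floating axis perpendicular to both companions in random poses
  set.seed(5)
  for (i in 1:20) {
    p <- make_pose(m, stats::setNames(stats::runif(3, -60, 60),
      c("glenohumeral.protraction", "glenohumeral.adduction",
        "glenohumeral.medial_rotation")))
    fl <- joint_axis_world(m, p, "glenohumeral", "protraction")$direction
    pr <- joint_axis_world(m, p, "glenohumeral", "adduction")$direction
    di <- joint_axis_world(m, p, "glenohumeral", "medial_rotation")$direction
    expect_lt(abs(sum(fl * pr)), 1e-9)
    expect_lt(abs(sum(fl * di)), 1e-9)
  }
})

test_that("posed bodies are rigid: distances, determinants, determinism", {
  m <- two_joint_model()
  set.seed(11)
  lm_ref <- landmark_positions(m, make_pose(m))
  d_ref <- stats::dist(lm_ref[lm_ref$segment == "humerus", c("x", "y", "z")])
  for (i in 1:15) {
    ang <- stats::setNames(stats::runif(6, -80, 80), names(make_pose(m)))
    p <- make_pose(m, ang)
    W <- apply_pose(m, p)
    for (nm in names(W))
      expect_lt(abs(det(ossomech:::tf_rotation(W[[nm]])) - 1), 1e-9)
    lm <- landmark_positions(m, p)
    d <- stats::dist(lm[lm$segment == "humerus", c("x", "y", "z")])
    expect_lt(max(abs(d - d_ref)), 1e-9)
    # purity: identical inputs, bit-identical outputs
    expect_identical(W, apply_pose(m, p))
  }
})

test_that("undoing a pose about the posed axes returns landmarks to reference", {
  m <- two_joint_model()
  set.seed(23)
  for (i in 1:10) {
    ang <- c(glenohumeral.protraction = stats::runif(1, -40, 40),
             glenohumeral.adduction = stats::runif(1, -40, 40),
             glenohumeral.medial_rotation = stats::runif(1, -40, 40))
    p <- make_pose(m, ang)
    W <- apply_pose(m, p)
    x <- ossomech:::tf_point(W$humerus, m$segments$humerus$landmarks$dpc)
    # undo in reverse order about the posed world axes
    for (dof in c("medial_rotation", "adduction", "protraction")) {
      ax <- joint_axis_world(m, p, "glenohumeral", dof)
      und <- ossomech:::rot_about_line(
        ax$point, ax$direction,
        -ang[[paste0("glenohumeral.", dof)]] * pi / 180)
      x <- ossomech:::tf_point(und, x)
      p <- ossomech:::pose_set(p, "glenohumeral", dof, 0)
    }
    x_ref <- ossomech:::tf_point(
      ossomech:::reference_transforms(m)$humerus,
      m$segments$humerus$landmarks$dpc)
    expect_lt(sqrt(sum((x - x_ref)^2)), 1e-9)
  }
})

test_that("near-parallel companion axes make the floating axis singular", {
  m <- two_joint_model()
  # adduction axis +x, distal long axis +y: a 90 deg protraction (about +z)
  # rotates the distal axis onto -x, parallel to the proximal axis
  p <- make_pose(m, c(glenohumeral.protraction = 90))
  expect_error(joint_axis_world(m, p, "glenohumeral", "protraction"),
               "singular pose")
  p2 <- make_pose(m, c(glenohumeral.protraction = 89.6))
  expect_error(joint_axis_world(m, p2, "glenohumeral", "protraction"),
               "singular pose")
  p3 <- make_pose(m, c(glenohumeral.protraction = 85))
  ax <- joint_axis_world(m, p3, "glenohumeral", "protraction")
  expect_equal(norm(ax$direction, type = "2"), 1, tolerance = 1e-12)
})

test_that("model validation catches structural defects", {
  expect_error(segment("s", rest_rotation = diag(3) * 1.01), "proper rotation")
  segs <- list(segment("a"), segment("b"))
  expect_error(limb_model("t", segs, list(), norm_circumference = 0.1),
               "exactly one root")
  expect_error(limb_model("t", list(segment("a")), list(),
                          norm_circumference = -1), "positive")
  # non-perpendicular axis triad
  segs2 <- list(segment("root"), segment("arm", parent = "root"))
  jbad <- joint_axis_system("j", "root", "arm", c(0, 0, 0), list(
    list(action_pair = c("a", "b"), axis_parent = "proximal",
         axis_direction = c(0, 0, 1)),
    list(action_pair = c("c", "d"), axis_parent = "floating",
         axis_direction = c(0, 1, 0)),
    list(action_pair = c("e", "f"), axis_parent = "distal",
         axis_direction = c(0, 0.2, 1))))
  expect_error(limb_model("t", segs2, list(jbad), norm_circumference = 0.1),
               "perpendicular")
  expect_error(make_pose(hinge_model(), c(nope.flex = 1)), "unknown joint DOF")
})

test_that("limb models round-trip through the JSON schema losslessly", {
  g <- generate_limb(synthetic_limb_spec(seed = 3, n_muscles = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_limb_model(g$model, path)
  back <- read_limb_model(path)
  expect_equal(back, g$model, tolerance = 1e-12)
  # strict validation with informative errors
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$units$angle <- "rad"
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, bad, auto_unbox = TRUE)
  expect_error(read_limb_model(bad), "units")
})
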