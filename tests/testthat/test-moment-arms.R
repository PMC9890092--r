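test_that("a coaxial wrap has moment arm equal to the cylinder radius", {
  r <- 0.03
  cyl <- wrap_cylinder("coax", "root", radius = r, half_length = 0.3,
                       side = c(0, 1, 0))
  st <- muscle_strand("single",
                      origin = list(segment = "root", point = c(-2 * r, 0, 0)),
                      insertion = list(segment = "arm", point = c(2 * r, 0, 0)),
                      obstacles = "coax")
  m <- hinge_model(cylinders = list(cyl))
  for (th in c(-30, 0, 25)) {
    p <- make_pose(m, c(hinge.flex = th))
    expect_equal(abs(moment_arm_at(m, st, "hinge", "flex", p)), r,
                 tolerance = 1e-8)
  }
})

test_that("straight strands match the analytic lever (cross-product) formula", {
  set.seed(31)
  n_checked <- 0L
  for (i in 1:10) {
    g <- generate_limb(synthetic_limb_spec(seed = 400 + i, n_muscles = 4,
                                           obstacle_density = 0))
    m <- g$model
    for (rec in g$oracle) {
      if (rec$tag != "straight-line") next
      st <- muscle_strand_of(m, rec$muscle, rec$strand)
      th <- stats::runif(1, -35, 35)
      p <- ossomech:::pose_set(make_pose(m), rec$joint, rec$dof, th)
      r_num <- moment_arm_at(m, st, rec$joint, rec$dof, p, h = 0.02)
      r_ana <- oracle_moment_arm(rec, th)
      expect_lt(abs(r_num - r_ana) / max(abs(r_ana), 1e-3), 1e-4)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 30L)
})

test_that("a well-conditioned straight strand matches the lever formula to 1e-6", {
  # strand parallel to x crossing the hinge (axis z) at common-perpendicular
  # distance 0.05 below it
  st <- muscle_strand("single",
                      origin = list(segment = "root",
                                    point = c(-0.2, -0.05, 0)),
                      insertion = list(segment = "arm",
                                       point = c(0.2, -0.05, 0)))
  m <- hinge_model()
  r_num <- moment_arm_at(m, st, "hinge", "flex", make_pose(m), h = 0.05)
  # analytic lever: r = -u . (a x (q - c)) with u = +x, a = +z; positive
  # rotation lengthens this strand, so the arm is -0.05
  r_ana <- -sum(c(1, 0, 0) *
                  ossomech:::cross3(c(0, 0, 1), c(0.2, -0.05, 0)))
  expect_equal(abs(r_ana), 0.05)
  expect_lt(abs(r_num - r_ana) / abs(r_ana), 1e-6)
})

test_that("a strand line intersecting the axis has zero moment arm", {
  # strand through the joint centre: the hinge axis (z) intersects the
  # strand line (x axis through origin)
  st <- muscle_strand("single",
                      origin = list(segment = "root", point = c(-0.2, 0, 0)),
                      insertion = list(segment = "arm", point = c(0.2, 0, 0)))
  m <- hinge_model()
  expect_lt(abs(moment_arm_at(m, st, "hinge", "flex", make_pose(m))), 1e-9)
  # and a strand unaffected by the swept DOF is identically zero
  m2 <- two_joint_model()
  st2 <- muscle_strand("single",
                       origin = list(segment = "scapulocoracoid",
                                     point = c(0.02, 0.05, 0)),
                       insertion = list(segment = "humerus",
                                        point = c(0.03, -0.12, 0.02)))
  grid <- pose_grid("elbow", "flexion", seq(10, 100, 5), make_pose(m2))
  mu <- muscle("SHM", list(st2), spanned_joints = "glenohumeral")
  m2$muscles <- stats::setNames(list(mu), "SHM")
  sw <- sweep_moment_arms(m2, "SHM", "elbow", "flexion", grid)
  expect_true(all(abs(sw$r_raw_m) < 1e-9))
})

test_that("study grids contain 17 glenohumeral and 19 elbow poses", {
  m <- two_joint_model()
  gh <- paper_glenohumeral_grid(m)
  el <- paper_elbow_grid(m)
  expect_length(gh$values, 17L)
  expect_identical(range(gh$values), c(-40, 40))
  expect_equal(ossomech:::pose_get(gh$fixed_context, "glenohumeral",
                                   "adduction"), 90)
  expect_equal(ossomech:::pose_get(gh$fixed_context, "elbow", "flexion"), 45)
  expect_length(el$values, 19L)
  expect_identical(range(el$values), c(10, 100))
  expect_equal(ossomech:::pose_get(el$fixed_context, "glenohumeral",
                                   "protraction"), 20)
})

test_that("sweeps satisfy the excursion-integral identity exactly", {
  g <- generate_limb(synthetic_limb_spec(seed = 55, n_muscles = 6))
  m <- g$model
  grid <- pose_grid("glenohumeral", "protraction", seq(-40, 40, 5),
                    make_pose(m))
  for (mu in names(m$muscles)[1:3]) {
    if (!"glenohumeral" %in% m$muscles[[mu]]$spanned_joints) next
    sw <- sweep_moment_arms(m, mu, "glenohumeral", "protraction", grid)
    for (s in unique(sw$strand)) {
      ss <- sw[sw$strand == s, ]
      if (!all(ss$feasible)) next
      dth <- 5 * pi / 180
      trap <- dth * (sum(ss$r_raw_m) - (ss$r_raw_m[1L] +
                                          ss$r_raw_m[nrow(ss)]) / 2)
      expect_equal(ss$length_m[nrow(ss)] - ss$length_m[1L], -trap,
                   tolerance = 1e-6)
    }
  }
})

test_that("halving the step shrinks the truncation error quadratically", {
  m <- two_joint_model()
  st <- muscle_strand("single",
                      origin = list(segment = "scapulocoracoid",
                                    point = c(0.05, 0.03, 0.01)),
                      insertion = list(segment = "humerus",
                                       point = c(0.04, -0.15, 0.03)))
  p <- make_pose(m, c(glenohumeral.protraction = 10))
  r_exact <- moment_arm_at(m, st, "glenohumeral", "protraction", p, h = 1e-3)
  e2 <- abs(moment_arm_at(m, st, "glenohumeral", "protraction", p, h = 2) -
              r_exact)
  e1 <- abs(moment_arm_at(m, st, "glenohumeral", "protraction", p, h = 1) -
              r_exact)
  expect_lt(e1, e2 / 3)  # O(h^2): factor 4 expected, allow margin
})

test_that("normalized moment arms are scale invariant", {
  for (sd_ in c(91, 92)) {
    g1 <- generate_limb(synthetic_limb_spec(seed = sd_, n_muscles = 4))
    g2 <- generate_limb(synthetic_limb_spec(seed = sd_, n_muscles = 4,
                                            scale = 3))
    grid1 <- pose_grid("glenohumeral", "protraction", seq(-40, 40, 10),
                       make_pose(g1$model))
    grid2 <- pose_grid("glenohumeral", "protraction", seq(-40, 40, 10),
                       make_pose(g2$model))
    mu <- names(g1$model$muscles)[1L]
    s1 <- sweep_moment_arms(g1$model, mu, "glenohumeral", "protraction", grid1)
    s2 <- sweep_moment_arms(g2$model, mu, "glenohumeral", "protraction", grid2)
    expect_equal(s2$r_norm, s1$r_norm, tolerance = 1e-9)
    expect_equal(s2$r_raw_m, 3 * s1$r_raw_m, tolerance = 1e-9)
  }
})

test_that("pooled summaries respect mean/min/max over all strand samples", {
  sw <- data.frame(muscle = "M", strand = rep(c("a", "b", "c"), each = 1L),
                   joint = "glenohumeral", dof = "protraction",
                   angle_deg = 0, length_m = 0.1,
                   r_raw_m = c(0.01, 0.02, 0.03),
                   r_norm = c(0.1, 0.2, 0.3),
                   feasible = TRUE, flagged = FALSE)
  agg <- aggregate_sweep(sw)
  expect_equal(agg$mean, 0.2)
  expect_equal(agg$min, 0.1)
  expect_equal(agg$max, 0.3)
  # pooling three identical strands equals the single-strand summary
  sw2 <- sw; sw2$r_norm <- rep(0.2, 3L)
  expect_equal(aggregate_sweep(sw2)[, c("mean", "min", "max")],
               data.frame(mean = 0.2, min = 0.2, max = 0.2))
  # sign-mixed values can straddle zero
  sw3 <- sw[1:2, ]; sw3$r_norm <- c(-0.1, 0.3)
  expect_equal(aggregate_sweep(sw3)$mean, 0.1)
  # zero feasible cells is an error
  sw4 <- sw; sw4$feasible <- FALSE
  expect_error(aggregate_sweep(sw4), class = "ossomech_empty_sweep")
})

test_that("minimum shaft circumference matches closed forms", {
  mesh <- tube_mesh(radius = 0.02, n = 256L)
  expect_equal(min_shaft_circumference(mesh, c(0, 0, 1)),
               2 * pi * 0.02, tolerance = 0.005 * 2 * pi * 0.02)
  # elliptical shaft vs numerically integrated perimeter
  a <- 0.02; b <- 0.01
  emesh <- tube_mesh(radius = a, ry = b, n = 512L)
  th <- seq(0, 2 * pi, length.out = 20001L)
  peri <- sum(sqrt((a * diff(sin(th)))^2 + (b * diff(cos(th)))^2))
  expect_equal(min_shaft_circumference(emesh, c(0, 0, 1)), peri,
               tolerance = 0.005 * peri)
  # open mesh errors with advice
  open_mesh <- mesh
  open_mesh$faces <- open_mesh$faces[-1L, ]
  expect_error(min_shaft_circumference(open_mesh, c(0, 0, 1)), "watertight")
  # profile-curve input
  loops <- lapply(c(0.021, 0.02, 0.022), function(r)
    cbind(r * cos(seq(0, 2 * pi, length.out = 200L)),
          r * sin(seq(0, 2 * pi, length.out = 200L)), 0))
  expect_equal(min_shaft_circumference(loops, c(0, 0, 1)), 2 * pi * 0.02,
               tolerance = 1e-3)
})

test_that("OBJ meshes round-trip through the minimal reader", {
  mesh <- tube_mesh(n = 16L)
  path <- withr::local_tempfile(fileext = ".obj")
  writeLines(c(
    apply(mesh$vertices, 1L, function(v)
      sprintf("v %.9f %.9f %.9f", v[1L], v[2L], v[3L])),
    apply(mesh$faces, 1L, function(f)
      sprintf("f %d/%d %d/%d %d/%d", f[1L], f[1L], f[2L], f[2L],
              f[3L], f[3L]))), path)
  back <- read_obj(path)
  expect_lt(max(abs(back$vertices - unname(mesh$vertices))), 1e-8)
  expect_equal(back$faces, unname(mesh$faces))
})
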