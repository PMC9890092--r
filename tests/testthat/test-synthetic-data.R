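test_that("limb generation is deterministic and seed-fanned", {
  g1 <- generate_limb(synthetic_limb_spec(seed = 9, n_muscles = 5))
  g2 <- generate_limb(synthetic_limb_spec(seed = 9, n_muscles = 5))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_limb_model(g1$model, p1)
  write_limb_model(g2$model, p2)
  expect_identical(readLines(p1), readLines(p2))
  g3 <- generate_limb(synthetic_limb_spec(seed = 10, n_muscles = 5))
  expect_false(identical(g1$model$joints, g3$model$joints))
  # generation does not disturb the caller's RNG stream
  set.seed(1); a <- stats::runif(1)
  set.seed(1); invisible(generate_limb(synthetic_limb_spec(seed = 2,
                                                           n_muscles = 2)))
  b <- stats::runif(1)
  expect_identical(a, b)
})

test_that("generated models carry the study's muscle-architecture shape", {
  g <- generate_limb(synthetic_limb_spec(seed = 21))
  expect_length(g$model$muscles, 23L)
  n_multi <- sum(vapply(g$model$muscles, function(m)
    length(m$strands) == 3L, logical(1L)))
  expect_gt(n_multi, 8L)  # 16/23 in expectation
  expect_true(all(vapply(g$model$muscles, function(m)
    length(m$strands) %in% c(1L, 3L), logical(1L))))
  expect_silent(validate_limb_model(g$model))
  # every oracle tag is one of the three closed forms
  expect_true(all(vapply(g$oracle, `[[`, "", "tag") %in%
                    c("straight-line", "coaxial-wrap", "zero")))
})

test_that("oracle moment arms hold across the pipeline on mixed strands", {
  # one compact model covering all three oracle classes
  g <- generate_limb(synthetic_limb_spec(seed = 64, n_muscles = 6,
                                         obstacle_density = 0.5))
  m <- g$model
  worst <- 0
  for (rec in g$oracle) {
    st <- muscle_strand_of(m, rec$muscle, rec$strand)
    for (th in c(-40, -15, 0, 20, 40)) {
      p <- ossomech:::pose_set(make_pose(m), rec$joint, rec$dof, th)
      r_num <- moment_arm_at(m, st, rec$joint, rec$dof, p, h = 0.02)
      r_ana <- oracle_moment_arm(rec, th)
      worst <- max(worst, abs(r_num - r_ana) / max(abs(r_ana), 1e-3))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("doubling the geometry scale leaves normalized arms identical", {
  g1 <- generate_limb(synthetic_limb_spec(seed = 33, n_muscles = 4))
  g2 <- generate_limb(synthetic_limb_spec(seed = 33, n_muscles = 4,
                                          scale = 2))
  grid1 <- pose_grid("glenohumeral", "protraction", seq(-40, 40, 20),
                     make_pose(g1$model))
  grid2 <- pose_grid("glenohumeral", "protraction", seq(-40, 40, 20),
                     make_pose(g2$model))
  for (mu in names(g1$model$muscles)[1:2]) {
    s1 <- sweep_moment_arms(g1$model, mu, "glenohumeral", "protraction",
                            grid1)
    s2 <- sweep_moment_arms(g2$model, mu, "glenohumeral", "protraction",
                            grid2)
    expect_equal(s1$r_norm, s2$r_norm, tolerance = 1e-10)
  }
})

test_that("Brownian simulation respects degenerate and additive limits", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  X0 <- simulate_bm_traits(tr, matrix(0, 2, 2), root_state = c(3, -1),
                           seed = 5)
  expect_true(all(X0[, 1L] == 3))
  expect_true(all(X0[, 2L] == -1))
  expect_error(simulate_bm_traits(tr, matrix(c(1, 2, 2, 1), 2)), "semidefinite")
  expect_error(simulate_bm_traits(tr, matrix(c(1, 2, 3, 4), 2)), "symmetric")
  # variance additivity: Var(x1 - x2) = t1 + t2 over many replicates
  tr2 <- ape::read.tree(text = "(A:2,B:3);")
  d <- vapply(1:2000, function(i) {
    X <- simulate_bm_traits(tr2, matrix(1), seed = i)
    X[1L] - X[2L]
  }, numeric(1L))
  expect_lt(abs(stats::var(d) - 5) / 5, 0.1)
})

test_that("empirical tip covariance approaches the BM tree law", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  Sig <- matrix(c(1, 0.5, 0.5, 2), 2)
  tips <- vapply(1:2000, function(i)
    as.vector(simulate_bm_traits(tr, Sig, seed = 40000 + i)),
    numeric(6L))
  emp <- stats::cov(t(tips))
  theo <- Sig %x% phylo_vcv(tr)  # vec() stacks tips within traits
  expect_lt(max(abs(emp - theo)), 0.1 * max(abs(theo)))
})

test_that("clade generation time-scales consistently with its FADs", {
  cl <- generate_clade(synthetic_clade_spec(seed = 2, n_tips = 17))
  expect_length(cl$tree$tip.label, 17L)
  expect_true(all(cl$tree$edge.length >= 1 - 1e-12))
  ages <- attr(cl$tree, "node_ages")
  expect_equal(unname(ages[seq_len(17L)]),
               cl$ages$FAD_Ma[match(cl$tree$tip.label, cl$ages$taxon)])
  # newick round trip preserves topology and branch lengths
  path <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(cl$tree, path)
  back <- ape::read.tree(path)
  expect_true(ape::all.equal.phylo(back, cl$tree,
                                   use.edge.length = FALSE))
  expect_equal(sort(back$edge.length), sort(cl$tree$edge.length),
               tolerance = 1e-8)
  bal <- generate_clade(synthetic_clade_spec(seed = 3, n_tips = 16,
                                             topology = "balanced"))
  expect_length(bal$tree$tip.label, 16L)
  expect_error(generate_clade(synthetic_clade_spec(seed = 3, n_tips = 12,
                                                   topology = "balanced")),
               "power of two")
})

test_that("generated action tables have the study shape and nonnegativity", {
  out <- generate_action_table(seed = 6)
  expect_identical(dim(out$table), c(17L, 13L))
  expect_identical(names(out$table)[1L], "taxon")
  expect_identical(names(out$table)[-1L], action_columns())
  expect_true(all(as.matrix(out$table[, -1L]) >= 0))
  expect_identical(sort(out$tree$tip.label), sort(out$table$taxon))
  # determinism
  out2 <- generate_action_table(seed = 6)
  expect_identical(out$table, out2$table)
})

test_that("zero effect size plants no clade signal", {
  # with effect 0 the generated table is exactly the shift-free BM table:
  # any clade-level differences that remain are shared-ancestry (Brownian)
  # structure, which is the signal pPCA is designed to discount, not a
  # planted effect
  out0 <- generate_action_table(seed = 8, effect_size = 0)
  ref <- generate_action_table(seed = 8, effect_size = 0,
                               shift_actions = "el_flexion")
  expect_identical(out0$table, ref$table)

  # permutation machinery calibrates correctly under a truly exchangeable
  # null: iid tips (star tree, equal branches), random grouping
  star <- ape::stree(17, "star")
  star$edge.length <- rep(50, 17)
  X <- simulate_bm_traits(star, diag(4e-4 * 50, 12), seed = 8)
  g <- with(list(), {set.seed(8); sample(rep(1:3, length.out = 17))})
  stat <- function(grp) {
    cent <- apply(X, 2L, function(col) tapply(col, grp, mean))
    sum(stats::dist(cent)^2)
  }
  obs <- stat(g)
  set.seed(99)
  null <- vapply(1:1000, function(i) stat(sample(g)), numeric(1L))
  expect_gt(mean(null >= obs), 0.05)
})

test_that("planted clade shifts dominate the recovered first axis", {
  out <- generate_action_table(seed = 12, effect_size = 1.5)
  X <- as.matrix(out$table[, -1L])
  rownames(X) <- out$table$taxon
  res <- ppca(X, out$tree, mode = "bm-correlation")
  l1 <- abs(res$loadings[, 1L])
  planted <- mean(l1[out$shift_actions])
  others <- mean(l1[setdiff(action_columns(), out$shift_actions)])
  expect_gt(planted, 2 * others)
})
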