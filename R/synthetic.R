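#' Synthetic data with known ground truth
#'
#' Generators for every input class the pipeline consumes: articulated limb
#' models whose annotated strands have closed-form moment arms
#' (straight-line lever, coaxial-wrap radius, or exactly zero), Brownian
#' trait tables simulated on known trees, and study-shaped 17-taxon action
#' tables with planted clade structure. All generators are pure functions of
#' their spec and seed; geometry is abstract and makes no attempt to mimic
#' real anatomy.
#'
#' @name synthetic_data
NULL

# Stable fan-out of one global seed into independent per-component streams,
# kept below 2^31 so downstream set.seed() stays in integer range. The seed
# is folded in multiplicatively (exact in doubles: operands stay < 2^53) so
# that nearby (seed, name) pairs cannot collide the way an additive hash
# would.
component_seed <- function(seed, name) {
  M <- 2147483647
  h <- 17
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% M
  s <- seed %% M
  for (k in 1:3) {
    h <- (h * 48271 + s + 1) %% M
    s <- (s * 69621 + 7) %% M
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  force(seed)  # before snapshotting the RNG: seed may itself draw from it
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Specification for a synthetic limb model
#'
#' @param seed integer seed.
#' @param n_muscles number of muscles (the study models carry 23).
#' @param frac_multistrand fraction of muscles modelled with three strands
#'   (posterior/midline/anterior); the study interprets 16 of 23 muscles as
#'   broad-attachment, three-strand pathways.
#' @param obstacle_density probability that a strand is built as a
#'   coaxial-wrap configuration (with its own wrapping cylinder) rather than
#'   a straight line.
#' @param scale global geometry scale factor (1 = decimetre-scale limb).
#' @return an object of class `synthetic_limb_spec`.
#' @export
synthetic_limb_spec <- function(seed = 1L, n_muscles = 23L,
                                frac_multistrand = 16 / 23,
                                obstacle_density = 0.3, scale = 1) {
  structure(list(seed = as.integer(seed), n_muscles = as.integer(n_muscles),
                 frac_multistrand = frac_multistrand,
                 obstacle_density = obstacle_density, scale = scale),
            class = "synthetic_limb_spec")
}

#' Generate a synthetic limb model with moment-arm oracles
#'
#' Builds a three-segment chain (scapulocoracoid, humerus, antebrachium)
#' with randomly oriented glenohumeral and elbow axis triads, and muscles
#' whose strands are constructed so that closed-form moment arms are known:
#' straight-line strands (cross-product lever formula about each spanned
#' DOF), coaxial-wrap strands (planar attachments around a cylinder coaxial
#' with one DOF axis, arm = +/- the cylinder radius, placed so the wrap
#' cannot change state across the standardized sweeps), and exact zeros
#' (strands not crossing the measured joint). Every oracle is valid for
#' single-DOF sweeps with the other two DOFs of that joint at zero.
#'
#' @param spec a [synthetic_limb_spec()].
#' @return list with `model` (a validated `limb_model`) and `oracle` (list
#'   of records consumed by [oracle_moment_arm()]).
#' @export
generate_limb <- function(spec) {
  stopifnot(inherits(spec, "synthetic_limb_spec"))
  for (attempt in seq_len(100L)) {
    g <- with_seed(
      component_seed(spec$seed, sprintf("limb-attempt%03d", attempt)),
      generate_limb_impl(spec))
    if (protocol_feasible(g$model)) return(g)
  }
  stop("infeasible random placement: no protocol-feasible model after ",
       "100 attempts")
}

# Probe every strand at the standardized protocol poses (grid ends and
# centre, plus the finite-difference perturbations of each same-joint DOF at
# the centre pose): placements whose attachments fall inside an obstacle
# there are rejected so the generator can retry.
protocol_feasible <- function(model, h = 2.5) {
  probes <- list()
  grids <- list(glenohumeral = paper_glenohumeral_grid(model),
                elbow = paper_elbow_grid(model))
  for (jn in names(grids)) {
    g <- grids[[jn]]
    vals <- c(g$values[1L], g$values[ceiling(length(g$values) / 2)],
              g$values[length(g$values)])
    for (v in vals)
      probes[[length(probes) + 1L]] <- pose_set(g$fixed_context, g$joint,
                                                g$dof, v)
    mid <- pose_set(g$fixed_context, g$joint, g$dof, vals[2L])
    for (dof in names(model$joints[[jn]]$dofs)) for (s in c(-h, h))
      probes[[length(probes) + 1L]] <-
        pose_set(mid, jn, dof, pose_get(mid, jn, dof) + s)
  }
  for (p in probes) {
    W <- apply_pose(model, p)
    for (mu in model$muscles) for (st in mu$strands) {
      ok <- tryCatch({
        strand_length(model, p, st, transforms = W)
        TRUE
      }, ossomech_infeasible = function(e) FALSE,
         ossomech_convergence = function(e) FALSE)
      if (!ok) return(FALSE)
    }
  }
  TRUE
}

generate_limb_impl <- function(spec) {
  k <- spec$scale
  gh_centre <- k * c(0, -0.10, 0.05)
  el_centre <- gh_centre + k * c(0.02, -0.30, 0)
  R_gh <- random_rotation()
  R_el <- random_rotation()
  gh_dofs <- list(
    list(action_pair = c("adduction", "abduction"), axis_parent = "proximal",
         axis_direction = R_gh[, 1L]),
    list(action_pair = c("protraction", "retraction"),
         axis_parent = "floating", axis_direction = R_gh[, 2L]),
    list(action_pair = c("medial_rotation", "lateral_rotation"),
         axis_parent = "distal", axis_direction = R_gh[, 3L]))
  el_dofs <- list(
    list(action_pair = c("flexion", "extension"), axis_parent = "proximal",
         axis_direction = R_el[, 1L]),
    list(action_pair = c("adduction", "abduction"), axis_parent = "floating",
         axis_direction = R_el[, 2L]),
    list(action_pair = c("medial_rotation", "lateral_rotation"),
         axis_parent = "distal", axis_direction = R_el[, 3L]))
  flex_axis <- R_el[, 1L]
  segs <- list(
    segment("scapulocoracoid"),
    segment("humerus", parent = "scapulocoracoid",
            landmarks = list(
              lateral_epicondyle = el_centre + k * 0.03 * flex_axis,
              medial_epicondyle = el_centre - k * 0.03 * flex_axis)),
    segment("antebrachium", parent = "humerus"))
  joints <- list(
    joint_axis_system("glenohumeral", "scapulocoracoid", "humerus",
                      gh_centre, gh_dofs),
    joint_axis_system("elbow", "humerus", "antebrachium", el_centre, el_dofs))
  joint_info <- list(
    glenohumeral = list(centre = gh_centre, R = R_gh,
                        prox = "scapulocoracoid", dist = "humerus",
                        dofs = c("adduction", "protraction",
                                 "medial_rotation")),
    elbow = list(centre = el_centre, R = R_el, prox = "humerus",
                 dist = "antebrachium",
                 dofs = c("flexion", "adduction", "medial_rotation")))
  muscles <- list()
  cylinders <- list()
  oracle <- list()
  for (mi in seq_len(spec$n_muscles)) {
    jname <- if (mi %% 2L == 1L) "glenohumeral" else "elbow"
    ji <- joint_info[[jname]]
    multi <- stats::runif(1L) < spec$frac_multistrand
    n_strand <- if (multi) 3L else 1L
    labels <- if (multi) c("posterior", "midline", "anterior") else "single"
    mu_name <- sprintf("SYN%02d", mi)
    strands <- list()
    for (si in seq_len(n_strand)) {
      wrap <- stats::runif(1L) < spec$obstacle_density
      if (wrap) {
        dof_idx <- sample(3L, 1L)
        axis <- ji$R[, dof_idx]
        r <- k * stats::runif(1L, 0.02, 0.04)
        xhat <- unit3(cross3(axis, if (abs(axis[1L]) < 0.9) c(1, 0, 0)
                             else c(0, 1, 0)))
        yhat <- cross3(axis, xhat)
        cyl_name <- sprintf("%s_cyl%d", mu_name, si)
        cylinders[[length(cylinders) + 1L]] <- wrap_cylinder(
          cyl_name, segment = ji$prox,
          frame_rotation = cbind(xhat, yhat, axis),
          frame_translation = ji$centre,
          radius = r, half_length = k * 0.2, side = yhat)
        origin <- ji$centre - 2 * r * xhat
        insertion <- ji$centre + 2 * r * xhat
        strands[[si]] <- muscle_strand(
          labels[si],
          origin = list(segment = ji$prox, point = origin),
          insertion = list(segment = ji$dist, point = insertion),
          obstacles = cyl_name)
        oracle[[length(oracle) + 1L]] <- list(
          muscle = mu_name, strand = si, joint = jname,
          dof = ji$dofs[dof_idx], tag = "coaxial-wrap",
          params = list(radius = r))
      } else {
        off_o <- k * stats::runif(1L, 0.08, 0.18) *
          unit3(stats::rnorm(3L))
        off_i <- k * stats::runif(1L, 0.08, 0.18) *
          unit3(stats::rnorm(3L))
        while (norm3(off_i - off_o) < k * 0.04)
          off_i <- k * stats::runif(1L, 0.08, 0.18) * unit3(stats::rnorm(3L))
        origin <- ji$centre + off_o
        insertion <- ji$centre + off_i
        strands[[si]] <- muscle_strand(
          labels[si],
          origin = list(segment = ji$prox, point = origin),
          insertion = list(segment = ji$dist, point = insertion))
        for (dof_idx in 1:3)
          oracle[[length(oracle) + 1L]] <- list(
            muscle = mu_name, strand = si, joint = jname,
            dof = ji$dofs[dof_idx], tag = "straight-line",
            params = list(p = origin, q0 = insertion, centre = ji$centre,
                          axis = ji$R[, dof_idx]))
      }
      other <- setdiff(names(joint_info), jname)
      for (dof in joint_info[[other]]$dofs)
        oracle[[length(oracle) + 1L]] <- list(
          muscle = mu_name, strand = si, joint = other, dof = dof,
          tag = "zero", params = list())
    }
    muscles[[length(muscles) + 1L]] <-
      muscle(mu_name, strands, spanned_joints = jname)
  }
  model <- limb_model(
    taxon = sprintf("synthetic_seed%d", spec$seed),
    segments = segs, joints = joints, muscles = muscles,
    cylinders = cylinders,
    norm_circumference = k * 0.12,
    meta = list(scapular_slope_deg = 50, synthetic = TRUE))
  list(model = model, oracle = oracle)
}

#' Closed-form oracle moment arm for an annotated synthetic strand
#'
#' Evaluates the analytic moment arm of one oracle record at a swept angle,
#' valid when the other two DOFs of the measured joint are zero:
#' straight-line strands use the lever (cross-product) formula
#' `r = -u . (a x (q - c))` with the insertion rotated rigidly about the
#' reference axis; coaxial-wrap strands return the cylinder radius (positive
#' by construction of the canonical wrap geometry); zero strands return 0.
#'
#' @param record one element of the `oracle` list from [generate_limb()].
#' @param theta_deg swept angle of the measured DOF (degrees).
#' @return analytic moment arm (m).
#' @export
oracle_moment_arm <- function(record, theta_deg) {
  switch(record$tag,
    "zero" = 0,
    "coaxial-wrap" = record$params$radius,
    "straight-line" = {
      pr <- record$params
      Rm <- rot_axis_angle(pr$axis, theta_deg * DEG2RAD)
      q <- pr$centre + as.numeric(Rm %*% (pr$q0 - pr$centre))
      u <- unit3(q - pr$p)
      -sum(u * cross3(pr$axis, q - pr$centre))
    },
    stop("unknown oracle tag '", record$tag, "'"))
}

#' Specification for a synthetic clade
#'
#' @param seed integer seed.
#' @param n_tips number of tips.
#' @param topology `"birth-death"` (ape::rphylo) or `"balanced"`
#'   (ape::stree; n_tips must be a power of two).
#' @param fad_range range (Ma) from which tip first-appearance ages are
#'   drawn uniformly; the default spans most of the ornithischian record.
#' @param Sigma p x p symmetric positive semidefinite Brownian rate matrix
#'   (trait variance per Myr).
#' @param root_state length-p root trait state.
#' @return an object of class `synthetic_clade_spec`.
#' @export
synthetic_clade_spec <- function(seed = 1L, n_tips = 17L,
                                 topology = c("birth-death", "balanced"),
                                 fad_range = c(70, 200),
                                 Sigma = diag(2), root_state = NULL) {
  topology <- match.arg(topology)
  Sigma <- as.matrix(Sigma)
  check_psd(Sigma)
  if (is.null(root_state)) root_state <- numeric(ncol(Sigma))
  if (length(root_state) != ncol(Sigma))
    stop("root_state length must match ncol(Sigma)")
  structure(list(seed = as.integer(seed), n_tips = as.integer(n_tips),
                 topology = topology, fad_range = as.numeric(fad_range),
                 Sigma = Sigma, root_state = as.numeric(root_state)),
            class = "synthetic_clade_spec")
}

check_psd <- function(Sigma) {
  if (!isSymmetric(Sigma, tol = 1e-10))
    stop("Sigma must be symmetric")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(abs(ev), 1)))
    stop("Sigma must be positive semidefinite")
  invisible(TRUE)
}

#' Generate a time-scalable synthetic clade
#'
#' @param spec a [synthetic_clade_spec()].
#' @param min_bl minimum branch length (Myr) passed to [time_scale_tree()].
#' @return list with `topology` (phylo, no meaningful branch lengths),
#'   `ages` (data frame `taxon`, `FAD_Ma`), and `tree` (the time-scaled
#'   phylo).
#' @export
generate_clade <- function(spec, min_bl = 1.0) {
  stopifnot(inherits(spec, "synthetic_clade_spec"))
  with_seed(component_seed(spec$seed, "clade"), {
    topo <- if (spec$topology == "balanced") {
      if (abs(log2(spec$n_tips) %% 1) > 1e-9)
        stop("balanced topology requires n_tips to be a power of two")
      ape::stree(spec$n_tips, "balanced")
    } else {
      ape::rphylo(spec$n_tips, birth = 0.1, death = 0.03)
    }
    topo$tip.label <- sprintf("t%02d", seq_len(spec$n_tips))
    topo$edge.length <- NULL
    fads <- stats::runif(spec$n_tips, spec$fad_range[1L], spec$fad_range[2L])
    ages <- data.frame(taxon = topo$tip.label, FAD_Ma = fads,
                       stringsAsFactors = FALSE)
    list(topology = topo, ages = ages,
         tree = time_scale_tree(topo, ages, min_bl = min_bl))
  })
}

#' Simulate Brownian-motion traits on a tree
#'
#' Recursive branch-wise Gaussian increments with covariance
#' `branch length * Sigma`, root at `root_state`.
#'
#' @param tree an `ape::phylo` with branch lengths (Myr).
#' @param Sigma p x p symmetric PSD rate matrix.
#' @param root_state length-p root state (default zero).
#' @param seed integer seed (deterministic output).
#' @return n x p matrix of tip states, rownames = tip labels.
#' @export
simulate_bm_traits <- function(tree, Sigma, root_state = NULL, seed = 1L) {
  Sigma <- as.matrix(Sigma)
  check_psd(Sigma)
  p <- ncol(Sigma)
  if (is.null(root_state)) root_state <- numeric(p)
  if (length(root_state) != p) stop("root_state length must match ncol(Sigma)")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  # matrix square root via eigen (tolerates semidefinite Sigma)
  es <- eigen(Sigma, symmetric = TRUE)
  Shalf <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), p) %*% t(es$vectors)
  n <- length(tree$tip.label)
  with_seed(seed, {
    states <- matrix(NA_real_, n + tree$Nnode, p)
    states[n + 1L, ] <- root_state
    eo <- ape::reorder.phylo(tree, "cladewise")
    for (i in seq_len(nrow(eo$edge))) {
      par <- eo$edge[i, 1L]; child <- eo$edge[i, 2L]
      bl <- eo$edge.length[i]
      states[child, ] <- states[par, ] +
        sqrt(bl) * as.numeric(Shalf %*% stats::rnorm(p))
    }
    X <- states[seq_len(n), , drop = FALSE]
    rownames(X) <- tree$tip.label
    colnames(X) <- colnames(Sigma) %||% paste0("trait", seq_len(p))
    X
  })
}

#' Generate a study-shaped action-summary table
#'
#' A 17-taxon, 12-action table shaped exactly like the pipeline's real
#' output: nonnegative summed magnitudes built from a baseline plus
#' Brownian-motion noise on a time-scaled synthetic clade, with clade-level
#' mean shifts of configurable effect size planted on designated actions.
#'
#' @param seed integer seed.
#' @param n_taxa number of taxa (the study models 17).
#' @param n_clades number of clades receiving distinct mean shifts.
#' @param effect_size magnitude of the clade shifts (0 = pure BM null).
#' @param shift_actions action columns carrying the shifts.
#' @param baseline baseline summed magnitude for every action.
#' @param bm_rate Brownian rate (variance per Myr) per action.
#' @param min_bl minimum branch length (Myr) for time-scaling.
#' @return list with `table` (data frame: `taxon` + 12 action columns, all
#'   values >= 0), `tree`, `ages`, `clades` (named clade assignment), and
#'   `shift_actions`.
#' @export
generate_action_table <- function(seed = 1L, n_taxa = 17L, n_clades = 3L,
                                  effect_size = 0.5,
                                  shift_actions = c("gh_adduction",
                                                    "gh_medial_rotation",
                                                    "gh_protraction"),
                                  baseline = 1.0, bm_rate = 4e-4,
                                  min_bl = 1.0) {
  stopifnot(all(shift_actions %in% action_columns()))
  cl <- generate_clade(synthetic_clade_spec(
    seed = component_seed(seed, "table-clade"), n_tips = n_taxa,
    Sigma = diag(12)), min_bl = min_bl)
  p <- 12L
  Sigma <- diag(bm_rate, p)
  dimnames(Sigma) <- list(action_columns(), action_columns())
  X <- simulate_bm_traits(cl$tree, Sigma,
                          root_state = rep(baseline, p),
                          seed = component_seed(seed, "table-bm"))
  colnames(X) <- action_columns()
  groups <- stats::cutree(stats::hclust(
    stats::as.dist(stats::cophenetic(cl$tree)), method = "average"),
    k = n_clades)
  shifts <- with_seed(component_seed(seed, "table-shift"), {
    sh <- matrix(0, n_clades, p, dimnames = list(NULL, action_columns()))
    for (g in seq_len(n_clades))
      sh[g, shift_actions] <- effect_size * (g - (n_clades + 1) / 2)
    sh
  })
  Xs <- X + shifts[groups[rownames(X)], , drop = FALSE]
  Xs <- pmax(Xs, 0)
  table <- data.frame(taxon = rownames(Xs), Xs, row.names = NULL,
                      check.names = FALSE, stringsAsFactors = FALSE)
  list(table = table, tree = cl$tree, ages = cl$ages,
       clades = groups, shift_actions = shift_actions)
}
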