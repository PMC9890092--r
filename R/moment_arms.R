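#' Tendon-excursion moment arms
#'
#' Moment arms are computed by the muscle-tendon unit travel path method:
#' the moment arm about a joint degree of freedom is the negative derivative
#' of muscle path length with respect to the joint angle (in radians),
#' estimated by finite differences of [strand_length()]. Positive values are
#' torques toward the DOF's positive-named action. Normalized moment arms
#' divide by the model's minimum humeral shaft circumference, giving
#' dimensionless values comparable across taxa of different body size.
#'
#' @name moment_arms
NULL

#' Moment arm of one strand about one joint DOF at one pose
#'
#' Central difference `r = -(L(theta + h) - L(theta - h)) / (2 h pi/180)`.
#' If one neighbouring pose is infeasible a one-sided difference is used with
#' a warning; if both are infeasible an error is raised.
#'
#' @param model a `limb_model`.
#' @param strand a [muscle_strand()].
#' @param joint joint name.
#' @param dof the DOF's positive action name.
#' @param pose evaluation pose (degrees).
#' @param h finite-difference half-step in degrees (default 2.5, half the
#'   standard 5-degree grid spacing).
#' @return raw moment arm (m), positive toward the positive-named action.
#' @export
moment_arm_at <- function(model, strand, joint, dof, pose, h = 2.5) {
  if (h <= 0) stop("h must be > 0")
  theta <- pose_get(pose, joint, dof)
  L_at <- function(ang) {
    p <- pose_set(pose, joint, dof, ang)
    strand_length(model, p, strand)$length
  }
  Lp <- tryCatch(L_at(theta + h), ossomech_infeasible = function(e) NA_real_)
  Lm <- tryCatch(L_at(theta - h), ossomech_infeasible = function(e) NA_real_)
  if (is.na(Lp) && is.na(Lm))
    infeasible_error("both neighbouring poses infeasible; moment arm undefined")
  if (is.na(Lp) || is.na(Lm)) {
    warning("one-sided difference used at an infeasibility boundary",
            call. = FALSE)
    L0 <- L_at(theta)
    return(if (is.na(Lp)) -(L0 - Lm) / (h * DEG2RAD)
           else -(Lp - L0) / (h * DEG2RAD))
  }
  -(Lp - Lm) / (2 * h * DEG2RAD)
}

#' Standardized pose grid
#'
#' @param joint,dof the swept joint DOF.
#' @param values strictly increasing, uniformly spaced angles (degrees).
#' @param fixed_context a full pose giving every other DOF's angle.
#' @return an object of class `pose_grid`.
#' @export
pose_grid <- function(joint, dof, values, fixed_context) {
  values <- as.numeric(values)
  if (length(values) < 2L || any(diff(values) <= 0))
    stop("grid values must be strictly increasing")
  if (max(abs(diff(values) - diff(values)[1L])) > 1e-9)
    stop("grid values must be uniformly spaced")
  structure(list(joint = joint, dof = dof, values = values,
                 fixed_context = fixed_context), class = "pose_grid")
}

#' Study-protocol pose grids
#'
#' `paper_glenohumeral_grid()`: protraction-retraction swept at 5-degree
#' intervals from 40 degrees retraction (-40) to 40 degrees protraction (+40)
#' (17 poses) with the humerus adducted 90 degrees, neutral long-axis
#' rotation, elbow flexed 45 degrees. `paper_elbow_grid()`: elbow flexion
#' swept from 10 to 100 degrees at 5-degree intervals (19 poses) with the
#' humerus adducted 90 degrees and protracted 20 degrees.
#'
#' @param model a `limb_model` with joints named `glenohumeral` and `elbow`.
#' @param adduction override for the fixed glenohumeral adduction angle
#'   (degrees); the sensitivity protocol uses 75 and 115.
#' @return a [pose_grid()].
#' @export
paper_glenohumeral_grid <- function(model, adduction = 90) {
  ctx <- make_pose(model, c(glenohumeral.adduction = adduction,
                            elbow.flexion = 45))
  pose_grid("glenohumeral", "protraction", seq(-40, 40, by = 5), ctx)
}

#' @rdname paper_glenohumeral_grid
#' @export
paper_elbow_grid <- function(model, adduction = 90) {
  ctx <- make_pose(model, c(glenohumeral.adduction = adduction,
                            glenohumeral.protraction = 20))
  pose_grid("elbow", "flexion", seq(10, 100, by = 5), ctx)
}

#' Moment-arm sweep of one muscle about one joint DOF
#'
#' Path length is evaluated for every strand at every grid angle. When the
#' measured DOF is the swept DOF, moment arms come from central differences
#' on the grid (one-sided at the two ends); otherwise [moment_arm_at()]
#' perturbs the measured DOF at each grid pose. Cells whose pose is
#' infeasible are flagged rather than aborting the sweep, and cells adjacent
#' to a wrap on/off transition are flagged (they still enter pooled
#' statistics).
#'
#' @param model a `limb_model`.
#' @param muscle muscle name.
#' @param joint,dof the measured joint DOF.
#' @param grid a [pose_grid()].
#' @param h half-step (degrees) for off-grid differentiation.
#' @return a `moment_arm_sweep`: data frame with columns `muscle`, `strand`,
#'   `joint`, `dof`, `angle_deg`, `length_m`, `r_raw_m`, `r_norm`,
#'   `feasible`, `flagged`, plus metadata attributes.
#' @export
sweep_moment_arms <- function(model, muscle, joint, dof, grid, h = 2.5) {
  if (!muscle %in% names(model$muscles)) stop("unknown muscle '", muscle, "'")
  mu <- model$muscles[[muscle]]
  if (!joint %in% names(model$joints)) stop("unknown joint '", joint, "'")
  if (!dof %in% names(model$joints[[joint]]$dofs))
    stop("unknown DOF '", dof, "' for joint '", joint, "'")
  on_grid <- identical(joint, grid$joint) && identical(dof, grid$dof)
  nv <- length(grid$values)
  dtheta <- diff(grid$values)[1L]
  rows <- list()
  for (si in seq_along(mu$strands)) {
    st <- mu$strands[[si]]
    strand_lab <- if (st$label == "single" && length(mu$strands) > 1L)
      as.character(si) else st$label
    Ls <- rep(NA_real_, nv)
    wrapped <- rep(NA, nv)
    for (i in seq_len(nv)) {
      p <- pose_set(grid$fixed_context, grid$joint, grid$dof, grid$values[i])
      res <- tryCatch(strand_length(model, p, st),
                      ossomech_infeasible = function(e) NULL)
      if (!is.null(res)) {
        Ls[i] <- res$length
        wrapped[i] <- res$n_wraps > 0L
      }
    }
    r_raw <- rep(NA_real_, nv)
    if (on_grid) {
      for (i in seq_len(nv)) {
        if (is.na(Ls[i])) next
        lo <- if (i > 1L) Ls[i - 1L] else NA_real_
        hi <- if (i < nv) Ls[i + 1L] else NA_real_
        r_raw[i] <- if (!is.na(lo) && !is.na(hi))
          -(hi - lo) / (2 * dtheta * DEG2RAD)
        else if (!is.na(hi)) -(hi - Ls[i]) / (dtheta * DEG2RAD)
        else if (!is.na(lo)) -(Ls[i] - lo) / (dtheta * DEG2RAD)
        else NA_real_
      }
    } else {
      for (i in seq_len(nv)) {
        if (is.na(Ls[i])) next
        p <- pose_set(grid$fixed_context, grid$joint, grid$dof,
                      grid$values[i])
        r_raw[i] <- tryCatch(
          moment_arm_at(model, st, joint, dof, p, h = h),
          ossomech_infeasible = function(e) NA_real_)
      }
    }
    transition <- rep(FALSE, nv)
    wr <- wrapped
    for (i in seq_len(nv)) {
      nb <- c(if (i > 1L) wr[i - 1L], if (i < nv) wr[i + 1L])
      transition[i] <- !is.na(wr[i]) && any(!is.na(nb) & nb != wr[i])
    }
    rows[[si]] <- data.frame(
      muscle = muscle, strand = strand_lab, joint = joint, dof = dof,
      angle_deg = grid$values, length_m = Ls, r_raw_m = r_raw,
      r_norm = r_raw / model$norm_circumference,
      feasible = !is.na(Ls) & !is.na(r_raw), flagged = transition,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "taxon") <- model$taxon
  attr(out, "norm_circumference") <- model$norm_circumference
  attr(out, "swept") <- c(joint = grid$joint, dof = grid$dof)
  class(out) <- c("moment_arm_sweep", class(out))
  out
}

#' Pool a sweep into a per-muscle action summary
#'
#' Mean, minimum and maximum of the normalized moment arm pooled over the
#' multiset of all strand-by-angle samples (multi-strand muscles pool all
#' strands together). Infeasible cells are excluded and counted.
#'
#' @param sweep a `moment_arm_sweep`.
#' @return one-row data frame: `muscle`, `joint`, `dof`, `mean`, `min`,
#'   `max`, `n_samples`, `n_infeasible`.
#' @export
aggregate_sweep <- function(sweep) {
  ok <- sweep$feasible & is.finite(sweep$r_norm)
  if (!any(ok))
    stop(errorCondition("empty sweep: zero feasible cells",
                        class = c("ossomech_empty_sweep", "error",
                                  "condition")))
  v <- sweep$r_norm[ok]
  data.frame(muscle = sweep$muscle[1L], joint = sweep$joint[1L],
             dof = sweep$dof[1L], mean = mean(v), min = min(v), max = max(v),
             n_samples = sum(ok), n_infeasible = sum(!ok),
             stringsAsFactors = FALSE)
}

#' Minimum shaft circumference from a mesh or profile curves
#'
#' Estimates the minimum cross-sectional circumference of a long bone shaft,
#' the body-size proxy used to normalize moment arms. Cross-sections
#' perpendicular to the declared long axis are sampled at `n_stations`
#' stations over the middle 60% of the shaft; each section's circumference is
#' the perimeter of the convex hull of the mesh-plane intersection, and the
#' minimum over stations is returned. A scalar circumference in the model
#' file bypasses this helper entirely.
#'
#' @param x either a mesh (list with `vertices` n x 3 and `faces` m x 3
#'   1-based triangle indices, e.g. from [read_obj()]), or a list of closed
#'   planar profile loops (each an n x 3 matrix).
#' @param long_axis unit 3-vector: the shaft's long axis.
#' @param n_stations number of sampling stations (>= 100 recommended).
#' @return minimum circumference (m).
#' @export
min_shaft_circumference <- function(x, long_axis, n_stations = 100L) {
  long_axis <- unit3(long_axis)
  if (is.list(x) && !is.null(x$vertices) && !is.null(x$faces)) {
    if (!mesh_is_closed(x))
      stop("mesh is not watertight; supply norm_circumference directly ",
           "in the model file instead")
    V <- as.matrix(x$vertices)
    s <- V %*% long_axis
    lo <- min(s); hi <- max(s)
    mid_lo <- lo + 0.2 * (hi - lo); mid_hi <- hi - 0.2 * (hi - lo)
    stations <- seq(mid_lo, mid_hi, length.out = max(n_stations, 100L))
    perims <- vapply(stations, function(st)
      section_perimeter(V, x$faces, long_axis, st), numeric(1L))
    min(perims[is.finite(perims)])
  } else if (is.list(x)) {
    perims <- vapply(x, function(loop) {
      loop <- as.matrix(loop)
      pts2 <- project_to_plane(loop, long_axis)
      hull_perimeter(pts2)
    }, numeric(1L))
    min(perims)
  } else stop("x must be a mesh (vertices/faces) or a list of profile loops")
}

# Perimeter of the convex hull of the intersection of mesh triangles with the
# plane {p : p . axis = station}
section_perimeter <- function(V, F_, axis, station) {
  s <- as.numeric(V %*% axis) - station
  pts <- list()
  for (fi in seq_len(nrow(F_))) {
    tri <- F_[fi, ]
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      a <- tri[e[1L]]; b <- tri[e[2L]]
      sa <- s[a]; sb <- s[b]
      if ((sa <= 0 && sb > 0) || (sa > 0 && sb <= 0)) {
        t_ <- sa / (sa - sb)
        pts[[length(pts) + 1L]] <- V[a, ] + t_ * (V[b, ] - V[a, ])
      }
    }
  }
  if (length(pts) < 3L) return(Inf)
  P <- do.call(rbind, pts)
  hull_perimeter(project_to_plane(P, axis))
}

project_to_plane <- function(pts, axis) {
  axis <- unit3(axis)
  ref <- if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit3(cross3(axis, ref))
  v <- cross3(axis, u)
  cbind(pts %*% u, pts %*% v)
}

hull_perimeter <- function(pts2) {
  h <- grDevices::chull(pts2)
  hp <- pts2[c(h, h[1L]), , drop = FALSE]
  sum(sqrt(rowSums(diff(hp)^2)))
}

mesh_is_closed <- function(mesh) {
  F_ <- as.matrix(mesh$faces)
  edges <- rbind(F_[, c(1L, 2L)], F_[, c(2L, 3L)], F_[, c(3L, 1L)])
  keys <- paste(pmin(edges[, 1L], edges[, 2L]),
                pmax(edges[, 1L], edges[, 2L]))
  all(table(keys) == 2L)
}

#' Minimal OBJ mesh reader
#'
#' Reads vertex (`v`) and triangular face (`f`) records from a Wavefront OBJ
#' file; faces with texture/normal indices (`f 1/1/1 ...`) are accepted and
#' only the vertex index is used. Intended for the circumference helper and
#' synthetic fixtures, not general mesh processing.
#'
#' @param path OBJ file path.
#' @return list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @export
read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                                 function(x) {
    idx <- as.integer(vapply(strsplit(x, "/"), `[[`, "", 1L))
    if (length(idx) != 3L) stop("read_obj: only triangular faces supported")
    idx
  }))
  list(vertices = verts, faces = faces)
}
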