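#' Pose the articulated model
#'
#' Computes the world-frame rigid transform of every segment for a pose. The
#' root sits at its rest transform (identity by convention); at each joint the
#' distal segment is rotated about the single fixed joint centre, applying in
#' order the proximal-parented axis, then the floating axis, then the
#' distal-parented axis (a Grood--Suntay-style joint coordinate system). The
#' floating axis is the orthogonalized cross product of its two companions,
#' sign-matched to the model's declared direction; axes within 0.5 degrees of
#' parallel raise a singular-pose error rather than silently ill-conditioning.
#'
#' @param model a `limb_model`.
#' @param pose a [make_pose()] pose (degrees).
#' @return named list of 4x4 world transforms, one per segment.
#' @export
apply_pose <- function(model, pose) {
  if (!inherits(pose, "pose")) pose <- make_pose(model, pose)
  joints_by_distal <- stats::setNames(
    model$joints, vapply(model$joints, `[[`, "", "distal_segment"))
  W <- list()
  for (nm in topo_order(model)) {
    s <- model$segments[[nm]]
    if (is.null(s$parent)) {
      W[[nm]] <- s$rest_transform
      next
    }
    W0 <- W[[s$parent]] %*% s$rest_transform
    j <- joints_by_distal[[nm]]
    if (is.null(j)) {
      W[[nm]] <- W0
      next
    }
    jr <- joint_rotation(model, j, pose,
                         W_prox = W[[j$proximal_segment]], W_distal0 = W0)
    W[[nm]] <- jr$transform %*% W0
  }
  W
}

# Rotation of one joint given the posed proximal transform and the distal
# transform before this joint's own rotation. Returns the homogeneous
# transform (rotation about the posed fixed centre), the world centre, and the
# world axis triad used.
joint_rotation <- function(model, joint, pose, W_prox, W_distal0) {
  Rp <- tf_rotation(W_prox)
  centre <- tf_point(W_prox, joint$centre)
  by_parent <- stats::setNames(joint$dofs,
                               vapply(joint$dofs, `[[`, "", "axis_parent"))
  e1 <- unit3(as.numeric(Rp %*% by_parent$proximal$axis_direction))
  e3 <- unit3(as.numeric(tf_rotation(W_distal0) %*%
                           by_parent$distal$axis_direction))
  e2_ref <- as.numeric(Rp %*% by_parent$floating$axis_direction)
  e2 <- cross3(e3, e1)
  sin_lim <- sin(0.5 * DEG2RAD)
  if (norm3(e2) < sin_lim)
    stop("singular pose at joint '", joint$name,
         "': proximal and distal axes within 0.5 degrees of parallel")
  e2 <- unit3(e2)
  if (sum(e2 * e2_ref) < 0) e2 <- -e2
  th <- vapply(c("proximal", "floating", "distal"), function(ap)
    pose_get(pose, joint$name, by_parent[[ap]]$action_pair[1L]) * DEG2RAD,
    numeric(1L))
  # Rotating about body-updated axes in proximal->floating->distal order
  # equals the matrix product about the pre-rotation axis directions.
  R <- rot_axis_angle(e1, th[[1L]]) %*% rot_axis_angle(e2, th[[2L]]) %*%
    rot_axis_angle(e3, th[[3L]])
  list(transform = rigid_tf(R, centre - R %*% centre),
       centre = centre, axes = list(proximal = e1, floating = e2, distal = e3),
       R = R)
}

#' World-frame joint axis for one degree of freedom
#'
#' The proximal-parented axis moves rigidly with the posed proximal segment
#' and the distal-parented axis with the posed distal segment; the floating
#' axis is recomputed as the orthogonalized unit cross product of the other
#' two. All three pass through the posed joint centre.
#'
#' @inheritParams apply_pose
#' @param joint joint name.
#' @param dof the DOF's positive action name.
#' @return list with `point` (posed joint centre) and `direction`
#'   (unit 3-vector).
#' @export
joint_axis_world <- function(model, pose, joint, dof) {
  if (!joint %in% names(model$joints)) stop("unknown joint '", joint, "'")
  j <- model$joints[[joint]]
  if (!dof %in% names(j$dofs))
    stop("unknown DOF '", dof, "' for joint '", joint, "'")
  if (!inherits(pose, "pose")) pose <- make_pose(model, pose)
  W <- apply_pose(model, pose)
  Rp <- tf_rotation(W[[j$proximal_segment]])
  Rd <- tf_rotation(W[[j$distal_segment]])
  centre <- tf_point(W[[j$proximal_segment]], j$centre)
  by_parent <- stats::setNames(j$dofs,
                               vapply(j$dofs, `[[`, "", "axis_parent"))
  e1 <- unit3(as.numeric(Rp %*% by_parent$proximal$axis_direction))
  e3 <- unit3(as.numeric(Rd %*% by_parent$distal$axis_direction))
  parent <- j$dofs[[dof]]$axis_parent
  dir <- switch(parent,
    proximal = e1,
    distal = e3,
    floating = {
      u <- cross3(e3, e1)
      if (norm3(u) < sin(0.5 * DEG2RAD))
        stop("singular pose at joint '", joint,
             "': floating axis undefined (companion axes near parallel)")
      u <- unit3(u)
      # sign continuity with the declared direction carried by the posed
      # proximal frame, rotated by the proximal-axis component of the pose
      th1 <- pose_get(pose, j$name,
                      by_parent$proximal$action_pair[1L]) * DEG2RAD
      e2_ref <- as.numeric(rot_axis_angle(e1, th1) %*%
                             (Rp %*% by_parent$floating$axis_direction))
      if (sum(u * e2_ref) < 0) u <- -u
      u
    })
  list(point = centre, direction = dir)
}

#' World-frame landmark positions
#'
#' @inheritParams apply_pose
#' @return data frame with columns `segment`, `landmark`, `x`, `y`, `z` (m).
#' @export
landmark_positions <- function(model, pose) {
  W <- apply_pose(model, pose)
  rows <- list()
  for (s in model$segments) {
    if (!length(s$landmarks)) next
    for (ln in names(s$landmarks)) {
      p <- tf_point(W[[s$name]], s$landmarks[[ln]])
      rows[[length(rows) + 1L]] <- data.frame(
        segment = s$name, landmark = ln, x = p[1L], y = p[2L], z = p[3L])
    }
  }
  if (!length(rows)) return(data.frame(segment = character(),
                                       landmark = character(),
                                       x = numeric(), y = numeric(),
                                       z = numeric()))
  do.call(rbind, rows)
}
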