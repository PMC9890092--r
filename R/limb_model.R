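#' Articulated limb model containers
#'
#' A `limb_model` bundles the articulated segment hierarchy of a pectoral
#' girdle + forelimb (one taxon), its three-axis joints, wrapping cylinders,
#' muscle strands, and the size-normalization scalar (minimum humeral shaft
#' circumference). The global frame is right-handed with +x anterior,
#' +y dorsal, +z lateral (right side); lengths are metres, angles degrees.
#'
#' @name limb_model
NULL

#' Create a segment
#'
#' @param name segment identifier.
#' @param parent parent segment name, or `NULL` for the root
#'   (torso/scapulocoracoid).
#' @param rest_rotation 3x3 proper rotation of the segment frame in its parent
#'   frame at the reference pose (all joint angles 0).
#' @param rest_translation length-3 translation (m) of the segment frame in its
#'   parent frame at the reference pose.
#' @param landmarks named list of 3-vectors (m) in the segment frame.
#' @param mesh_ref optional path to an OBJ mesh in the segment frame.
#' @return an object of class `segment`.
#' @export
segment <- function(name, parent = NULL, rest_rotation = diag(3),
                    rest_translation = c(0, 0, 0), landmarks = list(),
                    mesh_ref = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  rest_rotation <- matrix(as.numeric(rest_rotation), 3L, 3L)
  if (!is_rotation_matrix(rest_rotation))
    stop("segment '", name, "': rest rotation is not a proper rotation ",
         "(orthonormal, det +1 within 1e-9)")
  structure(list(
    name = name, parent = parent,
    rest_transform = rigid_tf(rest_rotation, as.numeric(rest_translation)),
    landmarks = lapply(landmarks, as.numeric),
    mesh_ref = mesh_ref
  ), class = "segment")
}

#' Create a three-axis joint coordinate system
#'
#' One rotational axis is parented to the proximal segment, one to the distal
#' segment, and a floating axis is kept mutually perpendicular; all three pass
#' through a single fixed centre (Grood--Suntay-style joint coordinate system).
#'
#' @param name joint identifier (e.g. `"glenohumeral"`, `"elbow"`).
#' @param proximal_segment,distal_segment segment names; the distal segment's
#'   tree parent must be the proximal segment.
#' @param centre 3-point (m) in the proximal segment frame.
#' @param dofs list of exactly three degree-of-freedom specs, each a list with
#'   `action_pair` (character 2-vector: positive then negative action name),
#'   `axis_parent` (one of `"proximal"`, `"floating"`, `"distal"`), and
#'   `axis_direction` (unit 3-vector; proximal- and floating-parented axes are
#'   declared in the proximal segment frame, distal-parented in the distal
#'   frame). Positive rotation follows the right-hand rule about
#'   `axis_direction`, so the sign convention is data, not code.
#' @return an object of class `joint_axis_system`.
#' @export
joint_axis_system <- function(name, proximal_segment, distal_segment,
                              centre, dofs) {
  if (length(dofs) != 3L) stop("joint '", name, "': exactly three DOFs required")
  parents <- vapply(dofs, function(d) d$axis_parent, character(1L))
  if (!setequal(parents, c("proximal", "floating", "distal")) ||
      anyDuplicated(parents))
    stop("joint '", name, "': need exactly one proximal, one floating and one ",
         "distal-parented axis")
  dofs <- lapply(dofs, function(d) {
    d$axis_direction <- unit3(as.numeric(d$axis_direction))
    d$action_pair <- as.character(d$action_pair)
    if (length(d$action_pair) != 2L)
      stop("joint '", name, "': action_pair must name the positive and ",
           "negative action")
    d
  })
  names(dofs) <- vapply(dofs, function(d) d$action_pair[1L], character(1L))
  structure(list(
    name = name, proximal_segment = proximal_segment,
    distal_segment = distal_segment, centre = as.numeric(centre), dofs = dofs
  ), class = "joint_axis_system")
}

#' Create a wrapping cylinder
#'
#' A geometrically simplified obstacle through which a muscle path must not
#' pass; paths deflect around it as tangent-arc-tangent shortest routes.
#'
#' @param name cylinder identifier.
#' @param segment name of the segment the cylinder is rigid with.
#' @param frame_rotation,frame_translation rigid placement of the cylinder in
#'   the segment frame; the cylinder axis is the local z axis.
#' @param radius,half_length cylinder radius and half-length (m). Tangency math
#'   treats the cylinder as infinite; arcs leaving the half-length band warn.
#' @param side unit hint vector in the segment frame selecting the deflection
#'   side (the tangent solution whose arc midpoint points along `side`).
#' @return an object of class `wrap_cylinder`.
#' @export
wrap_cylinder <- function(name, segment, frame_rotation = diag(3),
                          frame_translation = c(0, 0, 0), radius, half_length,
                          side = c(0, 1, 0)) {
  if (radius <= 0) stop("cylinder '", name, "': radius must be > 0")
  if (half_length <= 0) stop("cylinder '", name, "': half_length must be > 0")
  frame_rotation <- matrix(as.numeric(frame_rotation), 3L, 3L)
  if (!is_rotation_matrix(frame_rotation))
    stop("cylinder '", name, "': frame rotation is not a proper rotation")
  structure(list(
    name = name, segment = segment,
    frame = rigid_tf(frame_rotation, as.numeric(frame_translation)),
    radius = radius, half_length = half_length,
    side = unit3(as.numeric(side))
  ), class = "wrap_cylinder")
}

#' Create a muscle strand
#'
#' @param label one of `"single"`, `"posterior"`, `"midline"`, `"anterior"`.
#' @param origin,insertion lists `list(segment = , point = )` with the point in
#'   the segment frame (m).
#' @param via_points ordered list of `list(segment = , point = )` hard anchors.
#' @param obstacles character vector of wrap-cylinder names, solved between the
#'   anchors that bracket each path leg.
#' @return an object of class `muscle_strand`.
#' @export
muscle_strand <- function(label = "single", origin, insertion,
                          via_points = list(), obstacles = character()) {
  label <- match.arg(label, c("single", "posterior", "midline", "anterior"))
  chk <- function(a, what) {
    if (!is.list(a) || is.null(a$segment) || length(a$point) != 3L)
      stop("strand ", what, " must be list(segment=, point=) with a 3-point")
    list(segment = a$segment, point = as.numeric(a$point))
  }
  structure(list(
    label = label, origin = chk(origin, "origin"),
    insertion = chk(insertion, "insertion"),
    via_points = lapply(via_points, chk, what = "via point"),
    obstacles = as.character(obstacles)
  ), class = "muscle_strand")
}

#' Create a muscle
#'
#' @param name muscle code (e.g. `"PEC"`, `"DCL"`, `"TRL"`).
#' @param strands list of 1 (single pathway) or 3 (posterior/midline/anterior)
#'   [muscle_strand()] objects.
#' @param spanned_joints names of the joints the muscle crosses.
#' @return an object of class `muscle`.
#' @export
muscle <- function(name, strands, spanned_joints) {
  if (!length(strands) %in% c(1L, 3L))
    stop("muscle '", name, "': strand count must be 1 or 3")
  structure(list(name = name, strands = strands,
                 spanned_joints = as.character(spanned_joints)),
            class = "muscle")
}

#' Assemble and validate a limb model
#'
#' @param taxon taxon identifier.
#' @param segments list of [segment()] objects; exactly one root.
#' @param joints list of [joint_axis_system()] objects.
#' @param muscles list of [muscle()] objects.
#' @param cylinders list of [wrap_cylinder()] objects.
#' @param norm_circumference minimum humeral shaft circumference (m), the
#'   size-normalization scalar applied to all moment arms.
#' @param meta optional named list of free metadata (e.g. `scapular_slope_deg`
#'   used by the scapular-slope sensitivity variant).
#' @return a validated object of class `limb_model`.
#' @export
limb_model <- function(taxon, segments, joints, muscles = list(),
                       cylinders = list(), norm_circumference, meta = list()) {
  m <- structure(list(
    taxon = taxon,
    units = list(length = "m", angle = "deg"),
    segments = stats::setNames(segments,
                               vapply(segments, `[[`, "", "name")),
    joints = stats::setNames(joints, vapply(joints, `[[`, "", "name")),
    muscles = stats::setNames(muscles, vapply(muscles, `[[`, "", "name")),
    cylinders = stats::setNames(cylinders,
                                vapply(cylinders, `[[`, "", "name")),
    norm_circumference = as.numeric(norm_circumference),
    meta = meta
  ), class = "limb_model")
  validate_limb_model(m)
  m
}

#' Validate a limb model
#'
#' Checks the segment graph is a tree with one root, all cross-references
#' resolve, joints have a proper axis triad (mutually perpendicular at the
#' reference pose within 1e-6), and the normalization circumference is
#' positive.
#'
#' @param model a `limb_model`.
#' @return the model, invisibly; errors describe the offending element.
#' @export
validate_limb_model <- function(model) {
  segs <- model$segments
  if (anyDuplicated(names(segs))) stop("duplicate segment names")
  roots <- names(segs)[vapply(segs, function(s) is.null(s$parent), logical(1L))]
  if (length(roots) != 1L)
    stop("segment graph must have exactly one root, found ", length(roots))
  for (s in segs) {
    if (!is.null(s$parent) && !s$parent %in% names(segs))
      stop("segment '", s$name, "': unknown parent '", s$parent, "'")
  }
  # cycle check: every segment must reach the root
  for (s in segs) {
    seen <- character(); cur <- s
    while (!is.null(cur$parent)) {
      if (cur$name %in% seen) stop("segment graph contains a cycle at '",
                                   cur$name, "'")
      seen <- c(seen, cur$name)
      cur <- segs[[cur$parent]]
    }
  }
  if (!is.numeric(model$norm_circumference) ||
      length(model$norm_circumference) != 1L ||
      !is.finite(model$norm_circumference) || model$norm_circumference <= 0)
    stop("norm_circumference must be a single positive length (m)")
  for (j in model$joints) {
    for (nm in c(j$proximal_segment, j$distal_segment))
      if (!nm %in% names(segs))
        stop("joint '", j$name, "': unknown segment '", nm, "'")
    if (segs[[j$distal_segment]]$parent != j$proximal_segment)
      stop("joint '", j$name, "': distal segment's tree parent must be the ",
           "proximal segment")
    ax <- reference_axes(model, j)
    g <- abs(c(sum(ax$proximal * ax$floating),
               sum(ax$proximal * ax$distal),
               sum(ax$floating * ax$distal)))
    if (any(g > 1e-6))
      stop("joint '", j$name, "': axis triad not mutually perpendicular at ",
           "the reference pose (max |dot| = ", format(max(g)), ")")
  }
  for (cy in model$cylinders)
    if (!cy$segment %in% names(segs))
      stop("cylinder '", cy$name, "': unknown segment '", cy$segment, "'")
  for (mu in model$muscles) {
    for (jn in mu$spanned_joints)
      if (!jn %in% names(model$joints))
        stop("muscle '", mu$name, "': unknown joint '", jn, "'")
    for (st in mu$strands) {
      pts <- c(list(st$origin, st$insertion), st$via_points)
      for (p in pts)
        if (!p$segment %in% names(segs))
          stop("muscle '", mu$name, "': attachment on unknown segment '",
               p$segment, "'")
      if (st$origin$segment == st$insertion$segment)
        stop("muscle '", mu$name, "': origin and insertion must be on ",
             "different segments")
      for (ob in st$obstacles)
        if (!ob %in% names(model$cylinders))
          stop("muscle '", mu$name, "': unknown wrap cylinder '", ob, "'")
    }
  }
  invisible(model)
}

root_segment <- function(model) {
  names(model$segments)[vapply(model$segments,
                               function(s) is.null(s$parent), logical(1L))]
}

# Segment names ordered root-first (parents before children)
topo_order <- function(model) {
  out <- root_segment(model)
  remaining <- setdiff(names(model$segments), out)
  while (length(remaining)) {
    nxt <- remaining[vapply(model$segments[remaining],
                            function(s) s$parent %in% out, logical(1L))]
    if (!length(nxt)) stop("segment graph is not connected")
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  out
}

# Reference-pose world transform of every segment (all angles zero)
reference_transforms <- function(model) {
  W <- list()
  for (nm in topo_order(model)) {
    s <- model$segments[[nm]]
    W[[nm]] <- if (is.null(s$parent)) s$rest_transform
               else W[[s$parent]] %*% s$rest_transform
  }
  W
}

# World-frame axis directions of a joint's three DOFs at the reference pose
reference_axes <- function(model, joint) {
  W <- reference_transforms(model)
  Rp <- tf_rotation(W[[joint$proximal_segment]])
  Rd <- tf_rotation(W[[joint$distal_segment]])
  out <- list()
  for (d in joint$dofs) {
    dir <- switch(d$axis_parent,
                  proximal = , floating = as.numeric(Rp %*% d$axis_direction),
                  distal = as.numeric(Rd %*% d$axis_direction))
    out[[d$axis_parent]] <- unit3(dir)
  }
  out
}

#' Create a pose
#'
#' A pose assigns an angle (degrees) to every joint degree of freedom of a
#' model; unlisted DOFs default to 0 (the reference pose).
#'
#' @param model a `limb_model`.
#' @param angles named numeric vector, names `"<joint>.<positive action>"`
#'   (e.g. `c(glenohumeral.protraction = 20, glenohumeral.adduction = 90)`).
#' @return a named numeric vector of class `pose` with one finite entry per
#'   joint DOF.
#' @export
make_pose <- function(model, angles = numeric()) {
  keys <- unlist(lapply(model$joints, function(j)
    paste(j$name, names(j$dofs), sep = ".")), use.names = FALSE)
  p <- stats::setNames(numeric(length(keys)), keys)
  if (length(angles)) {
    bad <- setdiff(names(angles), keys)
    if (length(bad)) stop("unknown joint DOF(s): ", paste(bad, collapse = ", "))
    if (!all(is.finite(angles))) stop("pose angles must be finite")
    p[names(angles)] <- angles
  }
  structure(p, class = "pose")
}

pose_get <- function(pose, joint, dof) {
  key <- paste(joint, dof, sep = ".")
  if (!key %in% names(pose)) stop("unknown joint DOF '", key, "'")
  unname(pose[[key]])
}

pose_set <- function(pose, joint, dof, value) {
  key <- paste(joint, dof, sep = ".")
  if (!key %in% names(pose)) stop("unknown joint DOF '", key, "'")
  pose[[key]] <- value
  pose
}

#' @export
print.limb_model <- function(x, ...) {
  cat("<limb_model> taxon:", x$taxon, "\n",
      " segments:", length(x$segments),
      " joints:", length(x$joints),
      " muscles:", length(x$muscles),
      " cylinders:", length(x$cylinders), "\n",
      " normalization circumference (m):", x$norm_circumference, "\n")
  invisible(x)
}
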