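#' Read and write limb model JSON
#'
#' One JSON document per taxon holds the full model: segments, joints,
#' muscles, wrapping cylinders and the normalization circumference, with an
#' explicit units declaration (`length: "m"`, `angle: "deg"`). Meshes, when
#' used, are referenced by relative OBJ path.
#'
#' @param path file path.
#' @return [read_limb_model()] returns a validated `limb_model`.
#' @export
read_limb_model <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("failed to parse model JSON '", path, "': ",
                             conditionMessage(e)))
  req <- function(x, field, where) {
    if (is.null(x[[field]]))
      stop("model JSON '", path, "': missing required field '", field,
           "' in ", where)
    x[[field]]
  }
  units <- req(doc, "units", "document")
  if (!identical(units$length, "m") || !identical(units$angle, "deg"))
    stop("model JSON '", path, "': units must declare length \"m\" and ",
         "angle \"deg\"")
  num3 <- function(v, where) {
    v <- as.numeric(unlist(v))
    if (length(v) != 3L || !all(is.finite(v)))
      stop("model JSON '", path, "': ", where, " must be a finite 3-vector")
    v
  }
  mat3 <- function(v, where) {
    v <- as.numeric(unlist(v))
    if (length(v) != 9L)
      stop("model JSON '", path, "': ", where,
           " must be a 3x3 matrix (9 numbers, row-major)")
    matrix(v, 3L, 3L, byrow = TRUE)
  }
  segs <- lapply(req(doc, "segments", "document"), function(s) {
    segment(name = req(s, "name", "segment"),
            parent = s$parent,
            rest_rotation = mat3(req(s, "rest_rotation", "segment"),
                                 paste0("segment '", s$name, "' rest_rotation")),
            rest_translation = num3(req(s, "rest_translation", "segment"),
                                    paste0("segment '", s$name,
                                           "' rest_translation")),
            landmarks = lapply(s$landmarks %||% list(), function(p)
              num3(p, "landmark")),
            mesh_ref = s$mesh_ref)
  })
  joints <- lapply(doc$joints %||% list(), function(j) {
    joint_axis_system(
      name = req(j, "name", "joint"),
      proximal_segment = req(j, "proximal_segment", "joint"),
      distal_segment = req(j, "distal_segment", "joint"),
      centre = num3(req(j, "centre", "joint"),
                    paste0("joint '", j$name, "' centre")),
      dofs = lapply(req(j, "dofs", "joint"), function(d) list(
        action_pair = unlist(req(d, "action_pair", "dof")),
        axis_parent = req(d, "axis_parent", "dof"),
        axis_direction = num3(req(d, "axis_direction", "dof"),
                              "dof axis_direction"))))
  })
  cyls <- lapply(doc$cylinders %||% list(), function(cy) {
    wrap_cylinder(name = req(cy, "name", "cylinder"),
                  segment = req(cy, "segment", "cylinder"),
                  frame_rotation = mat3(req(cy, "frame_rotation", "cylinder"),
                                        "cylinder frame_rotation"),
                  frame_translation = num3(req(cy, "frame_translation",
                                               "cylinder"),
                                           "cylinder frame_translation"),
                  radius = as.numeric(req(cy, "radius", "cylinder")),
                  half_length = as.numeric(req(cy, "half_length", "cylinder")),
                  side = num3(req(cy, "side", "cylinder"), "cylinder side"))
  })
  muscles <- lapply(doc$muscles %||% list(), function(mu) {
    muscle(name = req(mu, "name", "muscle"),
           strands = lapply(req(mu, "strands", "muscle"), function(st) {
             att <- function(a, what) list(
               segment = req(a, "segment", what),
               point = num3(req(a, "point", what), what))
             muscle_strand(
               label = st$label %||% "single",
               origin = att(req(st, "origin", "strand"), "strand origin"),
               insertion = att(req(st, "insertion", "strand"),
                               "strand insertion"),
               via_points = lapply(st$via_points %||% list(), att,
                                   what = "via point"),
               obstacles = unlist(st$obstacles %||% character()))
           }),
           spanned_joints = unlist(req(mu, "spanned_joints", "muscle")))
  })
  limb_model(taxon = req(doc, "taxon", "document"),
             segments = segs, joints = joints, muscles = muscles,
             cylinders = cyls,
             norm_circumference = as.numeric(req(doc, "norm_circumference",
                                                 "document")),
             meta = doc$meta %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_limb_model
#' @param model a `limb_model`.
#' @return [write_limb_model()] returns `path` invisibly.
#' @export
write_limb_model <- function(model, path) {
  as_att <- function(a) list(segment = a$segment, point = a$point)
  doc <- list(
    taxon = model$taxon,
    units = list(length = "m", angle = "deg"),
    norm_circumference = model$norm_circumference,
    segments = unname(lapply(model$segments, function(s) {
      out <- list(name = s$name,
                  rest_rotation = as.vector(t(tf_rotation(s$rest_transform))),
                  rest_translation = tf_translation(s$rest_transform),
                  landmarks = s$landmarks)
      if (!is.null(s$parent)) out$parent <- s$parent
      if (!is.null(s$mesh_ref)) out$mesh_ref <- s$mesh_ref
      out
    })),
    joints = unname(lapply(model$joints, function(j) list(
      name = j$name, proximal_segment = j$proximal_segment,
      distal_segment = j$distal_segment, centre = j$centre,
      dofs = unname(lapply(j$dofs, function(d) list(
        action_pair = d$action_pair, axis_parent = d$axis_parent,
        axis_direction = d$axis_direction)))))),
    cylinders = unname(lapply(model$cylinders, function(cy) list(
      name = cy$name, segment = cy$segment,
      frame_rotation = as.vector(t(tf_rotation(cy$frame))),
      frame_translation = tf_translation(cy$frame),
      radius = cy$radius, half_length = cy$half_length, side = cy$side))),
    muscles = unname(lapply(model$muscles, function(mu) list(
      name = mu$name, spanned_joints = mu$spanned_joints,
      strands = unname(lapply(mu$strands, function(st) list(
        label = st$label, origin = as_att(st$origin),
        insertion = as_att(st$insertion),
        via_points = lapply(st$via_points, as_att),
        obstacles = st$obstacles)))))),
    meta = model$meta
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
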