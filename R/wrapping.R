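#' Muscle path wrapping around cylinders
#'
#' Muscle strands run from origin to insertion through optional via points;
#' between consecutive anchors the path is the shortest route around the
#' leg's wrapping cylinders, built from straight tangent segments and
#' helical geodesic arcs on the cylinder surface (an obstacle-set method).
#'
#' @name wrapping
NULL

infeasible_error <- function(msg) {
  stop(errorCondition(msg, class = c("ossomech_infeasible", "error",
                                     "condition")))
}

convergence_error <- function(msg) {
  stop(errorCondition(msg, class = c("ossomech_convergence", "error",
                                     "condition")))
}

# A cylinder placed in the world for a given set of segment transforms
cylinder_world <- function(cyl, transforms) {
  Wseg <- transforms[[cyl$segment]]
  list(name = cyl$name,
       frame = Wseg %*% cyl$frame,
       radius = cyl$radius,
       half_length = cyl$half_length,
       side = tf_vector(Wseg, cyl$side))
}

#' Shortest path between two points around one cylinder
#'
#' If the straight segment from `p` to `q` misses the (infinite) cylinder the
#' path is the straight line; otherwise it is the tangent line, helical
#' geodesic on the surface, tangent line route, with the deflection side
#' chosen by the cylinder's side hint (the candidate whose arc midpoint has
#' the larger positive projection on the hint; exact tie takes the
#' first-listed, positive-handed candidate). Length is the exact analytic
#' sum; a wrap arc leaving the +/- half-length band warns but proceeds.
#'
#' @param p,q world 3-points strictly outside the cylinder surface.
#' @param cyl a world-frame cylinder as produced internally
#'   (list: `frame` 4x4, `radius`, `half_length`, `side`).
#' @return list with `length` (m), `wrap_active` (logical), `path` (n x 3
#'   world polyline; arc discretized for output, length is analytic),
#'   `tangent_in`, `tangent_out` (world 3-points, `NULL` when inactive),
#'   `arc_angle` (radians) and `helix_length` (m).
#' @export
solve_wrap_single <- function(p, q, cyl) {
  Tinv <- tf_inverse(cyl$frame)
  P <- tf_point(Tinv, p)
  Q <- tf_point(Tinv, q)
  r <- cyl$radius
  dp <- sqrt(P[1L]^2 + P[2L]^2)
  dq <- sqrt(Q[1L]^2 + Q[2L]^2)
  if (dp < r - 1e-12 || dq < r - 1e-12)
    infeasible_error(paste0("attachment point strictly inside wrap cylinder '",
                            cyl$name, "'"))
  # 2D distance from the cylinder axis to the chord
  seg_dist <- dist_point_segment_2d(c(0, 0), P[1:2], Q[1:2])
  if (seg_dist >= r) {
    return(list(length = norm3(q - p), wrap_active = FALSE,
                path = rbind(p, q), tangent_in = NULL, tangent_out = NULL,
                arc_angle = 0, helix_length = 0))
  }
  thP <- atan2(P[2L], P[1L]); thQ <- atan2(Q[2L], Q[1L])
  bp <- acos(min(1, r / max(dp, r))); bq <- acos(min(1, r / max(dq, r)))
  cand <- lapply(c(1, -1), function(s) {
    phi_p <- thP + s * bp
    phi_q <- thQ - s * bq
    delta <- (s * (phi_q - phi_p)) %% (2 * pi)
    mid <- phi_p + s * delta / 2
    list(s = s, phi_p = phi_p, phi_q = phi_q, delta = delta,
         mid_dir = c(cos(mid), sin(mid)))
  })
  side2 <- (tf_rotation(Tinv) %*% cyl$side)[1:2]
  dots <- vapply(cand, function(cd) sum(cd$mid_dir * side2), numeric(1L))
  pick <- if (dots[1L] >= dots[2L]) cand[[1L]] else cand[[2L]]
  tp <- sqrt(max(dp^2 - r^2, 0)); tq <- sqrt(max(dq^2 - r^2, 0))
  arc2d <- r * pick$delta
  U <- tp + arc2d + tq
  dz <- Q[3L] - P[3L]
  len <- sqrt(U^2 + dz^2)
  z_in <- P[3L] + if (U > 0) (tp / U) * dz else 0
  z_out <- P[3L] + if (U > 0) ((tp + arc2d) / U) * dz else dz
  if (max(abs(z_in), abs(z_out)) > cyl$half_length)
    warning("wrap arc on cylinder '", cyl$name,
            "' leaves the +/- half_length band", call. = FALSE)
  n_arc <- max(2L, ceiling(pick$delta / (5 * DEG2RAD)) + 1L)
  phis <- pick$phi_p + pick$s * pick$delta * seq(0, 1, length.out = n_arc)
  zs <- z_in + (z_out - z_in) * seq(0, 1, length.out = n_arc)
  arc_local <- cbind(r * cos(phis), r * sin(phis), zs)
  path <- rbind(p, tf_point(cyl$frame, arc_local), q)
  list(length = len, wrap_active = TRUE, path = path,
       tangent_in = tf_point(cyl$frame, c(r * cos(pick$phi_p),
                                          r * sin(pick$phi_p), z_in)),
       tangent_out = tf_point(cyl$frame, c(r * cos(pick$phi_q),
                                           r * sin(pick$phi_q), z_out)),
       arc_angle = pick$delta,
       helix_length = sqrt(arc2d^2 + (z_out - z_in)^2))
}

dist_point_segment_2d <- function(x, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t_ <- if (len2 == 0) 0 else max(0, min(1, sum((x - a) * ab) / len2))
  sqrt(sum((a + t_ * ab - x)^2))
}

#' Muscle strand path length in a pose
#'
#' Via points are hard anchors; between consecutive anchors the path is
#' solved over that leg's wrapping cylinders by fixed-point iteration
#' (each cylinder re-solved against its neighbouring tangent points) until
#' the relative length change falls below 1e-10 or 100 iterations.
#'
#' @param model a `limb_model`.
#' @param pose a pose (degrees).
#' @param strand a [muscle_strand()] (or a muscle name plus strand index via
#'   [muscle_strand_of()]).
#' @param transforms optional precomputed [apply_pose()] result, for callers
#'   evaluating many strands in the same pose.
#' @return list with `length` (m) and `path` (n x 3 world polyline).
#' @export
strand_length <- function(model, pose, strand, transforms = NULL) {
  if (is.null(transforms)) transforms <- apply_pose(model, pose)
  anchors <- c(list(strand$origin), strand$via_points, list(strand$insertion))
  apts <- lapply(anchors, function(a) tf_point(transforms[[a$segment]],
                                               a$point))
  cyls <- lapply(model$cylinders[strand$obstacles], cylinder_world,
                 transforms = transforms)
  total <- 0
  n_wraps <- 0L
  path <- NULL
  for (i in seq_len(length(apts) - 1L)) {
    leg <- solve_leg(apts[[i]], apts[[i + 1L]], cyls)
    total <- total + leg$length
    n_wraps <- n_wraps + leg$n_active
    path <- if (is.null(path)) leg$path else rbind(path, leg$path[-1L, ,
                                                                  drop = FALSE])
  }
  list(length = total, path = path, n_wraps = n_wraps)
}

# Shortest path from a to b around an ordered list of cylinders
solve_leg <- function(a, b, cyls) {
  K <- length(cyls)
  if (K == 0L)
    return(list(length = norm3(b - a), path = rbind(a, b), n_active = 0L))
  state <- replicate(K, list(active = FALSE, t_in = NULL, t_out = NULL,
                             res = NULL), simplify = FALSE)
  leg_length <- function() {
    pts <- list(a)
    segs <- 0
    for (k in seq_len(K)) if (state[[k]]$active) {
      segs <- segs + norm3(state[[k]]$t_in - pts[[length(pts)]]) +
        state[[k]]$res$helix_length
      pts[[length(pts) + 1L]] <- state[[k]]$t_out
    }
    segs + norm3(b - pts[[length(pts)]])
  }
  prev_len <- Inf
  for (iter in seq_len(100L)) {
    for (k in seq_len(K)) {
      left <- a
      for (j in seq_len(K)) if (j < k && state[[j]]$active)
        left <- state[[j]]$t_out
      right <- b
      for (j in rev(seq_len(K))) if (j > k && state[[j]]$active)
        right <- state[[j]]$t_in
      res <- solve_wrap_single(left, right, cyls[[k]])
      state[[k]] <- list(active = res$wrap_active, t_in = res$tangent_in,
                         t_out = res$tangent_out, res = res)
    }
    cur <- leg_length()
    if (is.finite(prev_len) &&
        abs(cur - prev_len) <= 1e-10 * max(cur, .Machine$double.eps)) {
      prev_len <- cur
      break
    }
    if (iter == 100L)
      convergence_error(paste0(
        "wrap fixed-point iteration did not converge in 100 iterations ",
        "(last lengths ", format(prev_len), " -> ", format(cur), ")"))
    prev_len <- cur
  }
  path <- rbind(a)
  for (k in seq_len(K)) if (state[[k]]$active) {
    sub <- state[[k]]$res$path
    path <- rbind(path, sub[-c(1L, nrow(sub)), , drop = FALSE])
  }
  path <- rbind(path, b)
  list(length = prev_len, path = path,
       n_active = sum(vapply(state, `[[`, logical(1L), "active")))
}

#' Look up one strand of a named muscle
#'
#' @param model a `limb_model`.
#' @param muscle muscle name.
#' @param strand strand index or label.
#' @return a `muscle_strand`.
#' @export
muscle_strand_of <- function(model, muscle, strand = 1L) {
  if (!muscle %in% names(model$muscles))
    stop("unknown muscle '", muscle, "'")
  strands <- model$muscles[[muscle]]$strands
  if (is.character(strand)) {
    labels <- vapply(strands, `[[`, "", "label")
    idx <- match(strand, labels)
    if (is.na(idx)) stop("muscle '", muscle, "' has no strand '", strand, "'")
    strands[[idx]]
  } else strands[[strand]]
}
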