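#' Planar landmark displacement from a joint centre
#'
#' Projects a named landmark and a joint centre into a declared coordinate
#' plane of one segment's frame (at the reference pose) and returns their
#' in-plane distance normalized by the model's minimum humeral shaft
#' circumference. These displacements are the osteological measurements
#' correlated against mean moment arms (e.g. the deltopectoral-crest apex
#' from the glenohumeral centre in the humeral XY plane).
#'
#' @param model a `limb_model`.
#' @param landmark list `list(segment = , name = )` naming a segment
#'   landmark, or `list(segment = , point = )` with an explicit 3-point.
#' @param joint joint name whose centre is the reference, or a
#'   `list(segment = , point = )`.
#' @param plane list `list(segment = , axes = )` with `axes` one of
#'   `"xy"`, `"xz"`, `"yz"` of that segment's frame.
#' @return dimensionless displacement `d >= 0`.
#' @export
planar_displacement <- function(model, landmark, joint, plane) {
  ax <- match.arg(plane$axes, c("xy", "xz", "yz"))
  if (is.null(plane$segment) || !plane$segment %in% names(model$segments))
    stop("plane must declare a known segment")
  W <- reference_transforms(model)
  to_world <- function(spec) {
    if (!is.null(spec$point)) return(tf_point(W[[spec$segment]], spec$point))
    lm <- model$segments[[spec$segment]]$landmarks[[spec$name]]
    if (is.null(lm))
      stop("segment '", spec$segment, "' has no landmark '", spec$name, "'")
    tf_point(W[[spec$segment]], lm)
  }
  p_lm <- to_world(landmark)
  p_jc <- if (is.list(joint)) to_world(joint) else {
    if (!joint %in% names(model$joints)) stop("unknown joint '", joint, "'")
    j <- model$joints[[joint]]
    tf_point(W[[j$proximal_segment]], j$centre)
  }
  # both points in the plane segment's frame
  Tinv <- tf_inverse(W[[plane$segment]])
  a <- tf_point(Tinv, p_lm)
  b <- tf_point(Tinv, p_jc)
  keep <- switch(ax, xy = c(1L, 2L), xz = c(1L, 3L), yz = c(2L, 3L))
  sqrt(sum((a[keep] - b[keep])^2)) / model$norm_circumference
}

#' Correlate osteological displacements with mean moment arms
#'
#' Ordinary least squares of moment arm `m` on displacement `d` with Pearson
#' correlation, fitted on the non-excluded taxa; a second fit including all
#' taxa is also returned. Exclusion is data-driven (a per-taxon flag with a
#' reason), mirroring taxon-specific flags in the source measurements, and a
#' reduced-major-axis slope is available behind `rma = TRUE`.
#'
#' @param d named numeric vector of per-taxon displacements.
#' @param m named numeric vector of per-taxon mean moment arms (same taxa).
#' @param exclusions character vector of taxa to exclude from the primary
#'   fit, or a data frame with columns `taxon` and `reason`.
#' @param rma also report the reduced-major-axis slope/intercept.
#' @return list with `fit` (slope, intercept, r, r_squared, n_used),
#'   `fit_all` (same, all taxa), `excluded` (taxa + reasons), and optional
#'   `rma`.
#' @export
osteo_correlate <- function(d, m, exclusions = character(), rma = FALSE) {
  taxa <- names(d)
  if (is.null(taxa) || !identical(sort(taxa), sort(names(m))))
    stop("d and m must be named by the same taxa")
  m <- m[taxa]
  excl_df <- if (is.data.frame(exclusions)) exclusions
             else data.frame(taxon = exclusions,
                             reason = rep("flagged", length(exclusions)),
                             stringsAsFactors = FALSE)
  bad <- setdiff(excl_df$taxon, taxa)
  if (length(bad)) stop("unknown excluded taxa: ", paste(bad, collapse = ", "))
  use <- !(taxa %in% excl_df$taxon)
  fit_one <- function(x, y) {
    if (length(x) < 3L) stop("need at least 3 taxa for the fit")
    if (stats::sd(x) == 0)
      stop(errorCondition("zero variance in displacements: correlation undefined",
                          class = c("ossomech_undefined_correlation", "error",
                                    "condition")))
    fm <- stats::lm(y ~ x)
    r <- stats::cor(x, y)
    list(slope = unname(stats::coef(fm)[2L]),
         intercept = unname(stats::coef(fm)[1L]),
         r = r, r_squared = r^2, n_used = length(x))
  }
  out <- list(fit = fit_one(d[use], m[use]),
              fit_all = fit_one(d, m),
              excluded = excl_df)
  if (rma) {
    x <- d[use]; y <- m[use]
    slope <- sign(stats::cor(x, y)) * stats::sd(y) / stats::sd(x)
    out$rma <- list(slope = slope, intercept = mean(y) - slope * mean(x))
  }
  out
}
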