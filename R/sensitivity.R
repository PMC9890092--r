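#' Sensitivity variant specifications
#'
#' The variant protocol probes how summed moment-arm patterns respond to
#' posture and axis-placement choices: splayed (75 degrees) and tucked
#' (115 degrees) humeral adduction in place of the standard 90; a steeper
#' (70 degree) scapular slope; and mediolateral translation of the elbow
#' abduction-adduction rotational centre to 1/3 or 2/3 across the condyle
#' width (base: the middle of the lateral distal epicondyle).
#'
#' @param kind one of `"pose-adduction"`, `"scapular-slope"`,
#'   `"elbow-axis-translation"`.
#' @param parameter the variant parameter: an adduction angle in degrees
#'   (75 or 115 in the study protocol), a scapular slope in degrees (70), or
#'   a condyle-width fraction in (0, 1) (1/3 or 2/3).
#' @return an object of class `variant_spec`.
#' @export
variant_spec <- function(kind = c("pose-adduction", "scapular-slope",
                                  "elbow-axis-translation"), parameter) {
  kind <- match.arg(kind)
  parameter <- as.numeric(parameter)
  if (!is.finite(parameter)) stop("variant parameter must be finite")
  if (kind == "elbow-axis-translation" && (parameter <= 0 || parameter >= 1))
    stop("condyle fraction must lie in (0, 1)")
  structure(list(kind = kind, parameter = parameter), class = "variant_spec")
}

#' Build a variant model or protocol
#'
#' `pose-adduction` acts on a [pose_grid()] (replaces the fixed glenohumeral
#' adduction context angle); the other kinds act on a `limb_model`.
#' `scapular-slope` rotates the scapulocoracoid's rest orientation about the
#' mediolateral (+z) axis anchored at the glenohumeral joint centre, so the
#' glenoid stays fixed in space while the blade is re-sloped;
#' `elbow-axis-translation` moves the elbow joint centre along the
#' lateral-to-medial epicondyle chord to the stated fraction (the humerus
#' must carry `lateral_epicondyle` and `medial_epicondyle` landmarks).
#'
#' @param x a `limb_model` or [pose_grid()] as appropriate for the kind.
#' @param spec a [variant_spec()].
#' @return an object of the same type as `x`.
#' @export
make_variant <- function(x, spec) {
  stopifnot(inherits(spec, "variant_spec"))
  switch(spec$kind,
    "pose-adduction" = {
      if (!inherits(x, "pose_grid"))
        stop("pose-adduction variants act on a pose_grid")
      x$fixed_context <- pose_set(x$fixed_context, "glenohumeral",
                                  "adduction", spec$parameter)
      x
    },
    "scapular-slope" = {
      if (!inherits(x, "limb_model"))
        stop("scapular-slope variants act on a limb_model")
      cur <- x$meta$scapular_slope_deg
      if (is.null(cur))
        stop("model must declare meta$scapular_slope_deg for the ",
             "scapular-slope variant")
      j <- x$joints[["glenohumeral"]]
      if (is.null(j)) stop("model has no 'glenohumeral' joint")
      seg <- j$proximal_segment
      s <- x$segments[[seg]]
      # pivot: the glenohumeral centre, expressed in seg's parent frame;
      # axis: the world mediolateral (+z) axis pulled back to that frame
      centre_parent <- tf_point(s$rest_transform, j$centre)
      if (is.null(s$parent)) {
        z_parent <- c(0, 0, 1)
      } else {
        W <- reference_transforms(x)
        z_parent <- as.numeric(t(tf_rotation(W[[s$parent]])) %*% c(0, 0, 1))
      }
      delta <- (spec$parameter - cur) * DEG2RAD
      x$segments[[seg]]$rest_transform <-
        rot_about_line(centre_parent, z_parent, delta) %*% s$rest_transform
      x$meta$scapular_slope_deg <- spec$parameter
      validate_limb_model(x)
      x
    },
    "elbow-axis-translation" = {
      if (!inherits(x, "limb_model"))
        stop("elbow-axis-translation variants act on a limb_model")
      j <- x$joints[["elbow"]]
      if (is.null(j)) stop("model has no 'elbow' joint")
      hum <- x$segments[[j$proximal_segment]]
      lat <- hum$landmarks[["lateral_epicondyle"]]
      med <- hum$landmarks[["medial_epicondyle"]]
      if (is.null(lat) || is.null(med))
        stop("humerus must carry 'lateral_epicondyle' and ",
             "'medial_epicondyle' landmarks for the elbow-axis variant")
      x$joints[["elbow"]]$centre <- lat + spec$parameter * (med - lat)
      validate_limb_model(x)
      x
    })
}

#' Rank-order consistency of summed moment arms across variants
#'
#' Compares the qualitative ordering of taxa by one summed action column
#' across variant analyses. Rankings are deterministic (descending value,
#' ties broken by taxon name); each variant is compared with the base (the
#' first table) by Kendall's tau, with explicit rank-inversion pairs, and
#' per-taxon min-max envelopes across variants are checked for between-taxon
#' overlap.
#'
#' @param tables named list of action-summary tables (data frames with a
#'   `taxon` column), the first being the base analysis; all must contain
#'   the same taxa.
#' @param action an action column name present in every table.
#' @return list with `rankings` (taxon orderings per variant), `tau` (named
#'   Kendall tau of each variant vs the base), `inversions` (per variant, a
#'   data frame of taxon pairs ordered differently from the base), and
#'   `overlap` (data frame of taxon pairs whose value envelopes across
#'   variants intersect).
#' @export
rank_consistency <- function(tables, action) {
  if (is.null(names(tables)) || any(names(tables) == ""))
    stop("tables must be a named list (first = base)")
  taxa <- sort(tables[[1L]]$taxon)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    if (!action %in% names(tb))
      stop("table '", nm, "' lacks action column '", action, "'")
    if (!identical(sort(tb$taxon), taxa))
      stop("table '", nm, "' has a different taxon set")
  }
  vals <- sapply(tables, function(tb)
    stats::setNames(tb[[action]], tb$taxon)[taxa])
  rank_of <- function(v) {
    ord <- order(-v, taxa)
    stats::setNames(seq_along(ord), taxa[ord])[taxa]
  }
  ranks <- apply(vals, 2L, rank_of)
  base <- ranks[, 1L]
  tau <- vapply(seq_len(ncol(ranks)), function(k)
    stats::cor(base, ranks[, k], method = "kendall"), numeric(1L))
  names(tau) <- colnames(ranks)
  inversions <- lapply(seq_len(ncol(ranks)), function(k) {
    prs <- utils::combn(taxa, 2L)
    inv <- apply(prs, 2L, function(pr) {
      sign(base[pr[1L]] - base[pr[2L]]) !=
        sign(ranks[pr[1L], k] - ranks[pr[2L], k])
    })
    data.frame(taxon_a = prs[1L, inv], taxon_b = prs[2L, inv],
               stringsAsFactors = FALSE)
  })
  names(inversions) <- colnames(ranks)
  env <- data.frame(taxon = taxa,
                    lo = apply(vals, 1L, min), hi = apply(vals, 1L, max))
  prs <- utils::combn(taxa, 2L)
  ov <- apply(prs, 2L, function(pr) {
    a <- env[env$taxon == pr[1L], ]; b <- env[env$taxon == pr[2L], ]
    a$lo <= b$hi && b$lo <= a$hi
  })
  list(rankings = apply(ranks, 2L, function(rk)
         taxa[order(rk)], simplify = FALSE),
       tau = tau,
       inversions = inversions,
       overlap = data.frame(taxon_a = prs[1L, ], taxon_b = prs[2L, ],
                            overlap = ov, stringsAsFactors = FALSE))
}
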