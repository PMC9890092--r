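#' Per-taxon summed action magnitudes
#'
#' The twelve named joint actions, in the fixed column order used by every
#' downstream table: glenohumeral protraction, retraction, abduction,
#' adduction, medial rotation, lateral rotation; elbow extension, flexion,
#' abduction, adduction, medial rotation, lateral rotation.
#'
#' @return character vector of 12 column names.
#' @export
action_columns <- function() {
  c("gh_protraction", "gh_retraction", "gh_abduction", "gh_adduction",
    "gh_medial_rotation", "gh_lateral_rotation",
    "el_extension", "el_flexion", "el_abduction", "el_adduction",
    "el_medial_rotation", "el_lateral_rotation")
}

# (joint, dof, sign of mean) -> action column
action_column_for <- function(joint, dof, positive) {
  key <- paste(joint, dof, sep = ".")
  map <- list(
    "glenohumeral.protraction" = c("gh_protraction", "gh_retraction"),
    "glenohumeral.adduction" = c("gh_adduction", "gh_abduction"),
    "glenohumeral.medial_rotation" = c("gh_medial_rotation",
                                       "gh_lateral_rotation"),
    "elbow.flexion" = c("el_flexion", "el_extension"),
    "elbow.adduction" = c("el_adduction", "el_abduction"),
    "elbow.medial_rotation" = c("el_medial_rotation", "el_lateral_rotation"))
  cols <- map[[key]]
  if (is.null(cols)) stop("no action mapping for joint DOF '", key, "'")
  if (positive) cols[1L] else cols[2L]
}

#' Sum per-muscle mean moment arms into a per-taxon action row
#'
#' Each muscle contributes the magnitude of its mean normalized moment arm to
#' exactly one column of each opposing action pair: the positive-named action
#' when the mean is positive, the negative-named action when negative, and
#' neither when exactly zero. Sums are thus of magnitudes of means (a
#' muscle's within-sweep sign variation is collapsed before summation).
#'
#' @param summaries data frame of pooled summaries as produced by
#'   [aggregate_sweep()] (one row per muscle per joint DOF; columns `muscle`,
#'   `joint`, `dof`, `mean`).
#' @param taxon taxon identifier for the row.
#' @return one-row data frame: `taxon` plus the 12 [action_columns()].
#' @export
classify_and_sum <- function(summaries, taxon) {
  if (anyDuplicated(summaries[, c("muscle", "joint", "dof")]))
    stop("duplicate (muscle, joint, dof) entries in summaries")
  row <- stats::setNames(as.list(numeric(12L)), action_columns())
  for (i in seq_len(nrow(summaries))) {
    m <- summaries$mean[i]
    if (m == 0) next
    col <- action_column_for(summaries$joint[i], summaries$dof[i], m > 0)
    row[[col]] <- row[[col]] + abs(m)
  }
  cbind(data.frame(taxon = taxon, stringsAsFactors = FALSE),
        as.data.frame(row))
}

#' Opposing-action ratios
#'
#' Ratio of the positive-action sum to the opposing negative-action sum
#' (e.g. protraction/retraction). A zero denominator with a positive
#' numerator records `Inf` with a flag; 0/0 records `NaN` with a flag.
#'
#' @param table an action-summary table ([classify_and_sum()] rows).
#' @param pairs list of character 2-vectors `c(numerator, denominator)`;
#'   default: all six opposing pairs.
#' @return the table with appended `ratio_<num>_<den>` columns and a
#'   `ratio_flags` attribute marking non-finite ratios.
#' @export
action_ratios <- function(table, pairs = default_action_pairs()) {
  flags <- list()
  for (pr in pairs) {
    if (!all(pr %in% names(table)))
      stop("unknown action pair: ", paste(pr, collapse = "/"))
    rc <- paste0("ratio_", pr[1L], "_", pr[2L])
    table[[rc]] <- table[[pr[1L]]] / table[[pr[2L]]]
    flags[[rc]] <- !is.finite(table[[rc]])
  }
  attr(table, "ratio_flags") <- as.data.frame(flags)
  table
}

#' @rdname action_ratios
#' @export
default_action_pairs <- function() {
  list(c("gh_protraction", "gh_retraction"),
       c("gh_adduction", "gh_abduction"),
       c("gh_medial_rotation", "gh_lateral_rotation"),
       c("el_flexion", "el_extension"),
       c("el_adduction", "el_abduction"),
       c("el_medial_rotation", "el_lateral_rotation"))
}

#' Full per-taxon action summary from a model
#'
#' Runs the standardized glenohumeral and elbow sweeps for every muscle and
#' every joint DOF the muscle spans, pools strands, and sums magnitudes into
#' the taxon's action row.
#'
#' @param model a `limb_model` with `glenohumeral` and `elbow` joints.
#' @param gh_grid,el_grid pose grids; defaults are the study protocols.
#' @return list with `summaries` (per muscle x DOF pooled means) and `row`
#'   (the taxon's 12-column action row).
#' @export
taxon_action_summary <- function(model,
                                 gh_grid = paper_glenohumeral_grid(model),
                                 el_grid = paper_elbow_grid(model)) {
  grids <- list(glenohumeral = gh_grid, elbow = el_grid)
  out <- list()
  for (mu in model$muscles) {
    for (jn in mu$spanned_joints) {
      grid <- grids[[jn]]
      if (is.null(grid)) next
      for (dof in names(model$joints[[jn]]$dofs)) {
        sw <- sweep_moment_arms(model, mu$name, jn, dof, grid)
        out[[length(out) + 1L]] <- aggregate_sweep(sw)
      }
    }
  }
  summaries <- do.call(rbind, out)
  list(summaries = summaries,
       row = classify_and_sum(summaries, model$taxon))
}

#' Write an action-summary table as CSV
#'
#' One row per taxon, the 12 action columns and any ratio columns, preceded
#' by `#`-comment metadata lines recording the protocol, normalization and
#' package version.
#'
#' @param table the table to write.
#' @param path output path.
#' @param protocol free-text protocol label for the header.
#' @return `path`, invisibly.
#' @export
write_action_table <- function(table, path, protocol = "study-replica") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# protocol: ", protocol),
    "# normalization: moment arms / minimum humeral shaft circumference (dimensionless)",
    paste0("# ossomech version: ",
           as.character(utils::packageVersion("ossomech")))), con)
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read an action-summary table written by [write_action_table()]
#'
#' @param path CSV path (lines starting with `#` are metadata comments).
#' @return data frame.
#' @export
read_action_table <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
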