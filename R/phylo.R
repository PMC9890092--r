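#' Time-scale a fossil tree from first appearance dates
#'
#' "Basic" stratigraphic dating: each internal node is aged at the oldest
#' first appearance datum (FAD) among its descendants; tips sit at their
#' FADs. Zero-length branches are then resolved by pushing parent nodes
#' rootward (a single rootward post-order pass, oldest constraints first)
#' until every branch is at least `min_bl` long.
#'
#' @param topology an `ape::phylo` tree or a newick string (branch lengths,
#'   if any, are ignored).
#' @param first_appearances named numeric vector or data frame with columns
#'   `taxon` and `FAD_Ma`: first appearance ages (Ma) for every tip.
#' @param min_bl minimum branch length (Myr); the study protocol uses 1.0.
#' @return an `ape::phylo` with branch lengths in Myr, a `root.time`
#'   element (age of the root, Ma) and a `node_ages` attribute (ages of all
#'   tips then internal nodes, Ma).
#' @export
time_scale_tree <- function(topology, first_appearances, min_bl = 1.0) {
  tree <- if (is.character(topology)) ape::read.tree(text = topology)
          else topology
  if (!inherits(tree, "phylo")) stop("topology must be a phylo or newick text")
  if (is.data.frame(first_appearances)) {
    fads <- stats::setNames(first_appearances$FAD_Ma,
                            first_appearances$taxon)
  } else fads <- first_appearances
  missing_tips <- setdiff(tree$tip.label, names(fads))
  if (length(missing_tips))
    stop("missing first appearance age for tip(s): ",
         paste(missing_tips, collapse = ", "))
  if (any(!is.finite(fads)) || any(fads <= 0))
    stop("first appearance ages must be positive and finite")
  n <- length(tree$tip.label)
  n_node <- tree$Nnode
  age <- numeric(n + n_node)
  age[seq_len(n)] <- fads[tree$tip.label]
  eo <- ape::reorder.phylo(tree, "postorder")
  for (i in seq_len(nrow(eo$edge))) {
    par <- eo$edge[i, 1L]; child <- eo$edge[i, 2L]
    age[par] <- max(age[par], age[child] + min_bl)
  }
  tree$edge.length <- age[tree$edge[, 1L]] - age[tree$edge[, 2L]]
  tree$root.time <- age[n + 1L]
  attr(tree, "node_ages") <- age
  tree
}

#' Brownian-motion tree covariance
#'
#' `C[i, j]` is the shared branch length from the root to the most recent
#' common ancestor of tips i and j: under Brownian motion, tip trait
#' covariances are proportional to this matrix.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return symmetric positive semidefinite n x n matrix with tip-label
#'   dimnames.
#' @export
phylo_vcv <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  ape::vcv.phylo(tree)
}

#' Phylogenetic principal components analysis
#'
#' Computes the generalized-least-squares phylogenetic mean
#' `a = (1' C^-1 1)^-1 1' C^-1 X` and the evolutionary covariance
#' `R = (X - 1a)' C^-1 (X - 1a) / (n - 1)` under a Brownian-motion tree
#' covariance `C`, then eigen-decomposes either the evolutionary correlation
#' matrix (`bm-correlation`, the default, with scores computed on
#' standardized deviations) or the covariance (`bm-covariance`).
#' `uniform-bl` substitutes unit branch lengths before building `C`;
#' `ordinary` ignores the tree entirely (arithmetic mean and sample
#' covariance/correlation, equivalent to `C = I`). Loading columns are
#' sign-fixed so each column's largest-magnitude element is positive.
#'
#' @param X numeric n x p trait matrix (rownames = taxa; no missing values,
#'   n >= 3, p >= 2).
#' @param tree time-scaled `ape::phylo`; ignored for mode `"ordinary"`.
#' @param mode one of `"bm-correlation"`, `"bm-covariance"`, `"uniform-bl"`,
#'   `"ordinary"`.
#' @param use_correlation override the mode's default standardization
#'   (`TRUE` for `bm-correlation` and `uniform-bl`, `FALSE` otherwise).
#' @return an object of class `ppca_result`: `mean` (1 x p GLS mean),
#'   `evo_cov`, `evo_cor`, `C`, `eigenvalues`, `loadings`, `scores`,
#'   `var_prop`, `mode`.
#' @export
ppca <- function(X, tree = NULL,
                 mode = c("bm-correlation", "bm-covariance", "uniform-bl",
                          "ordinary"),
                 use_correlation = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (anyNA(X)) stop("trait table contains missing values")
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("need at least 3 taxa")
  if (p < 2L) stop("need at least 2 traits")
  if (is.null(use_correlation))
    use_correlation <- mode %in% c("bm-correlation", "uniform-bl")
  if (mode == "ordinary") {
    C <- diag(n)
    dimnames(C) <- list(rownames(X), rownames(X))
  } else {
    if (is.null(tree)) stop("mode '", mode, "' requires a tree")
    if (!setequal(tree$tip.label, rownames(X)))
      stop("tree tips and trait-table rows must match 1:1")
    if (mode == "uniform-bl") tree$edge.length <- rep(1, nrow(tree$edge))
    C <- phylo_vcv(tree)
    X <- X[rownames(C), , drop = FALSE]
  }
  invC <- tryCatch(solve(C), error = function(e)
    stop("singular tree covariance; enforce a positive minimum branch length"))
  one <- matrix(1, n, 1L)
  a <- as.numeric(solve(t(one) %*% invC %*% one) %*% (t(one) %*% invC %*% X))
  names(a) <- colnames(X)
  Xc <- sweep(X, 2L, a)
  R <- t(Xc) %*% invC %*% Xc / (n - 1)
  if (use_correlation && any(diag(R) <= 0))
    stop("trait(s) with zero evolutionary variance: ",
         paste(colnames(X)[diag(R) <= 0], collapse = ", "),
         "; correlation-mode pPCA is undefined (drop them or use a ",
         "covariance mode)")
  if (use_correlation) {
    decomp <- stats::cov2cor(R)
    Y <- sweep(Xc, 2L, sqrt(diag(R)), "/")
  } else {
    decomp <- R
    Y <- Xc
  }
  eig <- eigen(decomp, symmetric = TRUE)
  lam <- eig$values
  lam[lam < 0 & lam > -1e-10] <- 0
  if (p > n) lam[seq.int(n + 1L, p)] <- pmax(lam[seq.int(n + 1L, p)], 0)
  V <- eig$vectors
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  dimnames(V) <- list(colnames(X), paste0("PC", seq_len(p)))
  S <- Y %*% V
  dimnames(S) <- list(rownames(X), colnames(V))
  structure(list(
    mean = a, evo_cov = R, evo_cor = stats::cov2cor(R), C = C,
    eigenvalues = lam, loadings = V, scores = S,
    var_prop = lam / sum(lam), mode = mode,
    use_correlation = use_correlation
  ), class = "ppca_result")
}

#' @export
print.ppca_result <- function(x, ...) {
  cat("<ppca_result> mode:", x$mode, "\n")
  cat(" variance proportions:",
      paste0(sprintf("%.1f%%", 100 * x$var_prop), collapse = " "), "\n")
  invisible(x)
}

#' Write pPCA outputs as CSV
#'
#' Writes `<stem>_scores.csv`, `<stem>_loadings.csv`,
#' `<stem>_eigenvalues.csv` into `dir`.
#'
#' @param result a `ppca_result`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return character vector of written paths, invisibly.
#' @export
write_ppca <- function(result, dir, stem = "ppca") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(stem, "_",
                                 c("scores", "loadings", "eigenvalues"),
                                 ".csv"))
  utils::write.csv(data.frame(taxon = rownames(result$scores),
                              result$scores, check.names = FALSE),
                   paths[1L], row.names = FALSE)
  utils::write.csv(data.frame(trait = rownames(result$loadings),
                              result$loadings, check.names = FALSE),
                   paths[2L], row.names = FALSE)
  utils::write.csv(data.frame(component = colnames(result$loadings),
                              eigenvalue = result$eigenvalues,
                              var_prop = result$var_prop),
                   paths[3L], row.names = FALSE)
  invisible(paths)
}
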