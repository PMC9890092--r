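#' Fit a joint centre to articular-surface points
#'
#' Least-squares circle or sphere fit used for joint-centre estimation from
#' digitized articular surface points. An algebraic (linearized) fit provides
#' the start for a nonlinear least-squares refinement of the geometric
#' (radial) residuals. In circle mode a best-fit plane is first obtained by
#' total least squares (SVD) and the fit is carried out in-plane; the centre
#' is returned in 3D.
#'
#' @param points numeric n x 3 matrix, n >= 3 (circle) or n >= 4 (sphere),
#'   non-collinear (and non-coplanar for spheres).
#' @param mode `"circle"` or `"sphere"`.
#' @return list with `centre` (3-vector), `radius` (m), `rms_residual` (root
#'   mean square radial residual, m), and for circles `normal` (unit plane
#'   normal).
#' @export
fit_joint_centre <- function(points, mode = c("circle", "sphere")) {
  mode <- match.arg(mode)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  n <- nrow(points)
  if (n < 3L) stop("degenerate input: at least 3 points required")
  ctr <- colMeans(points)
  X <- sweep(points, 2L, ctr)
  sv <- svd(X)
  if (sv$d[2L] < 1e-12 * max(sv$d[1L], 1e-300))
    stop("degenerate input: points are collinear")
  if (mode == "circle") {
    normal <- sv$v[, 3L]
    # in-plane coordinates
    U <- X %*% sv$v[, 1:2, drop = FALSE]
    fit2 <- fit_circle_2d(U)
    refine <- stats::optim(
      fit2$centre,
      function(c2) {
        r <- sqrt((U[, 1L] - c2[1L])^2 + (U[, 2L] - c2[2L])^2)
        sum((r - mean(r))^2)
      },
      method = "BFGS", control = list(reltol = 1e-14))
    c2 <- refine$par
    r_each <- sqrt((U[, 1L] - c2[1L])^2 + (U[, 2L] - c2[2L])^2)
    radius <- mean(r_each)
    centre <- ctr + as.numeric(sv$v[, 1:2, drop = FALSE] %*% c2)
    list(centre = centre, radius = radius,
         rms_residual = sqrt(mean((r_each - radius)^2)),
         normal = unit3(normal))
  } else {
    if (n < 4L) stop("degenerate input: sphere fit requires at least 4 points")
    if (sv$d[3L] < 1e-9 * sv$d[1L])
      stop("degenerate input: points are coplanar; use mode = \"circle\"")
    # algebraic fit: |x|^2 = 2 c.x + (r^2 - |c|^2)
    A <- cbind(2 * points, 1)
    b <- rowSums(points^2)
    sol <- qr.solve(A, b)
    c0 <- sol[1:3]
    refine <- stats::optim(
      c0,
      function(cc) {
        r <- sqrt(colSums((t(points) - cc)^2))
        sum((r - mean(r))^2)
      },
      method = "BFGS", control = list(reltol = 1e-14))
    cc <- refine$par
    r_each <- sqrt(colSums((t(points) - cc)^2))
    radius <- mean(r_each)
    list(centre = as.numeric(cc), radius = radius,
         rms_residual = sqrt(mean((r_each - radius)^2)))
  }
}

# Algebraic 2D circle fit (Kasa): x^2 + y^2 = 2 a x + 2 b y + c
fit_circle_2d <- function(U) {
  A <- cbind(2 * U, 1)
  b <- rowSums(U^2)
  sol <- qr.solve(A, b)
  list(centre = sol[1:2],
       radius = sqrt(sol[3L] + sum(sol[1:2]^2)))
}
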