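## Low-level rigid-body and internal-coordinate geometry shared by the
## observable and clustering code. Coordinates are n x 3 matrices in Angstrom.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' coordinate sets over a mask, and reports the minimized RMSD. The transform
#' maps the mobile coordinates onto the reference frame; reflections are
#' excluded so the result is always a physical rigid move.
#'
#' @param mobile numeric matrix (n x 3) to be moved.
#' @param reference numeric matrix (n x 3), same row order as \code{mobile}.
#' @param mask integer indices of rows used to fit (default: all rows). At
#'   least 3 non-collinear points are required.
#' @return list with \code{rotation} (3 x 3 proper rotation), \code{translation}
#'   (length-3; apply as \code{coords \%*\% t(R) + t}), \code{rmsd} (Angstrom,
#'   over the mask), and \code{transform(x)}, a function applying the move.
#' @export
superpose <- function(mobile, reference, mask = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference)))
    stop("mobile and reference must have identical dimensions")
  if (is.null(mask)) mask <- seq_len(nrow(mobile))
  if (length(mask) < 3L)
    stop("superposition mask must select at least 3 atoms")
  xm <- mobile[mask, , drop = FALSE]
  xr <- reference[mask, , drop = FALSE]
  cm <- colMeans(xm)
  cr <- colMeans(xr)
  a <- sweep(xm, 2L, cm)
  b <- sweep(xr, 2L, cr)
  h <- crossprod(a, b)
  sv <- svd(h)
  if (min(sv$d) < 1e-10 && sv$d[2] < 1e-10)
    stop("degenerate superposition mask (collinear or coincident atoms)")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cr - as.vector(rot %*% cm)
  moved <- xm %*% t(rot) + matrix(trans, nrow(xm), 3L, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((moved - xr)^2)))
  list(
    rotation = rot,
    translation = trans,
    rmsd = rmsd,
    transform = function(x) {
      x <- as.matrix(x)
      x %*% t(rot) + matrix(trans, nrow(x), 3L, byrow = TRUE)
    }
  )
}

## RMSD between two coordinate sets without fitting.
.rmsd_raw <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

## Torsion angle (degrees, in [-180, 180)) defined by four points.
## Accepts 3-vectors or m x 3 matrices (one angle per row set).
.torsion <- function(p1, p2, p3, p4) {
  to_mat <- function(p) if (is.null(dim(p))) matrix(p, 1L, 3L) else as.matrix(p)
  p1 <- to_mat(p1); p2 <- to_mat(p2); p3 <- to_mat(p3); p4 <- to_mat(p4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cbind(b1[, 2] * b2[, 3] - b1[, 3] * b2[, 2],
              b1[, 3] * b2[, 1] - b1[, 1] * b2[, 3],
              b1[, 1] * b2[, 2] - b1[, 2] * b2[, 1])
  n2 <- cbind(b2[, 2] * b3[, 3] - b2[, 3] * b3[, 2],
              b2[, 3] * b3[, 1] - b2[, 1] * b3[, 3],
              b2[, 1] * b3[, 2] - b2[, 2] * b3[, 1])
  m1 <- cbind(n1[, 2] * b2[, 3] - n1[, 3] * b2[, 2],
              n1[, 3] * b2[, 1] - n1[, 1] * b2[, 3],
              n1[, 1] * b2[, 2] - n1[, 2] * b2[, 1])
  b2n <- sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2) / b2n
  ## IUPAC sign convention (matches bio3d::torsion.xyz)
  ang <- -atan2(y, x) * 180 / pi
  ## principal value with left-closed convention at -180
  ang[ang >= 180] <- ang[ang >= 180] - 360
  ang[ang < -180] <- ang[ang < -180] + 360
  ang
}

## Angle at vertex b (degrees) for points a-b-c; rows of matrices or 3-vectors.
.angle <- function(a, b, c) {
  to_mat <- function(p) if (is.null(dim(p))) matrix(p, 1L, 3L) else as.matrix(p)
  a <- to_mat(a); b <- to_mat(b); c <- to_mat(c)
  u <- a - b
  v <- c - b
  cosang <- rowSums(u * v) / (sqrt(rowSums(u^2)) * sqrt(rowSums(v^2)))
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

## Least-squares plane fit: returns unit normal and centroid; deviations are
## |(x - centroid) . normal|.
.fit_plane <- function(coords) {
  coords <- as.matrix(coords)
  ctr <- colMeans(coords)
  x <- sweep(coords, 2L, ctr)
  sv <- svd(x)
  normal <- sv$v[, 3L]
  list(normal = normal / sqrt(sum(normal^2)), centroid = ctr,
       deviations = abs(x %*% normal))
}

## Edge-shrunk centered running average: value i averages the window of
## half-width floor(w/2) clipped to the series; output length = input length.
runningAverage <- function(x, window) {
  n <- length(x)
  if (window <= 1L || n == 0L) return(x)
  half <- floor(window / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Rotation matrix about z by degrees.
.rotz <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3L, 3L)
}

## Minimum-image displacement for an orthorhombic box (box = 3-vector or NULL).
.min_image <- function(d, box) {
  if (is.null(box)) return(d)
  for (k in 1:3) {
    if (box[k] > 0) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  }
  d
}

## fail fast on missing input files (readers would otherwise warn first)
.check_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  invisible(path)
}
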