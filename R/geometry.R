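#' Wrap an angle into (-180, 180]
#'
#' Torsion angles throughout the package are reported in degrees on the
#' half-open interval (-180, 180], so that the trans conformer is labelled
#' +180 rather than -180.
#'
#' @param angle numeric vector of angles in degrees.
#' @return numeric vector wrapped into (-180, 180].
#' @export
#' @examples
#' wrap_angle(c(-180, 270, 540))
wrap_angle <- function(angle) {
  a <- ((angle + 180) %% 360) - 180
  a[a == -180] <- 180
  a
}

## Coerce an atom coordinate to a length-3 numeric vector (nm).
as_coord <- function(x, what = "coordinate") {
  x <- as.numeric(x)
  if (length(x) != 3L || any(!is.finite(x)))
    stop(what, " must be a finite length-3 numeric vector", call. = FALSE)
  x
}

## Validate a periodic box: length-3 edge vector (orthorhombic) or a 3x3
## matrix of row box vectors (triclinic). Returns a 3x3 matrix.
as_box <- function(box) {
  if (is.null(box)) return(NULL)
  if (is.matrix(box)) {
    if (!all(dim(box) == c(3L, 3L)) || any(!is.finite(box)))
      stop("box matrix must be 3x3 and finite", call. = FALSE)
    m <- box
  } else {
    b <- as.numeric(box)
    if (length(b) != 3L || any(!is.finite(b)))
      stop("box must be a length-3 edge vector or a 3x3 matrix", call. = FALSE)
    m <- diag(b)
  }
  if (abs(det(m)) < 1e-12)
    stop("degenerate periodic box (zero volume)", call. = FALSE)
  m
}

#' Distance between two atoms, optionally under periodic boundary conditions
#'
#' Plain Euclidean distance, or the minimum-image distance when a periodic
#' box is supplied. The minimum image is found by wrapping the fractional
#' difference vector and scanning the 27 neighbouring images, which is exact
#' for any (possibly skewed) triclinic box whose images are convex.
#'
#' @param a,b length-3 coordinates in nm.
#' @param box optional periodic box: length-3 edge vector (nm) for an
#'   orthorhombic box, or a 3x3 matrix of row box vectors for triclinic.
#' @return distance in nm.
#' @export
#' @examples
#' pair_distance(c(0, 0, 0), c(0.9, 0, 0), box = c(1, 1, 1))  # 0.1
pair_distance <- function(a, b, box = NULL) {
  a <- as_coord(a, "a")
  b <- as_coord(b, "b")
  d <- b - a
  m <- as_box(box)
  if (is.null(m)) return(sqrt(sum(d * d)))
  ## fractional coordinates, wrapped to [-0.5, 0.5)
  f <- solve(t(m), d)
  f <- f - round(f)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  best <- Inf
  for (i in seq_len(nrow(shifts))) {
    v <- crossprod(m, f + shifts[i, ])
    best <- min(best, sum(v * v))
  }
  sqrt(best)
}

## Vectorised squared distances between one point and an n x 3 matrix,
## minimum-image if box given. Workhorse for group/water scans.
dist2_point_set <- function(p, xyz, box = NULL) {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3L)
  d <- sweep(xyz, 2L, p)
  m <- as_box(box)
  if (is.null(m)) return(rowSums(d * d))
  if (all(m[lower.tri(m)] == 0) && all(m[upper.tri(m)] == 0)) {
    ## orthorhombic fast path
    e <- diag(m)
    for (k in 1:3) d[, k] <- d[, k] - e[k] * round(d[, k] / e[k])
    return(rowSums(d * d))
  }
  apply(d, 1L, function(v) {
    f <- solve(t(m), v)
    f <- f - round(f)
    best <- Inf
    for (s1 in -1:1) for (s2 in -1:1) for (s3 in -1:1) {
      u <- crossprod(m, f + c(s1, s2, s3))
      best <- min(best, sum(u * u))
    }
    best
  })
}

#' Minimum distance between two atom groups
#'
#' @param groupA,groupB matrices (n x 3) of coordinates in nm; a single
#'   length-3 vector is accepted for a one-atom group.
#' @param box optional periodic box, as in [pair_distance()].
#' @return smallest cross-pair distance in nm.
#' @export
min_group_distance <- function(groupA, groupB, box = NULL) {
  if (is.null(dim(groupA))) groupA <- matrix(as_coord(groupA, "groupA"), ncol = 3L)
  if (is.null(dim(groupB))) groupB <- matrix(as_coord(groupB, "groupB"), ncol = 3L)
  if (nrow(groupA) == 0L || nrow(groupB) == 0L)
    stop("empty atom selection", call. = FALSE)
  best <- Inf
  for (i in seq_len(nrow(groupA)))
    best <- min(best, dist2_point_set(groupA[i, ], groupB, box))
  sqrt(best)
}

#' Signed dihedral angle of an atom quartet
#'
#' Standard IUPAC torsion: looking down the b2 = c-b axis, the angle from the
#' a-b-c plane to the b-c-d plane, signed by the right-hand rule and wrapped
#' into (-180, 180]. Reversing the quartet order leaves the angle unchanged.
#'
#' @param a,b,c,d length-3 coordinates of the quartet, in order.
#' @return torsion angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(a, b, c, d) {
  a <- as_coord(a, "a"); b <- as_coord(b, "b")
  c <- as_coord(c, "c"); d <- as_coord(d, "d")
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1 * n1) < 1e-18 || sum(n2 * n2) < 1e-18)
    stop("collinear atom triple: dihedral undefined", call. = FALSE)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2 * b2))
  wrap_angle(atan2(y, x) * 180 / pi)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Place an atom from internal coordinates
#'
#' Positions atom D given three reference atoms A-B-C, the C-D bond length,
#' the B-C-D angle, and the A-B-C-D torsion (the NeRF construction used by
#' the synthetic model builder, so planted chi angles are exact).
#'
#' @param a,b,c reference coordinates (length-3, nm).
#' @param bond C-D distance in nm.
#' @param angle B-C-D angle in degrees.
#' @param dihedral A-B-C-D torsion in degrees.
#' @return length-3 coordinate of D.
#' @export
place_atom <- function(a, b, c, bond, angle, dihedral) {
  a <- as_coord(a, "a"); b <- as_coord(b, "b"); c <- as_coord(c, "c")
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc * bc))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n * n))
  m <- cross3(n, bc)
  d_local <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}
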