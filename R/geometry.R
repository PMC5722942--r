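# Core computational geometry: distances, torsions, superposition, helix axes.

#' Euclidean distance between two points
#'
#' @param a,b Numeric 3-vectors (Angstrom).
#' @return Distance in Angstrom.
#' @export
#' @examples
#' point_distance(c(0, 0, 0), c(3, 4, 0))
point_distance <- function(a, b) {
  stopifnot(length(a) == 3L, length(b) == 3L, all(is.finite(a)), all(is.finite(b)))
  sqrt(sum((a - b)^2))
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Map an angle in degrees to (-180, 180].
wrap_angle <- function(x) {
  x <- (x + 180) %% 360 - 180
  x[x <= -180 + 1e-12 & x != 0 & abs(x + 180) < 1e-9] <- 180
  ifelse(x == -180, 180, x)
}

#' Torsion (dihedral) angle of four points
#'
#' IUPAC sign convention: cis (eclipsed) = 0 degrees, trans = 180 degrees,
#' range (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-9 || sqrt(sum(b2^2)) < 1e-9 || sqrt(sum(b3^2)) < 1e-9)
    stop("undefined torsion: consecutive points coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9)
    stop("undefined torsion: collinear points")
  y <- sum(cross3(n1, n2) * unit(b2))
  x <- sum(n1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation mapping `mobile` onto `reference`,
#' with the reflection branch forbidden (rotation determinant +1).
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3.
#' @param weights Optional non-negative per-point weights (default uniform).
#' @return Object of class `superposition`: list with `rotation` (3 x 3,
#'   applied as `coords %*% rotation`), `translation` (length-3),
#'   `rmsd` (Angstrom) and `n_atoms`. Transformed mobile coordinates are
#'   `mobile %*% rotation + translation` (row-wise).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n < 3L || nrow(reference) != n)
    stop("superposition requires two equal-length point sets with N >= 3")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights < 0) || sum(weights) <= 0)
    stop("invalid superposition weights")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w)
  cr <- colSums(reference * w)
  pm <- sweep(mobile, 2, cm)
  pr <- sweep(reference, 2, cr)
  if (qr(pm * sqrt(w))$rank < 2L)
    stop("degenerate (rank < 2) point set: superposition undefined")
  h <- t(pm * w) %*% pr
  sv <- svd(h)
  d <- sign(det(sv$u %*% t(sv$v)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- pm %*% rot
  rmsd <- sqrt(sum(w * rowSums((fitted - pr)^2)))
  structure(list(rotation = rot,
                 translation = as.numeric(cr - cm %*% rot),
                 rmsd = rmsd, n_atoms = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Rigid-body superposition of %d atoms, RMSD %.4f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

apply_superposition <- function(coords, sup) {
  sweep(as.matrix(coords) %*% sup$rotation, 2, sup$translation, `+`)
}

#' RMSD on one selection after fitting on another
#'
#' The superposition is computed on the fit selections only; the RMSD is
#' then evaluated on the (possibly different) measure selections. This is
#' the usual "fit on the stable helix, measure the mobile segment"
#' contract of ensemble analyses.
#'
#' @param mobile_sel,reference_sel M x 3 matrices measured after the fit.
#' @param fit_mobile,fit_reference N x 3 matrices (N >= 3) defining the fit.
#' @return RMSD in Angstrom over the measure selections.
#' @export
rmsd_after_superposition <- function(mobile_sel, reference_sel,
                                     fit_mobile, fit_reference) {
  mobile_sel <- as.matrix(mobile_sel); reference_sel <- as.matrix(reference_sel)
  if (nrow(mobile_sel) != nrow(reference_sel) || nrow(mobile_sel) < 1L)
    stop("measure selections must have equal length >= 1")
  sup <- kabsch_superpose(fit_mobile, fit_reference)
  moved <- apply_superposition(mobile_sel, sup)
  sqrt(mean(rowSums((moved - reference_sel)^2)))
}

#' Fit a helix axis through ordered C-alpha positions
#'
#' Local helix centres are computed for each residue quadruple by the
#' bisector construction (the bisectors of the angles at residues i and
#' i+1 both point at the axis); a least-squares line through the centres
#' gives the axis. Rise and twist are the mean axial and angular steps of
#' successive C-alpha projections.
#'
#' @param ca_coords N x 3 matrix of ordered C-alpha coordinates, N >= 5.
#' @param labels Optional residue labels for the azimuth map.
#' @return Object of class `helix_frame`: `axis_point`, `axis_dir` (unit),
#'   `rise_per_residue` (Angstrom), `twist_per_residue` (degrees),
#'   `azimuth` (named vector, degrees in (-180, 180], zero at the
#'   perpendicular component of the first C-alpha), `low_confidence`.
#' @export
fit_helix_axis <- function(ca_coords, labels = NULL) {
  ca <- as.matrix(ca_coords)
  n <- nrow(ca)
  if (n < 5L) stop("helix axis fit requires >= 5 C-alpha positions")
  if (is.null(labels)) labels <- as.character(seq_len(n))

  bis <- function(i) unit(unit(ca[i - 1, ] - ca[i, ]) + unit(ca[i + 1, ] - ca[i, ]))
  centers <- NULL
  for (i in 2:(n - 2)) {
    b1 <- bis(i); b2 <- bis(i + 1)
    d <- cross3(b1, b2)
    if (sqrt(sum(d^2)) < 1e-8) next          # locally straight
    d <- unit(d)
    if (sum(d * (ca[i + 1, ] - ca[i, ])) < 0) d <- -d
    delta <- ca[i + 1, ] - ca[i, ]
    bdif <- b2 - b1
    pd <- delta - sum(delta * d) * d
    pb <- bdif - sum(bdif * d) * d
    r <- if (sum(pb * pb) < 1e-10) 0 else -sum(pd * pb) / sum(pb * pb)
    centers <- rbind(centers, ca[i, ] + r * b1, ca[i + 1, ] + r * b2)
  }
  if (is.null(centers) || nrow(centers) < 2L)
    stop("helix axis fit failed: input is essentially straight")
  axis_point <- colMeans(centers)
  pc <- prcomp(centers, center = TRUE)
  axis_dir <- unit(pc$rotation[, 1])
  if (sum(axis_dir * (ca[n, ] - ca[1, ])) < 0) axis_dir <- -axis_dir

  t_proj <- as.numeric((ca - matrix(axis_point, n, 3, byrow = TRUE)) %*% axis_dir)
  rise <- mean(diff(t_proj))

  # in-plane reference frame for azimuths
  perp <- function(v) v - sum(v * axis_dir) * axis_dir
  ref <- perp(ca[1, ] - axis_point)
  if (sqrt(sum(ref^2)) < 1e-8) ref <- perp(ca[2, ] - axis_point)
  e1 <- unit(ref)
  e2 <- cross3(axis_dir, e1)
  az <- vapply(seq_len(n), function(i) {
    p <- perp(ca[i, ] - axis_point)
    wrap_angle(atan2(sum(p * e2), sum(p * e1)) * 180 / pi)
  }, numeric(1))
  names(az) <- labels

  steps <- wrap_angle(diff(az))
  twist <- mean(steps)
  structure(list(axis_point = axis_point, axis_dir = axis_dir,
                 rise_per_residue = rise, twist_per_residue = twist,
                 azimuth = az, e1 = e1, e2 = e2,
                 low_confidence = mean(abs(steps)) < 5),
            class = "helix_frame")
}

#' @export
print.helix_frame <- function(x, ...) {
  cat(sprintf("Helix frame: rise %.3f A/res, twist %.1f deg/res%s\n",
              x$rise_per_residue, x$twist_per_residue,
              if (isTRUE(x$low_confidence)) " (low confidence)" else ""))
  invisible(x)
}

#' Azimuthal positions of A-chain N-terminal residues about the helix axis
#'
#' Fits the helix axis through the C-alpha atoms of `helix_range` and
#' reports each residue's azimuth about that axis. The azimuth zero is the
#' perpendicular component of the Cys-A6 C-alpha direction, so that
#' differences between structures are well defined once both are
#' superposed on their B8-B20 helices (done automatically when
#' `reference_monomer` is supplied, in which case per-residue azimuth
#' *differences* mobile - reference are returned).
#'
#' @param monomer An `insulin_monomer`.
#' @param helix_range Residue labels of the helix used for the axis fit
#'   (default A1-A8).
#' @param reference_monomer Optional `insulin_monomer` to compare against.
#' @param report_range Residue labels whose azimuths are reported
#'   (default A1-A5).
#' @return Named numeric vector of azimuths (or azimuth differences),
#'   degrees in (-180, 180].
#' @export
azimuth_profile <- function(monomer, helix_range = paste0("A", 1:8),
                            reference_monomer = NULL,
                            report_range = paste0("A", 1:5)) {
  azimuth_of_dir <- function(fr, v) {
    p <- v - sum(v * fr$axis_dir) * fr$axis_dir
    wrap_angle(atan2(sum(p * fr$e2), sum(p * fr$e1)) * 180 / pi)
  }
  one_profile <- function(mon, zero_dir = NULL) {
    ca <- monomer_coords(mon, helix_range, "CA")
    if (nrow(ca) < 5L) stop("helix_range must resolve to >= 5 C-alpha atoms")
    fr <- fit_helix_axis(ca, rownames(ca))
    if (is.null(zero_dir)) {
      a6 <- atom_xyz(mon, "A6", "CA")
      zero_dir <- if (!is.null(a6)) a6 - fr$axis_point else fr$e1
    }
    list(az = wrap_angle(fr$azimuth - azimuth_of_dir(fr, zero_dir)), fr = fr)
  }
  if (is.null(reference_monomer)) {
    pr <- one_profile(monomer)
    return(pr$az[intersect(report_range, names(pr$az))])
  }
  fitted <- superpose_on_b_helix(monomer, reference_monomer)
  pr_ref <- one_profile(reference_monomer)
  # common azimuth zero: the reference structure's A6 direction
  a6_ref <- atom_xyz(reference_monomer, "A6", "CA")
  zero_dir <- if (!is.null(a6_ref)) a6_ref - pr_ref$fr$axis_point else pr_ref$fr$e1
  pr_mob <- one_profile(fitted, zero_dir = zero_dir)
  keep <- intersect(report_range, intersect(names(pr_mob$az), names(pr_ref$az)))
  wrap_angle(pr_mob$az[keep] - pr_ref$az[keep])
}

#' Superpose a monomer on another via the B8-B20 helix
#'
#' @param monomer,reference `insulin_monomer` objects.
#' @param fit_range Residue labels used for the fit (default B8-B20 C-alpha).
#' @return The monomer with transformed coordinates.
#' @export
superpose_on_b_helix <- function(monomer, reference,
                                 fit_range = paste0("B", 8:20)) {
  cm <- monomer_coords(monomer, fit_range, "CA")
  cr <- monomer_coords(reference, fit_range, "CA")
  common <- intersect(rownames(cm), rownames(cr))
  if (length(common) < 3L) stop("too few common B-helix C-alpha atoms for fit")
  sup <- kabsch_superpose(cm[common, , drop = FALSE], cr[common, , drop = FALSE])
  transform_monomer(monomer, sup)
}
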