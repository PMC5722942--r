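# Geometry of the three insulin bridges: distances, chi conformers,
# dicarba cis/trans assignment. Bridge typing is connectivity-based
# (atom distances), never residue-name-based, because dicarba half-residue
# naming varies between deposited files.

BRIDGE_RESIDUES <- list(A6A11 = c("A6", "A11"),
                        A7B7 = c("A7", "B7"),
                        A20B19 = c("A20", "B19"))

# candidate gamma carbons of a dicarba half-residue: carbons bonded to CB
gamma_carbons <- function(at, cb) {
  carbons <- at[grepl("^C", trimws(at$elety)) &
                !(trimws(at$elety) %in% c("C", "CA", "CB")), , drop = FALSE]
  if (!nrow(carbons) || is.null(cb)) return(NULL)
  xyz <- as.matrix(carbons[, c("x", "y", "z")])
  d <- sqrt(rowSums(sweep(xyz, 2, cb)^2))
  xyz[d < 1.75, , drop = FALSE]
}

#' Extract the geometry of one insulin bridge
#'
#' Measures the C-alpha to C-alpha distance, types the bridge from atom
#' connectivity (disulfide: both Sgamma present and within 2.5 Angstrom;
#' dicarba: a Cbeta-Cgamma=Cgamma'-Cbeta' carbon path with the gamma
#' carbons within 1.75 Angstrom), and computes the chi dihedrals along the
#' bridge path. For dicarba bridges the core Cbeta-Cgamma=Cgamma'-Cbeta'
#' torsion assigns the cis (|tau| < 90 deg) or trans stereo-isomer.
#'
#' Degenerate (collinear) chi paths yield NA angles rather than errors.
#'
#' @param monomer An `insulin_monomer`.
#' @param bridge_id `"A6A11"`, `"A7B7"` or `"A20B19"`.
#' @return Object of class `bridge_geometry`: `bridge_id`, `bridge_type`
#'   (`disulfide`/`dicarba`/`other`), `ca_ca`, `sg_sg` (disulfide only),
#'   `chi` (named: chi1, chi2, chi3, chi2p, chi1p for disulfides; chi1,
#'   core, chi1p for dicarba), `chi_rev` (walked from the second residue),
#'   `cis_trans` (`cis`/`trans`/`n/a`).
#' @export
extract_bridge_geometry <- function(monomer,
                                    bridge_id = c("A6A11", "A7B7", "A20B19")) {
  bridge_id <- match.arg(bridge_id)
  labs <- BRIDGE_RESIDUES[[bridge_id]]
  get <- function(lab, nm) atom_xyz(monomer, lab, nm)
  ca1 <- get(labs[1], "CA"); ca2 <- get(labs[2], "CA")
  if (is.null(ca1) || is.null(ca2))
    stop("bridge ", bridge_id, ": missing CA atom(s) at ",
         paste(labs[c(is.null(ca1), is.null(ca2))], collapse = ", "))
  ca_ca <- point_distance(ca1, ca2)

  sg1 <- get(labs[1], "SG"); sg2 <- get(labs[2], "SG")
  cb1 <- get(labs[1], "CB"); cb2 <- get(labs[2], "CB")
  n1 <- get(labs[1], "N"); n2 <- get(labs[2], "N")

  type <- "other"; sg_sg <- NA_real_; chi <- NULL; chi_rev <- NULL
  cis_trans <- "n/a"
  dihedral_or_na <- function(p1, p2, p3, p4) {
    if (is.null(p1) || is.null(p2) || is.null(p3) || is.null(p4))
      return(NA_real_)
    tryCatch(dihedral_angle(p1, p2, p3, p4), error = function(e) NA_real_)
  }
  if (!is.null(sg1) && !is.null(sg2) && point_distance(sg1, sg2) <= 2.5) {
    type <- "disulfide"
    sg_sg <- point_distance(sg1, sg2)
    chi <- c(chi1 = dihedral_or_na(n1, ca1, cb1, sg1),
             chi2 = dihedral_or_na(ca1, cb1, sg1, sg2),
             chi3 = dihedral_or_na(cb1, sg1, sg2, cb2),
             chi2p = dihedral_or_na(sg1, sg2, cb2, ca2),
             chi1p = dihedral_or_na(sg2, cb2, ca2, n2))
    chi_rev <- c(chi1 = dihedral_or_na(n2, ca2, cb2, sg2),
                 chi2 = dihedral_or_na(ca2, cb2, sg2, sg1),
                 chi3 = dihedral_or_na(cb2, sg2, sg1, cb1),
                 chi2p = dihedral_or_na(sg2, sg1, cb1, ca1),
                 chi1p = dihedral_or_na(sg1, cb1, ca1, n1))
  } else if (!is.null(cb1) && !is.null(cb2)) {
    g1 <- gamma_carbons(residue_atoms(monomer, labs[1]), cb1)
    g2 <- gamma_carbons(residue_atoms(monomer, labs[2]), cb2)
    if (!is.null(g1) && !is.null(g2) && nrow(g1) && nrow(g2)) {
      dmat <- outer(seq_len(nrow(g1)), seq_len(nrow(g2)),
                    Vectorize(function(i, j) point_distance(g1[i, ], g2[j, ])))
      if (min(dmat) < 1.75) {
        type <- "dicarba"
        hit <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
        cg1 <- as.numeric(g1[hit[1], ]); cg2 <- as.numeric(g2[hit[2], ])
        core <- dihedral_or_na(cb1, cg1, cg2, cb2)
        chi <- c(chi1 = dihedral_or_na(n1, ca1, cb1, cg1),
                 core = core,
                 chi1p = dihedral_or_na(cg2, cb2, ca2, n2))
        chi_rev <- c(chi1 = dihedral_or_na(n2, ca2, cb2, cg2),
                     core = dihedral_or_na(cb2, cg2, cg1, cb1),
                     chi1p = dihedral_or_na(cg1, cb1, ca1, n1))
        cis_trans <- if (is.na(core)) "n/a" else if (abs(core) < 90) "cis" else "trans"
      }
    }
  }
  structure(list(bridge_id = bridge_id, bridge_type = type,
                 ca_ca = ca_ca, sg_sg = sg_sg,
                 chi = chi, chi_rev = chi_rev, cis_trans = cis_trans),
            class = "bridge_geometry")
}

#' @export
print.bridge_geometry <- function(x, ...) {
  cat(sprintf("Bridge %s (%s): Ca-Ca %.2f A", x$bridge_id, x$bridge_type, x$ca_ca))
  if (!is.na(x$sg_sg)) cat(sprintf(", Sg-Sg %.2f A", x$sg_sg))
  if (x$cis_trans != "n/a") cat(", ", x$cis_trans)
  cat("\n")
  invisible(x)
}

chi_sign <- function(x) ifelse(x >= 0, "+", "-")   # 0 deg boundary -> "+"

#' Sign-bin conformer label of a disulfide bridge
#'
#' Deterministic label from the chi dihedrals: the signs of
#' (chi1, chi3, chi1') with the 0-degree boundary assigned to "+", plus a
#' 60-degree bin index of the core chi3 torsion. This sign-bin scheme is a
#' documented stand-in for finer disulfide-conformer taxonomies.
#'
#' @param geom A `bridge_geometry` with `bridge_type == "disulfide"`.
#' @return Object of class `conformer_label`: `signs` (3 of "+"/"-"),
#'   `core_bin` (0..5), `label` string like `"-,-,- [core bin 1]"`.
#' @export
disulfide_conformer_label <- function(geom) {
  if (!inherits(geom, "bridge_geometry") || geom$bridge_type != "disulfide")
    stop("conformer labels are defined for disulfide bridges only")
  chi <- geom$chi
  signs <- chi_sign(chi[c("chi1", "chi3", "chi1p")])
  core_bin <- min(floor((chi[["chi3"]] + 180) / 60), 5)
  structure(list(signs = unname(signs), core_bin = core_bin,
                 label = sprintf("%s [core bin %d]",
                                 paste(signs, collapse = ","), core_bin)),
            class = "conformer_label")
}

#' @export
print.conformer_label <- function(x, ...) {
  cat("Disulfide conformer ", x$label, "\n", sep = "")
  invisible(x)
}
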