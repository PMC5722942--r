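# Multi-model (MD-frame) ensemble statistics: per-frame RMSD against a
# Class 2 reference, Thr-A8 hydrogen-bond partner occupancies, class
# occupancy, bridge-distance and helicity summaries.

#' Assemble an ensemble from monomers
#'
#' @param frames List of `insulin_monomer` objects sharing residue labels.
#' @param segment_boundaries Optional frame indices starting new
#'   independent segments (e.g. separate simulation runs); frame 1 always
#'   starts the first segment.
#' @return Object of class `insulin_ensemble`.
#' @export
as_ensemble <- function(frames, segment_boundaries = NULL) {
  if (!length(frames)) stop("an ensemble needs at least one frame")
  sig <- function(m) paste(m$atoms$chain, m$atoms$pos, trimws(m$atoms$elety),
                           collapse = ";")
  ref_sig <- sig(frames[[1]])
  for (i in seq_along(frames)) {
    if (!inherits(frames[[i]], "insulin_monomer"))
      stop("frame ", i, " is not an insulin_monomer")
    if (sig(frames[[i]]) != ref_sig)
      stop("topology mismatch at frame ", i,
           ": atom set differs from frame 1")
  }
  structure(list(frames = frames, segment_boundaries = segment_boundaries),
            class = "insulin_ensemble")
}

#' @export
print.insulin_ensemble <- function(x, ...) {
  cat(sprintf("Insulin ensemble: %d frame(s)%s\n", length(x$frames),
              if (!is.null(x$segment_boundaries))
                sprintf(", %d segment(s)", length(x$segment_boundaries))
              else ""))
  invisible(x)
}

#' Load a multi-model coordinate file as an ensemble
#'
#' Each model must contain exactly one insulin monomer with a topology
#' consistent across models; an inconsistent or unidentifiable model is
#' rejected with its frame index.
#'
#' @param path Multi-model PDB/mmCIF file.
#' @param segment_boundaries Passed to [as_ensemble()].
#' @return An `insulin_ensemble`.
#' @export
load_ensemble <- function(path, segment_boundaries = NULL) {
  models <- parse_structure(path)
  frames <- list()
  for (i in seq_along(models$models)) {
    one <- list(models = models$models[i], resolution = models$resolution,
                pdb_id = models$pdb_id)
    mons <- withCallingHandlers(identify_insulin_monomers(one),
                                warning = function(w) invokeRestart("muffleWarning"))
    if (length(mons) != 1L)
      stop("frame ", i, ": expected 1 insulin monomer, found ", length(mons))
    mons[[1]]$model_no <- i
    frames[[i]] <- mons[[1]]
  }
  tryCatch(as_ensemble(frames, segment_boundaries),
           error = function(e) stop("ensemble load failed: ",
                                    conditionMessage(e)))
}

#' Per-frame RMSD against a reference conformation
#'
#' For each frame, the fit selection (default: C-alpha of the conserved
#' B9-B19 helix) is superposed on the reference, and the RMSD is measured
#' on the measure selection (default: all heavy atoms of residues A1-A4,
#' the observable separating Class 1 from Class 2 conformers).
#'
#' @param ensemble An `insulin_ensemble`.
#' @param reference An `insulin_monomer` (typically a representative
#'   Class 2 structure).
#' @param measure_residues Residue labels measured (default A1-A4).
#' @param fit_residues Residue labels fitted (default B9-B19).
#' @param fit_elety Atom type(s) for the fit (default `"CA"`).
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_vs_reference <- function(ensemble, reference,
                              measure_residues = paste0("A", 1:4),
                              fit_residues = paste0("B", 9:19),
                              fit_elety = "CA") {
  ref_fit <- monomer_coords(reference, fit_residues, fit_elety)
  ref_meas <- monomer_coords(reference, measure_residues)
  vapply(seq_along(ensemble$frames), function(i) {
    fr <- ensemble$frames[[i]]
    ffit <- monomer_coords(fr, fit_residues, fit_elety)
    fmeas <- monomer_coords(fr, measure_residues)
    cf <- intersect(rownames(ffit), rownames(ref_fit))
    cm <- intersect(rownames(fmeas), rownames(ref_meas))
    if (length(cf) < 3L || length(cm) < 1L)
      stop("frame ", i, ": unresolvable fit/measure selection")
    rmsd_after_superposition(fmeas[cm, , drop = FALSE],
                             ref_meas[cm, , drop = FALSE],
                             ffit[cf, , drop = FALSE],
                             ref_fit[cf, , drop = FALSE])
  }, numeric(1))
}

#' Hydrogen-bond partner occupancy of a backbone amide over an ensemble
#'
#' Fraction of frames in which the donor's best acceptor is each candidate
#' (default: the three partners seen for Thr-A8 — Val-A3, Glu-A4, Gln-A5 —
#' plus `none`). Fractions sum to 1.
#'
#' @param ensemble An `insulin_ensemble`.
#' @param donor Donor residue label (default `"A8"`).
#' @param acceptors Acceptor labels tracked individually.
#' @return Named numeric vector of fractions (`...,  other, none`).
#' @export
partner_occupancy <- function(ensemble, donor = "A8",
                              acceptors = c("A3", "A4", "A5")) {
  hits <- vapply(ensemble$frames, function(fr) {
    ba <- backbone_hbond_map(fr)$best_acceptor
    acc <- if (donor %in% names(ba)) ba[[donor]] else NULL
    if (is.null(acc) || is.na(acc)) "none"
    else if (acc %in% acceptors) acc else "other"
  }, character(1))
  lv <- c(acceptors, "other", "none")
  out <- as.numeric(table(factor(hits, levels = lv))) / length(hits)
  names(out) <- lv
  out
}

frame_stats <- function(rmsd, ca, cls_frac_threshold) {
  in2 <- rmsd < cls_frac_threshold
  list(rmsd_mean = mean(rmsd), rmsd_sd = stats::sd(rmsd),
       class2_fraction = mean(in2),
       ca_ca_mean_by_class = c(
         class2 = if (any(in2)) mean(ca[in2]) else NA_real_,
         other = if (any(!in2)) mean(ca[!in2]) else NA_real_))
}

#' Summarise an ensemble
#'
#' Computes the per-frame RMSD series against the reference, its mean and
#' SD, the fraction of frames within `class_threshold` of the Class 2
#' reference, Thr-A8 partner occupancies, the A6-A11 C-alpha distance per
#' frame (with means split by the RMSD-threshold class assignment), and
#' per-residue helicity (fraction of frames assigned H/G/I). With
#' `segment_boundaries`, per-segment RMSD summaries are added.
#'
#' @param ensemble An `insulin_ensemble`.
#' @param reference Reference `insulin_monomer` (default: the noiseless
#'   CLASS2 toy from [build_class_toy()]).
#' @param class_threshold RMSD below which a frame counts as Class 2
#'   (Angstrom, default 1.5).
#' @return Object of class `ensemble_stats`.
#' @export
summarize_ensemble <- function(ensemble, reference = NULL,
                               class_threshold = 1.5) {
  if (is.null(reference)) reference <- build_class_toy("CLASS2")
  rmsd <- rmsd_vs_reference(ensemble, reference)
  occ <- partner_occupancy(ensemble)
  ca <- vapply(ensemble$frames, function(fr)
    extract_bridge_geometry(fr, "A6A11")$ca_ca, numeric(1))
  labs <- residue_labels_in_order(ensemble$frames[[1]])
  hel <- rowMeans(vapply(ensemble$frames, function(fr) {
    ss <- assign_helix_types(fr)
    as.numeric(ss[labs] %in% c("H", "G", "I"))
  }, numeric(length(labs))))
  names(hel) <- labs
  st <- frame_stats(rmsd, ca, class_threshold)
  segs <- NULL
  sb <- ensemble$segment_boundaries
  if (!is.null(sb)) {
    starts <- sort(unique(c(1L, sb)))
    ends <- c(starts[-1] - 1L, length(rmsd))
    segs <- lapply(seq_along(starts), function(k) {
      idx <- starts[k]:ends[k]
      c(list(frames = length(idx)),
        frame_stats(rmsd[idx], ca[idx], class_threshold))
    })
  }
  structure(c(list(rmsd_series = rmsd, partner_occupancy = occ,
                   ca_ca_series = ca, helicity = hel,
                   class_threshold = class_threshold,
                   n_frames = length(rmsd), segments = segs), st),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  cat(sprintf("Ensemble of %d frames: RMSD %.2f +/- %.2f A vs Class 2 reference\n",
              x$n_frames, x$rmsd_mean, x$rmsd_sd))
  cat(sprintf("  Class 2 occupancy (RMSD < %.1f A): %.3f\n",
              x$class_threshold, x$class2_fraction))
  cat("  Thr-A8 partner occupancy: ",
      paste(sprintf("%s %.3f", names(x$partner_occupancy),
                    x$partner_occupancy), collapse = ", "), "\n", sep = "")
  invisible(x)
}
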