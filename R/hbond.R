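# Backbone hydrogen bonds (Kabsch-Sander energies), DSSP-style helix
# assignment, and the two monomer classifiers (T/R state; Class 1 vs 2).

KS_COUPLING <- 0.084 * 332    # kcal/mol * Angstrom, Kabsch-Sander constant
HBOND_CUTOFF <- -0.5          # kcal/mol

#' Place (or retrieve) the backbone amide hydrogen of a residue
#'
#' X-ray structures usually lack hydrogens; the amide H is reconstructed at
#' 1.01 Angstrom from N, in the C(prev)-N-CA plane, opposing the bisector
#' of the C(prev)-N and CA-N directions (the trigonal sp2 position). An
#' experimentally present H atom is reused in preference. Prolines and
#' chain-start residues have no amide hydrogen and are never donors.
#'
#' @param monomer An `insulin_monomer`.
#' @param label Residue label, e.g. `"A8"`.
#' @return Numeric 3-vector, or NULL when the residue cannot donate.
#' @export
place_amide_hydrogen <- function(monomer, label) {
  at <- residue_atoms(monomer, label)
  if (!nrow(at) || toupper(at$resid[1]) == "PRO") return(NULL)
  h <- at[trimws(at$elety) %in% c("H", "HN"), , drop = FALSE]
  if (nrow(h)) return(as.numeric(h[1, c("x", "y", "z")]))
  rl <- parse_reslabel(label)
  prev <- paste0(rl$chain, rl$pos - 1L)
  n <- atom_xyz(monomer, label, "N")
  ca <- atom_xyz(monomer, label, "CA")
  cp <- atom_xyz(monomer, prev, "C")
  if (is.null(n) || is.null(ca) || is.null(cp)) return(NULL)
  n + 1.01 * unit(-(unit(cp - n) + unit(ca - n)))
}

#' Kabsch-Sander hydrogen-bond energy
#'
#' `E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)` kcal/mol, the
#' electrostatic dipole model used by DSSP; a bond is recorded when
#' `E < -0.5` kcal/mol.
#'
#' @param n,h Donor backbone N and amide H coordinates (3-vectors).
#' @param c,o Acceptor backbone C and carbonyl O coordinates.
#' @return Energy in kcal/mol.
#' @export
hbond_energy <- function(n, h, c, o) {
  r_on <- point_distance(o, n); r_ch <- point_distance(c, h)
  r_oh <- point_distance(o, h); r_cn <- point_distance(c, n)
  if (min(r_on, r_ch, r_oh, r_cn) < 0.5)
    stop("atomic clash: inter-atom distance below 0.5 Angstrom")
  KS_COUPLING * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
}

residue_labels_in_order <- function(monomer) {
  at <- monomer$atoms
  lab <- paste0(at$chain, at$pos)
  lab[!duplicated(lab)]
}

#' Backbone hydrogen-bond map of a monomer
#'
#' Evaluates the Kabsch-Sander energy for every backbone donor-acceptor
#' pair (both chains; inter-chain pairs allowed; same-chain sequence
#' separation >= 2) and records bonds below the energy cutoff. The best
#' acceptor of each donor is the minimum-energy bond; ties break to the
#' smaller sequence separation, then the lower residue number.
#'
#' @param monomer An `insulin_monomer`.
#' @param energy_cutoff Bond threshold in kcal/mol (default -0.5).
#' @return Object of class `hbond_map`: `bonds` data frame (`donor`,
#'   `acceptor`, `energy`, `n_o_distance`) and `best_acceptor` (named
#'   character vector donor -> acceptor).
#' @export
backbone_hbond_map <- function(monomer, energy_cutoff = HBOND_CUTOFF) {
  labs <- residue_labels_in_order(monomer)
  rl <- parse_reslabel(labs)
  at <- monomer$atoms
  key <- paste0(at$chain, at$pos, ":", trimws(at$elety))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  fetch <- function(res_labs, nm) {
    m <- xyz[match(paste0(res_labs, ":", nm), key), , drop = FALSE]
    rownames(m) <- res_labs
    m
  }
  n_m <- fetch(labs, "N"); ca_m <- fetch(labs, "CA")
  c_m <- fetch(labs, "C"); o_m <- fetch(labs, "O")
  prev_labs <- paste0(rl$chain, rl$pos - 1L)
  cp_m <- fetch(prev_labs, "C")
  # amide H: reuse experimental H, else trigonal reconstruction
  h_m <- fetch(labs, "H")
  hn <- fetch(labs, "HN")
  h_m[is.na(h_m[, 1]), ] <- hn[is.na(h_m[, 1]), ]
  rownames(h_m) <- labs
  rebuild <- which(is.na(h_m[, 1]) & !is.na(n_m[, 1]) & !is.na(ca_m[, 1]) &
                   !is.na(cp_m[, 1]))
  if (length(rebuild)) {
    u1 <- cp_m[rebuild, , drop = FALSE] - n_m[rebuild, , drop = FALSE]
    u2 <- ca_m[rebuild, , drop = FALSE] - n_m[rebuild, , drop = FALSE]
    u1 <- u1 / sqrt(rowSums(u1^2)); u2 <- u2 / sqrt(rowSums(u2^2))
    hd <- -(u1 + u2)
    hd <- hd / sqrt(rowSums(hd^2))
    h_m[rebuild, ] <- n_m[rebuild, , drop = FALSE] + 1.01 * hd
  }
  is_pro <- toupper(at$resid[match(paste0(labs, ":CA"), key)]) == "PRO"
  is_pro[is.na(is_pro)] <- FALSE
  d_ok <- !is.na(n_m[, 1]) & !is.na(h_m[, 1]) & !is_pro
  a_ok <- !is.na(c_m[, 1]) & !is.na(o_m[, 1])
  donors <- lapply(which(d_ok), function(i) list(n = n_m[i, ], h = h_m[i, ]))
  names(donors) <- labs[d_ok]
  acceptors <- lapply(which(a_ok), function(i) list(c = c_m[i, ], o = o_m[i, ]))
  names(acceptors) <- labs[a_ok]
  empty <- data.frame(donor = character(0), acceptor = character(0),
                      energy = numeric(0), n_o_distance = numeric(0),
                      separation = integer(0), acceptor_pos = integer(0))
  if (!length(donors) || !length(acceptors)) {
    return(structure(list(bonds = empty[, 1:4], best_acceptor = character(0)),
                     class = "hbond_map"))
  }
  nm <- do.call(rbind, lapply(donors, `[[`, "n"))
  hm <- do.call(rbind, lapply(donors, `[[`, "h"))
  cm <- do.call(rbind, lapply(acceptors, `[[`, "c"))
  om <- do.call(rbind, lapply(acceptors, `[[`, "o"))
  pdist <- function(a, b)
    sqrt(pmax(outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b), 0))
  r_on <- pdist(om, nm); r_ch <- pdist(cm, hm)
  r_oh <- pdist(om, hm); r_cn <- pdist(cm, nm)
  dl <- parse_reslabel(names(donors)); al <- parse_reslabel(names(acceptors))
  same_chain <- outer(al$chain, dl$chain, `==`)
  sep <- abs(outer(al$pos, dl$pos, `-`))
  valid <- !(same_chain & sep < 2L)
  if (any(pmin(r_on, r_ch, r_oh, r_cn)[valid] < 0.5))
    stop("atomic clash: inter-atom distance below 0.5 Angstrom")
  e_mat <- KS_COUPLING * (1 / r_on + 1 / r_ch - 1 / r_oh - 1 / r_cn)
  hit <- which(valid & e_mat < energy_cutoff, arr.ind = TRUE)
  bonds <- if (nrow(hit)) data.frame(
    donor = names(donors)[hit[, 2]], acceptor = names(acceptors)[hit[, 1]],
    energy = e_mat[hit], n_o_distance = r_on[hit],
    separation = ifelse(same_chain[hit], sep[hit], NA_integer_),
    acceptor_pos = al$pos[hit[, 1]], stringsAsFactors = FALSE)
  else empty
  best <- character(0)
  for (dn in unique(bonds$donor)) {
    sub <- bonds[bonds$donor == dn, ]
    sep <- ifelse(is.na(sub$separation), .Machine$integer.max, sub$separation)
    sub <- sub[order(sub$energy, sep, sub$acceptor_pos), ]
    best[dn] <- sub$acceptor[1]
  }
  structure(list(bonds = bonds[, c("donor", "acceptor", "energy", "n_o_distance")],
                 best_acceptor = best),
            class = "hbond_map")
}

#' @export
print.hbond_map <- function(x, ...) {
  cat(sprintf("Backbone H-bond map: %d bonds, %d donors\n",
              nrow(x$bonds), length(x$best_acceptor)))
  invisible(x)
}

# n-turns per chain: acceptor i bonded to donor i+n
turn_set <- function(hb, chain, n_res, n) {
  has <- rep(FALSE, n_res)
  if (!nrow(hb$bonds)) return(has)
  d <- parse_reslabel(hb$bonds$donor); a <- parse_reslabel(hb$bonds$acceptor)
  sel <- d$chain == chain & a$chain == chain & (d$pos - a$pos) == n
  has[a$pos[sel][a$pos[sel] >= 1 & a$pos[sel] <= n_res]] <- TRUE
  has
}

#' DSSP-style helix-type assignment
#'
#' Priority follows DSSP: two consecutive 4-turns make an alpha helix (H),
#' then two consecutive 3-turns a 3-10 helix (G), then two consecutive
#' 5-turns a pi helix (I); residues in isolated turns are T, the rest C.
#'
#' @param monomer An `insulin_monomer`.
#' @param hbmap Optional precomputed [backbone_hbond_map()].
#' @return Named character vector residue label -> one of H, G, I, T, C.
#' @export
assign_helix_types <- function(monomer, hbmap = NULL) {
  if (is.null(hbmap)) hbmap <- backbone_hbond_map(monomer)
  out <- character(0)
  for (ch in c("A", "B")) {
    pos <- sort(unique(monomer$atoms$pos[monomer$atoms$chain == ch]))
    if (!length(pos)) next
    n_res <- max(pos)
    turns <- lapply(c(3, 4, 5), function(n) turn_set(hbmap, ch, n_res, n))
    names(turns) <- c("3", "4", "5")
    ss <- rep("C", n_res)
    mark <- function(n, code) {
      tt <- turns[[as.character(n)]]
      for (i in seq_len(n_res - 1)) {
        if (i >= 2 && tt[i - 1] && tt[i]) {
          span <- i:min(i + n - 1, n_res)
          free <- ss[span] %in% c("C", "T")
          if (code == "H" || all(ss[span] %in% c("C", "T", code)))
            ss[span[free]] <<- code
        }
      }
    }
    mark(4, "H"); mark(3, "G"); mark(5, "I")
    for (n in c(3, 4, 5)) {
      tt <- turns[[as.character(n)]]
      for (i in which(tt)) {
        span <- (i + 1):min(i + n - 1, n_res)
        ss[span][ss[span] == "C"] <- "T"
      }
    }
    names(ss) <- paste0(ch, seq_len(n_res))
    out <- c(out, ss[paste0(ch, pos)])
  }
  out
}

#' Classify the T/R state of an insulin monomer
#'
#' The R (and Rf) states extend the B9-B19 helix N-terminally; a monomer is
#' called R when at least `min_helical` residues among B1-B7 are assigned
#' alpha- or 3-10-helical (H or G), otherwise T. The threshold is a
#' documented convention, exposed as a parameter.
#'
#' @param monomer An `insulin_monomer`.
#' @param hbmap Optional precomputed [backbone_hbond_map()].
#' @param min_helical R-state threshold (default 3).
#' @return Object of class `state_label`: `label` ("T"/"R", or
#'   "UNDETERMINED" when the B1-B7 backbone is incomplete) and
#'   `helical_b1_b7_count`.
#' @export
classify_tr_state <- function(monomer, hbmap = NULL, min_helical = 3L) {
  b_labs <- paste0("B", 1:7)
  complete <- vapply(b_labs, function(l) backbone_complete(monomer, l), logical(1))
  if (!all(complete))
    return(structure(list(label = "UNDETERMINED",
                          helical_b1_b7_count = NA_integer_,
                          min_helical = min_helical), class = "state_label"))
  ss <- assign_helix_types(monomer, hbmap)
  cnt <- sum(ss[b_labs] %in% c("H", "G"), na.rm = TRUE)
  structure(list(label = if (cnt >= min_helical) "R" else "T",
                 helical_b1_b7_count = cnt, min_helical = min_helical),
            class = "state_label")
}

#' @export
print.state_label <- function(x, ...) {
  cat(sprintf("State %s (%s helical residues in B1-B7, threshold %d)\n",
              x$label, ifelse(is.na(x$helical_b1_b7_count), "?",
                              x$helical_b1_b7_count), x$min_helical))
  invisible(x)
}

#' Classify the A-chain N-terminal helix conformation (Class 1 vs Class 2)
#'
#' The defining observable is the best hydrogen-bond acceptor of the
#' Thr-A8 backbone amide: Glu-A4 (i,i+4; alpha-helical) gives CLASS1,
#' Val-A3 (i,i+5; pi-like) gives CLASS2, Gln-A5 (i,i+3) gives THREE_TEN,
#' anything else (or no bond) is UNCLASSIFIED.
#'
#' @param monomer An `insulin_monomer`.
#' @param hbmap Optional precomputed [backbone_hbond_map()].
#' @return Object of class `conformational_class`: `label` and `evidence`
#'   (the A8 best acceptor, or NA).
#' @export
classify_a1_helix <- function(monomer, hbmap = NULL) {
  if (is.null(hbmap)) hbmap <- backbone_hbond_map(monomer)
  acc <- if ("A8" %in% names(hbmap$best_acceptor))
    hbmap$best_acceptor[["A8"]] else NULL
  if (is.null(acc) || is.na(acc)) {
    reason <- if (is.null(place_amide_hydrogen(monomer, "A8")))
      "A8 amide donor unusable" else "no hydrogen bond from A8"
    return(structure(list(label = "UNCLASSIFIED", evidence = NA_character_,
                          reason = reason), class = "conformational_class"))
  }
  label <- switch(acc, A4 = "CLASS1", A3 = "CLASS2", A5 = "THREE_TEN",
                  "UNCLASSIFIED")
  structure(list(label = label, evidence = acc, reason = NULL),
            class = "conformational_class")
}

#' @export
print.conformational_class <- function(x, ...) {
  cat(sprintf("A1-helix conformation %s (Thr-A8 amide -> %s)\n", x$label,
              ifelse(is.na(x$evidence), "none", x$evidence)))
  invisible(x)
}
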