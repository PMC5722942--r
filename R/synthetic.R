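# Synthetic insulin-like structures: ideal helices from backbone torsions
# (NeRF construction), two-chain class toys with placed bridges, Gaussian
# coordinate noise, and multi-model ensembles with known class mixtures.

# canonical backbone internal coordinates (Angstrom / degrees)
BB_GEOM <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                ang_n_ca_c = 111.2, ang_ca_c_n = 116.2, ang_c_n_ca = 121.7,
                b_c_o = 1.231, ang_ca_c_o = 120.8,
                b_ca_cb = 1.53, ang_n_ca_cb = 110.5, tor_c_n_ca_cb = -120,
                b_cb_sg = 1.808, ang_ca_cb_sg = 114.2,
                b_cb_cg = 1.50, ang_ca_cb_cg = 111.5)

AA1TO3 <- structure(names(AA3TO1), names = unname(AA3TO1))

# Natural-extension reference frame: place D given A, B, C and the
# internal coordinates bond |C-D|, angle B-C-D, torsion A-B-C-D.
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  d2 <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  c + as.numeric(m %*% d2)
}

#' Build a peptide backbone from torsions (NeRF construction)
#'
#' Places N, CA, C, O and (except glycine) CB atoms with canonical bond
#' lengths and angles; only the torsions vary. Amide hydrogens (known
#' exactly by the construction) are emitted for non-proline residues
#' after the first. Recomputing (phi, psi, omega) from the output
#' reproduces the inputs to numerical precision.
#'
#' @param sequence One-letter string (e.g. `"GIVEQ"`) or character vector
#'   of 3-letter codes.
#' @param phi,psi Backbone torsions in degrees, one per residue (`phi[1]`
#'   is undefined and ignored; `psi[n]` orients the final carbonyl).
#' @param omega Peptide-bond torsions (default all 180; `omega[1]` ignored).
#' @param chain Canonical chain label for the output table.
#' @return Atom data frame suitable for [insulin_monomer()].
#' @export
build_backbone <- function(sequence, phi, psi, omega = NULL, chain = "A") {
  res3 <- if (length(sequence) == 1L && !sequence[1] %in% names(AA3TO1)) {
    v <- strsplit(sequence, "")[[1]]
    unname(AA1TO3[v])
  } else toupper(sequence)
  if (anyNA(res3)) stop("unknown residue code in sequence")
  n_res <- length(res3)
  if (n_res < 2L) stop("sequence length must be >= 2")
  stopifnot(length(phi) == n_res, length(psi) == n_res)
  if (is.null(omega)) omega <- rep(180, n_res)
  g <- BB_GEOM
  N <- CA <- C <- matrix(NA_real_, n_res, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$ang_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in 2:n_res) {
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         g$b_c_n, g$ang_ca_c_n, psi[i - 1])
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$b_n_ca, g$ang_c_n_ca, omega[i])
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                         g$b_ca_c, g$ang_n_ca_c, phi[i])
  }
  pos_v <- integer(0); ety_v <- character(0); esy_v <- character(0)
  xyz_v <- matrix(numeric(0), 0, 3)
  for (i in seq_len(n_res)) {
    o_xyz <- nerf_place(N[i, ], CA[i, ], C[i, ],
                        g$b_c_o, g$ang_ca_c_o, psi[i] - 180)
    xyz_i <- rbind(N[i, ], CA[i, ], C[i, ], o_xyz)
    ety_i <- c("N", "CA", "C", "O"); esy_i <- c("N", "C", "C", "O")
    if (i > 1L && res3[i] != "PRO") {
      u1 <- unit(C[i - 1, ] - N[i, ]); u2 <- unit(CA[i, ] - N[i, ])
      h_xyz <- N[i, ] + 1.01 * unit(-(u1 + u2))
      xyz_i <- rbind(xyz_i, h_xyz)
      ety_i <- c(ety_i, "H"); esy_i <- c(esy_i, "H")
    }
    if (res3[i] != "GLY") {
      cb <- nerf_place(C[i, ], N[i, ], CA[i, ],
                       g$b_ca_cb, g$ang_n_ca_cb, g$tor_c_n_ca_cb)
      xyz_i <- rbind(xyz_i, cb)
      ety_i <- c(ety_i, "CB"); esy_i <- c(esy_i, "C")
    }
    pos_v <- c(pos_v, rep(i, length(ety_i)))
    ety_v <- c(ety_v, ety_i); esy_v <- c(esy_v, esy_i)
    xyz_v <- rbind(xyz_v, xyz_i)
  }
  data.frame(chain = chain, pos = pos_v, resid = res3[pos_v], elety = ety_v,
             x = xyz_v[, 1], y = xyz_v[, 2], z = xyz_v[, 3],
             o = 1, b = 0, elesy = esy_v, stringsAsFactors = FALSE)
}

#' Recompute backbone torsions from an atom table
#'
#' Inverse of [build_backbone()]; used for round-trip checks.
#'
#' @param atoms Atom data frame with N/CA/C per residue (one chain).
#' @return Data frame with `pos`, `phi`, `psi`, `omega` (NA where undefined).
#' @export
backbone_torsions <- function(atoms) {
  pos <- sort(unique(atoms$pos))
  get <- function(p, nm) {
    r <- atoms[atoms$pos == p & trimws(atoms$elety) == nm, ]
    if (!nrow(r)) NULL else as.numeric(r[1, c("x", "y", "z")])
  }
  out <- data.frame(pos = pos, phi = NA_real_, psi = NA_real_, omega = NA_real_)
  for (k in seq_along(pos)) {
    p <- pos[k]
    n0 <- get(p, "N"); ca0 <- get(p, "CA"); c0 <- get(p, "C")
    cm <- get(p - 1L, "C"); cam <- get(p - 1L, "CA"); np <- get(p + 1L, "N")
    if (!is.null(cm) && !is.null(n0) && !is.null(ca0) && !is.null(c0))
      out$phi[k] <- dihedral_angle(cm, n0, ca0, c0)
    if (!is.null(n0) && !is.null(ca0) && !is.null(c0) && !is.null(np))
      out$psi[k] <- dihedral_angle(n0, ca0, c0, np)
    if (!is.null(cam) && !is.null(cm) && !is.null(n0) && !is.null(ca0))
      out$omega[k] <- dihedral_angle(cam, cm, n0, ca0)
  }
  out
}

# side-chain bridge atom (SG for cysteine-like, CG for dicarba halves)
place_bridge_atom <- function(atoms, pos, chi1, kind = c("SG", "CG")) {
  kind <- match.arg(kind)
  g <- BB_GEOM
  get <- function(nm) {
    r <- atoms[atoms$pos == pos & trimws(atoms$elety) == nm, ]
    as.numeric(r[1, c("x", "y", "z")])
  }
  xyz <- nerf_place(get("N"), get("CA"), get("CB"),
                    if (kind == "SG") g$b_cb_sg else g$b_cb_cg,
                    if (kind == "SG") g$ang_ca_cb_sg else g$ang_ca_cb_cg,
                    chi1)
  rbind(atoms, data.frame(chain = atoms$chain[1], pos = pos,
                          resid = atoms$resid[atoms$pos == pos][1],
                          elety = kind, x = xyz[1], y = xyz[2], z = xyz[3],
                          o = 1, b = 0,
                          elesy = if (kind == "SG") "S" else "C",
                          stringsAsFactors = FALSE))
}

rotvec_to_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  k <- v / th
  kk <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + sin(th) * kk + (1 - cos(th)) * (kk %*% kk)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Gaussian coordinate noise
#'
#' Adds i.i.d. Gaussian displacement (per coordinate, standard deviation
#' `sigma`) to every atom. `sigma = 0` is the identity; output is
#' deterministic given `seed`.
#'
#' @param coords N x 3 matrix, atom data frame, or `insulin_monomer`.
#' @param sigma Standard deviation in Angstrom (>= 0).
#' @param seed Integer seed.
#' @return Same type as the input, perturbed.
#' @export
perturb <- function(coords, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(coords)
  if (inherits(coords, "insulin_monomer")) {
    coords$atoms <- perturb(coords$atoms, sigma, seed)
    return(coords)
  }
  if (is.data.frame(coords)) {
    m <- as.matrix(coords[, c("x", "y", "z")])
    m <- perturb(m, sigma, seed)
    coords[, c("x", "y", "z")] <- m
    return(coords)
  }
  with_seed(seed, coords + matrix(stats::rnorm(length(coords), 0, sigma),
                                  nrow(coords), 3))
}

# ---- class-toy construction -----------------------------------------------

# Torsion programme of the A chain for each conformational class.
# Class 1: A1-A9 near-ideal alpha (psi8/phi9 may relax slightly: an exact
# ideal helix caps the reachable A6-A11 Ca-Ca span above the Class 1
# construction target, as in real structures whose helices are not ideal).
# Class 2: one alpha turn (A1-A3) then pi-widened torsions for A4-A9 so
# the Thr-A8 amide reaches the Val-A3 carbonyl. A12-A18 is the second A
# helix; the A8-A12 linker torsions and the bridge chi angles are frozen
# closure solutions (see toy_params.R).
a_chain_torsions <- function(class_label, link) {
  phi <- rep(-120, 21); psi <- rep(135, 21)
  if (class_label == "CLASS1") {
    phi[1:9] <- -57; psi[1:9] <- -47
  } else {
    phi[1:3] <- -57; psi[1:3] <- -47
    phi[4:9] <- -57; psi[4:9] <- -70
  }
  phi[13:18] <- -57; psi[12:18] <- -47
  lk <- function(nm, default) if (nm %in% names(link)) link[[nm]] else default
  psi[8] <- lk("psi8", psi[8]); phi[9] <- lk("phi9", phi[9])
  phi[10] <- link[["phi10"]]; psi[9] <- link[["psi9"]]
  psi[10] <- link[["psi10"]]; phi[11] <- link[["phi11"]]
  psi[11] <- link[["psi11"]]; phi[12] <- link[["phi12"]]
  list(phi = phi, psi = psi)
}

b_chain_torsions <- function(state = c("T", "R"), link = NULL) {
  state <- match.arg(state)
  phi <- rep(-120, 30); psi <- rep(135, 30)
  if (state == "T") {
    phi[9:19] <- -57; psi[9:19] <- -47
  } else {
    phi[2:19] <- -57; psi[1:19] <- -47
  }
  if (!is.null(link)) {
    phi[8] <- link[["phiB8"]]; psi[8] <- link[["psiB8"]]
    phi[20] <- link[["phiB20"]]; psi[20] <- link[["psiB20"]]
  }
  list(phi = phi, psi = psi)
}

build_class_toy_raw <- function(class_label, bridge_variant, params,
                                state = "T") {
  tor <- a_chain_torsions(class_label, params$link)
  a <- build_backbone(A_CHAIN_SEQ, tor$phi, tor$psi, chain = "A")
  dicarba <- bridge_variant %in% c("cis_dicarba", "trans_dicarba")
  kind <- if (dicarba) "CG" else "SG"
  if (dicarba) a$resid[a$pos %in% c(6L, 11L)] <- "ALG"  # dicarba half-residue
  a <- place_bridge_atom(a, 6L, params$chi[["chiA6"]], kind)
  a <- place_bridge_atom(a, 11L, params$chi[["chiA11"]], kind)
  a <- place_bridge_atom(a, 7L, params$chi[["chiA7"]], "SG")
  a <- place_bridge_atom(a, 20L, params$chi[["chiA20"]], "SG")

  torb <- b_chain_torsions(state, params$blink)
  b <- build_backbone(B_CHAIN_SEQ, torb$phi, torb$psi, chain = "B")
  b <- place_bridge_atom(b, 7L, params$chi[["chiB7"]], "SG")
  b <- place_bridge_atom(b, 19L, params$chi[["chiB19"]], "SG")
  rot <- rotvec_to_matrix(params$rigid[1:3])
  xyz <- as.matrix(b[, c("x", "y", "z")]) %*% rot
  xyz <- sweep(xyz, 2, params$rigid[4:6], `+`)
  b[, c("x", "y", "z")] <- xyz

  insulin_monomer(rbind(a, b),
                  pdb_id = paste0("SYN", substr(class_label, 6, 6)),
                  model_no = 1L, resolution = 1.5)
}

toy_cache <- new.env(parent = emptyenv())

#' Build a synthetic insulin monomer of a requested conformational class
#'
#' The noiseless construction is deterministic: an ideal-torsion A chain
#' (alpha-helical A1-A9 for CLASS1; one alpha turn then pi-widened A4-A9
#' torsions for CLASS2), a T-state B chain (extended B1-B8, alpha B9-B19),
#' and bridges closed by frozen torsion solutions per bridge variant.
#' `classify_a1_helix()` on the noiseless output returns the requested
#' class, and the A6-A11 C-alpha distance is shorter for CLASS2 than
#' CLASS1 (the direction separating active from inactive conformers).
#'
#' @param class_label `"CLASS1"` or `"CLASS2"`.
#' @param bridge_variant `"disulfide"`, `"cis_dicarba"` or `"trans_dicarba"`.
#' @param noise_sigma Gaussian coordinate noise (Angstrom, default 0).
#' @param seed Seed for the noise.
#' @param state B-chain state, `"T"` (default) or `"R"` (continuous
#'   B1-B19 helix; bridges are not re-closed for R toys).
#' @return An `insulin_monomer`.
#' @export
build_class_toy <- function(class_label = c("CLASS1", "CLASS2"),
                            bridge_variant = c("disulfide", "cis_dicarba",
                                               "trans_dicarba"),
                            noise_sigma = 0, seed = 1L,
                            state = c("T", "R")) {
  class_label <- match.arg(class_label)
  bridge_variant <- match.arg(bridge_variant)
  state <- match.arg(state)
  key <- paste(class_label, bridge_variant, state, sep = "|")
  if (is.null(toy_cache[[key]])) {
    params <- TOY_PARAMS[[class_label]][[bridge_variant]]
    if (is.null(params))
      stop("infeasible bridge closure: no construction for ", class_label,
           " with a ", bridge_variant, " bridge")
    toy_cache[[key]] <- build_class_toy_raw(class_label, bridge_variant,
                                            params, state)
  }
  mon <- toy_cache[[key]]
  if (noise_sigma > 0) {
    mon <- perturb(mon, noise_sigma, seed)
    # emulate restrained refinement: deposited structures keep bridge bond
    # lengths at their restraint targets while positions carry noise
    mon <- restrain_bridge_bonds(mon, dicarba = bridge_variant != "disulfide")
  }
  mon
}

# rescale each bridge bond about its midpoint to the ideal length
restrain_bridge_bonds <- function(mon, dicarba = FALSE) {
  fix_pair <- function(mon, lab1, lab2, elety, target) {
    at <- mon$atoms
    lab <- paste0(at$chain, at$pos)
    i1 <- which(lab == lab1 & trimws(at$elety) == elety)[1]
    i2 <- which(lab == lab2 & trimws(at$elety) == elety)[1]
    if (is.na(i1) || is.na(i2)) return(mon)
    p1 <- as.numeric(at[i1, c("x", "y", "z")])
    p2 <- as.numeric(at[i2, c("x", "y", "z")])
    d <- sqrt(sum((p2 - p1)^2))
    if (d < 1e-6) return(mon)
    mid <- (p1 + p2) / 2; u <- (p2 - p1) / d
    mon$atoms[i1, c("x", "y", "z")] <- mid - u * target / 2
    mon$atoms[i2, c("x", "y", "z")] <- mid + u * target / 2
    mon
  }
  if (dicarba) mon <- fix_pair(mon, "A6", "A11", "CG", 1.33)
  else mon <- fix_pair(mon, "A6", "A11", "SG", 2.04)
  mon <- fix_pair(mon, "A7", "B7", "SG", 2.04)
  fix_pair(mon, "A20", "B19", "SG", 2.04)
}

#' Build a synthetic multi-model ensemble with a known class mixture
#'
#' Frames are drawn i.i.d. from the class mixture, each perturbed by
#' Gaussian coordinate noise; the true labels are returned (and written to
#' a sidecar JSON next to `path`) so estimators can be validated against
#' known truth.
#'
#' @param mixture Named fractions, e.g. `c(CLASS1 = 0.7, CLASS2 = 0.3)`;
#'   must sum to 1.
#' @param n_frames Number of frames (>= 1).
#' @param noise_sigma Per-frame coordinate noise (Angstrom).
#' @param seed Integer seed (drives both labels and noise).
#' @param bridge_variant Bridge variant for every frame.
#' @param path Optional output path; writes a multi-model PDB plus
#'   `<path>.labels.json`.
#' @return List with `frames` (list of `insulin_monomer`), `labels`
#'   (character vector), and `spec` (the generating parameters).
#' @export
build_ensemble <- function(mixture = c(CLASS1 = 0.7, CLASS2 = 0.3),
                           n_frames = 100L, noise_sigma = 0.1, seed = 1L,
                           bridge_variant = "disulfide", path = NULL) {
  stopifnot(n_frames >= 1L, abs(sum(mixture) - 1) < 1e-9)
  labels <- with_seed(seed, sample(names(mixture), n_frames, replace = TRUE,
                                   prob = mixture))
  base <- lapply(unique(labels), function(cl)
    build_class_toy(cl, bridge_variant))
  names(base) <- unique(labels)
  frames <- lapply(seq_len(n_frames), function(i) {
    mon <- perturb(base[[labels[i]]], noise_sigma,
                   seed = (abs(seed) %% 20000L) * 100000L + i)
    mon$model_no <- i
    mon
  })
  spec <- list(mixture = as.list(mixture), n_frames = n_frames,
               noise_sigma = noise_sigma, seed = seed,
               bridge_variant = bridge_variant)
  if (!is.null(path)) {
    write_monomers_pdb(frames, path, multi_model = TRUE)
    jsonlite::write_json(list(spec = spec, labels = labels),
                         paste0(path, ".labels.json"), auto_unbox = TRUE)
  }
  list(frames = frames, labels = labels, spec = spec)
}
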