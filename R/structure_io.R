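# Reading coordinate files, identifying insulin monomers, curation filters.

#' Parse a PDB or mmCIF coordinate file
#'
#' Returns all models as lists of per-chain atom tables. Alternate
#' locations are resolved to the highest-occupancy conformer (ties to
#' altloc "A"); HETATM records are retained so that modified residues
#' (e.g. dicarba half-residues) survive. Resolution is read from
#' `REMARK   2` (PDB) or `_refine.ls_d_res_high` (mmCIF).
#'
#' @param path Path to the coordinate file.
#' @param dialect `"pdb"`, `"mmcif"` or `"auto"` (by extension/content).
#' @return Object of class `structure_models`: list with `models` (each a
#'   named list of chain atom data frames), `resolution`, `pdb_id`,
#'   `dialect`.
#' @export
parse_structure <- function(path, dialect = c("auto", "pdb", "mmcif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("unreadable file: ", path)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("cif", "mmcif")) "mmcif"
    else if (ext %in% c("pdb", "ent")) "pdb"
    else {
      head1 <- readLines(path, n = 50L, warn = FALSE)
      if (any(grepl("^data_|^loop_|^_atom_site", head1))) "mmcif" else "pdb"
    }
  }
  raw <- switch(dialect, pdb = read_pdb_models(path), mmcif = read_mmcif_models(path))
  raw$dialect <- dialect
  class(raw) <- "structure_models"
  raw
}

#' @export
print.structure_models <- function(x, ...) {
  cat(sprintf("structure_models %s (%s): %d model(s), chains %s\n",
              x$pdb_id, x$dialect, length(x$models),
              paste(names(x$models[[1]]), collapse = ",")))
  invisible(x)
}

resolve_altlocs <- function(at) {
  alt <- at$alt
  alt[is.na(alt) | alt == "?" | alt == "."] <- ""
  at$alt <- alt
  if (!any(at$alt != "")) return(at)
  key <- paste(at$chain, at$resno, at$insert, trimws(at$elety))
  keep <- unsplit(lapply(split(seq_len(nrow(at)), key), function(idx) {
    if (length(idx) == 1L) return(TRUE)
    occ <- at$o[idx]; occ[is.na(occ)] <- 1
    best <- idx[occ == max(occ)]
    if (length(best) > 1L) best <- best[order(at$alt[best])][1] else best <- best[1]
    idx == best
  }), key)
  at[keep, , drop = FALSE]
}

split_models <- function(at_list, resolution, pdb_id) {
  models <- lapply(at_list, function(at) {
    at <- resolve_altlocs(at)
    at <- at[order(at$chain, at$resno, at$insert), ]
    split(at, at$chain)
  })
  list(models = models, resolution = resolution, pdb_id = pdb_id)
}

read_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  res <- NA_real_
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rl)) {
    m <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
    if (length(m)) res <- as.numeric(m)
  }
  hdr <- grep("^HEADER", lines, value = TRUE)
  pdb_id <- if (length(hdr) && nchar(hdr[1]) >= 66) trimws(substr(hdr[1], 63, 66))
            else toupper(tools::file_path_sans_ext(basename(path)))
  # validate MODEL blocks: every frame must carry the same atom count
  mstart <- grep("^MODEL", lines)
  if (length(mstart) > 1L) {
    mend <- grep("^ENDMDL", lines)
    counts <- vapply(seq_along(mstart), function(i)
      sum(grepl("^(ATOM|HETATM)", lines[mstart[i]:mend[i]])), integer(1))
    bad <- which(counts != counts[1])
    if (length(bad))
      stop("topology mismatch in model/frame ", bad[1],
           ": atom count differs from frame 1")
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("parse error in PDB file ", path,
                                           ": ", conditionMessage(e)))
  nmod <- nrow(pdb$xyz)
  base <- data.frame(chain = ifelse(is.na(pdb$atom$chain), " ", pdb$atom$chain),
                     resno = pdb$atom$resno,
                     insert = ifelse(is.na(pdb$atom$insert), "", pdb$atom$insert),
                     resid = pdb$atom$resid,
                     elety = pdb$atom$elety,
                     alt = pdb$atom$alt,
                     o = pdb$atom$o, b = pdb$atom$b,
                     elesy = ifelse(is.na(pdb$atom$elesy) | pdb$atom$elesy == "",
                                    substr(trimws(pdb$atom$elety), 1, 1),
                                    trimws(pdb$atom$elesy)),
                     stringsAsFactors = FALSE)
  at_list <- lapply(seq_len(nmod), function(i) {
    xyz <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
    cbind(base, data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  })
  split_models(at_list, res, pdb_id)
}

# Minimal mmCIF reader: _atom_site loop plus _refine.ls_d_res_high.
read_mmcif_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  res <- NA_real_
  rl <- grep("^_refine\\.ls_d_res_high", lines, value = TRUE)
  if (length(rl)) {
    v <- strsplit(trimws(rl[1]), "[[:space:]]+")[[1]]
    if (length(v) >= 2) res <- suppressWarnings(as.numeric(v[2]))
  }
  pdb_id <- toupper(sub("^data_", "", grep("^data_", lines, value = TRUE)[1]))
  if (is.na(pdb_id) || !nzchar(pdb_id))
    pdb_id <- toupper(tools::file_path_sans_ext(basename(path)))

  loop_starts <- grep("^loop_", lines)
  tags <- NULL; body <- NULL
  for (ls in loop_starts) {
    i <- ls + 1L; tg <- character(0)
    while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
      tg <- c(tg, trimws(lines[i])); i <- i + 1L
    }
    if (any(grepl("^_atom_site\\.", tg))) {
      j <- i
      while (j <= length(lines) &&
             !grepl("^(loop_|_|#|data_)", trimws(lines[j])) &&
             nzchar(trimws(lines[j]))) j <- j + 1L
      tags <- sub("^_atom_site\\.", "", tg)
      body <- lines[i:(j - 1L)]
      break
    }
  }
  if (is.null(tags)) stop("parse error in mmCIF file ", path,
                          ": no _atom_site loop found")
  toks <- scan(text = paste(body, collapse = "\n"), what = "character",
               quiet = TRUE)
  if (length(toks) %% length(tags) != 0)
    stop("parse error in mmCIF file ", path, ": ragged _atom_site loop")
  m <- matrix(toks, ncol = length(tags), byrow = TRUE)
  colnames(m) <- tags
  col <- function(nm, default = NA) if (nm %in% tags) m[, nm] else rep(default, nrow(m))
  num <- function(v) suppressWarnings(as.numeric(v))
  at <- data.frame(chain = col("auth_asym_id", col("label_asym_id", " ")),
                   resno = as.integer(num(col("auth_seq_id", col("label_seq_id", "0")))),
                   insert = "",
                   resid = col("auth_comp_id", col("label_comp_id", "UNK")),
                   elety = col("auth_atom_id", col("label_atom_id", "")),
                   alt = col("label_alt_id", ""),
                   o = num(col("occupancy", "1")),
                   b = num(col("B_iso_or_equiv", "0")),
                   elesy = col("type_symbol", ""),
                   x = num(col("Cartn_x")), y = num(col("Cartn_y")),
                   z = num(col("Cartn_z")),
                   model = as.integer(num(col("pdbx_PDB_model_num", "1"))),
                   stringsAsFactors = FALSE)
  if (anyNA(at$x)) stop("parse error in mmCIF file ", path, ": bad coordinates")
  at_list <- split(at, at$model)
  split_models(unname(at_list), res, pdb_id)
}

score_alignment <- function(chain_seq, canon) {
  canon <- strsplit(canon, "")[[1]]
  best <- list(score = -Inf, offset = NA_integer_)
  for (off in -3:3) {
    pos <- seq_along(chain_seq) + off     # canonical positions
    ok <- pos >= 1 & pos <= length(canon)
    if (sum(ok) < 0.75 * length(canon)) next
    cs <- chain_seq[ok]; cn <- canon[pos[ok]]
    informative <- cs != "X"
    if (!any(informative)) next
    score <- sum(cs[informative] == cn[informative]) / sum(informative)
    if (score > best$score) best <- list(score = score, offset = off, n = sum(ok))
  }
  best
}

chain_residue_table <- function(at) {
  key <- paste(at$resno, at$insert)
  res <- at[!duplicated(key), c("resno", "insert", "resid")]
  res[order(res$resno, res$insert), ]
}

#' Identify insulin monomers within parsed models
#'
#' Chains of A-chain-like length (19-23 residues) and B-chain-like length
#' (26-32) are aligned without gaps to the human insulin A and B sequences,
#' tolerating substitutions (including dicarba replacements at A6/A11,
#' matched as wildcards). A/B pairing minimises the A7-B7 bridge-atom
#' distance; equidistant alternatives are broken by chain-id order and
#' flagged (`attr(, "pairing_tie")`). Unpaired candidate chains produce a
#' warning, never a silent drop.
#'
#' @param models A `structure_models` object from [parse_structure()].
#' @param min_identity Minimum fractional sequence identity for a chain to
#'   be accepted (default 0.5).
#' @return List of `insulin_monomer` objects (possibly empty).
#' @export
identify_insulin_monomers <- function(models, min_identity = 0.5) {
  out <- list()
  for (mi in seq_along(models$models)) {
    chains <- models$models[[mi]]
    cand <- list(A = list(), B = list())
    for (cid in names(chains)) {
      at <- chains[[cid]]
      at <- at[trimws(at$elety) != "" & !is.na(at$resno), ]
      res <- chain_residue_table(at)
      n <- nrow(res)
      seq1 <- aa_one(res$resid)
      if (n >= 19 && n <= 23) {
        al <- score_alignment(seq1, A_CHAIN_SEQ)
        if (is.finite(al$score) && al$score >= min_identity)
          cand$A[[cid]] <- list(at = at, res = res, offset = al$offset)
      }
      if (n >= 26 && n <= 32) {
        al <- score_alignment(seq1, B_CHAIN_SEQ)
        if (is.finite(al$score) && al$score >= min_identity)
          cand$B[[cid]] <- list(at = at, res = res, offset = al$offset)
      }
    }
    canon_atoms <- function(c_entry, canon_chain, max_pos) {
      at <- c_entry$at; res <- c_entry$res
      pos_map <- seq_len(nrow(res)) + c_entry$offset
      names(pos_map) <- paste(res$resno, res$insert)
      pos <- pos_map[paste(at$resno, at$insert)]
      ok <- !is.na(pos) & pos >= 1 & pos <= max_pos
      data.frame(chain = canon_chain, pos = as.integer(pos[ok]),
                 resid = at$resid[ok], elety = at$elety[ok],
                 x = at$x[ok], y = at$y[ok], z = at$z[ok],
                 o = at$o[ok], b = at$b[ok], elesy = at$elesy[ok],
                 stringsAsFactors = FALSE)
    }
    bridge_atom <- function(atoms, chain, pos) {
      sel <- atoms[atoms$chain == chain & atoms$pos == pos, ]
      for (nm in c("SG", "CG", "CB", "CA")) {
        hit <- sel[trimws(sel$elety) == nm, ]
        if (nrow(hit)) return(as.numeric(hit[1, c("x", "y", "z")]))
      }
      NULL
    }
    a_ids <- names(cand$A); b_ids <- names(cand$B)
    a_tabs <- lapply(cand$A, canon_atoms, canon_chain = "A", max_pos = 21L)
    b_tabs <- lapply(cand$B, canon_atoms, canon_chain = "B", max_pos = 30L)
    # pair greedily by A7-B7 bridge-atom distance
    while (length(a_ids) && length(b_ids)) {
      dm <- matrix(Inf, length(a_ids), length(b_ids))
      for (i in seq_along(a_ids)) for (j in seq_along(b_ids)) {
        pa <- bridge_atom(a_tabs[[a_ids[i]]], "A", 7L)
        pb <- bridge_atom(b_tabs[[b_ids[j]]], "B", 7L)
        if (!is.null(pa) && !is.null(pb)) dm[i, j] <- point_distance(pa, pb)
      }
      if (!any(is.finite(dm))) break
      best <- which(dm == min(dm), arr.ind = TRUE)
      tie <- nrow(best) > 1L
      best <- best[order(a_ids[best[, 1]], b_ids[best[, 2]]), , drop = FALSE][1, ]
      mon <- insulin_monomer(rbind(a_tabs[[a_ids[best[1]]]], b_tabs[[b_ids[best[2]]]]),
                             pdb_id = models$pdb_id, model_no = mi,
                             resolution = models$resolution,
                             source_chains = c(A = a_ids[best[1]], B = b_ids[best[2]]))
      if (tie) attr(mon, "pairing_tie") <- TRUE
      out[[length(out) + 1L]] <- mon
      a_ids <- a_ids[-best[1]]; b_ids <- b_ids[-best[2]]
    }
    if (length(a_ids) || length(b_ids))
      warning(sprintf("model %d: unpaired insulin-like chain(s): %s", mi,
                      paste(c(a_ids, b_ids), collapse = ", ")))
  }
  if (!length(out)) warning("no insulin-like chains found")
  out
}

#' Apply the curation filters of the structure survey
#'
#' A monomer passes when (i) the resolution is strictly better than the
#' cutoff, (ii) if the A6-A11 bridge is a disulfide, its Sgamma-Sgamma bond
#' length lies within [1.95, 2.05] Angstrom (dicarba bridges are exempt but
#' flagged), and (iii) the entry is not on the insulin-degrading-enzyme
#' exclusion list.
#'
#' @param monomer An `insulin_monomer`.
#' @param resolution Resolution in Angstrom (default: the monomer's own).
#' @param resolution_cutoff Strict upper bound (default 2.8).
#' @param ss_range Allowed Sgamma-Sgamma range (default c(1.95, 2.05)).
#' @param exclude_ids Character vector of PDB ids to exclude (IDE complexes).
#' @return Object of class `curation_report`: `id`, `passed`, `reasons`,
#'   `dicarba` flag, and the measured `sg_sg` when applicable.
#' @export
apply_curation_filters <- function(monomer, resolution = monomer$resolution,
                                   resolution_cutoff = 2.8,
                                   ss_range = c(1.95, 2.05),
                                   exclude_ids = character(0)) {
  reasons <- character(0)
  if (is.na(resolution) || resolution >= resolution_cutoff)
    reasons <- c(reasons, "resolution_fail")
  if (toupper(monomer$pdb_id) %in% toupper(exclude_ids))
    reasons <- c(reasons, "ide_complex_excluded")
  geom <- tryCatch(extract_bridge_geometry(monomer, "A6A11"),
                   error = function(e) NULL)
  sg_sg <- NA_real_
  dicarba <- FALSE
  if (is.null(geom)) {
    reasons <- c(reasons, "incomplete_backbone")
  } else if (geom$bridge_type == "disulfide") {
    sg_sg <- geom$sg_sg
    if (is.na(sg_sg) || sg_sg < ss_range[1] || sg_sg > ss_range[2])
      reasons <- c(reasons, "ss_bond_length_fail")
  } else if (geom$bridge_type == "dicarba") {
    dicarba <- TRUE
  } else {
    reasons <- c(reasons, "incomplete_backbone")
  }
  structure(list(id = sprintf("%s/%d", monomer$pdb_id, monomer$model_no),
                 passed = length(reasons) == 0L, reasons = reasons,
                 dicarba = dicarba, sg_sg = sg_sg),
            class = "curation_report")
}

#' @export
print.curation_report <- function(x, ...) {
  cat(sprintf("Curation %s: %s%s\n", x$id,
              if (x$passed) "PASS" else "FAIL",
              if (length(x$reasons)) paste0(" (", paste(x$reasons, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Write a per-monomer survey table
#'
#' Tab-separated, header + one row per monomer, distances to 0.01 A and
#' angles to 0.1 degrees, rows ordered by (pdb_id, model_no, then input
#' order) so output is deterministic.
#'
#' @param records Data frame of per-monomer metric rows.
#' @param path Output path.
#' @return The formatted data frame, invisibly.
#' @export
write_survey <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records)) {
    ord <- seq_len(nrow(records))
    if (all(c("pdb_id", "model_no") %in% names(records)))
      ord <- order(records$pdb_id, records$model_no, seq_len(nrow(records)))
    records <- records[ord, , drop = FALSE]
    for (nm in names(records)) {
      if (!is.numeric(records[[nm]])) next
      digits <- if (grepl("chi|azimuth|twist|angle", nm)) 1L
      else if (grepl("ca_ca|sg_sg|dist|rmsd|rise|resolution", nm)) 2L
      else NA_integer_
      if (!is.na(digits)) records[[nm]] <- round(records[[nm]], digits)
    }
  }
  ok <- tryCatch({
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) stop("cannot write survey to ", path, ": ",
                              conditionMessage(e)))
  invisible(records)
}

# ---- PDB writing (fixed-width; supports MODEL blocks and REMARK 2) -------

format_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                             o = 1, b = 0, elesy = "") {
  name <- trimws(elety)
  name_f <- if (nchar(name) >= 4L) substr(name, 1, 4)
            else sprintf(" %-3s", name)
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000, name_f, substr(resid, 1, 3), chain, resno,
          x, y, z, o, b, toupper(substr(if (nzchar(elesy)) elesy
                                        else substr(name, 1, 1), 1, 2)))
}

monomer_pdb_lines <- function(monomer, chain_map = c(A = "A", B = "B"),
                              serial_start = 1L) {
  at <- monomer$atoms
  lines <- character(0)
  serial <- serial_start
  for (ch in c("A", "B")) {
    sub <- at[at$chain == ch, ]
    if (!nrow(sub)) next
    for (k in seq_len(nrow(sub))) {
      lines <- c(lines, format_atom_line(serial, sub$elety[k], sub$resid[k],
                                         chain_map[[ch]], sub$pos[k],
                                         sub$x[k], sub$y[k], sub$z[k],
                                         sub$o[k], sub$b[k], sub$elesy[k]))
      serial <- serial + 1L
    }
    lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d",
                              serial, sub$resid[nrow(sub)], chain_map[[ch]],
                              sub$pos[nrow(sub)]))
    serial <- serial + 1L
  }
  list(lines = lines, next_serial = serial)
}

#' Write insulin monomers to a PDB file
#'
#' With `multi_model = TRUE` each monomer becomes one MODEL block (an
#' ensemble file); otherwise all monomers share one model and chains are
#' relabelled A,B,C,D,... in order. A `REMARK   2` resolution record is
#' emitted when available so fixtures round-trip through
#' [parse_structure()].
#'
#' @param monomers A single `insulin_monomer` or a list of them.
#' @param path Output path.
#' @param multi_model Write MODEL/ENDMDL blocks (default: TRUE when more
#'   than one monomer is given).
#' @param resolution Resolution recorded in the header (default: from the
#'   first monomer).
#' @return `path`, invisibly.
#' @export
write_monomers_pdb <- function(monomers, path,
                               multi_model = NULL, resolution = NULL) {
  if (inherits(monomers, "insulin_monomer")) monomers <- list(monomers)
  if (is.null(multi_model)) multi_model <- length(monomers) > 1L
  if (is.null(resolution)) resolution <- monomers[[1]]$resolution
  out <- c(sprintf("HEADER    HORMONE                                 01-JAN-00   %s",
                   substr(paste0(monomers[[1]]$pdb_id, "    "), 1, 4)))
  if (!is.null(resolution) && !is.na(resolution))
    out <- c(out, sprintf("REMARK   2 RESOLUTION.    %.2f ANGSTROMS.", resolution))
  if (multi_model) {
    for (i in seq_along(monomers)) {
      out <- c(out, sprintf("MODEL     %4d", i),
               monomer_pdb_lines(monomers[[i]])$lines, "ENDMDL")
    }
  } else {
    chain_pool <- c(LETTERS, letters)
    serial <- 1L
    for (i in seq_along(monomers)) {
      map <- c(A = chain_pool[2 * i - 1], B = chain_pool[2 * i])
      res <- monomer_pdb_lines(monomers[[i]], chain_map = map,
                               serial_start = serial)
      out <- c(out, res$lines)
      serial <- res$next_serial
    }
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}
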