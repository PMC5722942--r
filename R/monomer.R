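# The insulin_monomer container: a canonically numbered two-chain atom table.

A_CHAIN_SEQ <- "GIVEQCCTSICSLYQLENYCN"   # human insulin A chain, A1..A21
B_CHAIN_SEQ <- "FVNQHLCGSHLVEALYLVCGERGFFYTPKT"  # B1..B30

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

aa_one <- function(res3) {
  out <- AA3TO1[toupper(res3)]
  out[is.na(out)] <- "X"
  unname(out)
}

#' Construct an insulin monomer
#'
#' The unit of all classification: a two-chain coordinate set with canonical
#' insulin numbering (A1..A21, B1..B30). `atoms` must have columns
#' `chain` ("A"/"B"), `pos` (1-based canonical position), `resid`
#' (3-letter code), `elety` (atom name), `x`, `y`, `z`, and optionally
#' `o` (occupancy), `b` (B-factor), `elesy` (element symbol).
#'
#' @param atoms Atom data frame (see Details).
#' @param pdb_id 4-character accession or synthetic tag.
#' @param model_no Model number (>= 1).
#' @param resolution Resolution in Angstrom, or NA when unknown.
#' @param source_chains Named character vector: file chain ids for A and B.
#' @return Object of class `insulin_monomer`.
#' @export
insulin_monomer <- function(atoms, pdb_id = "SYNT", model_no = 1L,
                            resolution = NA_real_,
                            source_chains = c(A = "A", B = "B")) {
  need <- c("chain", "pos", "resid", "elety", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns ", paste(need, collapse = ", "))
  if (!all(atoms$chain %in% c("A", "B")))
    stop("monomer chains must be canonical 'A' and 'B'")
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$elesy)) atoms$elesy <- substr(trimws(atoms$elety), 1, 1)
  atoms <- atoms[order(match(atoms$chain, c("A", "B")), atoms$pos), ]
  rownames(atoms) <- NULL
  structure(list(pdb_id = pdb_id, model_no = as.integer(model_no),
                 resolution = resolution, source_chains = source_chains,
                 atoms = atoms),
            class = "insulin_monomer")
}

#' @export
print.insulin_monomer <- function(x, ...) {
  cat(sprintf("Insulin monomer %s (model %d): %d A-chain / %d B-chain atoms",
              x$pdb_id, x$model_no,
              sum(x$atoms$chain == "A"), sum(x$atoms$chain == "B")))
  if (!is.na(x$resolution)) cat(sprintf(", %.2f A resolution", x$resolution))
  cat("\n")
  invisible(x)
}

parse_reslabel <- function(labels) {
  data.frame(chain = substr(labels, 1, 1),
             pos = as.integer(substring(labels, 2)))
}

#' Coordinates of selected atoms of a monomer
#'
#' @param monomer An `insulin_monomer`.
#' @param residues Residue labels such as `"A8"` or `c("B9","B10")`;
#'   NULL selects all residues.
#' @param elety Atom names to keep (e.g. `"CA"`); NULL keeps all.
#' @param heavy_only Drop hydrogens.
#' @return M x 3 matrix with rownames `"<label>:<atom>"` (or `<label>` when a
#'   single atom type is requested).
#' @export
monomer_coords <- function(monomer, residues = NULL, elety = NULL,
                           heavy_only = TRUE) {
  at <- monomer$atoms
  lab <- paste0(at$chain, at$pos)
  keep <- rep(TRUE, nrow(at))
  if (!is.null(residues)) keep <- keep & lab %in% residues
  if (!is.null(elety)) keep <- keep & trimws(at$elety) %in% elety
  if (heavy_only) keep <- keep & !(at$elesy %in% c("H", "D"))
  at <- at[keep, , drop = FALSE]
  lab <- lab[keep]
  m <- as.matrix(at[, c("x", "y", "z")])
  rownames(m) <- if (!is.null(elety) && length(elety) == 1L) lab
                 else paste0(lab, ":", trimws(at$elety))
  # preserve requested residue order for single-atom selections
  if (!is.null(residues) && !is.null(elety) && length(elety) == 1L)
    m <- m[order(match(rownames(m), residues)), , drop = FALSE]
  m
}

atom_xyz <- function(monomer, label, atom) {
  m <- monomer_coords(monomer, label, atom, heavy_only = FALSE)
  if (nrow(m) < 1L) return(NULL)
  as.numeric(m[1, ])
}

residue_atoms <- function(monomer, label) {
  at <- monomer$atoms
  at[paste0(at$chain, at$pos) == label, , drop = FALSE]
}

#' Apply a rigid transform to a monomer
#'
#' @param monomer An `insulin_monomer`.
#' @param sup A `superposition` (from [kabsch_superpose()]), or NULL with
#'   `rotation`/`translation` given explicitly.
#' @param rotation 3x3 rotation applied as `coords %*% rotation`.
#' @param translation Length-3 translation.
#' @return The transformed monomer.
#' @export
transform_monomer <- function(monomer, sup = NULL,
                              rotation = diag(3), translation = c(0, 0, 0)) {
  if (!is.null(sup)) { rotation <- sup$rotation; translation <- sup$translation }
  xyz <- as.matrix(monomer$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% rotation, 2, translation, `+`)
  monomer$atoms[, c("x", "y", "z")] <- xyz
  monomer
}

#' Residue sequence of one canonical chain
#'
#' @param monomer An `insulin_monomer`.
#' @param chain `"A"` or `"B"`.
#' @return Character vector of one-letter codes in canonical order
#'   (names = canonical positions).
#' @export
monomer_sequence <- function(monomer, chain = "A") {
  at <- monomer$atoms[monomer$atoms$chain == chain, ]
  res <- at[!duplicated(at$pos), ]
  out <- aa_one(res$resid)
  names(out) <- res$pos
  out
}

backbone_complete <- function(monomer, label) {
  at <- residue_atoms(monomer, label)
  all(c("N", "CA", "C", "O") %in% trimws(at$elety))
}
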