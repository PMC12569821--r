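# Residue-name tables used to assign entity classes.
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.DNA_RES <- c("DA", "DT", "DG", "DC")
.ION_RES <- c("MG")
.LIGAND_RES <- c("FAD")

#' Construct a structure model
#'
#' A `structure_model` holds an ordered atom table plus a chain-level entity
#' map partitioning the complex into protein, DNA, ion and ligand components.
#' Per-atom confidence is a pLDDT-like score on \[0, 100\], conventionally
#' carried in the B-factor column of predicted models.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `chain`, `resno`, `insert`, `x`, `y`, `z`, `occupancy`,
#'   `confidence`.
#' @param chains named character vector mapping chain id to one of
#'   `"protein"`, `"dna"`, `"ion"`, `"ligand"`. If `NULL`, classes are
#'   assigned from residue names (unknown residues become ligand, with a
#'   warning).
#' @param name model label.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, chains = NULL, name = "model") {
  required <- c("serial", "name", "element", "resname", "chain", "resno",
                "insert", "x", "y", "z", "occupancy", "confidence")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("empty model: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  if (any(atoms$confidence < 0 | atoms$confidence > 100, na.rm = TRUE)) {
    stop("confidence values must lie in [0, 100]")
  }
  atoms$chain <- as.character(atoms$chain)
  atoms$element <- toupper(as.character(atoms$element))
  if (is.null(chains)) {
    chains <- .classify_chains(atoms)
  } else {
    chains <- vapply(chains, as.character, character(1))
    bad <- setdiff(unique(atoms$chain), names(chains))
    if (length(bad)) {
      stop("atoms reference chains absent from the chain map: ",
           paste(bad, collapse = ", "))
    }
    ok <- chains %in% c("protein", "dna", "ion", "ligand")
    if (!all(ok)) stop("invalid entity class: ", paste(chains[!ok], collapse = ", "))
  }
  structure(list(atoms = atoms, chains = chains, name = name),
            class = "structure_model")
}

# Assign one entity class per chain from the residue names it contains.
.classify_chains <- function(atoms) {
  classify_res <- function(rn) {
    if (rn %in% .AA3) "protein"
    else if (rn %in% .DNA_RES) "dna"
    else if (rn %in% .ION_RES) "ion"
    else if (rn %in% .LIGAND_RES) "ligand"
    else NA_character_
  }
  chains <- unique(atoms$chain)
  out <- character(length(chains))
  names(out) <- chains
  for (ch in chains) {
    rn <- unique(atoms$resname[atoms$chain == ch])
    cls <- vapply(rn, classify_res, character(1))
    if (anyNA(cls)) {
      warning("unknown residue name(s) ", paste(rn[is.na(cls)], collapse = ", "),
              " in chain ", ch, "; classed as ligand")
      cls[is.na(cls)] <- "ligand"
    }
    # a chain's class is decided by majority; mixed chains take the modal class
    out[ch] <- names(sort(table(cls), decreasing = TRUE))[1L]
  }
  out
}

#' @export
print.structure_model <- function(x, ...) {
  cls <- table(factor(x$chains, levels = c("protein", "dna", "ion", "ligand")))
  cat("structure_model '", x$name, "': ", nrow(x$atoms), " atoms, ",
      length(x$chains), " chains (",
      paste(paste0(names(cls), "=", as.integer(cls)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Subset a model to a set of chains
#'
#' @param model a `structure_model`.
#' @param chain_ids chains to keep.
#' @return A `structure_model` containing only those chains.
#' @export
subset_chains <- function(model, chain_ids) {
  missing <- setdiff(chain_ids, names(model$chains))
  if (length(missing)) stop("unknown chain(s): ", paste(missing, collapse = ", "))
  atoms <- model$atoms[model$atoms$chain %in% chain_ids, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("chain subset contains no atoms")
  structure_model(atoms, model$chains[chain_ids], name = model$name)
}

#' Parse a structure model from PDB or mmCIF
#'
#' Reads ATOM/HETATM records, keeps blank/'A' alternate locations, and
#' assigns entity classes from residue names. Per-atom confidence is taken
#' from the B-factor (`B_iso_or_equiv`) column, the convention used by
#' structure-prediction servers for pLDDT.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (detect from extension:
#'   `.pdb` vs `.cif`/`.mmcif`).
#' @return A `structure_model`.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     pdb = "pdb", ent = "pdb",
                     cif = "mmcif", mmcif = "mmcif",
                     stop("cannot detect structure format from extension '.",
                          ext, "'"))
  }
  if (format == "pdb") .check_pdb_lines(path)
  pdb <- if (format == "pdb") {
    bio3d::read.pdb(path, verbose = FALSE)
  } else {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  }
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty model: ", path)
  if (!is.null(at$alt)) {
    keep <- is.na(at$alt) | at$alt %in% c("", "A")
    at <- at[keep, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("empty model after altloc filtering: ", path)
  elem <- toupper(trimws(at$elesy))
  no_elem <- is.na(elem) | elem == ""
  if (any(no_elem)) elem[no_elem] <- toupper(substr(trimws(at$elety[no_elem]), 1, 1))
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = elem,
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", as.character(at$chain)),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), NA_character_, as.character(at$insert)),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    confidence = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE
  )
  structure_model(atoms, name = basename(path))
}

# Pre-validate the fixed coordinate columns of a PDB file so malformed lines
# are reported with their line number rather than as an opaque parser error.
.check_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed coordinate line ", i, " in ", path, ": too short")
    }
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz)))) {
      stop("malformed coordinate line ", i, " in ", path,
           ": non-numeric coordinate field")
    }
  }
  invisible(TRUE)
}

#' Write a structure model as fixed-column PDB
#'
#' Round-trips all fields carried by [structure_model()]: `parse_structure()`
#' applied to the output reproduces the model field-by-field.
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @param format only `"pdb"` is supported for writing.
#' @export
write_structure <- function(model, path, format = "pdb") {
  if (!inherits(model, "structure_model")) stop("not a structure_model")
  format <- match.arg(format, "pdb")
  at <- model$atoms
  if (nrow(at) == 0L) stop("empty model")
  if (any(nchar(at$name) > 4L)) {
    stop("atom name(s) exceed 4 characters: ",
         paste(unique(at$name[nchar(at$name) > 4L]), collapse = ", "))
  }
  xyz <- c(at$x, at$y, at$z)
  if (any(xyz <= -1000 | xyz >= 10000)) {
    stop("coordinate overflow: values outside the fixed-column PDB range")
  }
  cls <- model$chains[at$chain]
  type <- ifelse(cls %in% c("protein", "dna"), "ATOM", "HETATM")
  bio3d::write.pdb(
    pdb = NULL, file = path,
    type = type,
    eleno = at$serial,
    elety = at$name,
    resid = at$resname,
    chain = at$chain,
    resno = at$resno,
    insert = at$insert,
    xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
    o = at$occupancy,
    b = at$confidence,
    elesy = at$element
  )
  invisible(path)
}

#' Per-residue confidence summary
#'
#' @param model a `structure_model`.
#' @return data.frame with one row per residue (`chain`, `resno`, `resname`,
#'   `plddt`), where `plddt` is the unweighted mean of the residue's atom
#'   confidences.
#' @export
plddt_by_residue <- function(model) {
  at <- model$atoms
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               sep = "\r")
  first <- !duplicated(key)
  means <- tapply(at$confidence, key, mean)
  data.frame(chain = at$chain[first], resno = at$resno[first],
             resname = at$resname[first],
             plddt = as.numeric(means[key[first]]),
             stringsAsFactors = FALSE)
}

#' Model-level mean pLDDT
#'
#' Averages confidences per residue first, then averages over residues, so
#' residues with different atom counts weigh equally (prediction servers
#' write identical per-residue values to every atom, making the two
#' conventions agree on their output; they differ on hand-built fixtures).
#'
#' @param model a `structure_model`.
#' @return mean confidence on \[0, 100\].
#' @export
mean_plddt <- function(model) {
  if (nrow(model$atoms) == 0L) stop("empty model")
  mean(plddt_by_residue(model)$plddt)
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired coordinate sets; reflections are disallowed.
#'
#' @param mobile n x 3 matrix of coordinates to move.
#' @param reference n x 3 matrix of target coordinates (same pairing order).
#' @return An object of class `superposition` with elements `rotation`
#'   (3 x 3, det = +1), `translation` (length 3), `rmsd` (post-fit, in the
#'   coordinate units) and `n_pairs`. The fitted mobile coordinates are
#'   `mobile %*% t(rotation) + translation` (rows).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L) stop("coordinates must be n x 3")
  n <- nrow(mobile)
  if (nrow(reference) != n) stop("coordinate lists differ in length")
  if (n < 3L) stop("need at least 3 paired points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  H <- crossprod(P, Q)
  sv <- svd(H)
  # degenerate (collinear) configurations leave the rotation underdetermined
  scale_ref <- max(sv$d[1], .Machine$double.eps)
  if (sv$d[2] / scale_ref < 1e-8) {
    stop("degenerate (rank-deficient) coordinate configuration")
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  translation <- as.numeric(cr - R %*% cm)
  structure(list(rotation = R, translation = translation,
                 rmsd = rmsd, n_pairs = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition over %d pairs: rmsd = %.4f\n", x$n_pairs, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sup a `superposition`.
#' @param coords n x 3 matrix.
#' @return transformed n x 3 matrix.
#' @export
apply_superposition <- function(sup, coords) {
  sweep(as.matrix(coords) %*% t(sup$rotation), 2, sup$translation, "+")
}
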