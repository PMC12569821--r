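# Hydrogen-bond and metal-coordination geometry.
#
# Donor/acceptor assignment is purely distance-based on heavy atoms (no
# angle term): the criterion is a donor-acceptor separation at or below a
# threshold, 3.5 A by default.

# Protein side-chain donors (N/O bearing a polar hydrogen).
.PROT_SC_DONORS <- list(
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), SER = "OG", THR = "OG1",
  TYR = "OH", TRP = "NE1", HIS = c("ND1", "NE2"), ASN = "ND2", GLN = "NE2"
)
# Protein side-chain acceptors (lone-pair N/O).
.PROT_SC_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2")
)
# Watson-Crick edge donors/acceptors per base; backbone oxygens accept.
.DNA_DONORS <- list(DA = "N6", DT = "N3", DG = c("N1", "N2"), DC = "N4")
.DNA_ACCEPTORS <- list(
  DA = c("N1", "N3", "N7"), DT = c("O2", "O4"),
  DG = c("O6", "N7", "N3"), DC = c("O2", "N3")
)
.DNA_BACKBONE_ACC <- c("OP1", "OP2", "O1P", "O2P", "O3'", "O4'", "O5'")

# Flag the donor/acceptor atoms of a model; returns logical vectors.
.hbond_roles <- function(atoms, chains) {
  cls <- chains[atoms$chain]
  donor <- rep(FALSE, nrow(atoms))
  acceptor <- rep(FALSE, nrow(atoms))
  prot <- cls == "protein"
  donor[prot & atoms$name == "N"] <- TRUE
  acceptor[prot & atoms$name %in% c("O", "OXT")] <- TRUE
  for (rn in names(.PROT_SC_DONORS)) {
    donor[prot & atoms$resname == rn & atoms$name %in% .PROT_SC_DONORS[[rn]]] <- TRUE
  }
  for (rn in names(.PROT_SC_ACCEPTORS)) {
    acceptor[prot & atoms$resname == rn &
               atoms$name %in% .PROT_SC_ACCEPTORS[[rn]]] <- TRUE
  }
  dna <- cls == "dna"
  for (rn in names(.DNA_DONORS)) {
    donor[dna & atoms$resname == rn & atoms$name %in% .DNA_DONORS[[rn]]] <- TRUE
  }
  for (rn in names(.DNA_ACCEPTORS)) {
    acceptor[dna & atoms$resname == rn & atoms$name %in% .DNA_ACCEPTORS[[rn]]] <- TRUE
  }
  acceptor[dna & atoms$name %in% .DNA_BACKBONE_ACC] <- TRUE
  list(donor = donor, acceptor = acceptor)
}

#' Find hydrogen bonds by donor-acceptor distance
#'
#' Enumerates heavy-atom donor/acceptor pairs at or below the distance
#' threshold. In `inter_entity` mode only protein-DNA pairs are kept (the
#' usual question for a protein-DNA complex); `all` keeps every pair across
#' or within entities, excluding self and same-residue pairs.
#'
#' @param model a `structure_model`.
#' @param threshold donor-acceptor distance cutoff in Angstrom.
#' @param mode `"inter_entity"` or `"all"`.
#' @return data.frame sorted by distance with donor and acceptor chain,
#'   residue number, atom name, and the distance.
#' @export
find_hbonds <- function(model, threshold = 3.5,
                        mode = c("inter_entity", "all")) {
  mode <- match.arg(mode)
  at <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  roles <- .hbond_roles(at, model$chains)
  di <- which(roles$donor); ai <- which(roles$acceptor)
  empty <- data.frame(donor_chain = character(), donor_resno = integer(),
                      donor_atom = character(), acceptor_chain = character(),
                      acceptor_resno = integer(), acceptor_atom = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  if (!length(di) || !length(ai)) return(empty)
  cls <- model$chains[at$chain]
  coords <- as.matrix(at[, c("x", "y", "z")])
  pairs <- expand.grid(d = di, a = ai)
  pairs <- pairs[pairs$d != pairs$a, , drop = FALSE]
  # drop same-residue pairs
  same_res <- at$chain[pairs$d] == at$chain[pairs$a] &
    at$resno[pairs$d] == at$resno[pairs$a]
  pairs <- pairs[!same_res, , drop = FALSE]
  if (mode == "inter_entity") {
    keep <- (cls[pairs$d] == "protein" & cls[pairs$a] == "dna") |
      (cls[pairs$d] == "dna" & cls[pairs$a] == "protein")
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (!nrow(pairs)) return(empty)
  dvec <- sqrt(rowSums((coords[pairs$d, , drop = FALSE] -
                          coords[pairs$a, , drop = FALSE])^2))
  keep <- dvec <= threshold
  pairs <- pairs[keep, , drop = FALSE]; dvec <- dvec[keep]
  if (!nrow(pairs)) return(empty)
  out <- data.frame(donor_chain = at$chain[pairs$d],
                    donor_resno = at$resno[pairs$d],
                    donor_atom = at$name[pairs$d],
                    acceptor_chain = at$chain[pairs$a],
                    acceptor_resno = at$resno[pairs$a],
                    acceptor_atom = at$name[pairs$a],
                    distance = dvec, stringsAsFactors = FALSE)
  out <- out[order(out$distance, out$donor_chain, out$donor_resno,
                   out$donor_atom, out$acceptor_chain, out$acceptor_resno,
                   out$acceptor_atom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Metal coordination shells
#'
#' For each ion of the requested element, lists every nitrogen/oxygen atom
#' within the coordination cutoff (the typical Mg-O distance is ~2.1 A; the
#' default 3.0 A cutoff absorbs model error in predicted structures).
#'
#' @param model a `structure_model`.
#' @param element ion element symbol (default `"MG"`).
#' @param cutoff coordination distance cutoff, Angstrom.
#' @return list of ion sites; each has `ion` (chain, resno, element) and
#'   `coordinating`, a data.frame (chain, resno, atom, distance) ordered by
#'   (chain, resno, atom). Ions with empty shells are kept.
#' @export
metal_coordination <- function(model, element = "MG", cutoff = 3.0) {
  at <- model$atoms
  ions <- which(at$element == toupper(element))
  coords <- as.matrix(at[, c("x", "y", "z")])
  lapply(ions, function(i) {
    cand <- which(at$element %in% c("N", "O") & seq_len(nrow(at)) != i)
    d <- sqrt(rowSums((coords[cand, , drop = FALSE] -
                         matrix(coords[i, ], length(cand), 3, byrow = TRUE))^2))
    keep <- d <= cutoff
    df <- data.frame(chain = at$chain[cand[keep]],
                     resno = at$resno[cand[keep]],
                     atom = at$name[cand[keep]],
                     distance = d[keep], stringsAsFactors = FALSE)
    df <- df[order(df$chain, df$resno, df$atom), , drop = FALSE]
    rownames(df) <- NULL
    list(ion = list(chain = at$chain[i], resno = at$resno[i],
                    element = at$element[i]),
         coordinating = df)
  })
}
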