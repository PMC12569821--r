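# Cleavage-site and overhang inference from catalytic-ion placement.
#
# The geometric logic mirrors how a type II restriction enzyme's cut is read
# off a predicted complex: each catalytic metal ion marks a scissile
# phosphate; the cut is the phosphodiester bond 5' of that nucleotide; and
# the offset between the two strands' cuts, mapped onto a common duplex
# axis, gives the overhang length, sequence, and end chemistry.

.COMPLEMENT <- c(A = "T", T = "A", G = "C", C = "G", N = "N")

#' Reverse complement of a DNA string
#'
#' @param seq character string over ACGTN (case-insensitive).
#' @return reverse-complemented uppercase string.
#' @export
reverse_complement <- function(seq) {
  s <- toupper(seq)
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# Ordered nucleotide table for one dna chain: resno order, base letter and a
# representative atom (C1' preferred, then base reference, then P).
.chain_nucleotides <- function(atoms, chain_id) {
  ca <- atoms[atoms$chain == chain_id, , drop = FALSE]
  resnos <- sort(unique(ca$resno))
  base <- character(length(resnos))
  rep_xyz <- matrix(NA_real_, length(resnos), 3)
  p_xyz <- matrix(NA_real_, length(resnos), 3)
  for (k in seq_along(resnos)) {
    ra <- ca[ca$resno == resnos[k], , drop = FALSE]
    base[k] <- sub("^D", "", ra$resname[1])
    pick <- which(ra$name %in% c("N9", "N1"))
    if (!length(pick)) pick <- which(ra$name == "C1'")
    if (!length(pick)) pick <- 1L
    rep_xyz[k, ] <- as.numeric(ra[pick[1], c("x", "y", "z")])
    p <- which(ra$name == "P")
    if (length(p)) p_xyz[k, ] <- as.numeric(ra[p[1], c("x", "y", "z")])
  }
  list(resno = resnos, base = base, rep_xyz = rep_xyz, p_xyz = p_xyz)
}

#' Infer the cleavage call of a protein-DNA-ion complex
#'
#' Each catalytic ion is assigned to its nearest backbone phosphorus within
#' `p_cutoff`; the scissile bond is the phosphodiester bond 5' of that
#' phosphate's nucleotide (0-based bond convention: bond i lies 5' of
#' nucleotide i on its strand). Base pairing between the two DNA chains is
#' established from complementarity plus proximity, never from residue
#' numbering, and both cuts are mapped onto the top strand's axis; the
#' signed offset between them yields the overhang.
#'
#' @param model a `structure_model` with exactly two dna chains and at least
#'   one ion of `ion_element`.
#' @param recognition_motif motif reported alongside the call (annotation
#'   only; the geometry decides the cut).
#' @param ion_element catalytic ion element symbol.
#' @param p_cutoff maximum ion-to-phosphorus distance, Angstrom; ions with
#'   no phosphorus inside it are skipped with a warning.
#' @param pair_cutoff maximum representative-atom distance for calling a
#'   base pair.
#' @return An object of class `cleavage_call`: `cut_top`, `cut_bottom`
#'   (0-based bond indices on each strand's own 5'->3' axis),
#'   `overhang_length`, `overhang_sequence` (top-strand sequence of the
#'   single-stranded region), `end_type` (`"five_prime_overhang"`,
#'   `"three_prime_overhang"` or `"blunt"`), and `incomplete` (TRUE when a
#'   strand lacks a cut, in which case no overhang is reported).
#' @export
infer_cleavage <- function(model, recognition_motif = "GATC",
                           ion_element = "MG", p_cutoff = 6.0,
                           pair_cutoff = 12.0) {
  dna_chains <- names(model$chains)[model$chains == "dna"]
  if (length(dna_chains) != 2L) {
    stop("model must contain exactly one DNA duplex (two dna chains); found ",
         length(dna_chains))
  }
  at <- model$atoms
  ions <- which(at$element == toupper(ion_element))
  if (!length(ions)) stop("no ion of element ", ion_element, " in model")

  top <- .chain_nucleotides(at, dna_chains[1])
  bot <- .chain_nucleotides(at, dna_chains[2])
  n_top <- length(top$resno); n_bot <- length(bot$resno)

  # pair bottom nucleotides to top positions by complementarity + proximity
  pair_of_bot <- rep(NA_integer_, n_bot)  # axis (top, 0-based) index
  for (j in seq_len(n_bot)) {
    comp <- which(top$base == .COMPLEMENT[bot$base[j]])
    if (!length(comp)) next
    d <- sqrt(rowSums((top$rep_xyz[comp, , drop = FALSE] -
                         matrix(bot$rep_xyz[j, ], length(comp), 3,
                                byrow = TRUE))^2))
    if (min(d) <= pair_cutoff) pair_of_bot[j] <- comp[which.min(d)] - 1L
  }
  paired <- which(!is.na(pair_of_bot))
  if (length(paired) < 2L || any(diff(pair_of_bot[paired]) >= 0)) {
    stop("cannot establish an antiparallel duplex pairing from geometry")
  }

  # assign each ion to its nearest P (ties: lower residue number, then the
  # first dna chain); collect the best (closest) cut per strand
  strand_cut <- c(top = NA_integer_, bottom = NA_integer_)
  strand_best <- c(top = Inf, bottom = Inf)
  p_rows <- which(at$chain %in% dna_chains & at$name == "P")
  for (i in ions) {
    if (!length(p_rows)) break
    d <- sqrt((at$x[p_rows] - at$x[i])^2 + (at$y[p_rows] - at$y[i])^2 +
                (at$z[p_rows] - at$z[i])^2)
    ord <- order(d, at$resno[p_rows], match(at$chain[p_rows], dna_chains))
    best <- ord[1]
    if (d[best] > p_cutoff) {
      warning("ion at serial ", at$serial[i], " has no phosphorus within ",
              p_cutoff, " A; skipped")
      next
    }
    row <- p_rows[best]
    side <- if (at$chain[row] == dna_chains[1]) "top" else "bottom"
    nuc <- if (side == "top") top else bot
    k <- match(at$resno[row], nuc$resno) - 1L  # 0-based nucleotide index
    if (d[best] < strand_best[side]) {
      strand_best[side] <- d[best]
      strand_cut[side] <- k
    }
  }

  if (anyNA(strand_cut)) {
    warning("fewer than one cut per strand; incomplete cleavage call")
    return(structure(list(cut_top = unname(strand_cut["top"]),
                          cut_bottom = unname(strand_cut["bottom"]),
                          overhang_length = NA_integer_,
                          overhang_sequence = NA_character_,
                          end_type = NA_character_,
                          recognition_motif = recognition_motif,
                          incomplete = TRUE),
                     class = "cleavage_call"))
  }

  a <- unname(strand_cut["top"])     # top-strand bond index = axis coordinate
  b <- unname(strand_cut["bottom"])  # bottom-strand bond index
  # bond b sits 5' of bottom nucleotide b; on the axis it lies just 3' (in
  # top coordinates) of the position paired with bottom nucleotide b
  axis_b <- if (b < n_bot && !is.na(pair_of_bot[b + 1L])) {
    pair_of_bot[b + 1L] + 1L
  } else if (b > 0 && !is.na(pair_of_bot[b])) {
    pair_of_bot[b]
  } else {
    stop("bottom-strand cut lies outside the paired duplex region")
  }
  offset <- axis_b - a
  len <- abs(offset)
  end_type <- if (offset > 0) "five_prime_overhang"
  else if (offset < 0) "three_prime_overhang"
  else "blunt"
  ov_seq <- if (len == 0) "" else {
    idx <- seq(min(a, axis_b) + 1L, max(a, axis_b))  # 1-based top positions
    paste(top$base[idx], collapse = "")
  }
  structure(list(cut_top = a, cut_bottom = b, overhang_length = len,
                 overhang_sequence = ov_seq, end_type = end_type,
                 recognition_motif = recognition_motif, incomplete = FALSE),
            class = "cleavage_call")
}

#' @export
print.cleavage_call <- function(x, ...) {
  if (isTRUE(x$incomplete)) {
    cat("cleavage_call: incomplete (missing cut on one strand)\n")
  } else {
    cat(sprintf(
      "cleavage_call: top bond %d / bottom bond %d -> %s, overhang %d nt%s\n",
      x$cut_top, x$cut_bottom, x$end_type, x$overhang_length,
      if (nzchar(x$overhang_sequence)) paste0(" (", x$overhang_sequence, ")")
      else ""))
  }
  invisible(x)
}
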