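# Synthetic structural fixtures: free-atom sphere sets, toy two-component
# complexes with a planted contact patch, and idealized B-DNA duplexes with
# positioned catalytic ions. All generators are pure functions of their
# arguments (and seed), so outputs are byte-identical across runs.

.new_atoms <- function(n) {
  data.frame(serial = integer(n), name = character(n), element = character(n),
             resname = character(n), chain = character(n), resno = integer(n),
             insert = rep(NA_character_, n), x = numeric(n), y = numeric(n),
             z = numeric(n), occupancy = rep(1, n),
             confidence = rep(90, n), stringsAsFactors = FALSE)
}

#' Free-standing atom fixture for SASA oracles
#'
#' @param elements character vector of element symbols.
#' @param positions n x 3 matrix of coordinates (Angstrom).
#' @param confidence per-atom confidence value.
#' @return a `structure_model` with a single ligand chain, one residue per
#'   atom.
#' @export
gen_sphere_fixture <- function(elements, positions, confidence = 90) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- length(elements)
  if (nrow(positions) != n) stop("elements and positions differ in length")
  at <- .new_atoms(n)
  at$serial <- seq_len(n)
  at$name <- toupper(elements)
  at$element <- toupper(elements)
  at$resname <- toupper(elements)
  at$chain <- "L"
  at$resno <- seq_len(n)
  at$x <- positions[, 1]; at$y <- positions[, 2]; at$z <- positions[, 3]
  at$confidence <- confidence
  structure_model(at, chains = c(L = "ligand"), name = "sphere_fixture")
}

#' Toy two-component complex with a planted contact patch
#'
#' Builds a "protein" plane of glycine CA atoms and a "dna" plane of DA C1'
#' atoms. The first `contact_atoms` atoms of the dna plane sit at van der
#' Waals contact distance (3.4 A) above their protein counterparts; the
#' rest sit at `separation`. With a large separation and zero contact atoms
#' the buried interface area is ~0.
#'
#' @param contact_atoms number of dna atoms placed in contact (>= 0).
#' @param separation z-offset (Angstrom) for the non-contact dna atoms.
#' @param seed deterministic jitter seed.
#' @param n_per_side atoms per square grid side for each component.
#' @return a `structure_model` with chains `P` (protein) and `D` (dna).
#' @export
gen_toy_complex <- function(contact_atoms = 6, separation = 100, seed = 1,
                            n_per_side = 4) {
  if (contact_atoms < 0) stop("contact_atoms must be >= 0")
  n <- n_per_side^2
  if (contact_atoms > n) stop("contact_atoms exceeds grid size ", n)
  set.seed(seed)
  g <- expand.grid(ix = seq_len(n_per_side), iy = seq_len(n_per_side))
  px <- g$ix * 5; py <- g$iy * 5
  jit <- matrix(runif(2 * n, -0.2, 0.2), ncol = 2)
  at_p <- .new_atoms(n)
  at_p$serial <- seq_len(n)
  at_p$name <- "CA"; at_p$element <- "C"; at_p$resname <- "GLY"
  at_p$chain <- "P"; at_p$resno <- seq_len(n)
  at_p$x <- px; at_p$y <- py; at_p$z <- 0
  at_d <- .new_atoms(n)
  at_d$serial <- n + seq_len(n)
  at_d$name <- "C1'"; at_d$element <- "C"; at_d$resname <- "DA"
  at_d$chain <- "D"; at_d$resno <- seq_len(n)
  at_d$x <- px + jit[, 1]; at_d$y <- py + jit[, 2]
  at_d$z <- ifelse(seq_len(n) <= contact_atoms, 3.4, separation)
  structure_model(rbind(at_p, at_d), chains = c(P = "protein", D = "dna"),
                  name = "toy_complex")
}

#' Idealized B-DNA duplex with positioned catalytic ions
#'
#' Builds a reduced-atom B-form duplex (helical rise 3.4 A, twist 36
#' degrees per base pair) with P, C1' and a base reference atom (N9 for
#' purines, N1 for pyrimidines) per nucleotide, plus the complementary
#' antiparallel strand. Mg ions can be placed at a radial offset from any
#' nucleotide's phosphorus, which is how cleavage-competent geometries are
#' staged for [infer_cleavage()].
#'
#' @param sequence top-strand sequence over ACGT, 5' to 3'.
#' @param place_ions list of `list(strand =, index =, offset =)` entries:
#'   strand `"top"`/`"bottom"`, 0-based nucleotide index on that strand's
#'   own 5'->3' axis, and the ion's radial offset (Angstrom) from that
#'   nucleotide's P atom.
#' @param confidence per-atom confidence written to the model.
#' @return a `structure_model` with dna chains `T` (top), `B` (bottom) and,
#'   if ions are placed, ion chain `M`; exactly `2 * nchar(sequence)`
#'   nucleotides.
#' @export
gen_bdna <- function(sequence, place_ions = list(), confidence = 90) {
  s <- toupper(sequence)
  bases <- strsplit(s, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    stop("sequence must contain only A, C, G, T")
  }
  n <- length(bases)
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  bot_bases <- rev(unname(comp[bases]))  # bottom strand 5'->3'
  rise <- 3.4; twist <- 36 * pi / 180
  r_p <- 8.9; r_c1 <- 5.9; r_base <- 2.0
  polar <- function(r, theta, z) c(r * cos(theta), r * sin(theta), z)

  rows <- list()
  add <- function(name, element, resname, chain, resno, xyz) {
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = 0L, name = name, element = element, resname = resname,
      chain = chain, resno = resno, insert = NA_character_,
      x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1,
      confidence = confidence, stringsAsFactors = FALSE)
  }
  base_ref <- function(b) if (b %in% c("A", "G")) "N9" else "N1"
  # top strand: nucleotide i (0-based) at angle i*twist, height i*rise
  for (i in seq_len(n) - 1L) {
    th <- i * twist; z <- i * rise
    add("P", "P", paste0("D", bases[i + 1]), "T", i + 1L,
        polar(r_p, th - 30 * pi / 180, z))
    add("C1'", "C", paste0("D", bases[i + 1]), "T", i + 1L,
        polar(r_c1, th, z))
    add(base_ref(bases[i + 1]), "N", paste0("D", bases[i + 1]), "T", i + 1L,
        polar(r_base, th, z))
  }
  # bottom strand nucleotide j pairs with top nucleotide n-1-j
  for (j in seq_len(n) - 1L) {
    i <- n - 1L - j
    th <- i * twist; z <- i * rise
    add("P", "P", paste0("D", bot_bases[j + 1]), "B", j + 1L,
        polar(r_p, th + 90 * pi / 180, z))
    add("C1'", "C", paste0("D", bot_bases[j + 1]), "B", j + 1L,
        polar(r_c1, th + 60 * pi / 180, z))
    add(base_ref(bot_bases[j + 1]), "N", paste0("D", bot_bases[j + 1]), "B",
        j + 1L, polar(r_base, th + 60 * pi / 180, z))
  }
  at <- do.call(rbind, rows)
  chains <- c(T = "dna", B = "dna")
  if (length(place_ions)) {
    for (k in seq_along(place_ions)) {
      pi_ <- place_ions[[k]]
      strand <- match.arg(pi_$strand, c("top", "bottom"))
      idx <- pi_$index
      if (idx < 0 || idx >= n) stop("ion placement index out of bounds")
      ch <- if (strand == "top") "T" else "B"
      prow <- at[at$chain == ch & at$resno == idx + 1L & at$name == "P", ]
      p_xyz <- as.numeric(prow[1, c("x", "y", "z")])
      radial <- c(p_xyz[1], p_xyz[2], 0)
      radial <- radial / sqrt(sum(radial^2))
      ion_xyz <- p_xyz + pi_$offset * radial
      at <- rbind(at, data.frame(
        serial = 0L, name = "MG", element = "MG", resname = "MG",
        chain = "M", resno = k, insert = NA_character_,
        x = ion_xyz[1], y = ion_xyz[2], z = ion_xyz[3], occupancy = 1,
        confidence = confidence, stringsAsFactors = FALSE))
    }
    chains <- c(chains, M = "ion")
  }
  at$serial <- seq_len(nrow(at))
  structure_model(at, chains = chains, name = "bdna")
}
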