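# Fixture builders and independent oracles used across the suite.

# Build an atom table row-by-row; columns match structure_model().
make_atoms <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(serial = i, name = r$name, element = r$element,
               resname = r$resname, chain = r$chain, resno = r$resno,
               insert = NA_character_,
               x = r$xyz[1], y = r$xyz[2], z = r$xyz[3],
               occupancy = 1,
               confidence = if (is.null(r$conf)) 90 else r$conf,
               stringsAsFactors = FALSE)
  }))
  df
}

atom <- function(name, element, resname, chain, resno, xyz, conf = NULL) {
  list(name = name, element = element, resname = resname, chain = chain,
       resno = resno, xyz = xyz, conf = conf)
}

# Independent plain-loop Shrake-Rupley used as the point-level oracle for
# the vectorised engine (same lattice definition, naive point-by-point
# occlusion test).
oracle_sasa <- function(coords, radii, probe = 1.4, n_points = 960) {
  i_seq <- seq_len(n_points) - 1
  z <- 1 - 2 * (i_seq + 0.5) / n_points
  phi <- i_seq * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  n <- nrow(coords)
  area <- numeric(n)
  for (i in seq_len(n)) {
    Ri <- radii[i] + probe
    n_acc <- 0L
    for (p in seq_len(n_points)) {
      pt <- coords[i, ] + Ri * pts[p, ]
      ok <- TRUE
      for (j in seq_len(n)) {
        if (j == i) next
        Rj <- radii[j] + probe
        if (sum((pt - coords[j, ])^2) < Rj^2) { ok <- FALSE; break }
      }
      if (ok) n_acc <- n_acc + 1L
    }
    area[i] <- n_acc / n_points * 4 * pi * Ri^2
  }
  area
}

# Brute-force all-pairs hydrogen-bond scan using the package's own
# donor/acceptor role tables but an independent double loop.
oracle_hbonds <- function(model, threshold = 3.5, mode = "inter_entity") {
  at <- model$atoms[model$atoms$element != "H", , drop = FALSE]
  roles <- magtaq:::.hbond_roles(at, model$chains)
  cls <- model$chains[at$chain]
  hits <- list()
  for (d in which(roles$donor)) {
    for (a in which(roles$acceptor)) {
      if (d == a) next
      if (at$chain[d] == at$chain[a] && at$resno[d] == at$resno[a]) next
      if (mode == "inter_entity") {
        pair <- sort(unname(c(cls[d], cls[a])))
        if (!identical(pair, c("dna", "protein"))) next
      }
      dist <- sqrt(sum((unlist(at[d, c("x", "y", "z")]) -
                          unlist(at[a, c("x", "y", "z")]))^2))
      if (dist <= threshold) {
        hits[[length(hits) + 1L]] <- data.frame(
          donor_chain = at$chain[d], donor_resno = at$resno[d],
          donor_atom = at$name[d], acceptor_chain = at$chain[a],
          acceptor_resno = at$resno[a], acceptor_atom = at$name[a],
          distance = dist, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(donor_chain = character(), donor_resno = integer(),
                      donor_atom = character(), acceptor_chain = character(),
                      acceptor_resno = integer(), acceptor_atom = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$distance, out$donor_chain, out$donor_resno,
                   out$donor_atom, out$acceptor_chain, out$acceptor_resno,
                   out$acceptor_atom), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random mixed protein/DNA fixture for the hbond oracle comparison.
random_hbond_fixture <- function(n_atoms = 50, seed = 1) {
  set.seed(seed)
  prot_res <- c("SER", "LYS", "ASP", "ASN", "GLY", "ARG", "GLU", "THR")
  prot_atoms <- c("N", "O", "OG", "NZ", "OD1", "OD2", "ND2", "CA", "CB",
                  "NE", "OE1", "OG1")
  dna_res <- c("DA", "DT", "DG", "DC")
  dna_atoms <- c("N1", "N2", "N3", "N6", "N7", "O2", "O4", "O6", "N4",
                 "OP1", "OP2", "P", "C1'")
  rows <- lapply(seq_len(n_atoms), function(i) {
    if (runif(1) < 0.5) {
      nm <- sample(prot_atoms, 1)
      atom(nm, substr(nm, 1, 1), sample(prot_res, 1), "A", i,
           runif(3, 0, 12))
    } else {
      nm <- sample(dna_atoms, 1)
      atom(nm, substr(nm, 1, 1), sample(dna_res, 1), "B", i,
           runif(3, 0, 12))
    }
  })
  at <- do.call(make_atoms, rows)
  structure_model(at, chains = c(A = "protein", B = "dna"), name = "rand")
}

# 3D rotation matrix from an axis and angle (for rigid-motion invariance).
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle); C <- 1 - c_
  matrix(c(a[1]^2 * C + c_, a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
           a[1] * a[2] * C + a[3] * s, a[2]^2 * C + c_, a[2] * a[3] * C - a[1] * s,
           a[1] * a[3] * C - a[2] * s, a[2] * a[3] * C + a[1] * s, a[3]^2 * C + c_),
         3, 3, byrow = TRUE)
}

rigid_transform_model <- function(model, R, t) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  model$atoms$x <- xyz[, 1] + t[1]
  model$atoms$y <- xyz[, 2] + t[2]
  model$atoms$z <- xyz[, 3] + t[3]
  model
}

# One simulated isolate with a fixed event template; returns truth plus
# everything the caller needs. Used by the recovery property and the
# orchestration tests.
simulate_isolate <- function(seed, coverage = 30) {
  g <- gen_hybrid_genome(n_chromosomes = 4, chrom_length = 120000,
                         divergence = 0.007, seed = seed)
  repeats <- data.frame(chrom = "chr02", start = 20000, end = 23000,
                        name = "Ty")
  events <- list(
    list(klass = "SGC", chrom = "chr01", start = 40000, end = 70000,
         haplotype = "p1"),
    list(klass = "BIR", chrom = "chr02", start = 80000, end = 120000,
         haplotype = "p2"),
    list(klass = "aneuploidy", chrom = "chr03", subtype = "gain",
         haplotype = "p1"),
    list(klass = "NMTL", chrom_a = "chr01", pos_a = 100000,
         chrom_b = "chr04", pos_b = 30000))
  st <- implant_events(g, events, coverage = coverage, seed = seed + 1000,
                       repeats = repeats)
  list(genome = g, sim = st, repeats = repeats)
}

reciprocal_overlap_frac <- function(s1, e1, s2, e2) {
  ov <- min(e1, e2) - max(s1, s2) + 1
  if (ov <= 0) return(0)
  min(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}
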