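# Shrake-Rupley solvent-accessible surface area with a deterministic
# golden-spiral point set, and buried-interface metrics built on it.

.DEFAULT_VDW <- c(C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
                  MG = 1.73, H = 1.20)
.FALLBACK_VDW <- 1.70

#' SASA parameters
#'
#' @param probe_radius solvent probe radius in Angstrom (water, 1.4).
#' @param n_sphere_points number of test points per atom sphere (>= 12);
#'   the point set is a fixed golden-spiral lattice, so results are
#'   bit-reproducible for a given count.
#' @param radius_table named vector of van der Waals radii (Angstrom) by
#'   element symbol; elements absent from the table fall back to 1.70 with
#'   a warning.
#' @param include_hydrogens keep hydrogen atoms in the calculation
#'   (predicted models are usually hydrogen-free, so the default drops them).
#' @return A list of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, n_sphere_points = 960,
                        radius_table = .DEFAULT_VDW,
                        include_hydrogens = FALSE) {
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (n_sphere_points < 12) stop("n_sphere_points must be >= 12")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 radius_table = radius_table,
                 include_hydrogens = include_hydrogens),
            class = "sasa_params")
}

# Deterministic golden-spiral unit sphere lattice, fixed ordering.
.sphere_points <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

.atom_radii <- function(elements, radius_table) {
  r <- unname(radius_table[elements])
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("no van der Waals radius for element(s) ",
            paste(unique(elements[unknown]), collapse = ", "),
            "; using fallback ", .FALLBACK_VDW, " A")
    r[unknown] <- .FALLBACK_VDW
  }
  r
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For every atom, a golden-spiral lattice of points is placed on the sphere
#' of radius (vdW + probe); points not occluded by any neighbouring atom's
#' expanded sphere are accessible, and the atom's SASA is the accessible
#' fraction times the full sphere area.
#'
#' @param model a `structure_model`.
#' @param params a [sasa_params()] object.
#' @return list with `area` (per-atom SASA, Angstrom^2, aligned to the rows
#'   of `atoms`), `total`, and `atoms` (the atom table actually used, after
#'   any hydrogen filtering).
#' @export
compute_sasa <- function(model, params = sasa_params()) {
  if (!inherits(model, "structure_model")) stop("not a structure_model")
  at <- model$atoms
  if (!params$include_hydrogens) at <- at[at$element != "H", , drop = FALSE]
  if (nrow(at) == 0L) stop("no atoms left for SASA computation")
  coords <- as.matrix(at[, c("x", "y", "z")])
  R <- .atom_radii(at$element, params$radius_table) + params$probe_radius
  n <- nrow(at)
  pts <- .sphere_points(params$n_sphere_points)
  area <- numeric(n)
  # pairwise squared distances between atom centres
  d2 <- as.matrix(dist(coords))^2
  for (i in seq_len(n)) {
    cutoff2 <- (R[i] + R)^2
    nb <- which(d2[i, ] < cutoff2)
    nb <- nb[nb != i]
    sphere <- sweep(pts * R[i], 2, coords[i, ], "+")
    accessible <- rep(TRUE, nrow(sphere))
    for (j in nb) {
      idx <- which(accessible)
      if (!length(idx)) break
      dx <- sphere[idx, 1] - coords[j, 1]
      dy <- sphere[idx, 2] - coords[j, 2]
      dz <- sphere[idx, 3] - coords[j, 3]
      blocked <- (dx * dx + dy * dy + dz * dz) < R[j]^2
      accessible[idx[blocked]] <- FALSE
    }
    area[i] <- mean(accessible) * 4 * pi * R[i]^2
  }
  list(area = area, total = sum(area), atoms = at)
}

#' Buried surface area between two chain groups
#'
#' The buried (interface) area is the SASA lost on complex formation:
#' `sasa(A) + sasa(B) - sasa(A+B)`, each part computed with the other part's
#' atoms removed. Per-residue burial localises the interface.
#'
#' @param model a `structure_model` containing both parts.
#' @param part_a_chains,part_b_chains disjoint chain-id vectors.
#' @param params a [sasa_params()].
#' @param min_residue_burial report residues burying at least this many
#'   Angstrom^2 as interface residues.
#' @return An object of class `interface_metrics`: `sasa_complex`,
#'   `sasa_part_a`, `sasa_part_b`, `buried_area` (>= 0 for contacting
#'   parts, up to point-sampling tolerance) and `interface_residues`
#'   (data.frame chain/resno/buried).
#' @export
buried_surface_area <- function(model, part_a_chains, part_b_chains,
                                params = sasa_params(),
                                min_residue_burial = 0.1) {
  if (length(intersect(part_a_chains, part_b_chains))) {
    stop("part_a and part_b chain sets overlap")
  }
  sub_a <- subset_chains(model, part_a_chains)
  sub_b <- subset_chains(model, part_b_chains)
  sub_ab <- subset_chains(model, c(part_a_chains, part_b_chains))
  s_a <- compute_sasa(sub_a, params)
  s_b <- compute_sasa(sub_b, params)
  s_ab <- compute_sasa(sub_ab, params)
  buried <- s_a$total + s_b$total - s_ab$total

  # per-atom burial: isolated minus in-complex, matched on atom identity
  akey <- function(at) paste(at$chain, at$resno, at$name, sep = "\r")
  iso_area <- c(s_a$area, s_b$area)
  names(iso_area) <- c(akey(s_a$atoms), akey(s_b$atoms))
  cplx_key <- akey(s_ab$atoms)
  atom_burial <- iso_area[cplx_key] - s_ab$area
  res_key <- paste(s_ab$atoms$chain, s_ab$atoms$resno, sep = "\r")
  res_burial <- tapply(atom_burial, res_key, sum)
  first <- !duplicated(res_key)
  res_df <- data.frame(chain = s_ab$atoms$chain[first],
                       resno = s_ab$atoms$resno[first],
                       buried = as.numeric(res_burial[res_key[first]]),
                       stringsAsFactors = FALSE)
  res_df <- res_df[res_df$buried >= min_residue_burial, , drop = FALSE]
  res_df <- res_df[order(res_df$chain, res_df$resno), , drop = FALSE]
  rownames(res_df) <- NULL
  structure(list(sasa_complex = s_ab$total,
                 sasa_part_a = s_a$total,
                 sasa_part_b = s_b$total,
                 buried_area = buried,
                 interface_residues = res_df),
            class = "interface_metrics")
}

#' @export
print.interface_metrics <- function(x, ...) {
  cat(sprintf(paste0("interface_metrics: complex %.1f A^2, parts %.1f + %.1f",
                     " A^2, buried %.1f A^2 (%d interface residues)\n"),
              x$sasa_complex, x$sasa_part_a, x$sasa_part_b, x$buried_area,
              nrow(x$interface_residues)))
  invisible(x)
}
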