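# Sequence-composition utilities and the D6 double-ring coordinate
# builder for the toroidal particle.

#' Average residue masses
#'
#' Frozen table of average (isotope-abundance-weighted) residue masses
#' in daltons, i.e. the free amino-acid mass minus one water; a peptide
#' of n residues weighs the sum of its residue masses plus one water
#' (18.0153 Da). Average rather than monoisotopic masses are used to
#' match light-scattering-scale molecular-mass comparisons.
#'
#' @format Named numeric vector over the 20 canonical one-letter codes.
#' @export
residue_masses <- c(
  A =  71.0779, R = 156.1857, N = 114.1026, D = 115.0874, C = 103.1429,
  E = 129.1140, Q = 128.1292, G =  57.0513, H = 137.1393, I = 113.1576,
  L = 113.1576, K = 128.1723, M = 131.1961, F = 147.1739, P =  97.1152,
  S =  87.0773, T = 101.1039, V =  99.1311, W = 186.2099, Y = 163.1733)

.water_mass <- 18.0153

#' Average molecular mass of a protein sequence
#'
#' Sum of standard average residue masses plus one water. Non-canonical
#' letters are rejected with the offending position named.
#'
#' @param seq One-letter amino-acid sequence (character scalar, 20
#'   canonical letters, nonempty; case-insensitive).
#' @return Molecular mass, Da.
#' @examples
#' average_mass("G")  # glycine: 75.07 Da
#' @export
average_mass <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) abort("Empty sequence.")
  letters1 <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!letters1 %in% names(residue_masses))
  if (length(bad))
    abort(sprintf("Non-canonical residue '%s' at position %d.",
                  letters1[bad[1]], bad[1]))
  sum(residue_masses[letters1]) + .water_mass
}

#' Mass of a non-covalent oligomer
#'
#' `n` times the monomer mass; association adds no mass correction.
#'
#' @param monomer Monomer mass, Da.
#' @param n Number of subunits (integer >= 1).
#' @return Oligomer mass, Da.
#' @examples
#' oligomer_mass(7332.5, 6)   # hexamer, ~44 kDa
#' @export
oligomer_mass <- function(monomer, n) {
  if (any(n < 1)) abort("`n` must be >= 1.")
  monomer * n
}

#' Read protein sequences from FASTA or plain text
#'
#' @param path FASTA file path.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    abort("Reading FASTA requires the Biostrings package.")
  ss <- Biostrings::readAAStringSet(path)
  tibble(id = names(ss), seq = as.character(ss))
}

#' Toroid geometry specification
#'
#' Dimensions of the double-ring toroidal particle: two stacked
#' hexameric rings of monomer placeholders, packed head to head with a
#' rotational stagger. Defaults follow the reconstructed particle:
#' ~65 A wide (outer diameter), ~55 A high, ~15 A axial channel, ~5 A
#' inter-ring gap, rings rotated by ~30 degrees.
#'
#' @param n_per_ring Monomers per ring (>= 2). Default 6.
#' @param rings Number of stacked rings. Default 2.
#' @param outer_diameter,height,channel_diameter,inter_ring_gap Lengths
#'   in angstroms (all > 0; channel < outer).
#' @param stagger_deg Rotation of the second ring, degrees. Default 30
#'   (= half the inter-subunit angle for a hexamer, giving full D6
#'   symmetry).
#' @return An object of class `toroid_spec`.
#' @export
toroid_spec <- function(n_per_ring = 6L, rings = 2L, outer_diameter = 65,
                        height = 55, channel_diameter = 15,
                        inter_ring_gap = 5, stagger_deg = 30) {
  if (n_per_ring < 2L) abort("`n_per_ring` must be >= 2.")
  lens <- c(outer_diameter, height, channel_diameter, inter_ring_gap)
  if (any(lens <= 0)) abort("All lengths must be positive.")
  if (channel_diameter >= outer_diameter)
    abort("Geometrically impossible: channel must be narrower than the particle.")
  structure(list(n_per_ring = as.integer(n_per_ring),
                 rings = as.integer(rings),
                 outer_diameter = outer_diameter, height = height,
                 channel_diameter = channel_diameter,
                 inter_ring_gap = inter_ring_gap,
                 stagger_deg = stagger_deg),
            class = "toroid_spec")
}

#' Build D6 double-ring pseudo-atom coordinates
#'
#' Places one coarse monomer placeholder (a small fixed set of
#' pseudo-atoms spanning the monomer envelope; no side-chain model) at
#' each of `n_per_ring` positions per ring, at radius
#' `(outer + channel)/4` from the principal (z) axis; rings sit at
#' +/- (gap/2 + monomer half-height) and the second ring is rotated by
#' the stagger angle. By construction the set is invariant under
#' rotation by `360/n_per_ring` degrees about z, and with the default
#' stagger (half the inter-subunit angle) it carries the perpendicular
#' two-fold axes of the dihedral point group (axes at
#' `stagger/2 + k*stagger` degrees).
#'
#' @param spec A [toroid_spec()].
#' @return An object of class `d6_toroid`: list with `coords` (tibble
#'   `chain`, `atom`, `x`, `y`, `z` in angstroms; chains `A`-`L`,
#'   right-handed axes, principal axis = z) and `spec`.
#' @examples
#' tor <- build_d6_toroid(toroid_spec())
#' range(tor$coords$z)   # spans the particle height
#' @export
build_d6_toroid <- function(spec = toroid_spec()) {
  stopifnot(inherits(spec, "toroid_spec"))
  n <- spec$n_per_ring
  ring_radius <- (spec$outer_diameter + spec$channel_diameter) / 4
  radial_off <- (spec$outer_diameter - spec$channel_diameter) / 4
  half_h <- (spec$height - spec$inter_ring_gap) / 4
  z_center <- spec$inter_ring_gap / 2 + half_h
  tang_off <- 0.9 * ring_radius * sin(pi / n)
  # local pseudo-atom offsets (radial u, tangential v, axial w); the
  # +/- pairs make the placeholder symmetric under the ring two-folds
  local <- rbind(c(0, 0, 0),
                 c(radial_off, 0, 0), c(-radial_off, 0, 0),
                 c(0, tang_off, 0), c(0, -tang_off, 0),
                 c(0, 0, half_h), c(0, 0, -half_h))
  chains <- LETTERS[seq_len(n * spec$rings)]
  rows <- list()
  k <- 0L
  for (ring in seq_len(spec$rings)) {
    zc <- if (ring == 1L) z_center else -z_center
    phi0 <- if (ring == 1L) 0 else spec$stagger_deg * pi / 180
    for (j in seq_len(n)) {
      k <- k + 1L
      phi <- phi0 + (j - 1L) * 2 * pi / n
      u <- c(cos(phi), sin(phi), 0)
      v <- c(-sin(phi), cos(phi), 0)
      w <- c(0, 0, 1)
      center <- ring_radius * u + c(0, 0, zc)
      xyz <- t(apply(local, 1L, function(o)
        center + o[1] * u + o[2] * v + o[3] * w))
      rows[[k]] <- tibble(chain = chains[k],
                          atom = seq_len(nrow(local)),
                          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    }
  }
  structure(list(coords = bind_rows(rows), spec = spec),
            class = "d6_toroid")
}

#' Symmetry deviation of a toroid under a point-group transform
#'
#' Applies a rotation about the principal axis (`angle_deg`) or a
#' two-fold rotation about an in-plane axis at `axis_angle_deg`
#' (`c2 = TRUE`), and returns the RMSD between the transformed
#' pseudo-atoms and their nearest originals. Exact symmetry gives 0 to
#' floating-point precision.
#'
#' @param toroid A `d6_toroid` from [build_d6_toroid()].
#' @param angle_deg Rotation about z, degrees (ignored if `c2`).
#' @param c2 Apply an in-plane two-fold instead?
#' @param axis_angle_deg Azimuth of the two-fold axis, degrees.
#' @return RMSD in angstroms.
#' @export
toroid_symmetry_rmsd <- function(toroid, angle_deg = 60, c2 = FALSE,
                                 axis_angle_deg = 0) {
  xyz <- as.matrix(toroid$coords[, c("x", "y", "z")])
  rotz <- function(a) {
    c_ <- cos(a); s_ <- sin(a)
    matrix(c(c_, -s_, 0, s_, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  }
  M <- if (c2) {
    phi <- axis_angle_deg * pi / 180
    rotz(phi) %*% diag(c(1, -1, -1)) %*% rotz(-phi)
  } else {
    rotz(angle_deg * pi / 180)
  }
  moved <- xyz %*% t(M)
  d2 <- apply(moved, 1L, function(p)
    min(colSums((t(xyz) - p)^2)))
  sqrt(mean(d2))
}

#' Write toroid coordinates as a PDB file
#'
#' One placeholder pseudo-atom per row (CA records), chains `A`-`L`,
#' one TER per chain, no heteroatoms.
#'
#' @param toroid A `d6_toroid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_toroid_pdb <- function(toroid, path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    abort("Writing PDB requires the bio3d package.")
  co <- toroid$coords
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(co[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(co)),
                   resno = co$atom, resid = rep("ALA", nrow(co)),
                   elety = rep("CA", nrow(co)), chain = co$chain)
  invisible(path)
}
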