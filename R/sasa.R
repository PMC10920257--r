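## Solvent-accessible surface area, Shrake-Rupley.
##
## Deterministic: a fixed golden-spiral point set (default 960 points per
## atom) is rolled over heavy atoms only, with an element-based van der Waals
## radii table and the standard 1.4-Angstrom water probe.

.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)

# Extended Gly-X-Gly maximal per-residue SASA (Angstrom^2), Miller-style
# reference values; denominator of the 5% surface-exposure threshold.
.max_sasa_gxg <- c(
  ALA = 113, ARG = 241, ASN = 158, ASP = 151, CYS = 140,
  GLN = 189, GLU = 183, GLY =  85, HIS = 194, ILE = 182,
  LEU = 180, LYS = 211, MET = 204, PHE = 218, PRO = 143,
  SER = 122, THR = 146, TRP = 259, TYR = 229, VAL = 160)

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(phi) * cos(theta),
        y = sin(phi) * sin(theta),
        z = cos(phi))
}

.element_of <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    elesy <- toupper(trimws(elesy))
    elesy[is.na(elesy)] <- ""
  } else {
    elesy <- rep("", length(elety))
  }
  guess <- toupper(substr(sub("^[0-9 ]*", "", elety), 1L, 1L))
  el <- ifelse(nzchar(elesy), elesy, guess)
  # selenium (MSE) treated with the sulfur radius
  el[el == "SE"] <- "S"
  el[!el %in% names(.vdw_radii)] <- substr(el[!el %in% names(.vdw_radii)], 1, 1)
  el
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes the accessible area of each atom by placing a deterministic
#' golden-spiral point set on each atom's solvent-expanded sphere
#' (van der Waals radius + probe radius) and counting the points not buried
#' inside any neighbouring atom's expanded sphere.
#'
#' @param xyz Numeric matrix (n x 3) of heavy-atom coordinates in Angstrom.
#' @param elements Character vector of element symbols (C, N, O, S, P).
#'   Unknown elements fall back to the carbon radius with a warning.
#' @param probe_radius Probe sphere radius in Angstrom (default 1.4, water).
#' @param n_points Number of sphere sample points per atom (default 960).
#' @param radii Named van der Waals radii table in Angstrom.
#' @return Numeric vector of per-atom accessible areas in Angstrom^2.
#' @export
sasa_atoms <- function(xyz, elements, probe_radius = 1.4, n_points = 960,
                       radii = .vdw_radii) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n == 0L) stop("no atoms: cannot compute SASA on an empty structure")
  stopifnot(ncol(xyz) == 3L, length(elements) == n,
            probe_radius > 0, n_points >= 12)
  unknown <- !elements %in% names(radii)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(elements[unknown]),
            collapse = ", "), "; using carbon radius")
    elements[unknown] <- "C"
  }
  r <- radii[elements] + probe_radius
  pts0 <- .sphere_points(n_points)
  area <- numeric(n)
  # neighbour candidates: centre distance below the sum of expanded radii
  rmax <- max(r)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ], `-`)^2)
    nbr <- which(d2 < (r[i] + r)^2 & seq_len(n) != i)
    pts <- sweep(pts0 * r[i], 2, xyz[i, ], `+`)
    if (length(nbr)) {
      ctr <- xyz[nbr, , drop = FALSE]
      # squared distances point-to-neighbour-centre, one BLAS product
      d2m <- matrix(rowSums(pts^2), n_points, length(nbr)) +
        matrix(rowSums(ctr^2), n_points, length(nbr), byrow = TRUE) -
        2 * pts %*% t(ctr)
      buried <- d2m < matrix(r[nbr]^2, n_points, length(nbr), byrow = TRUE)
      acc <- rowSums(buried) == 0L
    } else {
      acc <- rep(TRUE, n_points)
    }
    area[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  unname(area)
}

#' Fill per-residue SASA on an antigen structure
#'
#' Sums heavy-atom accessible areas per residue ([sasa_atoms()]). All atoms of
#' the structure (including non-standard polymer residues) occlude; hydrogens
#' are ignored at parse time.
#'
#' @param structure An `antigen` object from [read_antigen()].
#' @param probe_radius,n_points,radii Passed to [sasa_atoms()].
#' @return The structure with `residues$sasa` (and per-atom `atoms$sasa`)
#'   filled.
#' @export
#' @examples
#' fx <- make_toy_antigen(length = 8, geometry = "extended", seed = 1)
#' ant <- read_antigen(text = fx$pdb)
#' ant <- compute_sasa(ant)
#' head(ant$residues[, c("key", "resid", "sasa")])
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 960,
                         radii = .vdw_radii) {
  stopifnot(inherits(structure, "antigen"))
  at <- structure$atoms
  if (nrow(at) == 0L) stop("empty structure: no atoms to compute SASA on")
  a <- sasa_atoms(cbind(at$x, at$y, at$z), at$element,
                  probe_radius = probe_radius, n_points = n_points,
                  radii = radii)
  structure$atoms$sasa <- a
  per <- tapply(a, at$key, sum)
  res <- structure$residues
  res$sasa <- as.numeric(per[res$key])
  res$sasa[is.na(res$sasa)] <- 0
  structure$residues <- res
  structure$probe_radius <- probe_radius
  structure
}

#' Select solvent-exposed (surface) residues
#'
#' A residue is on the surface when its SASA strictly exceeds `fraction`
#' (default 5%) of its maximal SASA, the reference accessibility of the
#' residue type in an extended Gly-X-Gly tripeptide.
#'
#' @param structure An `antigen` with SASA computed ([compute_sasa()]).
#' @param fraction Exposure threshold as a fraction of maximal SASA.
#' @param max_sasa Named per-residue-type (three-letter code) maximal SASA
#'   table in Angstrom^2.
#' @return Character vector of surface residue keys. Residue types absent
#'   from `max_sasa` are excluded with a warning.
#' @export
select_surface_residues <- function(structure, fraction = 0.05,
                                    max_sasa = .max_sasa_gxg) {
  stopifnot(inherits(structure, "antigen"), fraction >= 0)
  res <- structure$residues
  if (all(is.na(res$sasa)))
    stop("SASA not computed; call compute_sasa() first")
  mx <- max_sasa[res$resid]
  if (anyNA(mx)) {
    miss <- unique(res$resid[is.na(mx)])
    warning("no maximal-SASA reference for residue type(s) ",
            paste(miss, collapse = ", "), "; excluded from the surface set")
  }
  keys <- res$key[!is.na(mx) & res$sasa > fraction * mx]
  keys
}
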