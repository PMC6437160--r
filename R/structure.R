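# Static-structure solvent-accessible surface area (Shrake-Rupley), with a
# minimal fixed-width PDB reader. Intended for the heme-exposure observable;
# MD-ensemble SASA is out of scope.

# van der Waals radii (Angstrom); standard values.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, FE = 2.00,
               H = 1.20, P = 1.80)
DEFAULT_RADIUS <- 1.70

#' Parse a PDB file or text into an atom table
#'
#' Reads ATOM/HETATM records (fixed-width columns). The element comes from
#' columns 77-78 when present, otherwise from the atom name. Alternate
#' locations keep the highest occupancy (ties resolve to altloc 'A').
#'
#' @param pdb Path to a PDB file, or a character vector of record lines.
#' @return A `pdb_structure` data.frame: `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resno`, `x`, `y`, `z`, `occupancy`, `element`,
#'   `radius`, `element_known`.
#' @export
parse_structure <- function(pdb) {
  lines <- if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    readLines(pdb)
  } else {
    unlist(strsplit(pdb, "\n", fixed = TRUE))
  }
  rec <- lines[startsWith(lines, "ATOM") | startsWith(lines, "HETATM")]
  if (!length(rec)) stop_input("no ATOM/HETATM records found")
  fx <- function(l, a, b) substr(l, a, b)
  num <- function(s, what, ln) {
    v <- suppressWarnings(as.numeric(s))
    if (any(bad <- is.na(v) & nzchar(trimws(s)) | is.na(v))) {
      stop_input("malformed %s in PDB record at line %d", what, ln[bad][1])
    }
    v
  }
  lnos <- match(rec, lines)
  wide <- nchar(rec) >= 54
  if (any(!wide)) {
    stop_input("malformed fixed-width record at line %d", lnos[!wide][1])
  }
  at <- data.frame(
    serial = num(fx(rec, 7, 11), "serial", lnos),
    name = trimws(fx(rec, 13, 16)),
    altloc = fx(rec, 17, 17),
    resname = trimws(fx(rec, 18, 20)),
    chain = fx(rec, 22, 22),
    resno = num(fx(rec, 23, 26), "residue number", lnos),
    x = num(fx(rec, 31, 38), "x", lnos),
    y = num(fx(rec, 39, 46), "y", lnos),
    z = num(fx(rec, 47, 54), "z", lnos),
    occupancy = ifelse(nchar(rec) >= 60,
                       suppressWarnings(as.numeric(fx(rec, 55, 60))), 1),
    element = toupper(trimws(ifelse(nchar(rec) >= 78, fx(rec, 77, 78), ""))),
    stringsAsFactors = FALSE
  )
  at$occupancy[is.na(at$occupancy)] <- 1
  # element fallback from the atom name: first alphabetic character(s)
  guess <- toupper(sub("^[0-9 ]*([A-Za-z]+).*$", "\\1", at$name))
  two <- substr(guess, 1, 2)
  g <- ifelse(two %in% names(VDW_RADII), two, substr(guess, 1, 1))
  at$element <- ifelse(nzchar(at$element), at$element, g)
  at$element_known <- at$element %in% names(VDW_RADII)
  at$radius <- ifelse(at$element_known, VDW_RADII[at$element], DEFAULT_RADIUS)
  # altloc resolution
  if (any(at$altloc != " ")) {
    key <- paste(at$name, at$resname, at$chain, at$resno)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(idx) {
      if (length(idx) == 1L) return(idx)
      occ <- at$occupancy[idx]
      best <- idx[occ == max(occ)]
      if (length(best) > 1L) {
        a <- best[at$altloc[best] == "A"]
        best <- if (length(a)) a[1] else best[1]
      }
      best
    }))
    at <- at[sort(keep), , drop = FALSE]
  }
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    stop_input("non-finite coordinates")
  }
  rownames(at) <- NULL
  class(at) <- c("pdb_structure", "data.frame")
  at
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) - 1)            # golden angle
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- phi * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples `n_points` deterministic Fibonacci-lattice points on each atom's
#' probe-expanded sphere and counts those not buried inside any neighbour's
#' expanded sphere.
#'
#' @param structure A `pdb_structure`.
#' @param probe Probe radius (Angstrom), default 1.4 (water).
#' @param n_points Sample points per atom (default 960).
#' @return A `sasa_result`: list with `per_atom` (Angstrom^2), `total`,
#'   `by_residue` (named by "resname resno chain"), `probe`, `n_points`.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960) {
  stopifnot(inherits(structure, "pdb_structure"))
  n <- nrow(structure)
  if (n == 0L) stop_input("structure has zero atoms")
  xyz <- as.matrix(structure[, c("x", "y", "z")])
  r <- structure$radius + probe
  pts <- fibonacci_sphere(n_points)
  per_atom <- numeric(n)
  # pairwise distances once; neighbour lists keep the inner loop small
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    if (!length(nb)) {
      per_atom[i] <- 4 * pi * r[i]^2
      next
    }
    p <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
            (p[free, 3] - xyz[j, 3])^2
      free[free] <- dj > r[j]^2
    }
    per_atom[i] <- 4 * pi * r[i]^2 * sum(free) / n_points
  }
  resid <- paste(structure$resname, structure$resno, structure$chain)
  res <- list(per_atom = per_atom, total = sum(per_atom),
              by_residue = tapply(per_atom, resid, sum),
              probe = probe, n_points = n_points)
  class(res) <- "sasa_result"
  res
}

#' Heme solvent-accessible surface area in nm^2
#'
#' Sums SASA over atoms of residues named HEM or HEC and converts
#' Angstrom^2 to nm^2 (/100).
#'
#' @inheritParams sasa
#' @return Heme SASA in nm^2.
#' @export
heme_sasa <- function(structure, probe = 1.4, n_points = 960) {
  stopifnot(inherits(structure, "pdb_structure"))
  heme <- structure$resname %in% c("HEM", "HEC")
  if (!any(heme)) stop_input("no heme (HEM/HEC) atoms in structure")
  res <- sasa(structure, probe, n_points)
  sum(res$per_atom[heme]) / 100
}
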