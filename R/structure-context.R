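## Crystal-structure contact observables: nearest hydrogen-bond donors to
## the nitrile nitrogen, and probe-ring to chromophore-ring distances.

#' Read a PDB structure
#'
#' Parses a PDB file (via bio3d) into a [StructureModel-class]. Alternate
#' locations are resolved to the highest-occupancy conformer; ties keep
#' altloc "A".
#'
#' @param path PDB file path.
#' @param chain optional chain filter.
#' @return a [StructureModel-class].
#' @export
readStructure <- function(path, chain = NULL) {
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                                   rm.alt = FALSE)),
                  error = function(e)
                    stop("unparseable PDB file: ", conditionMessage(e)))
  at <- pdb$atom
  atoms <- data.frame(
    eleno = at$eleno, elety = trimws(at$elety), alt = trimws(at$alt),
    resid = trimws(at$resid), chain = trimws(at$chain), resno = at$resno,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    element = trimws(at$elesy), stringsAsFactors = FALSE)
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  ## fall back to the first character of the atom name when the element
  ## column is absent (hand-written minimal files)
  noEl <- !nzchar(atoms$element)
  atoms$element[noEl] <- substr(gsub("[0-9']", "", atoms$elety[noEl]), 1, 1)
  ## altloc resolution
  alt <- ifelse(is.na(atoms$alt) | atoms$alt == "", "0", atoms$alt)
  key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$elety)
  ord <- order(key, -atoms$occupancy, alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms <- atoms[order(atoms$eleno), , drop = FALSE]
  rownames(atoms) <- NULL
  new("StructureModel", atoms = atoms, sourceId = basename(path))
}

#' Write a structure as PDB text
#'
#' Minimal fixed-width PDB writer for the package's synthetic site models.
#'
#' @param struct a [StructureModel-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeStructurePDB <- function(struct, path) {
  at <- struct@atoms
  fmtName <- function(n) ifelse(nchar(n) < 4, sprintf(" %-3s", n),
                                sprintf("%-4s", n))
  rec <- ifelse(at$resid %in% c("HOH", "HC4"), "HETATM", "ATOM")
  lines <- sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, seq_len(nrow(at)), fmtName(at$elety), "",
                   at$resid, at$chain, at$resno, at$x, at$y, at$z,
                   if (!is.null(at$occupancy)) at$occupancy else 1, 0,
                   at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Packaged ring / nitrile atom-name map
#'
#' Atom names for the oCNF phenyl ring and nitrile atoms, and the pCA
#' chromophore (HC4) phenol-ring carbons, as used by the synthetic site
#' models.
#'
#' @return data.frame: resname, role, atom.
#' @export
ringAtomMap <- function() {
  path <- system.file("extdata", "ring_atom_map.csv", package = "nitrileIR",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Synthetic probe-site structure models
#'
#' Programmatically built stand-ins for the deposited crystal structures
#' (which this package does not ship): each variant's model embodies the
#' reported contact geometry — F28: one water donor at 3.2 A, chromophore
#' ring ~15 A away; F62: carbon-only environment within 3.5 A, ring ~10 A;
#' F92: T90 hydroxyl at 2.9 A plus a water at 3.2 A, ring ~12 A; F96:
#' carbon-only environment, ring ~5 A. These are synthetic geometric
#' models, not deposited coordinates.
#'
#' @param variant "F28", "F62", "F92" or "F96" (an "oCNF" suffix is
#'   accepted).
#' @return a [StructureModel-class].
#' @export
syntheticSite <- function(variant = c("F92", "F28", "F62", "F96")) {
  variant <- sub("oCNF$", "", variant[1])
  variant <- match.arg(variant)
  resno <- switch(variant, F28 = 28, F62 = 62, F92 = 92, F96 = 96)
  ringDist <- switch(variant, F28 = 15, F62 = 10, F92 = 12, F96 = 5)

  u <- c(cos(pi / 3), sin(pi / 3), 0)    # nitrile axis direction
  ringNames <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  angles <- pi / 3 * (0:5)               # CG at 0 deg, CD1 on the axis
  ring <- t(vapply(angles, function(a) 1.39 * c(cos(a), sin(a), 0),
                   numeric(3)))
  cm <- ring[2, ] + 1.43 * u             # ortho nitrile carbon off CD1
  nn <- cm + 1.16 * u

  mk <- function(elety, resid, chain, resno, xyz, element)
    data.frame(elety = elety, resid = resid, chain = chain, resno = resno,
               x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1,
               element = element, stringsAsFactors = FALSE)
  rows <- list(mk("CB", "CNF", "A", resno, c(1.39 + 1.5, 0, 0), "C"))
  for (i in seq_along(ringNames))
    rows <- c(rows, list(mk(ringNames[i], "CNF", "A", resno, ring[i, ], "C")))
  rows <- c(rows, list(mk("CM", "CNF", "A", resno, cm, "C"),
                       mk("NN", "CNF", "A", resno, nn, "N")))

  if (variant == "F92") {
    og1 <- nn + 2.9 * u
    rows <- c(rows,
              list(mk("OG1", "THR", "A", 90, og1, "O"),
                   mk("CB", "THR", "A", 90, og1 + 1.43 * u, "C")))
    v2 <- c(cos(pi / 12), sin(pi / 12), 0.45)
    v2 <- v2 / sqrt(sum(v2^2))
    rows <- c(rows, list(mk("O", "HOH", "A", 201, nn + 3.2 * v2, "O")))
  } else if (variant == "F28") {
    rows <- c(rows, list(mk("O", "HOH", "A", 202, nn + 3.2 * u, "O")))
  } else if (variant == "F62") {
    rows <- c(rows, list(mk("CD1", "LEU", "A", 61, nn + 3.4 * u, "C")))
  } else {
    rows <- c(rows, list(mk("CB", "ALA", "A", 95, nn + 3.3 * u, "C")))
  }

  ## chromophore phenol ring, centroid ringDist from the probe-ring centroid
  w <- c(-1, 0, 0)
  cen <- ringDist * w
  for (i in 0:5) {
    a <- pi / 3 * i
    rows <- c(rows, list(mk(paste0("C", i + 1), "HC4", "A", 169,
                            cen + 1.39 * c(0, cos(a), sin(a)), "C")))
  }

  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  atoms$alt <- ""
  new("StructureModel", atoms = atoms,
      sourceId = paste0("synthetic_site_", variant))
}

## Resolve an atom selector (list of column filters) to row indices.
selectAtoms <- function(atoms, selector) {
  idx <- seq_len(nrow(atoms))
  for (nm in names(selector)) {
    col <- switch(nm, resno = "resno", chain = "chain", resname = "resid",
                  elety = "elety", atoms = "elety", stop("unknown selector ", nm))
    idx <- idx[atoms[[col]][idx] %in% selector[[nm]]]
  }
  idx
}

#' Nearest hydrogen-bond donor heavy atoms to the nitrile nitrogen
#'
#' All whitelist-element heavy atoms within the cutoff of the selected
#' nitrile nitrogen, excluding the probe's own residue, sorted by distance.
#' Crystal structures carry no hydrogens, so this reports heavy-atom
#' contacts, not full hydrogen-bond classification.
#'
#' @param struct a [StructureModel-class].
#' @param nitrogen selector list for the nitrile N (e.g.
#'   `list(resno = 92, elety = "NN", chain = "A")`); must match exactly one
#'   atom.
#' @param cutoff_A distance cutoff, Angstrom (default 3.5).
#' @param whitelist donor element whitelist; `NULL` disables filtering.
#' @return data.frame: elety, element, resid, resno, chain, distance_A,
#'   sorted ascending (possibly 0 rows).
#' @export
nearestDonors <- function(struct, nitrogen, cutoff_A = 3.5,
                          whitelist = c("N", "O")) {
  at <- struct@atoms
  iN <- selectAtoms(at, nitrogen)
  if (length(iN) != 1)
    stop("nitrile nitrogen selector matched ", length(iN),
         " atoms (must match exactly 1)")
  pN <- as.numeric(at[iN, c("x", "y", "z")])
  own <- at$chain == at$chain[iN] & at$resno == at$resno[iN] &
    at$resid == at$resid[iN]
  cand <- which(!own)
  if (!is.null(whitelist))
    cand <- cand[at$element[cand] %in% whitelist]
  cand <- cand[at$element[cand] != "H"]
  if (!length(cand))
    return(data.frame(elety = character(), element = character(),
                      resid = character(), resno = integer(),
                      chain = character(), distance_A = numeric()))
  d <- sqrt((at$x[cand] - pN[1])^2 + (at$y[cand] - pN[2])^2 +
              (at$z[cand] - pN[3])^2)
  keep <- d <= cutoff_A
  out <- data.frame(elety = at$elety[cand][keep],
                    element = at$element[cand][keep],
                    resid = at$resid[cand][keep],
                    resno = at$resno[cand][keep],
                    chain = at$chain[cand][keep],
                    distance_A = d[keep], stringsAsFactors = FALSE)
  out[order(out$distance_A), , drop = FALSE]
}

#' Centroid-to-centroid ring distance
#'
#' @param struct a [StructureModel-class].
#' @param ringA,ringB selector lists, each resolving to >= 5 ring atoms
#'   (e.g. `list(resno = 92, atoms = c("CG","CD1","CE1","CZ","CE2","CD2"))`).
#' @return distance between the two ring-atom centroids, Angstrom.
#' @export
ringToRingDistance <- function(struct, ringA, ringB) {
  at <- struct@atoms
  iA <- selectAtoms(at, ringA)
  iB <- selectAtoms(at, ringB)
  if (length(iA) < 5 || length(iB) < 5)
    stop("each ring selector must resolve at least 5 atoms (got ",
         length(iA), " and ", length(iB), ")")
  cA <- colMeans(at[iA, c("x", "y", "z")])
  cB <- colMeans(at[iB, c("x", "y", "z")])
  sqrt(sum((cA - cB)^2))
}
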