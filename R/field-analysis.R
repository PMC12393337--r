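## Bond-projected Coulomb electric fields and hydrogen-bond classification
## along coordinate trajectories.

## Coulomb constant: a unit charge at 1 A produces 14.3996 V/A = 1439.96
## MV/cm. Point-charge sum only, no periodic images.
KE_MVCM <- 1439.96

#' Construct hydrogen-bond geometric criteria
#'
#' Defaults follow the standard geometric definition used for nitrile
#' acceptors: heavy-atom N...donor distance <= 4.0 Angstrom and a
#' donor-vertex angle (between D->H and D->acceptor) <= 30 degrees, both
#' inclusive.
#'
#' @param distanceCutoff_A heavy-atom distance cutoff, Angstrom.
#' @param angleCutoff_deg angle cutoff, degrees.
#' @param angleVertex "donor" or "hydrogen" (see [HBondCriteria-class]).
#' @param donorElements donor heavy-atom whitelist.
#' @return an [HBondCriteria-class].
#' @export
hbondCriteria <- function(distanceCutoff_A = 4.0, angleCutoff_deg = 30,
                          angleVertex = c("donor", "hydrogen"),
                          donorElements = c("N", "O")) {
  angleVertex <- match.arg(angleVertex)
  new("HBondCriteria", distanceCutoff_A = distanceCutoff_A,
      angleCutoff_deg = angleCutoff_deg, angleVertex = angleVertex,
      donorElements = donorElements)
}

#' Coulomb electric field at a point
#'
#' Direct point-charge sum E(p) = sum_i ke q_i (p - r_i) / |p - r_i|^3 over
#' all non-excluded atoms, in MV/cm (ke e / A^2 = 14.3996 V/A = 1439.96
#' MV/cm).
#'
#' @param coords numeric [nAtoms, 3] matrix, Angstrom.
#' @param charges_e per-atom charges, e.
#' @param point evaluation point, length-3, Angstrom.
#' @param exclude integer atom indices excluded from the sum.
#' @return length-3 field vector, MV/cm.
#' @export
fieldAtPoint <- function(coords, charges_e, point, exclude = integer()) {
  stopifnot(ncol(coords) == 3, nrow(coords) == length(charges_e))
  keep <- setdiff(seq_len(nrow(coords)), exclude)
  if (!length(keep)) return(c(0, 0, 0))
  d <- sweep(coords[keep, , drop = FALSE], 2, point, `-`)   # r_i - p
  r2 <- rowSums(d * d)
  if (any(r2 == 0))
    stop("field singularity: atom ", keep[which(r2 == 0)[1]],
         " coincides with the evaluation point")
  w <- KE_MVCM * charges_e[keep] / (r2 * sqrt(r2))
  -colSums(d * w)   # (p - r_i) = -d
}

#' Bond-projected electric field on the nitrile
#'
#' Projects the Coulomb field onto the C->N unit vector. By default the
#' fields at the carbon and nitrogen positions are averaged; midpoint
#' evaluation is available. With this convention a positive charge beyond N
#' on the bond axis yields a negative projected field (field pointing
#' N -> C), matching the usual sign convention for hydrogen-bond donors.
#'
#' @param coords numeric [nAtoms, 3] matrix, Angstrom.
#' @param charges_e per-atom charges, e.
#' @param probe integer c(C, N) atom indices.
#' @param exclude additional excluded atoms; the probe atoms themselves are
#'   always excluded.
#' @param evaluate "average" (fields at C and N averaged) or "midpoint".
#' @return scalar projected field, MV/cm.
#' @export
projectedField <- function(coords, charges_e, probe, exclude = integer(),
                           evaluate = c("average", "midpoint")) {
  evaluate <- match.arg(evaluate)
  rC <- coords[probe[1], ]
  rN <- coords[probe[2], ]
  bond <- rN - rC
  bl <- sqrt(sum(bond^2))
  if (bl < 1.0 || bl > 1.4)
    stop("probe C-N distance ", round(bl, 3),
         " A outside the [1.0, 1.4] sanity band")
  nhat <- bond / bl
  excl <- union(probe, exclude)
  if (evaluate == "average") {
    eC <- fieldAtPoint(coords, charges_e, rC, excl)
    eN <- fieldAtPoint(coords, charges_e, rN, excl)
    sum(0.5 * (eC + eN) * nhat)
  } else {
    eM <- fieldAtPoint(coords, charges_e, 0.5 * (rC + rN), excl)
    sum(eM * nhat)
  }
}

#' Classify the hydrogen-bond state of one frame
#'
#' A frame is hydrogen-bonded iff some donor satisfies both the heavy-atom
#' distance and the angular criterion (cutoffs inclusive); the nearest
#' qualifying donor is reported.
#'
#' @param coords numeric [nAtoms, 3] matrix, Angstrom.
#' @param nitrogen index of the acceptor (nitrile N).
#' @param donors data.frame with columns `d` (donor heavy atom index), `h`
#'   (attached hydrogen index) and optionally `element`.
#' @param criteria an [HBondCriteria-class].
#' @return list(bonded, donor (index or NA), distance_A, angle_deg) for the
#'   nearest qualifying donor (or the nearest candidate when unbonded).
#' @export
classifyHbond <- function(coords, nitrogen, donors,
                          criteria = hbondCriteria()) {
  if (!nrow(donors))
    return(list(bonded = FALSE, donor = NA_integer_,
                distance_A = NA_real_, angle_deg = NA_real_))
  if (any(is.na(donors$h)))
    stop("donor without an attached hydrogen position")
  if (!is.null(donors$element)) {
    ok <- donors$element %in% criteria@donorElements
    donors <- donors[ok, , drop = FALSE]
    if (!nrow(donors))
      return(list(bonded = FALSE, donor = NA_integer_,
                  distance_A = NA_real_, angle_deg = NA_real_))
  }
  rA <- coords[nitrogen, ]
  dist <- ang <- numeric(nrow(donors))
  for (i in seq_len(nrow(donors))) {
    rD <- coords[donors$d[i], ]
    rH <- coords[donors$h[i], ]
    dist[i] <- sqrt(sum((rA - rD)^2))
    if (criteria@angleVertex == "donor") {
      v1 <- rH - rD
      v2 <- rA - rD
    } else {
      ## deviation of the D-H...A angle from linearity, vertex at H
      v1 <- rD - rH
      v2 <- rA - rH
      ## linear D-H...A means v1 and v2 antiparallel; deviation angle:
      v1 <- -v1
    }
    cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
    ang[i] <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  }
  qual <- dist <= criteria@distanceCutoff_A & ang <= criteria@angleCutoff_deg
  if (any(qual)) {
    j <- which(qual)[which.min(dist[qual])]
    list(bonded = TRUE, donor = donors$d[j], distance_A = dist[j],
         angle_deg = ang[j])
  } else {
    j <- which.min(dist)
    list(bonded = FALSE, donor = NA_integer_, distance_A = dist[j],
         angle_deg = ang[j])
  }
}

#' Analyze a trajectory: per-frame fields and H-bond states
#'
#' Computes the bond-projected field and the hydrogen-bond state for every
#' frame, then summarises: state-resolved means/SDs and populations, pooled
#' mean, per-replicate means and their aggregate (mean of replicate means),
#' and a field histogram.
#'
#' @param traj a [ProbeTrajectory-class]. Probe and donor atoms are found
#'   from the charge-table roles (probe_C/probe_N/donor_D/donor_H); donor_D
#'   and donor_H rows are paired in order.
#' @param criteria an [HBondCriteria-class].
#' @param evaluate field evaluation convention, see [projectedField()].
#' @param binWidth histogram bin width, MV/cm (default 2).
#' @return list with `records` (data.frame: frame, replicate, field_MVcm,
#'   hbond, donor, dist_A, angle_deg) and `summary` ([FieldSummary-class]).
#' @export
analyzeTrajectory <- function(traj, criteria = hbondCriteria(),
                              evaluate = "average", binWidth = 2) {
  validObject(traj)
  ch <- traj@charges
  probe <- c(ch$atom_index[ch$role == "probe_C"],
             ch$atom_index[ch$role == "probe_N"])
  if (length(probe) != 2) stop("charge table must define probe_C and probe_N")
  dIdx <- ch$atom_index[ch$role == "donor_D"]
  hIdx <- ch$atom_index[ch$role == "donor_H"]
  if (length(dIdx) != length(hIdx))
    stop("donor without an attached hydrogen position")
  donors <- data.frame(d = dIdx, h = hIdx,
                       element = if (!is.null(ch$element))
                         ch$element[match(dIdx, ch$atom_index)] else
                           rep("O", length(dIdx)))
  nFrames <- dim(traj@coords)[3]
  field <- numeric(nFrames)
  bonded <- logical(nFrames)
  donor <- integer(nFrames)
  dist <- ang <- numeric(nFrames)
  for (f in seq_len(nFrames)) {
    xyz <- traj@coords[, , f]
    field[f] <- projectedField(xyz, ch$charge_e, probe, evaluate = evaluate)
    cls <- classifyHbond(xyz, probe[2], donors, criteria)
    bonded[f] <- cls$bonded
    donor[f] <- if (is.na(cls$donor)) NA_integer_ else cls$donor
    dist[f] <- cls$distance_A
    ang[f] <- cls$angle_deg
  }
  records <- data.frame(frame = seq_len(nFrames),
                        replicate = traj@replicate,
                        field_MVcm = field, hbond = bonded, donor = donor,
                        dist_A = dist, angle_deg = ang)

  states <- c("bonded", "free")
  lab <- ifelse(bonded, "bonded", "free")
  pops <- vapply(states, function(s) mean(lab == s), numeric(1))
  mns <- vapply(states, function(s)
    if (any(lab == s)) mean(field[lab == s]) else NA_real_, numeric(1))
  sds <- vapply(states, function(s)
    if (sum(lab == s) > 1) stats::sd(field[lab == s]) else NA_real_,
    numeric(1))
  repMeans <- tapply(field, traj@replicate, mean)
  lo <- floor(min(field) / binWidth) * binWidth
  hi <- ceiling(max(field) / binWidth) * binWidth
  if (hi <= lo) hi <- lo + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  counts <- graphics::hist(field, breaks = breaks, plot = FALSE)$counts

  summary <- new("FieldSummary",
                 stateMeans = mns, stateSDs = sds, populations = pops,
                 overallMean = mean(field),
                 replicateMeans = as.numeric(repMeans),
                 aggregateMean = mean(as.numeric(repMeans)),
                 histBreaks = breaks, histCounts = as.numeric(counts),
                 criteria = criteria)
  list(records = records, summary = summary)
}
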