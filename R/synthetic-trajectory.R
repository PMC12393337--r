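## Synthetic two-state probe trajectories with known ground truth.
##
## Geometry (Angstrom): nitrile C at origin, N at (1.16, 0, 0); a single
## hydrogen-bond donor group (heavy atom D + hydrogen H) on the bond axis,
## close and oriented in the bonded state, far and misoriented in the free
## state; a fixed axial background charge standing in for the mean protein
## field; and a shell of alternating-sign solvent charges resampled every
## frame (zero mean, adds realistic field broadening). The donor-charge
## scale and background charge are solved so the two noiseless state fields
## equal the requested state means.

BOND_CN_A <- 1.16

## Noiseless donor-group projected field with unit-scale charges
## (qD = -0.6, qH = +0.4), for a given N...D distance and orientation.
.donorUnitField <- function(distance_A, bonded) {
  xD <- BOND_CN_A + distance_A
  rD <- c(xD, 0, 0)
  rH <- if (bonded) c(xD - 1.0, 0, 0) else c(xD, 1.0, 0)
  coords <- rbind(c(0, 0, 0), c(BOND_CN_A, 0, 0), rD, rH)
  projectedField(coords, c(0, 0, -0.6, 0.4), probe = c(1, 2))
}

.backgroundUnitField <- function(distance_A) {
  coords <- rbind(c(0, 0, 0), c(BOND_CN_A, 0, 0),
                  c(BOND_CN_A + distance_A, 0, 0))
  projectedField(coords, c(0, 0, 1), probe = c(1, 2))
}

#' Construct a two-state trajectory model
#'
#' The donor-charge scale and the axial background charge are solved so
#' that the noiseless bonded-state and free-state projected fields equal
#' `stateMeans_MVcm`; the solved values become the model's ground truth.
#'
#' @param occupancy stationary hydrogen-bonded probability p.
#' @param stateMeans_MVcm named c(bonded=, free=) target state-mean
#'   projected fields, MV/cm.
#' @param nFrames frames per replicate.
#' @param nReplicates independent replicate chains.
#' @param switchScale Markov switching scale s in (0, 1]; transition
#'   probabilities are s*p (free->bonded) and s*(1-p) (bonded->free), so the
#'   chain's stationary distribution is (p, 1-p) for any s.
#' @param bondedDistance_A,freeDistance_A N...D distance in the two states.
#' @param backgroundDistance_A axial background-charge distance beyond N.
#' @param nSolvent,solventCharge_e,solventShell_A solvent shell parameters.
#' @param jitterSD_A per-frame positional jitter SD on donor and solvent
#'   atoms.
#' @return a [TrajectoryModel-class].
#' @export
trajectoryModel <- function(occupancy = 0.5,
                            stateMeans_MVcm = c(bonded = -75, free = -30),
                            nFrames = 2500, nReplicates = 4,
                            switchScale = 0.8,
                            bondedDistance_A = 2.9, freeDistance_A = 6.5,
                            backgroundDistance_A = 5.0,
                            nSolvent = 24, solventCharge_e = 0.3,
                            solventShell_A = 8, jitterSD_A = 0.05) {
  stopifnot(all(c("bonded", "free") %in% names(stateMeans_MVcm)))
  phiB <- .donorUnitField(bondedDistance_A, bonded = TRUE)
  phiF <- .donorUnitField(freeDistance_A, bonded = FALSE)
  beta <- .backgroundUnitField(backgroundDistance_A)
  s <- (stateMeans_MVcm[["bonded"]] - stateMeans_MVcm[["free"]]) /
    (phiB - phiF)
  qBg <- (stateMeans_MVcm[["bonded"]] - s * phiB) / beta
  new("TrajectoryModel",
      nFrames = nFrames, nReplicates = nReplicates,
      occupancy = occupancy, switchScale = switchScale,
      bondedDistance_A = bondedDistance_A, freeDistance_A = freeDistance_A,
      donorChargeD_e = -0.6 * s, donorChargeH_e = 0.4 * s,
      backgroundCharge_e = qBg, backgroundDistance_A = backgroundDistance_A,
      nSolvent = nSolvent, solventCharge_e = solventCharge_e,
      solventShell_A = solventShell_A, jitterSD_A = jitterSD_A,
      stateMeans_MVcm = stateMeans_MVcm)
}

#' Preset trajectory models anchored to the AMOEBA mean fields
#'
#' Presets "apo_F92", "holo_F92", "apo_F96" and "holo_F96" share
#' variant-specific state means and differ in hydrogen-bond occupancy, so
#' their overall mean projected fields reproduce the reported -44 / -67
#' (F92) and -23 / -26 (F96) MV/cm. F92 exchanges with the T90 hydroxyl
#' (strong donor, well-separated states); F96 with transient solvent
#' (weaker donor, closer states).
#'
#' @param name preset name.
#' @param nFrames,nReplicates trajectory size (defaults 2500 x 4,
#'   mirroring four 25-ns replicates).
#' @return a [TrajectoryModel-class] whose ground truth includes the target
#'   overall mean field.
#' @export
trajectoryPreset <- function(name = c("apo_F92", "holo_F92", "apo_F96",
                                      "holo_F96"),
                             nFrames = 2500, nReplicates = 4) {
  name <- match.arg(name)
  cfg <- switch(name,
    apo_F92 = list(states = c(bonded = -75, free = -30), overall = -44),
    holo_F92 = list(states = c(bonded = -75, free = -30), overall = -67),
    apo_F96 = list(states = c(bonded = -35, free = -20), overall = -23),
    holo_F96 = list(states = c(bonded = -35, free = -20), overall = -26))
  p <- (cfg$overall - cfg$states[["free"]]) /
    (cfg$states[["bonded"]] - cfg$states[["free"]])
  trajectoryModel(occupancy = unname(p), stateMeans_MVcm = cfg$states,
                  nFrames = nFrames, nReplicates = nReplicates)
}

#' Generate a synthetic two-state trajectory
#'
#' Each replicate runs an independent two-state Markov chain initialised
#' from its stationary distribution (so the empirical occupancy is unbiased
#' at finite length). Ground-truth per-frame state labels and the
#' generative parameters are carried on the returned object.
#'
#' @param model a [TrajectoryModel-class].
#' @param seed integer RNG seed.
#' @return a [ProbeTrajectory-class].
#' @export
generateTrajectory <- function(model, seed = 1) {
  validObject(model)
  p <- model@occupancy
  s <- model@switchScale
  nF <- as.integer(model@nFrames)
  nR <- as.integer(model@nReplicates)
  nTot <- nF * nR
  nSolv <- as.integer(model@nSolvent)
  nAtoms <- 5L + nSolv

  charges <- data.frame(
    atom_index = seq_len(nAtoms),
    charge_e = c(0.2, -0.2, model@donorChargeD_e, model@donorChargeH_e,
                 model@backgroundCharge_e,
                 rep_len(c(model@solventCharge_e, -model@solventCharge_e),
                         nSolv)),
    role = c("probe_C", "probe_N", "donor_D", "donor_H", "background",
             rep("solvent", nSolv)),
    element = c("C", "N", "O", "H", "C", rep("O", nSolv)),
    stringsAsFactors = FALSE)

  coords <- array(0, dim = c(nAtoms, 3, nTot))
  labels <- character(nTot)
  replicate <- rep(seq_len(nR), each = nF)

  xD_b <- BOND_CN_A + model@bondedDistance_A
  xD_f <- BOND_CN_A + model@freeDistance_A
  mid <- c(BOND_CN_A / 2, 0, 0)

  withSeed(seed, {
    for (r in seq_len(nR)) {
      state <- logical(nF)   # TRUE = bonded
      state[1] <- stats::runif(1) < p
      if (nF > 1) {
        u <- stats::runif(nF - 1)
        for (f in 2:nF)
          state[f] <- if (state[f - 1]) u[f - 1] >= s * (1 - p)
                      else u[f - 1] < s * p
      }
      for (f in seq_len(nF)) {
        i <- (r - 1L) * nF + f
        xyz <- matrix(0, nAtoms, 3)
        xyz[1, ] <- c(0, 0, 0)
        xyz[2, ] <- c(BOND_CN_A, 0, 0)
        if (state[f]) {
          xyz[3, ] <- c(xD_b, 0, 0)
          xyz[4, ] <- c(xD_b - 1.0, 0, 0)
        } else {
          xyz[3, ] <- c(xD_f, 0, 0)
          xyz[4, ] <- c(xD_f, 1.0, 0)
        }
        xyz[5, ] <- c(BOND_CN_A + model@backgroundDistance_A, 0, 0)
        if (nSolv > 0) {
          dir <- matrix(stats::rnorm(3 * nSolv), nSolv, 3)
          dir <- dir / sqrt(rowSums(dir^2))
          rad <- pmax(model@solventShell_A +
                        stats::rnorm(nSolv, 0, 0.8),
                      model@solventShell_A - 2)
          xyz[5L + seq_len(nSolv), ] <-
            sweep(dir * rad, 2, mid, `+`)
        }
        if (model@jitterSD_A > 0) {
          jit <- matrix(stats::rnorm(3 * (nAtoms - 2L), 0,
                                     model@jitterSD_A), nAtoms - 2L, 3)
          xyz[3:nAtoms, ] <- xyz[3:nAtoms, ] + jit
        }
        coords[, , i] <- xyz
        labels[i] <- if (state[f]) "bonded" else "free"
      }
    }
  })

  new("ProbeTrajectory", coords = coords, charges = charges,
      stateLabels = labels, replicate = as.integer(replicate),
      truth = list(occupancy = p,
                   stateMeans_MVcm = model@stateMeans_MVcm,
                   overallMean_MVcm = p * model@stateMeans_MVcm[["bonded"]] +
                     (1 - p) * model@stateMeans_MVcm[["free"]],
                   model = model, seed = seed))
}
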