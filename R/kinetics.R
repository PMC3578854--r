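#' Kinetic parameters with the published per-NTP values
#'
#' Builds a \linkS4class{KineticParams}. \code{vmax} and \code{km}
#' default to the experimentally determined per-NTP values (Vmax 50, 18,
#' 36, 33 1/s and Km 38, 24, 62, 7 uM for ATP, UTP, GTP, CTP). NTP
#' concentrations have \emph{no} default and must be supplied.
#'
#' Backtracking is controlled by three tunable model parameters: the
#' attempt prefactor \code{k0}, the intrinsic hop barrier \code{dG0},
#' and the free-energy penalty \code{dGbt} of backtracked states, which
#' reflects the disengagement of the RNA 3' end from the active site.
#' Entry into backtracking is uphill by \code{dGbt} (rare away from
#' pause-prone sequences) while recovery is downhill (fast); the
#' defaults (10 1/s, 1.2 kcal/mol, 4 kcal/mol) give second-scale
#' backtracking pauses concentrated at sequence-determined sites (see
#' the package vignette).
#' \code{force} is an external load applied to every polymerase
#' (positive = assisting, default 0); \code{collisionForce} is the force
#' a polymerase exerts on a neighbor while the two are in contact
#' (default 25 pN, the average stalling force of RNA polymerase).
#'
#' @param ntpConc named numeric of NTP concentrations in uM (names ATP,
#'   CTP, GTP, UTP), or a single number used for all four
#' @param vmax,km named numeric per-NTP rate parameters
#' @param k0 backtrack attempt prefactor (1/s)
#' @param dG0 intrinsic hop barrier (kcal/mol)
#' @param dGbt backtracked-state free-energy penalty (kcal/mol)
#' @param force external force on each polymerase (pN)
#' @param collisionForce force transmitted during contact (pN)
#' @param temperature kelvin (default 297.15 K, i.e. 24 C)
#' @return a \linkS4class{KineticParams}
#' @examples
#' kineticParams(ntpConc = 250)
#' @export
kineticParams <- function(ntpConc,
                          vmax = c(ATP = 50, UTP = 18, GTP = 36, CTP = 33),
                          km = c(ATP = 38, UTP = 24, GTP = 62, CTP = 7),
                          k0 = 10, dG0 = 1.2, dGbt = 4, force = 0,
                          collisionForce = 25, temperature = 297.15) {
  if (missing(ntpConc))
    stop("NTP concentrations are a mandatory input (uM); no default")
  if (length(ntpConc) == 1L && is.null(names(ntpConc)))
    ntpConc <- stats::setNames(rep(as.numeric(ntpConc), 4L), .NTPS)
  new("KineticParams",
    vmax = vmax[.NTPS], km = km[.NTPS], ntpConc = ntpConc[.NTPS],
    k0 = as.numeric(k0), dG0 = as.numeric(dG0),
    dGbt = as.numeric(dGbt), force = as.numeric(force),
    collisionForce = as.numeric(collisionForce),
    temperature = as.numeric(temperature)
  )
}

#' Thermal energy in kcal/mol
#'
#' @param temperature kelvin
#' @return kB * T in kcal/mol (about 0.59 at 24 C)
#' @examples
#' kBT(297.15)
#' @export
kBT <- function(temperature) .kB * temperature

#' Convert a force step to kcal/mol
#'
#' Mechanical work of a force over one translocation step,
#' F * delta, converted with 1 kcal/mol = 6.9477 pN nm.
#'
#' @param force pN
#' @param delta step length in nm (default 0.34)
#' @return energy in kcal/mol
#' @examples
#' forceStepEnergy(25)  # about 1.223 kcal/mol
#' @export
forceStepEnergy <- function(force, delta = 0.34) {
  force * delta / .PNNM_PER_KCAL
}

#' Translocation equilibrium factor from free energies
#'
#' Boltzmann ratio of pre- to post-translocated occupancy,
#' exp((dGpost - dGpre - F*delta) / kBT). A pre-translocated state that
#' is more stable than the post state (dGpre < dGpost) gives a factor
#' greater than 1 and slows incorporation; an assisting force (F > 0)
#' tilts the equilibrium toward the post state and shrinks the factor.
#'
#' @param dGpost,dGpre TEC standard free energies of the post- and
#'   pre-translocated registers (kcal/mol)
#' @param force pN, positive = assisting
#' @param temperature kelvin
#' @param delta nm per step
#' @return dimensionless equilibrium factor
#' @examples
#' translocationFactor(0, 0, force = 0)   # symmetric landscape: 1
#' @export
translocationFactor <- function(dGpost, dGpre, force = 0,
                                temperature = 297.15, delta = 0.34) {
  exp((dGpost - dGpre - forceStepEnergy(force, delta)) / kBT(temperature))
}

#' Translocation bias of an elongating TEC
#'
#' Evaluates \code{\link{translocationFactor}} at the state's template
#' position from the sequence-dependent landscape.
#'
#' @param state an elongating \linkS4class{TECState}
#' @param template sense strand 5'->3'
#' @param model an \linkS4class{EnergyModel}
#' @param force pN
#' @param temperature kelvin
#' @return dimensionless equilibrium factor
#' @export
translocationBias <- function(state, template, model = energyModel(),
                              force = 0, temperature = 297.15) {
  if (state@mode != "elongating")
    stop("translocation bias is defined for elongating states")
  post <- tecFreeEnergy(tecState(state@n, register = "post"), template,
                        model, temperature)
  pre <- tecFreeEnergy(tecState(state@n, register = "pre"), template,
                       model, temperature)
  translocationFactor(post, pre, force, temperature, model@geometry@delta)
}

#' Effective nucleotide-incorporation rate
#'
#' Michaelis-Menten incorporation limited by the translocation
#' equilibrium: k = Vmax [NTP] / ([NTP] + Km (1 + bias)). With bias = 0
#' (post register infinitely favored) this is plain Michaelis-Menten; a
#' large bias (pre register favored) inflates the apparent Km and slows
#' incorporation.
#'
#' @param ntp the incoming nucleotide: "ATP", "CTP", "GTP", "UTP" or the
#'   corresponding template (sense-strand) base "A", "C", "G", "T"
#' @param params a \linkS4class{KineticParams}
#' @param bias dimensionless translocation factor
#' @return rate in 1/s
#' @examples
#' p <- kineticParams(ntpConc = 250)
#' incorporationRate("ATP", p, bias = 0)
#' @export
incorporationRate <- function(ntp, params, bias) {
  if (ntp %in% .BASES) ntp <- .NTP_OF_BASE[[ntp]]
  if (!ntp %in% .NTPS) stop("unknown nucleotide: ", ntp)
  if (bias < 0) stop("bias must be non-negative")
  conc <- params@ntpConc[[ntp]]
  params@vmax[[ntp]] * conc / (conc + params@km[[ntp]] * (1 + bias))
}

# Arrhenius-type hop rate over a landscape barrier:
# k = k0 exp(-(max(0, dGtarget - dGcurrent) + dG0 +/- F*delta/2) / kBT).
# The force tilt is +F*delta/2 for a backward hop (assisting force
# hinders it) and -F*delta/2 for a forward hop. `pen` shifts the target
# energy (used for the dGbt penalty when crossing between the
# elongating and backtracked pathways).
.hopRate <- function(k0, dG0, dGcur, dGtarget, force, temperature, delta,
                     dir, pen = 0) {
  tilt <- -dir * forceStepEnergy(force, delta) / 2
  barrier <- max(0, dGtarget + pen - dGcur) + dG0 + tilt
  k0 * exp(-barrier / kBT(temperature))
}

#' Backtracking and forwardtracking hop rates
#'
#' Thermally activated hops of the polymerase along the template,
#' k = k0 exp(-dGbarrier / kBT), with the barrier taken as the positive
#' part of the landscape free-energy difference toward the target state
#' plus a constant intrinsic offset dG0, tilted by -/+ F*delta/2 for
#' forward/backward hops. Hops that cross between the elongating and
#' backtracked pathways additionally carry the backtracked-state
#' penalty \code{params@dGbt} (uphill on entry, downhill on recovery).
#' This construction satisfies detailed balance against the TEC
#' landscape at zero force.
#'
#' For an elongating state the backward rate is the entry into
#' backtracking and the forward rate is 0 (there is no forward hop; the
#' forward pathway is nucleotide incorporation). For a backtracked state
#' with offset 1 the forward hop re-enters the elongation pathway. Hops
#' beyond the template start have rate 0 (reflecting boundary).
#'
#' @param state a \linkS4class{TECState} (elongating or backtracked)
#' @param template sense strand 5'->3'
#' @param model an \linkS4class{EnergyModel}
#' @param params a \linkS4class{KineticParams}
#' @param force pN; defaults to \code{params@force}
#' @return named numeric \code{c(backward=, forward=)} in 1/s
#' @examples
#' p <- kineticParams(ntpConc = 250)
#' tpl <- paste(rep("ACGT", 30), collapse = "")
#' backtrackRates(tecState(n = 60, backtrackOffset = 2), tpl, params = p)
#' @export
backtrackRates <- function(state, template, model = energyModel(),
                           params, force = params@force) {
  if (state@mode == "terminated") stop("state is terminated")
  temperature <- params@temperature
  delta <- model@geometry@delta
  gAt <- function(q) tecFreeEnergy(
    if (q == state@n) tecState(state@n) else
      tecState(state@n, backtrackOffset = state@n - q),
    template, model, temperature
  )
  q <- state@m
  gCur <- gAt(q)
  penB <- if (state@mode == "elongating") params@dGbt else 0
  penF <- if (state@mode == "backtracked" && state@backtrackOffset == 1L)
    -params@dGbt else 0
  kb <- if (q - 1L < 1L) 0 else
    .hopRate(params@k0, params@dG0, gCur, gAt(q - 1L), force,
             temperature, delta, dir = -1L, pen = penB)
  kf <- if (state@mode == "elongating") 0 else
    .hopRate(params@k0, params@dG0, gCur, gAt(q + 1L), force,
             temperature, delta, dir = +1L, pen = penF)
  c(backward = kb, forward = kf)
}
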