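#' @import methods
#' @importFrom stats median quantile rexp runif sd ks.test
#' @importFrom utils read.delim write.table
NULL

# Boltzmann constant, kcal/(mol K)
.kB <- 1.987204e-3
# unit conversion: 1 kcal/mol = 6.9477 pN nm (per molecule); defined once here
.PNNM_PER_KCAL <- 6.9477

.BASES <- c("A", "C", "G", "T")
.NTP_OF_BASE <- c(A = "ATP", C = "CTP", G = "GTP", T = "UTP")
.NTPS <- c("ATP", "CTP", "GTP", "UTP")

#' Geometry of the transcription elongation complex
#'
#' Describes the physical extent of the elongation complex (TEC) on the
#' template: the RNA-DNA hybrid length in the post- and pre-translocated
#' registers (8 and 9 bp), the transcription-bubble length (12 bp), the
#' distance between adjacent template nucleotides (0.34 nm), and the
#' footprint of the polymerase in front of and behind its active site,
#' which sets the hard-core exclusion distance between molecules.
#'
#' The hybrid occupies the upstream part of the bubble; the remaining
#' bubble base pairs lie downstream of the RNA 3' end. Only free-energy
#' differences between adjacent states enter the kinetics, so this
#' placement convention does not affect rates away from template ends.
#'
#' @slot hybridLenPost integer, hybrid length in the post-translocated
#'   register (bp)
#' @slot hybridLenPre integer, hybrid length in the pre-translocated
#'   register (bp); always \code{hybridLenPost + 1}
#' @slot bubbleLen integer, melted-bubble length (bp)
#' @slot delta numeric, distance between adjacent nucleotides (nm)
#' @slot footprintFront integer, nt from active site to the leading edge
#' @slot footprintBack integer, nt from active site to the trailing edge
#' @export
setClass("TECGeometry",
  representation(
    hybridLenPost = "integer", hybridLenPre = "integer",
    bubbleLen = "integer", delta = "numeric",
    footprintFront = "integer", footprintBack = "integer"
  )
)

setValidity("TECGeometry", function(object) {
  msg <- character()
  if (object@hybridLenPre != object@hybridLenPost + 1L)
    msg <- c(msg, "hybridLenPre must equal hybridLenPost + 1")
  if (object@footprintFront <= 0L || object@footprintBack <= 0L)
    msg <- c(msg, "footprints must be positive")
  if (object@footprintFront + object@footprintBack < object@bubbleLen)
    msg <- c(msg, "footprints must cover at least the bubble")
  if (object@delta <= 0) msg <- c(msg, "delta must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a TECGeometry
#'
#' Defaults follow the canonical TEC picture: 8/9-bp hybrid, 12-bp bubble,
#' 0.34 nm per nucleotide, and a ~35-bp polymerase footprint split evenly
#' around the active site (17 nt on each side).
#'
#' @param hybridLenPost hybrid length in the post-translocated register (bp)
#' @param bubbleLen bubble length (bp)
#' @param delta inter-nucleotide distance (nm)
#' @param footprintFront,footprintBack nt from the active site to the
#'   leading/trailing edge of the polymerase
#' @return a \code{TECGeometry} object
#' @examples
#' tecGeometry()
#' @export
tecGeometry <- function(hybridLenPost = 8L, bubbleLen = 12L, delta = 0.34,
                        footprintFront = 17L, footprintBack = 17L) {
  new("TECGeometry",
    hybridLenPost = as.integer(hybridLenPost),
    hybridLenPre = as.integer(hybridLenPost) + 1L,
    bubbleLen = as.integer(bubbleLen), delta = as.numeric(delta),
    footprintFront = as.integer(footprintFront),
    footprintBack = as.integer(footprintBack)
  )
}

setMethod("show", "TECGeometry", function(object) {
  cat("TECGeometry: hybrid ", object@hybridLenPost, "/",
    object@hybridLenPre, " bp (post/pre), bubble ", object@bubbleLen,
    " bp, delta ", object@delta, " nm, footprint -", object@footprintBack,
    "/+", object@footprintFront, " nt\n",
    sep = ""
  )
})

#' Nearest-neighbor energy model for the elongation complex
#'
#' Bundles the two nearest-neighbor parameter tables used to evaluate the
#' standard Gibbs free energy of a TEC configuration - DNA/DNA duplex
#' steps (bubble melting) and RNA/DNA hybrid steps - together with the
#' TEC geometry. Tables carry dH (kcal/mol) and dS (cal/mol/K) per
#' dinucleotide step so that dG can be recomputed at any simulation
#' temperature.
#'
#' @slot dnaDNA data.frame of DNA/DNA steps (step, dH, dS, dG37, source)
#' @slot rnaDNA data.frame of RNA/DNA hybrid steps, keyed by the RNA
#'   dinucleotide 5'->3'
#' @slot geometry a \linkS4class{TECGeometry}
#' @export
setClass("EnergyModel",
  representation(
    dnaDNA = "data.frame", rnaDNA = "data.frame", geometry = "TECGeometry"
  )
)

.checkNNTable <- function(df, steps, what) {
  need <- c("step", "dH_kcal_mol", "dS_cal_mol_K")
  if (!all(need %in% names(df)))
    return(sprintf("%s table must have columns %s", what,
                   paste(need, collapse = ", ")))
  missing <- setdiff(steps, df$step)
  if (length(missing))
    return(sprintf("%s table lacks steps: %s", what,
                   paste(missing, collapse = ", ")))
  TRUE
}

setValidity("EnergyModel", function(object) {
  dsteps <- as.vector(outer(.BASES, .BASES, paste0))
  rsteps <- gsub("T", "U", dsteps)
  ok1 <- .checkNNTable(object@dnaDNA, dsteps, "DNA/DNA")
  ok2 <- .checkNNTable(object@rnaDNA, rsteps, "RNA/DNA")
  msg <- c(if (!isTRUE(ok1)) ok1, if (!isTRUE(ok2)) ok2)
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnergyModel", function(object) {
  cat("EnergyModel:",
    nrow(object@dnaDNA), "DNA/DNA entries,",
    nrow(object@rnaDNA), "RNA/DNA entries\n"
  )
  show(object@geometry)
})

#' One polymerase's instantaneous configuration
#'
#' @slot m integer, active-site template position (1-based nt); equals
#'   \code{n - backtrackOffset} in the coordinate frame where transcript
#'   position 1 corresponds to template position 1
#' @slot n integer, transcript length (nt)
#' @slot register "pre" or "post" translocation register
#' @slot backtrackOffset integer >= 0, nt the active site sits behind the
#'   RNA 3' end
#' @slot mode "elongating", "backtracked" or "terminated"
#' @export
setClass("TECState",
  representation(
    m = "integer", n = "integer", register = "character",
    backtrackOffset = "integer", mode = "character"
  )
)

setValidity("TECState", function(object) {
  msg <- character()
  if (!object@register %in% c("pre", "post"))
    msg <- c(msg, "register must be 'pre' or 'post'")
  if (!object@mode %in% c("elongating", "backtracked", "terminated"))
    msg <- c(msg, "unknown mode")
  if (object@mode == "elongating" && object@backtrackOffset != 0L)
    msg <- c(msg, "elongating state must have backtrackOffset 0")
  if (object@mode == "backtracked" && object@backtrackOffset < 1L)
    msg <- c(msg, "backtracked state must have backtrackOffset >= 1")
  if (object@m != object@n - object@backtrackOffset)
    msg <- c(msg, "m must equal n - backtrackOffset")
  if (length(msg)) msg else TRUE
})

#' Construct a TECState
#'
#' @param n transcript length (nt)
#' @param register translocation register, "post" (default) or "pre"
#' @param backtrackOffset nt behind the RNA 3' end (0 when elongating)
#' @param mode state mode; inferred from \code{backtrackOffset} by default
#' @return a \code{TECState}
#' @examples
#' tecState(n = 50)               # elongating, post register
#' tecState(n = 50, backtrackOffset = 3)
#' @export
tecState <- function(n, register = "post", backtrackOffset = 0L,
                     mode = if (backtrackOffset > 0) "backtracked"
                            else "elongating") {
  if (mode == "backtracked") register <- "post"
  new("TECState",
    m = as.integer(n) - as.integer(backtrackOffset), n = as.integer(n),
    register = register, backtrackOffset = as.integer(backtrackOffset),
    mode = mode
  )
}

setMethod("show", "TECState", function(object) {
  cat("TECState:", object@mode, "n =", object@n,
    "m =", object@m, "register =", object@register,
    "offset =", object@backtrackOffset, "\n"
  )
})

#' Kinetic parameters of the elongation model
#'
#' @slot vmax named numeric, maximal incorporation rate per NTP (1/s)
#' @slot km named numeric, Michaelis constant per NTP (uM)
#' @slot ntpConc named numeric, NTP concentration (uM)
#' @slot k0 numeric, backtracking attempt prefactor (1/s)
#' @slot dG0 numeric, intrinsic hop barrier offset (kcal/mol)
#' @slot dGbt numeric, free-energy penalty of backtracked states
#'   relative to the elongating pathway (kcal/mol); entering
#'   backtracking is uphill by this amount and recovery downhill
#' @slot force numeric, external force applied to every polymerase (pN,
#'   positive = assisting)
#' @slot collisionForce numeric, force transmitted between polymerases in
#'   contact (pN)
#' @slot temperature numeric, kelvin
#' @export
setClass("KineticParams",
  representation(
    vmax = "numeric", km = "numeric", ntpConc = "numeric",
    k0 = "numeric", dG0 = "numeric", dGbt = "numeric",
    force = "numeric", collisionForce = "numeric",
    temperature = "numeric"
  )
)

setValidity("KineticParams", function(object) {
  msg <- character()
  for (sl in c("vmax", "km", "ntpConc")) {
    v <- slot(object, sl)
    if (!all(.NTPS %in% names(v)))
      msg <- c(msg, sprintf("%s must be named for all of %s", sl,
                            paste(.NTPS, collapse = ", ")))
    else if (any(v[.NTPS] <= 0))
      msg <- c(msg, sprintf("%s must be strictly positive", sl))
  }
  if (object@k0 <= 0) msg <- c(msg, "k0 must be positive")
  if (object@temperature <= 0) msg <- c(msg, "temperature must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "KineticParams", function(object) {
  cat("KineticParams @", object@temperature, "K, force",
    object@force, "pN, collision force", object@collisionForce, "pN\n")
  m <- rbind(
    `Vmax (1/s)` = object@vmax[.NTPS],
    `Km (uM)` = object@km[.NTPS],
    `[NTP] (uM)` = object@ntpConc[.NTPS]
  )
  print(m)
  cat("backtracking: k0 =", object@k0, "1/s, dG0 =", object@dG0,
      "kcal/mol, dGbt =", object@dGbt, "kcal/mol\n")
})

#' A run configuration
#'
#' @slot template DNAString, sense strand 5'->3'
#' @slot templateName character label
#' @slot params a \linkS4class{KineticParams}
#' @slot model an \linkS4class{EnergyModel}
#' @slot nRnapMax integer, maximum number of polymerases on the template
#' @slot initiationInterval numeric, seconds between initiation attempts
#' @slot nReplicates integer
#' @slot tMax numeric, safety cap on simulated time (s)
#' @slot seed integer master seed
#' @export
setClass("RunConfig",
  representation(
    template = "ANY", templateName = "character",
    params = "KineticParams", model = "EnergyModel",
    nRnapMax = "integer", initiationInterval = "numeric",
    nReplicates = "integer", tMax = "numeric", seed = "integer"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character()
  if (object@nRnapMax < 1L) msg <- c(msg, "nRnapMax must be >= 1")
  if (object@initiationInterval <= 0)
    msg <- c(msg, "initiationInterval must be positive")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  seq <- as.character(object@template)
  if (grepl("[^ACGT]", seq))
    msg <- c(msg, "template may contain only A/C/G/T")
  g <- object@model@geometry
  if (nchar(seq) < g@bubbleLen + g@hybridLenPre)
    msg <- c(msg, "template shorter than the minimum TEC span")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig '", object@templateName, "': ",
    nchar(as.character(object@template)), " nt, N <= ", object@nRnapMax,
    ", ", object@nReplicates, " replicate(s), seed ", object@seed, "\n",
    sep = ""
  )
})

#' One polymerase's trajectory
#'
#' Piecewise-linear position-vs-time record with event annotations. The
#' \code{events} data frame has columns \code{time} (s), \code{position}
#' (active-site position, nt; fractional at collision breakpoints),
#' \code{n} (transcript length), \code{offset} (backtrack offset) and
#' \code{kind} (one of initiation, incorporation, backtrack_step,
#' forward_step, collision, push, termination, truncated).
#'
#' @slot rnapIndex integer binding order (1 = first to initiate)
#' @slot tInit,tEnd numeric, initiation and termination/stop times (s)
#' @slot finalLength integer, transcript length at the end of the record
#' @slot truncated logical, TRUE if the run hit the time cap
#' @slot events data.frame of breakpoints/events
#' @export
setClass("Trajectory",
  representation(
    rnapIndex = "integer", tInit = "numeric", tEnd = "numeric",
    finalLength = "integer", truncated = "logical", events = "data.frame"
  )
)

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory rnap", object@rnapIndex, ": ", nrow(object@events),
    " events, length ", object@finalLength, " nt in [",
    round(object@tInit, 3), ", ", round(object@tEnd, 3), "] s",
    if (object@truncated) " (truncated)", "\n",
    sep = ""
  )
})

#' An ensemble of simulated transcription runs
#'
#' @slot mode "sra" (single molecule) or "mra" (multi-molecule with
#'   collisions)
#' @slot config the \linkS4class{RunConfig} used
#' @slot replicates list; element r is the list of \linkS4class{Trajectory}
#'   objects of replicate r (ordered by binding order)
#' @export
setClass("TrafficSim",
  representation(mode = "character", config = "RunConfig",
                 replicates = "list")
)

setMethod("show", "TrafficSim", function(object) {
  nr <- length(object@replicates)
  np <- if (nr) length(object@replicates[[1]]) else 0L
  cat("TrafficSim (", object@mode, "): ", nr, " replicate(s), up to ", np,
    " polymerase(s) each, template '", object@config@templateName, "'\n",
    sep = ""
  )
})

#' Per-position dwell-time profile
#'
#' @slot samples list of numeric vectors, dwell-time samples per position
#' @slot tq named numeric, third-quartile dwell time per position (s)
#' @slot tauMin numeric, minimum of the profile statistic over positions (s)
#' @slot positions integer vector of positions with samples
#' @slot missing integer vector of positions never reached
#' @export
setClass("DwellProfile",
  representation(
    samples = "list", tq = "numeric", tauMin = "numeric",
    positions = "integer", missing = "integer"
  )
)

setMethod("show", "DwellProfile", function(object) {
  cat("DwellProfile over", length(object@positions), "positions; tauMin =",
    signif(object@tauMin, 4), "s; max TQ dwell =",
    signif(max(object@tq), 4), "s\n")
})

#' Called pause sites
#'
#' @slot positions integer, called pause positions (1-based)
#' @slot tq named numeric, the dwell statistic at the calls
#' @slot alpha numeric threshold parameter
#' @slot threshold numeric, implied absolute dwell threshold (s)
#' @slot clusters list of integer vectors, calls grouped within 3 bp
#' @export
setClass("PauseReport",
  representation(
    positions = "integer", tq = "numeric", alpha = "numeric",
    threshold = "numeric", clusters = "list"
  )
)

setMethod("show", "PauseReport", function(object) {
  cat("PauseReport:", length(object@positions), "pause site(s) in",
    length(object@clusters), "cluster(s); alpha =", object@alpha,
    "=> dwell threshold", signif(object@threshold, 4), "s\n")
})

#' Transcription-efficiency curve
#'
#' @slot n integer vector of maximum polymerase counts
#' @slot tAvg numeric, average transcription time per N (s)
#' @slot eps numeric, relative transcription efficiency per N
#' @slot medians list of per-binding-order median completion times per N
#' @export
setClass("EfficiencyCurve",
  representation(n = "integer", tAvg = "numeric", eps = "numeric",
                 medians = "list")
)

setMethod("show", "EfficiencyCurve", function(object) {
  print(data.frame(N = object@n, Tavg = object@tAvg, eps = object@eps))
})

#' Simulated transcription gel
#'
#' @slot counts matrix, transcript-length (rows) by timepoint (columns)
#'   counts of transcripts
#' @slot lengths integer vector of transcript lengths (row labels)
#' @slot timepoints numeric vector of sampling times (s)
#' @export
setClass("GelImage",
  representation(counts = "matrix", lengths = "integer",
                 timepoints = "numeric")
)

setMethod("show", "GelImage", function(object) {
  cat("GelImage:", nrow(object@counts), "lengths x",
    ncol(object@counts), "timepoints; lane masses:",
    paste(colSums(object@counts), collapse = ", "), "\n")
})

#' Pause-prediction quality
#'
#' @slot tp,fp,fn integer cluster counts
#' @slot q numeric quality statistic
#' @slot bootstrapSd numeric, bootstrap standard deviation of q over
#'   sequences (NA if not computed)
#' @export
setClass("QualityResult",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 q = "numeric", bootstrapSd = "numeric")
)

setMethod("show", "QualityResult", function(object) {
  cat("QualityResult: TP =", object@tp, "FP =", object@fp,
    "FN =", object@fn, "Q =", signif(object@q, 4))
  if (!is.na(object@bootstrapSd))
    cat(" (bootstrap sd", signif(object@bootstrapSd, 3), ")")
  cat("\n")
})
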