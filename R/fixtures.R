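#' Specification of a planted sequence motif
#'
#' @slot kind "strong_pause", "backtrack_trap" or "neutral"
#' @slot position integer, the site of interest (1-based nt)
#' @slot length integer, upstream extent of the mutable window (nt)
#' @export
setClass("MotifSpec",
  representation(kind = "character", position = "integer",
                 length = "integer")
)

setValidity("MotifSpec", function(object) {
  if (!object@kind %in% c("strong_pause", "backtrack_trap", "neutral"))
    return("kind must be strong_pause, backtrack_trap or neutral")
  if (object@position < 1L || object@length < 4L)
    return("position must be >= 1 and length >= 4")
  TRUE
})

#' @rdname MotifSpec-class
#' @param kind,position,length see slots
#' @return a \code{MotifSpec}
#' @export
motifSpec <- function(kind, position, length = 16L) {
  new("MotifSpec", kind = kind, position = as.integer(position),
      length = as.integer(length))
}

# the sequence window a motif occupies: [position - length + 1,
# position + 4]; the 4 nt of downstream context are part of the bubble
# ahead of the site and are mutated along with the upstream window
.motifWindow <- function(m, L) {
  c(max(1L, m@position - m@length + 1L), min(L, m@position + 4L))
}

# raw energetic scores of a motif site: the pre-vs-post stabilization
# (controls incorporation slowdown) and the drop of the first
# backtracked state below the elongating state (controls how often
# excursions start; escape stays fast because recovery into elongation
# is downhill by the dGbt penalty)
.motifRaw <- function(land, m) {
  p <- m@position
  Gpost <- land$Gpost
  c(pause = Gpost[p + 1L] - land$Gpre[p],
    drop = Gpost[p + 1L] - Gpost[p],
    tail = (Gpost[p] - Gpost[p - 4L]) / 4)
}

# distance of a value from a target band [tgt, tgt + width]; the search
# drives this to zero so motif strength is controlled, not maximized
.bandMiss <- function(x, tgt, width = 0.5) {
  max(0, tgt - x) + max(0, x - tgt - width)
}

# per-position excess of a background sequence over the quiet band:
# translocation bias capped (no accidental strong pauses) and backward
# landscape descent capped over 1..6 steps (no accidental deep
# backtracking wells). Positions inside motif windows are exempt.
.backgroundExcess <- function(land, caps, skip = integer(0)) {
  Gpost <- land$Gpost
  L <- land$L
  ps <- setdiff(12:(L - 5L), skip)
  if (!length(ps)) return(0)
  dgTrans <- Gpost[ps + 1L] - land$Gpre[ps]
  ex <- pmax(0, dgTrans - caps[["bias"]])
  for (k in 1:6)
    ex <- ex + pmax(0, (Gpost[ps + 1L] - Gpost[ps + 1L - k]) -
                      caps[["descent"]])
  stats::setNames(ex, ps)
}

# total deficiency of a candidate at a motif; 0 means the motif is
# planted. A backtrack trap carries a moderate pause component too:
# excursions only start where incorporation is slow enough to compete.
.motifDeficiency <- function(land, m, targets) {
  raw <- .motifRaw(land, m)
  if (m@kind == "strong_pause") {
    .bandMiss(raw["pause"], targets[["strong_pause"]], 1.0)
  } else if (m@kind == "backtrack_trap") {
    # entry state below the elongating state, a gently descending well
    # behind it (deep but climbable excursions), and a co-located pause
    .bandMiss(raw["drop"], targets[["backtrack_trap"]], 1.0) +
      .bandMiss(raw["tail"], targets[["trap_tail"]], 0.5) +
      .bandMiss(raw["pause"], targets[["trap_pause"]], 1.5)
  } else 0
}

#' Generate a synthetic template with planted motifs
#'
#' Draws a random background sequence, quiets it, and plants motifs by
#' local search against the package's own energetics: a
#' \code{strong_pause} window is mutated to stabilize the
#' pre-translocated state relative to the post state at the site
#' (slowing incorporation there); a \code{backtrack_trap} window is
#' mutated so that the first backtracked state at the site lies below
#' the elongating state (favoring backtracking excursions), together
#' with a moderate pause. Deterministic given \code{seed}.
#'
#' Before planting, the background is driven into a quiet band: the
#' translocation bias and the backward landscape descent are capped at
#' every interior position outside motif windows, so that planted
#' motifs are the only strong kinetic features and no accidental
#' arrest-depth backtracking wells occur in the background.
#'
#' @param length template length (nt)
#' @param motifs list of \linkS4class{MotifSpec} objects; windows
#'   (including 4 nt of downstream context) must not overlap
#' @param seed integer seed for background and search
#' @param model an \linkS4class{EnergyModel}
#' @param temperature kelvin, used when scoring candidates
#' @param gc background GC fraction
#' @param iterations hill-climbing mutations attempted per motif
#' @param targetGap named numeric, target energy gaps (kcal/mol): the
#'   pre-state stabilization of a strong pause, the per-state landscape
#'   drop of a backtrack trap, and the pause component co-planted with a
#'   trap (\code{trap_pause}). The search drives each site into a band
#'   just above its target - motif strength is controlled, not
#'   maximized - and fails with the achieved values if the iteration
#'   budget runs out first
#' @param backgroundCaps named numeric: \code{bias}, the maximum
#'   background pre-vs-post stabilization (kcal/mol), and
#'   \code{descent}, the maximum drop of the backtracked landscape over
#'   1-6 backward steps (kcal/mol)
#' @param sanitationIterations mutation budget for quieting the
#'   background
#' @return a \code{DNAString} with attributes \code{"motifs"} (the spec
#'   list) and \code{"achieved"} (score per motif)
#' @examples
#' tpl <- makeTemplate(150, list(motifSpec("strong_pause", 80)), seed = 3)
#' attr(tpl, "achieved")
#' @export
makeTemplate <- function(length, motifs = list(), seed = 1,
                         model = energyModel(), temperature = 297.15,
                         gc = 0.5, iterations = 1500,
                         targetGap = c(strong_pause = 3.3,
                                       backtrack_trap = 2.2,
                                       trap_tail = 0.5,
                                       trap_pause = 3.5),
                         backgroundCaps = c(bias = 2.0, descent = 2.5),
                         sanitationIterations = 6000) {
  length <- as.integer(length)
  wins <- lapply(motifs, .motifWindow, L = length)
  if (base::length(wins) > 1L) {
    ord <- order(vapply(wins, `[`, numeric(1), 1L))
    for (i in seq_len(base::length(ord) - 1L))
      if (wins[[ord[i + 1L]]][1L] <= wins[[ord[i]]][2L])
        stop("motif windows overlap")
  }
  for (m in motifs)
    if (m@position + 4L > length || m@position - m@length + 1L < 1L)
      stop("motif at ", m@position, " does not fit the template")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  ch <- sample(names(probs), length, replace = TRUE, prob = probs)
  # quiet the background before planting anything; positions whose
  # 6-step backward lookback reaches a motif window are exempt too
  skipSites <- unlist(lapply(wins, function(w) w[1L]:w[2L]))
  skip <- unlist(lapply(wins, function(w) w[1L]:(w[2L] + 6L)))
  land <- .landscape(paste(ch, collapse = ""), model, temperature)
  ex <- .backgroundExcess(land, backgroundCaps, skip)
  tot <- sum(ex)
  for (it in seq_len(sanitationIterations)) {
    if (tot <= 0) break
    bad <- ex[ex > 0]
    tgt <- as.integer(names(bad))
    focus <- if (base::length(tgt) == 1L) tgt else
      sample(tgt, 1L, prob = bad)
    lo <- max(1L, focus - 14L); hi <- min(length, focus + 4L)
    sites <- setdiff(lo:hi, skipSites)
    if (!base::length(sites)) break
    site <- if (base::length(sites) == 1L) sites else sample(sites, 1L)
    cand <- ch
    cand[site] <- sample(setdiff(.BASES, ch[site]), 1L)
    landC <- .landscape(paste(cand, collapse = ""), model, temperature)
    exC <- .backgroundExcess(landC, backgroundCaps, skip)
    if (sum(exC) < tot) {
      ch <- cand; land <- landC; ex <- exC; tot <- sum(exC)
    }
  }
  # a small residual (well under one hop's thermal scale above the
  # band) is harmless; only a clearly unquiet background is an error
  if (tot > 2)
    stop("background sanitation failed: residual excess ",
         signif(tot, 4), " kcal/mol over the quiet band")
  achieved <- numeric(base::length(motifs))
  for (k in seq_along(motifs)) {
    m <- motifs[[k]]
    if (m@kind == "neutral") next
    win <- .motifWindow(m, length)
    land <- .landscape(paste(ch, collapse = ""), model, temperature)
    def <- .motifDeficiency(land, m, targetGap)
    for (it in seq_len(iterations)) {
      if (def <= 0) break
      site <- sample(win[1L]:win[2L], 1L)
      base <- sample(setdiff(.BASES, ch[site]), 1L)
      cand <- ch
      cand[site] <- base
      landC <- .landscape(paste(cand, collapse = ""), model, temperature)
      dc <- .motifDeficiency(landC, m, targetGap)
      if (dc < def) { def <- dc; ch <- cand; land <- landC }
    }
    raw <- .motifRaw(land, m)
    achieved[k] <- unname(
      if (m@kind == "strong_pause") raw["pause"] else raw["drop"])
    if (def > 0)
      stop("motif planting failed at ", m@position, " (", m@kind,
           "): residual deficiency ", signif(def, 4),
           " kcal/mol (pause gap ", signif(raw["pause"], 3),
           ", backtrack drop ", signif(raw["drop"], 3), ")")
  }
  out <- Biostrings::DNAString(paste(ch, collapse = ""))
  attr(out, "motifs") <- motifs
  attr(out, "achieved") <- achieved
  out
}

#' Build a scripted trajectory for analysis-layer tests
#'
#' Constructs a \linkS4class{Trajectory} from a scripted event list and
#' passes it through the same validator applied to engine output.
#'
#' @param times numeric event times (strictly increasing)
#' @param kinds character event kinds, from initiation, incorporation,
#'   backtrack_step, forward_step, termination
#' @param rnapIndex binding order label
#' @return a validated \linkS4class{Trajectory}
#' @examples
#' makeTrajectoryFixture(c(0, 1, 2, 3), c("initiation", "incorporation",
#'                                        "incorporation", "termination"))
#' @export
makeTrajectoryFixture <- function(times, kinds, rnapIndex = 1L) {
  stopifnot(length(times) == length(kinds))
  n <- 0L; off <- 0L
  pos <- numeric(length(times)); ns <- integer(length(times))
  offs <- integer(length(times))
  for (i in seq_along(kinds)) {
    switch(kinds[i],
      initiation = NULL,
      incorporation = { n <- n + 1L },
      backtrack_step = { off <- off + 1L },
      forward_step = { off <- off - 1L },
      termination = NULL,
      truncated = NULL,
      stop("unknown scripted event kind: ", kinds[i])
    )
    if (off < 0L) stop("scripted forward_step without prior backtracking")
    pos[i] <- n - off; ns[i] <- n; offs[i] <- off
  }
  tr <- new("Trajectory",
    rnapIndex = as.integer(rnapIndex), tInit = times[1L],
    tEnd = times[length(times)], finalLength = n,
    truncated = "truncated" %in% kinds,
    events = data.frame(time = times, position = pos, n = ns,
                        offset = offs, kind = kinds,
                        stringsAsFactors = FALSE)
  )
  validateTrajectory(tr)
  tr
}

#' Validate a trajectory record
#'
#' Checks the invariants shared by engine output and scripted fixtures:
#' non-decreasing times, unit lattice steps for movement events, and a
#' consistent backtrack offset.
#'
#' @param traj a \linkS4class{Trajectory}
#' @return \code{TRUE} invisibly; stops on violation
#' @export
validateTrajectory <- function(traj) {
  ev <- traj@events
  if (is.unsorted(ev$time)) stop("event times decrease")
  mv <- ev$kind %in% c("incorporation", "backtrack_step", "forward_step",
                       "push")
  lat <- ev$n - ev$offset
  if (any(mv)) {
    prev <- c(0L, lat[-length(lat)])
    step <- lat[mv] - prev[mv]
    if (any(abs(step) != 1L))
      stop("movement event with lattice step != 1")
  }
  if (any(ev$offset < 0L)) stop("negative backtrack offset")
  if (any(ev$offset > 0L & ev$kind == "incorporation"))
    stop("incorporation while backtracked")
  invisible(TRUE)
}

#' Minimum pairwise gap of a replicate's trajectories
#'
#' Evaluates the hard-core exclusion constraint on the piecewise-linear
#' position functions of all adjacent polymerase pairs: the gap
#' \code{xLead - xTrail - (d1 + d2)} at every breakpoint of either
#' trajectory while both molecules are on the template. Non-negative
#' everywhere (up to numerical tolerance) means no overlap.
#'
#' @param trajectories list of \linkS4class{Trajectory} (one replicate,
#'   ordered by binding order)
#' @param geometry a \linkS4class{TECGeometry}
#' @return the minimum gap (nt) over all pairs and times; \code{Inf}
#'   if fewer than two molecules
#' @export
minPairGap <- function(trajectories, geometry = tecGeometry()) {
  D <- geometry@footprintFront + geometry@footprintBack
  if (length(trajectories) < 2L) return(Inf)
  posFun <- function(tr) {
    ev <- tr@events
    keep <- !duplicated(ev$time, fromLast = TRUE)
    list(t = ev$time[keep], x = ev$position[keep])
  }
  gmin <- Inf
  for (i in seq_len(length(trajectories) - 1L)) {
    lead <- posFun(trajectories[[i]])
    trail <- posFun(trajectories[[i + 1L]])
    lo <- max(min(lead$t), min(trail$t))
    hi <- min(max(lead$t), max(trail$t))
    if (lo > hi) next
    ts <- sort(unique(c(lead$t, trail$t)))
    ts <- ts[ts >= lo & ts <= hi]
    if (!length(ts)) next
    xl <- stats::approx(lead$t, lead$x, ts, rule = 2)$y
    xt <- stats::approx(trail$t, trail$x, ts, rule = 2)$y
    gmin <- min(gmin, min(xl - xt - D))
  }
  gmin
}
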