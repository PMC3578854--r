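#' Construct a run configuration
#'
#' @param template character or \code{DNAString}, sense strand 5'->3'
#'   (A/C/G/T only)
#' @param params a \linkS4class{KineticParams}
#' @param nRnapMax maximum number of polymerases allowed on the template
#' @param initiationInterval seconds between successive initiation
#'   attempts (default 0.5 s); an attempt succeeds only if the
#'   promoter-proximal footprint is clear and is otherwise retried at the
#'   next interval
#' @param nReplicates number of independent replicates
#' @param seed master seed; every random draw in the run derives from it
#' @param tMax safety cap on simulated time (s); trajectories still
#'   running at \code{tMax} are truncated and flagged
#' @param model an \linkS4class{EnergyModel}
#' @param templateName label for outputs
#' @return a \linkS4class{RunConfig}
#' @examples
#' cfg <- runConfig(makeTemplate(120, seed = 1),
#'                  kineticParams(ntpConc = 250), nReplicates = 2, seed = 7)
#' @export
runConfig <- function(template, params, nRnapMax = 10L,
                      initiationInterval = 0.5, nReplicates = 1L,
                      seed = 1L, tMax = 1e4, model = energyModel(),
                      templateName = "template") {
  if (is(template, "DNAStringSet")) {
    if (length(template) != 1L)
      stop("supply a single template (or index the DNAStringSet)")
    if (!is.null(names(template))) templateName <- names(template)[1L]
    template <- template[[1L]]
  }
  if (is.character(template)) template <- Biostrings::DNAString(template)
  new("RunConfig",
    template = template, templateName = templateName, params = params,
    model = model, nRnapMax = as.integer(nRnapMax),
    initiationInterval = as.numeric(initiationInterval),
    nReplicates = as.integer(nReplicates), tMax = as.numeric(tMax),
    seed = as.integer(seed)
  )
}

#' One step of the Gillespie first-reaction method
#'
#' Draws an independent exponential waiting time for every reaction
#' channel and executes the earliest: returns the realized waiting time
#' and the winning channel. Channels with zero rate never fire; if all
#' rates are zero the state is stalled and an error is raised.
#'
#' @param rates named numeric vector of channel rates (1/s)
#' @return list with \code{dt} (s) and \code{channel} (name or index of
#'   the winning channel)
#' @examples
#' set.seed(1)
#' gillespieStep(c(incorporation = 20, backtrack = 0.1))
#' @export
gillespieStep <- function(rates) {
  if (length(rates) == 0L || all(rates <= 0))
    stop("stalled state: all channel rates are zero")
  dts <- rep(Inf, length(rates))
  pos <- rates > 0
  dts[pos] <- rexp(sum(pos), rates[pos])
  i <- which.min(dts)
  list(dt = dts[i],
       channel = if (!is.null(names(rates))) names(rates)[i] else i)
}

#' Time of contact between two linearly moving polymerases
#'
#' Both molecules move uniformly between reactions, x(t) = x0 + v (t -
#' tStart). Contact occurs when the gap between the leading molecule's
#' trailing edge and the trailing molecule's leading edge closes:
#' xL - xT = d1 + d2. Returns the earliest contact time within
#' \code{[tStart, tEnd]}, or \code{NA} if the pair does not meet before
#' \code{tEnd}.
#'
#' @param xT,vT trailing polymerase position (nt, at \code{tStart}) and
#'   velocity (nt/s)
#' @param xL,vL leading polymerase position and velocity
#' @param tStart,tEnd time window (s)
#' @param d1 trailing molecule's front footprint (nt)
#' @param d2 leading molecule's back footprint (nt)
#' @return contact time in seconds, or \code{NA_real_}
#' @examples
#' collisionTime(10, 2, 30, 1)  # meet at t = 20
#' @export
collisionTime <- function(xT, vT, xL, vL, tStart = 0, tEnd = Inf,
                          d1 = 0, d2 = 0) {
  gap0 <- xL - xT - (d1 + d2)
  if (gap0 < -1e-9)
    stop("exclusion violated: molecules already overlap (gap ", gap0, ")")
  rel <- vT - vL
  if (rel <= 1e-12) return(NA_real_)
  tc <- tStart + max(gap0, 0) / rel
  if (tc > tEnd) NA_real_ else tc
}

#' Resolve a collision between two polymerases
#'
#' Applies the collision rules for the six contact categories, named by
#' the trailing (T) and leading (L) molecule's motion: N = normal
#' elongation, Bb = backtracking moving backward, Bf = backtracking
#' moving forward.
#'
#' \itemize{
#' \item \code{TN.LN}, \code{TN.LBf}: the trailing molecule transmits its
#'   pushing force to the leader (assisting, +F) and receives the
#'   reaction (-F); while in contact the trailer cannot advance into the
#'   leader and the leader cannot move backward. Both molecules' rates
#'   are recomputed.
#' \item \code{TN.LBb}: as above; the leader's backward hop is cancelled
#'   and, being blocked backward, its only available move is the pushed
#'   forward step.
#' \item \code{TBf.LBb}, \code{TBf.LBf}, \code{TBb.LBb} (both
#'   backtracking): perfectly elastic - the pair exchange their intended
#'   step directions and remaining flight times; positions are unchanged.
#' }
#'
#' Contact categories with a backtracked trailer and a leader in normal
#' elongation (\code{TBf.LN}, \code{TBb.LN}) are resolved as
#' \code{TN.LN}-style roadblocks.
#'
#' Each molecule is described by a list with fields \code{mode}
#' ("elongating"/"backtracked"), \code{n}, \code{offset}, \code{x}
#' (continuous position at contact), \code{pendDir} (intended step, -1,
#' 0 or +1) and \code{pendTime} (absolute completion time of the
#' intended step).
#'
#' @param case collision category string, e.g. \code{"TN.LN"}
#' @param trailing,leading molecule records (see Details)
#' @param tc contact time (s)
#' @param params a \linkS4class{KineticParams}; \code{params@collisionForce}
#'   is the transmitted force
#' @return list with updated \code{trailing} and \code{leading} records,
#'   \code{contact} (logical: does a lasting roadblock contact form),
#'   \code{forceTrailing}/\code{forceLeading} (pN force modifiers while
#'   in contact) and \code{redrawTrailing}/\code{redrawLeading} (should
#'   the molecule's reaction be redrawn)
#' @examples
#' tr <- list(mode = "elongating", n = 40, offset = 0, x = 40.5,
#'            pendDir = 1, pendTime = 1.02)
#' ld <- list(mode = "elongating", n = 75, offset = 0, x = 74.5,
#'            pendDir = 1, pendTime = 1.05)
#' resolveCollision("TN.LN", tr, ld, tc = 1.0,
#'                  params = kineticParams(ntpConc = 250))
#' @export
resolveCollision <- function(case, trailing, leading, tc, params) {
  valid <- c("TN.LN", "TN.LBb", "TN.LBf", "TBf.LBb", "TBf.LBf",
             "TBb.LBb", "TBf.LN", "TBb.LN")
  if (!case %in% valid)
    stop("unreachable collision case: ", case)
  Fc <- params@collisionForce
  elastic <- trailing$mode == "backtracked" && leading$mode == "backtracked"
  if (elastic) {
    remT <- trailing$pendTime - tc
    remL <- leading$pendTime - tc
    newT <- trailing
    newL <- leading
    newT$pendDir <- leading$pendDir
    newT$pendTime <- tc + remL
    newL$pendDir <- trailing$pendDir
    newL$pendTime <- tc + remT
    list(trailing = newT, leading = newL, contact = FALSE,
         forceTrailing = 0, forceLeading = 0,
         redrawTrailing = FALSE, redrawLeading = FALSE)
  } else {
    # roadblock/force transmission: trailer pushes the leader forward,
    # leader pushes back; trailer cannot advance, leader cannot retreat
    list(trailing = trailing, leading = leading, contact = TRUE,
         forceTrailing = -Fc, forceLeading = +Fc,
         redrawTrailing = TRUE, redrawLeading = TRUE)
  }
}

# ---- internal engine ---------------------------------------------------

.EVENT_KINDS <- c("initiation", "incorporation", "backtrack_step",
                  "forward_step", "collision", "push", "termination",
                  "truncated", "release")

.deriveSeeds <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  s <- sample.int(2147483646L, k)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

# precompute everything sequence-dependent once per config
.prepEngine <- function(config) {
  params <- config@params
  model <- config@model
  g <- model@geometry
  temp <- params@temperature
  land <- .landscape(config@template, model, temp)
  L <- land$L
  d1 <- g@footprintFront
  d2 <- g@footprintBack
  nStop <- L - d1
  if (nStop < 2L)
    stop("template too short for the polymerase footprint")
  ch <- land$chars
  ntp <- .NTP_OF_BASE[ch]
  kT <- kBT(temp)
  Gpost <- land$Gpost # index p+1, p = 0..L
  Gpre <- land$Gpre   # index p,   p = 1..L
  # Gpost is indexed by p+1 (p = 0..L); shift accordingly
  dgTrans <- Gpost[2:(L + 1L)] - Gpre                  # index n = 1..L
  ddGb <- c(Inf, Gpost[2:L] - Gpost[3:(L + 1L)])       # q -> q-1, index q
  ddGf <- c(Gpost[3:(L + 1L)] - Gpost[2:L], Inf)       # q -> q+1, index q
  list(
    L = L, d1 = d1, d2 = d2, D = d1 + d2, nStop = nStop,
    delta = g@delta, kT = kT, temp = temp,
    vmaxP = unname(params@vmax[ntp]), kmP = unname(params@km[ntp]),
    concP = unname(params@ntpConc[ntp]),
    k0 = params@k0, dG0 = params@dG0, dGbt = params@dGbt,
    f0 = params@force, Fc = params@collisionForce,
    dgTrans = dgTrans, ddGb = ddGb, ddGf = ddGf
  )
}

# incorporation rate for an elongating molecule with 3' end at n,
# under total force f (pN)
.rateInc <- function(pp, n, f) {
  bias <- if (n == 0L) 0 else
    exp((pp$dgTrans[n] - f * pp$delta / .PNNM_PER_KCAL) / pp$kT)
  i <- n + 1L
  pp$vmaxP[i] * pp$concP[i] / (pp$concP[i] + pp$kmP[i] * (1 + bias))
}

# hop rate from lattice site q; dir = -1 backward, +1 forward; pen
# shifts the target energy (dGbt pathway-crossing penalty)
.rateHop <- function(pp, q, dir, f, pen = 0) {
  ddG <- if (dir < 0L) pp$ddGb[q] else pp$ddGf[q]
  if (!is.finite(ddG)) return(0)
  tilt <- -dir * f * pp$delta / .PNNM_PER_KCAL / 2
  pp$k0 * exp(-(max(0, ddG + pen) + pp$dG0 + tilt) / pp$kT)
}

# one replicate of the event loop; N = 1 is the single-round special case
.runReplicate <- function(pp, N, initInterval, tMax, rnapSeeds,
                          collisionsOn = TRUE) {
  # per-molecule random streams so collisions never perturb other
  # molecules' draws and N = 1 reproduces the single-round run bit-exactly
  streams <- vector("list", N)
  for (j in seq_len(N)) {
    set.seed(rnapSeeds[j])
    streams[[j]] <- get(".Random.seed", globalenv())
  }
  drawStep <- function(j, rates) {
    assign(".Random.seed", streams[[j]], envir = globalenv())
    res <- gillespieStep(rates)
    streams[[j]] <<- get(".Random.seed", globalenv())
    res
  }

  # molecule state vectors
  active <- integer(N)   # 0 pending, 1 on template, 2 finished
  mode <- integer(N)     # 1 elongating, 2 backtracked
  n <- integer(N); off <- integer(N)
  tSeg <- numeric(N); xSeg <- numeric(N); vel <- numeric(N)
  pendT <- rep(Inf, N); pendDir <- integer(N); pendKind <- integer(N)
  contactWith <- integer(N) # leader index this molecule is pressing on
  tInit <- rep(NA_real_, N); tEnd <- rep(NA_real_, N)
  truncated <- logical(N)

  # event recording (chunked matrices)
  buf <- vector("list", N); cnt <- integer(N)
  rec <- function(j, t, x, kind) {
    k <- cnt[j] + 1L
    if (is.null(buf[[j]]) || k > nrow(buf[[j]])) {
      add <- matrix(NA_real_, nrow = max(256L, k), ncol = 5L)
      buf[[j]] <<- rbind(buf[[j]], add)
    }
    buf[[j]][k, ] <<- c(t, x, n[j], off[j], kind)
    cnt[j] <<- k
  }

  posAt <- function(j, t) xSeg[j] + vel[j] * (t - tSeg[j])
  lattice <- function(j) n[j] - off[j]
  fMod <- function(j) {
    pp$Fc * sum(contactWith == j) - pp$Fc * (contactWith[j] > 0L)
  }
  isLeaderInContact <- function(j) any(contactWith == j)

  redraw <- function(j, t) {
    x <- posAt(j, t)
    xSeg[j] <<- x; tSeg[j] <<- t
    f <- pp$f0 + fMod(j)
    blockedF <- contactWith[j] > 0L      # trailer in contact
    blockedB <- isLeaderInContact(j)     # leader in contact
    q <- lattice(j)
    rates <- numeric(0)
    kinds <- integer(0); dirs <- integer(0)
    if (mode[j] == 1L) {
      if (!blockedF) {
        rates <- c(rates, .rateInc(pp, n[j], f))
        kinds <- c(kinds, 1L); dirs <- c(dirs, 1L)
      }
      if (!blockedB && n[j] >= 2L) {
        rates <- c(rates, .rateHop(pp, q, -1L, f, pen = pp$dGbt))
        kinds <- c(kinds, 4L); dirs <- c(dirs, -1L)
      }
    } else {
      if (!blockedB && q >= 2L) {
        rates <- c(rates, .rateHop(pp, q, -1L, f))
        kinds <- c(kinds, 2L); dirs <- c(dirs, -1L)
      }
      if (!blockedF) {
        pen <- if (off[j] == 1L) -pp$dGbt else 0
        rates <- c(rates, .rateHop(pp, q, 1L, f, pen = pen))
        kinds <- c(kinds, 3L); dirs <- c(dirs, 1L)
      }
    }
    keep <- rates > 0
    if (!any(keep)) { # fully blocked; dormant until released
      pendT[j] <<- Inf; pendDir[j] <<- 0L; pendKind[j] <<- 0L
      vel[j] <<- 0
      return(invisible())
    }
    res <- drawStep(j, rates[keep])
    i <- which(keep)[res$channel]
    pendT[j] <<- t + res$dt
    pendDir[j] <<- dirs[i]
    pendKind[j] <<- kinds[i]
    vel[j] <<- (lattice(j) + dirs[i] - x) / res$dt
  }

  gapNow <- function(lead, trail, t) posAt(lead, t) - posAt(trail, t) - pp$D

  releaseContacts <- function(j, t) {
    # after j moved (or terminated): drop any contact whose gap opened.
    # The partner's velocity changes, so a breakpoint is recorded to keep
    # the emitted piecewise-linear record faithful.
    if (contactWith[j] > 0L) {
      i <- contactWith[j]
      if (active[i] != 1L || gapNow(i, j, t) > 1e-9) {
        contactWith[j] <<- 0L
        if (active[i] == 1L) { rec(i, t, posAt(i, t), 9L); redraw(i, t) }
      }
    }
    for (k in which(contactWith == j)) {
      if (active[j] != 1L || gapNow(j, k, t) > 1e-9) {
        contactWith[k] <<- 0L
        if (active[k] == 1L) { rec(k, t, posAt(k, t), 9L); redraw(k, t) }
      }
    }
  }

  execEvent <- function(j, t) {
    kind <- pendKind[j]
    target <- lattice(j) + pendDir[j]
    xSeg[j] <<- target; tSeg[j] <<- t; vel[j] <<- 0
    if (kind == 1L) {            # incorporation
      n[j] <<- n[j] + 1L
      rec(j, t, target, 2L)
    } else if (kind == 4L) {     # entry into backtracking
      mode[j] <<- 2L; off[j] <<- 1L
      rec(j, t, target, 3L)
    } else if (kind == 2L) {     # deeper backward hop
      off[j] <<- off[j] + 1L
      rec(j, t, target, 3L)
    } else if (kind == 3L) {     # forward hop / re-entry / pushed step
      pushed <- isLeaderInContact(j)
      off[j] <<- off[j] - 1L
      if (off[j] == 0L) mode[j] <<- 1L
      rec(j, t, target, if (pushed) 6L else 4L)
    }
    if (mode[j] == 1L && n[j] >= pp$nStop) {  # leading edge at last base
      rec(j, t, target, 7L)
      active[j] <<- 2L; tEnd[j] <<- t
      pendT[j] <<- Inf
    }
    releaseContacts(j, t)
    if (active[j] == 1L) redraw(j, t)
  }

  handleCollision <- function(i, j, tc) {
    # i leads, j trails; contact at tc
    xL <- posAt(i, tc)
    xT <- xL - pp$D
    labT <- if (mode[j] == 1L) "TN" else if (pendDir[j] > 0L) "TBf"
            else "TBb"
    labL <- if (mode[i] == 1L) "LN" else if (pendDir[i] > 0L) "LBf"
            else "LBb"
    case <- paste(labT, labL, sep = ".")
    mk <- function(k, x) list(
      mode = if (mode[k] == 1L) "elongating" else "backtracked",
      n = n[k], offset = off[k], x = x,
      pendDir = pendDir[k], pendTime = pendT[k]
    )
    res <- resolveCollision(case, mk(j, xT), mk(i, xL), tc, paramsLite)
    xSeg[j] <<- xT; tSeg[j] <<- tc
    xSeg[i] <<- xL; tSeg[i] <<- tc
    rec(j, tc, xT, 5L); rec(i, tc, xL, 5L)
    applyContact <- function() {
      contactWith[j] <<- i
      redraw(i, tc); redraw(j, tc)
    }
    if (res$contact) {
      applyContact()
    } else {
      # elastic: adopt the exchanged intentions, provided they are
      # feasible (no hop beyond the template start, no violation of a
      # standing contact with a third molecule) and actually separate
      # the pair; otherwise the contact degrades to a roadblock, which
      # preserves exclusion by blocking the approaching channels
      feas <- function(k, upd) {
        dir <- upd$pendDir
        dir != 0L &&
          !(dir < 0L && (lattice(k) - 1L < 1L || isLeaderInContact(k))) &&
          !(dir > 0L && contactWith[k] > 0L) &&
          is.finite(upd$pendTime) && upd$pendTime > tc
      }
      vNew <- function(k, upd) {
        (lattice(k) + upd$pendDir - posAt(k, tc)) / (upd$pendTime - tc)
      }
      if (feas(j, res$trailing) && feas(i, res$leading) &&
          vNew(j, res$trailing) <= vNew(i, res$leading) + 1e-12) {
        for (side in c("T", "L")) {
          k <- if (side == "T") j else i
          upd <- if (side == "T") res$trailing else res$leading
          pendDir[k] <<- upd$pendDir
          pendKind[k] <<- if (upd$pendDir < 0L) 2L else 3L
          pendT[k] <<- upd$pendTime
          vel[k] <<- vNew(k, upd)
          xSeg[k] <<- posAt(k, tc); tSeg[k] <<- tc
        }
      } else {
        applyContact()
      }
    }
  }

  # lightweight params stand-in for resolveCollision (only the collision
  # force is consulted there)
  paramsLite <- new("KineticParams",
    vmax = stats::setNames(rep(1, 4), .NTPS),
    km = stats::setNames(rep(1, 4), .NTPS),
    ntpConc = stats::setNames(rep(1, 4), .NTPS),
    k0 = 1, dG0 = 0, dGbt = 0, force = pp$f0, collisionForce = pp$Fc,
    temperature = pp$temp
  )

  nStarted <- 0L
  tNextInit <- 0
  tNow <- 0
  collStreak <- 0L
  repeat {
    act <- which(active == 1L)
    if (length(act) == 0L && nStarted >= N) break
    tEv <- if (length(act)) min(pendT[act]) else Inf
    jEv <- if (length(act)) act[which.min(pendT[act])] else NA_integer_
    tIn <- if (nStarted < N) tNextInit else Inf
    tHor <- min(tEv, tIn)
    # earliest pairwise collision before the next scheduled event
    tColl <- Inf; collPair <- NULL
    if (collisionsOn && length(act) >= 2L) {
      for (a in seq_len(length(act) - 1L)) {
        i <- act[a]; j <- act[a + 1L]   # i initiated earlier => leads
        if (contactWith[j] == i) next
        tc <- tryCatch(
          collisionTime(posAt(j, tNow), vel[j], posAt(i, tNow), vel[i],
                        tStart = tNow, tEnd = tHor + 1e-12,
                        d1 = pp$d1, d2 = pp$d2),
          error = function(e) stop("exclusion invariant breached between ",
                                   i, " and ", j, ": ", conditionMessage(e))
        )
        if (!is.na(tc) && tc < tColl) { tColl <- tc; collPair <- c(i, j) }
      }
    }
    tStar <- min(tHor, tColl)
    if (tStar > tMax) {
      for (j in which(active == 1L)) {
        rec(j, tMax, posAt(j, tMax), 8L)
        truncated[j] <- TRUE
        tEnd[j] <- tMax
        active[j] <- 2L
      }
      break
    }
    if (!is.null(collPair) && tColl <= tHor + 1e-12) {
      collStreak <- collStreak + 1L
      if (collStreak > 10000L)
        stop("livelock: too many collision resolutions without progress")
      handleCollision(collPair[1L], collPair[2L], tColl)
      tNow <- tColl
    } else if (tIn <= tEv) {
      # initiation attempt: promoter footprint must be unoccupied
      clear <- !length(act) || min(vapply(act, posAt, numeric(1),
                                          t = tIn)) >= pp$D
      if (clear) {
        nStarted <- nStarted + 1L
        k <- nStarted
        active[k] <- 1L; mode[k] <- 1L; n[k] <- 0L; off[k] <- 0L
        xSeg[k] <- 0; tSeg[k] <- tIn; vel[k] <- 0
        tInit[k] <- tIn
        rec(k, tIn, 0, 1L)
        redraw(k, tIn)
      }
      tNextInit <- tNextInit + initInterval
      tNow <- tIn
      collStreak <- 0L
    } else {
      execEvent(jEv, tEv)
      tNow <- tEv
      collStreak <- 0L
    }
  }

  # assemble trajectories
  out <- vector("list", nStarted)
  for (j in seq_len(nStarted)) {
    m <- buf[[j]][seq_len(cnt[j]), , drop = FALSE]
    ev <- data.frame(
      time = m[, 1L], position = m[, 2L], n = as.integer(m[, 3L]),
      offset = as.integer(m[, 4L]), kind = .EVENT_KINDS[m[, 5L]],
      stringsAsFactors = FALSE
    )
    out[[j]] <- new("Trajectory",
      rnapIndex = j, tInit = tInit[j],
      tEnd = if (is.na(tEnd[j])) m[nrow(m), 1L] else tEnd[j],
      finalLength = n[j], truncated = truncated[j], events = ev
    )
  }
  out
}

.simulate <- function(config, N, mode) {
  oldSeed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed))
      assign(".Random.seed", oldSeed, envir = globalenv())
  })
  pp <- .prepEngine(config)
  R <- config@nReplicates
  repSeeds <- .deriveSeeds(config@seed, R)
  reps <- vector("list", R)
  for (r in seq_len(R)) {
    rnapSeeds <- .deriveSeeds(repSeeds[r], N)
    reps[[r]] <- .runReplicate(pp, N, config@initiationInterval,
                               config@tMax, rnapSeeds,
                               collisionsOn = (N > 1L))
  }
  new("TrafficSim", mode = mode, config = config, replicates = reps)
}

#' Single-round simulation (one polymerase)
#'
#' Runs the sequence-dependent stochastic elongation kinetics for a
#' single polymerase per replicate (the single-round approach). The
#' multi-molecule limit of the engine reduces to this case exactly: with
#' the shared per-molecule seeding discipline,
#' \code{simulateMRA} with \code{nRnapMax = 1} is bit-identical.
#'
#' @param config a \linkS4class{RunConfig}; \code{nRnapMax} is ignored
#' @return a \linkS4class{TrafficSim}
#' @examples
#' cfg <- runConfig(makeTemplate(120, seed = 1),
#'                  kineticParams(ntpConc = 250), nReplicates = 2, seed = 7)
#' sim <- simulateSRA(cfg)
#' @export
simulateSRA <- function(config) .simulate(config, 1L, "sra")

#' Multiple-round simulation (polymerase traffic with collisions)
#'
#' Event loop for up to \code{nRnapMax} polymerases on the same
#' template: each molecule's next reaction is drawn by the Gillespie
#' first-reaction method; positions are interpolated linearly between
#' reactions; the earliest of (molecular event, pairwise collision,
#' initiation attempt) is executed. Collisions are resolved by force
#' transmission, pushing, or elastic exchange (see
#' \code{\link{resolveCollision}}); hard-core exclusion between
#' footprints is enforced throughout. New molecules initiate at the
#' promoter at fixed intervals when the promoter-proximal footprint is
#' clear; each molecule terminates and is removed when its leading edge
#' reaches the last template base.
#'
#' @param config a \linkS4class{RunConfig}
#' @return a \linkS4class{TrafficSim}
#' @examples
#' cfg <- runConfig(makeTemplate(120, seed = 1),
#'                  kineticParams(ntpConc = 250), nRnapMax = 3,
#'                  nReplicates = 2, seed = 7)
#' sim <- simulateMRA(cfg)
#' @export
simulateMRA <- function(config) .simulate(config, config@nRnapMax, "mra")
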