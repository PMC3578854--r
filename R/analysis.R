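# All quantile statistics in the package go through this one definition
# (linear interpolation, the default type-7 quantile), so third-quartile
# summaries agree across analyses.
.q3 <- function(x) unname(quantile(x, 0.75, type = 7, names = FALSE))

.flatTrajectories <- function(sim, rnapIndex = NULL) {
  out <- list()
  for (rep in sim@replicates)
    for (tr in rep)
      if (is.null(rnapIndex) || tr@rnapIndex %in% rnapIndex)
        out[[length(out) + 1L]] <- tr
  out
}

.maxDwellPosition <- function(sim) {
  L <- nchar(as.character(sim@config@template))
  L - sim@config@model@geometry@footprintFront - 1L
}

#' Per-position dwell-time profile of a trajectory ensemble
#'
#' The dwell time at template position i is the time between the
#' incorporation that brings the RNA 3' end to i and the incorporation
#' advancing past i; backtracking excursions that start from i fall
#' inside that interval and are charged to i. Samples are pooled across
#' replicates (and, for multi-molecule runs, across polymerases unless
#' \code{rnapIndex} selects specific binding orders), and summarized by
#' the third quartile (TQ) per position.
#'
#' @param sim a \linkS4class{TrafficSim}
#' @param rnapIndex optional integer vector restricting to specific
#'   binding orders
#' @return a \linkS4class{DwellProfile}
#' @examples
#' cfg <- runConfig(makeTemplate(120, seed = 1),
#'                  kineticParams(ntpConc = 250), nReplicates = 4, seed = 7)
#' dwellProfile(simulateSRA(cfg))
#' @export
dwellProfile <- function(sim, rnapIndex = NULL) {
  trs <- .flatTrajectories(sim, rnapIndex)
  if (!length(trs)) stop("no trajectories to profile")
  posAll <- integer(0); dAll <- numeric(0)
  for (tr in trs) {
    ev <- tr@events
    t <- ev$time[ev$kind == "incorporation"]
    if (length(t) < 2L) next
    posAll <- c(posAll, seq_len(length(t) - 1L))
    dAll <- c(dAll, diff(t))
  }
  if (!length(posAll)) stop("no dwell samples in the ensemble")
  samples <- split(dAll, posAll)
  positions <- as.integer(names(samples))
  tq <- vapply(samples, .q3, numeric(1))
  names(tq) <- names(samples)
  domain <- seq_len(.maxDwellPosition(sim))
  new("DwellProfile",
    samples = samples, tq = tq, tauMin = min(tq),
    positions = positions,
    missing = setdiff(domain, positions)
  )
}

#' Group positions into clusters
#'
#' Maximal groups in which consecutive members are within \code{gap} bp
#' of each other (single-linkage chaining).
#'
#' @param positions integer vector (1-based template positions)
#' @param gap maximum intra-cluster spacing (bp, default 3)
#' @return list of integer vectors
#' @examples
#' clusterPositions(c(10, 12, 20))
#' @export
clusterPositions <- function(positions, gap = 3) {
  if (!length(positions)) return(list())
  p <- sort(unique(as.integer(positions)))
  grp <- cumsum(c(1L, diff(p) > gap))
  unname(split(p, grp))
}

#' Call pause sites from a dwell profile
#'
#' Position i is called a pause site when its third-quartile dwell time
#' exceeds \code{tauMin / alpha}, where \code{tauMin} is the shortest
#' third-quartile dwell time on the template. Larger \code{alpha} means
#' a larger implied absolute dwell threshold. Calls are grouped into
#' 3-bp clusters.
#'
#' @param profile a \linkS4class{DwellProfile}
#' @param alpha positive threshold parameter (the original single-round
#'   literature value is 0.05)
#' @param clusterGap clustering distance in bp (default 3)
#' @return a \linkS4class{PauseReport}
#' @examples
#' prof <- new("DwellProfile", samples = list(), tauMin = 0.1,
#'             tq = c(`5` = 1.5, `9` = 0.9), positions = c(5L, 9L),
#'             missing = integer(0))
#' callPauses(prof, alpha = 0.1)   # threshold 1 s: only position 5 called
#' @export
callPauses <- function(profile, alpha, clusterGap = 3) {
  if (alpha <= 0) stop("alpha must be positive")
  threshold <- profile@tauMin / alpha
  hit <- profile@tq > threshold
  pos <- profile@positions[hit]
  new("PauseReport",
    positions = pos, tq = profile@tq[hit], alpha = alpha,
    threshold = threshold,
    clusters = clusterPositions(pos, clusterGap)
  )
}

# cluster-level confusion counts between predicted and true pause sites.
# A truth cluster is detected if any predicted position lies within
# matchTol of any of its members; an undetected predicted cluster is a
# false positive.
.matchCounts <- function(calls, truth, clusterGap = 3, matchTol = 3) {
  cc <- clusterPositions(calls, clusterGap)
  tc <- clusterPositions(truth, clusterGap)
  near <- function(a, b) {
    length(a) && length(b) && min(vapply(a, function(x)
      min(abs(b - x)), numeric(1))) <= matchTol
  }
  tpHit <- vapply(tc, function(t) any(vapply(cc, near, logical(1), b = t)),
                  logical(1))
  fpHit <- vapply(cc, function(p) !any(vapply(tc, near, logical(1), b = p)),
                  logical(1))
  c(tp = sum(tpHit), fn = sum(!tpHit), fp = sum(fpHit))
}

#' Pause-prediction quality against experimental pause sites
#'
#' Predicted and experimental pause positions are grouped into 3-bp
#' clusters; detected experimental clusters are true positives,
#' undetected ones false negatives, and predicted clusters with no
#' experimental counterpart false positives. The quality statistic is
#' \code{Q = TP / (TP + FP + FN)} by default (\code{form = "fraction"});
#' \code{form = "ratio"} instead reports the incorrect-to-correct
#' proportion \code{(FP + FN) / TP}. With multiple sequences, counts are
#' pooled and a bootstrap over the sequence set yields a standard
#' deviation for Q.
#'
#' @param calls numeric vector of predicted pause positions, or a named
#'   list of such vectors (one per sequence)
#' @param truth experimental pause positions, matching the shape of
#'   \code{calls}
#' @param clusterGap,matchTol clustering and matching distances (bp)
#' @param form "fraction" (default) or "ratio"
#' @param bootstrap number of bootstrap resamples of the sequence set
#'   (0 = none)
#' @param bootstrapSeed seed for the bootstrap
#' @return a \linkS4class{QualityResult}
#' @examples
#' qualityMetric(c(11, 80), c(10, 50))  # TP 1, FN 1, FP 1
#' @export
qualityMetric <- function(calls, truth, clusterGap = 3, matchTol = 3,
                          form = c("fraction", "ratio"), bootstrap = 0,
                          bootstrapSeed = 1) {
  form <- match.arg(form)
  if (!is.list(calls)) calls <- list(seq1 = calls)
  if (!is.list(truth)) truth <- list(seq1 = truth)
  if (!identical(sort(names(calls)), sort(names(truth))) &&
      length(calls) != length(truth))
    stop("calls and truth must describe the same sequences")
  if (!sum(lengths(truth)))
    stop("quality metric undefined: no experimental pause sites supplied")
  nm <- if (!is.null(names(calls))) names(calls) else seq_along(calls)
  counts <- vapply(seq_along(calls), function(i)
    .matchCounts(calls[[i]], truth[[i]], clusterGap, matchTol),
    numeric(3))
  qOf <- function(cnt) {
    tp <- unname(cnt[1]); fn <- unname(cnt[2]); fp <- unname(cnt[3])
    if (form == "fraction") {
      if (tp + fp + fn == 0) NA_real_ else tp / (tp + fp + fn)
    } else {
      if (tp == 0) Inf else (fp + fn) / tp
    }
  }
  tot <- rowSums(counts)
  bsd <- NA_real_
  if (bootstrap > 0 && ncol(counts) >= 2L) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(bootstrapSeed)
    qs <- replicate(bootstrap, {
      idx <- sample.int(ncol(counts), ncol(counts), replace = TRUE)
      qOf(rowSums(counts[, idx, drop = FALSE]))
    })
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    bsd <- sd(qs[is.finite(qs)])
  }
  new("QualityResult",
    tp = as.integer(tot[1]), fn = as.integer(tot[2]),
    fp = as.integer(tot[3]), q = qOf(tot), bootstrapSd = bsd
  )
}

#' Tune the pause-calling threshold parameter
#'
#' Grid search for the \code{alpha} minimizing the proportion of
#' incorrect to correct predictions, (FP + FN) / TP, pooled over
#' sequences after 3-bp clustering. Ties resolve to the smallest alpha.
#'
#' @param profiles list of \linkS4class{DwellProfile} objects, one per
#'   sequence
#' @param truth list of experimental pause-position vectors, parallel to
#'   \code{profiles}
#' @param grid candidate alpha values (ascending)
#' @param clusterGap,matchTol clustering and matching distances (bp)
#' @return the selected alpha (numeric scalar) with attribute
#'   \code{"objective"} (the attained objective value per grid point)
#' @export
tuneAlpha <- function(profiles, truth, grid = seq(0.01, 1, by = 0.01),
                      clusterGap = 3, matchTol = 3) {
  if (!length(profiles) || length(profiles) != length(truth))
    stop("profiles and truth must be parallel non-empty lists")
  obj <- vapply(grid, function(a) {
    cnt <- rowSums(vapply(seq_along(profiles), function(i)
      .matchCounts(callPauses(profiles[[i]], a, clusterGap)@positions,
                   truth[[i]], clusterGap, matchTol),
      numeric(3)))
    if (cnt[1] == 0) Inf else (cnt[3] + cnt[2]) / cnt[1]
  }, numeric(1))
  if (all(!is.finite(obj)))
    stop("objective undefined: no true positives anywhere on the grid")
  best <- grid[which.min(obj)]
  structure(best, objective = stats::setNames(obj, grid))
}

#' Backtracking excursion distances
#'
#' One sample per backtracking excursion: the maximum distance (nt) the
#' active site retreated behind the excursion's starting position before
#' the polymerase re-entered elongation (or the record ended).
#'
#' @param sim a \linkS4class{TrafficSim}
#' @return numeric vector of excursion distances (nt); empty if no
#'   backtracking occurred
#' @export
backtrackDistances <- function(sim) {
  out <- numeric(0)
  for (tr in .flatTrajectories(sim)) {
    offs <- tr@events$offset
    cur <- 0L
    for (o in offs) {
      if (o > 0L) {
        if (o > cur) cur <- o
      } else if (cur > 0L) {
        out <- c(out, cur)
        cur <- 0L
      }
    }
    if (cur > 0L) out <- c(out, cur)  # excursion unfinished at record end
  }
  out
}

#' Completion-time distributions by binding order
#'
#' Time from a polymerase's initiation to its termination, per binding
#' order across replicates. Truncated trajectories (time cap hit) are
#' excluded and counted in the \code{"nTruncated"} attribute.
#'
#' @param sim a \linkS4class{TrafficSim}
#' @return data.frame with columns \code{replicate}, \code{rnapIndex},
#'   \code{time}
#' @export
completionTimes <- function(sim) {
  rep <- integer(0); idx <- integer(0); tt <- numeric(0)
  nTrunc <- 0L
  for (r in seq_along(sim@replicates)) {
    for (tr in sim@replicates[[r]]) {
      if (tr@truncated) { nTrunc <- nTrunc + 1L; next }
      rep <- c(rep, r); idx <- c(idx, tr@rnapIndex)
      tt <- c(tt, tr@tEnd - tr@tInit)
    }
  }
  structure(data.frame(replicate = rep, rnapIndex = idx, time = tt),
            nTruncated = nTrunc)
}

#' Median completion time per binding order
#'
#' @param sim a \linkS4class{TrafficSim}
#' @return named numeric vector, median completion time (s) for binding
#'   orders 1..N
#' @export
medianCompletionByIndex <- function(sim) {
  ct <- completionTimes(sim)
  if (!nrow(ct)) stop("no completed trajectories")
  vapply(split(ct$time, ct$rnapIndex), median, numeric(1))
}

#' Relative transcription efficiency curve
#'
#' The average transcription time for a run allowing at most N
#' polymerases is \code{Tavg(N) = (1/N) * sum_j median_j}, the mean over
#' binding orders of the median completion time; the relative
#' transcription efficiency is \code{eps(N) = Tavg(1) / Tavg(N)}, equal
#' to 1 at N = 1 by construction. Values above 1 mean that collisions
#' speed transcription up.
#'
#' @param medians named list: element \code{"N"} holds the vector of
#'   per-binding-order median completion times of the run with maximum
#'   polymerase count N (length N). Must include \code{"1"}.
#' @return an \linkS4class{EfficiencyCurve}
#' @examples
#' efficiencyCurve(list(`1` = 10, `2` = c(10, 6)))   # Tavg(2)=8, eps=1.25
#' @export
efficiencyCurve <- function(medians) {
  ns <- as.integer(names(medians))
  if (any(is.na(ns))) stop("medians must be a list named by N")
  if (!1L %in% ns) stop("the N = 1 run is required as reference")
  ord <- order(ns)
  ns <- ns[ord]; medians <- medians[ord]
  tAvg <- vapply(seq_along(ns), function(i) {
    m <- medians[[i]]
    if (length(m) != ns[i] || any(is.na(m)))
      stop("missing per-binding-order median for N = ", ns[i])
    mean(m)
  }, numeric(1))
  eps <- tAvg[ns == 1L] / tAvg
  new("EfficiencyCurve", n = ns, tAvg = tAvg, eps = eps,
      medians = medians)
}

#' Simulated transcription gel
#'
#' Counts, per sampling timepoint, the transcripts of each length
#' present across the ensemble (completed transcripts keep their final
#' length), like band intensities on a transcription gel.
#'
#' @param sim a \linkS4class{TrafficSim}
#' @param timepoints numeric vector of times (s)
#' @return a \linkS4class{GelImage}
#' @export
simulatedGel <- function(sim, timepoints) {
  timepoints <- sort(as.numeric(timepoints))
  L <- nchar(as.character(sim@config@template))
  nMax <- L - sim@config@model@geometry@footprintFront
  counts <- matrix(0L, nrow = nMax, ncol = length(timepoints),
                   dimnames = list(seq_len(nMax), timepoints))
  for (tr in .flatTrajectories(sim)) {
    incT <- tr@events$time[tr@events$kind == "incorporation"]
    for (k in seq_along(timepoints)) {
      t <- timepoints[k]
      if (is.na(tr@tInit) || t < tr@tInit) next
      len <- sum(incT <= t)
      if (len >= 1L) counts[len, k] <- counts[len, k] + 1L
    }
  }
  new("GelImage", counts = counts, lengths = seq_len(nMax),
      timepoints = timepoints)
}

#' Plot polymerase trajectories of one replicate
#'
#' Position of each polymerase's active site against reaction time;
#' colors follow binding order. Occupied regions never overlap.
#'
#' @param sim a \linkS4class{TrafficSim}
#' @param replicate which replicate to draw
#' @param ... passed to \code{plot}
#' @return invisibly, the replicate's trajectory list
#' @export
plotTrajectories <- function(sim, replicate = 1, ...) {
  trs <- sim@replicates[[replicate]]
  tmax <- max(vapply(trs, function(tr) tr@tEnd, numeric(1)))
  xmax <- max(vapply(trs, function(tr) max(tr@events$position),
                     numeric(1)))
  graphics::plot(NA, xlim = c(0, tmax), ylim = c(0, xmax),
                 xlab = "time (s)", ylab = "active-site position (nt)",
                 ...)
  for (tr in trs)
    graphics::lines(tr@events$time, tr@events$position,
                    col = tr@rnapIndex)
  invisible(trs)
}

#' Plot a simulated gel
#'
#' @param gel a \linkS4class{GelImage}
#' @param ... passed to \code{image}
#' @return invisibly, the count matrix
#' @export
plotGel <- function(gel, ...) {
  graphics::image(
    x = seq_along(gel@timepoints), y = gel@lengths,
    z = t(gel@counts), xlab = "lane (timepoint)",
    ylab = "transcript length (nt)",
    col = grDevices::gray.colors(64, start = 1, end = 0), axes = FALSE,
    ...
  )
  graphics::axis(1, at = seq_along(gel@timepoints),
                 labels = gel@timepoints)
  graphics::axis(2)
  invisible(gel@counts)
}
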