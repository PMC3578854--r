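#' Read DNA templates from FASTA
#'
#' @param file path to a (multi-)FASTA of sense-strand templates
#' @return a \code{DNAStringSet}; record ids become element names
#' @export
readTemplates <- function(file) Biostrings::readDNAStringSet(file)

#' Read experimentally observed pause positions
#'
#' Two-column TSV: sequence name, 1-based template position. A header
#' line is detected and skipped if the second field is not numeric.
#'
#' @param file path to the TSV
#' @return named list of integer vectors, one per sequence
#' @export
readPauseList <- function(file) {
  df <- read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df[1, 2]))))
    df <- df[-1, , drop = FALSE]
  if (ncol(df) < 2L) stop("pause list must have two columns")
  lapply(split(as.integer(df[[2]]), df[[1]]), sort)
}

#' Write a pause list
#'
#' @param pauses named list of integer vectors
#' @param file output path
#' @return invisibly, the file path
#' @export
writePauseList <- function(pauses, file) {
  df <- data.frame(
    sequence = rep(names(pauses), lengths(pauses)),
    position = unlist(pauses, use.names = FALSE)
  )
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

.trafficMode <- function(ev) {
  ifelse(ev$kind == "termination", "terminated",
         ifelse(ev$offset > 0L, "backtracked", "elongating"))
}

#' Write a simulation as per-replicate event streams
#'
#' One TSV per replicate (columns time, rnap, position, n, offset, mode,
#' event) plus a JSON manifest capturing the full configuration for
#' provenance.
#'
#' @param sim a \linkS4class{TrafficSim}
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
writeEventStreams <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim@config
  p <- cfg@params
  manifest <- list(
    mode = sim@mode, templateName = cfg@templateName,
    template = as.character(cfg@template),
    nRnapMax = cfg@nRnapMax,
    initiationInterval = cfg@initiationInterval,
    nReplicates = cfg@nReplicates, tMax = cfg@tMax, seed = cfg@seed,
    params = list(
      vmax = as.list(p@vmax), km = as.list(p@km),
      ntpConc = as.list(p@ntpConc), k0 = p@k0, dG0 = p@dG0,
      dGbt = p@dGbt, force = p@force,
      collisionForce = p@collisionForce,
      temperature = p@temperature
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (r in seq_along(sim@replicates)) {
    rows <- do.call(rbind, lapply(sim@replicates[[r]], function(tr) {
      ev <- tr@events
      data.frame(time = ev$time, rnap = tr@rnapIndex,
                 position = ev$position, n = ev$n, offset = ev$offset,
                 mode = .trafficMode(ev), event = ev$kind,
                 stringsAsFactors = FALSE)
    }))
    rows <- rows[order(rows$time, rows$rnap), ]
    write.table(rows, file.path(dir, sprintf("replicate_%04d.tsv", r)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read event streams written by \code{\link{writeEventStreams}}
#'
#' @param dir directory containing \code{manifest.json} and
#'   \code{replicate_*.tsv}
#' @return a \linkS4class{TrafficSim}
#' @export
readEventStreams <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  params <- kineticParams(
    ntpConc = unlist(man$params$ntpConc),
    vmax = unlist(man$params$vmax), km = unlist(man$params$km),
    k0 = man$params$k0, dG0 = man$params$dG0, dGbt = man$params$dGbt,
    force = man$params$force,
    collisionForce = man$params$collisionForce,
    temperature = man$params$temperature
  )
  cfg <- runConfig(man$template, params, nRnapMax = man$nRnapMax,
                   initiationInterval = man$initiationInterval,
                   nReplicates = man$nReplicates, tMax = man$tMax,
                   seed = man$seed, templateName = man$templateName)
  files <- sort(list.files(dir, pattern = "^replicate_.*\\.tsv$",
                           full.names = TRUE))
  reps <- lapply(files, function(f) {
    rows <- read.delim(f, stringsAsFactors = FALSE)
    lapply(sort(unique(rows$rnap)), function(j) {
      ev <- rows[rows$rnap == j, ]
      ev <- ev[order(ev$time), ]
      new("Trajectory",
        rnapIndex = as.integer(j),
        tInit = ev$time[ev$event == "initiation"][1L],
        tEnd = ev$time[nrow(ev)],
        finalLength = max(ev$n),
        truncated = any(ev$event == "truncated"),
        events = data.frame(time = ev$time, position = ev$position,
                            n = as.integer(ev$n),
                            offset = as.integer(ev$offset),
                            kind = ev$event, stringsAsFactors = FALSE)
      )
    })
  })
  new("TrafficSim", mode = man$mode, config = cfg, replicates = reps)
}

#' Write a simulated gel as TSV
#'
#' @param gel a \linkS4class{GelImage}
#' @param file output path
#' @return invisibly, the file path
#' @export
writeGel <- function(gel, file) {
  df <- data.frame(length = gel@lengths, gel@counts, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
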