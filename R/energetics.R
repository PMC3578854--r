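.pkgCache <- new.env(parent = emptyenv())

#' Load a nearest-neighbor parameter table
#'
#' Reads a tab-separated table with columns \code{step},
#' \code{dH_kcal_mol}, \code{dS_cal_mol_K} and optionally
#' \code{dG37_kcal_mol} and \code{source}. The tables shipped with the
#' package are the unified DNA/DNA duplex parameters and the RNA/DNA
#' hybrid parameters; users can point to their own files to swap
#' parameter sets.
#'
#' @param file path to a TSV file
#' @return a data.frame
#' @export
readNNTable <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("step", "dH_kcal_mol", "dS_cal_mol_K")
  if (!all(need %in% names(df)))
    stop("nearest-neighbor table must have columns: ",
         paste(need, collapse = ", "))
  df
}

#' Construct the energy model
#'
#' @param dnaFile TSV of DNA/DNA duplex steps; default: packaged unified
#'   parameters
#' @param rnaFile TSV of RNA/DNA hybrid steps (keyed by the RNA
#'   dinucleotide, 5'->3'); default: packaged hybrid parameters
#' @param geometry a \linkS4class{TECGeometry}
#' @return an \linkS4class{EnergyModel}
#' @examples
#' model <- energyModel()
#' model
#' @export
energyModel <- function(dnaFile = NULL, rnaFile = NULL,
                        geometry = tecGeometry()) {
  useDefault <- is.null(dnaFile) && is.null(rnaFile) &&
    identical(geometry, tecGeometry())
  if (useDefault && !is.null(.pkgCache$defaultModel))
    return(.pkgCache$defaultModel)
  if (is.null(dnaFile))
    dnaFile <- system.file("extdata", "nn_dna_dna_santalucia.tsv",
                           package = "RNAPtraffic", mustWork = TRUE)
  if (is.null(rnaFile))
    rnaFile <- system.file("extdata", "nn_rna_dna_sugimoto.tsv",
                           package = "RNAPtraffic", mustWork = TRUE)
  m <- new("EnergyModel", dnaDNA = readNNTable(dnaFile),
           rnaDNA = readNNTable(rnaFile), geometry = geometry)
  if (useDefault) .pkgCache$defaultModel <- m
  m
}

# named vector of step dG(T) = dH - T*dS for the 16 dinucleotide entries
.stepDG <- function(df, temperature) {
  steps <- df$step[nchar(df$step) == 2L]
  dg <- df$dH_kcal_mol - temperature * df$dS_cal_mol_K / 1000
  stats::setNames(dg[nchar(df$step) == 2L], steps)
}

.seqChars <- function(seq) {
  s <- toupper(as.character(seq))
  strsplit(s, "", fixed = TRUE)[[1]]
}

.checkWindow <- function(L, start, end, minLen = 2L) {
  if (start < 1L || end > L) stop("window [", start, ", ", end,
                                  "] out of template bounds [1, ", L, "]")
  if (end - start + 1L < minLen)
    stop("degenerate window: length must be >= ", minLen)
}

#' Free energy of a double-stranded DNA window
#'
#' Sums nearest-neighbor formation free energies dG(T) = dH - T*dS over
#' the dinucleotide steps in the (inclusive, 1-based) window of the sense
#' strand. The returned value is the duplex \emph{formation} free energy
#' (negative for a stable duplex); it enters the TEC free energy with
#' opposite sign, because melting the bubble costs that energy.
#'
#' @param template character or \code{DNAString}, sense strand 5'->3'
#' @param start,end 1-based inclusive window bounds, \code{end - start >= 1}
#' @param temperature kelvin (default 310.15, the tables' reference)
#' @param model an \linkS4class{EnergyModel}
#' @return free energy in kcal/mol
#' @examples
#' duplexDnaEnergy("CAAT", 2, 3)  # one AA step at 37 C
#' @export
duplexDnaEnergy <- function(template, start, end, temperature = 310.15,
                            model = energyModel()) {
  ch <- .seqChars(template)
  .checkWindow(length(ch), start, end)
  dg <- .stepDG(model@dnaDNA, temperature)
  steps <- paste0(ch[start:(end - 1L)], ch[(start + 1L):end])
  if (any(!steps %in% names(dg)))
    stop("template contains non-ACGT characters in the window")
  sum(dg[steps])
}

#' Free energy of an RNA/DNA hybrid window
#'
#' The RNA sequence is the transcript of the template window (sense
#' strand with T read as U); hybrid steps are keyed by the RNA
#' dinucleotide 5'->3' and summed as formation free energies (negative =
#' stabilizing, lowering the TEC free energy).
#'
#' @param template character or \code{DNAString}, sense strand 5'->3'
#' @param rna3p template position of the RNA 3' end (1-based nt)
#' @param hybridLen hybrid length in bp
#' @inheritParams duplexDnaEnergy
#' @return free energy in kcal/mol
#' @examples
#' hybridEnergy("ACGTACGTACGT", rna3p = 10, hybridLen = 8)
#' @export
hybridEnergy <- function(template, rna3p, hybridLen, temperature = 310.15,
                         model = energyModel()) {
  ch <- .seqChars(template)
  start <- rna3p - hybridLen + 1L
  .checkWindow(length(ch), start, rna3p)
  dg <- .stepDG(model@rnaDNA, temperature)
  rna <- gsub("T", "U", ch[start:rna3p])
  steps <- paste0(rna[-length(rna)], rna[-1L])
  if (any(!steps %in% names(dg)))
    stop("template contains non-ACGT characters in the window")
  sum(dg[steps])
}

# window sum with clamping at template ends; cum = cumsum of per-step dG,
# step i covers positions (i, i+1). Returns 0 for windows with < 2 bases.
.clampedWindowSum <- function(cum, L, start, end) {
  a <- max(1L, start); b <- min(L, end)
  if (b - a < 1L) return(0)
  cum[b - 1L] - if (a > 1L) cum[a - 1L] else 0
}

# Precompute the TEC free-energy landscape of a template.
# Returns Gpost[p] for p = 0..L (index p+1) and Gpre[p] for p = 1..L
# (index p), where p is the template position of the RNA 3' end.
# Windows are clamped at template ends; vectorized over positions.
.landscape <- function(template, model, temperature) {
  ch <- .seqChars(template)
  L <- length(ch)
  g <- model@geometry
  dgD <- .stepDG(model@dnaDNA, temperature)
  dgR <- .stepDG(model@rnaDNA, temperature)
  steps <- paste0(ch[-L], ch[-1L])
  if (any(!steps %in% names(dgD)))
    stop("template may contain only A/C/G/T")
  rsteps <- gsub("T", "U", steps)
  cumD <- c(0, cumsum(unname(dgD[steps])))  # cumD[i+1] = steps 1..i
  cumR <- c(0, cumsum(unname(dgR[rsteps])))
  wsum <- function(cum, a, b) {
    # sum of step free energies inside window positions [a, b], clamped
    lo <- pmax(1L, a)
    hi <- pmin(L, b) - 1L
    res <- cum[pmax(pmin(hi, L - 1L), 0L) + 1L] - cum[pmax(lo, 1L)]
    res[hi < lo] <- 0
    res
  }
  gAt <- function(p, hlen) {
    hstart <- p - hlen + 1L
    -wsum(cumD, hstart, hstart + g@bubbleLen - 1L) + wsum(cumR, hstart, p)
  }
  Gpost <- gAt(0:L, g@hybridLenPost)
  Gpre <- gAt(1:L, g@hybridLenPre)
  list(Gpost = Gpost, Gpre = Gpre, L = L, chars = ch)
}

#' Standard Gibbs free energy of a TEC configuration
#'
#' Evaluates the TEC stability as the sum of its sequence-dependent
#' components: the cost of melting the transcription bubble (minus the
#' DNA/DNA duplex formation energy over the bubble window) plus the
#' RNA/DNA hybrid formation energy (8 bp in the post-translocated
#' register, 9 bp in the pre-translocated register). The
#' polymerase-nucleic-acid interaction term is sequence-independent and
#' set to zero. Windows are clamped at template boundaries.
#'
#' @param state a \linkS4class{TECState}
#' @param template character or \code{DNAString}, sense strand 5'->3'
#' @param model an \linkS4class{EnergyModel}
#' @param temperature kelvin
#' @return standard free energy in kcal/mol
#' @examples
#' tpl <- paste(rep("ACGT", 20), collapse = "")
#' tecFreeEnergy(tecState(n = 40), tpl)
#' @export
tecFreeEnergy <- function(state, template, model = energyModel(),
                          temperature = 310.15) {
  stopifnot(is(state, "TECState"))
  ch <- .seqChars(template)
  L <- length(ch)
  p <- if (state@mode == "backtracked") state@m else state@n
  if (p < 0L || p > L) stop("state outside the template")
  g <- model@geometry
  hlen <- if (state@mode == "elongating" && state@register == "pre")
    g@hybridLenPre else g@hybridLenPost
  hstart <- p - hlen + 1L
  dgD <- .stepDG(model@dnaDNA, temperature)
  dgR <- .stepDG(model@rnaDNA, temperature)
  winSum <- function(dg, rna, a, b) {
    a <- max(1L, a); b <- min(L, b)
    if (b - a < 1L) return(0)
    s <- ch[a:b]
    if (rna) s <- gsub("T", "U", s)
    sum(dg[paste0(s[-length(s)], s[-1L])])
  }
  bub <- -winSum(dgD, FALSE, hstart, hstart + g@bubbleLen - 1L)
  hyb <- winSum(dgR, TRUE, hstart, p)
  bub + hyb
}
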