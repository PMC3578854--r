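# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

stdParams <- function(...) kineticParams(ntpConc = 250, ...)

# standard study conditions: 250 uM each NTP, 24 C, no external load,
# 25 pN transmitted on contact
cachedTemplate <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

plainTemplate <- function() cachedTemplate("plain", function()
  makeTemplate(160, seed = 11))

pauseTemplate <- function() cachedTemplate("pause", function()
  makeTemplate(260, list(motifSpec("strong_pause", 120)), seed = 7))

motifTemplate <- function() cachedTemplate("motif3", function()
  makeTemplate(400, list(motifSpec("strong_pause", 130),
                         motifSpec("backtrack_trap", 220),
                         motifSpec("strong_pause", 310)), seed = 3))

cachedSim <- function(key, builder) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- builder()
  .fixtureCache[[key]]
}

# independently typed published nearest-neighbor values (kcal/mol,
# cal/mol/K, kcal/mol at 37 C); used as oracles against the packaged
# tables
publishedDnaNN <- function() {
  m <- rbind(
    AA = c(-7.9, -22.2, -1.00), AC = c(-8.4, -22.4, -1.44),
    AG = c(-7.8, -21.0, -1.28), AT = c(-7.2, -20.4, -0.88),
    CA = c(-8.5, -22.7, -1.45), CC = c(-8.0, -19.9, -1.84),
    CG = c(-10.6, -27.2, -2.17), CT = c(-7.8, -21.0, -1.28),
    GA = c(-8.2, -22.2, -1.30), GC = c(-9.8, -24.4, -2.24),
    GG = c(-8.0, -19.9, -1.84), GT = c(-8.4, -22.4, -1.44),
    TA = c(-7.2, -21.3, -0.58), TC = c(-8.2, -22.2, -1.30),
    TG = c(-8.5, -22.7, -1.45), TT = c(-7.9, -22.2, -1.00)
  )
  colnames(m) <- c("dH", "dS", "dG37")
  m
}

publishedRnaDnaNN <- function() {
  m <- rbind(
    AA = c(-7.8, -21.9, -1.0), AC = c(-5.9, -12.3, -2.1),
    AG = c(-9.1, -23.5, -1.8), AU = c(-8.3, -23.9, -0.9),
    CA = c(-9.0, -26.1, -0.9), CC = c(-9.3, -23.2, -2.1),
    CG = c(-16.3, -47.1, -1.7), CU = c(-7.0, -19.7, -0.9),
    GA = c(-5.5, -13.5, -1.3), GC = c(-8.0, -17.1, -2.7),
    GG = c(-12.8, -31.9, -2.9), GU = c(-7.8, -21.6, -1.1),
    UA = c(-7.8, -23.2, -0.6), UC = c(-8.6, -22.9, -1.5),
    UG = c(-10.4, -28.4, -1.6), UU = c(-11.5, -36.4, -0.2)
  )
  colnames(m) <- c("dH", "dS", "dG37")
  m
}

# brute-force TEC free energy: re-derived from the raw sequence with
# plain loops, independent of the package's windowing code
bruteTecEnergy <- function(seq, p, hybridLen, bubbleLen = 12,
                           temperature = 310.15) {
  ch <- strsplit(toupper(seq), "")[[1]]
  L <- length(ch)
  dna <- publishedDnaNN(); rna <- publishedRnaDnaNN()
  dgD <- dna[, "dH"] - temperature * dna[, "dS"] / 1000
  dgR <- rna[, "dH"] - temperature * rna[, "dS"] / 1000
  hstart <- p - hybridLen + 1
  tot <- 0
  for (i in max(1, hstart):(min(L, hstart + bubbleLen - 1) - 1)) {
    if (i + 1 > min(L, hstart + bubbleLen - 1)) break
    tot <- tot - dgD[paste0(ch[i], ch[i + 1])]
  }
  if (p >= max(1, hstart) + 1) {
    for (i in max(1, hstart):(p - 1)) {
      s <- chartr("T", "U", paste0(ch[i], ch[i + 1]))
      tot <- tot + dgR[s]
    }
  }
  unname(tot)
}

# brute-force contact-time scan on a fine time grid
bruteCollisionScan <- function(xT, vT, xL, vL, tEnd, D, dt = 1e-4) {
  ts <- seq(0, tEnd, by = dt)
  gap <- (xL + vL * ts) - (xT + vT * ts) - D
  k <- which(gap <= 0)
  if (!length(k)) NA_real_ else ts[k[1]]
}
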