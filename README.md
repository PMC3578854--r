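# RNAPtraffic

Sequence-dependent stochastic simulation of transcription elongation by
one or many RNA polymerases (RNAPs) on the same DNA template, with
collision resolution, plus the analysis layer that turns trajectory
ensembles into pause calls, backtracking statistics, simulated
transcription gels, transcription-efficiency curves and
pause-prediction quality scores.

## The problem and the model

During elongation, RNAP moves along DNA in single-nucleotide steps,
oscillating between a pre- and a post-translocated register; only the
post state accepts the next NTP. The stability of the elongation
complex — the cost of the melted 12-bp transcription bubble plus the
formation energy of the 8/9-bp RNA-DNA hybrid, both from
nearest-neighbor thermodynamics — biases this ratchet, so incorporation
follows an effective Michaelis-Menten law

$$k \;=\; \frac{V_{\max}\,[\mathrm{NTP}]}{[\mathrm{NTP}] + K_m\,(1+B)},
\qquad
B = e^{(\Delta G^\circ_{\text{post}} - \Delta G^\circ_{\text{pre}} - F\delta)/k_BT},$$

with $\delta = 0.34$ nm and per-NTP $V_{\max}$, $K_m$. Sites whose
pre-translocated state is strongly stabilized transcribe slowly — these
are sequence-encoded pause sites — and can seed backtracking, modeled
as thermally activated hops on the same free-energy landscape
($k = k_0 e^{-\Delta G^\ddagger/k_BT}$, obeying detailed balance).

When several RNAPs transcribe the same template, the engine simulates
all of them with the Gillespie first-reaction method, interpolates
positions linearly between reactions, solves pairwise collision times
in closed form, and resolves collisions by force transmission (a
trailing RNAP pushes its leader with the ~25 pN stalling force and is
pushed back), by roadblocking (a trailing RNAP prevents the leader's
backward motion — converting backtracking pauses into forward
recovery), or by elastic exchange when both molecules are backtracking.
Hard-core exclusion between polymerase footprints is enforced
throughout. This is the mechanism behind cooperative multi-round
transcription: trailing polymerases rescue paused and backtracked
leaders, raising the overall transcription rate.

Because real benchmark templates are not bundled, a fixture generator
(`makeTemplate`) builds synthetic templates with a quieted background
and planted pause/backtracking motifs of controlled strength, searched
against the package's own energetics.

## Worked example

```r
library(RNAPtraffic)

params <- kineticParams(ntpConc = 250)   # 250 uM each NTP, 24 C
tpl <- makeTemplate(300, list(motifSpec("strong_pause", 120),
                              motifSpec("backtrack_trap", 200)), seed = 3)

cfgS <- runConfig(tpl, params, nReplicates = 40, seed = 5)            # 1 RNAP
cfgM <- runConfig(tpl, params, nRnapMax = 6, nReplicates = 40, seed = 5)
simS <- simulateSRA(cfgS)      # single-round ensemble
simM <- simulateMRA(cfgM)      # polymerase traffic with collisions

callPauses(dwellProfile(simS), alpha = 0.05)
#> PauseReport: 10 pause site(s) in 7 cluster(s); alpha = 0.05 => dwell threshold 0.5176 s

efficiencyCurve(list(`1` = medianCompletionByIndex(simS),
                     `6` = medianCompletionByIndex(simM)))
#>   N     Tavg      eps
#> 1 1 36.56805 1.000000
#> 2 6 33.14047 1.103426

quantile(backtrackDistances(simS), 0.75)   # 7 nt
quantile(backtrackDistances(simM), 0.75)   # 2 nt
```

Reading the output: the pause caller flags the planted sites (120 and
200, with clustered shoulders) once the third-quartile dwell exceeds
`tauMin/alpha` (0.52 s here). Allowing six polymerases raises the
relative transcription efficiency to ε = 1.10 — collisions accelerate
transcription by ~10% on this template — and trailing polymerases cut
the third quartile of backtracking excursion distances from 7 nt to
2 nt (the roadblock effect).

`plotTrajectories(simM)` draws the position-versus-time fronts of one
replicate (occupied regions never overlap); `simulatedGel(simM,
c(10, 30, 60))` gives a transcript-length-by-time band matrix.

A thin command-line wrapper is installed at
`system.file("exec", "rnaptraffic", package = "RNAPtraffic")` with
`make-template`, `simulate`, `pauses`, `gel`, `efficiency` and
`quality` subcommands operating on FASTA templates and TSV event
streams.

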