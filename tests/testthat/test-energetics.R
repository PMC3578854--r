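test_that("packaged tables agree with the published sources within the
           rounding-propagation bound", {
  model <- energyModel()
  # dH printed to 0.1 kcal/mol and dS to 0.1 cal/mol/K; recomputing
  # dG37 from the rounded values can deviate from the printed dG37 by
  # up to 0.05 + 310.15 * 0.00005 = 0.066 kcal/mol
  bound <- 0.05 + 310.15 * 5e-5
  for (src in list(list(pub = publishedDnaNN(), df = model@dnaDNA),
                   list(pub = publishedRnaDnaNN(), df = model@rnaDNA))) {
    df <- src$df[nchar(src$df$step) == 2L, ]
    pub <- src$pub[df$step, ]
    expect_equal(df$dH_kcal_mol, unname(pub[, "dH"]))
    expect_equal(df$dS_cal_mol_K, unname(pub[, "dS"]))
    dg <- df$dH_kcal_mol - 310.15 * df$dS_cal_mol_K / 1000
    expect_true(all(abs(dg - pub[, "dG37"]) <= bound))
  }
})

test_that("window energies equal hand-summed published entries", {
  pub <- publishedDnaNN()
  dg37 <- function(step) pub[step, "dH"] - 310.15 * pub[step, "dS"] / 1000
  expect_equal(duplexDnaEnergy("CAAT", 2, 3), unname(dg37("AA")))
  expect_equal(duplexDnaEnergy("GATTAC", 1, 5),
               unname(dg37("GA") + dg37("AT") + dg37("TT") + dg37("TA")))
  rpub <- publishedRnaDnaNN()
  rg <- function(step) rpub[step, "dH"] - 310.15 * rpub[step, "dS"] / 1000
  # poly-purine template window; RNA is the transcript (T -> U)
  expect_equal(hybridEnergy("GAGAG", rna3p = 5, hybridLen = 5),
               unname(rg("GA") + rg("AG") + rg("GA") + rg("AG")))
  # temperature recomputation: dG(T) = dH - T dS
  expect_equal(duplexDnaEnergy("CAAT", 2, 3, temperature = 297.15),
               -7.9 - 297.15 * (-22.2) / 1000)
})

test_that("window bounds and degenerate windows are rejected", {
  expect_error(duplexDnaEnergy("ACGT", 0, 2), "bounds")
  expect_error(duplexDnaEnergy("ACGT", 3, 5), "bounds")
  expect_error(duplexDnaEnergy("ACGT", 2, 2), "degenerate")
  expect_error(hybridEnergy("ACGT", rna3p = 2, hybridLen = 4), "bounds")
})

test_that("DNA table is reverse-complement symmetric for all 16 steps", {
  model <- energyModel()
  df <- model@dnaDNA[nchar(model@dnaDNA$step) == 2L, ]
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (i in seq_len(nrow(df))) {
    j <- match(rc(df$step[i]), df$step)
    expect_equal(df$dH_kcal_mol[i], df$dH_kcal_mol[j])
    expect_equal(df$dS_cal_mol_K[i], df$dS_cal_mol_K[j])
  }
})

test_that("window energies are additive under splits", {
  set.seed(42)
  for (rep in 1:20) {
    seq <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                 collapse = "")
    a <- sample(1:20, 1); b <- a + sample(4:15, 1); m <- a + 2
    whole <- duplexDnaEnergy(seq, a, b)
    # parts share the step (m, m+1) boundary exactly once when split
    # at m: [a, m] covers steps a..m-1 and [m, b] covers m..b-1
    expect_equal(whole,
                 duplexDnaEnergy(seq, a, m) + duplexDnaEnergy(seq, m, b))
    expect_equal(hybridEnergy(seq, b, b - a + 1),
                 hybridEnergy(seq, m, m - a + 1) +
                   hybridEnergy(seq, b, b - m + 1))
  }
})

test_that("TEC free energy is deterministic, translation-invariant on
           homopolymers, and matches a brute-force oracle", {
  tpl <- paste(rep("A", 60), collapse = "")
  g1 <- tecFreeEnergy(tecState(n = 30), tpl)
  expect_identical(g1, tecFreeEnergy(tecState(n = 30), tpl))
  for (p in 25:35)
    expect_equal(tecFreeEnergy(tecState(n = p), tpl), g1)
  set.seed(7)
  for (rep in 1:100) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    p <- sample(12:55, 1)
    reg <- sample(c("post", "pre"), 1)
    st <- tecState(n = p, register = reg)
    hl <- if (reg == "pre") 9 else 8
    expect_equal(tecFreeEnergy(st, seq), bruteTecEnergy(seq, p, hl),
                 tolerance = 1e-10)
  }
})

test_that("pre-post free-energy difference equals the window-diff
           oracle", {
  set.seed(13)
  for (rep in 1:25) {
    seq <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                 collapse = "")
    p <- sample(15:50, 1)
    direct <- tecFreeEnergy(tecState(n = p, register = "pre"), seq) -
      tecFreeEnergy(tecState(n = p), seq)
    oracle <- bruteTecEnergy(seq, p, 9) - bruteTecEnergy(seq, p, 8)
    expect_equal(direct, oracle, tolerance = 1e-10)
  }
})

test_that("a more stable hybrid lowers the TEC free energy", {
  # rGG/dCC steps are strongly stabilizing; rUU/dAA steps barely so.
  # Compare TECs whose hybrid windows differ only in that respect.
  strong <- paste(c(rep("A", 20), rep("G", 10), rep("A", 20)),
                  collapse = "")
  weak <- paste(rep("A", 50), collapse = "")
  expect_lt(tecFreeEnergy(tecState(n = 28), strong),
            tecFreeEnergy(tecState(n = 28), weak))
})

test_that("templates with ambiguity codes are rejected", {
  expect_error(duplexDnaEnergy("ACGN", 1, 4), "non-ACGT")
  expect_error(runConfig("ACGNACGTACGTACGTACGTACGTACGTACGTACGT",
                         stdParams()), "A/C/G/T|TEC span")
})
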