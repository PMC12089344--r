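# fixtures are built in code; all randomness goes through fixed seeds

# single-chromosome landscape with isolated origins on a passive background
originLandscape <- function(n, originSites, originRates, bg = 1e-10,
                            chrom = "chrS") {
  f <- rep(bg, n)
  f[originSites] <- originRates
  firingRateProfile(f, genomeGrid(setNames(as.integer(n), chrom)))
}

# brute-force min-formula: exhaustive double loop (independent oracle)
bruteMinFormula <- function(A, v) {
  n <- length(A)
  vapply(seq_len(n), function(j)
    min(A + abs(seq_len(n) - j) / v), numeric(1))
}

# write lines to a temp file, returning the path
tmpTextFile <- function(lines, ext = ".bedgraph") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
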