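# Independent brute-force oracle for the junction scanner, written against
# the decision rule itself (all ungapped offsets, both orientations), not
# against the package internals. Deliberately slow and simple.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

# best qualifying placement of `read` on `contig` (breakpoint offset b,
# 0-based) or NULL; same tie-break as the scanner: fewest mismatches, then
# smallest contig start, then forward before revcomp
oracle_scan <- function(read, contig, b, params) {
  w <- nchar(read)
  L <- nchar(contig)
  if (w < 2L * params$min_overhang) return(NULL)
  cint <- utf8ToInt(contig)
  cbad <- !(cint %in% utf8ToInt("ACGT"))
  orients <- if (params$both_orientations) c("forward", "revcomp") else "forward"
  best <- NULL
  for (orient in orients) {
    s <- if (orient == "forward") read else oracle_revcomp(read)
    rint <- utf8ToInt(s)
    rbad <- !(rint %in% utf8ToInt("ACGT"))
    for (d in (-(w - 1L)):(L - 1L)) {
      cs <- max(0L, d); ce <- min(L, d + w)
      A <- ce - cs
      if (A <= 0L) next
      if (A < params$min_aligned_fraction * w) next
      if (b - cs < params$min_overhang || ce - b < params$min_overhang) next
      ri <- (cs - d + 1L):(ce - d)
      cj <- (cs + 1L):ce
      mm <- sum(rint[ri] != cint[cj] | rbad[ri] | cbad[cj])
      if (mm > params$max_mismatches) next
      cand <- list(contig_start = cs, aligned_length = A, mismatches = mm,
                   overhang5 = b - cs, overhang3 = ce - b,
                   orientation = orient)
      better <- is.null(best) ||
        mm < best$mismatches ||
        (mm == best$mismatches && cs < best$contig_start)
      if (better) best <- cand
    }
  }
  best
}

# enumeration oracle for expected_spanning_fragments: count fragment starts
# whose read 1 or read 2 window covers the breakpoint with >= o bases on
# each side, over all valid starts
oracle_spanning_starts <- function(L, Fl, R, b, o) {
  n <- 0L
  for (s in 0:(L - Fl)) {
    covers <- function(w) (b - w) >= o && (w + R - b) >= o
    if (covers(s) || covers(s + Fl - R)) n <- n + 1L
  }
  n
}
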