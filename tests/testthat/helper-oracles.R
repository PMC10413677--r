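# Independent oracles and small generators used across the suite. The
# oracles are deliberately written from the definitions (per-window loops,
# explicit bottom-strand reading, exhaustive path enumeration) and share no
# code with the implementation they check.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
  D = c("A", "G", "T"), H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

# One-position rule: window base concrete and inside the pattern base's set.
oracle_base_match <- function(p, w) {
  w %in% c("A", "C", "G", "T") && w %in% ORACLE_SETS[[p]]
}

# All-windows scan from the definition; minus-strand windows are read off
# the bottom strand (complemented, right to left).
oracle_scan <- function(residues, pattern, strands = c("+", "-")) {
  tc <- strsplit(residues, "", fixed = TRUE)[[1]]
  pc <- strsplit(pattern, "", fixed = TRUE)[[1]]
  m <- length(pc)
  out <- NULL
  for (s in 0:(length(tc) - m)) {
    win <- tc[(s + 1):(s + m)]
    if ("+" %in% strands && all(mapply(oracle_base_match, pc, win))) {
      out <- rbind(out, data.frame(start = s, end = s + m, strand = "+"))
    }
    if ("-" %in% strands) {
      bottom <- rev(unname(ORACLE_COMP[win]))
      bottom[is.na(bottom)] <- "?"
      if (all(mapply(oracle_base_match, pc, bottom))) {
        out <- rbind(out, data.frame(start = s, end = s + m, strand = "-"))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0))
  }
  out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
}

# Exhaustive per-offset Hamming scan over both strands.
oracle_min_mismatch <- function(guide, residues) {
  gc <- strsplit(guide, "", fixed = TRUE)[[1]]
  rc <- rev(unname(ORACLE_COMP[gc]))
  tc <- strsplit(residues, "", fixed = TRUE)[[1]]
  m <- length(gc)
  best <- m + 1L
  for (s in 0:(length(tc) - m)) {
    win <- tc[(s + 1):(s + m)]
    best <- min(best, sum(win != gc), sum(win != rc))
  }
  best
}

# Exhaustive global-alignment score with affine gaps: enumerate every
# monotone move path and account gap runs explicitly. Only viable for tiny
# strings.
oracle_global_score <- function(a, b, match, mismatch, gap_open, gap_extend) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]]
  bc <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- -Inf
  recurse <- function(i, j, score, last_move) {
    if (i > length(ac) && j > length(bc)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ac) && j <= length(bc)) {
      s <- if (ac[i] == bc[j]) match else mismatch
      recurse(i + 1, j + 1, score + s, "d")
    }
    if (i <= length(ac)) {
      open <- if (identical(last_move, "v")) 0 else gap_open
      recurse(i + 1, j, score + open + gap_extend, "v")
    }
    if (j <= length(bc)) {
      open <- if (identical(last_move, "h")) 0 else gap_open
      recurse(i, j + 1, score + open + gap_extend, "h")
    }
  }
  recurse(1, 1, 0, "none")
  best
}

# A template carrying one perfect protospacer+PAM site at a known offset.
planted_template <- function(guide, left = 60, right = 60, pam = "AGG") {
  paste0(rand_dna(left), guide, pam, rand_dna(right))
}
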