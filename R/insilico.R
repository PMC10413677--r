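# In-silico genotyping design: PCR amplicon extraction, Cas9 cut placement,
# T7 endonuclease I fragment sizes, and the frameshift fraction of an indel
# spectrum.

#' Construct a primer pair
#'
#' @param forward,reverse Primer sequences, each written 5'->3' on its own
#'   strand, at least 15 nt.
#' @return A list of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse) {
  forward <- as_residues(forward)
  reverse <- as_residues(reverse)
  if (nchar(forward) < 15L || nchar(reverse) < 15L) {
    stop("primers must be >= 15 nt")
  }
  structure(list(forward = forward, reverse = reverse), class = "primer_pair")
}

#' Extract the PCR amplicon of a primer pair from a template
#'
#' Matching is exact and case-insensitive (design-time prediction; no
#' 3'-mismatch tolerance, no degenerate primers): the forward primer must
#' match the top strand and the reverse primer the bottom strand downstream
#' of it. Exactly one product must exist.
#'
#' @param template A [nuc_seq].
#' @param primers A [primer_pair].
#' @return A list of class `amplicon`: `template_id`, `start`, `end`
#'   (top-strand, half-open, forward-primer start through reverse-binding
#'   end), `sequence`, `length`.
#' @export
find_amplicon <- function(template, primers) {
  stopifnot(inherits(primers, "primer_pair"))
  tres <- as_residues(template)
  tid <- if (inherits(template, "nuc_seq")) template$id else "template"
  if (nchar(tres) <= max(nchar(primers$forward), nchar(primers$reverse))) {
    stop("template shorter than the primers")
  }
  f_hits <- scan_motif(nuc_seq(tid, tres), primers$forward, strands = "+")
  r_hits <- scan_motif(nuc_seq(tid, tres), primers$reverse, strands = "-")
  products <- NULL
  for (i in seq_len(nrow(f_hits))) {
    for (j in seq_len(nrow(r_hits))) {
      if (r_hits$start[j] >= f_hits$end[i]) {
        products <- rbind(products, data.frame(
          start = f_hits$start[i], end = r_hits$end[j]))
      }
    }
  }
  if (is.null(products)) {
    stop("no amplification: primer pair has no oriented product on '",
         tid, "'")
  }
  if (nrow(products) > 1L) {
    stop("ambiguous amplification: ", nrow(products), " products (",
         paste(sprintf("[%d,%d)", products$start, products$end),
               collapse = ", "), ")")
  }
  seq <- substr(tres, products$start + 1L, products$end)
  structure(list(template_id = tid, start = products$start,
                 end = products$end, sequence = seq, length = nchar(seq)),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  cat(sprintf("<amplicon> %s [%d,%d) %d bp\n", x$template_id, x$start, x$end,
              x$length))
  invisible(x)
}

#' Cas9 cut positions inside an amplicon
#'
#' For every perfect protospacer+PAM site in the amplicon (both strands),
#' the blunt double-strand break sits `cut_offset` nt 5' of the PAM on the
#' protospacer strand (default 3, the canonical spCas9 cut between positions
#' 17 and 18 of a 20-nt protospacer), reported as a single top-strand
#' coordinate: a cut at `c` splits the amplicon into `[0,c)` and `[c,L)`.
#'
#' @param amplicon An `amplicon`.
#' @param guide Protospacer string.
#' @param pam IUPAC PAM pattern.
#' @param cut_offset Nucleotides 5' of the PAM (0 < offset < guide length).
#' @return Sorted integer vector of cut positions; empty when the guide has
#'   no site in the amplicon.
#' @export
cut_positions <- function(amplicon, guide, pam = "NGG", cut_offset = 3L) {
  stopifnot(inherits(amplicon, "amplicon"))
  guide <- as_residues(guide)
  if (cut_offset <= 0L || cut_offset >= nchar(guide)) {
    stop("cut_offset must be in (0, guide length)")
  }
  sites <- find_perfect_sites(guide, nuc_seq("amplicon", amplicon$sequence),
                              pam = pam, require_pam = TRUE)
  if (!nrow(sites)) return(integer(0))
  cuts <- ifelse(sites$strand == "+",
                 sites$end - cut_offset,   # PAM 3' on top strand
                 sites$start + cut_offset) # PAM-proximal end at site start
  sort(unique(as.integer(cuts)))
}

#' T7 endonuclease I fragment sizes
#'
#' Assumes full cleavage at every heteroduplex mismatch positioned at a Cas9
#' cut: fragments are the consecutive intervals between cuts, and always
#' partition the amplicon.
#'
#' @param amplicon An `amplicon`.
#' @param cuts Sorted integer cut positions inside the amplicon (from
#'   [cut_positions]).
#' @return Integer vector of fragment lengths summing to the amplicon
#'   length; `[L]` when there are no cuts.
#' @export
t7_fragment_sizes <- function(amplicon, cuts) {
  stopifnot(inherits(amplicon, "amplicon"))
  L <- amplicon$length
  if (length(cuts)) {
    cuts <- as.integer(cuts)
    if (is.unsorted(cuts, strictly = TRUE)) stop("cuts must be sorted, unique")
    if (any(cuts <= 0L) || any(cuts >= L)) {
      stop("cut outside amplicon (0, ", L, ")")
    }
  }
  diff(c(0L, cuts, L))
}

#' Fraction of an indel spectrum causing a frameshift
#'
#' Given weights over indel lengths, the probability mass on lengths not
#' divisible by 3 — the standard argument for why roughly two-thirds of
#' Cas9-induced mutant alleles are nonfunctional when indel lengths spread
#' over the residue classes.
#'
#' @param weights Numeric vector of nonnegative weights named by nonzero
#'   integer indel lengths (insertions positive, deletions negative), total
#'   weight > 0.
#' @return Numeric scalar in `[0, 1]`.
#' @examples
#' frameshift_fraction(c(`1` = 1, `2` = 1, `3` = 1)) # 2/3
#' @export
frameshift_fraction <- function(weights) {
  lens <- suppressWarnings(as.integer(names(weights)))
  if (any(is.na(lens))) stop("weights must be named by integer indel lengths")
  if (any(lens == 0L)) stop("zero-length indel entry")
  if (any(weights < 0)) stop("negative weight")
  total <- sum(weights)
  if (total <= 0) stop("zero total weight")
  sum(weights[abs(lens) %% 3L != 0L]) / total
}

#' Fragment report for a genotyping assay
#'
#' Human-readable "virtual gel" plus TSV-ready table for one amplicon/guide
#' combination.
#'
#' @param amplicon An `amplicon`.
#' @param guide Protospacer string.
#' @param pam IUPAC PAM pattern.
#' @param cut_offset Passed to [cut_positions].
#' @return A list: `cuts`, `fragments`, `text` (character vector of report
#'   lines).
#' @export
t7_report <- function(amplicon, guide, pam = "NGG", cut_offset = 3L) {
  cuts <- cut_positions(amplicon, guide, pam = pam, cut_offset = cut_offset)
  frags <- t7_fragment_sizes(amplicon, cuts)
  text <- c(
    sprintf("amplicon\t%s\t%d bp [%d,%d)", amplicon$template_id,
            amplicon$length, amplicon$start, amplicon$end),
    sprintf("cuts\t%s", if (length(cuts)) paste(cuts, collapse = ",") else "-"),
    sprintf("fragments\t%s", paste(frags, collapse = ",")),
    "virtual_gel:",
    sprintf("  %4d bp  %s", sort(frags, decreasing = TRUE),
            strrep("#", pmax(1L, round(sort(frags, decreasing = TRUE) / 25))))
  )
  list(cuts = cuts, fragments = frags, text = text)
}
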