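# Conserved-window detection in an alignment and enumeration of PAM-adjacent
# guide candidates: the design step of the cross-species strategy.

aln_char_matrix <- function(aln) {
  do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
}

#' Find perfectly conserved runs in an alignment
#'
#' A column is conserved when every row carries the identical, unambiguous
#' base (A/C/G/T; no gaps, no ambiguity codes). Returns all maximal runs of
#' conserved columns of at least `min_len` columns.
#'
#' @param aln An `msa_aln`.
#' @param min_len Minimum run length in columns (default 20, one full
#'   protospacer).
#' @return A `data.frame` with 0-based half-open `col_start`, `col_end` and
#'   `length`, sorted by `col_start`.
#' @export
find_conserved_runs <- function(aln, min_len = 20L) {
  if (min_len < 1L) stop("min_len must be >= 1")
  mat <- aln_char_matrix(aln)
  conserved <- apply(mat, 2L, function(col) {
    col[1] %in% c("A", "C", "G", "T") && all(col == col[1])
  })
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(
    col_start = starts[keep] - 1L,
    col_end = ends[keep],
    length = r$lengths[keep]
  )
}

# Observed PAM trinucleotide of one row for a protospacer occupying alignment
# columns [w_start, w_end) on `strand`. Returns NULL if the PAM slot falls
# outside the alignment or hits a gap in this row.
row_pam <- function(aln, row_id, w_start, w_end, strand) {
  pam_cols <- if (strand == "+") w_end + 0:2 else w_start - 3:1
  if (any(pam_cols < 0L) || any(pam_cols >= aln$n_cols)) return(NULL)
  chars <- strsplit(aln$rows[[row_id]], "", fixed = TRUE)[[1]][pam_cols + 1L]
  if (any(chars == "-")) return(NULL)
  pam <- paste(chars, collapse = "")
  if (strand == "-") reverse_complement(pam) else pam
}

#' Enumerate PAM-adjacent guide candidates from conserved runs
#'
#' For each run and each strand, every `guide_len`-column window lying fully
#' inside the run is a candidate provided the 3-column PAM slot immediately
#' 3' of the protospacer (on the protospacer strand) is gap-free in every
#' row. The PAM slot may extend beyond the conserved run: PAM presence is a
#' per-row, per-species property (the spiny-mouse situation, where one
#' species lacks the NGG next to an otherwise perfect target). With
#' `require_pam_conserved = TRUE` every row's observed PAM must satisfy
#' `pam`; with `FALSE`, rows failing it are retained but flagged.
#'
#' @param aln The `msa_aln` the runs came from.
#' @param runs Output of [find_conserved_runs] on the same alignment.
#' @param guide_len Protospacer length (17-25; default 20).
#' @param pam IUPAC PAM pattern, default `"NGG"`.
#' @param require_pam_conserved Drop candidates for which any row's PAM slot
#'   fails the pattern (default `TRUE`).
#' @return A list of `guide_candidate` objects, each with the protospacer
#'   (5'->3' on its own strand), strand, source run, and a per-row site table
#'   (`sites`: top-strand 0-based intervals, observed PAM, `pam_ok`).
#' @export
enumerate_guides <- function(aln, runs, guide_len = 20L, pam = "NGG",
                             require_pam_conserved = TRUE) {
  if (guide_len < 17L || guide_len > 25L) {
    stop("guide_len must be in [17, 25]")
  }
  out <- list()
  seen <- character(0)
  for (r in seq_len(nrow(runs))) {
    cs <- runs$col_start[r]; ce <- runs$col_end[r]
    if (ce - cs < guide_len) next
    for (w_start in cs:(ce - guide_len)) {
      w_end <- w_start + guide_len
      for (strand in c("+", "-")) {
        cand <- build_candidate(aln, w_start, w_end, strand, pam, r)
        if (is.null(cand)) next
        if (require_pam_conserved && !cand$pam_conserved) next
        key <- paste(cand$protospacer, strand)
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- cand
      }
    }
  }
  for (i in seq_along(out)) out[[i]]$guide_id <- sprintf("g%03d", i)
  out
}

# Assemble one candidate from a conserved window; NULL when any row's PAM
# slot is out of bounds or gapped.
build_candidate <- function(aln, w_start, w_end, strand, pam, run_index) {
  mat <- aln_char_matrix(aln)
  window <- paste(mat[1, (w_start + 1L):w_end], collapse = "")
  protospacer <- if (strand == "-") reverse_complement(window) else window
  sites <- NULL
  pams <- character(0)
  for (row_id in aln$ids) {
    pam_obs <- row_pam(aln, row_id, w_start, w_end, strand)
    if (is.null(pam_obs)) return(NULL)
    start <- column_to_residue(aln, row_id, w_start)
    sites <- rbind(sites, data.frame(
      row_id = row_id, start = start, end = start + (w_end - w_start),
      strand = strand, pam = pam_obs,
      pam_ok = iupac_match(pam, pam_obs),
      stringsAsFactors = FALSE
    ))
    pams <- c(pams, pam_obs)
  }
  structure(list(
    guide_id = NA_character_, protospacer = protospacer, strand = strand,
    pam_pattern = pam, sites = sites, run_index = run_index,
    col_start = w_start, col_end = w_end,
    pam_conserved = all(sites$pam_ok)
  ), class = "guide_candidate")
}

#' @export
print.guide_candidate <- function(x, ...) {
  cat(sprintf("<guide_candidate> %s %s strand %s cols [%d,%d) pam_conserved=%s\n",
              x$guide_id, x$protospacer, x$strand, x$col_start, x$col_end,
              x$pam_conserved))
  invisible(x)
}

#' Annotate guide candidates on their alignment
#'
#' Per candidate: the covered column interval plus, per row, whether that
#' row's ungapped sequence carries a perfect protospacer-plus-PAM match at
#' the recorded site (the asterisk semantics of a per-species match track).
#'
#' @param aln The source `msa_aln`.
#' @param candidates List of `guide_candidate` objects from this alignment.
#' @return A `data.frame` with one row per (candidate, alignment row):
#'   `guide_id`, `col_start`, `col_end`, `strand`, `row_id`, `perfect`.
#' @export
annotate_guides_on_alignment <- function(aln, candidates) {
  out <- NULL
  for (cand in candidates) {
    if (cand$col_end > aln$n_cols ||
        !all(cand$sites$row_id %in% aln$ids)) {
      stop("candidate ", cand$guide_id, " does not belong to this alignment")
    }
    for (i in seq_len(nrow(cand$sites))) {
      row_id <- cand$sites$row_id[i]
      hits <- find_perfect_sites(cand$protospacer,
                                 nuc_seq(row_id, ungap_row(aln, row_id)),
                                 pam = cand$pam_pattern, require_pam = TRUE)
      out <- rbind(out, data.frame(
        guide_id = cand$guide_id, col_start = cand$col_start,
        col_end = cand$col_end, strand = cand$strand, row_id = row_id,
        perfect = nrow(hits) > 0L, stringsAsFactors = FALSE
      ))
    }
  }
  if (is.null(out)) {
    out <- data.frame(guide_id = character(0), col_start = integer(0),
                      col_end = integer(0), strand = character(0),
                      row_id = character(0), perfect = logical(0))
  }
  out
}

#' Write guide candidates as TSV
#'
#' One row per candidate: id, protospacer, strand, source columns, PAM
#' conservation flag, and per-row site/PAM columns.
#'
#' @param candidates List of `guide_candidate` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guides_tsv <- function(candidates, path) {
  rows <- lapply(candidates, function(cand) {
    site_str <- paste(sprintf("%s:%d-%d(%s)", cand$sites$row_id,
                              cand$sites$start, cand$sites$end,
                              cand$sites$pam),
                      collapse = ";")
    data.frame(guide_id = cand$guide_id, protospacer = cand$protospacer,
               strand = cand$strand, col_start = cand$col_start,
               col_end = cand$col_end, pam_conserved = cand$pam_conserved,
               sites = site_str, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(df)) {
    df <- data.frame(guide_id = character(0), protospacer = character(0),
                     strand = character(0), col_start = integer(0),
                     col_end = integer(0), pam_conserved = logical(0),
                     sites = character(0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write guide protospacers as FASTA
#'
#' @param candidates List of `guide_candidate` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guides_fasta <- function(candidates, path) {
  seqs <- lapply(candidates, function(cand) {
    nuc_seq(cand$guide_id, cand$protospacer)
  })
  write_fasta(seqs, path)
}
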