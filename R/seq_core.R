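# Sequence data model, IUPAC-aware matching, motif scanning, FASTA I/O.
# All genomic coordinates in this package are 0-based, half-open, on the top
# strand; the strand of a feature is carried separately.

#' Create a nucleotide sequence record
#'
#' The atomic record of every scan in the package: a DNA sequence over the
#' IUPAC alphabet with an identifier and an optional species label. Residues
#' are uppercased on ingestion (softmasked input loses its masking); gaps are
#' rejected.
#'
#' @param id Character scalar, unique identifier.
#' @param residues Character scalar over the IUPAC DNA alphabet
#'   (`ACGTRYSWKMBDHVN`), any case.
#' @param species Optional character scalar species label.
#' @return An object of class `nuc_seq` with fields `id`, `species`,
#'   `residues`.
#' @examples
#' nuc_seq("g1", "ggtgcttcATGAAAAAGAAG", species = "Mus musculus")
#' @export
nuc_seq <- function(id, residues, species = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) {
    stop("sequence '", id, "' is empty")
  }
  bad <- bad_dna_position(residues)
  if (!is.na(bad)) {
    stop("sequence '", id, "': non-IUPAC character '",
         substr(residues, bad, bad), "' at position ", bad)
  }
  structure(
    list(id = id, species = as.character(species), residues = residues),
    class = "nuc_seq"
  )
}

#' @export
print.nuc_seq <- function(x, ...) {
  n <- nchar(x$residues)
  preview <- if (n > 48) paste0(substr(x$residues, 1, 48), "...") else x$residues
  cat(sprintf("<nuc_seq> %s%s (%d nt)\n  %s\n", x$id,
              if (!is.na(x$species)) paste0(" [", x$species, "]") else "",
              n, preview))
  invisible(x)
}

# First 1-based position holding a non-IUPAC character, or NA if clean.
bad_dna_position <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_CODES))
  if (length(bad)) bad[1] else NA_integer_
}

as_residues <- function(x) {
  if (inherits(x, "nuc_seq")) x$residues else toupper(as.character(x))
}

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented correctly (N to N, R to Y, ...).
#'
#' @param seq DNA string (character scalar) or a [nuc_seq].
#' @return Character scalar, the reverse complement.
#' @examples
#' reverse_complement("GGTGCTTCATGAAAAAGAAG")
#' @export
reverse_complement <- function(seq) {
  s <- as_residues(seq)
  bad <- bad_dna_position(s)
  if (!is.na(bad)) {
    stop("non-IUPAC character '", substr(s, bad, bad), "' at position ", bad)
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Match a window against an IUPAC pattern
#'
#' True iff at every position the window base belongs to the pattern base's
#' IUPAC set. Ambiguity in the *target* window counts as a mismatch even
#' against `N` in the pattern: a permissive pattern never certifies an
#' uncertain base (prevents spurious "perfect" calls in low-quality
#' assemblies).
#'
#' @param pattern IUPAC DNA pattern, e.g. `"NGG"`.
#' @param window Candidate window of the same length.
#' @return Logical scalar.
#' @examples
#' iupac_match("NGG", "AGG") # TRUE
#' iupac_match("NGG", "NGG") # FALSE: ambiguous target base
#' @export
iupac_match <- function(pattern, window) {
  pattern <- toupper(pattern)
  window <- toupper(window)
  if (nchar(pattern) != nchar(window)) {
    stop("pattern and window lengths differ (", nchar(pattern), " vs ",
         nchar(window), ")")
  }
  p <- strsplit(pattern, "", fixed = TRUE)[[1]]
  w <- strsplit(window, "", fixed = TRUE)[[1]]
  if (any(!p %in% names(IUPAC_CODES))) stop("non-IUPAC character in pattern")
  all(w %in% c("A", "C", "G", "T") &
        mapply(grepl, w, unname(IUPAC_CODES[p]), MoreArgs = list(fixed = TRUE)))
}

# Logical matrix helper: rows = pattern chars, one column per window offset.
# Returns starts (0-based) on the given character vector where the pattern
# matches under the iupac_match rule. Vectorised over all offsets.
iupac_scan_starts <- function(chars, pattern_chars) {
  n <- length(chars)
  m <- length(pattern_chars)
  if (m > n) return(integer(0))
  n_off <- n - m + 1L
  ok <- rep(TRUE, n_off)
  concrete <- chars %in% c("A", "C", "G", "T")
  for (i in seq_len(m)) {
    idx <- i:(i + n_off - 1L)
    allowed <- IUPAC_CODES[[pattern_chars[i]]]
    hit <- concrete[idx]
    if (allowed != "ACGT") {
      sets <- strsplit(allowed, "", fixed = TRUE)[[1]]
      hit <- hit & chars[idx] %in% sets
    }
    ok <- ok & hit
    if (!any(ok)) return(integer(0))
  }
  which(ok) - 1L
}

#' Scan a sequence for an IUPAC motif
#'
#' Finds every occurrence of `pattern` in `seq` under the [iupac_match] rule,
#' on the requested strands. Minus-strand hits are reported as top-strand
#' intervals with strand `"-"`.
#'
#' @param seq A [nuc_seq] (or DNA string).
#' @param pattern IUPAC pattern, non-empty.
#' @param strands Character vector, subset of `c("+", "-")`.
#' @return A `data.frame` of genomic sites (`seq_id`, `start`, `end`,
#'   `strand`), 0-based half-open, sorted by (`start`, `strand`).
#' @examples
#' scan_motif(nuc_seq("s", "AAGGAA"), "NGG")
#' @export
scan_motif <- function(seq, pattern, strands = c("+", "-")) {
  if (!nchar(pattern)) stop("empty pattern")
  stopifnot(all(strands %in% c("+", "-")))
  id <- if (inherits(seq, "nuc_seq")) seq$id else "seq"
  s <- as_residues(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  pattern <- toupper(pattern)
  hits <- list()
  if ("+" %in% strands) {
    p <- strsplit(pattern, "", fixed = TRUE)[[1]]
    st <- iupac_scan_starts(chars, p)
    if (length(st)) {
      hits[["+"]] <- genomic_site(id, st, st + nchar(pattern), "+")
    }
  }
  if ("-" %in% strands) {
    # a minus-strand occurrence reads as revcomp(pattern) on the top strand
    p <- strsplit(reverse_complement(pattern), "", fixed = TRUE)[[1]]
    st <- iupac_scan_starts(chars, p)
    if (length(st)) {
      hits[["-"]] <- genomic_site(id, st, st + nchar(pattern), "-")
    }
  }
  out <- do.call(rbind, c(hits, list(genomic_site())))
  rownames(out) <- NULL
  out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
}

#' Construct genomic site records
#'
#' @param seq_id,start,end,strand Vectors of equal length; `start`/`end` are
#'   0-based half-open top-strand coordinates.
#' @return A `data.frame` with one row per site.
#' @export
genomic_site <- function(seq_id = character(0), start = integer(0),
                         end = integer(0), strand = character(0)) {
  n <- max(length(seq_id), length(start), length(end), length(strand))
  df <- data.frame(
    seq_id = rep_len(as.character(seq_id), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  if (n) {
    stopifnot(all(df$start >= 0L), all(df$end > df$start),
              all(df$strand %in% c("+", "-")))
  }
  df
}

# Extract the residues covered by a 0-based half-open top-strand interval.
site_sequence <- function(residues, start, end, strand = "+") {
  s <- substr(residues, start + 1L, end)
  if (strand == "-") reverse_complement(s) else s
}

#' Read sequences from a FASTA file
#'
#' Headers are parsed as `id [species=...]` with the species tag optional;
#' residues are uppercased. Duplicate ids and empty records are rejected.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A named list of [nuc_seq] objects, named by id.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  species <- rep(NA_character_, length(ids))
  m <- regmatches(headers, regexec("\\[species=([^]]+)\\]", headers))
  has <- lengths(m) == 2L
  species[has] <- vapply(m[has], `[`, "", 2L)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    res <- as.character(set[[i]])
    if (!nchar(res)) stop("empty FASTA record: '", ids[i], "'")
    out[[i]] <- nuc_seq(ids[i], res, species[i])
  }
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' Wrapped at 60 columns; species labels are emitted as `[species=...]`
#' header tags so that a write/read round trip is the identity.
#'
#' @param seqs A list of [nuc_seq] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "nuc_seq")) seqs <- list(seqs)
  ids <- vapply(seqs, function(s) s$id, "")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  }
  headers <- vapply(seqs, function(s) {
    if (!is.na(s$species)) paste0(s$id, " [species=", s$species, "]") else s$id
  }, "")
  set <- Biostrings::BStringSet(vapply(seqs, function(s) s$residues, ""))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
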