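# Progressive multiple alignment of ortholog CDSs: k-mer distances, UPGMA
# guide tree, profile-profile merges over an affine-gap DP, alignment I/O and
# column<->residue coordinate maps.

#' Alignment scoring parameters
#'
#' Defaults (match +2, mismatch -1, gap open -10, gap extend -0.5, k = 4)
#' suit closely related coding orthologs; a gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param match,mismatch Per-column substitution scores.
#' @param gap_open,gap_extend Gap penalties (negative contributions).
#' @param k k-mer size for guide-tree distances.
#' @return A list of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -1, gap_open = -10,
                         gap_extend = -0.5, k = 4L) {
  stopifnot(k >= 1)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, k = as.integer(k)),
            class = "align_params")
}

#' k-mer distance between two sequences
#'
#' `1 - shared distinct k-mers / min(distinct k-mers of a, of b)`: 0 for
#' identical sequences, 1 for disjoint k-mer sets; symmetric. Used to build
#' the guide tree.
#'
#' @param a,b [nuc_seq] objects or DNA strings.
#' @param k k-mer size, at most the length of either sequence.
#' @return Numeric scalar in `[0, 1]`.
#' @export
kmer_distance <- function(a, b, k = 4L) {
  sa <- as_residues(a); sb <- as_residues(b)
  if (k < 1 || k > nchar(sa) || k > nchar(sb)) {
    stop("k must satisfy 1 <= k <= min sequence length")
  }
  ka <- unique(substring(sa, 1:(nchar(sa) - k + 1), k:nchar(sa)))
  kb <- unique(substring(sb, 1:(nchar(sb) - k + 1), k:nchar(sb)))
  1 - length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' UPGMA guide tree from a distance matrix
#'
#' Average-linkage clustering with deterministic tie-breaking: among equally
#' close pairs, the lexicographically smallest (by the smallest member id of
#' each cluster) is joined first.
#'
#' @param D Symmetric numeric matrix with zero diagonal; dimnames give the
#'   leaf ids.
#' @return A nested-list binary tree of class `guide_tree`; leaves are
#'   `list(id = ...)`, internal nodes `list(left, right, height, id)` where
#'   `id` is the smallest member id (used for tie-breaks).
#' @export
build_guide_tree <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  ids <- rownames(D)
  if (is.null(ids)) ids <- colnames(D)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12))) {
    stop("distance matrix is not symmetric")
  }
  dimnames(D) <- list(ids, ids)
  clusters <- lapply(ids, function(i) list(id = i))
  names(clusters) <- ids
  sizes <- stats::setNames(rep(1L, length(ids)), ids)
  while (length(clusters) > 1L) {
    labs <- names(clusters)
    best <- NULL
    for (i in seq_along(labs)[-length(labs)]) {
      for (j in (i + 1):length(labs)) {
        pr <- sort(c(labs[i], labs[j]))
        d <- D[labs[i], labs[j]]
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (pr[1] < best$pr[1] ||
              (pr[1] == best$pr[1] && pr[2] < best$pr[2])))) {
          best <- list(d = d, pr = pr)
        }
      }
    }
    a <- best$pr[1]; b <- best$pr[2]
    node <- list(left = clusters[[a]], right = clusters[[b]],
                 height = best$d / 2, id = a)
    others <- setdiff(names(clusters), c(a, b))
    # UPGMA update: size-weighted average distance to the merged cluster
    newd <- (D[a, others] * sizes[a] + D[b, others] * sizes[b]) /
      (sizes[a] + sizes[b])
    keep <- c(others, a)
    D <- D[keep, keep, drop = FALSE]
    D[a, others] <- newd
    D[others, a] <- newd
    D[a, a] <- 0
    sizes[a] <- sizes[a] + sizes[b]
    clusters[[b]] <- NULL
    clusters[[a]] <- node
  }
  structure(clusters[[1]], class = "guide_tree")
}

guide_tree_leaves <- function(node) {
  if (is.null(node$left)) return(node$id)
  c(guide_tree_leaves(node$left), guide_tree_leaves(node$right))
}

# Encode a gapped row as integer categories for profile counting.
encode_row <- function(row) {
  match(strsplit(row, "", fixed = TRUE)[[1]], ALN_ALPHABET)
}

# Column category counts: length(ALN_ALPHABET) x n_cols.
profile_counts <- function(rows) {
  enc <- vapply(rows, encode_row, integer(nchar(rows[[1]])))
  enc <- matrix(enc, ncol = length(rows))
  apply(enc, 1L, tabulate, nbins = length(ALN_ALPHABET))
}

# Profile-profile column score matrix: average substitution score over all
# row pairs; a gap in either row contributes 0.
profile_score_matrix <- function(rows_a, rows_b, params) {
  S <- matrix(params$mismatch, length(ALN_ALPHABET), length(ALN_ALPHABET))
  diag(S) <- params$match
  S[length(ALN_ALPHABET), ] <- 0
  S[, length(ALN_ALPHABET)] <- 0
  ca <- profile_counts(rows_a)  # alphabet x La
  cb <- profile_counts(rows_b)
  crossprod(ca, S %*% cb) / (length(rows_a) * length(rows_b))
}

insert_gaps <- function(row, cols) {
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  out <- rep("-", length(cols))
  out[!is.na(cols)] <- chars[cols[!is.na(cols)]]
  paste(out, collapse = "")
}

#' Optimal global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch with the three-state (Gotoh) recursion. Traceback
#' tie-breaking is fixed (diagonal > vertical > horizontal) so results are
#' bit-reproducible.
#'
#' @param a,b [nuc_seq] objects or DNA strings, non-empty.
#' @param params An [align_params] object.
#' @return A list with `a`, `b` (gapped strings of equal length) and `score`.
#' @examples
#' pairwise_align_affine("ACGT", "ACT",
#'   align_params(match = 1, mismatch = -1, gap_open = 0, gap_extend = -2))
#' @export
pairwise_align_affine <- function(a, b, params = align_params()) {
  sa <- as_residues(a); sb <- as_residues(b)
  stopifnot(nzchar(sa), nzchar(sb))
  cs <- profile_score_matrix(list(sa), list(sb), params)
  res <- nw_affine_path(cs, params$gap_open, params$gap_extend)
  list(a = insert_gaps(sa, res$a_cols),
       b = insert_gaps(sb, res$b_cols),
       score = res$score)
}

#' Construct an alignment object
#'
#' @param rows Named character vector (or named list) of equal-length gapped
#'   strings over the IUPAC alphabet plus `-`.
#' @return An object of class `msa_aln` with fields `ids`, `rows`, `n_cols`.
#' @export
alignment <- function(rows) {
  rows <- vapply(rows, function(r) toupper(as.character(r)), "")
  ids <- names(rows)
  stopifnot(!is.null(ids), !anyDuplicated(ids), length(rows) >= 1L)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) {
    shortest <- ids[which.min(widths)]
    stop("ragged alignment rows: shortest row is '", shortest, "' (",
         min(widths), " columns vs ", max(widths), ")")
  }
  ungapped <- gsub("-", "", rows, fixed = TRUE)
  if (any(!nzchar(ungapped))) stop("all-gap row in alignment")
  structure(list(ids = ids, rows = rows, n_cols = unname(widths[1])),
            class = "msa_aln")
}

#' @export
print.msa_aln <- function(x, ...) {
  cat(sprintf("<msa_aln> %d rows x %d columns\n", length(x$ids), x$n_cols))
  invisible(x)
}

# Ungapped sequence of one row.
ungap_row <- function(aln, row_id) {
  gsub("-", "", aln$rows[[row_id]], fixed = TRUE)
}

#' Progressive multiple alignment
#'
#' ClustalW-style strategy: pairwise k-mer distances, a UPGMA guide tree, then
#' profile-profile merges in tree order under the affine-gap DP ("once a gap,
#' always a gap"). Deterministic for fixed parameters. All-gap columns
#' produced by merges are dropped.
#'
#' @param seqs List of two or more [nuc_seq] objects with unique ids.
#' @param params An [align_params] object.
#' @return An `msa_aln`; rows are in input order and ungap to the inputs.
#' @export
progressive_align <- function(seqs, params = align_params()) {
  if (length(seqs) < 2L) stop("progressive alignment needs >= 2 sequences")
  ids <- vapply(seqs, function(s) s$id, "")
  stopifnot(!anyDuplicated(ids))
  names(seqs) <- ids
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- kmer_distance(seqs[[i]], seqs[[j]], params$k)
    }
  }
  tree <- build_guide_tree(D)
  align_node <- function(node) {
    if (is.null(node$left)) {
      return(stats::setNames(list(seqs[[node$id]]$residues), node$id))
    }
    ra <- align_node(node$left)
    rb <- align_node(node$right)
    cs <- profile_score_matrix(ra, rb, params)
    res <- nw_affine_path(cs, params$gap_open, params$gap_extend)
    merged <- c(lapply(ra, insert_gaps, cols = res$a_cols),
                lapply(rb, insert_gaps, cols = res$b_cols))
    # drop columns that are gaps in every row (defensive; merges should not
    # create them)
    mat <- do.call(rbind, strsplit(unlist(merged), "", fixed = TRUE))
    allgap <- colSums(mat != "-") == 0L
    if (any(allgap)) {
      merged <- lapply(merged, function(r) {
        paste(strsplit(r, "", fixed = TRUE)[[1]][!allgap], collapse = "")
      })
    }
    merged
  }
  rows <- align_node(tree)
  alignment(unlist(rows[ids]))
}

#' Map an alignment column to a residue index
#'
#' @param aln An `msa_aln`.
#' @param row_id Row identifier.
#' @param col 0-based alignment column.
#' @return 0-based residue index in the ungapped row, or `NA` if the column
#'   is a gap in that row.
#' @export
column_to_residue <- function(aln, row_id, col) {
  if (!row_id %in% names(aln$rows)) stop("unknown row id: ", row_id)
  row <- aln$rows[[row_id]]
  if (col < 0 || col >= aln$n_cols) {
    stop("column ", col, " out of range [0, ", aln$n_cols, ")")
  }
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  if (chars[col + 1L] == "-") return(NA_integer_)
  sum(chars[seq_len(col + 1L)] != "-") - 1L
}

#' Map a residue index to its alignment column
#'
#' Inverse of [column_to_residue] on non-gap columns; strictly increasing in
#' `pos`.
#'
#' @param aln An `msa_aln`.
#' @param row_id Row identifier.
#' @param pos 0-based residue index in the ungapped row.
#' @return 0-based alignment column.
#' @export
residue_to_column <- function(aln, row_id, pos) {
  if (!row_id %in% names(aln$rows)) stop("unknown row id: ", row_id)
  row <- aln$rows[[row_id]]
  chars <- strsplit(row, "", fixed = TRUE)[[1]]
  nongap <- which(chars != "-")
  if (pos < 0 || pos >= length(nongap)) {
    stop("residue index ", pos, " out of range [0, ", length(nongap), ")")
  }
  nongap[pos + 1L] - 1L
}

#' Read an alignment from file
#'
#' @param path Input path.
#' @param dialect `"fasta"` (aligned FASTA) or `"clustal"`.
#' @return An `msa_aln`.
#' @export
read_alignment <- function(path, dialect = c("fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (dialect == "fasta") {
    set <- Biostrings::readBStringSet(path)
    ids <- sub("\\s.*$", "", names(set))
    rows <- stats::setNames(toupper(as.character(set)), ids)
    return(alignment(rows))
  }
  lines <- readLines(path)
  if (!length(lines) || !grepl("^CLUSTAL", lines[1])) {
    stop("not a CLUSTAL file (missing CLUSTAL header line)")
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  # conservation lines start with whitespace; sequence lines with an id
  body <- body[!grepl("^\\s", body)]
  parts <- regmatches(body, regexec("^(\\S+)\\s+(\\S+)", body))
  ids <- vapply(parts, `[`, "", 2L)
  chunks <- vapply(parts, `[`, "", 3L)
  rows <- vapply(split(chunks, factor(ids, levels = unique(ids))),
                 paste, "", collapse = "")
  alignment(rows)
}

#' Write an alignment to file
#'
#' @param aln An `msa_aln`.
#' @param path Output path.
#' @param dialect `"fasta"` (aligned FASTA, wrapped at 60) or `"clustal"`
#'   (interleaved blocks of 60).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, dialect = c("fasta", "clustal")) {
  dialect <- match.arg(dialect)
  if (dialect == "fasta") {
    set <- Biostrings::BStringSet(aln$rows)
    names(set) <- aln$ids
    Biostrings::writeXStringSet(set, path, width = 60L)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("CLUSTAL multiple sequence alignment", con)
  writeLines("", con)
  width <- max(nchar(aln$ids)) + 3L
  starts <- seq(1L, aln$n_cols, by = 60L)
  for (s in starts) {
    for (id in aln$ids) {
      chunk <- substr(aln$rows[[id]], s, min(s + 59L, aln$n_cols))
      writeLines(sprintf("%-*s%s", width, id, chunk), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
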