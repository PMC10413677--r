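# Per-species functionality prediction by exact protospacer+PAM matching,
# minimal-mismatch off-target scanning, flanking-context homology, and
# species-by-guide aggregation.

STATUS_LEVELS <- c("predicted_functional", "pam_absent", "mismatched", "absent")

#' Find perfect protospacer sites
#'
#' All zero-mismatch occurrences of the protospacer in a target, on both
#' strands. With `require_pam = TRUE` (the functionality criterion) the
#' 3-nt slot immediately 3' of the protospacer must exist in-bounds and
#' satisfy the PAM pattern; edge sites lacking a full PAM slot are excluded.
#'
#' @param guide Protospacer string (concrete A/C/G/T, length >= 17).
#' @param target A [nuc_seq] (or DNA string).
#' @param pam IUPAC PAM pattern, default `"NGG"`.
#' @param require_pam Require a valid adjacent PAM (default `TRUE`).
#' @return A `data.frame` of genomic sites of the protospacer (PAM not
#'   included in the interval).
#' @export
find_perfect_sites <- function(guide, target, pam = "NGG",
                               require_pam = TRUE) {
  guide <- as_residues(guide)
  if (nchar(guide) < 17L) stop("guide shorter than 17 nt")
  tid <- if (inherits(target, "nuc_seq")) target$id else "seq"
  tres <- as_residues(target)
  if (!nzchar(tres)) stop("empty target")
  hits <- scan_motif(nuc_seq(tid, tres), guide, strands = c("+", "-"))
  if (!require_pam || !nrow(hits)) return(hits)
  ok <- vapply(seq_len(nrow(hits)), function(i) {
    p <- site_pam(tres, hits$start[i], hits$end[i], hits$strand[i])
    !is.null(p) && iupac_match(pam, p)
  }, TRUE)
  hits[ok, , drop = FALSE]
}

# Observed PAM trinucleotide 3' of a protospacer site, read 5'->3' on the
# protospacer strand; NULL when the slot runs off the sequence.
site_pam <- function(residues, start, end, strand) {
  n <- nchar(residues)
  if (strand == "+") {
    if (end + 3L > n) return(NULL)
    substr(residues, end + 1L, end + 3L)
  } else {
    if (start - 3L < 0L) return(NULL)
    reverse_complement(substr(residues, start - 2L, start))
  }
}

#' Minimal-mismatch off-target scan
#'
#' Slides the protospacer over both strands of the target, counting Hamming
#' mismatches at every offset (ungapped; bulged off-targets are out of
#' scope), and returns the genome-wide minimum together with every site
#' achieving it. `pam_mode = "required"` restricts the scan to PAM-adjacent
#' offsets.
#'
#' @param guide Protospacer string.
#' @param target A [nuc_seq] (or DNA string), at least as long as the guide.
#' @param pam_mode `"ignored"` (default: raw sequence homology, the usual
#'   way mismatch counts to paralogs are quoted) or `"required"`.
#' @param pam IUPAC PAM pattern used for `pam_valid` flags and
#'   `pam_mode = "required"`.
#' @return A list with `k_min` (integer) and `hits`, a `data.frame` of
#'   best-scoring sites with columns `target_id`, `start`, `end`, `strand`,
#'   `k`, `pam_valid`, `guide_seq`, `site_seq`.
#' @export
min_mismatch_scan <- function(guide, target, pam_mode = c("ignored", "required"),
                              pam = "NGG") {
  pam_mode <- match.arg(pam_mode)
  guide <- as_residues(guide)
  tid <- if (inherits(target, "nuc_seq")) target$id else "seq"
  tres <- as_residues(target)
  m <- nchar(guide)
  n <- nchar(tres)
  if (n < m) stop("target shorter than guide")
  tchars <- strsplit(tres, "", fixed = TRUE)[[1]]
  best <- NULL
  for (strand in c("+", "-")) {
    # on the minus strand the protospacer reads as its reverse complement
    # along the top strand
    probe <- if (strand == "-") reverse_complement(guide) else guide
    gchars <- strsplit(probe, "", fixed = TRUE)[[1]]
    n_off <- n - m + 1L
    mism <- integer(n_off)
    for (i in seq_len(m)) {
      mism <- mism + (tchars[i:(i + n_off - 1L)] != gchars[i])
    }
    starts <- 0:(n_off - 1L)
    pam_valid <- vapply(starts, function(s) {
      p <- site_pam(tres, s, s + m, strand)
      !is.null(p) && iupac_match(pam, p)
    }, TRUE)
    keep <- if (pam_mode == "required") pam_valid else rep(TRUE, n_off)
    if (!any(keep)) next
    df <- data.frame(
      target_id = tid, start = starts[keep], end = starts[keep] + m,
      strand = strand, k = mism[keep], pam_valid = pam_valid[keep],
      stringsAsFactors = FALSE
    )
    best <- rbind(best, df)
  }
  if (is.null(best)) {
    stop("no scannable offsets (pam_mode = 'required' found no PAM-adjacent ",
         "site)")
  }
  k_min <- min(best$k)
  hits <- best[best$k == k_min, , drop = FALSE]
  hits$guide_seq <- guide
  hits$site_seq <- vapply(seq_len(nrow(hits)), function(i) {
    site_sequence(tres, hits$start[i], hits$end[i], hits$strand[i])
  }, "")
  hits <- hits[order(hits$start, match(hits$strand, c("+", "-"))), ,
               drop = FALSE]
  rownames(hits) <- NULL
  list(k_min = k_min, hits = hits)
}

#' Classify a guide's predicted functionality in one species
#'
#' Applies the perfect-alignment criterion over all sequences supplied for a
#' species (multiple records, e.g. unplaced scaffolds, are allowed; the best
#' status wins): `predicted_functional` when some sequence carries a
#' zero-mismatch protospacer site with a valid adjacent PAM; `pam_absent`
#' when a zero-mismatch site exists but never with a valid PAM;
#' `mismatched` with the minimum mismatch count `k` when `1 <= k <=
#' report_threshold`; `absent` otherwise.
#'
#' @param guide Protospacer string.
#' @param species_sequences Non-empty list of [nuc_seq] for one species.
#' @param species Species label (defaults to the first sequence's label).
#' @param guide_id Label stored in the output.
#' @param pam IUPAC PAM pattern.
#' @param report_threshold Mismatch count above which a target is reported
#'   `absent` (default 10, mirroring ">10-bp mismatches" treated as
#'   non-alignment).
#' @return A one-row `data.frame`: `species`, `guide_id`, `status`, `k_min`,
#'   `seq_id`, `start`, `end`, `strand`.
#' @export
classify_species <- function(guide, species_sequences, species = NULL,
                             guide_id = "guide", pam = "NGG",
                             report_threshold = 10L) {
  if (inherits(species_sequences, "nuc_seq")) {
    species_sequences <- list(species_sequences)
  }
  stopifnot(length(species_sequences) >= 1L)
  if (is.null(species)) {
    sp <- species_sequences[[1]]$species
    species <- if (!is.na(sp)) sp else species_sequences[[1]]$id
  }
  guide <- as_residues(guide)
  best <- list(status = "absent", k = NA_integer_, site = NULL)
  rank <- function(status) match(status, STATUS_LEVELS)
  for (sq in species_sequences) {
    if (nchar(sq$residues) < nchar(guide)) next
    perfect <- find_perfect_sites(guide, sq, pam = pam, require_pam = TRUE)
    if (nrow(perfect)) {
      best <- list(status = "predicted_functional", k = 0L,
                   site = perfect[1, ])
      break
    }
    res <- min_mismatch_scan(guide, sq, pam_mode = "ignored", pam = pam)
    status <- if (res$k_min == 0L) "pam_absent"
    else if (res$k_min <= report_threshold) "mismatched"
    else "absent"
    better <- rank(status) < rank(best$status) ||
      (status == "mismatched" && best$status == "mismatched" &&
         res$k_min < best$k)
    if (better) {
      site <- if (status != "absent") res$hits[1, ] else NULL
      best <- list(status = status, k = res$k_min, site = site)
    }
  }
  data.frame(
    species = species, guide_id = guide_id, status = best$status,
    k_min = if (best$status == "predicted_functional") 0L else best$k,
    seq_id = if (!is.null(best$site)) best$site$seq_id %||% best$site$target_id
             else NA_character_,
    start = if (!is.null(best$site)) best$site$start else NA_integer_,
    end = if (!is.null(best$site)) best$site$end else NA_integer_,
    strand = if (!is.null(best$site)) best$site$strand else NA_character_,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percent identity of the flanking context of a hit
#'
#' To decide whether a raw-genome hit really is the intended gene, the
#' regions flanking the hit are globally aligned against the flanks of the
#' guide in an annotated reference context; percent identity is identical
#' columns over alignment columns.
#'
#' @param guide_site One-row site `data.frame` (as from [find_perfect_sites])
#'   locating the hit in `target`.
#' @param target The [nuc_seq] containing the hit.
#' @param reference_context A [nuc_seq] known to contain the guide with
#'   flanking sequence (e.g. the annotated ortholog CDS).
#' @param guide Protospacer string used to locate the site in the reference.
#' @param flank_len Flank length on each side (default 50). Clipped flanks
#'   (hit near a sequence edge) are allowed: the percentage is computed on
#'   the available columns and `clipped = TRUE` is set, with a warning.
#' @param params Alignment parameters for the flank alignment.
#' @return A list: `identity_pct`, `clipped`, `n_cols`.
#' @export
flank_identity <- function(guide_site, target, reference_context, guide,
                           flank_len = 50L, params = align_params()) {
  tres <- as_residues(target)
  ref <- as_residues(reference_context)
  ref_hits <- find_perfect_sites(guide, reference_context, require_pam = FALSE)
  if (!nrow(ref_hits)) stop("reference context does not contain the guide")
  rs <- ref_hits$start[1]; re <- ref_hits$end[1]
  if (rs < flank_len || re + flank_len > nchar(ref)) {
    stop("reference context has < ", flank_len, " nt of flank on each side")
  }
  hs <- guide_site$start[1]; he <- guide_site$end[1]
  left_av <- min(flank_len, hs)
  right_av <- min(flank_len, nchar(tres) - he)
  clipped <- left_av < flank_len || right_av < flank_len
  if (clipped) {
    warning("hit flanks clipped to ", left_av, "/", right_av, " nt")
  }
  if (left_av + right_av == 0L) {
    return(list(identity_pct = NA_real_, clipped = TRUE, n_cols = 0L))
  }
  hit_fl <- paste0(substr(tres, hs - left_av + 1L, hs),
                   substr(tres, he + 1L, he + right_av))
  ref_fl <- paste0(substr(ref, rs - left_av + 1L, rs),
                   substr(ref, re + 1L, re + right_av))
  if (guide_site$strand[1] == "-") {
    hit_fl <- reverse_complement(
      paste0(substr(tres, hs - right_av + 1L, hs),
             substr(tres, he + 1L, he + left_av)))
  }
  al <- pairwise_align_affine(hit_fl, ref_fl, params)
  a <- strsplit(al$a, "", fixed = TRUE)[[1]]
  b <- strsplit(al$b, "", fixed = TRUE)[[1]]
  ident <- sum(a == b & a != "-")
  list(identity_pct = 100 * ident / length(a), clipped = clipped,
       n_cols = length(a))
}

#' Build a prediction table
#'
#' Complete guides-by-species matrix of per-species predictions: the
#' species-list analogue of a published cross-species compatibility table.
#'
#' @param guides Named character vector of protospacers (names = guide ids).
#' @param species_sets Named list (names = species) of lists of [nuc_seq].
#' @param pam,report_threshold Passed to [classify_species].
#' @return An object of class `prediction_table`: a list with `df` (one row
#'   per species x guide), `guides`, `species` (stable orders).
#' @export
prediction_table <- function(guides, species_sets, pam = "NGG",
                             report_threshold = 10L) {
  stopifnot(!is.null(names(guides)), !is.null(names(species_sets)))
  rows <- list()
  for (sp in names(species_sets)) {
    for (g in names(guides)) {
      rows[[length(rows) + 1L]] <- classify_species(
        guides[[g]], species_sets[[sp]], species = sp, guide_id = g,
        pam = pam, report_threshold = report_threshold)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else empty_prediction_df()
  rownames(df) <- NULL
  new_prediction_table(df, guides, names(species_sets))
}

empty_prediction_df <- function() {
  data.frame(species = character(0), guide_id = character(0),
             status = character(0), k_min = integer(0),
             seq_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), stringsAsFactors = FALSE)
}

new_prediction_table <- function(df, guides, species) {
  have <- interaction(df$species, df$guide_id, drop = FALSE)
  expected <- length(guides) * length(species)
  if (nrow(df) != expected || anyDuplicated(have)) {
    stop("incomplete prediction table: expected every (species, guide) pair ",
         "exactly once")
  }
  structure(list(df = df, guides = guides, species = species),
            class = "prediction_table")
}

#' @export
print.prediction_table <- function(x, ...) {
  cat(sprintf("<prediction_table> %d species x %d guides\n",
              length(x$species), length(x$guides)))
  invisible(x)
}

#' Aggregate a prediction table
#'
#' Per-guide counts of species predicted functional, and the union count
#' (species predicted functional for at least one guide) — the headline
#' "likely to function in at least N species" number.
#'
#' @param table A `prediction_table`.
#' @return A list: `per_guide` (named integer vector in guide order),
#'   `union` (integer), `n_species` (integer).
#' @export
aggregate_predictions <- function(table) {
  stopifnot(inherits(table, "prediction_table"))
  df <- table$df
  fun <- df[df$status == "predicted_functional", , drop = FALSE]
  per_guide <- vapply(names(table$guides), function(g) {
    sum(fun$guide_id == g)
  }, 0L)
  list(per_guide = per_guide,
       union = length(unique(fun$species)),
       n_species = length(table$species))
}

#' Write a prediction table as TSV
#'
#' The compatibility-table view: one row per species, one Yes/No column per
#' guide (`Yes` iff `predicted_functional`). Set `full = TRUE` for the long
#' format with full statuses and mismatch counts.
#'
#' @param table A `prediction_table`.
#' @param path Output path.
#' @param full Write the long per-pair format instead of the Yes/No matrix.
#' @return `path`, invisibly.
#' @export
write_prediction_tsv <- function(table, path, full = FALSE) {
  if (full) {
    utils::write.table(table$df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  df <- table$df
  wide <- data.frame(species = table$species, stringsAsFactors = FALSE)
  for (g in names(table$guides)) {
    st <- df$status[match(paste(table$species, g),
                          paste(df$species, df$guide_id))]
    wide[[g]] <- ifelse(st == "predicted_functional", "Yes", "No")
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a prediction table as JSON
#'
#' Full status detail plus the aggregate summary.
#'
#' @param table A `prediction_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prediction_json <- function(table, path) {
  agg <- aggregate_predictions(table)
  obj <- list(
    species = table$species,
    guides = as.list(table$guides),
    predictions = table$df,
    summary = list(per_guide = as.list(agg$per_guide), union = agg$union,
                   n_species = agg$n_species)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a Yes/No compatibility table as a prediction table
#'
#' Parses a TSV with a `species` column and one Yes/No column per guide
#' (`Yes` -> `predicted_functional`, `No` -> `absent`); the format of the
#' packaged species-list fixtures.
#'
#' @param path TSV path.
#' @return A `prediction_table` (sites and mismatch counts are `NA`: the
#'   fixture records status only).
#' @export
read_prediction_tsv <- function(path) {
  wide <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(names(wide)[1] == "species", ncol(wide) >= 2L)
  guide_cols <- names(wide)[-1]
  rows <- list()
  for (i in seq_len(nrow(wide))) {
    for (g in guide_cols) {
      val <- wide[[g]][i]
      if (!val %in% c("Yes", "No")) {
        stop("unexpected cell value '", val, "' (want Yes/No)")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species = wide$species[i], guide_id = g,
        status = if (val == "Yes") "predicted_functional" else "absent",
        k_min = NA_integer_, seq_id = NA_character_, start = NA_integer_,
        end = NA_integer_, strand = NA_character_, stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows)
  guides <- stats::setNames(rep(NA_character_, length(guide_cols)), guide_cols)
  new_prediction_table(df, guides, wide$species)
}
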