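# Seeded generators: ortholog families under a star phylogeny with planted
# conserved windows and per-species PAM knockouts, paralogs at a chosen
# mismatch distance, and the packaged printed-table / sequence-constant
# fixtures. Everything is bit-reproducible for a fixed seed.

# Run code under a private RNG state so generators never disturb (or depend
# on) the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

#' Generate a random ancestral sequence
#'
#' iid bases with the requested GC fraction; deterministic for a fixed seed.
#'
#' @param length Sequence length (>= 1).
#' @param gc_fraction Expected G+C fraction (default 0.5).
#' @param seed Integer seed.
#' @param id Record id.
#' @return A [nuc_seq].
#' @export
generate_ancestor <- function(length, gc_fraction = 0.5, seed = 1L,
                              id = "ancestor") {
  if (length < 1L) stop("length must be >= 1")
  stopifnot(gc_fraction >= 0, gc_fraction <= 1)
  probs <- c((1 - gc_fraction) / 2, gc_fraction / 2, gc_fraction / 2,
             (1 - gc_fraction) / 2)
  res <- with_seed(seed, paste(
    sample(DNA_BASES, length, replace = TRUE, prob = probs), collapse = ""))
  nuc_seq(id, res)
}

#' Specify a synthetic ortholog family
#'
#' The stated world the generators emulate: a star phylogeny of `n_species`
#' orthologs diverging independently from one ancestor at per-site
#' substitution probability `divergence` outside planted conserved
#' intervals, which stay untouched. Intervals with `pam_terminal = TRUE`
#' end in `GG` (so their final 3 nt are an NGG PAM for the 20-mer before
#' them) in every species except those in `pam_knockout`, whose terminal
#' dinucleotide is forced to a non-GG pair — the species-lacking-a-PAM
#' situation observed in real assemblies.
#'
#' @param n_species Number of species.
#' @param length Sequence length.
#' @param divergence Per-site substitution probability in `[0, 1)`.
#' @param conserved `data.frame` with 0-based half-open `start`, `end` and
#'   logical `pam_terminal`; intervals must be disjoint and in-bounds.
#' @param pam_knockout Character vector of species ids (subset of
#'   `sp1..spN`) whose planted PAM is destroyed.
#' @param seed Integer seed.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n_species, length, divergence = 0.1,
                        conserved = NULL, pam_knockout = character(0),
                        seed = 1L) {
  stopifnot(n_species >= 1L, length >= 1L, divergence >= 0, divergence < 1)
  if (is.null(conserved)) {
    conserved <- data.frame(start = integer(0), end = integer(0),
                            pam_terminal = logical(0))
  }
  stopifnot(all(c("start", "end", "pam_terminal") %in% names(conserved)))
  if (nrow(conserved)) {
    o <- order(conserved$start)
    conserved <- conserved[o, , drop = FALSE]
    stopifnot(all(conserved$start >= 0L), all(conserved$end <= length),
              all(conserved$end > conserved$start))
    if (nrow(conserved) > 1L &&
        any(conserved$start[-1] < conserved$end[-nrow(conserved)])) {
      stop("conserved intervals overlap")
    }
  }
  ids <- sprintf("sp%d", seq_len(n_species))
  if (!all(pam_knockout %in% ids)) {
    stop("pam_knockout species not in family: ",
         paste(setdiff(pam_knockout, ids), collapse = ", "))
  }
  structure(list(n_species = n_species, length = length,
                 divergence = divergence, conserved = conserved,
                 pam_knockout = pam_knockout, seed = as.integer(seed),
                 ids = ids),
            class = "family_spec")
}

#' Evolve an ortholog family from an ancestor
#'
#' Substitutions are iid per site (uniform over the three alternatives) at
#' rate `divergence` outside conserved intervals and zero inside; no indels.
#' PAM-terminal intervals have their last two ancestor bases set to `GG`
#' before evolution, then knocked out per species as specified.
#'
#' @param ancestor A [nuc_seq] of length `spec$length` (generated if
#'   omitted).
#' @param spec A [family_spec].
#' @return Named list of [nuc_seq], ids `sp1..spN` (species label = id).
#' @export
evolve_family <- function(ancestor = NULL, spec) {
  stopifnot(inherits(spec, "family_spec"))
  if (is.null(ancestor)) {
    ancestor <- generate_ancestor(spec$length, seed = spec$seed + 1L)
  }
  stopifnot(nchar(ancestor$residues) == spec$length)
  anc <- strsplit(ancestor$residues, "", fixed = TRUE)[[1]]
  conserved_mask <- rep(FALSE, spec$length)
  for (i in seq_len(nrow(spec$conserved))) {
    iv <- spec$conserved[i, ]
    conserved_mask[(iv$start + 1L):iv$end] <- TRUE
    if (iv$pam_terminal) anc[(iv$end - 1L):iv$end] <- c("G", "G")
  }
  with_seed(spec$seed, {
    out <- lapply(seq_len(spec$n_species), function(si) {
      chars <- anc
      mut <- runif(spec$length) < spec$divergence & !conserved_mask
      if (any(mut)) {
        chars[mut] <- vapply(chars[mut], function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, "")
      }
      id <- spec$ids[si]
      if (id %in% spec$pam_knockout) {
        for (i in seq_len(nrow(spec$conserved))) {
          iv <- spec$conserved[i, ]
          if (!iv$pam_terminal) next
          # destroy NGG: force a terminal dinucleotide that is not GG
          repeat {
            dinuc <- sample(DNA_BASES, 2L, replace = TRUE)
            if (!(dinuc[1] == "G" && dinuc[2] == "G")) break
          }
          chars[(iv$end - 1L):iv$end] <- dinuc
        }
      }
      nuc_seq(id, paste(chars, collapse = ""), species = id)
    })
    names(out) <- spec$ids
    out
  })
}

#' Specify a planted paralog
#'
#' @param source A [nuc_seq] containing the guide site (e.g. one family
#'   member).
#' @param guide_site One-row site `data.frame` locating the protospacer in
#'   `source`.
#' @param k Number of mismatches to plant inside the protospacer
#'   (`0 <= k <= guide length`).
#' @param background_divergence Per-site substitution probability outside
#'   the protospacer site and its PAM slot.
#' @param seed Integer seed.
#' @return A list of class `paralog_spec`.
#' @export
paralog_spec <- function(source, guide_site, k, background_divergence = 0.2,
                         seed = 1L) {
  glen <- guide_site$end[1] - guide_site$start[1]
  if (k < 0L || k > glen) stop("k must be in [0, guide length]")
  structure(list(source = source, guide_site = guide_site, k = as.integer(k),
                 background_divergence = background_divergence,
                 seed = as.integer(seed)),
            class = "paralog_spec")
}

#' Plant a paralog at a chosen mismatch distance
#'
#' Copies the source, applies background divergence everywhere except the
#' protospacer site and its 3-nt PAM slot (both left intact), then plants
#' exactly `k` substitutions at seeded positions (drawn without replacement)
#' inside the protospacer. [min_mismatch_scan] recovers `k` by
#' construction.
#'
#' @param spec A [paralog_spec].
#' @param id Record id for the product.
#' @return A [nuc_seq].
#' @export
plant_paralog <- function(spec, id = "paralog") {
  stopifnot(inherits(spec, "paralog_spec"))
  chars <- strsplit(spec$source$residues, "", fixed = TRUE)[[1]]
  s <- spec$guide_site$start[1]; e <- spec$guide_site$end[1]
  strand <- spec$guide_site$strand[1]
  protected <- rep(FALSE, length(chars))
  protected[(s + 1L):e] <- TRUE
  pam_idx <- if (strand == "+") (e + 1L):(e + 3L) else (s - 2L):s
  pam_idx <- pam_idx[pam_idx >= 1L & pam_idx <= length(chars)]
  protected[pam_idx] <- TRUE
  with_seed(spec$seed, {
    mut <- runif(length(chars)) < spec$background_divergence & !protected
    if (any(mut)) {
      chars[mut] <- vapply(chars[mut], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, "")
    }
    if (spec$k > 0L) {
      pos <- sample((s + 1L):e, spec$k)
      chars[pos] <- vapply(chars[pos], function(b) {
        sample(setdiff(DNA_BASES, b), 1L)
      }, "")
    }
    nuc_seq(id, paste(chars, collapse = ""))
  })
}

#' The printed guide and primer constants
#'
#' The four published 20-nt guides (three against the oxytocin receptor
#' coding sequence, one bacterial lacZ control) and the genotyping primer
#' pair.
#'
#' @return `oxtr_guides()`: named character vector of protospacers;
#'   `t7_primers()`: a [primer_pair].
#' @export
oxtr_guides <- function() {
  c(gRNA_dOXTR.1 = "GGTGCTTCATGAAAAAGAAG",
    gRNA_dOXTR.2 = "GTGATGTCCCACAGCAGCTG",
    gRNA_dOXTR.3 = "GCCCGACCTGCTGTGTCGTC",
    gRNA_CTRL = "GTGAGCGAGTAACAACCCGT")
}

#' @rdname oxtr_guides
#' @export
t7_primers <- function() {
  primer_pair(forward = "AGCAGTCAAAAACACCGTCC",
              reverse = "GACACCTGGACAACTCATCGG")
}

#' Load a packaged fixture
#'
#' `"table1"`, `"table2"`, `"table3"`: the transcribed published
#' species-by-guide compatibility tables (rodent genomes, mammalian Oxtr,
#' mammalian Avpr1b) as [prediction_table]s (Yes -> `predicted_functional`,
#' No -> `absent`). `"guides"`: the printed protospacers. `"t7_primers"`:
#' the genotyping primer pair. `"demo_family"`: a small synthetic ortholog
#' family FASTA (generated, not biological — see its header).
#'
#' @param name Fixture name.
#' @return See above.
#' @export
load_fixture <- function(name) {
  files <- c(table1 = "table1_rodent_genomes.tsv",
             table2 = "table2_mammal_oxtr.tsv",
             table3 = "table3_mammal_avpr1b.tsv")
  if (name %in% names(files)) {
    path <- system.file("extdata", files[[name]], package = "crossguide",
                        mustWork = TRUE)
    return(read_prediction_tsv(path))
  }
  switch(name,
    guides = oxtr_guides(),
    t7_primers = t7_primers(),
    demo_family = read_fasta(system.file(
      "extdata", "synthetic_demo_family.fasta", package = "crossguide",
      mustWork = TRUE)),
    stop("unknown fixture: '", name, "'")
  )
}
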