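site_pam_test <- function(res, s, e, strand) {
  crossguide:::site_pam(res, s, e, strand)
}

test_that("find_perfect_sites locates constructed sites on both strands", {
  set.seed(1)
  g <- rand_dna(20)
  plus <- planted_template(g, pam = "TGG")
  hits <- find_perfect_sites(g, nuc_seq("t", plus))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 60L)
  expect_equal(hits$strand, "+")
  # minus-strand planting: embed revcomp(protospacer + PAM)
  minus <- paste0(rand_dna(40), reverse_complement(paste0(g, "AGG")),
                  rand_dna(40))
  mh <- find_perfect_sites(g, nuc_seq("t", minus))
  expect_equal(nrow(mh), 1L)
  expect_equal(mh$strand, "-")
  expect_equal(mh$start, 43L)  # 3-nt PAM sits at [40,43) on the top strand
  expect_equal(site_pam_test(minus, mh$start, mh$end, "-"), "AGG")
  expect_error(find_perfect_sites("ACGTACGTACGTACGT", "ACGT"), "17")
})

test_that("PAM requirement excludes edge sites and non-NGG neighbours", {
  set.seed(2)
  g <- rand_dna(20)
  # site at the very end: no room for a PAM slot
  edge <- paste0(rand_dna(30), g)
  expect_equal(nrow(find_perfect_sites(g, nuc_seq("t", edge))), 0L)
  expect_equal(nrow(find_perfect_sites(g, nuc_seq("t", edge),
                                       require_pam = FALSE)), 1L)
  # protospacer followed by ATT: not a PAM
  noPam <- paste0(rand_dna(30), g, "ATT", rand_dna(30))
  expect_equal(nrow(find_perfect_sites(g, nuc_seq("t", noPam))), 0L)
})

test_that("control guide hits nothing in synthetic vertebrate-like families", {
  spec <- family_spec(n_species = 6, length = 1500, divergence = 0.15,
                      seed = 4242)
  fam <- evolve_family(spec = spec)
  ctrl <- oxtr_guides()[["gRNA_CTRL"]]
  for (sq in fam) {
    expect_equal(nrow(find_perfect_sites(ctrl, sq, require_pam = FALSE)), 0L)
  }
})

test_that("min_mismatch_scan equals the exhaustive Hamming oracle (property)", {
  set.seed(5)
  for (rep in 1:10) {
    g <- rand_dna(20)
    t <- rand_dna(sample(100:5000, 1))
    res <- min_mismatch_scan(g, nuc_seq("t", t))
    expect_equal(res$k_min, oracle_min_mismatch(g, t))
    expect_true(all(res$hits$k == res$k_min))
    # recorded aligned pairs have exactly k mismatches
    for (i in seq_len(nrow(res$hits))) {
      a <- strsplit(res$hits$guide_seq[i], "")[[1]]
      b <- strsplit(res$hits$site_seq[i], "")[[1]]
      expect_equal(sum(a != b), res$hits$k[i])
    }
  }
})

test_that("min_mismatch_scan: self-site, planted k, pam_mode, monotonicity", {
  set.seed(6)
  g <- rand_dna(20)
  tpl <- planted_template(g)
  expect_equal(min_mismatch_scan(g, nuc_seq("t", tpl))$k_min, 0L)
  expect_error(min_mismatch_scan(g, nuc_seq("t", "ACGT")), "shorter")

  # find_perfect_sites == min_mismatch_scan restricted to k = 0 with PAM
  res0 <- min_mismatch_scan(g, nuc_seq("t", tpl), pam_mode = "required")
  perf <- find_perfect_sites(g, nuc_seq("t", tpl))
  expect_equal(res0$k_min, 0L)
  expect_equal(res0$hits$start, perf$start)

  # mutating one protospacer base raises k_min by at most 1, never lowers it
  for (rep in 1:10) {
    base <- planted_template(g)
    k0 <- min_mismatch_scan(g, nuc_seq("t", base))$k_min
    pos <- 60 + sample(0:19, 1)
    old <- substr(base, pos + 1, pos + 1)
    substr(base, pos + 1, pos + 1) <- sample(setdiff(c("A", "C", "G", "T"),
                                                     old), 1)
    k1 <- min_mismatch_scan(g, nuc_seq("t", base))$k_min
    expect_gte(k1, k0)
    expect_lte(k1, k0 + 1L)
  }
})

test_that("classify_species implements the status hierarchy", {
  set.seed(7)
  g <- rand_dna(20)
  functional <- nuc_seq("a", planted_template(g), species = "spX")
  no_pam <- nuc_seq("b", paste0(rand_dna(50), g, "ATT", rand_dna(50)))
  spec <- paralog_spec(functional,
                       data.frame(start = 60L, end = 80L, strand = "+"),
                       k = 4, background_divergence = 0, seed = 8)
  mm4 <- plant_paralog(spec)
  far <- nuc_seq("d", rand_dna(400))

  expect_equal(classify_species(g, functional)$status, "predicted_functional")
  expect_equal(classify_species(g, functional)$k_min, 0L)
  expect_equal(classify_species(g, no_pam)$status, "pam_absent")
  cl <- classify_species(g, mm4)
  expect_equal(cl$status, "mismatched")
  expect_equal(cl$k_min, 4L)
  k_far <- min_mismatch_scan(g, far)$k_min
  want <- if (k_far > 10) "absent" else "mismatched"
  expect_equal(classify_species(g, far)$status, want)
  # threshold rule: k above report_threshold reports absent
  expect_equal(classify_species(g, mm4, report_threshold = 3L)$status,
               "absent")
  # best status wins across multiple sequences per species
  expect_equal(classify_species(g, list(far, no_pam, functional))$status,
               "predicted_functional")
  expect_equal(classify_species(g, list(far, mm4))$status, "mismatched")
})

test_that("flank_identity: self-hit 100%, random ~25%, ortholog ~90%", {
  set.seed(9)
  g <- rand_dna(20)
  ref <- nuc_seq("ref", planted_template(g, left = 80, right = 80))
  hit <- find_perfect_sites(g, ref)
  self <- flank_identity(hit, ref, ref, g)
  expect_equal(self$identity_pct, 100)
  expect_false(self$clipped)

  # uniformly random flanks: ~25% identity before alignment gain; the global
  # alignment inflates it somewhat, so allow a generous band around 25%
  set.seed(10)
  rand_target <- nuc_seq("r", paste0(rand_dna(60), g, "AGG", rand_dna(60)))
  rh <- find_perfect_sites(g, rand_target)
  rid <- flank_identity(rh, rand_target, ref, g)
  expect_lt(rid$identity_pct, 60)

  # ortholog-like flanks at divergence 0.1: ~90%
  res <- ref$residues
  chars <- strsplit(res, "")[[1]]
  # protect the protospacer [80,100) and its PAM slot (1-based 81:103)
  protected <- rep(FALSE, length(chars)); protected[81:103] <- TRUE
  mut <- runif(length(chars)) < 0.1 & !protected
  chars[mut] <- vapply(chars[mut], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1)
  }, "")
  ortho <- nuc_seq("o", paste(chars, collapse = ""))
  oh <- find_perfect_sites(g, ortho)
  oid <- flank_identity(oh, ortho, ref, g)
  expect_gt(oid$identity_pct, 80)
  expect_lt(oid$identity_pct, 100)

  # clipped flanks warn and flag
  short <- nuc_seq("s", paste0(rand_dna(10), g, "AGG", rand_dna(60)))
  sh <- find_perfect_sites(g, short)
  expect_warning(sid <- flank_identity(sh, short, ref, g), "clipped")
  expect_true(sid$clipped)
})

test_that("prediction tables are complete, aggregate correctly, and round trip", {
  set.seed(11)
  g1 <- rand_dna(20); g2 <- rand_dna(20)
  guides <- c(gA = g1, gB = g2)
  sets <- list(
    sp1 = list(nuc_seq("s1", planted_template(g1), species = "sp1")),
    sp2 = list(nuc_seq("s2", planted_template(g2), species = "sp2")),
    sp3 = list(nuc_seq("s3", paste0(planted_template(g1), g2, "TGG"),
                       species = "sp3"))
  )
  tab <- prediction_table(guides, sets)
  agg <- aggregate_predictions(tab)
  expect_equal(unname(agg$per_guide), c(2L, 2L))
  expect_equal(agg$union, 3L)
  expect_gte(agg$union, max(agg$per_guide))
  expect_lte(agg$union, agg$n_species)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_prediction_tsv(tab, tsv)
  back <- read_prediction_tsv(tsv)
  agg2 <- aggregate_predictions(back)
  expect_equal(unname(agg2$per_guide), unname(agg$per_guide))
  expect_equal(agg2$union, agg$union)

  json <- withr::local_tempfile(fileext = ".json")
  write_prediction_json(tab, json)
  obj <- jsonlite::read_json(json)
  expect_equal(obj$summary$union, 3L)

  # empty table: all counts zero
  empty <- prediction_table(guides, stats::setNames(list(), character(0)))
  agg0 <- aggregate_predictions(empty)
  expect_equal(unname(agg0$per_guide), c(0L, 0L))
  expect_equal(agg0$union, 0L)

  # one guide, one species
  one <- prediction_table(guides[1], sets[1])
  expect_equal(unname(aggregate_predictions(one)$per_guide), 1L)
})
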