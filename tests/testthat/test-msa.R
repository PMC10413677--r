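test_that("kmer_distance matches a set-arithmetic oracle", {
  expect_equal(kmer_distance("ACGTACGT", "ACGTACGT", 4), 0)
  # disjoint 4-mer sets
  expect_equal(kmer_distance(strrep("A", 20), strrep("C", 20), 4), 1)
  set.seed(11)
  for (rep in 1:10) {
    a <- rand_dna(sample(10:120, 1))
    b <- rand_dna(sample(10:120, 1))
    ka <- unique(substring(a, 1:(nchar(a) - 3), 4:nchar(a)))
    kb <- unique(substring(b, 1:(nchar(b) - 3), 4:nchar(b)))
    want <- 1 - length(intersect(ka, kb)) / min(length(ka), length(kb))
    expect_equal(kmer_distance(a, b, 4), want)
    expect_equal(kmer_distance(a, b, 4), kmer_distance(b, a, 4))
  }
  expect_error(kmer_distance("ACG", "ACGT", 4), "k must")
})

test_that("build_guide_tree joins closest pairs with deterministic ties", {
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  t2 <- build_guide_tree(D2)
  expect_equal(t2$height, 0.2)
  expect_setequal(crossguide:::guide_tree_leaves(t2), c("a", "b"))

  D3 <- matrix(c(0, .1, .5, .1, 0, .5, .5, .5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- build_guide_tree(D3)
  expect_setequal(crossguide:::guide_tree_leaves(t3$left), c("a", "b"))
  expect_error(build_guide_tree(matrix(c(0, 1, 2, 0), 2, 2,
    dimnames = list(c("a", "b"), c("a", "b")))), "symmetric")
})

test_that("build_guide_tree equals a hand-executed UPGMA on 4 taxa", {
  # D(ab)=2 joins first at h=1; D((ab)c) = (4+6)/2 = 5, D((ab)d)=(8+8)/2=8,
  # D(cd)=8 -> join (ab) with c at h=2.5; root height = ((8+8)/2*2+8)/3... use
  # size-weighted: D((abc)d) = (8*2+8)/3 = 8 -> root at 4.
  ids <- c("a", "b", "c", "d")
  D <- matrix(c(0, 2, 4, 8,
                2, 0, 6, 8,
                4, 6, 0, 8,
                8, 8, 8, 0), 4, 4, byrow = TRUE, dimnames = list(ids, ids))
  tr <- build_guide_tree(D)
  expect_equal(tr$height, 4)
  expect_setequal(crossguide:::guide_tree_leaves(tr$left), c("a", "b", "c"))
  expect_equal(tr$left$height, 2.5)
  expect_setequal(crossguide:::guide_tree_leaves(tr$left$left), c("a", "b"))
  expect_equal(tr$left$left$height, 1)
})

test_that("build_guide_tree heights agree with hclust average linkage", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 5
    M <- matrix(runif(n * n, 0.1, 1), n, n)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    ids <- letters[1:n]
    dimnames(D) <- list(ids, ids)
    tr <- build_guide_tree(D)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(tr$height, max(hc$height) / 2, tolerance = 1e-12)
  }
})

test_that("pairwise_align_affine reproduces documented examples", {
  p <- align_params(match = 1, mismatch = -1, gap_open = 0, gap_extend = -2)
  res <- pairwise_align_affine("ACGT", "ACT", p)
  expect_equal(res$a, "ACGT")
  expect_equal(res$b, "AC-T")
  expect_equal(res$score, 1)

  ident <- pairwise_align_affine("ACGTACGT", "ACGTACGT",
                                 align_params(match = 1))
  expect_equal(ident$score, 8)
  expect_false(grepl("-", ident$a, fixed = TRUE))
})

test_that("pairwise_align_affine score equals exhaustive enumeration and is symmetric", {
  set.seed(31)
  p <- align_params(match = 2, mismatch = -1, gap_open = -3, gap_extend = -1)
  for (rep in 1:10) {
    a <- rand_dna(sample(2:5, 1))
    b <- rand_dna(sample(2:5, 1))
    want <- oracle_global_score(a, b, 2, -1, -3, -1)
    got <- pairwise_align_affine(a, b, p)
    expect_equal(got$score, want, label = paste(a, b))
    expect_equal(pairwise_align_affine(b, a, p)$score, got$score)
    # gapped strings reproduce the inputs
    expect_equal(gsub("-", "", got$a, fixed = TRUE), a)
    expect_equal(gsub("-", "", got$b, fixed = TRUE), b)
  }
})

test_that("pairwise_align_affine score agrees with Biostrings on longer pairs", {
  set.seed(41)
  p <- align_params(match = 2, mismatch = -1, gap_open = -10,
                    gap_extend = -0.5)
  mat <- matrix(-1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  diag(mat) <- 2
  for (rep in 1:6) {
    a <- rand_dna(sample(30:120, 1))
    b <- rand_dna(sample(30:120, 1))
    got <- pairwise_align_affine(a, b, p)$score
    want <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
    expect_equal(got, want)
  }
})

test_that("progressive_align stacks identical or indel-free families without gaps", {
  seqs <- lapply(1:4, function(i) nuc_seq(paste0("s", i), strrep("ACGT", 25)))
  aln <- progressive_align(seqs)
  expect_equal(aln$n_cols, 100)
  expect_false(any(grepl("-", aln$rows, fixed = TRUE)))

  # low divergence, no indels: alignment is plain stacking
  spec <- family_spec(n_species = 4, length = 300, divergence = 0.05,
                      seed = 9)
  fam <- evolve_family(spec = spec)
  aln2 <- progressive_align(fam)
  expect_equal(aln2$n_cols, 300)
  for (id in names(fam)) {
    expect_equal(aln2$rows[[id]], fam[[id]]$residues)
  }
  expect_error(progressive_align(seqs[1]), ">= 2")
})

test_that("a 3-nt deletion aligns as one 3-column gap run", {
  set.seed(51)
  base <- rand_dna(240)
  del <- paste0(substr(base, 1, 120), substr(base, 124, 240))
  seqs <- list(nuc_seq("full1", base), nuc_seq("full2", base),
               nuc_seq("short", del))
  aln <- progressive_align(seqs)
  expect_equal(aln$n_cols, 240)
  gaps <- gregexpr("-+", aln$rows[["short"]])[[1]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 3L)
  # ungap round trip holds for every row
  expect_equal(gsub("-", "", aln$rows[["short"]], fixed = TRUE), del)
  expect_equal(aln$rows[["full1"]], base)
})

test_that("alignment I/O round trips in both dialects and rejects ragged rows", {
  spec <- family_spec(n_species = 3, length = 150, divergence = 0.1, seed = 3)
  aln <- progressive_align(evolve_family(spec = spec))
  for (dialect in c("fasta", "clustal")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_alignment(aln, path, dialect = dialect)
    back <- read_alignment(path, dialect = dialect)
    expect_equal(back$rows, aln$rows)
    expect_equal(back$ids, aln$ids)
  }
  expect_error(alignment(c(a = "ACGT", b = "AC")), "shortest row is 'b'")
  bad <- withr::local_tempfile(fileext = ".aln")
  writeLines(c("not clustal", "a ACGT"), bad)
  expect_error(read_alignment(bad, "clustal"), "CLUSTAL")
})

test_that("coordinate maps are mutually inverse and monotone", {
  aln <- alignment(c(r1 = "AC-GT-A", r2 = "ACCG-TA"))
  expect_equal(column_to_residue(aln, "r1", 0), 0)
  expect_true(is.na(column_to_residue(aln, "r1", 2)))
  expect_equal(column_to_residue(aln, "r1", 3), 2)
  expect_equal(residue_to_column(aln, "r1", 2), 3)
  expect_error(column_to_residue(aln, "r1", 7), "out of range")
  expect_error(residue_to_column(aln, "r1", 5), "out of range")
  expect_error(residue_to_column(aln, "zz", 0), "unknown row")
  set.seed(61)
  spec <- family_spec(n_species = 3, length = 120, divergence = 0.2, seed = 8)
  fam <- evolve_family(spec = spec)
  fam$sp2 <- nuc_seq("sp2", paste0(substr(fam$sp2$residues, 1, 50),
                                   substr(fam$sp2$residues, 56, 120)))
  aln2 <- progressive_align(fam)
  for (id in aln2$ids) {
    n <- nchar(gsub("-", "", aln2$rows[[id]], fixed = TRUE))
    cols <- vapply(0:(n - 1), residue_to_column, 0L, aln = aln2, row_id = id)
    expect_true(all(diff(cols) > 0))
    back <- vapply(cols, column_to_residue, 0L, aln = aln2, row_id = id)
    expect_equal(back, 0:(n - 1))
  }
})
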