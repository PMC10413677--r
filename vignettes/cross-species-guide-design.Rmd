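---
title: "Cross-species guide design: model, parameters, and validation scope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species guide design: model, parameters, and validation scope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossguide)
```

## The design problem

A Cas9 ribonucleoprotein cuts where its 20-nt spacer matches genomic DNA
(the protospacer) immediately 5′ of an NGG PAM. A *cross-species* tool must
satisfy this in every target genome simultaneously, which reduces to three
sequence-level questions this package answers:

* **Where is the target gene identical across the panel?** Maximal runs of
  alignment columns in which every ortholog carries the same unambiguous
  base, at least one protospacer long.
* **Is each candidate usable in each species?** Exact protospacer match plus
  a valid per-species PAM. The PAM is checked per row and may lie outside
  the conserved run: PAM presence is a species property, and a single
  species can lack the NGG next to an otherwise perfect target (observable
  only once its assembly exists). We model this explicitly with the
  `pam_absent` status and the generator's PAM-knockout switch.
* **What else could it cut?** The closest paralogs (for a peptide-hormone
  receptor, its sister receptor genes) ranked by minimal ungapped Hamming
  distance over both strands, optionally with flanking-context identity to
  disambiguate hits in unannotated assemblies.

## Matching model

Matching is asymmetric by design. Pattern ambiguity codes are *permissive*
(N in NGG matches any base); target ambiguity codes are *strict* — an N in
an assembly never satisfies any pattern base, including N. A permissive
pattern should not certify an uncertain base: in low-quality assemblies this
would inflate "perfect" calls. Consequently conservation also requires
unambiguous bases: one N in one row breaks a conserved run.

Coordinates are 0-based, half-open, always on the top strand, with strand
carried separately; minus-strand protospacers are reported 5′→3′ on their
own strand while their sites stay top-strand intervals. This makes cut-site
and fragment arithmetic exact: a cut at coordinate *c* splits an amplicon
into `[0, c)` and `[c, L)`.

## Aligner

The progressive aligner follows the classic ClustalW recipe — pairwise
k-mer distances (`1 − shared/min`), a UPGMA guide tree, profile–profile
merges under a three-state affine-gap Needleman–Wunsch ("once a gap, always
a gap") — with every tie broken deterministically (diagonal > vertical >
horizontal in traceback; lexicographically smallest pair in UPGMA joins), so
alignments are bit-reproducible. Column pair scores between profiles are the
mean substitution score over row pairs with gaps contributing 0, computed as
a matrix product over IUPAC-category counts; the DP itself is compiled code.

Defaults: match +2, mismatch −1, gap open −10, gap extend −0.5 (a gap of
length L costs `gap_open + L·gap_extend`), k = 4. These suit closely related
coding orthologs, where the true alignment is nearly gap-free; they are not
tuned for distant or intron-containing sequences, and the original analysis
this workflow mirrors used an external ClustalW with unstated parameters, so
exact reproduction of any particular published alignment is not guaranteed.
Users can import an external alignment (aligned FASTA or CLUSTAL) instead.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `guide_len` | 20 nt | protospacer length; enumeration rejects < 17 or > 25 |
| `pam` | `NGG` | spCas9 PAM, IUPAC pattern |
| `min_window` | 20 columns | minimum conserved-run length; "long enough for a guide" means one full protospacer, i.e. a strict > 19 |
| `report_threshold` | 10 mismatches | above this, a target is reported `absent` rather than `mismatched(k)` — mirroring the convention that > 10 mismatches is non-alignment |
| `flank_len` | 50 nt | flank on each side for context-identity checks |
| `cut_offset` | 3 nt | blunt cut 5′ of the PAM (canonical spCas9, between protospacer positions 17/18); exposed because nickase or engineered variants differ |

With multiple sequences per species (unplaced scaffolds), the best status
wins in the order functional > pam_absent > mismatched(k, smaller k better)
> absent.

## What the synthetic generator emulates — and what it does not

`family_spec`/`evolve_family` produce a star phylogeny: each species draws
iid substitutions (uniform over the three alternatives) from one ancestor at
per-site probability `divergence`, zero inside planted conserved intervals;
`pam_terminal` intervals end in GG so that their final three bases form the
PAM of the 20-mer before them; knockout species get a forced non-GG terminal
dinucleotide. `plant_paralog` copies a source, protects the guide site and
its PAM, applies background divergence elsewhere, and plants exactly *k*
protospacer mismatches. Defaults (6 species, ~0.1 divergence, one 23-nt
planted window) reflect the scale of a realistic rodent ortholog panel:
coding-sequence identity between congeneric rodents is typically ≥ 90%.

Deliberately missing: indels (optional only, to exercise the aligner),
transition/transversion bias, codon structure and selection, tree-shaped
relatedness, assembly gaps/ambiguity. A green end-to-end test therefore
establishes that the design–predict loop is *internally consistent* (planted
windows are found, knockouts classified `pam_absent`, planted k recovered)
— not that any particular biological genome will yield the published guide
set. The packaged compatibility tables are transcriptions of published
species lists and exercise only parsing/aggregation, not sequence scanning.

## Numerical and degenerate-input choices

* Mismatch counting is ungapped (Hamming); bulged off-targets are out of
  scope, as are heuristic aligners — scanning is exhaustive, so "perfect
  alignment" is literal and complete at desk scale.
* `min_mismatch_scan` with `pam_mode = "required"` errors when no
  PAM-adjacent offset exists (rather than inventing a value).
* Flank identity clips at sequence edges with a warning and computes the
  percentage on available columns; zero available flank yields `NA`.
* Amplicon extraction requires exactly one oriented product; zero and
  multiple products are distinct errors listing the sites.
* `frameshift_fraction` rejects zero-length indels and zero total weight;
  with one representative per residue class modulo 3 it returns 2/3, the
  standard estimate of the nonfunctional fraction among mutant alleles.
* All generators use a private RNG stream (seed in, caller's
  `.Random.seed` untouched); identical seeds give byte-identical FASTA/TSV
  outputs through the CLI.

## Open design choices made here

* Guide enumeration deduplicates by (protospacer, strand) across runs.
* Candidate selection beyond enumeration (on-target efficiency scores,
  chromatin context) is intentionally out of scope; published workflows
  delegate that ranking to external services.
* Which species panel to design on is the user's: designing on a subset
  without a problem species, or enumerating with
  `require_pam_conserved = FALSE` and reading per-row flags, are both
  supported routes to the same decision.

## Known limitations

Ortholog identification, taxonomy, and genome retrieval are upstream of this
package — inputs are FASTA the user asserts to be orthologs/paralogs. The
aligner is O(n²·L²) in time over profile pairs and not meant for
genome-scale input. T7 digestion is modelled as complete cleavage at the
Cas9 cut; partial digestion and band intensities are not predicted.
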