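---
title: "Methods: mining disulfide-rich toxin peptides from venom-gland transcriptomes"
author: "knotminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining disulfide-rich toxin peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotminer)
```

## The problem

Tarantula venoms are dominated by disulfide-rich peptides (DRPs) of 3-10
kDa, many adopting the inhibitor cystine knot (ICK) fold, that modulate
voltage-gated ion channels. Characterizing them requires joining two very
different data streams: a venom-gland transcriptome assembly, which holds
full precursor sequences but no direct evidence the peptide is in the
venom, and mass spectrometry of the venom itself (intact MALDI-TOF masses
per chromatographic fraction, plus de novo sequenced tryptic MS/MS
fragments), which proves presence but yields only partial sequence.
knotminer implements the inference that connects them:

1. six-frame translation of assembled transcripts and ORF extraction;
2. precursor segmentation into signal peptide, propeptide and mature
   peptide;
3. cysteine-framework extraction, superfamily classification and domain
   signature matching;
4. theoretical mass computation under PTM sets, MALDI mass matching and
   amide/acid pair detection;
5. Smith-Waterman mapping of MS/MS fragments onto the translated
   transcripts, with region labels and mature-peptide coverage;
6. rational toxin naming and catalogue assembly.

A seeded synthetic-data generator with planted ground truth makes every
stage testable without any external download.

## Precursor model

A secreted toxin precursor is `signal + propeptide + mature`; segmentation
always preserves this concatenation exactly.

**Signal peptide.** In place of a learned model, the package uses an
explicit hydrophobicity heuristic. A protein has a signal only if some
7-residue window starting within residues 2-20 reaches a mean
Kyte-Doolittle hydropathy of `core_threshold` (default 1.6) -- the
h-region. Candidate cleavage sites are positions 10-35 (cleaving after
that residue) that satisfy the small-residue rule at -3 and -1 (A, G, S,
C, T), where any such site exists. Each candidate is scored as the mean
hydropathy of the 7 residues ending at its -2 position *minus* the mean
hydropathy of the 3 residues after the cut. The subtraction matters: a
true site sits at the h-region/c-region boundary, where hydrophobicity
drops into polar or charged sequence, and scoring only the upstream core
systematically picks compliant sites that are still inside the h-region.
Ties go to the earliest site.

```{r signal}
predictSignalCleavage("MKTLVLVAVLGLALAEDAESEEARIFECVFSCDIEK")
```

**Propeptide.** Spider-toxin propeptides typically end in a processing
quadruplet motif (PQM): arginine at -1 with a glutamate within positions
-2..-4. Cleavage is placed after such an R; among candidates, the last
one before the first cysteine is chosen, because the mature domain of a
DRP starts at or just before its first cysteine. With no admissible site
the whole post-signal sequence is the mature peptide. Mature peptides
shorter than 10 residues are flagged, never dropped.

**ORF selection.** A transcript's coding ORF is *not* reliably its
longest ORF: on a transcript of a few hundred nucleotides the probability
that some reverse-strand frame carries a long stop-free stretch is
substantial ((61/64)^k per k codons), and such junk ORFs regularly exceed
the true precursor in length. `segmentTranscripts()` therefore segments
every ORF of every transcript and keeps the candidate that looks most
like a secreted precursor: signal peptide present, then PQM cleavage
found, then highest mature cysteine count, then length. This is the same
reasoning toxin-annotation pipelines apply.

## Cysteine frameworks and superfamilies

The canonical framework records only the order and adjacency of
cysteines: consecutive cysteines collapse to a doublet token (`CC`;
triplets stay `CCC` and never match a doublet scheme), and every non-zero
spacer becomes `-`. Exact spacer lengths are deliberately excluded --
several 8-cysteine superfamilies in the shipped scheme differ *only* in
where the doublet sits. Classification is exact string match on this
canonical pattern; a mature length outside the superfamily's observed
range warns but never rejects, and unmatched patterns are `novel`.

The shipped scheme (`superfamilyDefinitions()`) has eight superfamilies
with 5-10 cysteines and mature lengths 43-88; disulfide connectivities
and free cysteines are stored as validated annotations
(`validateConnectivity()` checks admissibility), never predicted.

Domain signatures (WAP four-disulfide core, SVWC, astakine patterns and
the short astakine motifs) are written in the field's spacing notation
and parsed by a small grammar: literals, `X` wildcards, exact spacers
`X5`, spacer alternations `X6/8`, unbounded `Xn`, residue alternations
`(P/R/A)`. Matching expands the finite spacer choices into concrete
regular expressions and reports the leftmost-longest span; tests check it
against an independent backtracking matcher.

```{r sig}
matchSignature("GAARYSAPAC", "GX2RYSX(P/R/A)XC")
```

## Masses and modifications

Monoisotopic residue masses, water (18.010565), the proton (1.007276)
and the modification deltas (carbamidomethyl +57.02146, Met oxidation
+15.99491, C-terminal amide -0.98402, disulfide -2 x 1.0078250319 Da)
live in one constants table (`massConstants()`), so the calculator, the
MALDI simulator and the matchers cannot drift apart. "All cysteines
oxidized" means floor(n_cys/2) disulfide bonds; an odd count leaves a
flagged free cysteine. An average-mass mode exists, but monoisotopic is
the default. The test suite checks the calculator against an independent
elemental-composition oracle (atom counts times atomic masses) to 1e-4 Da
over 1000 random peptides.

MALDI matching uses a 0.5 Da default tolerance (MS1, linear/reflector
MALDI of intact peptides); amide/acid pair detection uses a 0.05 Da
tolerance on the pair delta. The amide form is 0.98402 Da lighter than
the acid, which operators read as "about 1 Da":

```{r amide}
as.data.frame(detectAmidationPairs(c(3810.60, 3809.61)))
```

## Fragment mapping

`localAlign()` is Smith-Waterman under BLOSUM62 with affine gaps
(open -10, extend -1 per gapped position; a length-1 gap costs 11). Two
conventions are specific to de novo MS data: I and L are isobaric and
therefore scored and counted as identical, and `X` (a residue called but
not identified) aligns to anything at score 0 and is excluded from the
identity denominator -- so a de novo read like `CVFSCDXEK` counts as a
full match to `CVFSCDIEK`. The instrument's own "score" column on
fragment tables is a different quantity and is not reproduced.
Mature-peptide coverage is the union of mature-region match spans (an
`IRanges` reduction) over the mature length, computed exactly and only
rounded for display. Alignment scores are verified against an
independently written Gotoh dynamic program on short sequences.

## Nomenclature

Names follow the rational convention
`<activity>-<family>-<species abbrev><paralog><isoform>[_<variant>]`,
e.g. `U29-theraphositoxin-Pv1b_1`. Activity prefixes: omega for CaV
modulators, mu/beta for NaV, kappa for KV, `U<n>` for unknown activity.
The catalogue allocates one U-number per superfamily group (smallest
unused integer), isoform letters across distinct mature sequences within
the group, and variant numbers across identical sequences; the published
U-number usage is not fully systematic, so allocation is configuration,
not inference. `parseToxinName()` inverts rendering exactly. The family
string is configurable because the literature alternates
"theraphotoxin"/"theraphositoxin"; the default is "theraphotoxin".

## The synthetic-data generator

`generateTranscriptome()` emulates the study inputs with planted truth:

- **Toxin genes** (default 26, superfamily mix proportional to the
  scheme's member counts 1,1,2,4,2,6,2,8): signal peptide (M + charged
  residue + 8-12 hydrophobic core residues + `AQA` c-region), acidic
  propeptide (Glu-rich body, no Arg or Cys, ending in `E-x-x-R`), and a
  mature domain realizing the superfamily's canonical pattern within its
  length range, with spare residues distributed randomly over prefix,
  inter-cysteine gaps and tail (no Arg before the first cysteine, so the
  planted PQM stays the last candidate). Proteins are encoded with
  random synonymous codons; the 5' UTR is kept ATG-free so the planted
  start is the first in-frame methionine.
- **Decoys** (10% of gene count): hydrophilic, cysteine-free ORFs of
  120-250 residues -- housekeeping-like transcripts that should never
  enter a DRP catalogue.
- **Abundances**: TPM from simulated log-normal counts,
  `1e6 * (c_i/l_i) / sum(c_j/l_j)`; toxin genes draw from a higher
  meanlog than decoys, as venom-gland toxin transcripts are strongly
  expressed.
- **MALDI lists**: each mature contributes its fully-oxidized acid mass
  to its fraction; an `amidation_fraction` (default 0.5) of genes also
  contribute the amide form; Gaussian noise (default 0.02 Da) on every
  observation.
- **MS/MS fragments**: tryptic digestion (cleave after K/R, not before
  P) with up to 2 missed cleavages, carbamidomethylated cysteines for
  m/z, flanking residues in dot notation, fragments under 5 residues
  dropped.

All randomness hangs off one integer seed. What the generator does *not*
emulate -- and hence what passing tests cannot show about real data:
sequencing/assembly error and chimeric contigs, non-tryptic and
semi-tryptic fragments, de novo sequencing errors beyond `X`, isotope
envelopes and intensity structure, shared peptides between paralogs, and
signal peptides that violate the simple h-region model. Recovery rates on
synthetic data are upper bounds for real data.

## Numerical and design choices

- Coordinates are 0-based half-open everywhere; frames are `+1..+3` on
  the forward strand and `-1..-3` on the reverse complement.
- Minimum ORF length defaults to 40 residues (shortest plausible
  precursor: short signal + no propeptide + ~30-residue mature);
  incomplete (no-stop) ORFs are kept and flagged.
- `min_cysteines` for catalogue entry defaults to 5, the scheme minimum
  (a DRP needs at least two bridges); this also keeps rare
  cysteine-bearing junk ORFs from decoy transcripts out.
- Logo information content uses a uniform background over 20 residues
  (no composition correction), in bits; gap characters are excluded from
  column frequencies.
- Ranked fragment hits break ties by database order, then target id.
- Degenerate inputs: cysteine-free sequences yield an empty framework;
  empty fragment files yield zero coverage; a mass list with no partner
  masses yields no amidation pairs; `N`-containing codons translate to
  `X`, which the mass calculator rejects (an unknown residue has no
  mass) but the aligner accepts.

## Problem sizes used by the test suite

The planted-truth end-to-end test uses 80 toxin genes with a uniform
superfamily mix and zero mass noise, and requires >= 95% exact mature
recovery, exact superfamily assignment for every correctly segmented
gene, and >= 99% amide/acid pair detection. Oracle-backed property tests
use 1000 random peptides (mass), several hundred random short pairs
(alignment, 4-letter alphabet, lengths 1-8), and 4 signature patterns x
50 random sequences. These sizes exercise every rule branch while
keeping the default `R CMD check`-style run to a few minutes.

## Known limitations

- The signal heuristic is a deliberately simple stand-in for a learned
  model; on real, divergent signal peptides it will under-call.
- Superfamily assignment is exact pattern match: a single extra or
  missing cysteine sends a sequence to `novel` rather than the nearest
  family.
- Disulfide connectivity is validated annotation only; the package never
  predicts bonding.
- The ortholog-completeness helper is plain arithmetic
  (`round(100 * complete / total, 1)`); it reports what the numbers give,
  which can disagree with a misrounded figure quoted elsewhere.
- MALDI matching is mass-list level; no peak processing, deisotoping or
  calibration.
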