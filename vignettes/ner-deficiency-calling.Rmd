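---
title: "Calling NER deficiency from somatic indel signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling NER deficiency from somatic indel signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nerdsig)
```

## The problem

Nucleotide excision repair (NER) removes bulky DNA adducts; tumors with an
inactivated NER pathway are selectively killed by drugs such as irofulven,
whose lesions can only be repaired by NER. No functional NER assay works on
clinical biopsies, but NER deficiency leaves a genomic scar: an excess of
the COSMIC small insertion/deletion signature ID8, dominated by deletions
longer than 5 bp with no or short (1--2 bp) flanking microhomology. Because
irofulven is a prodrug activated by prostaglandin reductase 1 (PTGR1), a
tumor is a plausible responder only if it shows both the ID8 scar and
sufficient PTGR1 expression.

`nerdsig` implements this two-gate biomarker as a reusable pipeline over
per-sample somatic VCFs (MuTect2 dialect), a reference FASTA, an ID
signature matrix, expression tables and an Intervar-style annotation table:

1. **filter** -- stringent somatic-variant and sample-level filtering;
2. **catalog** -- ID-83 indel catalog construction;
3. **refit** -- non-negative least-squares (NNLS) signature refitting;
4. **call** -- the ID8 threshold, the PTGR1 gate, ERCC-family enrichment,
   and cohort summaries;
5. **simulate** -- a synthetic-cohort generator with a complete
   ground-truth ledger, so every stage is testable without any download.

## Variant and sample filtering

Variant-level predicates (all comparisons inclusive, evaluated per ALT
allele after multi-allelic splitting): FILTER is exactly `PASS`,
TLOD $\ge$ 6, NLOD $\ge$ 3, normal depth $\ge$ 15, tumor depth $\ge$ 20,
tumor ALT reads $\ge$ 5, normal ALT reads $= 0$, tumor allele fraction
$\ge$ 0.05. The tumor allele fraction is the caller's FORMAT/AF value when
present, and ALT reads / depth otherwise. A record missing any tested field
is rejected with the distinct reason `"unevaluable"` rather than silently
dropped, so exclusion reports always reconcile.

Sample-level rules: whole-genome-amplified, FFPE and MSI-flagged samples
are excluded (the flags are consumed as metadata; MSI detection itself is
out of scope); one sample per patient is kept (lowest `preference_rank`,
ties broken lexicographically -- the tie-break is this package's own
convention, since only the WGA-removal rule is prescribed); samples with
fewer than 50 retained variants are dropped, because signature refitting is
unreliable below that burden. Whether the caller statistics should be
tested before or after multi-allelic splitting is not prescribed anywhere;
this package tests them per split record, which is the allele-level reading
of the predicates.

## The ID-83 catalog

Each indel is first reduced to a canonical event: shared suffix then prefix
bases (including the VCF anchor) are stripped; events that remain
multi-base on both alleles are *complex*, excluded and counted, never
force-classified; the pure insertion/deletion is then left-aligned by
repeated unit rotation. All VCF spellings of the same physical indel reach
the same `(start, seq, kind)` -- this canonicality is enforced by test,
with an independent whole-string edit-comparison oracle.

Classification then follows the COSMIC ID-83 conventions:

* **1 bp indels** go to homopolymer channels, the base expressed as its
  pyrimidine representative (A counted as T, G as C). The homopolymer
  length is counted rightward from the left-aligned locus: for deletions
  it includes the deleted base (bins 1..6+); for insertions it counts only
  pre-existing copies (bins 0..5+).
* **Longer indels** are scanned for exact tandem copies of the event
  sequence, contiguously rightward from the left-aligned start. Deletions
  with $\ge 2$ copies (including the deleted one) and all insertions go to
  repeat channels.
* **Deletions at a single copy** are checked for flanking microhomology:
  the longest $k < \mathrm{len}$ such that the first $k$ deleted bases
  equal the reference immediately after the segment, or symmetrically the
  last $k$ against the reference immediately before; the maximum of the
  two flanks is used (after left-alignment the left flank is provably 0,
  but both are evaluated so the definition is representation-free). A full
  copy is a repeat, never microhomology, hence the cap at
  $\mathrm{len}-1$. Single-copy deletions without homology land in the
  repeat channel with copy bin 1.

Sizes cap at 5+ and context counts at their top catalog bins. Channel
labels use the `size:kind:context:n` spelling with the zero-based COSMIC
trailing number; the underscored spellings of published signature files
(`DEL_repeats_2_1`, `INS_T_1_4`, ...) are accepted and normalized on
reading, which is where the off-by-one between display bins (homopolymer
1..6+) and zero-based labels is pinned down.

Reference access refuses contigs absent from the FASTA: silently skipping
a contig would corrupt catalogs. Users of real exome data must supply the
FASTA matching their alignments' genome build, since repeat context depends
on it.

## NNLS refitting and the ID8 exposure

With the 83-channel catalog $y$ and the signature matrix $S$ (83 x K,
columns summing to 1), exposures solve

$$\hat e = \arg\min_{e \ge 0} \lVert y - S e \rVert_2 ,$$

a convex problem solved to its global optimum by the Lawson--Hanson
active-set algorithm. Exposures are reported in attributed-mutation-count
units and deliberately *not* renormalized to the catalog total: plain NNLS
imposes no such constraint, and the downstream threshold is defined on the
raw ID8 component. No sparsity penalties or bootstrap layers are added.
If signature columns are collinear the solver's solution is accepted with
a degeneracy warning. The test suite checks every fit against an
independent projected-gradient solver to $10^{-6}$ and verifies exact
recovery of noise-free mixtures, scale equivariance to $10^{-9}$ relative,
and local optimality under $\pm 10^{-3}$ exposure perturbations.

The published COSMIC ID signature matrix is not redistributable, so the
package ships `synthetic_id_signatures()`, a synthetic stand-in whose ID8
column concentrates its mass on long deletions with no or 1--2 bp
microhomology (the signature's defining feature) and whose other columns
model homopolymer-indel and diffuse-background processes; a 3-signature
toy file (labelled synthetic) ships under `inst/extdata/`.
`read_signature_matrix()` accepts the published file for real use, and
`nnls_refit(..., subset = )` restricts the refit to a named signature
subset, since nothing prescribes whether the full set or a subset was
used.

## Decision rules

* NER deficiency: ID8 exposure strictly greater than 5 (`id8 > 5`);
  the value is thresholded unrounded.
* Responder candidacy: NER-deficient *and* PTGR1 expression at or above
  the cutoff (inclusive), where the cutoff is the expression of a
  reference cell line (default A498) in a cell-line table sharing the
  cohort's normalization. Expression is log2-transformed with a
  pseudo-count (default 1). The pipeline refuses tables whose declared
  units differ, because harmonizing FPKM against TPM silently would move
  the gate.
* ERCC-family enrichment: a Fisher exact test (two-sided by default;
  sidedness is configurable since it is not prescribed) on the 2x2 table
  of any-deleterious-ERCC-mutation by above/below the ID8 cutoff, where a
  deleterious mutation is an exonic SNV or indel labelled
  Pathogenic/Likely Pathogenic, or any nonsense SNV. Degenerate margins
  give $p = 1$ with an undefined odds ratio. The implementation is checked
  against a full hypergeometric enumeration (log-choose densities, the
  conventional $1 + 10^{-7}$ tie tolerance) over every 2x2 table with
  $N \le 60$.
* Summaries report fractions at 0.1% precision. Because a
  mutation-quality-controlled cohort can be a subset of the expression
  cohort, both the QC denominator and an optional full denominator are
  reported rather than guessing which one a given figure should use.

## The synthetic-data generator

`generate_reference()` builds contigs ($\ge$ 10 kb, roughly uniform base
composition) from engineered locus blocks -- homopolymers to length 8,
tandem repeats of unit sizes 2--7, microhomology-flanked unique segments --
each insulated by guard bases so neighboring sequence cannot extend a
context. The registry of planted loci (26 per channel, of which 6 are
reserved) makes `realize_variant()` an exact inverse of the classifier:
round-tripping all 83 channels is a tested invariant, not a hope.

`simulate_cohort()` draws per-sample burdens from a Poisson law (default
mean 150 indels -- a free parameter chosen as a plausible post-filter
exome indel burden, documented here because no cohort value is printed
anywhere), channels multinomially from each sample's signature mixture
(default NERD group: ID8 weight 0.30; background: 0.01), plants an exact
count (`round(fraction * N)`, not a sample) of filter-failing records each
violating exactly one named predicate, plants deleterious ERCC annotations
at group rates (0.25 NERD / 0.02 background) on reserved loci so that
annotation keys stay globally unique, and draws PTGR1 directly in
log2(FPKM+1) units (avoiding a transcript-length model) from
high/low-mean Gaussians (6.5/3.5, sd 0.5) straddling a planted cell-line
cutoff at their midpoint. Random streams are split per purpose (sequence,
sampling frame, channels, caller statistics, expression, annotations) so
changing one knob leaves the other draws intact; everything is
reproducible from the master seed, down to byte-identical VCFs.

What the simulation does *not* emulate -- and therefore what passing tests
do not show about real data: real exome repeat-context composition and
capture bias, sequencing artifacts correlated across predicates (planted
failures violate exactly one), subclonality-driven allele-fraction
structure, copy-number-linked expression, and the published signatures
themselves (synthetic columns are sharper than COSMIC's, so real-data
exposures will carry more refit noise than the recovery tests display).

## Numerical choices and test scales

Signature columns must sum to 1 within $10^{-6}$; exposure/oracle
agreement is asserted at $10^{-6}$, scale equivariance at $10^{-9}$
relative, Fisher agreement at $10^{-10}$. Degenerate inputs are defined,
not errors: an all-zero catalog refits to all-zero exposures with zero
residual, an empty margin gives $p = 1$, and an empty cohort summary is an
error. The test suite runs at deliberately modest scales -- 50 seeded
realizations per channel for the classifier round-trip, 500 shifted
spellings for canonicality, 100 random catalogs for the NNLS oracle, 200
samples at burden 200 (ID8 share 0.4) for Poisson recovery, and 20 seeds
of 40-sample cohorts for the end-to-end check, which recovers the planted
NERD set with balanced accuracy $\ge$ 0.9 (in calibration runs it is
typically 1.0, with ID8 estimates within $3\sqrt{80}$ of the planted 80 in
$\ge$ 98% of samples). A fixed engineered reference is reused across
seeds; cohort draws vary.

## A worked run

```{r example}
sim <- simulate_cohort(simulation_config(seed = 11, n_samples = 40))
res <- ner_call_cohort(sim$variants, sim$meta, sim$genome, sim$signatures,
                       sim$expression, sim$cellline_expr,
                       annotations = sim$annotations)
res
table(planted = sim$samples$group[match(res$calls$sample_id,
                                        sim$samples$sample_id)],
      called_nerd = res$calls$nerd)
```

## Known limitations

The classifier targets pure small indels; complex substitutions are
excluded by design and reported, so cohorts rich in complex events will
have smaller catalogs than their VCF line counts suggest. The PTGR1 gate
presumes the cohort and cell-line tables share one normalization and
refuses anything else; it does not attempt cross-platform harmonization.
Exposure uncertainty is not quantified (no bootstrap); the ID8 > 5 rule is
a point threshold, and values near it should be treated with the caution
any hard biomarker cutoff deserves.
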