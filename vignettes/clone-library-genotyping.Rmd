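---
title: "Genotyping a duplicated MHC locus from clone libraries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping a duplicated MHC locus from clone libraries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcclone)
```

## The problem

MHC class II β exon 2 encodes most of the peptide-binding groove and is,
in passerines, carried by several duplicated loci that cross-amplify with
a single primer pair. A PCR from one bird therefore contains a mixture of
alleles from every copy, and plasmid cloning — sequencing one molecule
per colony — adds two artefact classes on top: polymerase point errors
and chimeras formed by template switching between alleles during PCR.
Neither artefact class recurs identically across independent
amplifications, which is the lever the whole validation strategy rests
on.

This vignette records how each analysis step is defined, which parameters
matter, and which design choices were genuinely open.

## Allele validation

Clones are collapsed by exact string identity (uppercased). Cloned
molecules are single templates, so ambiguity codes have no place in a
finished read; records with characters outside `A,C,G,T,N` are rejected
by name rather than silently merged.

**Acceptance rule.** A candidate is accepted iff observed in at least two
individuals (`min_individuals = 2`). Clone replication within one
individual never counts: a point error or chimera arises in one
amplification and can be re-sequenced from sister colonies, but the
probability that the *identical* artefact arises independently in a
second individual is negligible at realistic error rates. The rule is
monotone — new observations can only promote a sequence.

**Rescue screen.** Exclusion discards many true-but-rare sequences, so
excluded singletons are screened for divergence: a sequence whose minimum
distance to *every* accepted allele is strictly greater than 1.5 %
(about 3 bp on 159 bp) is too far to be a point-error or single-chimera
derivative of any accepted allele, and is flagged for inspection. Flagged
sequences are reported, never auto-accepted — the conservative choice,
since their single-individual support is still weak. Distance is the
proportion of mismatching sites: Hamming/length for equal lengths; for
lengths differing by a multiple of 3 the gap block is slid over every
codon boundary, a gapped codon counts as 3 differences, and the minimum
over placements is used (the threshold's "~3 bp on 159 bp" phrasing
implies a plain per-site proportion, which this generalises to in-frame
indels). Non-multiple-of-3 mismatches are frameshift-like and compared by
end-padding; they are pseudogene material either way.

**Functionality.** An allele is pseudogene-like iff its fixed-frame
translation contains a stop codon or its length differs from the
reference amplicon (159 bp by default) by a non-multiple of 3. The
reading frame is a property of the primer design, not of the data, so it
is a parameter (`frame = 0` by default). An in-frame two-codon insert
(165 bp) stays functional.

**Naming.** Accepted alleles are ranked by total clone count (ties broken
by lexicographic sequence order, for determinism) and named
`prefix + zero-padded rank`.

## Diversity and neutrality statistics

π is the mean over unordered sequence pairs of the proportion of
differing sites, with non-`ACGT` positions excluded pairwise. Tajima's
*D* uses the 1989 constants and contrasts mean pairwise differences with
Watterson's estimator from the number of segregating sites; its p-value
uses the bounded beta approximation to the null density. `S = 0` yields
an explicitly undefined statistic, never 0.

Fu & Li's starred statistics use the total mutation count η (alleles − 1
summed over sites) and the singleton count η<sub>s</sub> (bases carried
by exactly one sequence), with the corrected weight formulas of Simonsen,
Churchill & Aquadro (1995); the constants are spelled out in
`fu_li_star_constants()`. Significance is estimated by neutral coalescent
simulation conditional on the observed number of segregating sites
(mutations placed multinomially by branch length on simulated
genealogies) rather than from the 1993 critical-value tables: the
empirical null adapts to the exact (n, S) of the data set and one
machinery serves both the tests and their calibration suite. The
package's coalescent simulator (`sim_coalescent_alignment()`) is the
standard constant-size Hudson construction and is itself exercised by the
test suite: on neutral data the mean of *D* must sit near 0 and the
nominal 5 % test must reject at roughly 5 %.

## dN/dS with site partitions

The Nei–Gojobori (1986) method counts *potential* sites per codon as the
fraction of single-base changes that are synonymous (a change creating a
stop codon counts as nonsynonymous — it changes the protein), averaged
over the two sequences of each pair, and *observed* differences by
averaging over all minimal mutational pathways between the two codons
with equal weights. Pathways passing through a stop codon are excluded
from the average — the standard convention, since such intermediates are
strongly selected against; in the degenerate case where every pathway
does, all pathways are kept rather than dropping the codon. Codons
containing gaps, ambiguous bases, or an endpoint stop are excluded
pairwise. Proportions p<sub>S</sub> = S<sub>d</sub>/S and
p<sub>N</sub> = N<sub>d</sub>/N are Jukes–Cantor corrected
(d = −¾ ln(1 − 4p/3), undefined at p ≥ ¾ and reported as such), and the
group estimate is the mean over all sequence pairs.

Standard errors come from resampling codon columns with replacement
(default 1000 replicates, seeded); the resampling unit is the codon, the
unit at which synonymous/nonsynonymous structure lives. The z-test is
z = (d<sub>N</sub> − d<sub>S</sub>)/√(var d<sub>N</sub> + var
d<sub>S</sub>) against the normal; two-tailed by default, with a
one-tailed (positive-selection) variant exposed because the tail
convention in comparable studies is rarely printed.

PBR/non-PBR partitions come from a `site_mask`: a set of 1-based codon
indices. The structural PBR maps in use derive from human HLA-DRB
crystallography and must be lifted onto each study's amplicon coordinates
by the user; the package ships two *synthetic* illustrative masks
(`pbr_brown_synthetic.tsv`, `pbr_tong_synthetic.tsv`) whose coordinates
are placeholders, not the published human maps. Site counts are additive
across the partition by construction (S<sub>PBR</sub> +
S<sub>non-PBR</sub> = S<sub>all</sub>).

Pseudogene-like alleles are excluded from diversity and selection
statistics by the caller's filtering (the validation report carries the
flag); both inclusive and exclusive sets remain expressible.

## Locus number and rarefaction

With every locus heterozygous, an individual carries at most two distinct
alleles per locus, so the minimum locus number is ⌈max per-individual
count / 2⌉ over putatively functional alleles. Rarefaction resamples the
*clone records* of one individual without replacement at increasing
subset sizes (default {5, 10, 15, 20, 25}, 100 replicates) and counts
distinct validated alleles; clones, not distinct alleles, are the
sampling unit because saturation is a property of the sequencing process.
The expected curve is hypergeometric, which the tests exploit as an
oracle. "Plateau" is operationalised as a mean gain of fewer than
`epsilon = 0.25` alleles between the last two subset sizes (strict
inequality); a slope-normalised variant is available via
`method = "slope"` since the criterion used in comparable studies is
typically unstated.

## Allele sharing

Sharing is presence/absence at the population level: an incidence entry
is 1 iff the allele was seen in at least one individual of the
population, and shared counts are intersections of incidence rows —
unweighted by frequency, matching how such counts are reported.
Pseudogene alleles are included: a shared pseudogene is evidence of
shared ancestry just as a functional allele is. No test against a drift
expectation is attempted.

## Neighbour joining and bootstrap consensus

Distances are p-distances by default (uniform rates, homogeneous
substitution pattern — appropriate at the low divergences of allelic
data), with Jukes–Cantor available; gapped positions are excluded
pairwise and a JC distance at p ≥ ¾ is an error naming the pair. The NJ
implementation is the plain Saitou–Nei agglomeration on the Q criterion
with the standard branch-length and distance-update formulas, exact on
additive matrices (property-tested against randomly generated trees, and
cross-checked against an independent implementation). Ties in Q are
broken by the lexicographically smallest pair of cluster labels so that
results are reproducible; negative branch-length estimates are clamped to
zero with a message. Bootstrap resamples alignment columns, rebuilds the
tree per replicate, tallies bipartitions (each canonicalised by the side
not containing the alphabetically first taxon), and keeps those at
frequency ≥ 75 % by default; replicates with undefined distances are
dropped, and more than 10 % drops abort the run. Trees are unrooted;
rooting is presentation, not inference, at this scale.

## The simulator: what it emulates and what it does not

`sim_config()` encodes the study design the analysis assumes: a 53-codon
(159-bp) amplicon; 4 functional loci with 6 alleles each plus 2
pseudogene-like alleles at a separate pseudogene locus (every individual
carries two pseudogene slots, mirroring a fixed duplicated copy); one
allele carrying an in-frame two-codon insert; 3 populations of 10, 4 and
2 individuals; 12–29 clones per individual; and a sharing fraction of
0.65, matching the observed pattern that roughly two-thirds of alleles
recur across populations.

The allele pool is generated by fixed-count substitution from a shared
root: locus ancestors at 12 substitutions from the root and alleles at 4
from their ancestor, with draws creating in-frame stops resampled. A full
coalescent would add nothing the downstream statistics need; what matters
is a realistic distance structure, and these defaults put the pool's
nucleotide diversity near 0.15, the order observed for passerine MHC
allele sets (π ≈ 0.1). Artefact rates default to a per-base PCR error of
5 × 10⁻⁴ and a per-clone chimera probability of 0.05 — plausible for
multi-template Taq amplification; the real per-clone artefact rates of
any given study are unknowable from its accepted-allele counts alone, so
these are free parameters, not calibrated quantities. Chimeras have
exactly one breakpoint, uniform over interior codon boundaries (the
canonical single-template-switch model, frame-preserving by
construction); PCR errors are substitutions only, since indel artefacts
are rare for non-homopolymer templates and would anyway be caught by the
frameshift flag. One master seed drives everything, with per-individual
sub-streams derived deterministically so that outputs are byte-identical
across runs.

What the simulator does *not* model: sequencing quality (reads are
error-free beyond the PCR model), gene conversion tracts (only
single-breakpoint chimeras), allele frequency spectra within populations
(genotype slots draw uniformly from the available alleles), and
recombination in the genealogy. Passing parameter-recovery tests on this
generator therefore shows that the validation logic is correct under its
stated assumptions — not that those assumptions exhaust real clone
libraries.

## Problem sizes in the test and acceptance suites

The test suite runs the NG86 pathway oracle on 1,000 random 5-codon
pairs, Tajima calibration on 200 neutral coalescent replicates (n = 15,
θ = 5), validation recovery on 20 simulator replicates at the default
study design, NJ exactness on 200 random additive matrices of 4–8 taxa,
and rarefaction against hypergeometric expectations at 2,000–3,000
replicates; bootstrap-heavy examples use 100–1,000 replicates. These
sizes put Monte-Carlo error well below the tested tolerances while
keeping the whole suite around a minute.

## Known limitations

* Exact-identity collapse means a true allele observed only through
  errored clones is invisible; at 5 × 10⁻⁴ per base most clones are
  faithful, but deeper error rates would need quality-aware denoising,
  which is out of scope.
* The rescue screen reports candidates; promoting them is a judgement
  call left to the analyst.
* Significance classes for Fu & Li's tests are simulation-based and
  therefore seed-dependent in the last digit; the statistics themselves
  are exact.
* The NG86 implementation targets alignments of tens of sequences and
  tens of codons; it is quadratic in sequences and would need
  vectorisation for thousands of taxa.
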