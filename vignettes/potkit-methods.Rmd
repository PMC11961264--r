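---
title: "potkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{potkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potkit)
```

## What the package models

PCR-only tagging (pPOT) modifies a trypanosomatid gene in a single step: a
long primer pair amplifies a tag + drug-resistance cassette from a template
plasmid, and the amplicon integrates into the genome by homologous
recombination of the primers' 5' overhangs. Each primer is the concatenation
of a gene-specific *homology arm* (genomic sequence flanking the insertion
point) and a *universal annealing sequence* shared by every plasmid of the
series and embedded in glycine--serine linker coding sequence, so the same
cheap primer pair works with any tag of the series. potkit implements the
computational side of this workflow: primer design for four tagging
geometries, an in-silico round trip that proves each design yields an
in-frame fusion, codon-frequency recoding used when tag genes are
synthesized, tag molecular weight and isoelectric point, and the photometry
used to rank fluorescent proteins by brightness and photostability.

## Primer geometry and the round-trip oracle

The four design modes share one arithmetic core (all coordinates 0-based
half-open; GFF3 input is converted at the parser boundary):

* **C-terminal** (`design_c_tag`): forward arm = last `arm_len` nt of the CDS
  excluding the stop codon; reverse arm = reverse complement of the first
  `arm_len` nt of downstream flank. Integration replaces exactly the stop
  codon, fusing the tag to the full-length protein.
* **N-terminal** (`design_n_tag`): forward arm = last `arm_len` nt of
  upstream flank; reverse arm anneals to the CDS starting after the ATG. By
  default the target ATG is excluded (`include_start_codon = FALSE`) because
  the cassette's tag ORF supplies initiation; the flag preserves the
  alternative convention, and the in-silico frame check validates either.
* **SP replacement** (`design_sp_replacement`): like N-tagging but codons
  1..`sp_end_aa` (the predicted signal peptide) are removed so the cassette
  can supply a donor signal peptide fused to the tag.
* **CTD replacement** (`design_ctd_replacement`): like C-tagging but codons
  `ctd_start_aa`..stop (the predicted GPI-anchor addition/cleavage domain)
  are removed so the cassette supplies the tag fused to a donor CTD.

Signal-peptide and GPI omega-site positions are *inputs* (one TSV row per
gene), normally derived from Signal-P and NetGPI predictions; potkit does not
re-implement those predictors.

Because no published amplicon or junction sequence accompanies the tagging
scheme itself, the package treats the *round trip* as the specification:
every design must survive `simulate_pcr()` (exact, unique annealing-site
match; circular templates searched across the origin by doubling),
`integrate_amplicon()` (exact, unique arm matches; the segment strictly
between the arms is replaced) and `verify_fusion()` (ORF scan from the
retained target ATG, or from a cassette ATG for N-type modes, requiring the
retained target residues and the expected tag peptide contiguously in order,
with no premature stop). Integration is deliberately exact-match: the
underlying mechanism is homologous recombination of perfect overhangs, and a
mismatch tolerance would mask design bugs. Mis-integration into an already
tagged locus surfaces as the multiple-match error rather than as a
stochastic event.

Property tests run this round trip over hundreds of random loci (CDS length
60--3000 nt, random flanks) for all four modes and require a 100% in-frame
rate; the acceptance script repeats it at 200 loci x 4 modes.

The homology-arm length is not dictated by the biology beyond practical
bounds; the default is 80 nt, the established long-primer convention for
this system, and values outside roughly 20--120 nt are accepted but
unrealistic (short arms recombine poorly; longer primers synthesize poorly).
Arm uniqueness is checked within the supplied locus and its flanks only;
genome-wide off-target checking is out of scope and flagged as a warning
hook. Primer thermodynamics are deliberately not scored: arms are
fixed-length by construction in this scheme. Multi-exon CDS features are
rejected with a clear error -- trypanosomatid genes are overwhelmingly
single-exon, and this keeps arm extraction well defined. How batch designs
for whole genomes should treat flanks that overlap a neighbouring gene is
genuinely open; potkit uses fixed-length flanks and reports overlap/
uniqueness problems as row flags rather than resolving them.

## The bundled plasmid map

The universal annealing sequences of the distributed plasmid series live in
their GenBank maps, which are not bundled here. The package instead ships
`pPOT_synthetic.gb`, a fully synthetic circular map with the same *layout*
(N- and C-type annealing sites embedded in GS-linker coding sequence, in
frame with short synthetic tag ORFs and a synthetic resistance cassette),
generated by `scripts/make_plasmid_fixture.R`. Default annealing sequences
are extracted from this map at run time by feature label; users tagging with
real plasmids should point `tagging_config()`/`--plasmid` at the authentic
GenBank file, and everything downstream is unchanged. The stand-in is
clearly labelled synthetic in its file and never presented as a published
sequence.

## Codon recoding

`build_usage_table()` counts all in-frame codons of a CDS corpus and
normalizes within each amino acid (stop codons form their own class), giving
the relative synonymous codon frequencies f(c). `recode()` back-translates a
protein either with the per-residue argmax codon (ties broken alphabetically
-- the corpus does not dictate a rule and determinism is required) or by
sampling codon c with probability f(c) under a caller-supplied seed. Both
satisfy translate(recode(p)) = p by construction, which the tests fuzz over
hundreds of random proteins. Whether the original tag-synthesis scripts used
argmax or stochastic sampling is not documented, so both are provided.
Restriction-site avoidance (`avoid_motifs`) checks both strands -- the
plasmid series is organized around unique restriction sites -- and proceeds
greedily left to right with per-codon substitution and shallow backtracking;
an unsatisfiable window (e.g. forbidding `TT` in a phenylalanine run, since
every F codon starts TT) raises a constraint error naming the stuck
position. An appended stop uses the corpus's most frequent stop codon unless
overridden.

## Molecular weight and isoelectric point

`molecular_weight()` sums average residue masses plus one water (18.0153
Da); monoisotopic masses are switchable. `net_charge()` is the
Henderson--Hasselbalch sum over ionizable groups (N-terminus, H, K, R
positive; C-terminus, D, E, C, Y negative), strictly decreasing in pH, and
`isoelectric_point()` bisects its unique root in (0, 14) to an interval far
below the reported precision. The default pKa set is the
ExPASy/Bjellqvist-style table; an EMBOSS-style set ships as an alternative
and individual values are overridable, because published pI values for the
same peptide differ by a few tenths of a pH unit depending on the constants
used. Tests validate the bisection against an independent 10^-4-step
grid-search oracle over 1000 random peptides and against the two-group
closed form (pKa1 + pKa2)/2. pI is a composition-only property (permutation
invariant); a tandem duplication shifts pI toward the side-chain-dominated
limit because the termini's relative weight halves -- both are asserted as
properties. For dimeric proteins the monomer and dimer pI differ only
through this terminus effect, so reported per-protein values are computed on
the monomer sequence.

The bundled `tags_synthetic.fasta` peptides are canonical HA-epitope tandem
repeats standing in for the distributed triple- and deca-HA tag modules,
whose exact linker and scar composition is not public. Under the default
constants the stand-ins give pI 3.17 (triple) and 2.71 (deca): the ordering
(deca more acidic than triple, both far below a near-neutral target protein)
reproduces the qualitative argument for matching tag charge to target
charge, but the absolute values depend on the unknown full module sequences
and on the pKa set, so they are reported as synthetic stand-in values, not
as reproductions of the distributed modules' numbers.

## Spot photometry

Brightness follows the median-local-background recipe: the measured signal
is the pixel sum of a small square centred on the spot minus the median of a
larger concentric square times the inner area. The outer median includes the
inner pixels ("centred on", not an annulus); with the default 5/15 px
squares the spot occupies well under half the outer square, so the median is
a robust background estimate. "Signal intensity" is read as the ROI *sum* --
this makes comparison against the ground-truth integrated flux well defined
-- with a mean-based switch provided. ROI sides and the detection threshold
are configuration, not published values, and all outputs echo the
configuration used. Background subtraction is exactly invariant (to
floating-point reassociation) under any constant image offset, and linear in
spot amplitude on constant background; both are tested.

`find_maxima()` implements prominence-based peak detection as a persistence
sweep: pixels are processed in decreasing intensity with union-find merging
of 8-connected components, and a component dying at level v with peak h is a
maximum iff h - v exceeds the noise tolerance. This matches the behaviour of
prominence-style maxima finders in common image software, handles plateaus
(single row-major representative) and returns nothing on a flat image.
Automatic frame-to-frame re-centring (brightest pixel within a 2 px radius)
substitutes for manual curation of drifting spots; seeds always come from
the first frame, where brightness is defined.

`half_life()` uses the stated interpolation rule: with B0 the brightness at
the first time point, find the first adjacent sample pair bracketing B0/2
and interpolate linearly; the worked sequence [100, 80, 60, 40] at t = 1..4
s crosses at exactly 3.5 s. Both the absolute crossing time and the elapsed
time since the first exposure are returned, since either convention may be
wanted; series that never reach half are censored at the last observed time.
When noise creates several crossings, the first in time is used.

## The synthetic image generator

`render_field()` draws isotropic Gaussian spots (analytic flux 2*pi*A*sigma^2,
conserved to <0.5% after discretization for sigma >= 1 px) on a constant
background, with optional Gaussian or Poisson noise applied last under an
integer seed (R's default generator; identical seeds give bit-identical
frames). A Gaussian PSF is sufficient for validating photometry contracts;
no claim of optical realism (Airy rings, camera-specific noise, cellular
autofluorescence) is made, so passing tests demonstrate correctness of the
measurement arithmetic, not performance on real micrographs.
`render_bleach_series()` scales each spot by 2^-(t - t1)/tau per frame,
emulating a 30 x 1 s photobleaching acquisition.

The validation conditions are fixed once in `standard_field()`: 256 x 256
px, 100 spots (sigma 1.5 px) on a jittered grid, amplitudes log-spaced
100--2000 ADU, background 100 ADU, Gaussian noise sd 10 ADU. That puts
per-spot SNR between 10 and 200 -- typical of the well-visible puncta this
assay is used on and comfortably above the SNR 5 floor the detection
contract assumes. At these conditions detection recall is 100% and the
median relative brightness error ~2%. Half-life validation uses noiseless
sampled exponentials with tau in {3, 5, 10} s over 30 x 1 s frames
(recovered exactly, since each B0/2 falls on a sample) and 100 spots with
Gaussian noise of 2% of amplitude (median absolute error well under 0.5 s).
Problem sizes (200 loci, 1000 oracle peptides, 100-spot fields) were chosen
as the smallest that exercise the contracts convincingly.

## Command line

`potkit_main()` exposes the subcommands `design`, `simulate-tagging`,
`codon-table`, `recode`, `props`, `spots`, `bleach` and `synth`; a thin
wrapper script is installed at `inst/cli/potkit`. YAML configuration merges
under explicit flags (flags win), every output is accompanied by a JSON run
record (version, seed, configuration hash) for exact replay, and exit codes
distinguish usage errors (2), data errors (3) and design/verification
failures (4).

## Known limitations

* Arm uniqueness is local to the locus; no genome-wide off-target search.
* Exact-match integration cannot model partially homologous or mutated arms.
* Diploidy is implicit: one allele is modified, the untagged allele is not
  simulated.
* The GenBank reader is read-only and minimal (simple and complement
  locations, `/label` qualifiers); compound `join(...)` locations are
  rejected.
* Image analysis assumes small, approximately isotropic puncta; it is not a
  segmentation or kymograph tool.
* The bundled plasmid map and tag peptides are synthetic stand-ins; results
  derived from them characterize the algorithms, not the distributed
  reagents.
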