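---
title: "Detecting TPP riboswitches and classifying their regulatory mechanism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting TPP riboswitches and classifying their regulatory mechanism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboreg)
```

## The problem

Thiamin-pyrophosphate (TPP) riboswitches are the only riboswitch class known
to operate in eukaryotes. In fungi and oomycetes they sit in the
untranslated and intronic regions of thiamin biosynthesis genes (THI4,
NMT1), of various transporter genes, and occasionally in 3'UTRs, and they
regulate expression mostly through alternative splicing. Where a riboswitch
sits relative to the gene model, together with a handful of local sequence
features — alternative donor (GU) and acceptor (AG) splice sites, a short
upstream open reading frame (uORF), an in-frame stop codon, the length of
the riboswitch-carrying intron and a distal complementary "α" element —
determines which of four location-defined mechanisms is plausible:

* **Type I** — the aptamer lies in an intron of the 5'UTR that also carries
  a short uORF flanked by two alternative donors S1 (5' of the uORF) and S2
  (between uORF and aptamer), with the acceptor AG at the intron 3' end.
  TPP binding switches splicing from the long (uORF-removing) to the short
  intron, leaving the inhibitory uORF on the message.
* **Type II** — the aptamer lies in a long internal intron (650–900 nt) of
  urea-transporter-like genes. A 9-mer element α, with central consensus
  5'-RGCGGYRRY-3', sits several hundred nucleotides (~500) 5' of the
  aptamer and is complementary to the α' segment at the aptamer 3' end (the
  P1-stem-proximal window). Long-range α/α' pairing in the TPP-free state
  selects the distal donor; TPP binding sequesters α' and shifts splicing
  to proximal donors.
* **Type III** — the aptamer lies in a short internal intron (200–400 nt)
  with two alternative donors, a stop codon between them *in the reading
  frame of the upstream CDS*, and the acceptor AG downstream of the
  aptamer. Retention of the 5' part of the intron truncates the protein.
* **Type IV** — the aptamer lies in the 5'UTR of a single-exon gene whose
  UTR contains no donor or acceptor dinucleotides at all, so regulation
  cannot be splicing-based (the actual mechanism — e.g. translation
  inhibition versus premature termination — is unresolved; the classifier
  labels location only).

`riboreg` implements this inference chain end to end: a position-specific
log-odds profile scanner finds candidate aptamers, conserved motifs are
annotated, hits are mapped onto gene models, and each located hit is pushed
through the four rules. Two tabular decision rules from the same workflow —
transporter annotation from homology/domain/transmembrane evidence, and
single-copy phylogenetic marker selection — are included as pure table
filters. A synthetic-genome generator plants each architecture with ground
truth so the whole chain is testable without any external download.

## The profile scanner

No pretrained riboswitch profile HMM or covariance model is redistributed
here. Instead, `build_profile()` reconstructs the method class from a seed
alignment: per match column $c$ and base $b$,

$$ s_c(b) = \log_2 \frac{(n_{c,b} + \kappa)/(n_c + 4\kappa)}{0.25}, $$

with pseudocount $\kappa$ (default 1) against a uniform background.
Columns that are more than 50% gap are dropped. Uniform background makes
the calibration testable: a column with uniform counts scores exactly zero.
`scan_genome()` runs Smith–Waterman-style local alignment of the profile
against both strands with affine gaps (defaults: open −4, extend −1 bits),
reports maximal-scoring non-overlapping segments above a threshold, and
resolves cross-strand overlaps to the higher score (ties: leftmost, then
plus strand). `N` bases score zero (background) and fail every literal
motif match — conservative on ambiguity.

The reporting threshold is a knob, not a constant: no bit cutoff survives
from the original pretrained model, so the default is 60% of the profile
self-score (the score of the per-column consensus). With the bundled
generator (2% per-base mutation, ~163-bit self-score) planted aptamers
score ≥ ~150 bits while column-shuffled decoys and random sequence stay
below ~40 bits, so the default separates them by a wide margin; the tests
verify recall 1.0 with zero decoy overlap rather than assuming it.

Scanner correctness is anchored by an independent oracle: for small
profiles and sequences, every local alignment is an increasing sequence of
matched (base, column) pairs whose gaps cost `open + (len−1)·extend` per
side, so the optimum can be enumerated in closed form and compared to the
dynamic program to 1e−9.

## Motif annotation

Four conserved features of the TPP aptamer are annotated on the hit
sequence in the DNA alphabet (the genome is DNA; RNA motifs are stored with
U→T): the 5'-most `GAGAT` (pyrimidine-ring recognition), the first `GCG`
downstream of it (junction J4/5, pyrophosphate contact), the first `TAAT`
downstream of the GCG (loop L5), and a non-canonical G–G pair with a
conserved separation. "Separation corresponds to 18 bases" is ambiguous
between inclusive and intervening counts; it is implemented as *intervening
bases = 18*, configurable via `motif_config(gg_separation=)`, and the two
G's must be proximal to the GAGAT and GCG motifs respectively (window
controlled by `gg_flank`, default 2 nt). Each motif's `satisfied` flag is
independent and absence is never an error. Secondary structure (P2/P3
stems, energy minimisation) is deliberately out of scope.

## Context mapping and classification

Gene models are one-per-transcript (multi-isoform genes yield independent
models; the output is flagged per transcript — the source reasoning is per
depicted transcript, and no collapsing rule is stated anywhere). Introns
are derived as exon gaps and labelled `FIVE_UTR_INTRON` /
`INTERNAL_INTRON` / `THREE_UTR_INTRON` by their position relative to the
CDS in transcript orientation. All splice/ORF logic runs on the
transcript-sense sequence, so minus-strand genes share one code path.
`locate_hit()` assigns exactly one context class; boundary-straddling hits
are reported `AMBIGUOUS` rather than forced into a class, and hits in
coding exon sequence likewise (no rule is invented where the source
describes none). When several genes overlap a hit, the gene whose CDS
start is nearest downstream wins (a riboswitch is assumed to regulate its
downstream gene); ties break on gene id.

`classify_hit()` applies the rules in the fixed order II → III → I → IV and
the first full evidence set wins; everything else is `UNCLASSIFIED` with a
trace naming every failed condition of every rule. Type II carries the most
specific evidence (α complementarity), Type III the next; contexts make I
and IV disjoint from the internal-intron types in practice, but the fixed
order guarantees exclusivity by construction. Parameters, all exposed in
`classifier_params()`:

| parameter | default | meaning |
|---|---|---|
| `len2_lo`, `len2_hi` | 650, 900 nt | Type II intron window (closed) |
| `len3_lo`, `len3_hi` | 200, 400 nt | Type III intron window (closed) |
| `max_separation` | 700 nt | α-to-aptamer limit, covering the observed ~500 |
| `min_complementarity` | 6 / 9 | α/α' Watson–Crick pairs required |
| `min_uorf_codons`, `max_uorf_codons` | 10, 100 | "short uORF" bounds |
| `alpha_between_donors` | `FALSE` | optional strict α ∈ (S1, S2) placement |
| `utr_exclusion_pad` | 10 nt | Type IV hit-interval exclusion margin |

Choices worth flagging:

* The intron windows and separation are *observed ranges*, so they are
  closed-interval parameters, never hard-coded; an internal intron of, say,
  500 nt with otherwise perfect Type III evidence is `UNCLASSIFIED` and the
  trace cites both windows.
* α complementarity is required but never quantified in the source;
  6/9 passes every planted 9/9 element while random RGCGGYRRY matches
  rarely reach it. The source text places α both "between S1 and S2" and
  "between the 5′ and 3′ splice sites"; the default requires only
  5'-of-aptamer within `max_separation`, with `alpha_between_donors` for
  the strict reading.
* The Type III stop-codon frame is taken relative to the annotated
  upstream CDS phase ("the same reading frame" refers to main-ORF
  read-through).
* At least two donors are required for Type II but a third (S3) is
  accepted without being required.
* **Type IV and the aptamer itself.** A literal "no GT and no AG anywhere
  in the 5'UTR" is unsatisfiable whenever the aptamer sits in that UTR:
  the GAGAU motif itself contains AG. The check therefore applies to the
  UTR *outside* the hit interval (padded by `utr_exclusion_pad` so a
  slightly trimmed scan hit cannot leak aptamer bases into the checked
  region). This matches the evident meaning — no splice sites outside the
  riboswitch — and is the only self-consistent reading.

## The synthetic world

`sim_config()` states the simulated conditions once: 50 architectures per
type and 50 decoys by default, intergenic GC 0.45, Type I 5'UTR intron
300–600 nt with a 10–40-codon uORF, Type II intron 650–900 nt with α
separation 400–600 nt, Type III intron 200–400 nt, per-base aptamer
mutation rate 0.02 outside held positions. The bundled 100-nt consensus
satisfies every motif constraint by construction (GAGAT at 5, GCG at 24,
TAAT at 40, G–G pair at 18 intervening bases, P1 window `ATTACCGCT` whose
reverse complement `AGCGGTAAT` matches RGCGGYRRY). Each architecture draws
its RNG stream from `(seed, gene index)`, so generation is reproducible
and order-independent; a rerun with the same config is byte-identical.

Generator-side design choices:

* Both 10-nt aptamer edges, all motifs and the P1 window are held
  invariant under mutation. Holding the edges keeps the local-alignment
  hit interval stable over the planted interval (a mutated terminal base
  could otherwise be trimmed, shifting the P1 window the classifier pairs
  α against).
* Spurious GT/AG dinucleotides are *allowed* everywhere except the Type IV
  UTR — real introns contain extra donor candidates and the classifier
  must tolerate them — but incidental ATGs in Type I intron filler are
  rewritten (T→C, which can create no ATG, GT, AG or stop), so the planted
  uORF is the unique one and deleting it provably flips the call.
* Decoys carry a column-shuffled aptamer inside a 450–550-nt internal
  intron — a length strictly between the Type III and Type II windows — so
  they are structurally unclassifiable no matter what the random filler
  contains, and composition-matched so the scanner gets no free
  discrimination.
* What the generator does **not** emulate: codon usage, branch points or
  any splice-site consensus beyond GT/AG, transcript expression, and
  sequence evolution along a phylogeny. A green recovery test therefore
  establishes that the rules and coordinate handling are implemented
  correctly on data satisfying the model's assumptions — not that the
  thresholds would achieve the same accuracy on real genomes.

## Worked example

```{r example}
cfg <- sim_config(seed = 42, n_per_type = 2, n_decoys = 2)
sim <- simulate_run(cfg)
profile <- build_profile(make_seed_alignment(cfg))
profile

hits <- scan_genomes(profile, sim$genomes)
contexts <- locate_hits(hits, sim$genes)
calls <- classify_hits(hits, contexts, sim$genes, sim$genomes)
table(calls$reg_type)
calls[1, c("hit_id", "reg_type", "intron_length", "notes")]
```

Every planted architecture is recovered as its planted type and the decoys
yield no hits at the default threshold; the acceptance suite
(`tests/testthat/test-acceptance.R`) runs the same loop at the full stated
sizes (seed 42, 200 architectures + 50 decoys) together with the scanner,
uORF and motif oracles, the filter-rule boundary cases, round-trip
identity, and the perturbation flips.

## Numerical and degenerate-input notes

* Coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
  is converted only at the I/O boundary, the single place the conversion is
  tested.
* Scanner ties are broken deterministically (score, then leftmost, then
  plus strand); alignments start and end in match states, so hit intervals
  never include dangling gaps.
* Hits shorter than half or longer than twice the profile length are
  discarded as implausible aptamer spans.
* Empty genomes are errors in the pipeline (exit 2 from the CLI); a scan
  with no hits, a region with no splice sites, uORFs or α element, and a
  single-exon gene's empty intron list are all ordinary empty results.
* Genes without an annotated CDS get `INTERNAL_INTRON` labels for all
  introns (no UTR side is definable); such hits end `UNCLASSIFIED`.

## Limitations

The scanner is a sequence profile, not a covariance model: it captures no
secondary-structure covariation and is not calibrated to E-values, so its
threshold is a per-profile fraction rather than a significance level.
Classification is per transcript and single-gene; operon-like
multi-gene regulation, antisense arrangements, and any association of
intergenic hits with downstream genes are out of scope. Type IV is a
location label, not a mechanism call.
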