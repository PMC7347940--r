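---
title: "Methods: detecting and quantifying non-productive alternative splicing"
author: "nmdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and quantifying non-productive alternative splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmdscan)
```

## The problem

A large share of mammalian alternative-splicing (AS) events are
*non-productive*: the alternative splice choice introduces a premature
termination codon (PTC), and the resulting mRNA is degraded by
nonsense-mediated decay (NMD). Because these transcripts are actively
destroyed, they are nearly invisible in steady-state RNA-seq, yet they
are attractive therapeutic handles — blocking the non-productive choice
with a splice-switching oligonucleotide redirects the pre-mRNA into the
productive isoform and raises protein output from wild-type alleles.
`nmdscan` implements the computational side of this program: finding
NMD-inducing AS events in transcript annotations, quantifying their
usage from splice-junction counts, gating samples on quality, annotating
the hit genes against a gene–disease table, and partitioning exons for
conservation analysis. A first-class synthetic-data generator provides
ground-truth fixtures for every stage.

## Junction labeling and the 50-nt rule

The unit of evidence is the **exon–exon junction**. From the merged
transcript database (GTF and/or genePred input), every junction of every
multi-exon transcript is extracted, and a junction is labeled **NMD if
and only if every transcript containing it** is itself non-productive
(biotype `nmd` from a `nonsense_mediated_decay` GTF tag, or `noncoding`
from a RefSeq `NR_` accession). Any support from a protein-coding — or
unrecognized — transcript makes the junction `coding`; mislabeling
toward `coding` is the conservative direction because it can only
suppress, never create, an NMD event call.

Independently of annotation tags, `evaluate_ptc_rule()` applies the
classic **50-nt rule**: a transcript is predicted NMD-sensitive when its
stop codon lies at least 50 spliced nucleotides upstream of its 3′-most
exon–exon junction and not in the last exon. The comparison is
inclusive (a distance of exactly 50 nt predicts NMD), reading "at
least" literally. The rule is used two ways: as a user-facing
classifier, and inside the synthetic generator as the constraint that
planted poison isoforms must satisfy (the generator re-applies the rule
after construction and aborts on any disagreement, so the two code paths
cross-check each other).

Decisions where the inputs are underspecified, recorded here once:

* RefSeq's non-coding class is identified by the `NR_` accession prefix
  (`NM_` → protein-coding). genePred has no biotype column, so the
  prefix is the only available signal.
* When GTF and genePred describe the same locus, transcripts from both
  sources are pooled **before** the exclusivity rule is applied; the
  rule then sees the union of isoform evidence.
* Junctions are strand-aware, and introns shorter than 20 nt (a
  configurable floor) are not considered valid junctions — annotation
  noise below that scale would otherwise create degenerate events.

## Event enumeration

Four AS event classes are enumerated natively from the database, with
`.ioe`-format event files accepted as an interchangeable input path
(both representations are required by tests to decode to identical
event records):

* **SE (skipped exon)** — an internal exon of one transcript whose two
  flanking junctions are matched by a single *skipping* junction
  spanning the same outer boundaries. Events found through different
  transcript pairs but describing the same coordinates are merged.
* **A3 / A5 (alternative 3′/5′ splice site)** — two introns sharing
  their donor (A3) or acceptor (A5) but differing at the other end.
  The exons adjacent to the variable end must overlap; this prevents
  an inclusion/skipping junction pair from masquerading as an
  alternative splice site.
* **RI (retained intron / exitron)** — an intron of one transcript
  lying strictly inside a single exon of another. Strict containment
  (not touching either exon edge) distinguishes exitron geometry from
  alternative splice sites.

Mutually exclusive exons and alternative first/last exons are out of
scope. NMD classification is per event: for SE the skipping junction
is tested **first** (skipping junction NMD → `ES_NMD`), then the
inclusion junctions (either NMD → `EI_NMD`), else `cassette_exon`; the
ordering matters because a junction set can satisfy both, and the
precedence is asserted by tests. For A3/A5, exactly one NMD junction
gives `A3_NMD`/`A5_NMD`; when *both* junctions are NMD the local
splicing is likely complex and the event is dropped from all downstream
output (`dropped_complex`). For RI, an NMD alternative-intron junction
gives `AI_NMD`.

## PSI estimators

All quantification uses uniquely-mapped junction read-pair counts (the
STAR `SJ.out.tab` dialect; one count = one uniquely mapped read pair).
With role-summed counts per event:

* **Cassette**: \(\Psi = \mathrm{sj}_{inc} / (\mathrm{sj}_{inc} + 2\,
  \mathrm{sj}_{skip})\). Each included molecule contributes to *two*
  inclusion junctions but each skipping molecule to one, hence the
  factor 2. Skipping-type events report \(1 - \Psi\). Inclusion and
  skipping counts are summed across all events sharing the same
  alternative exon.
* **Alternative splice site**: \(\Psi = \mathrm{sj}_{NMD} /
  (\mathrm{sj}_{NMD} + \mathrm{sj}_{coding})\).
* **Alternative intron**: the host exon's expression is estimated as
  \((\mathrm{sj}_{3'} + \mathrm{sj}_{5'})/2\), summing every observed
  junction that uses the 3′ or 5′ splice site of any parent exon; the
  AI junction count is clipped at that estimate, so
  \(\Psi_{AI} = \min(\mathrm{sj}_{AI}, E) / E \in [0, 1]\). The
  clipping is implemented as exact equality of this expression — no
  additional smoothing or pseudocounts anywhere.

A zero denominator yields an explicitly *undefined* PSI (`NA`), never a
silent 0 or 1.

**Filters.** An event record passes when the count on its
NMD-supporting junction role(s) is ≥ 3 read pairs **and** PSI ≥ 0.03,
both inclusive. The read threshold is applied to the NMD role
(inclusion junctions for EI, the skipping junction for ES, the NMD
alternative-splice-site junction, the AI junction) rather than to all
junctions; `scope = "all_roles"` switches to the stricter reading.

**Multi-sample policy.** PSI is computed per sample; an event enters
the catalog when it passes in at least one sample, and the reported PSI
is the maximum over passing samples. This is the weaker assumption —
an event genuinely present in one tissue should not be diluted away by
others — and a pooled-counts mode is available for the alternative
reading. Headline gene counters count each gene once regardless of how
many event types it carries; per-type tallies may count a gene several
times.

## Sample QC and disease annotation

The QC module consumes precomputed metrics (any QC toolchain can fill
the documented TSV schema) and applies exclusion logic: capture
efficiency (fraction of reads uniquely mapped to the transcriptome)
below 0.70 fails, the boundary passes; an absolute R1/R2
duplication-rate difference above a cutoff fails. The cutoff's
magnitude is not standardized anywhere we know of, so it defaults to
0.10 (absolute) and is configurable and reported.

Disease annotation joins catalog gene symbols against a flattened
Orphadata-style TSV, expanded through NCBI gene_info synonyms. Matching
uppercases both sides; an alias claimed by two canonical symbols is
ambiguous and dropped with a warning (canonical symbols always win over
synonym claims on the same string). Flagged-gene counts are invariant
under replacing a symbol by any of its aliases, and each gene is
flagged at most once.

## Conservation

Three mutually exclusive exon sets are built: (1) exons whose inclusion
causes NMD (poison exons of `EI_NMD` events), (2) alternatively spliced
exons that do not cause NMD (`cassette_exon`), and (3) all remaining
protein-coding exons. An exon claimed by both (1) and (2) under
different flanks stays in (1). Per-exon conservation is the arithmetic
mean of a per-base score track (bedGraph or fixed-step wiggle; scores in
[0, 1]) over the exon body — intronic flanks are excluded by default
(`flank` support can be layered on the interval inputs), since the sets
are exon sets; the conserved fraction counts exons with mean ≥ 0.8
among exons with any data, computed per unique exon rather than per
event. Bases without data are distinguished from score 0 and excluded
from the mean.

## The synthetic study generator

The generator *is* the study design, not a test convenience. Each gene
receives a five-exon productive isoform and, per its assigned type, a
non-productive isoform: a poison exon inserted into an intron (EI), a
skipped coding exon with a downstream PTC (ES), a 3′ or 5′ splice-site
shift into a PTC-bearing extension (A3/A5), or an exitron spliced out
of a coding exon (AI). `none` genes carry a coding cassette exon —
an AS event that is *not* NMD-inducing — so specificity is tested, and
these exons populate conservation set 2. Genes alternate strands, and
minus-strand genes are built by mirroring transcript-space geometry,
which exercises all strand-aware code paths for free. A fifth of the
genes are emitted as RefSeq-style (NM_/NR_ accessions via genePred),
the rest GENCODE-style (GTF).

The abundance model: a fraction \(\psi\) of molecules take the
non-productive choice; NMD degrades a fraction \(d\) of those, so the
observable non-productive fraction is

\[ f(\psi, d) = \frac{\psi (1 - d)}{\psi (1 - d) + (1 - \psi)}, \]

which equals \(\psi\) under cycloheximide (CHX, NMD inhibition,
\(d = 0\)). Defaults encode the regime reported for validated AS-NMD
targets: \(\psi \sim U(0.186, 0.89)\) (the observed post-inhibition
abundance range) and per-gene \(d\) derived from a target CHX/DMSO fold
increase \(F \sim U(1.1, 9)\) via \(d = 1 - (1-\psi)/(F-\psi)\), so the
planted efficiencies reproduce that fold-change band exactly. Four
archetype genes mirror well-characterized targets — poison exons at
\(\psi = 0.30\) and \(0.89\), an alternative 3′ss with a 176-nt acceptor
shift at \(\psi = 0.47\), and an exitron at \(\psi = 0.20\).

Counts are Poisson per junction with intensity proportional to the
summed abundance of the isoforms carrying the junction, scaled so the
expected junction yield per gene equals `depth`. Under this model every
PSI estimator above is consistent for \(f(\psi, d)\) — the factor 2 in
the cassette formula exactly offsets the two inclusion junctions — and
the recovery tests exploit this: at `depth = 1e5` and \(d = 0\) the
mean estimated PSI must sit within 0.02 of the true \(\psi\), and on a
3×3 \((\psi, d)\) grid the observed non-productive fraction must match
the closed form within three binomial standard errors. Poisson (no
overdispersion) is deliberate for v1: the estimators are ratio
estimators with no variance model, so overdispersion would widen but
not bias the checks; a negative-binomial switch would slot into
`simulate_counts()` without touching the estimators.

What the generator does **not** emulate: mapping bias, multi-mapping
reads, overdispersed biological replication, incomplete annotation, and
genes sharing junctions across loci. Passing recovery tests therefore
demonstrates correctness of the estimators and plumbing under the
stated model, not robustness to every artifact of real libraries.

## Problem sizes and numerical choices

The shipped test-and-acceptance workloads use 60-gene end-to-end
studies, 100–200 random multi-isoform genes for the enumeration and
labeling oracles, depth \(10^5\) for estimator-consistency checks, and
1000 exons for conservation-exceedance recovery; these sizes give
comfortable statistical resolution (binomial SE well below the asserted
tolerances) while keeping a full run in tens of seconds. Other
numerical choices: all internal coordinates are 0-based half-open with
conversions only at I/O boundaries (GTF and STAR tables are 1-based
inclusive; genePred and bedGraph already half-open), which is round-trip
tested; PSI boundaries are inclusive; quadratic standard-curve inversion
selects the root on the monotone branch covering the standards and flags
extrapolations rather than refusing them.

## Known limitations

* Event enumeration is annotation-bound: junctions absent from the
  transcript models are never assembled into novel events.
* A3/A5 NMD classification requires exactly one NMD-labeled junction;
  whether that junction is the PTC-generating one specifically is not
  re-derived from sequence (no ORF inference anywhere by design).
* The pooled-versus-per-sample PSI question has no single right answer;
  both modes are provided and the default (per-sample, max over passing
  samples) is the more permissive catalog.
* Conservation analysis accepts any per-base [0, 1] track; it does not
  compute alignments or scores itself, and bigWig input should be
  converted to bedGraph upstream.
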