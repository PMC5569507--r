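---
title: "sporomir: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sporomir: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sporomir)
```

# The problem

Most lycophytes and ferns have no sequenced genome, so the standard
genome-anchored miRNA annotation toolchain does not apply. sporomir
implements a homology-first small-RNA workflow suited to such lineages:
mature miRNA candidates are identified by sequence similarity to
annotated plant miRNAs, isoform clouds are collapsed around their 5'
ends, candidates are (optionally) validated against whatever genomic
sequence exists, cleavage activity is confirmed in degradome/PARE
libraries, and conservation is summarized across a panel of species.
Because real surveys of this kind cannot be re-run at desk scale, the
package ships a seeded generator that produces ground-truthed synthetic
inputs, and every stage is tested by parameter recovery against that
ground truth.

# The model, stage by stage

## Preprocessing

Reads are kept when 16--26 nt long (both bounds inclusive). The
reads-per-million denominator is the 18--26-nt read total: the two
windows come from different halves of the protocol description and both
are honored literally -- the wider window feeds candidate discovery, the
narrower one normalizes abundance. Structural-RNA fragments (rRNA, tRNA,
snoRNA, snRNA) are removed when they match a same-length substring of a
user-supplied structural reference with at most 2 substitutions. The
scan covers both strands: structural RNAs are transcribed features, but
library artifacts can ligate in either orientation and the extra scan is
cheap. Finally, 3' uridine tails -- nontemplated U runs added to small
RNAs marked for degradation -- are shortened: a trailing run of two or
more U collapses to exactly one U, and sequences made identical by the
collapse have their counts summed. A single trailing U is untouched,
because a templated terminal U cannot be told from a 1-nt tail. An all-U
read degenerates to "U" and is discarded by the length filter.

## Candidate identification

A read matches a reference mature miRNA when it has at most 2
substitutions and at most 1 nt length difference ("fewer than 3" and
"fewer than 2"). Substitutions are counted with both 5' ends aligned and
the 3' overhang contributing only to the length difference. The 5'
anchor is a deliberate choice the protocol leaves open: plant miRNA
identity and ARGONAUTE sorting are 5'-defined, and the downstream
clustering keys on nucleotides 1--16, so anchoring at the 5' end keeps
one comparison frame throughout. Reads are assigned to the reference
with the lexicographically minimal (substitutions, |length difference|),
ties broken by family name.

Reference families whose sequences mutually satisfy the same rule are
merged (transitive closure; union-find), since their reads cannot be
told apart -- e.g. miR156 + miR157 become "miR156/157" ("miR156/7" in
short form). Candidates sharing 5' nucleotides 1--16 form one cluster
whose representative is the most abundant member (ties: shorter, then
alphabetical -- the protocol states only "most abundant", so the
remaining tie-break is ours and is documented rather than asserted).
Clusters are kept when the representative's raw count strictly exceeds
`max(10, 5 RPM expressed in reads)`; "whichever is higher" is read as
the more stringent threshold, with `abundance_rule = "either"` exposing
the permissive reading. Names follow
`{Species}-{family}[-arm].{serial}_{rawcount}` with serials in
descending cluster-count order (the original ordering is unstated).

## Hairpin validation

Candidates are mapped to the genome exactly (both strands), windows of
the hit plus 200 nt per side are extracted ("400-bp flanking" read as
400 nt total, configurable), and a candidate passes at a locus when
fewer than 4 of its positions are unpaired in the precursor structure
and it does not pair with itself (mature on one arm). A candidate
passes overall if any locus passes; more than 20 loci flags it
repeat-like.

Two structure engines exist:

* `fold_maxpair()` -- a Nussinov-style dynamic program maximizing
  Watson--Crick plus G:U pairs over non-crossing structures with
  hairpin loops of at least 3 nt, with a deterministic traceback. It is
  exactly verifiable against exhaustive enumeration and is the folding
  primitive and plug-in point (`fold_window(engine = )` accepts any
  function returning a dot-bracket string, e.g. an RNAfold wrapper).
* `hairpin_arm_fit()` -- the **default** for validation. It scans every
  gapless antiparallel register of a putative star arm in the window
  and keeps the one pairing the most candidate bases; the resulting
  duplex is what `validate_hairpin()` scores.

The default is not the global fold, and the reason is quantitative:
base-pair maximization over a ~420-nt window of random-flank sequence
pairs nearly every base *somewhere*. Measured on planted hairpins,
mature bases opposite 4--5 mutated star positions were re-paired
against flanking sequence in 33--67% of loci (falsely passing), while
at 3 mutations the traceback sometimes returned a co-optimal structure
off the stem (falsely failing). A thermodynamic folder does not behave
this way -- helix stacking makes the planted stem dominate -- and the
duplex scan reproduces that behavior: planted star mutations come back
as exactly that many unpaired mature positions, making the <4 boundary
sharp. Users wanting the literal global fold can pass
`method = "fold"` to `hairpin_validate_candidate()`.

## Degradome analysis

Tags shorter than 19 nt are dropped; the rest are mapped exactly, sense
strand only, and a tag's 5' end is accumulated at every occurrence
(multi-mapping tags count fully everywhere; no fractional weighting).
A position is a cleavage peak iff all four rules hold:

1. at least 12 unique tag sequences mapped to the transcript;
2. the position is among the top 12 positions by count (ties at the
   rank-12 boundary are all admitted);
3. its RPM exceeds 5 (RPM over total library tags);
4. its RPM exceeds mean + 5 × SE of the RPM of all positions with
   mapped reads, where SE = sample SD (n−1 denominator) / sqrt(n).

"Standard error" is not defined further in the source protocol; the
sample-SD/sqrt(n) reading is recorded here. A uniform profile can never
yield a peak (rule 4 is strict), and no spike can rescue a transcript
with fewer than 12 unique tags.

Peaks are linked to candidates by slicing geometry: the tag 5' end
marks the target base opposite miRNA position 10 (cleavage between
positions 10 and 11, the standard plant convention, unstated in the
protocol). The implied site window is scored with the target scorer and
linked at score ≤ 2.5.

## Target scoring

The scorer uses the classical plant penalty scheme: per miRNA position,
0 for a Watson--Crick pair, 0.5 for a G:U wobble, 1 for a mismatch, 2
for a gap; at most one single-nucleotide bulge, disallowed opposite
miRNA positions 10--11; all penalties doubled at positions 2--13.
Sites scoring at most 2.5 are reported. Alignment is antiparallel
(miRNA 5'→3' against the target window 3'→5'), sense strand only.
`predict_targets()` slides the scorer over windows of the miRNA's
length ±1 and reports every admissible site in deterministic order.

Orthogroup conservation profiles slide a 30-nt window (the protocol
body says 30, its figure legend 21; 30 is taken as normative and the
width is a parameter) over an equal-length alignment. Within each
window, each member's variation is its substitution count against the
group consensus, and the profile reports the mean and standard error
across members. The consensus (per-column majority, alphabetical
tie-break) replaces an ancestral-state reconstruction: it is
self-contained, order-independent, and for the conserved/variable
contrast these profiles are used for, the difference is immaterial.

## Conservation statistics

Size distributions, 24/21-nt count ratios (the heterochromatic-siRNA
vs miRNA peak contrast), 5' nucleotide composition, and per-family
consensus/variation are straightforward tabulations. Two tests are
implemented in-package and cross-validated against R's `stats`
implementations in the test suite (never substituted by them):

* `wilcoxon_rank_sum()` -- exact two-sided Mann--Whitney by dynamic
  programming over the rank-sum distribution (doubled midranks handle
  ties) for group sizes ≤ 12, otherwise the normal approximation with
  tie and continuity corrections. Two-sided p is
  `min(1, 2·min(P(W≤w), P(W≥w)))`.
* `chi2_composition_test()` -- Pearson χ² on a 2×2 (5'U vs non-U)
  table, no continuity correction, df = 1, upper tail.

`classify_conservation()` keeps the top 50 families by mean RPM across
all species (zeros included; averaging only over detected species is a
flag), clusters log2(RPM+1) rows with average-linkage hierarchical
clustering on Euclidean distances, cuts at k = 5, and labels groups
I--V by descending detection breadth then mean level; families detected
in more than 15 species are flagged broadly conserved. Two deliberate
choices: the +1 pseudocount (the source writes log2(RPM) without
handling zeros), and **no row scaling**. Row z-scoring was tried and
rejected on evidence: a family expressed uniformly at a high level in
every species scales to a unit-variance noise row, so the "high
everywhere" block that defines class I scatters across clusters.
Unscaled log2 rows recover block structure exactly and are stable under
uniform rescaling of all RPMs.

# The synthetic world

`sim_config()` states the world once; its defaults are the conditions
the analysis assumes, not dials: a dominant 21-nt mature class (length
weights 0.15/0.6/0.2/0.05 over 20--23 nt), per-read substitution
probability 0.02 (sequencing-error scale; at most one substitution per
read), 3' truncations up to 2 nt and U-tails up to 3 nt with
geometrically decaying probabilities, 30% 24-nt background, log-normal
per-family expression with sigma 1, and 10^5 reads. The source study
does not characterize its libraries' true isoform rates; these values
are test-design choices for a typical plant small-RNA library and are
not revisited.

The generator guarantees the invariants the tests rely on: read counts
sum exactly to the configured depth; every non-background read is
attributable to exactly one family; background reads are genome
substrings (so structural filtering and mapping behave realistically)
but are rejection-sampled so that none satisfies the homology rule
against the catalog -- otherwise substrings of a planted hairpin's
mature arm would be miRNA reads mislabeled as background, and the
"zero false families" recovery criterion would be unmeasurable.
Hairpins are planted as mature + loop + mutated-reverse-complement,
with star mutations chosen to pair with neither the original
complement nor (via wobble) the mature base, so planted damage is
never silently repaired. Degradome tags are 20-nt transcript suffixes
starting at planted cleavage positions plus uniform positional noise.

What the generator does **not** emulate: sequencing-quality error
profiles, adapters, ligation bias, multi-locus families, RNA editing,
or expression correlation across species. A green recovery test
establishes that the pipeline's rules compose correctly and recover a
stated world; it says nothing about the biological completeness of any
real annotation.

# Numerical and boundary conventions

* Internal coordinates are 0-based half-open; report TSVs are 1-based
  inclusive, converted only at the I/O boundary.
* All sequence input is normalized to the RNA alphabet (T→U) on read.
* All thresholds are strict where the source says "more than"/"over"
  (abundance, peak RPM, rule 4) and inclusive where it says ranges
  (16--26 nt).
* Every generator threads one explicit seed and restores the caller's
  RNG state; rerunning any stage on the same inputs is byte-identical
  (the config echo differs only in its recorded output directory).
* Degenerate inputs: empty read sets pass through filters; a zero
  21-nt count makes the 24/21 ratio NA; a single mapped degradome
  position has SE 0 and cannot beat rule 4's strict inequality;
  candidates shorter than the 16-nt prefix cluster by full sequence
  and are flagged.

# Known limitations

* Homology-only discovery: genuinely novel (non-conserved) miRNAs are
  out of scope by design.
* The duplex-based hairpin default ignores bulged stems (it scans
  gapless registers); precursors with indel-containing stems need the
  `method = "fold"` route or an external thermodynamic engine.
* Exact-match mapping everywhere (genome, degradome): SNP-carrying
  loci or tags are missed; this mirrors the no-mismatch genome-mapping
  setting of the source protocol but is stricter than its degradome
  mapping, which is not fully specified.
* The Wilcoxon exact mode enumerates via DP in O(n²·Σranks); fine for
  the ≤12-per-group sizes it is used for, not meant for large samples.
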