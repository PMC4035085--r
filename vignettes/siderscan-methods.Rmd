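---
title: "Methods: hallmark screening, fold validation and cleavage kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hallmark screening, fold validation and cleavage kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siderscan)
```

## The problem

Trypanosomatid genomes are littered with mobile elements of the
L1Tc/ingi clade. All of them share a conserved ~77-nt sequence at their
5' end — the Pr77 hallmark — which at the RNA level folds into an
HDV-like self-cleaving ribozyme and cleaves the bond immediately 5' of
its first nucleotide (+1). Finding these elements in a genome therefore
combines three kinds of evidence:

1. **sequence homology** to a hallmark consensus,
2. **mobile-element context** — a downstream poly-A tract at one of two
   characteristic distances and a 7–11-nt target-site duplication (TSD)
   flanking the insertion, the footprint of target-primed reverse
   transcription, and
3. **structure** — the candidate RNA must be able to adopt the HDV-like
   double-pseudoknot fold.

`siderscan` implements all three stages as testable code, plus the
two-phase cleavage-kinetics analysis used to characterise active
ribozymes, and a synthetic-data generator that produces genomes with
known ground truth so the whole pipeline can be validated at desk scale.

## Hallmark scanning

`scan_genome()` is a k-mer seed-and-extend local aligner (defaults:
k = 11, match +1, mismatch −1, linear gap −2). Exact seed matches on
either strand are clustered into windows and extended with a full
Smith–Waterman alignment of the query against the window; within a
window the aligned region is masked and the search repeated, so tandem
hallmark copies (the SIDER2 signature I/II arrangement) are both
reported. Identity is matches over aligned columns; IUPAC codes in the
query match any contained base and N in the genome matches nothing.
Overlapping same-strand hits are merged keeping the higher score.

Defaults `min_identity = 60`%, `min_length = 50` nt are deliberately
permissive — diverged hallmark subfamilies are expected — while keeping
the false-positive rate on i.i.d. sequence below 1e−4 per kb. The tests
include an oracle check: on small genomes the scanner must reproduce the
intervals and scores of `Biostrings::pairwiseAlignment` under the same
scoring scheme.

`iterative_scan()` re-screens with the sequences of new hits as queries
until no new hit appears, so copies reachable only through intermediate
homologues are recovered; hits are deduplicated at 80% reciprocal
overlap.

One empirical subtlety: the hallmark is mostly helices, so it is
partially self-complementary, and a genuine hit often drags along a
weaker antisense match over the same interval. `annotate_genome()`
suppresses any hit that overlaps a strictly higher-scoring hit on the
opposite strand by at least half of its own length.

## The fold descriptor

The HDV-like architecture is encoded as data (`ribozyme_descriptor()`):
per helix a length range, position windows for the 5' and 3' strands
(1-based, position 1 = the +1 nucleotide) and pairing rules. Defaults
describe an ~80-nt hallmark:

| helix | bp    | 5' window | 3' window | pairing |
|-------|-------|-----------|-----------|---------|
| P1    | 6–8   | 1–8       | 30–45     | WC + G·U |
| P2    | 4–7   | 8–18      | 20–34     | WC + G·U |
| P3    | 3–6   | 12–24     | 18–33     | WC + G·U |
| P1.1  | 2     | 15–28     | 36–52     | G·C only |
| P4    | 3–12  | 42–110    | 48–126    | WC + G·U |

P1 pairs the +1 nucleotide against a partner near position 39; P2
closes over the P3 hairpin; the two obligate G·C pairs of pseudoknot
P1.1 connect the P3 loop to the region just 3' of the P1 3' strand,
crossing P1, P2 and P3; P4 is a local hairpin downstream. Junction
ranges (J1/2 0–6 nt, J4/2 0–12 nt, P4 loop 3–12 nt) complete the
geometry. P1 must additionally contain a run of consecutive G·C pairs
(default 3, relaxable to 2 — some active natural ribozymes have only
two). The catalytic-nucleotide identity is deliberately *not* checked;
only the architecture is validated. Per-species geometries differ and
the published secondary structures are figures, not coordinates, so
every window is configuration, calibrated here against the generator.

`enumerate_foldings()` exhaustively combines legal helix placements
(position-disjoint; the base layer P1/P2/P4 non-crossing; P3 and P1.1
free to cross — dot-bracket output uses `()`, `[]`, `{}` for the three
layers). A helix is left unfolded **only when nothing can be placed**,
so each violation code means what it says: `P3_UNFOLDED` is a statement
about the sequence, not about one assignment. This also keeps the
assignment count small (tens to thousands for realistic sequences; a
hard cap of 5×10^5 guards against degenerate inputs). Sub-threshold
placements are enumerated for P1 (down to 3 bp, `P1_TOO_SHORT`) and P2
(3 bp, `P2_TOO_SHORT`), and a P1 register whose pairs are legal except
at the +1 nucleotide is reported as `P1_MISMATCH_AT_PLUS1` — the
C1·A39-type defect seen in weakly active natural copies.

`best_folding()` is an independent branch-and-bound search under the
total order *fewest violations → most base pairs → longest P1 G·C run →
leftmost P1 3' strand*, with a deterministic final tie-break. Its
agreement with the top of the full enumeration is asserted over
hundreds of generated positives, constraint-broken negatives and random
sequences — this dual route replaces the manual folding step of the
original screening protocol with something falsifiable.

`validate_hallmark()` accepts a candidate when its best assignment has
at most `max_violations` violations (default 0). The knob exists
because some natural subfamilies were retained in screens despite minor
structural disruptions; 0 is the conservative default.

## Element context and classification

`find_polyA()` scans the strand-aware downstream windows — 300–1000 nt
("SHORT", short-element architecture, poly-A ≈0.6 kb after the
hallmark) and 4500–6500 nt ("LONG", full-length LINE/DIRE architecture)
— for maximal runs of ≥10 nt with ≥90% A (T runs upstream for
minus-strand hits). Neighbouring runs of at least 3 nt each are joined
while the combined fraction stays above the purity floor; single stray
bases are never absorbed, so a clean tail reports fraction 1. The
operational definition (10 nt, 90%) keeps the per-window false-positive
rate on random sequence below 1e−3.

`find_TSD()` compares the L-mer ending at the element 5' boundary with
the L-mer starting after the poly-A end, L = 11 down to 7, boundary
offsets 0–5 nt per side; a pair is accepted at ≥80% identity with ≥7
matching positions ("partially or totally conserved" — a 1-mismatch
8-mer passes), tie-breaking to the longest L, highest identity,
smallest total offset. The thresholds were set by measuring the
false-acceptance rate on random flanks: with the offset slack a search
performs ~180 comparisons, and looser settings (say 75% with 6
matches) accept a spurious duplication at >10% of TSD-less loci, which
would defeat the `no_tsd` confidence flag; the defaults bring that
rate to ~2% while keeping every partially conserved case above
one mismatch per eight positions. Because a
poly-A-derived element edge can swallow a few adjacent background A/T
residues, the annotation stage retries a failed flush search with that
boundary pulled in by up to 5 nt; the pure function itself stays
flush-anchored so that exact plants are reported exactly.

`classify_element()` applies the annotation rules in order: two tandem
hallmarks (gap ≤ 200 nt) → SIDER2; span from first hallmark to poly-A
end ≥ 4 kb → LINE_DIRE; single hallmark + SHORT poly-A whose element
ends both align at ≥80% identity to a supplied full-length reference →
SIDE_NAR; single hallmark + SHORT poly-A → SIDER1; otherwise
UNCLASSIFIED. A missing TSD never changes the class — it downgrades
confidence to `no_tsd`. The 200-nt tandem gap is permissive relative to
the tightest natural tandem arrangement and is exposed in the
configuration.

`annotate_genome()` chains all stages (scan → per-strand locus grouping
→ poly-A → TSD → per-hallmark fold validation → classification); a
stage failure at one locus yields UNCLASSIFIED rather than aborting.

## Cleavage kinetics

The cleaved fraction follows the two-phase exponential decay
$f_c(t) = A + B e^{-k_1 t} + C e^{-k_2 t}$ with plateau $A$ (% at
infinite time), amplitudes $-B, -C$ and fast/slow rate constants
$k_1 \ge k_2$ (min⁻¹). `fit_two_phase()` uses a deterministic
multi-start: 28 log-spaced $(k_1, k_2)$ pairs in $[10^{-3}, 10]$
min⁻¹, an exact linear solve for $(A, B, C)$ at each pair (clamped to
$A \in [0, 100]$, $B, C \in [-100, 0]$), Levenberg–Marquardt polish of
the best starts, and relabelling so $k_1 \ge k_2$. $f_c(0)$ is *not*
constrained to zero — gel-purified constructs can carry a pre-cleaved
fraction at time 0 — so $A + B + C$ is reported for inspection. No
random numbers are used anywhere in fitting.

The competing model is the one-site hyperbola
$f_c = A_{max} t / (K + t)$ (the standard one-site saturation form), fitted the
same way over a $K$ grid. `compare_models()` declares the winner by
$R^2 = 1 - SS_{res}/SS_{tot}$; exact ties keep the two-phase model
flagged ambiguous. On two-phase data with well-separated rates and
moderate noise the two-phase fit wins essentially always, mirroring the
published model comparison. A "0 mM" control series is fitted like any
other.

`cleavage_fraction()` converts band intensities of body-labelled RNA to
molar amounts by dividing by the U count of each fragment (labelled
UTP), then reports $100 \cdot m_{3'} / (m_{3'} + m_{uncleaved})$, with
the 5' fragment as a separately reported cross-check. Length- or
raw-intensity normalisation can be emulated by passing proportional
`u_count`s. The published kinetics table has a typographically
ambiguous extra column in its header; `write_fit_tsv()` therefore uses
the unambiguous three-Mg layout (two-phase R², plateau and hyperbolic
R² per Mg concentration).

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated; its defaults are fixed, not tuning knobs.

* `sample_ribozyme()` draws helix placements within the descriptor
  windows, fills paired strands complementarily (C1·G at the +1 pair,
  extending into the required G·C run; G·C only in P1.1), fills
  junctions randomly and rejection-samples until validation passes
  (caps: 40 junction refills, then fresh placements).
* `break_constraint()` mutates a passing sequence until the *best* fold
  carries a named violation code — targeted knockouts guided by the
  current best fold, escalating to emptying a helix's windows when
  alternative registers keep reviving it. Re-validation after every
  step is what guarantees "no alternative passing fold exists".
* `build_element()` assembles hallmark(s) + random body + poly-A tail:
  body 550 nt for short classes (placing the tail at ≈0.6 kb, inside
  the SHORT window) and 5200 nt for LINE_DIRE (inside the LONG window);
  SIDER2 carries two tandem hallmark copies 10 nt apart by default;
  NAR-like elements copy 200-nt end regions from a reference long
  element. Point mutations at `divergence_pct` are applied per hallmark
  copy.
* `plant_genome()` inserts elements into i.i.d. background (GC 0.5)
  with ≥1 kb spacing, duplicating each element's TSD flush at both ends
  (decoys skip the duplication); minus-strand elements are inserted
  reverse-complemented while TSD copies stay direct repeats, as TPRT
  leaves them. Background is i.i.d. rather than Markov — sufficient for
  the false-positive targets and simpler to reason about.
* `synthetic_screen_fixture()` is the canonical study genome: one
  200 kb contig, 12 elements (4 SIDER1, 4 SIDER2, 2 LINE_DIRE, 2
  TSD-less SIDER1 decoys), mixed strands, hallmark divergence 0–10%.
* `simulate_timecourse()` adds Gaussian noise (default sd 2 percentage
  points) to the two-phase curve at 9 time points spanning 0–160 min
  and clips to [0, 100].

What the generator does *not* emulate — and hence what passing tests do
not show about real genomes: nucleotide composition bias and repeat
families in the background, indel divergence within hallmark copies
(substitutions only), nested or fragmented element insertions, and
sequencing gaps. The identity cut-offs and fold windows will need
species-specific adjustment on real data; every one of them is exposed
through `annotate_config()` / YAML.

## Numerical choices and edge cases

* Coordinates are 0-based half-open internally, 1-based inclusive in
  GFF3/BED output.
* The scanner's DP uses integer scores; ties in the best-cell choice
  resolve to the first cell in column-major order, making output
  byte-reproducible.
* Enumeration order and the branch-and-bound tie-break are total, so
  `best_folding()` is deterministic.
* R² on zero-variance data is defined as 1 when the residuals are also
  (numerically) zero, NA otherwise; flat-zero series fit to A ≈ 0 with
  degenerate amplitudes.
* Fitting with all starts failing returns the best grid start with
  `converged = FALSE`; `compare_models()` then prefers the converged
  model with a warning.
* Problem sizes in the checks — a 200 kb screen, 200 fold-oracle
  comparisons, 100-seed kinetics ensembles — were chosen so the full
  validation runs in minutes on one CPU while leaving the statistical
  assertions well-powered.

## Known limitations

* No thermodynamic folding: the descriptor checks architecture, not
  stability, and will accept a geometrically legal fold that real RNA
  would not adopt.
* No E-value model for hits; identity/length cut-offs are the only
  filters.
* The NAR-like class requires a user-supplied reference long element;
  without one, such elements are reported as SIDER1.
* Kinetic fits assume independent Gaussian noise on the cleaved
  fraction; gel quantification error is likely heteroscedastic.
* RNA degradation at high Mg²⁺ (which can inflate apparent cleavage) is
  not modelled; plateau values from such series should be read with the
  same caution the original measurements carry.
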