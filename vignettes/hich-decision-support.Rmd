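---
title: "Explainable decision support for hypertensive intracerebral hemorrhage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explainable decision support for hypertensive intracerebral hemorrhage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hichds)
```

## The problem

Hypertensive intracerebral hemorrhage (HICH) is an emergency in which the
first hours decide outcomes. The clinical information needed to plan care —
consciousness level, pupils, airway, blood pressure, hematoma location and
volume, midline shift, ventricular involvement, relevant history — arrives as
free-text notes and CT reports. `hichds` implements a complete desk-scale
pipeline that turns such text into an explainable treatment plan:

1. **Named entity recognition (NER)**: a neural sequence labeler locates and
   types the decision-relevant spans.
2. **Knowledge-graph normalization**: surface mentions are aligned to
   canonical entities of a provenance-tagged medical triple store, and
   numeric values are parsed with their units.
3. **Weighted rule engine**: the normalized patient state is mapped to a
   four-branch plan (diagnostic / surgical / rescue / drug), where every item
   carries machine-readable bases — the fired rules, their filled explanation
   text, and the supporting knowledge-graph triples with citations.
4. **Evaluation**: entity-level precision/recall/F1, ROC/AUC, Cohen's kappa,
   and a configurable 100-point plan rubric.

Because real HICH records cannot be shipped, the package includes a
first-class synthetic EMR generator, so the entire system is reproducible and
testable from a seed.

## The synthetic data generator

A `patient_profile` is sampled from a prevalence configuration
(`profile_config()`): age, sex, GCS, blood pressure, pupils, airway, SpO2,
hematoma location/volume, midline shift, ventricular findings, history and
suspicion flags. Clinically linked fields are sampled conditionally — airway
and pupil states depend on the GCS band, SpO2 on the airway, volume on the
compartment (log-normal with location-specific scale), midline shift on
volume. Every profile satisfies hard invariants (GCS 3–15, age 10–80,
non-negative volume and shift, SpO2 0–100).

The default prevalences describe a plausible emergency-room case mix (deep
supratentorial bleeds dominate, ~84% hypertensive) and are calibrated so that
roughly a third of profiles meet the default surgical criteria (30.7%
measured over 2,000 profiles at the shipped defaults). That balance is a test-design
choice — both plan branches must be exercised — not an epidemiological claim.

Rendering builds the note token-by-token from templates and phrase tables, so
BIO tags are correct by construction. Twelve entity types cover the clinical
and CT manifestations (chief complaint, vital signs, GCS, pupils, airway,
location, nature) and the quantitative hematoma parameters (volume, midline
shift, ventricular findings), plus history and suspicion items; the tag
alphabet is configuration, not a constant. Age and sex travel as structured
header fields, as they would in a real EMR.

Corruption injects exactly what the preprocessor is specified to undo:

* **Misspellings** — one random character edit per hit token, accepted only
  if the edit-distance-1 corrector uniquely maps it back to the original.
  This keeps the corrupter/preprocessor pair an exact inverse, which the
  suite tests as a property.
* **Abbreviations** — registered single-token pairs (e.g.
  hypertension ↔ HTN). Restricting to single tokens keeps corruption strictly
  1:1 per token, so tags never move. Multi-token acronyms like "GCS" are
  canonical surface forms resolved by the knowledge-graph synonym table
  instead.

Notes are English: the architecture is language-agnostic and an English
template bank keeps the repository self-contained. Synthetic prose is
deliberately schematic — it does not emulate negation scope, anaphora,
contradictory reports, or free-order clinical narrative. Passing tests
therefore demonstrate architectural and plumbing fidelity, not performance on
real clinical text.

Gold plans are derived from the clean profile through the same default
ruleset the pipeline applies. This circularity is deliberate and prominent:
the closed-loop benchmark measures extraction and normalization fidelity, not
clinical truth.

## The NER stack

Seven variants are composable from four blocks, named by application order
and always terminated by a CRF: `idcnn-crf`, `bilstm-crf`,
`bilstm-idcnn-crf`, `bert-crf`, `bert-idcnn-crf`, `bert-bilstm-crf`,
`bert-idcnn-bilstm-crf`.

**Attention.** The pretrained encoder uses standard scaled dot-product
attention, `softmax(QKᵀ/√d_k)V` (`attention()`); each output row is a convex
combination of value rows and each weight row sums to 1.

**The pretrained encoder.** A small transformer (default 2 layers, 2 heads,
dimension 64; the shipped experiments use 32) pretrained with a masked
language model objective on the working corpus, then fine-tuned end-to-end
inside the NER model. This is a desk-scale stand-in for a large pretrained
contextual encoder: the architecture and training objective are the same,
the capacity is not. Two numerical choices matter. Token embeddings are
initialized an order of magnitude larger than the additive sinusoidal
position code (0.3 vs 0.1 scale) so lexical identity dominates the input.
And the encoder output passes through a final layer normalization — without
it the residual stream's growing scale saturates any recurrent stack placed
on top (we observed exactly this failure: `bert-crf` trains while
`bert-bilstm-crf` stalls; normalization resolves it).

**Dilated convolutions.** Kernel-3 stacks with the doubling dilation
schedule 1, 2, 4, giving receptive field 2^(l+1) − 1 at layer l (3, 7, 15);
`receptive_field()` computes the exact count of influencing input positions
by support enumeration, which the tests verify independently. The stack
output is layer-normalized for the same reason as the encoder's.

**BiLSTM.** Standard gated recurrence: logistic input/forget/output gates on
`[h_prev, u_t]`, tanh candidate state, `C_t = f∘C_{t−1} + i∘C̃_t`,
`h_t = O_t∘tanh(C_t)` (`lstm_step()` exposes a single step for arithmetic
checks; training uses a fused-gate sequence implementation with a forget-gate
bias of 1).

**CRF.** A linear-chain CRF with learned transition and boundary
(start/stop) scores. The partition function is computed by the forward
recursion in log space; decoding is Viterbi with ties broken toward the
lowest tag index at the latest differing position (first-argmax
backtracking). Training minimizes the exact negative log-likelihood with
gradients from the forward–backward marginals. The suite checks partition,
normalization, and Viterbi against brute-force enumeration over all tag
sequences (length ≤ 5, alphabet ≤ 4, tolerance 1e−8).

All layers are implemented in vectorized base R with hand-derived gradients;
every gradient is verified against finite differences in the test suite.
Training is per-sentence Adam (default learning rate 0.01, 8 epochs) with
the best checkpoint chosen by dev-set entity F1. Defaults were chosen for
stability across all seven compositions; the deepest variant is the
slowest starter, which is why the default epoch count is 8 rather than the
3–4 the shallow variants need. No claim is made about matching any
particular convergence curve beyond reaching a plateau.

## The knowledge graph

The seed graph (~140 triples, shipped as editable TSV data) spans three
knowledge dimensions: *general* (canonical entities and their surface
synonyms), *subdomain* (the treatment-plan taxonomy), and
*subdomain-specific* (weight-system indication links, every one carrying a
source citation string). Queries are conjunctive basic graph patterns with
variable joins — the only query class the decision engine needs — and results
are returned in deterministic sorted order. Entity alignment tries an exact
synonym hit (after lowercasing and stripping laterality) before falling back
to maximum character-bigram Dice similarity over typed candidates with a
threshold (default 0.8), ties broken lexicographically. The graph schema and
scope are a reconstruction from the domain's structure; the synonym table is
co-designed with the synthesizer's phrase tables and the suite asserts full
coverage.

## The decision engine

A `patient_state` carries, per field, the value, its source span (or
"structured input"), the aligned knowledge-graph entity, and a confidence
flag (explicit / inferred / missing). Normalization processes mentions in
document order; duplicate conflicting values resolve in favor of the later
mention (CT reports supersede triage notes) and are logged. Flag-type fields
(history, suspicion, ventricular findings) are closed-world: no mention in a
non-empty document means `FALSE` with confidence "inferred"; an empty mention
list leaves everything missing. Unparseable numerics become missing with a
warning, never an error. Numeric/unit expressions (mL, mm, mmHg, %,
systolic/diastolic pairs) are parsed by pattern normalization in the engine,
not the store.

Rules are data (YAML): an antecedent conjunction over declared state fields
(threshold comparisons, category and flag tests, missingness tests), a
non-negative point weight, consequent plan items, a tier, a source citation,
and a basis template with `{field}` slots. An item activates when the summed
points of its fired rules reach the item's activation threshold (default 1
point), so the shipped ruleset behaves as crisp rules until weights are
edited — the fractional-weight vascular-imaging rules (0.5 + 0.5) are the
worked example of genuine weight pooling. Whether such weights should be
continuous scores or crisp thresholds is genuinely open; the point semantics
keeps default behavior auditable while leaving the dial exposed.

The default ruleset **R0 is a reconstruction** of the guideline tradition,
not a transcription of any published weight table: supratentorial volume
≥ 30 mL or midline shift ≥ 5 mm for surgical evacuation; cerebellar ≥ 10 mL
or ventricular compression; brainstem conservative by default (a weight-0
rule that still fires, so a negative surgical indication cites its reason);
GCS ≤ 8 for airway clearance, intubation and stress-ulcer prophylaxis;
SpO2 < 92% for ventilation; SBP ≥ 150 mmHg for antihypertensives; volume,
shift, GCS ≤ 12 or ventricular compression for ICP-lowering therapy;
coagulopathy history for the coagulation panel; suspicion flags or an
atypical profile (age < 45, lobar, no hypertension) for vascular imaging.
Missing-data rules keep the all-missing state on a minimal safe plan
(repeat head CT + vital-sign monitoring). Plan coherence invariants
(intubation ⇒ airway clearance, CPR ⇒ monitoring) are enforced by an
idempotent closure that attaches implication bases.

Surgical indication is monotone non-decreasing in hematoma volume and
midline shift by construction (volume and shift appear only under `≥` in
surgical antecedents), and the suite tests this as a property over random
states, along with determinism (identical state and ruleset give identical
plans), explanation completeness (every basis replays true on its state),
and missing-data safety (dropping any single field never drops vital-sign
monitoring).

## Evaluation

The plan rubric awards 15 points to diagnostic measures and 85 to
therapeutic measures, split 40 (surgical) + 35 (rescue) + 10 (drug).
Surgery is all-or-nothing; within the other categories each decisive item
carries an equal share of the category maximum, awarded when prediction and
gold agree on the item (both present or both absent). Per-item shares are a
design decision — the category maxima and score bins are fixed, equal shares
are the neutral default, and `rubric_config()` exposes them. Score
distributions use the <60% / 60–80% / >80% bins with the interior bin closed
on both ends.

Binary plan decisions are evaluated with the positive-event convention:
repeat head CT, surgical intervention, airway clearance, and ICP-lowering
treatment count as positives. AUC uses the Mann–Whitney rank formulation
with ties counted ½; because a binary decision needs a graded score, the
engine's summed rule weight serves as the ROC score. Cohen's kappa uses the
standard marginal-product chance correction. Metrics are reported on the
0–100 scale to two decimals with round-half-up; internal values keep full
precision. Degenerate branches (the always-selected repeat head CT has one
class in synthetic gold) report `NA` rather than a fabricated number.

## Problem sizes and reproducibility

The shipped experiments use: a 500-document corpus (2% misspelling, 10%
abbreviation) split 350/50/100 for the trained-NER recovery runs at reduced
model size (dimension 32, hidden 24); 1,000 documents for the exact
closed-loop check; 200 random instances for the CRF enumeration oracle; and
a 3-seed median for the stochastic recovery claims. At these sizes the full
suite and the acceptance script each run comfortably on a single CPU. Every
stochastic stage is seeded, plan JSON serialization is canonical, and
repeated runs are byte-identical — also a tested property.

## Known limitations

* Synthetic notes are schematic English; nothing here measures performance
  on real clinical narrative, Chinese-language records, or ambiguous EMRs.
* The encoder is a miniature; its pretraining corpus is the working corpus
  itself, so it demonstrates the mechanism, not transfer.
* R0's thresholds are a guideline-tradition reconstruction and are meant to
  be edited; the rubric's per-item shares are likewise configuration.
* Gold plans share the ruleset with the pipeline (deliberate circularity):
  end-to-end scores measure extraction and plumbing, not clinical validity.
* No dosing, surgical-approach selection, prognosis, or CT image analysis.
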