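---
title: "Diagnosis as an information content entity: the rtdx model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosis as an information content entity: the rtdx model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtdx)
```

## The model and its assumptions

`rtdx` treats a diagnostic assertion as an information content entity (ICE):
content that exists only through material concretizations and whose
correctness is a matter of *aboutness* toward a configuration — an organism,
a disease inhering in it, and a type the disease instantiates, anchored in
time. Two levels of aboutness are evaluated separately. At the level of
*reference* an assertion succeeds for each mentioned referent that exists;
at the level of *compound expression* it succeeds only if the entire
configuration holds as asserted. Reference failure entails compound failure
(a configuration cannot consist of what does not exist), but not conversely:
a misdiagnosis is exactly an assertion that keeps reference-level aboutness
to at least one referent while failing as a compound.

Three modelling commitments shape everything else:

* **Closed world within a knowledge base.** A scenario KB is taken to
  enumerate all relevant particulars, so "does this referent exist?" is
  decidable by lookup. A nonexistent organism or disease is simply an
  identifier the KB never declares. Nonexistent *types* are different: they
  are declared with `exists = FALSE` (think *dropsy*), so assertions
  mentioning them stay parseable while reference toward them fails. Only
  temporal entailment is ever three-valued.
* **Intention is data, not inference.** Which configuration an assertion is
  *intended* to be about is recorded in its content (`intended_target`),
  never computed from the text. This is why a misrepresentation relation can
  be derived at all: misrepresentation is being intended to be about a
  target while failing to be about it, and it is derived only toward the
  recorded target, never toward arbitrary configurations.
* **ICE identity is by minted identifier, not sentence text.** Two authors
  writing the same words create two ICEs; a verbatim copy creates none.
  `copy_concretization()` and `derive_new_ice()` are the only two ways a new
  representation enters a world, and the classifier reads hearsay off that
  provenance rather than off any linguistic cue ("so-and-so said" is not
  parsed).

## Temporal semantics

Spacetime anchoring is reduced to temporal regions; spatial location is not
modelled (every worked check in the source material is temporal). The seven
constraint relations are given endpoint semantics in the point algebra over
$\{<, \le, =\}$:

| relation | endpoint conditions | notes |
|---|---|---|
| `equals` | $a^- = b^-$, $a^+ = b^+$ | |
| `during` | $b^- \le a^-$, $a^+ \le b^+$ | contained-in; endpoints may coincide |
| `contains` | converse of `during` | |
| `ends` | $a^+ = b^+$, $b^- < a^-$ | proper final segment |
| `starts` | $a^- = b^-$, $a^+ < b^+$ | proper initial segment |
| `before` | $a^+ < b^-$ | strict precedence |
| `overlaps` | $a^- < b^- < a^+ < b^+$ | proper partial overlap |

`during` must include coincident endpoints: a declared "`t16` ends `t11`"
is required to entail "`t16` during `t11`", and a declared containment must
leave `equals` undecided rather than refuted. Both behaviours are pinned by
tests against a brute-force oracle that enumerates endpoint assignments on
an integer timeline of length $2n$ (long enough to realize every ordering
of $2n$ endpoints). Entailment itself is decided on the strictness-tracking
transitive closure of the endpoint graph: `holds` when the query's endpoint
conditions are all entailed, `fails` when adding them makes the network
inconsistent, `indeterminate` otherwise. This fragment of the point algebra
(no $\ne$) is convex, where transitive closure is complete; the oracle
batteries in the test suite check agreement on hundreds of random networks.
Enumeration cost restricts the oracle (not the engine) to networks of four
intervals or fewer; the engine itself has no such limit.

The timing condition of compound aboutness — the assertion must refer to
*some part* of the time occupied by the configuration, not its entirety — is
implemented as entailed strict intersection: the two regions must share more
than a boundary instant ($a^- < b^+$ and $b^- < a^+$). Sharing a single
boundary point (`ends`/`starts` adjacency across regions) was judged too
degenerate to count as "the patient had the disease then". An
`indeterminate` timing verdict propagates to an `indeterminate`
classification rather than defaulting to misdiagnosis: unknown timing is not
evidence of misplacement.

## The classifier and its tie-breaks

`classify_assertion()` is a fixed cascade; order resolves the genuinely
ambiguous cases:

1. If no mentioned referent exists, the assertion is `non_ice` — it is not
   about anything even at the level of reference.
2. If the assertion is tokened by a *copied* concretization, it is
   `hearsay_copy`, regardless of content correctness. Because the copy
   concretizes the original ICE, "the ICE" and "the assertion as tokened"
   can disagree; the optional `via` argument names the concretization under
   test, and the category describes the token. Classifying the same ICE
   through its original concretization still yields its own category.
3. A nonexistent *organism* short-circuits the diagnosis/misdiagnosis
   dichotomy entirely: with no patient there could not have been a clinical
   picture, so the assertion is routed to the non-diagnostic categories
   (still an ICE when the type exists — "James Bond has influenza").
4. Produced by a diagnostic process: `correct_diagnosis` /` misdiagnosis` /
   `indeterminate` according to compound aboutness. A diagnostic process
   requires among its inputs a clinical picture *and* a knowledge aggregate
   pairing at least one disease type with at least one phenotype type. The
   pairing is explicit data in the aggregate — no medical knowledge source
   is consulted — and a prior diagnosis counts wherever it appears (inside
   the clinical picture's `inferred_from` or alongside it among the process
   inputs; both readings are accepted, since neither is privileged).
5. Otherwise: `justified_conclusion` when a prior diagnosis (an ICE whose
   own producing process was diagnostic) was among the inputs,
   `lucky_guess` when nothing epistemically relevant was. Their
   misinformation counterparts are reported as the same base category with
   the failure modes in the rationale trail, not as separate categories —
   the `failure_modes` field is reserved for `misdiagnosis` and `non_ice`,
   where the typology is load-bearing.

One contract required a choice: the stated invariant "failure modes are
empty exactly on the benign categories" cannot hold for `indeterminate`,
which arises precisely when no mode is entailed. `rtdx` keeps
`failure_modes` empty on `indeterminate` and enforces non-emptiness only for
`misdiagnosis` and `non_ice`.

`check_precision()` is deliberately a warning, not a failure mode: how
specific a type must be to treat a patient is a clinical judgement, so the
"too general" stratum is a configuration knob with the hierarchy root as its
only default member.

## Fixtures and the synthetic generator

`build_scenario(1)` reproduces the reference tuple tables for the correct-
diagnosis scenario in full. Scenarios 2–6 are reconstructed from the main
text: their identifier ranges (IUI-23..33, IUI-43..53, IUI-63/68/71,
IUI-88/89) follow the reference account, whose supplementary tables were not
available, so the connecting tuples mirror Scenario 1's structure and the
remaining identifiers are documented placeholders. Two reconstructions are
substantive: every diagnostic process is given a knowledge-aggregate input
(the aggregate requirement is introduced with Scenario 4 but applies to the
diagnostic process generally), and aggregates pair diabetes with a
placeholder phenotype type (`UUI-3`, hyperglycemia), since the reference
aggregate row mentions associated phenotype types without naming them.
Scenario 5 ships in two variants — belief-derived (`justified_conclusion`)
and verbatim-copy (`hearsay_copy`) — because both are analyzed.

`random_scenario()` generates worlds whose classification labels are known
*by construction*: each case picks one of the four provenance routes and,
at the configured `fault_rate`, exactly one injected failure mode, and the
expected category follows from the build rules, never from the classifier.
Its defaults are the fixture world's conditions: types exist unless a fault
says otherwise, each case carries one organism/disease/type configuration,
and assertions are anchored at a region constrained to end the producing
process and fall within the disease's existence. Representations in random
worlds are inscriptions, not cognitive representations, so the generator
does not exercise the cognitive-system part-hood invariant (the fixtures
do). It also does not emulate volume or noise realism — no EHR-scale
populations, no garbled copies, no contradictory assertion streams — so a
green random-world battery establishes classifier/label agreement under
single faults, not robustness to messy real-world data.

## Serialization choices

JSON is the canonical tuple dialect (the TSV view is lossy). Serialization
is canonical — collections sorted by identifier, then relation — so equal
KBs produce identical bytes and round-trips are the identity; this is also
what makes insertion-order invariance testable end to end. Writing refuses
an inconsistent KB with the violation list rather than persisting it. The
OWL export targets representational fidelity, not DL reasoning: aboutness
toward particulars is asserted existentially at the instance level;
aboutness toward types uses an annotation property (object properties
cannot target classes); misrepresentation is a distinct object property;
and no universally-quantified ("only") aboutness is ever emitted, since
universal quantification over aboutness targets contradicts reference-level
aboutness. No pre-installed RDF parser exists in the test environment, so
the exported Turtle is checked by a small structural validator plus the
grep-level absence of `allValuesFrom`/`only`.

## Known limitations

Differential diagnosis, diagnoses of disorders/disease courses/health, and
incidence estimation of error subtypes are out of scope. Whether a
representation is about the inherence relation itself as a fourth
reference-level target is unsettled; only the three referents are scored.
Partially garbled copies are assumed faithful. Which anatomical entity
bears a cognitive representation is left open: any declared particular is
accepted as bearer, with only the part-of-a-cognitive-system assertion
required. The temporal algebra covers the seven named relations, not the
full thirteen-relation interval algebra; no scenario requires the rest.
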