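# rtdx: a Referent Tracking engine for diagnostic assertions

Clinical data systems routinely store a diagnosis as a bare code, losing the
distinctions between a correct diagnosis, a misdiagnosis, a coincidentally
correct statement, and a copied assertion. Those distinctions matter for data
quality in electronic health records: "patient X has disease type Y" can fail
in several structurally different ways, and whether it was produced by a
diagnostic process or merely transcribed changes what kind of information it
is. `rtdx` makes those distinctions computable. It is aimed at biomedical
ontologists and EHR data-quality researchers who want an executable,
realism-based model of what diagnostic assertions are about.

## The model

The engine is a Referent Tracking tuple store. Every concrete individual (a
patient, a disease instance, a process, an ink pattern) gets an *instance
unique identifier* `IUI-n`; every repeatable type gets a *universal unique
identifier* `UUI-n`, which may be flagged as not existing in reality (e.g.
*dropsy*). Assertions — instantiation, particular-to-particular relations,
and negative ("lacks") assertions — are indexed to temporal regions `tn`,
related by a seven-relation qualitative constraint vocabulary (`equals`,
`during`, `contains`, `ends`, `starts`, `before`, `overlaps`) with
three-valued entailment (`holds` / `fails` / `indeterminate`).

A diagnostic assertion is an **information content entity (ICE)**: content
that exists only through *concretizations* (a cognitive representation in
someone's head, an ink pattern on paper, bits in memory). Its truth-maker is
a **configuration**: the organism `o`, its disease `d`, and a type `U`, tied
together by `inheres_in(d, o)` and `instance_of(d, U)` and anchored in time.
Aboutness is evaluated at two levels:

* **reference** — does each mentioned referent (organism, disease, type)
  exist? An assertion about *something* is an ICE even when it is wrong.
* **compound expression** — does the whole asserted configuration hold:
  all referents exist, the disease inheres in the organism and instantiates
  the asserted type, and the asserted time overlaps the configuration's?

A representation intended to be about a configuration but failing compound
aboutness *is-misrepresentation-of* it. The classifier then combines
aboutness with provenance. A **diagnostic process** must take as input both a
clinical picture of the patient and an aggregate of disease-type/phenotype-
type representations (so a seer's horoscope reading does not qualify, while
an expert system does — nothing requires the agent to be human). The
categories are: `correct_diagnosis`, `misdiagnosis` (with a six-mode failure
typology: wrong-but-existing type, nonexistent type, nonexistent disease,
nonexistent organism, wrong bearer, spacetime misplacement), `lucky_guess`,
`justified_conclusion`, `hearsay_copy` (a copied concretization concretizes
the *original* ICE — no new ICE comes into being), `non_ice`, and
`indeterminate` (unresolved timing).

## A worked example

Scenario 3 of the bundled fixtures: the patient's type 2 diabetes mellitus is
asserted to be type 1 diabetes mellitus.

```r
library(rtdx)
s3 <- build_scenario(3)
classify_assertion(s3$kb, s3$ice)
#> $category       : "misdiagnosis"
#> $failure_modes  : "NONINST_TYPE_EXISTS"
#> $fails_first    : "compound"
#> $rationale      : "diagnostic_process_holds" "compound_aboutness_fails"
#>                   "mode:NONINST_TYPE_EXISTS"
```

The assertion came from a genuine diagnostic process, but its compound
aboutness fails because the disease instantiates a different (existing) type
than stated — so it is a misdiagnosis, and the failure is first visible at
the level of compound expression, not reference. The derived aboutness
relations show the same structure: the physician's cognitive representation
is still about the patient, the disease, and the (wrong) type individually,
while misrepresenting the configuration `IUI-7`:

```r
infer_aboutness_relations(s3$kb, "IUI-46")
#>   subject                relation object  at
#> 1  IUI-46                is_about  IUI-1 t46
#> 2  IUI-46                is_about  IUI-2 t46
#> 3  IUI-46                is_about  UUI-2 t46
#> 4  IUI-46 is_misrepresentation_of  IUI-7 t46
```

Knowledge bases round-trip through a versioned JSON tuple format
(`write_rt()` / `read_rt()`, canonical bytes), export to Turtle or OWL
functional syntax (`export_owl()`, aboutness kept existential; type-level
aboutness as annotations), and are scriptable through the CLI
(`inst/cli/rtdx`): `classify`, `validate`, `scenario`, `perturb`, `export`.

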