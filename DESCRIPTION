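Package: rtdx
Title: Referent Tracking Engine for Diagnostic Assertions
Version: 0.1.0
Authors@R:
    person("rtdx", "maintainers", email = "rtdx@example.org", role = c("aut", "cre"))
Description: A realism-based knowledge-base engine for clinical diagnostic
    assertions. Implements a Referent Tracking tuple store with temporally
    indexed instantiation, relation and negative assertions over particulars
    (IUIs) and universals (UUIs); a three-valued qualitative temporal
    entailment over interval constraints; a two-level aboutness evaluator
    (reference vs. compound expression) that derives is-about and
    is-misrepresentation-of relations; provenance tracking that distinguishes
    copying a concretization from creating a new information content entity;
    and a classifier that labels a diagnostic assertion as correct diagnosis,
    misdiagnosis (with a six-mode failure typology), lucky guess, hearsay,
    justified layperson conclusion, or non-ICE. Ships builders for six worked
    scenarios, a versioned tuple file format (JSON canonical, TSV view), an
    RDF/OWL exporter, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
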