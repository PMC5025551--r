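test_that("a diagnostic process needs a clinical picture and a knowledge aggregate", {
  s1 <- build_scenario(1)
  expect_identical(is_diagnostic_process(s1$kb, "IUI-11"), "holds")
  # writing the note is a process, but not a diagnostic one
  expect_identical(is_diagnostic_process(s1$kb, "IUI-13"), "fails")
  s4 <- build_scenario(4)
  expect_identical(is_diagnostic_process(s4$kb, "IUI-71"), "fails")
  s6 <- build_scenario(6)
  expect_identical(is_diagnostic_process(s6$kb, "IUI-111"), "holds")
  expect_false(s6$kb$processes[["IUI-111"]]$agent_is_human)
  expect_error(is_diagnostic_process(s1$kb, "IUI-404"), "declaration error")
})

test_that("failure modes match the six-mode typology, with fails-first levels", {
  s1 <- build_scenario(1)
  s3 <- build_scenario(3)

  fm <- classify_failure_modes(s3$kb$ices[["IUI-48"]]$content, s3$kb)
  expect_identical(fm$modes, "NONINST_TYPE_EXISTS")
  expect_identical(fm$fails_first, "compound")

  # the doctor ascribes the disease to the patient's twin
  kb <- kb_add(s1$kb, rt_region("t50"))
  kb <- kb_add(kb, rt_particular("IUI-50", "the twin", "t50"))
  twin <- kb$ices[["IUI-8"]]$content
  twin$asserted_organism <- "IUI-50"
  fm2 <- classify_failure_modes(twin, kb)
  expect_identical(fm2$modes, "NON_INHERENCE")
  expect_identical(fm2$fails_first, "compound")

  # a true disease anchored five years before onset
  kb3 <- kb_add(s1$kb, rt_region("t60"))
  kb3 <- kb_add(kb3, rt_constraint("t60", "before", "t2"))
  early <- kb3$ices[["IUI-8"]]$content
  early$asserted_anchor <- "t60"
  fm3 <- classify_failure_modes(early, kb3)
  expect_identical(fm3$modes, "SPACETIME_MISPLACEMENT")
  expect_identical(fm3$fails_first, "compound")

  fm4 <- classify_failure_modes(s1$kb$ices[["IUI-8"]]$content, s1$kb)
  expect_identical(fm4$modes, character(0))
  expect_identical(fm4$fails_first, "none")
})

test_that("single-fault perturbations of the correct scenario partition into the six modes", {
  s1 <- build_scenario(1)
  base <- s1$kb$ices[["IUI-8"]]$content

  # enumerate every single-field edit touching the configuration: each must
  # trigger exactly one mode, and together they must cover all six
  kb <- s1$kb
  kb <- kb_add(kb, rt_universal("UUI-2", "type 1 diabetes mellitus"))
  kb <- kb_add(kb, rt_universal("UUI-99", "dropsy", exists = FALSE))
  kb <- kb_add(kb, rt_region("t55"))
  kb <- kb_add(kb, rt_particular("IUI-55", "the twin", "t55"))
  kb <- kb_add(kb, rt_region("t99"))
  kb <- kb_add(kb, rt_constraint("t99", "before", "t2"))

  edits <- list(
    list(field = "asserted_type", value = "UUI-2",
         expect = "NONINST_TYPE_EXISTS"),
    list(field = "asserted_type", value = "UUI-99",
         expect = "NONINST_TYPE_NONEXISTENT"),
    list(field = "asserted_disease", value = "IUI-666",
         expect = "DISEASE_NONEXISTENT"),
    list(field = "asserted_organism", value = "IUI-777",
         expect = "ORGANISM_NONEXISTENT"),
    list(field = "asserted_organism", value = "IUI-55",
         expect = "NON_INHERENCE"),
    list(field = "asserted_anchor", value = "t99",
         expect = "SPACETIME_MISPLACEMENT"))

  seen <- character()
  reference_modes <- c("NONINST_TYPE_NONEXISTENT", "DISEASE_NONEXISTENT",
                       "ORGANISM_NONEXISTENT")
  for (e in edits) {
    content <- base
    content[[e$field]] <- e$value
    fm <- classify_failure_modes(content, kb)
    expect_identical(fm$modes, e$expect)
    expect_identical(fm$fails_first,
                     if (e$expect %in% reference_modes) "reference" else "compound")
    seen <- c(seen, fm$modes)
  }
  expect_setequal(seen, failure_modes())  # all six, no residue
})

test_that("the three nonexistence modes together collapse to non-ICE", {
  s1 <- build_scenario(1)
  kb <- kb_add(s1$kb, rt_universal("UUI-50", "spattergroit", exists = FALSE))
  # "Ron Weasley has spattergroit"
  kb$ices[["IUI-8"]]$content <- rt_content("IUI-800", "IUI-801", "UUI-50",
                                           "t16", "IUI-7")
  cl <- classify_assertion(kb, "IUI-8")
  expect_identical(cl$category, "non_ice")
  expect_true(all(c("ORGANISM_NONEXISTENT", "DISEASE_NONEXISTENT",
                    "NONINST_TYPE_NONEXISTENT") %in% cl$failure_modes))
  expect_identical(cl$fails_first, "reference")
})

test_that("a nonexistent organism never yields a diagnosis or misdiagnosis", {
  # "James Bond has influenza": still an ICE (the type exists), but with no
  # patient there is no clinical picture and hence no (mis)diagnosis
  s1 <- build_scenario(1)
  kb <- s1$kb
  kb$ices[["IUI-8"]]$content$asserted_organism <- "IUI-777"
  cl <- classify_assertion(kb, "IUI-8")
  expect_false(cl$category %in% c("correct_diagnosis", "misdiagnosis", "non_ice"))
  expect_true("mode:ORGANISM_NONEXISTENT" %in% cl$rationale)
})

test_that("a physician's coin flip is a lucky guess despite the correct content", {
  s1 <- build_scenario(1)
  kb <- s1$kb
  # strip the epistemic inputs from the diagnostic process
  proc <- kb$processes[["IUI-11"]]
  proc$inputs <- character()
  kb$processes[["IUI-11"]] <- proc
  cl <- classify_assertion(kb, "IUI-8")
  expect_identical(cl$category, "lucky_guess")
  expect_true("no_epistemically_relevant_input" %in% cl$rationale)
})

test_that("unresolved timing classifies as indeterminate, not misdiagnosis", {
  s1 <- build_scenario(1)
  kb <- kb_add(s1$kb, rt_region("t80"))
  kb$ices[["IUI-8"]]$content$asserted_anchor <- "t80"
  cl <- classify_assertion(kb, "IUI-8")
  expect_identical(cl$category, "indeterminate")
  expect_identical(cl$failure_modes, character(0))
})

test_that("correct diagnosis iff diagnostic process and compound aboutness hold", {
  set.seed(8002)
  for (seed in 1:40) {
    rs <- random_scenario(seed, n_particulars = 3L + seed %% 9L,
                          fault_rate = c(0, 0.5, 1)[seed %% 3 + 1])
    for (ice in names(rs$kb$ices)) {
      rec <- rs$kb$ices[[ice]]
      cl <- classify_assertion(rs$kb, ice)  # via = NULL: the ICE itself
      dp <- !is.null(rec$produced_by) &&
        is_diagnostic_process(rs$kb, rec$produced_by) == "holds"
      comp <- evaluate_compound(rec$content, rs$kb)$status
      expect_identical(cl$category == "correct_diagnosis",
                       dp && comp == "holds")
      if (cl$category == "misdiagnosis") {
        ref <- evaluate_reference(rec$content, rs$kb)
        expect_true(any(ref$per_referent == "holds"))
        expect_identical(comp, "fails")
        expect_gt(length(cl$failure_modes), 0L)
      }
      expect_identical(validate_record(cl), character(0))
    }
  }
})

test_that("unknown ICEs and dangling processes are declaration errors", {
  s1 <- build_scenario(1)
  expect_error(classify_assertion(s1$kb, "IUI-999"), "unknown ICE")
  kb <- s1$kb
  kb$ices[["IUI-8"]]$produced_by <- "IUI-555"
  expect_error(classify_assertion(kb, "IUI-8"), "declaration error.*IUI-555")
})

test_that("check_precision flags only too-general assertions", {
  hier <- data.frame(child = c("UUI-1", "UUI-2"), parent = c("UUI-10", "UUI-10"),
                     stringsAsFactors = FALSE)
  root_content <- rt_content("IUI-1", "IUI-2", "UUI-10", "t2", "IUI-7")
  leaf_content <- rt_content("IUI-1", "IUI-2", "UUI-1", "t2", "IUI-7")
  expect_match(check_precision(root_content, hier, root = "UUI-10"),
               "too general")
  expect_null(check_precision(leaf_content, hier, root = "UUI-10"))
  expect_match(check_precision(leaf_content, hier, root = "UUI-10",
                               too_general = "UUI-1"), "too general")
  expect_message(res <- check_precision(leaf_content, NULL, root = "UUI-10"),
                 "empty type hierarchy")
  expect_null(res)
})
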