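test_that("copying a concretization never creates a new ICE", {
  s1 <- build_scenario(1)
  kb <- s1$kb
  kb <- kb_add(kb, rt_region("t90"))
  kb <- kb_add(kb, rt_particular("IUI-89", "sentence in the letter", "t90"))
  n_ices <- length(kb$ices)

  # the daughter copies Dr. Smith's sentence word for word
  res <- copy_concretization(kb, "IUI-10", new_bearer = "IUI-89",
                             kind = "inscription_quality",
                             exists_during = "t90", id = "IUI-90")
  expect_identical(res$representation$concretizes, "IUI-8")
  expect_identical(res$representation$copied_from, "IUI-10")
  expect_length(res$kb$ices, n_ices)
  expect_true("IUI-90" %in% res$kb$ices[["IUI-8"]]$concretizations)

  # a copy of a copy still concretizes the original diagnosis
  kb2 <- kb_add(res$kb, rt_particular("IUI-91", "photocopy", "t90"))
  res2 <- copy_concretization(kb2, "IUI-90", new_bearer = "IUI-91",
                              kind = "inscription_quality", id = "IUI-92")
  expect_identical(res2$representation$concretizes, "IUI-8")
  expect_length(res2$kb$ices, n_ices)

  expect_error(copy_concretization(kb, "IUI-10", new_bearer = "IUI-404",
                                   kind = "inscription_quality"),
               "declaration error.*IUI-404")
})

test_that("authoring from belief mints exactly one new ICE", {
  s5 <- build_scenario(5, variant = "belief")
  # the daughter's conclusion is a new ICE distinct from the diagnosis
  expect_true("IUI-88" %in% names(s5$kb$ices))
  expect_true("IUI-8" %in% names(s5$kb$ices))
  expect_false(identical(s5$kb$ices[["IUI-88"]]$content,
                         NULL))
  expect_identical(s5$kb$representations[["IUI-86"]]$concretizes, "IUI-88")

  # two authors, same sentence text, different processes: two ICEs
  kb <- s5$kb
  n <- length(kb$ices)
  kb <- kb_add(kb, rt_region("t95"))
  kb <- kb_add(kb, rt_particular("IUI-95", "the brother", "t95"))
  kb <- kb_add(kb, rt_particular("IUI-96", "his reply", "t95"))
  kb <- kb_add(kb, rt_process("IUI-97", agent = "IUI-95", occupies = "t95"))
  content <- rt_content("IUI-1", "IUI-2", "UUI-1", "t95", "IUI-7")
  first <- rt_representation("IUI-98", kind = "inscription_quality",
                             bearer = "IUI-96", exists_during = "t95")
  res <- derive_new_ice(kb, author = "IUI-95", process = "IUI-97",
                        content = content, first_concretization = first,
                        id = "IUI-99")
  expect_length(res$kb$ices, n + 1L)
  expect_identical(res$ice$produced_by, "IUI-97")
  expect_true("IUI-99" %in% res$kb$processes[["IUI-97"]]$outputs)
  expect_identical(res$ice$first_concretized_at, "t95")

  # a representation that already concretizes something cannot found an ICE
  expect_error(derive_new_ice(res$kb, "IUI-95", "IUI-97", content,
                              res$kb$representations[["IUI-98"]]),
               "already concretizes")
  expect_error(derive_new_ice(res$kb, "IUI-95", "IUI-97",
                              content = list(text = "Dad is ill"),
                              first_concretization = first),
               "validation error")
})

test_that("ICE counting laws hold across random copies and derivations", {
  set.seed(31)
  rs <- random_scenario(31, n_particulars = 12L)
  kb <- rs$kb
  reps <- names(kb$representations)
  for (i in 1:10) {
    n <- length(kb$ices)
    src <- sample(reps, 1L)
    bearer <- kb$representations[[src]]$bearer
    res <- copy_concretization(kb, src, new_bearer = bearer,
                               kind = "inscription_quality")
    kb <- res$kb
    expect_length(kb$ices, n)
  }
})

test_that("conformance is concretizing the same ICE, and is an equivalence", {
  s2 <- build_scenario(2)
  expect_true(check_conformance(s2$kb, "IUI-10", "IUI-6"))
  expect_true(check_conformance(s2$kb, "IUI-30", "IUI-26"))
  # Dr. Smith's inscription and Dr. Brown's cognitive representation
  # concretize different diagnoses (IUI-8 vs IUI-28)
  expect_false(check_conformance(s2$kb, "IUI-10", "IUI-26"))
  expect_true(check_conformance(s2$kb, "IUI-10", "IUI-10"))
  expect_error(check_conformance(s2$kb, "IUI-10", "IUI-404"),
               "declaration error")

  # symmetry and transitivity over every representation pair
  reps <- names(s2$kb$representations)
  for (a in reps) for (b in reps) {
    expect_identical(check_conformance(s2$kb, a, b),
                     check_conformance(s2$kb, b, a))
    for (cc in reps) {
      if (check_conformance(s2$kb, a, b) && check_conformance(s2$kb, b, cc))
        expect_true(check_conformance(s2$kb, a, cc))
    }
  }
})

test_that("every ICE in a consistent KB is concretized and listed by its process", {
  for (n in 1:6) {
    kb <- build_scenario(n)$kb
    for (ice in kb$ices) {
      expect_gt(length(ice$concretizations), 0L)
      if (!is.null(ice$produced_by))
        expect_true(ice$id %in% kb$processes[[ice$produced_by]]$outputs)
    }
  }
})
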