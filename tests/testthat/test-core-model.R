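test_that("identifier namespaces are disjoint and enforced by constructors", {
  expect_error(rt_particular("UUI-1", "x", "t1"), "invalid IUI")
  expect_error(rt_universal("IUI-1"), "invalid UUI")
  expect_error(rt_region("IUI-1"), "invalid temporal identifier")
  expect_error(rt_particular("IUI-1", "x", "IUI-2"), "invalid temporal identifier")
  expect_error(rt_constraint("t1", "meets", "t2"), "unknown temporal relation")
  expect_error(rt_relation("IUI-1", "likes", "IUI-2", "t1"), "unknown relation")
  # aboutness may target a universal, other relations may not
  expect_silent(rt_relation("IUI-6", "is_about", "UUI-1", "t6"))
  expect_error(rt_relation("IUI-6", "inheres_in", "UUI-1", "t6"),
               "must target an IUI")
})

kb_jones <- function() {
  kb <- rt_kb()
  kb <- kb_add(kb, rt_region("t1"))
  kb <- kb_add(kb, rt_region("t2"))
  kb <- kb_add(kb, rt_universal("UUI-1", "type 2 diabetes mellitus"))
  kb <- kb_add(kb, rt_universal("UUI-2", "type 1 diabetes mellitus"))
  kb <- kb_add(kb, rt_particular("IUI-1", "Mr. Adam Jones", "t1"))
  kb <- kb_add(kb, rt_particular("IUI-2", "IUI-1's disease", "t2"))
  kb
}

test_that("make_configuration builds the organism-disease-type truth-maker", {
  kb <- kb_jones()
  cfg <- make_configuration(kb, "IUI-1", "IUI-2", "UUI-1", "t2", id = "IUI-7")
  expect_s3_class(cfg, "rt_configuration")
  expect_identical(cfg$id, "IUI-7")
  expect_setequal(cfg$members_particulars, c("IUI-1", "IUI-2"))
  expect_identical(cfg$members_universals, "UUI-1")
  kinds <- vapply(cfg$constituent_relations, function(x) class(x)[1], character(1))
  expect_setequal(kinds, c("rt_relation", "rt_instantiation"))
  rel <- cfg$constituent_relations[[which(kinds == "rt_relation")]]
  expect_identical(rel[c("subject", "relation", "object", "at")],
                   list(subject = "IUI-2", relation = "inheres_in",
                        object = "IUI-1", at = "t2"))
  inst <- cfg$constituent_relations[[which(kinds == "rt_instantiation")]]
  expect_identical(inst$universal, "UUI-1")

  # a type 1 DM configuration is never structurally equal to IUI-7's
  cfg2 <- make_configuration(kb, "IUI-1", "IUI-2", "UUI-2", "t2", id = "IUI-70")
  expect_false(identical(cfg$constituent_relations, cfg2$constituent_relations))

  # deterministic: same inputs, structurally identical output
  expect_identical(cfg, make_configuration(kb, "IUI-1", "IUI-2", "UUI-1", "t2",
                                           id = "IUI-7"))

  expect_error(make_configuration(kb, "IUI-99", "IUI-2", "UUI-1", "t2"),
               "declaration error.*IUI-99")
  expect_error(make_configuration(kb, "IUI-1", "IUI-2", "UUI-9", "t2"),
               "declaration error.*UUI-9")
})

test_that("validate_record returns violations instead of raising", {
  expect_identical(validate_record(rt_particular("IUI-1", "Mr. Adam Jones", "t1")),
                   character(0))

  ice <- rt_ice("IUI-8",
                rt_content("IUI-1", "IUI-2", "UUI-1", "t2", "IUI-7"),
                concretizations = character(),
                first_concretized_at = "t2")
  v <- validate_record(ice)
  expect_length(v, 1L)
  expect_match(v, "no concretization")

  agg <- rt_aggregate("IUI-14", "IUI-3", disease_types = "UUI-1",
                      phenotype_types = character())
  v <- validate_record(agg)
  expect_length(v, 1L)
  expect_match(v, "unfit for diagnosis")
})

test_that("validate_record is idempotent and order-insensitive over a set", {
  ice <- rt_ice("IUI-8", rt_content("IUI-1", "IUI-2", "UUI-1", "t2", "IUI-7"),
                concretizations = character(), first_concretized_at = "t2")
  agg <- rt_aggregate("IUI-14", "IUI-3", phenotype_types = "UUI-3")
  p <- rt_particular("IUI-1", "x", "t1")
  v1 <- validate_record(list(ice, agg, p))
  v2 <- validate_record(list(p, agg, ice))
  expect_identical(v1, v2)
  expect_identical(v1, validate_record(list(ice, agg, p, ice, agg)))
  expect_length(v1, 2L)  # unconcretized ICE + aggregate missing disease types
})

test_that("classification invariants pair failure modes with category", {
  ok <- rt_classification("misdiagnosis", failure_modes = "NON_INHERENCE",
                          fails_first = "compound")
  expect_identical(validate_record(ok), character(0))
  bad <- rt_classification("lucky_guess", failure_modes = "NON_INHERENCE",
                           fails_first = "compound")
  expect_match(validate_record(bad), "no failure modes")
  bad2 <- rt_classification("misdiagnosis", fails_first = "compound")
  expect_match(validate_record(bad2), "at least one failure mode")
})

test_that("the failure-mode enumeration has exactly six modes", {
  expect_setequal(failure_modes(),
                  c("NONINST_TYPE_EXISTS", "NONINST_TYPE_NONEXISTENT",
                    "DISEASE_NONEXISTENT", "ORGANISM_NONEXISTENT",
                    "NON_INHERENCE", "SPACETIME_MISPLACEMENT"))
  expect_length(failure_modes(), 6L)
})
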