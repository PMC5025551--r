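test_that("kb_add enforces referential closure and is idempotent", {
  kb <- rt_kb()
  kb <- kb_add(kb, rt_region("t1"))
  kb <- kb_add(kb, rt_region("t2"))
  kb <- kb_add(kb, rt_particular("IUI-1", "Mr. Jones", "t1"))
  kb <- kb_add(kb, rt_particular("IUI-2", "his disease", "t2"))

  kb1 <- kb_add(kb, rt_relation("IUI-2", "inheres_in", "IUI-1", "t2"))
  expect_identical(nrow(kb_query(kb1, "IUI-2", "inheres_in")), 1L)

  # adding twice equals adding once
  kb2 <- kb_add(kb1, rt_relation("IUI-2", "inheres_in", "IUI-1", "t2"))
  expect_identical(kb1, kb2)

  expect_error(kb_add(kb, rt_relation("IUI-99", "part_of", "IUI-1", "t1")),
               "declaration error.*IUI-99")
  expect_error(kb_add(kb, rt_instantiation("IUI-1", "UUI-5", "t1")),
               "declaration error.*UUI-5")
  expect_error(kb_add(kb, rt_particular("IUI-1", "someone else", "t2")),
               "identifier collision")
})

test_that("queries filter exactly, with wildcards, as canonical sets", {
  s1 <- build_scenario(1)$kb
  ab <- kb_query(s1, "IUI-6", "is_about")
  expect_identical(nrow(ab), 4L)
  expect_setequal(ab$object, c("IUI-7", "IUI-1", "IUI-2", "UUI-1"))

  expect_identical(nrow(kb_query(s1, relation = "is_misrepresentation_of")), 0L)

  conc <- kb_query(s1, relation = "concretizes", object = "IUI-8")
  expect_setequal(conc$subject, c("IUI-6", "IUI-10"))

  # instantiations surface as instance_of rows
  inst <- kb_query(s1, "IUI-2", "instance_of")
  expect_identical(inst$object, "UUI-1")
})

test_that("entailment follows the worked constraint example", {
  # "t16 ends t11" entails containment in t11
  s1 <- build_scenario(1)$kb
  expect_identical(entails_temporal(s1, "t16", "during", "t11"), "holds")
  expect_identical(entails_temporal(s1, "t16", "equals", "t11"), "fails")
  # reflexivity for every declared region
  for (t in names(s1$temporal_regions))
    expect_identical(entails_temporal(s1, t, "equals", t), "holds")
})

test_that("three-valued verdicts distinguish refuted from unknown", {
  kb <- rt_kb()
  kb <- kb_add(kb, rt_region("t21"))
  kb <- kb_add(kb, rt_region("t11"))
  kb <- kb_add(kb, rt_constraint("t21", "during", "t11"))
  # frozen from the endpoint-enumeration oracle: containment refutes strict
  # precedence but leaves identity open
  expect_identical(entails_temporal(kb, "t21", "before", "t11"), "fails")
  expect_identical(entails_temporal(kb, "t21", "equals", "t11"), "indeterminate")
  expect_identical(entails_temporal(kb, "t11", "contains", "t21"), "holds")
  expect_error(entails_temporal(kb, "t21", "during", "t99"),
               "declaration error")
})

test_that("inconsistent networks raise an error naming a violating cycle", {
  kb <- rt_kb()
  for (t in c("t1", "t2")) kb <- kb_add(kb, rt_region(t))
  kb <- kb_add(kb, rt_constraint("t1", "before", "t2"))
  kb <- kb_add(kb, rt_constraint("t2", "before", "t1"))
  expect_error(entails_temporal(kb, "t1", "before", "t2"),
               "violating cycle.*t1.*t2")
  expect_match(check_consistency(kb), "temporal inconsistency")
})

test_that("entailment agrees with endpoint enumeration on random networks", {
  # a fast slice of the full acceptance battery (criterion 4 runs 500)
  set.seed(421)
  n_checked <- 0L
  for (i in 1:120) {
    n <- sample(2:4, 1L)
    net <- random_network(n, n)
    models <- oracle_models(net$tids, net$constraints)
    if (nrow(models$S) == 0L) {
      expect_error(entails_temporal(net$kb, net$tids[1], "equals", net$tids[1]),
                   "violating cycle")
      next
    }
    for (k in 1:4) {
      ab <- sample(net$tids, 2L)
      r <- sample(c("equals", "during", "contains", "ends", "starts",
                    "before", "overlaps"), 1L)
      expect_identical(entails_temporal(net$kb, ab[1], r, ab[2]),
                       oracle_entails(models, ab[1], r, ab[2]),
                       label = sprintf("net %d: %s %s %s", i, ab[1], r, ab[2]))
      n_checked <- n_checked + 1L
    }
  }
  # roughly a third of random networks are consistent; the rest exercise
  # cycle detection above
  expect_gt(n_checked, 100L)
})

test_that("adding a constraint only resolves indeterminacy, never flips verdicts", {
  set.seed(99)
  rels <- c("equals", "during", "contains", "ends", "starts", "before",
            "overlaps")
  for (i in 1:25) {
    net <- random_network(3, 2)
    base_ok <- !inherits(try(entails_temporal(net$kb, "t1", "equals", "t1"),
                             silent = TRUE), "try-error")
    if (!base_ok) next
    verdicts <- expand.grid(a = net$tids, b = net$tids, r = rels,
                            stringsAsFactors = FALSE)
    verdicts <- verdicts[verdicts$a != verdicts$b, ]
    before <- mapply(function(a, r, b) entails_temporal(net$kb, a, r, b),
                     verdicts$a, verdicts$r, verdicts$b)
    extra <- rt_constraint(sample(net$tids, 1),
                           sample(rels, 1),
                           sample(net$tids, 1))
    if (extra$subject == extra$object) next
    kb2 <- kb_add(net$kb, extra)
    still_ok <- !inherits(try(entails_temporal(kb2, "t1", "equals", "t1"),
                              silent = TRUE), "try-error")
    if (!still_ok) next  # the addition made the network inconsistent
    after <- mapply(function(a, r, b) entails_temporal(kb2, a, r, b),
                    verdicts$a, verdicts$r, verdicts$b)
    flipped <- (before == "holds" & after == "fails") |
      (before == "fails" & after == "holds")
    expect_false(any(flipped))
  }
})

test_that("check_consistency reports existence-interval and clash violations", {
  expect_identical(check_consistency(build_scenario(1)$kb), character(0))

  # an assertion anchored before the organism existed
  kb <- rt_kb()
  for (t in c("t1", "t2", "t99")) kb <- kb_add(kb, rt_region(t))
  kb <- kb_add(kb, rt_universal("UUI-1", "type 2 DM"))
  kb <- kb_add(kb, rt_particular("IUI-1", "Mr. Jones", "t1"))
  kb <- kb_add(kb, rt_particular("IUI-2", "his disease", "t2"))
  kb <- kb_add(kb, rt_constraint("t99", "before", "t1"))
  kb <- kb_add(kb, rt_relation("IUI-2", "inheres_in", "IUI-1", "t99"))
  v <- check_consistency(kb)
  expect_length(v, 1L)
  expect_match(v, "entailed disjoint from IUI-1's existence")

  # positive vs negative clash over entailed-overlapping (distinct) regions
  kb2 <- rt_kb()
  for (t in c("t1", "t2", "t3")) kb2 <- kb_add(kb2, rt_region(t))
  kb2 <- kb_add(kb2, rt_universal("UUI-1", "type 2 DM"))
  kb2 <- kb_add(kb2, rt_particular("IUI-1", "Mr. Jones", "t1"))
  kb2 <- kb_add(kb2, rt_particular("IUI-2", "his disease", "t2"))
  kb2 <- kb_add(kb2, rt_instantiation("IUI-2", "UUI-1", "t2"))
  kb2 <- kb_add(kb2, rt_relation("IUI-1", "bearer_of", "IUI-2", "t2"))
  kb2 <- kb_add(kb2, rt_constraint("t3", "equals", "t2"))
  kb2 <- kb_add(kb2, rt_negative("IUI-1", "bearer_of", "UUI-1", "t3"))
  v2 <- check_consistency(kb2)
  expect_length(v2, 1L)
  expect_match(v2, "clash")
})
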