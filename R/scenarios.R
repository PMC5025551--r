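#' @title Worked scenarios and synthetic knowledge bases
#' @description
#' Builders for the six worked scenarios -- correct diagnosis, a second
#' diagnosis using the first, misdiagnosis, a layperson's lucky guess, a
#' layperson's justified conclusion, and a diagnosis by an expert system --
#' plus single-fault perturbation of a correct scenario and a seeded random
#' generator with constructively known classification labels. Scenario 1 is
#' reproduced from the reference tuple tables; the other scenarios'
#' identifier ranges follow the main text (IUI-23..33, IUI-43..53, IUI-63/68/71,
#' IUI-88/89) with documented reconstructions where the supplementary tables
#' are not available.
#' @name scenarios
NULL

declare_regions <- function(kb, tids) {
  for (t in tids) kb <- kb_add(kb, rt_region(t))
  kb
}

## Shared base: Mr. Jones (IUI-1), his disease (IUI-2), type 2 diabetes
## mellitus (UUI-1), and their configuration (IUI-7) anchored at the
## disease's existence interval t2. UUI-3 (a diabetes-associated phenotype
## type, reconstructed: the reference aggregate table mentions associated
## phenotype types without naming them) supports knowledge aggregates.
scenario_base <- function() {
  kb <- rt_kb()
  kb <- declare_regions(kb, c("t1", "t2", "t7"))
  kb <- kb_add(kb, rt_universal("UUI-1", "type 2 diabetes mellitus"))
  kb <- kb_add(kb, rt_universal("UUI-3", "hyperglycemia (phenotype)"))
  kb <- kb_add(kb, rt_particular("IUI-1", "Mr. Adam Jones", "t1"))
  kb <- kb_add(kb, rt_particular("IUI-2", "IUI-1's disease", "t2"))
  kb <- kb_add(kb, rt_relation("IUI-2", "inheres_in", "IUI-1", "t2"))
  kb <- kb_add(kb, rt_instantiation("IUI-2", "UUI-1", "t2"))
  kb <- kb_add(kb, make_configuration(kb, "IUI-1", "IUI-2", "UUI-1", "t2",
                                      id = "IUI-7"))
  kb
}

## One physician-style diagnostic chain, parameterized by identifier offsets.
## ids: named list with agent, cogsys, anat, cogrep, ice, paper, iqe, process,
## picture, writing, aggregate; tids likewise. Emits the same relation rows as
## the Scenario 1 table.
add_physician_chain <- function(kb, ids, tids, asserted_type, agent_label,
                                picture_sources = character(),
                                agent_is_human = TRUE,
                                cog_kind = "cognitive",
                                aggregate_disease_types = "UUI-1") {
  kb <- declare_regions(kb, unlist(tids, use.names = FALSE))
  kb <- kb_add(kb, rt_particular(ids$agent, agent_label, tids$agent))
  kb <- kb_add(kb, rt_particular(ids$cogsys, paste("cognitive system of", ids$agent), tids$cogsys))
  kb <- kb_add(kb, rt_particular(ids$anat, paste("anatomical part of", ids$cogsys), tids$anat))
  kb <- kb_add(kb, rt_particular(ids$cogrep, "cognitive representation", tids$cogrep))
  kb <- kb_add(kb, rt_particular(ids$paper, "sentence as written on paper", tids$paper))
  kb <- kb_add(kb, rt_particular(ids$iqe, "information quality entity", tids$iqe))

  kb <- kb_add(kb, rt_relation(ids$cogsys, "part_of", ids$agent, tids$cogsys))
  kb <- kb_add(kb, rt_relation(ids$anat, "part_of", ids$cogsys, tids$partof))
  kb <- kb_add(kb, rt_relation(ids$cogrep, "inheres_in", ids$anat, tids$cogrep))

  content <- rt_content(asserted_organism = "IUI-1", asserted_disease = "IUI-2",
                        asserted_type = asserted_type,
                        asserted_anchor = tids$conclude,
                        intended_target = "IUI-7")
  kb <- kb_add(kb, rt_clinical_picture(ids$picture, subject = "IUI-1",
                                       inferred_from = picture_sources,
                                       exists_during = tids$picture))
  kb <- kb_add(kb, rt_aggregate(ids$aggregate, owner = ids$agent,
                                disease_types = aggregate_disease_types,
                                phenotype_types = "UUI-3"))
  kb <- kb_add(kb, rt_ice(ids$ice, content = content,
                          concretizations = c(ids$cogrep, ids$iqe),
                          produced_by = ids$process,
                          first_concretized_at = tids$conclude))
  kb <- kb_add(kb, rt_process(ids$process, agent = ids$agent,
                              agent_is_human = agent_is_human,
                              inputs = c(ids$picture, ids$aggregate),
                              outputs = c(ids$cogrep, ids$ice),
                              occupies = tids$process))
  kb <- kb_add(kb, rt_representation(ids$cogrep, kind = cog_kind,
                                     bearer = ids$anat, concretizes = ids$ice,
                                     exists_during = tids$cogrep))
  kb <- kb_add(kb, rt_representation(ids$iqe, kind = "inscription_quality",
                                     bearer = ids$paper, concretizes = ids$ice,
                                     exists_during = tids$iqe))
  kb <- kb_add(kb, rt_process(ids$writing, agent = ids$agent,
                              agent_is_human = agent_is_human,
                              inputs = c(ids$ice, ids$cogrep),
                              outputs = ids$iqe, occupies = tids$writing))

  ## relation rows mirroring the reference table layout
  is_about_targets <- c("IUI-7", "IUI-1", "IUI-2", asserted_type)
  misrep <- asserted_type != "UUI-1"  # wrong type: not about the configuration
  for (subj in c(ids$cogrep, ids$iqe)) {
    at <- if (subj == ids$cogrep) tids$cogrep else tids$iqe
    for (tgt in is_about_targets) {
      if (misrep && tgt == "IUI-7") next
      kb <- kb_add(kb, rt_relation(subj, "is_about", tgt, at))
    }
    if (misrep)
      kb <- kb_add(kb, rt_relation(subj, "is_misrepresentation_of", "IUI-7", at))
    kb <- kb_add(kb, rt_relation(subj, "concretizes", ids$ice, at))
  }
  kb <- kb_add(kb, rt_relation(ids$iqe, "is_conformant_to", ids$cogrep, tids$iqe))
  kb <- kb_add(kb, rt_relation(ids$agent, "agent_in", ids$process, tids$process))
  kb <- kb_add(kb, rt_relation(ids$picture, "input_into", ids$process, tids$pic_in))
  kb <- kb_add(kb, rt_relation(ids$aggregate, "input_into", ids$process, tids$agg_in))
  kb <- kb_add(kb, rt_relation(ids$cogrep, "output_of", ids$process, tids$conclude))
  kb <- kb_add(kb, rt_relation(ids$ice, "output_of", ids$process, tids$conclude))
  kb <- kb_add(kb, rt_relation(ids$ice, "input_into", ids$writing, tids$dx_in))
  kb <- kb_add(kb, rt_relation(ids$cogrep, "input_into", ids$writing, tids$rep_in))
  kb <- kb_add(kb, rt_relation(ids$iqe, "output_of", ids$writing, tids$iqe_out))

  ## the conclusion instant ends the diagnostic process and falls within the
  ## disease's existence (the disease existed at the time of diagnosing)
  kb <- kb_add(kb, rt_constraint(tids$conclude, "ends", tids$process))
  kb <- kb_add(kb, rt_constraint(tids$conclude, "during", "t2"))
  kb <- kb_add(kb, rt_constraint(tids$pic_in, "during", tids$process))
  kb <- kb_add(kb, rt_constraint(tids$agg_in, "during", tids$process))
  kb
}

scenario1_tids <- function() {
  list(agent = "t3", cogsys = "t4", anat = "t5", cogrep = "t6",
       paper = "t9", iqe = "t10", process = "t11", picture = "t12",
       writing = "t13", partof = "t14", pic_in = "t15", conclude = "t16",
       dx_in = "t17", rep_in = "t18", iqe_out = "t19", agg = "t20",
       agg_in = "t21")
}

scenario1_ids <- function() {
  list(agent = "IUI-3", cogsys = "IUI-4", anat = "IUI-5", cogrep = "IUI-6",
       ice = "IUI-8", paper = "IUI-9", iqe = "IUI-10", process = "IUI-11",
       picture = "IUI-12", writing = "IUI-13", aggregate = "IUI-14")
}

shift_ids <- function(ids, offset) {
  lapply(ids, function(x) sprintf("IUI-%d", as.integer(sub("IUI-", "", x)) + offset))
}

shift_tids <- function(tids, offset) {
  lapply(tids, function(x) sprintf("t%d", as.integer(sub("t", "", x)) + offset))
}

#' Build one of the six worked scenarios
#'
#' Each scenario knowledge base contains the shared configuration of Mr.
#' Jones (IUI-1), his disease (IUI-2) and type 2 diabetes mellitus (UUI-1),
#' anchored at the disease's existence interval, plus the scenario's own
#' chain of agents, processes, representations and ICEs:
#' \enumerate{
#'   \item Dr. Smith's correct diagnosis IUI-8 (full reference tuple set).
#'   \item Dr. Brown's later correct diagnosis IUI-28, whose clinical picture
#'     is inferred from IUI-8; IUI-1, IUI-2 and IUI-7 are shared, so there is
#'     no IUI-21, IUI-22 or IUI-27.
#'   \item Dr. Miller's misdiagnosis IUI-48 asserting type 1 diabetes
#'     mellitus (UUI-2); the cognitive representation IUI-46 and the
#'     inscription IUI-50 misrepresent the configuration IUI-7.
#'   \item The seer's coincidentally correct conclusion IUI-68, produced by
#'     reasoning IUI-71 from a horoscope with neither clinical picture nor
#'     knowledge aggregate.
#'   \item The daughter's conclusion. \code{variant = "belief"}: she forms
#'     her own belief from Dr. Smith's diagnosis and authors a new ICE IUI-88.
#'     \code{variant = "copy"}: she copies Dr. Smith's sentence verbatim, so
#'     her inscription concretizes IUI-8 itself.
#'   \item An expert system's correct diagnosis with digital representations
#'     and a non-human diagnostic agent.
#' }
#'
#' @param n Scenario number, 1..6.
#' @param variant For scenario 5: \code{"belief"} (default) or \code{"copy"}.
#' @return List with elements \code{kb}, \code{ice} (IUI of the assertion
#'   under test) and \code{via} (concretization to classify through, or
#'   \code{NULL}).
#' @export
build_scenario <- function(n, variant = c("belief", "copy")) {
  if (!is.numeric(n) || length(n) != 1L || !(n %in% 1:6))
    stop("scenario number must be an integer in 1..6", call. = FALSE)
  variant <- match.arg(variant)
  kb <- scenario_base()
  via <- NULL

  if (n == 1L) {
    kb <- add_physician_chain(kb, scenario1_ids(), scenario1_tids(), "UUI-1",
                              "Dr. Anne Smith")
    ice <- "IUI-8"
  } else if (n == 2L) {
    ## Dr. Brown sees Mr. Jones later and uses Dr. Smith's diagnosis: the
    ## whole Scenario 1 chain is present, then a second chain IUI-23..IUI-34
    ## (IUI-34 = Dr. Brown's aggregate, reconstructed) whose clinical picture
    ## IUI-32 is inferred from the prior diagnosis IUI-8.
    kb <- add_physician_chain(kb, scenario1_ids(), scenario1_tids(), "UUI-1",
                              "Dr. Anne Smith")
    kb <- add_physician_chain(kb, shift_ids(scenario1_ids(), 20L),
                              shift_tids(scenario1_tids(), 20L), "UUI-1",
                              "Dr. John Brown", picture_sources = "IUI-8")
    kb <- kb_add(kb, rt_constraint("t11", "before", "t31"))
    ice <- "IUI-28"
  } else if (n == 3L) {
    ## Dr. Miller, without access to past records, asserts type 1 diabetes
    ## mellitus (UUI-2). IUI-54 = aggregate, reconstructed.
    kb <- kb_add(kb, rt_universal("UUI-2", "type 1 diabetes mellitus"))
    kb <- add_physician_chain(kb, shift_ids(scenario1_ids(), 40L),
                              shift_tids(scenario1_tids(), 40L), "UUI-2",
                              "Dr. Jane Miller",
                              aggregate_disease_types = c("UUI-1", "UUI-2"))
    ice <- "IUI-48"
  } else if (n == 4L) {
    ## The seer (IUI-63) reasons (IUI-71) from Mr. Jones' horoscope (IUI-69,
    ## reconstructed) to a coincidentally correct conclusion (IUI-68). No
    ## clinical picture and no aggregate of disease-type representations.
    kb <- declare_regions(kb, c("t63", "t64", "t65", "t66", "t69", "t71", "t76"))
    kb <- kb_add(kb, rt_particular("IUI-63", "the seer", "t63"))
    kb <- kb_add(kb, rt_particular("IUI-64", "cognitive system of IUI-63", "t64"))
    kb <- kb_add(kb, rt_particular("IUI-65", "anatomical part of IUI-64", "t65"))
    kb <- kb_add(kb, rt_particular("IUI-66", "cognitive representation", "t66"))
    kb <- kb_add(kb, rt_particular("IUI-69", "Mr. Jones' horoscope", "t69"))
    kb <- kb_add(kb, rt_relation("IUI-64", "part_of", "IUI-63", "t64"))
    kb <- kb_add(kb, rt_relation("IUI-65", "part_of", "IUI-64", "t65"))
    kb <- kb_add(kb, rt_relation("IUI-66", "inheres_in", "IUI-65", "t66"))
    content <- rt_content("IUI-1", "IUI-2", "UUI-1", "t76", "IUI-7")
    kb <- kb_add(kb, rt_ice("IUI-68", content = content,
                            concretizations = "IUI-66",
                            produced_by = "IUI-71",
                            first_concretized_at = "t76"))
    kb <- kb_add(kb, rt_process("IUI-71", agent = "IUI-63",
                                inputs = "IUI-69",
                                outputs = c("IUI-66", "IUI-68"),
                                occupies = "t71"))
    kb <- kb_add(kb, rt_representation("IUI-66", kind = "cognitive",
                                       bearer = "IUI-65",
                                       concretizes = "IUI-68",
                                       exists_during = "t66"))
    kb <- kb_add(kb, rt_relation("IUI-63", "agent_in", "IUI-71", "t71"))
    kb <- kb_add(kb, rt_relation("IUI-69", "input_into", "IUI-71", "t71"))
    kb <- kb_add(kb, rt_relation("IUI-66", "output_of", "IUI-71", "t76"))
    kb <- kb_add(kb, rt_relation("IUI-68", "output_of", "IUI-71", "t76"))
    kb <- kb_add(kb, rt_relation("IUI-66", "concretizes", "IUI-68", "t66"))
    kb <- kb_add(kb, rt_constraint("t76", "ends", "t71"))
    kb <- kb_add(kb, rt_constraint("t76", "during", "t2"))
    ice <- "IUI-68"
  } else if (n == 5L) {
    ## Both variants start from the full Scenario 1 world: the daughter read
    ## Dr. Smith's note. IUI-83..IUI-92 reconstructed around the documented
    ## IUI-88 (her new ICE) and IUI-89 (the sentence in her letter).
    kb <- add_physician_chain(kb, scenario1_ids(), scenario1_tids(), "UUI-1",
                              "Dr. Anne Smith")
    kb <- declare_regions(kb, c("t83", "t84", "t85", "t86", "t89", "t90",
                                "t91", "t94"))
    kb <- kb_add(kb, rt_particular("IUI-83", "Mr. Jones' daughter", "t83"))
    kb <- kb_add(kb, rt_particular("IUI-89", "sentence in the letter", "t89"))
    if (variant == "copy") {
      ## verbatim copy prefixed "Dr. Smith says": concretizes IUI-8 itself
      res <- copy_concretization(kb, "IUI-10", new_bearer = "IUI-89",
                                 kind = "inscription_quality",
                                 exists_during = "t90", id = "IUI-90")
      kb <- res$kb
      ice <- "IUI-8"
      via <- "IUI-90"
    } else {
      ## she forms her own belief from her trust in Dr. Smith: a new ICE
      kb <- kb_add(kb, rt_particular("IUI-84", "cognitive system of IUI-83", "t84"))
      kb <- kb_add(kb, rt_particular("IUI-85", "anatomical part of IUI-84", "t85"))
      kb <- kb_add(kb, rt_particular("IUI-86", "cognitive representation", "t86"))
      kb <- kb_add(kb, rt_relation("IUI-84", "part_of", "IUI-83", "t84"))
      kb <- kb_add(kb, rt_relation("IUI-85", "part_of", "IUI-84", "t85"))
      kb <- kb_add(kb, rt_relation("IUI-86", "inheres_in", "IUI-85", "t86"))
      kb <- kb_add(kb, rt_process("IUI-91", agent = "IUI-83",
                                  inputs = "IUI-8",
                                  outputs = "IUI-86", occupies = "t91"))
      content <- rt_content("IUI-1", "IUI-2", "UUI-1", "t94", "IUI-7")
      first <- rt_representation("IUI-86", kind = "cognitive",
                                 bearer = "IUI-85", exists_during = "t86")
      res <- derive_new_ice(kb, author = "IUI-83", process = "IUI-91",
                            content = content, first_concretization = first,
                            id = "IUI-88")
      kb <- res$kb
      ## her letter's inscription is an original concretization of her own
      ## ICE, conformant to her cognitive representation -- not a copy
      kb <- kb_add(kb, rt_representation("IUI-90", kind = "inscription_quality",
                                         bearer = "IUI-89",
                                         concretizes = "IUI-88",
                                         exists_during = "t90"))
      ice88 <- kb$ices[["IUI-88"]]
      ice88$concretizations <- sort(unique(c(ice88$concretizations, "IUI-90")))
      kb$ices[["IUI-88"]] <- ice88
      kb <- kb_add(kb, rt_relation("IUI-90", "concretizes", "IUI-88", "t90"))
      kb <- kb_add(kb, rt_relation("IUI-90", "is_conformant_to", "IUI-86", "t90"))
      kb <- kb_add(kb, rt_relation("IUI-8", "input_into", "IUI-91", "t91"))
      kb <- kb_add(kb, rt_constraint("t94", "ends", "t91"))
      kb <- kb_add(kb, rt_constraint("t94", "during", "t2"))
      ice <- "IUI-88"
    }
  } else {
    ## Expert system: digital representations in place of cognitive ones,
    ## non-human diagnostic agent. IUI-103..IUI-115 reconstructed.
    kb <- declare_regions(kb, c("t103", "t104", "t105", "t106", "t109",
                                "t110", "t111", "t112", "t113", "t116",
                                "t117", "t118"))
    kb <- kb_add(kb, rt_particular("IUI-103", "medical student", "t103"))
    kb <- kb_add(kb, rt_particular("IUI-104", "diagnostic expert system", "t104"))
    kb <- kb_add(kb, rt_particular("IUI-105", "memory component of IUI-104", "t105"))
    kb <- kb_add(kb, rt_particular("IUI-106", "digital representation", "t106"))
    kb <- kb_add(kb, rt_particular("IUI-109", "printed sentence", "t109"))
    kb <- kb_add(kb, rt_particular("IUI-110", "information quality entity", "t110"))
    kb <- kb_add(kb, rt_relation("IUI-105", "part_of", "IUI-104", "t105"))
    content <- rt_content("IUI-1", "IUI-2", "UUI-1", "t116", "IUI-7")
    kb <- kb_add(kb, rt_clinical_picture("IUI-112", subject = "IUI-1",
                                         exists_during = "t112"))
    kb <- kb_add(kb, rt_aggregate("IUI-114", owner = "IUI-104",
                                  disease_types = "UUI-1",
                                  phenotype_types = "UUI-3"))
    kb <- kb_add(kb, rt_ice("IUI-108", content = content,
                            concretizations = c("IUI-106", "IUI-110"),
                            produced_by = "IUI-111",
                            first_concretized_at = "t116"))
    kb <- kb_add(kb, rt_process("IUI-111", agent = "IUI-104",
                                agent_is_human = FALSE,
                                inputs = c("IUI-112", "IUI-114"),
                                outputs = c("IUI-106", "IUI-108"),
                                occupies = "t111"))
    kb <- kb_add(kb, rt_representation("IUI-106", kind = "digital",
                                       bearer = "IUI-105",
                                       concretizes = "IUI-108",
                                       exists_during = "t106"))
    kb <- kb_add(kb, rt_representation("IUI-110", kind = "inscription_quality",
                                       bearer = "IUI-109",
                                       concretizes = "IUI-108",
                                       exists_during = "t110"))
    kb <- kb_add(kb, rt_process("IUI-113", agent = "IUI-104",
                                agent_is_human = FALSE, inputs = "IUI-108",
                                outputs = "IUI-110", occupies = "t113"))
    for (subj in c("IUI-106", "IUI-110")) {
      at <- if (subj == "IUI-106") "t106" else "t110"
      for (tgt in c("IUI-7", "IUI-1", "IUI-2", "UUI-1"))
        kb <- kb_add(kb, rt_relation(subj, "is_about", tgt, at))
      kb <- kb_add(kb, rt_relation(subj, "concretizes", "IUI-108", at))
    }
    kb <- kb_add(kb, rt_relation("IUI-104", "agent_in", "IUI-111", "t111"))
    kb <- kb_add(kb, rt_relation("IUI-112", "input_into", "IUI-111", "t117"))
    kb <- kb_add(kb, rt_relation("IUI-114", "input_into", "IUI-111", "t118"))
    kb <- kb_add(kb, rt_relation("IUI-106", "output_of", "IUI-111", "t116"))
    kb <- kb_add(kb, rt_relation("IUI-108", "output_of", "IUI-111", "t116"))
    kb <- kb_add(kb, rt_relation("IUI-110", "output_of", "IUI-113", "t110"))
    kb <- kb_add(kb, rt_constraint("t116", "ends", "t111"))
    kb <- kb_add(kb, rt_constraint("t116", "during", "t2"))
    ice <- "IUI-108"
  }

  kb$metadata <- list(scenario = n,
                      variant = if (n == 5L) variant else NULL,
                      ice = ice, via = via)
  list(kb = kb, ice = ice, via = via)
}

#' Specify a single-fault perturbation
#'
#' @param mode One of \code{\link{failure_modes}()}.
#' @param seed Integer recorded in the perturbed knowledge base's metadata.
#' @param target Content field the edit touches; derived from the mode when
#'   omitted.
#' @return An object of class \code{rt_perturbation}.
#' @export
perturbation_spec <- function(mode, seed = 0L, target = NULL) {
  chk(mode %in% failure_modes(), "unknown failure mode '%s'", mode)
  if (is.null(target)) {
    target <- switch(mode,
                     NONINST_TYPE_EXISTS = "asserted_type",
                     NONINST_TYPE_NONEXISTENT = "asserted_type",
                     DISEASE_NONEXISTENT = "asserted_disease",
                     ORGANISM_NONEXISTENT = "asserted_organism",
                     NON_INHERENCE = "asserted_organism",
                     SPACETIME_MISPLACEMENT = "asserted_anchor")
  }
  structure(list(mode = mode, seed = as.integer(seed), target = target),
            class = c("rt_perturbation", "rt_record"))
}

#' Inject exactly one fault into a scenario knowledge base
#'
#' Returns an edited copy (the input knowledge base is unchanged) whose
#' assertion under test exhibits exactly the requested failure mode:
#' asserting an existing-but-wrong type, a nonexistent type, a nonexistent
#' disease or organism, an organism the disease does not inhere in, or an
#' anchor entailed disjoint from the configuration's time.
#'
#' @param kb A scenario knowledge base containing a diagnosis ICE (its
#'   metadata names the assertion under test).
#' @param spec An \code{\link{perturbation_spec}}, or a mode name.
#' @param ice IUI of the ICE to perturb; defaults to the knowledge base
#'   metadata's assertion under test.
#' @return List with elements \code{kb} (edited copy) and \code{content}
#'   (the perturbed \code{\link{rt_content}}).
#' @export
perturb <- function(kb, spec, ice = NULL) {
  stopifnot(inherits(kb, "rt_kb"))
  if (is.character(spec)) spec <- perturbation_spec(spec)
  stopifnot(inherits(spec, "rt_perturbation"))
  if (is.null(ice)) ice <- kb$metadata$ice
  if (is.null(ice) || !ice %in% names(kb$ices))
    stop("perturbation inapplicable: knowledge base has no diagnosis ICE under test",
         call. = FALSE)
  content <- kb$ices[[ice]]$content

  if (spec$mode == "NONINST_TYPE_EXISTS") {
    if (!"UUI-2" %in% names(kb$universals))
      kb <- kb_add(kb, rt_universal("UUI-2", "type 1 diabetes mellitus"))
    content$asserted_type <- "UUI-2"
  } else if (spec$mode == "NONINST_TYPE_NONEXISTENT") {
    if (!"UUI-99" %in% names(kb$universals))
      kb <- kb_add(kb, rt_universal("UUI-99", "dropsy", exists = FALSE))
    content$asserted_type <- "UUI-99"
  } else if (spec$mode == "DISEASE_NONEXISTENT") {
    content$asserted_disease <- "IUI-666"  # never declared
  } else if (spec$mode == "ORGANISM_NONEXISTENT") {
    content$asserted_organism <- "IUI-777"  # never declared
  } else if (spec$mode == "NON_INHERENCE") {
    if (!"IUI-55" %in% names(kb$particulars)) {
      if (!"t55" %in% names(kb$temporal_regions))
        kb <- kb_add(kb, rt_region("t55"))
      kb <- kb_add(kb, rt_particular("IUI-55", "Mr. Jones' twin", "t55"))
    }
    content$asserted_organism <- "IUI-55"
  } else if (spec$mode == "SPACETIME_MISPLACEMENT") {
    if (!"t99" %in% names(kb$temporal_regions)) {
      kb <- kb_add(kb, rt_region("t99"))
      cfg <- kb$configurations[[content$intended_target]]
      kb <- kb_add(kb, rt_constraint("t99", "before", cfg$anchor))
    }
    content$asserted_anchor <- "t99"
  }

  kb$ices[[ice]]$content <- content
  kb$metadata$perturbation <- list(mode = spec$mode, seed = spec$seed,
                                   target = spec$target)
  list(kb = kb, content = content)
}

#' Generate a random knowledge base with constructively known labels
#'
#' Builds a reproducible world of organisms bearing diseases of known types,
#' each with an assertion produced through one of four provenance routes
#' (diagnostic process, lucky guess, justified conclusion from a prior
#' diagnosis, verbatim copy). With probability \code{fault_rate} a case's
#' content is given exactly one fault drawn from the six failure modes. The
#' expected category of every case is computed constructively from how it
#' was built -- never by running the classifier -- so the result serves as an
#' oracle for \code{\link{classify_assertion}}. Representations in random
#' worlds are inscriptions, which carry no cognitive-system requirements.
#'
#' @param seed Integer seed; the same seed reproduces the same world.
#' @param n_particulars Approximate scale (>= 3); one case is generated per
#'   three particulars.
#' @param fault_rate Fraction of cases receiving one injected fault.
#' @return List with elements \code{kb} and \code{cases}, a data frame with
#'   columns \code{ice}, \code{via} (possibly \code{NA}), \code{expected}
#'   and \code{fault}.
#' @export
random_scenario <- function(seed, n_particulars = 9L, fault_rate = 0) {
  stopifnot(n_particulars >= 3L, fault_rate >= 0, fault_rate <= 1)
  set.seed(as.integer(seed))
  kb <- rt_kb()
  kb <- kb_add(kb, rt_universal("UUI-900", "generic phenotype"))
  n_cases <- max(1L, n_particulars %/% 3L)
  cases <- data.frame(ice = character(), via = character(),
                      expected = character(), fault = character(),
                      stringsAsFactors = FALSE)
  idn <- 0L; tn <- 0L; un <- 0L
  new_id <- function() { idn <<- idn + 1L; sprintf("IUI-%d", idn) }
  new_t <- function() { tn <<- tn + 1L; sprintf("t%d", tn) }
  new_u <- function() { un <<- un + 1L; sprintf("UUI-%d", un) }

  ## one diagnostic chain over a fresh configuration; returns ids
  build_chain <- function(kb, diagnostic, prior_ice = NULL) {
    t_org <- new_t(); t_dis <- new_t()
    org <- new_id(); dis <- new_id(); type <- new_u()
    kb <- kb_add(kb, rt_region(t_org)); kb <- kb_add(kb, rt_region(t_dis))
    kb <- kb_add(kb, rt_universal(type, paste("disease type", type)))
    kb <- kb_add(kb, rt_particular(org, "organism", t_org))
    kb <- kb_add(kb, rt_particular(dis, "disease", t_dis))
    kb <- kb_add(kb, rt_relation(dis, "inheres_in", org, t_dis))
    kb <- kb_add(kb, rt_instantiation(dis, type, t_dis))
    cfg <- new_id()
    kb <- kb_add(kb, make_configuration(kb, org, dis, type, t_dis, id = cfg))
    agent <- new_id(); t_ag <- new_t()
    kb <- kb_add(kb, rt_region(t_ag))
    kb <- kb_add(kb, rt_particular(agent, "agent", t_ag))
    t_proc <- new_t(); t_conc <- new_t()
    kb <- kb_add(kb, rt_region(t_proc)); kb <- kb_add(kb, rt_region(t_conc))
    kb <- kb_add(kb, rt_constraint(t_conc, "ends", t_proc))
    kb <- kb_add(kb, rt_constraint(t_conc, "during", t_dis))
    inputs <- character()
    if (diagnostic) {
      pic <- new_id(); agg <- new_id(); t_pic <- new_t()
      kb <- kb_add(kb, rt_region(t_pic))
      kb <- kb_add(kb, rt_clinical_picture(pic, subject = org,
                                           exists_during = t_pic))
      kb <- kb_add(kb, rt_aggregate(agg, owner = agent, disease_types = type,
                                    phenotype_types = "UUI-900"))
      inputs <- c(pic, agg)
    }
    if (!is.null(prior_ice)) inputs <- c(inputs, prior_ice)
    proc <- new_id()
    kb <- kb_add(kb, rt_process(proc, agent = agent, inputs = inputs,
                                outputs = character(), occupies = t_proc))
    bearer <- new_id(); t_b <- new_t(); t_rep <- new_t()
    kb <- kb_add(kb, rt_region(t_b)); kb <- kb_add(kb, rt_region(t_rep))
    kb <- kb_add(kb, rt_particular(bearer, "paper", t_b))
    content <- rt_content(org, dis, type, t_conc, cfg)
    first <- rt_representation(new_id(), kind = "inscription_quality",
                               bearer = bearer, exists_during = t_rep)
    res <- derive_new_ice(kb, author = agent, process = proc,
                          content = content, first_concretization = first,
                          id = new_id())
    list(kb = res$kb, ice = res$ice$id, rep = first$id, org = org, dis = dis,
         type = type, cfg = cfg, anchor = t_conc, t_dis = t_dis)
  }

  inject_fault <- function(kb, ch, mode) {
    content <- kb$ices[[ch$ice]]$content
    if (mode == "NONINST_TYPE_EXISTS") {
      alt <- new_u()
      kb <- kb_add(kb, rt_universal(alt, "some other existing type"))
      content$asserted_type <- alt
    } else if (mode == "NONINST_TYPE_NONEXISTENT") {
      alt <- new_u()
      kb <- kb_add(kb, rt_universal(alt, "abandoned type", exists = FALSE))
      content$asserted_type <- alt
    } else if (mode == "DISEASE_NONEXISTENT") {
      content$asserted_disease <- "IUI-999999"
    } else if (mode == "ORGANISM_NONEXISTENT") {
      content$asserted_organism <- "IUI-999998"
    } else if (mode == "NON_INHERENCE") {
      other <- new_id(); t_o <- new_t()
      kb <- kb_add(kb, rt_region(t_o))
      kb <- kb_add(kb, rt_particular(other, "other organism", t_o))
      content$asserted_organism <- other
    } else if (mode == "SPACETIME_MISPLACEMENT") {
      t_bad <- new_t()
      kb <- kb_add(kb, rt_region(t_bad))
      kb <- kb_add(kb, rt_constraint(t_bad, "before", ch$t_dis))
      content$asserted_anchor <- t_bad
    }
    kb$ices[[ch$ice]]$content <- content
    kb
  }

  routes <- c("diagnostic", "lucky", "justified", "hearsay")
  for (i in seq_len(n_cases)) {
    route <- sample(routes, 1L)
    fault <- if (stats::runif(1) < fault_rate) sample(failure_modes(), 1L) else NA_character_
    via <- NA_character_
    if (route == "diagnostic") {
      ch <- build_chain(kb, diagnostic = TRUE)
      kb <- ch$kb
      expected <- "correct_diagnosis"
      if (!is.na(fault)) {
        kb <- inject_fault(kb, ch, fault)
        ## an assertion about a nonexistent organism can have no clinical
        ## picture; it drops out of the diagnosis/misdiagnosis dichotomy
        expected <- if (fault == "ORGANISM_NONEXISTENT") "lucky_guess"
        else "misdiagnosis"
      }
      ice <- ch$ice
    } else if (route == "lucky") {
      ch <- build_chain(kb, diagnostic = FALSE)
      kb <- ch$kb
      ice <- ch$ice
      expected <- "lucky_guess"
      if (!is.na(fault)) kb <- inject_fault(kb, ch, fault)
    } else if (route == "justified") {
      prior <- build_chain(kb, diagnostic = TRUE)
      kb <- prior$kb
      ch <- build_chain(kb, diagnostic = FALSE, prior_ice = prior$ice)
      kb <- ch$kb
      ice <- ch$ice
      expected <- "justified_conclusion"
      if (!is.na(fault)) kb <- inject_fault(kb, ch, fault)
    } else {
      ch <- build_chain(kb, diagnostic = TRUE)
      kb <- ch$kb
      bearer2 <- new_id(); t_b2 <- new_t()
      kb <- kb_add(kb, rt_region(t_b2))
      kb <- kb_add(kb, rt_particular(bearer2, "copy bearer", t_b2))
      res <- copy_concretization(kb, ch$rep, new_bearer = bearer2,
                                 kind = "inscription_quality", id = new_id())
      kb <- res$kb
      ice <- ch$ice
      via <- res$representation$id
      expected <- "hearsay_copy"
      if (!is.na(fault)) kb <- inject_fault(kb, ch, fault)
    }
    cases <- rbind(cases, data.frame(ice = ice, via = via,
                                     expected = expected, fault = fault,
                                     stringsAsFactors = FALSE))
  }
  kb$metadata <- list(generator = "random_scenario", seed = as.integer(seed),
                      n_particulars = as.integer(n_particulars),
                      fault_rate = fault_rate)
  list(kb = kb, cases = cases)
}
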