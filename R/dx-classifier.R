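#' @title Classifying diagnostic assertions
#' @description
#' Labels an information content entity, relative to a knowledge base, as a
#' correct diagnosis, a misdiagnosis (with the six-mode failure typology and
#' the level at which aboutness fails first), a lucky guess, hearsay, a
#' justified layperson conclusion, or not an ICE at all. What separates a
#' diagnosis from a coincidentally correct statement is provenance: a
#' diagnosis is the output of a diagnostic process that took both a clinical
#' picture of the patient and an aggregate of disease-type/phenotype-type
#' representations as input. Nothing requires the diagnostic agent to be
#' human.
#' @name dx-classifier
NULL

#' Is a process a diagnostic process?
#'
#' Holds iff the process's inputs include (1) a clinical picture of some
#' organism and (2) a knowledge aggregate pairing at least one disease type
#' with at least one associated phenotype type. A prior diagnosis may appear
#' inside the clinical picture or alongside it among the inputs; neither
#' placement is required. The agent may be human or not. Closed world: never
#' indeterminate.
#'
#' @param kb An \code{rt_kb}.
#' @param process IUI of a declared process.
#' @return \code{"holds"} or \code{"fails"}.
#' @export
is_diagnostic_process <- function(kb, process) {
  stopifnot(inherits(kb, "rt_kb"))
  proc <- kb$processes[[process]]
  if (is.null(proc)) decl_err("process", process)
  has_picture <- any(proc$inputs %in% names(kb$clinical_pictures))
  has_aggregate <- FALSE
  for (x in proc$inputs) {
    agg <- kb$knowledge_aggregates[[x]]
    if (!is.null(agg) && length(agg$disease_types) > 0L &&
        length(agg$phenotype_types) > 0L && nrow(agg$associations) > 0L) {
      has_aggregate <- TRUE
      break
    }
  }
  if (has_picture && has_aggregate) "holds" else "fails"
}

#' Determine the applicable failure modes of an assertion
#'
#' Checks the six ways a diagnostic assertion can fail to be about its
#' configuration at the level of compound expression and reports every
#' applicable one, together with the level at which aboutness fails first:
#' \code{"reference"} when any of the three nonexistence modes applies
#' (stated type nonexistent, disease instance nonexistent, organism instance
#' nonexistent), \code{"compound"} when only structural or spacetime modes
#' apply, \code{"none"} when no mode applies.
#'
#' @param content An \code{\link{rt_content}}.
#' @param kb An \code{rt_kb}.
#' @return List with elements \code{modes} (character subset of
#'   \code{\link{failure_modes}()}) and \code{fails_first}.
#' @export
classify_failure_modes <- function(content, kb) {
  stopifnot(inherits(content, "rt_content"), inherits(kb, "rt_kb"))
  modes <- character()
  org_ok <- !is.null(content$asserted_organism) &&
    content$asserted_organism %in% names(kb$particulars)
  dis_ok <- !is.null(content$asserted_disease) &&
    content$asserted_disease %in% names(kb$particulars)
  u <- kb$universals[[content$asserted_type]]
  type_ok <- !is.null(u) && isTRUE(u$exists_flag)

  if (!org_ok) modes <- c(modes, "ORGANISM_NONEXISTENT")
  if (!dis_ok) modes <- c(modes, "DISEASE_NONEXISTENT")
  if (!type_ok) modes <- c(modes, "NONINST_TYPE_NONEXISTENT")
  if (type_ok && dis_ok &&
      nrow(kb$instantiations[kb$instantiations$particular == content$asserted_disease &
                               kb$instantiations$universal == content$asserted_type, ,
                             drop = FALSE]) == 0L)
    modes <- c(modes, "NONINST_TYPE_EXISTS")
  if (org_ok && dis_ok &&
      nrow(kb$relations[kb$relations$subject == content$asserted_disease &
                          kb$relations$relation == "inheres_in" &
                          kb$relations$object == content$asserted_organism, ,
                        drop = FALSE]) == 0L)
    modes <- c(modes, "NON_INHERENCE")
  cfg <- kb$configurations[[content$intended_target]]
  if (!is.null(cfg) &&
      entails_intersects(kb, content$asserted_anchor, cfg$anchor) == "fails")
    modes <- c(modes, "SPACETIME_MISPLACEMENT")

  reference_modes <- c("NONINST_TYPE_NONEXISTENT", "DISEASE_NONEXISTENT",
                       "ORGANISM_NONEXISTENT")
  fails_first <- if (any(modes %in% reference_modes)) "reference"
  else if (length(modes)) "compound"
  else "none"
  list(modes = sort(modes), fails_first = fails_first)
}

ice_is_diagnosis <- function(kb, ice_id) {
  ice <- kb$ices[[ice_id]]
  !is.null(ice) && !is.null(ice$produced_by) &&
    ice$produced_by %in% names(kb$processes) &&
    is_diagnostic_process(kb, ice$produced_by) == "holds"
}

has_prior_diagnosis_input <- function(kb, proc) {
  if (is.null(proc)) return(FALSE)
  candidates <- proc$inputs
  for (x in proc$inputs) {
    pic <- kb$clinical_pictures[[x]]
    if (!is.null(pic)) candidates <- c(candidates, pic$inferred_from)
  }
  for (x in unique(candidates)) {
    if (ice_is_diagnosis(kb, x)) return(TRUE)
    rep <- kb$representations[[x]]
    if (!is.null(rep) && !is.null(rep$concretizes) &&
        ice_is_diagnosis(kb, rep$concretizes)) return(TRUE)
  }
  FALSE
}

#' Classify a diagnostic assertion
#'
#' Decision cascade: (1) an assertion about nothing at the level of reference
#' is not an information content entity; (2) an assertion tokened by a copied
#' concretization is hearsay -- the copy concretizes the original ICE, and the
#' category describes the assertion-as-tokened; (3) if the asserted organism
#' does not exist, no clinical picture could have been inferred, so the
#' assertion is never a diagnosis or misdiagnosis, only a (possibly
#' misinformation-carrying) guess or conclusion; (4) an assertion produced by
#' a diagnostic process is a correct diagnosis when compound aboutness holds,
#' a misdiagnosis with its failure modes when it fails, and indeterminate when
#' the timing is unresolved; (5) otherwise the assertion is a justified
#' conclusion when a prior diagnosis was among the producing process's inputs
#' (directly or inside the clinical picture) and a lucky guess when nothing
#' epistemically relevant was -- the misinformation counterparts of these are
#' reported as the same category with the failure modes in the rationale
#' trail.
#'
#' @param kb An \code{rt_kb}.
#' @param ice IUI of the ICE under test.
#' @param via Optional IUI of the concretization through which the assertion
#'   is tokened (e.g. a copied inscription); defaults to the ICE's own
#'   provenance.
#' @return An \code{\link{rt_classification}}.
#' @export
classify_assertion <- function(kb, ice, via = NULL) {
  stopifnot(inherits(kb, "rt_kb"))
  rec <- kb$ices[[ice]]
  if (is.null(rec)) stop(sprintf("unknown ICE '%s'", ice), call. = FALSE)
  content <- rec$content
  rationale <- character()

  ref <- evaluate_reference(content, kb)
  comp <- evaluate_compound(content, kb)
  fm <- classify_failure_modes(content, kb)
  ff <- if (comp$status == "holds") "none"
  else if (fm$fails_first == "none") "compound"
  else fm$fails_first

  # (1) about nothing even at the level of reference: not an ICE
  if (ref$status == "fails") {
    rationale <- c(rationale, "reference_fails_entirely")
    return(rt_classification("non_ice", failure_modes = fm$modes,
                             fails_first = "reference", rationale = rationale))
  }

  # (2) copied concretization: hearsay of the original ICE
  if (!is.null(via)) {
    rep <- kb$representations[[via]]
    if (is.null(rep)) decl_err("representation", via)
    if (!identical(rep$concretizes, ice))
      stop(sprintf("representation '%s' does not concretize ICE '%s'", via, ice),
           call. = FALSE)
    if (!is.null(rep$copied_from)) {
      rationale <- c(rationale, "tokened_by_copied_concretization")
      if (length(fm$modes))
        rationale <- c(rationale, paste0("mode:", fm$modes))
      return(rt_classification("hearsay_copy", fails_first = ff,
                               rationale = rationale))
    }
  }

  proc <- NULL
  if (!is.null(rec$produced_by)) {
    proc <- kb$processes[[rec$produced_by]]
    if (is.null(proc)) decl_err("process", rec$produced_by)
  }

  # (3) nonexistent organism: no clinical picture could have been inferred,
  # so neither diagnosis nor misdiagnosis; still an ICE (about the type)
  if ("ORGANISM_NONEXISTENT" %in% fm$modes) {
    rationale <- c(rationale, "organism_nonexistent_not_a_diagnosis",
                   paste0("mode:", fm$modes))
    category <- if (has_prior_diagnosis_input(kb, proc)) "justified_conclusion"
    else "lucky_guess"
    return(rt_classification(category, fails_first = ff, rationale = rationale))
  }

  # (4) produced by a diagnostic process
  if (!is.null(proc) && is_diagnostic_process(kb, rec$produced_by) == "holds") {
    rationale <- c(rationale, "diagnostic_process_holds")
    if (comp$status == "holds") {
      rationale <- c(rationale, "compound_aboutness_holds")
      return(rt_classification("correct_diagnosis", fails_first = "none",
                               rationale = rationale))
    }
    if (comp$status == "fails") {
      rationale <- c(rationale, "compound_aboutness_fails",
                     paste0("mode:", fm$modes))
      return(rt_classification("misdiagnosis", failure_modes = fm$modes,
                               fails_first = ff, rationale = rationale))
    }
    rationale <- c(rationale, "compound_aboutness_indeterminate")
    return(rt_classification("indeterminate", fails_first = ff,
                             rationale = rationale))
  }

  # (5) no diagnostic process behind the assertion
  rationale <- c(rationale, "no_diagnostic_process")
  if (comp$status == "indeterminate") {
    rationale <- c(rationale, "compound_aboutness_indeterminate")
    return(rt_classification("indeterminate", fails_first = ff,
                             rationale = rationale))
  }
  category <- if (has_prior_diagnosis_input(kb, proc)) "justified_conclusion"
  else "lucky_guess"
  rationale <- c(rationale,
                 if (category == "justified_conclusion") "prior_diagnosis_input"
                 else "no_epistemically_relevant_input")
  if (comp$status == "fails") {
    rationale <- c(rationale, "compound_aboutness_fails",
                   paste0("mode:", fm$modes))
  }
  rt_classification(category, fails_first = ff, rationale = rationale)
}

#' Warn when an asserted type is too general to be clinically useful
#'
#' It is trivial to assert that a disease instantiates \emph{entity} or even
#' \emph{disease}; a diagnosis is expected to be as specific as is relevant
#' to treat the patient. The too-general stratum is a configuration knob, not
#' a fixed rule, because the clinically minimal granularity is a clinical
#' judgement.
#'
#' @param content An \code{\link{rt_content}}.
#' @param type_hierarchy Data frame with columns \code{child}, \code{parent}
#'   (UUIs), or an empty/\code{NULL} hierarchy.
#' @param root UUI of the hierarchy root.
#' @param too_general Additional UUIs considered too general; defaults to
#'   none beyond the root.
#' @return A character warning descriptor, or \code{NULL} when the asserted
#'   type is acceptably specific (or the hierarchy is degenerate, in which
#'   case a notice is logged via \code{message}).
#' @export
check_precision <- function(content, type_hierarchy, root,
                            too_general = character()) {
  stopifnot(inherits(content, "rt_content"))
  if (is.null(type_hierarchy) || nrow(type_hierarchy) == 0L) {
    message("check_precision: empty type hierarchy, precision not assessed")
    return(NULL)
  }
  flagged <- unique(c(root, too_general))
  if (content$asserted_type %in% flagged)
    return(sprintf("asserted type '%s' is too general for a clinically useful diagnosis",
                   content$asserted_type))
  NULL
}
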