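#' @title Core domain types for Referent Tracking
#' @description
#' Constructors for the record types shared by every other module: particulars
#' (IUI-identified individuals), universals (UUI-identified types), temporal
#' regions and qualitative constraints among them, temporally indexed
#' assertions, configurations (the truth-makers of diagnostic assertions),
#' information content entities and their concretizations, processes, clinical
#' pictures and knowledge aggregates. Pure data: no I/O, no inference.
#' @name core-model
NULL

RT_RELATIONS <- c("inheres_in", "bearer_of", "part_of", "is_about",
                  "concretizes", "is_conformant_to", "is_misrepresentation_of",
                  "agent_in", "input_into", "output_of")

RT_TEMPORAL_RELATIONS <- c("equals", "during", "contains", "ends", "starts",
                           "before", "overlaps")

RT_REPRESENTATION_KINDS <- c("cognitive", "inscription_quality", "digital")

RT_CATEGORIES <- c("correct_diagnosis", "misdiagnosis", "lucky_guess",
                   "hearsay_copy", "justified_conclusion", "non_ice",
                   "indeterminate")

#' The six failure modes of a diagnostic assertion
#'
#' Enumerates the ways a diagnosis can fail in aboutness at the level of
#' compound expression: the disease instantiates a different (existing) type
#' than stated; the stated type does not exist; the disease instance does not
#' exist; the organism instance does not exist; the disease inheres in a
#' different organism than stated; or the configuration is not located in the
#' part of spacetime the assertion places it in.
#'
#' @return Character vector of the six mode identifiers.
#' @export
failure_modes <- function() {
  c("NONINST_TYPE_EXISTS", "NONINST_TYPE_NONEXISTENT", "DISEASE_NONEXISTENT",
    "ORGANISM_NONEXISTENT", "NON_INHERENCE", "SPACETIME_MISPLACEMENT")
}

is_iui <- function(x) is.character(x) && length(x) == 1L && grepl("^IUI-[0-9]+$", x)
is_uui <- function(x) is.character(x) && length(x) == 1L && grepl("^UUI-[0-9]+$", x)
is_tid <- function(x) is.character(x) && length(x) == 1L && grepl("^t[0-9]+$", x)

chk <- function(ok, msg, ...) if (!isTRUE(ok)) stop(sprintf(msg, ...), call. = FALSE)

new_record <- function(fields, class) {
  structure(fields, class = c(class, "rt_record"))
}

#' Declare a particular
#'
#' A particular is a concrete individual entity (a patient, a disease
#' instance, a process, an inscription) identified by an instance unique
#' identifier of the form \code{"IUI-n"}. Every particular carries a temporal
#' region during which it exists; the region may be unconstrained.
#'
#' @param iui Identifier string, \code{"IUI-n"}.
#' @param label Free-text label.
#' @param existence_interval Temporal-region identifier (\code{"tn"}).
#' @return An object of class \code{rt_particular}.
#' @export
rt_particular <- function(iui, label = iui, existence_interval) {
  chk(is_iui(iui), "invalid IUI '%s'", iui)
  chk(is_tid(existence_interval), "invalid temporal identifier '%s' for %s",
      existence_interval, iui)
  new_record(list(iui = iui, label = as.character(label),
                  existence_interval = existence_interval), "rt_particular")
}

#' Declare a universal
#'
#' A universal is a repeatable type (e.g. type 2 diabetes mellitus) identified
#' by \code{"UUI-n"}. \code{exists} records whether the type is taken to exist
#' in reality: obsolete disease types such as dropsy are declared with
#' \code{exists = FALSE} so assertions mentioning them remain parseable while
#' reference-level aboutness toward them fails.
#'
#' @param uui Identifier string, \code{"UUI-n"}.
#' @param label Free-text label.
#' @param exists Logical; does the type exist in reality?
#' @return An object of class \code{rt_universal}.
#' @export
rt_universal <- function(uui, label = uui, exists = TRUE) {
  chk(is_uui(uui), "invalid UUI '%s'", uui)
  chk(is.logical(exists) && length(exists) == 1L && !is.na(exists),
      "exists must be TRUE or FALSE")
  new_record(list(uui = uui, label = as.character(label), exists_flag = exists),
             "rt_universal")
}

#' Declare a temporal region
#'
#' Distinct temporal identifiers may denote the same underlying period;
#' identity is never assumed from distinctness and must be asserted with an
#' \code{equals} constraint when intended.
#'
#' @param tid Identifier string, \code{"tn"}.
#' @return An object of class \code{rt_region}.
#' @export
rt_region <- function(tid) {
  chk(is_tid(tid), "invalid temporal identifier '%s'", tid)
  new_record(list(tid = tid), "rt_region")
}

#' Assert a qualitative constraint between two temporal regions
#'
#' @param subject,object Temporal-region identifiers.
#' @param relation One of \code{equals}, \code{during}, \code{contains},
#'   \code{ends}, \code{starts}, \code{before}, \code{overlaps}.
#'   \code{during} means contained-in (endpoints may coincide); \code{ends}
#'   and \code{starts} are proper (share one endpoint, differ in the other);
#'   \code{before} is strict precedence; \code{overlaps} is proper partial
#'   overlap with the subject starting first.
#' @return An object of class \code{rt_constraint}.
#' @export
rt_constraint <- function(subject, relation, object) {
  chk(is_tid(subject) && is_tid(object), "constraint endpoints must be tids")
  chk(relation %in% RT_TEMPORAL_RELATIONS,
      "unknown temporal relation '%s'", relation)
  new_record(list(subject = subject, relation = relation, object = object),
             "rt_constraint")
}

#' Assert that a particular instantiates a universal during a region
#'
#' @param particular IUI of the instance.
#' @param universal UUI of the type.
#' @param at Temporal-region identifier during which the instantiation holds.
#' @return An object of class \code{rt_instantiation}.
#' @export
rt_instantiation <- function(particular, universal, at) {
  chk(is_iui(particular), "invalid IUI '%s'", particular)
  chk(is_uui(universal), "invalid UUI '%s'", universal)
  chk(is_tid(at), "invalid temporal identifier '%s'", at)
  new_record(list(particular = particular, universal = universal, at = at),
             "rt_instantiation")
}

#' Assert a relation between particulars (or toward a universal)
#'
#' \code{is_about} and \code{is_misrepresentation_of} may target an IUI
#' (including a configuration's IUI) or a UUI; every other relation targets an
#' IUI.
#'
#' @param subject IUI of the subject.
#' @param relation Relation name; see \code{\link{rt_relations}}.
#' @param object IUI or (for aboutness relations) UUI of the object.
#' @param at Temporal-region identifier.
#' @return An object of class \code{rt_relation}.
#' @export
rt_relation <- function(subject, relation, object, at) {
  chk(is_iui(subject), "invalid subject IUI '%s'", subject)
  chk(relation %in% RT_RELATIONS, "unknown relation '%s'", relation)
  if (relation %in% c("is_about", "is_misrepresentation_of")) {
    chk(is_iui(object) || is_uui(object),
        "'%s' must target an IUI or UUI, got '%s'", relation, object)
  } else {
    chk(is_iui(object), "'%s' must target an IUI, got '%s'", relation, object)
  }
  chk(is_tid(at), "invalid temporal identifier '%s'", at)
  new_record(list(subject = subject, relation = relation, object = object,
                  at = at), "rt_relation")
}

#' Relation vocabulary
#' @return Character vector of the particular-to-particular relation names.
#' @export
rt_relations <- function() RT_RELATIONS

#' Assert that a particular lacks a relation to any instance of a universal
#'
#' Expresses, temporally indexed, that the particular stands in the named
#' relation to \emph{no} instance of the universal throughout the region
#' (e.g. a patient who participated in no coughing event in the last two
#' weeks).
#'
#' @param particular IUI.
#' @param relation Relation name.
#' @param universal UUI.
#' @param during Temporal-region identifier.
#' @return An object of class \code{rt_negative}.
#' @export
rt_negative <- function(particular, relation, universal, during) {
  chk(is_iui(particular), "invalid IUI '%s'", particular)
  chk(relation %in% c(RT_RELATIONS, "instance_of", "agent_of"),
      "unknown relation '%s'", relation)
  chk(is_uui(universal), "invalid UUI '%s'", universal)
  chk(is_tid(during), "invalid temporal identifier '%s'", during)
  new_record(list(particular = particular, relation = relation,
                  universal = universal, during = during), "rt_negative")
}

#' The propositional content of a diagnostic assertion
#'
#' Records what an assertion says: which organism bears which disease of which
#' type, anchored at which portion of time, and which configuration the author
#' intended the assertion to be about. Intention is recorded data, never
#' computed: a sentence is about that to which its author was directing their
#' thoughts.
#'
#' @param asserted_organism IUI of the organism said to bear the disease, or
#'   \code{NULL}.
#' @param asserted_disease IUI of the disease instance asserted, or \code{NULL}.
#' @param asserted_type UUI of the disease type asserted (required).
#' @param asserted_anchor Temporal-region identifier the assertion places the
#'   configuration at (required).
#' @param intended_target IUI of the configuration the assertion is intended
#'   to be about (required).
#' @return An object of class \code{rt_content}.
#' @export
rt_content <- function(asserted_organism = NULL, asserted_disease = NULL,
                       asserted_type, asserted_anchor, intended_target) {
  if (!is.null(asserted_organism)) chk(is_iui(asserted_organism) || is.character(asserted_organism),
                                       "asserted_organism must be an identifier or NULL")
  if (!is.null(asserted_disease)) chk(is.character(asserted_disease),
                                      "asserted_disease must be an identifier or NULL")
  chk(is.character(asserted_type) && length(asserted_type) == 1L,
      "asserted_type is required")
  chk(is_tid(asserted_anchor), "invalid temporal identifier '%s'", asserted_anchor)
  chk(is_iui(intended_target), "intended_target must be a configuration IUI")
  new_record(list(asserted_organism = asserted_organism,
                  asserted_disease = asserted_disease,
                  asserted_type = asserted_type,
                  asserted_anchor = asserted_anchor,
                  intended_target = intended_target), "rt_content")
}

#' A concretization of an information content entity
#'
#' A representation is a quality that concretizes an ICE in some material
#' bearer: a mental quality in an anatomical part of a cognitive system
#' (\code{cognitive}), an ink pattern on paper (\code{inscription_quality}),
#' or a digital pattern on a storage medium (\code{digital}). A cognitive
#' representation's bearer must be asserted \code{part_of} some cognitive
#' system during the representation's existence.
#'
#' @param id IUI of the representation.
#' @param kind One of \code{cognitive}, \code{inscription_quality},
#'   \code{digital}.
#' @param bearer IUI of the material bearer.
#' @param concretizes IUI of the ICE concretized, or \code{NULL} while the
#'   representation is being constructed (see \code{\link{derive_new_ice}}).
#' @param exists_during Temporal-region identifier.
#' @param copied_from IUI of the representation this one was copied from, or
#'   \code{NULL} if it is an original concretization.
#' @return An object of class \code{rt_representation}.
#' @export
rt_representation <- function(id, kind, bearer, concretizes = NULL,
                              exists_during, copied_from = NULL) {
  chk(is_iui(id), "invalid IUI '%s'", id)
  chk(kind %in% RT_REPRESENTATION_KINDS, "unknown representation kind '%s'", kind)
  chk(is_iui(bearer), "invalid bearer IUI '%s'", bearer)
  if (!is.null(concretizes)) chk(is_iui(concretizes), "invalid ICE IUI '%s'", concretizes)
  chk(is_tid(exists_during), "invalid temporal identifier '%s'", exists_during)
  if (!is.null(copied_from)) chk(is_iui(copied_from), "invalid IUI '%s'", copied_from)
  new_record(list(id = id, kind = kind, bearer = bearer,
                  concretizes = concretizes, exists_during = exists_during,
                  copied_from = copied_from), "rt_representation")
}

#' An information content entity
#'
#' An ICE generically depends on material bearers through its concretizations
#' and does not exist until its first concretization does. Identity is by
#' minted identifier, never by sentence text: the same sentence written by two
#' different authors yields two ICEs.
#'
#' @param id IUI of the ICE.
#' @param content An \code{\link{rt_content}}.
#' @param concretizations Character vector of representation IUIs (at least
#'   one once the ICE exists).
#' @param produced_by IUI of the producing process, or \code{NULL}.
#' @param first_concretized_at Temporal-region identifier at which the first
#'   concretization (and hence the ICE) began to exist.
#' @return An object of class \code{rt_ice}.
#' @export
rt_ice <- function(id, content, concretizations, produced_by = NULL,
                   first_concretized_at) {
  chk(is_iui(id), "invalid IUI '%s'", id)
  chk(inherits(content, "rt_content"), "content must be an rt_content")
  chk(is.character(concretizations), "concretizations must be IUIs")
  if (!is.null(produced_by)) chk(is_iui(produced_by), "invalid process IUI '%s'", produced_by)
  chk(is_tid(first_concretized_at), "invalid temporal identifier '%s'",
      first_concretized_at)
  new_record(list(id = id, content = content,
                  concretizations = sort(unique(concretizations)),
                  produced_by = produced_by,
                  first_concretized_at = first_concretized_at), "rt_ice")
}

#' A process with an agent, inputs and outputs
#'
#' @param id IUI of the process.
#' @param agent IUI of the agent; the agent may be human or not (an expert
#'   system counts).
#' @param agent_is_human Logical.
#' @param inputs,outputs Character vectors of IUIs.
#' @param occupies Temporal-region identifier.
#' @return An object of class \code{rt_process}.
#' @export
rt_process <- function(id, agent, agent_is_human = TRUE, inputs = character(),
                       outputs = character(), occupies) {
  chk(is_iui(id), "invalid IUI '%s'", id)
  chk(is_iui(agent), "invalid agent IUI '%s'", agent)
  chk(is.logical(agent_is_human) && length(agent_is_human) == 1L,
      "agent_is_human must be logical")
  chk(is.character(inputs) && is.character(outputs), "inputs/outputs must be IUIs")
  chk(is_tid(occupies), "invalid temporal identifier '%s'", occupies)
  new_record(list(id = id, agent = agent, agent_is_human = agent_is_human,
                  inputs = sort(unique(inputs)), outputs = sort(unique(outputs)),
                  occupies = occupies), "rt_process")
}

#' An aggregate of representations of disease and phenotype types
#'
#' The knowledge structure a diagnostic agent brings to bear: representations
#' of at least one disease type paired with at least one phenotype type whose
#' instances are associated with instances of that disease. The pairing is
#' explicit data, not derived from medical knowledge.
#'
#' @param id IUI of the aggregate.
#' @param owner IUI of the agent whose representations these are.
#' @param disease_types,phenotype_types Character vectors of UUIs.
#' @param associations Data frame with columns \code{disease} and
#'   \code{phenotype} (UUIs). Defaults to the full cross of the two type sets.
#' @return An object of class \code{rt_aggregate}.
#' @export
rt_aggregate <- function(id, owner, disease_types = character(),
                         phenotype_types = character(), associations = NULL) {
  chk(is_iui(id), "invalid IUI '%s'", id)
  chk(is_iui(owner), "invalid owner IUI '%s'", owner)
  if (is.null(associations)) {
    associations <- if (length(disease_types) && length(phenotype_types)) {
      expand.grid(disease = disease_types, phenotype = phenotype_types,
                  stringsAsFactors = FALSE)
    } else {
      data.frame(disease = character(), phenotype = character())
    }
  }
  chk(is.data.frame(associations) &&
        all(c("disease", "phenotype") %in% names(associations)),
      "associations must have columns disease, phenotype")
  associations <- unique(associations[order(associations$disease,
                                            associations$phenotype),
                                      c("disease", "phenotype"), drop = FALSE])
  rownames(associations) <- NULL
  associations$disease <- as.character(associations$disease)
  associations$phenotype <- as.character(associations$phenotype)
  new_record(list(id = id, owner = owner,
                  disease_types = sort(unique(disease_types)),
                  phenotype_types = sort(unique(phenotype_types)),
                  associations = associations),
             "rt_aggregate")
}

#' A clinical picture of a patient
#'
#' A representation of a clinical phenotype inferred from a combination of,
#' for example, prior diagnoses and laboratory, image, and clinical findings
#' about a given patient. \code{inferred_from} may be empty only in degenerate
#' test knowledge bases.
#'
#' @param id IUI of the picture.
#' @param subject IUI of the patient.
#' @param inferred_from Character vector of IUIs of findings and/or prior
#'   diagnosis ICEs.
#' @param exists_during Temporal-region identifier.
#' @return An object of class \code{rt_clinical_picture}.
#' @export
rt_clinical_picture <- function(id, subject, inferred_from = character(),
                                exists_during) {
  chk(is_iui(id), "invalid IUI '%s'", id)
  chk(is_iui(subject), "invalid subject IUI '%s'", subject)
  chk(is.character(inferred_from), "inferred_from must be IUIs")
  chk(is_tid(exists_during), "invalid temporal identifier '%s'", exists_during)
  new_record(list(id = id, subject = subject,
                  inferred_from = sort(unique(inferred_from)),
                  exists_during = exists_during), "rt_clinical_picture")
}

#' A configuration: the truth-maker of a diagnostic assertion
#'
#' A combination of particulars and/or universals and the relations that hold
#' among them, anchored at a location in spacetime (reduced here to a temporal
#' region). Configurations are first-class particulars with their own IUIs.
#' Prefer \code{\link{make_configuration}}, which builds the standard
#' organism--disease--type configuration against a knowledge base.
#'
#' @param id IUI of the configuration.
#' @param members_particulars,members_universals Member identifier vectors.
#' @param constituent_relations List of \code{rt_relation} /
#'   \code{rt_instantiation} records among the members.
#' @param anchor Temporal-region identifier.
#' @return An object of class \code{rt_configuration}.
#' @export
rt_configuration <- function(id, members_particulars = character(),
                             members_universals = character(),
                             constituent_relations = list(), anchor) {
  chk(is_iui(id), "invalid IUI '%s'", id)
  chk(is_tid(anchor), "invalid temporal identifier '%s'", anchor)
  chk(is.list(constituent_relations), "constituent_relations must be a list")
  new_record(list(id = id,
                  members_particulars = sort(unique(members_particulars)),
                  members_universals = sort(unique(members_universals)),
                  constituent_relations = constituent_relations,
                  anchor = anchor), "rt_configuration")
}

#' Build the organism--disease--type configuration
#'
#' Returns the configuration whose constituents are \emph{disease inheres_in
#' organism at anchor} and \emph{disease instance_of disease_type at anchor},
#' with the organism and disease as particular members and the type as a
#' universal member. Deterministic: the same inputs give a structurally
#' identical configuration.
#'
#' @param kb Knowledge base the referents are declared in.
#' @param organism,disease IUIs of the organism and its disease.
#' @param disease_type UUI of the disease type.
#' @param anchor Temporal-region identifier anchoring the configuration.
#' @param id IUI to assign to the configuration itself; defaults to the next
#'   free IUI in \code{kb}.
#' @return An object of class \code{rt_configuration}.
#' @export
make_configuration <- function(kb, organism, disease, disease_type, anchor,
                               id = NULL) {
  stopifnot(inherits(kb, "rt_kb"))
  for (x in c(organism, disease)) {
    if (!x %in% names(kb$particulars))
      stop(sprintf("declaration error: particular '%s' is not declared", x),
           call. = FALSE)
  }
  if (!disease_type %in% names(kb$universals))
    stop(sprintf("declaration error: universal '%s' is not declared", disease_type),
         call. = FALSE)
  if (!anchor %in% names(kb$temporal_regions))
    stop(sprintf("declaration error: temporal region '%s' is not declared", anchor),
         call. = FALSE)
  if (is.null(id)) id <- next_iui(kb)
  rt_configuration(
    id = id,
    members_particulars = c(organism, disease),
    members_universals = disease_type,
    constituent_relations = list(
      rt_relation(disease, "inheres_in", organism, anchor),
      rt_instantiation(disease, disease_type, anchor)
    ),
    anchor = anchor
  )
}

#' An aboutness verdict
#'
#' @param level \code{"reference"} or \code{"compound"}.
#' @param per_referent Named character vector over referent identifiers with
#'   values \code{"holds"} / \code{"fails"}.
#' @param status \code{"holds"}, \code{"fails"} or \code{"indeterminate"}.
#' @return An object of class \code{rt_verdict}.
#' @export
rt_verdict <- function(level, per_referent, status) {
  chk(level %in% c("reference", "compound"), "bad verdict level")
  chk(status %in% c("holds", "fails", "indeterminate"), "bad verdict status")
  new_record(list(level = level, per_referent = per_referent, status = status),
             "rt_verdict")
}

#' A classification result
#'
#' @param category One of \code{correct_diagnosis}, \code{misdiagnosis},
#'   \code{lucky_guess}, \code{hearsay_copy}, \code{justified_conclusion},
#'   \code{non_ice}, \code{indeterminate}.
#' @param failure_modes Subset of \code{\link{failure_modes}()}.
#' @param fails_first \code{"reference"}, \code{"compound"} or \code{"none"}.
#' @param rationale Ordered character vector of rule identifiers fired.
#' @return An object of class \code{rt_classification}.
#' @export
rt_classification <- function(category, failure_modes = character(),
                              fails_first = "none", rationale = character()) {
  chk(category %in% RT_CATEGORIES, "unknown category '%s'", category)
  chk(all(failure_modes %in% failure_modes()), "unknown failure mode")
  chk(fails_first %in% c("reference", "compound", "none"), "bad fails_first")
  new_record(list(category = category,
                  failure_modes = sort(unique(failure_modes)),
                  fails_first = fails_first, rationale = rationale),
             "rt_classification")
}

#' @export
print.rt_record <- function(x, ...) {
  cat("<", class(x)[1L], ">\n", sep = "")
  flat <- vapply(x, function(v) {
    if (is.null(v)) return("NULL")
    if (is.data.frame(v)) return(sprintf("<%d pairs>", nrow(v)))
    if (is.list(v)) return(sprintf("<%d records>", length(v)))
    paste(format(v), collapse = ", ")
  }, character(1))
  for (nm in names(flat)) cat("  ", nm, ": ", flat[[nm]], "\n", sep = "")
  invisible(x)
}

#' Validate a record (or a list of records) against the type invariants
#'
#' Violations are returned as a character vector of descriptors, never raised.
#' Some invariants are relational (a cognitive representation's bearer must be
#' part of a cognitive system; a knowledge aggregate must pair a disease type
#' with a phenotype type to be fit for diagnosis) and are only checked when a
#' knowledge base is supplied. Idempotent and order-insensitive over a record
#' set.
#'
#' @param record An \code{rt_*} record, or an unnamed list of them.
#' @param kb Optional knowledge base for relational invariants.
#' @return Character vector of violation descriptors; empty when all hold.
#' @export
validate_record <- function(record, kb = NULL) {
  if (is.list(record) && !inherits(record, "rt_record")) {
    out <- lapply(record, validate_record, kb = kb)
    return(sort(unique(unlist(out))))
  }
  v <- character()
  if (inherits(record, "rt_ice")) {
    if (length(record$concretizations) == 0L)
      v <- c(v, sprintf("ICE %s has no concretization: an ICE does not exist until its first concretization does",
                        record$id))
    if (!is.null(kb) && !is.null(record$produced_by) &&
        record$produced_by %in% names(kb$processes)) {
      proc <- kb$processes[[record$produced_by]]
      if (!record$id %in% proc$outputs)
        v <- c(v, sprintf("ICE %s names producing process %s which does not list it among outputs",
                          record$id, record$produced_by))
    }
  }
  if (inherits(record, "rt_aggregate")) {
    if (length(record$disease_types) == 0L)
      v <- c(v, sprintf("aggregate %s is unfit for diagnosis: no disease type represented", record$id))
    if (length(record$phenotype_types) == 0L)
      v <- c(v, sprintf("aggregate %s is unfit for diagnosis: no phenotype type represented", record$id))
    if (length(record$disease_types) > 0L && length(record$phenotype_types) > 0L &&
        nrow(record$associations) == 0L)
      v <- c(v, sprintf("aggregate %s is unfit for diagnosis: no disease-phenotype association", record$id))
  }
  if (inherits(record, "rt_clinical_picture")) {
    if (!is.null(kb) && !record$subject %in% names(kb$particulars))
      v <- c(v, sprintf("clinical picture %s has undeclared subject %s",
                        record$id, record$subject))
  }
  if (inherits(record, "rt_representation")) {
    if (!is.null(kb)) {
      if (!record$bearer %in% names(kb$particulars))
        v <- c(v, sprintf("representation %s has undeclared bearer %s",
                          record$id, record$bearer))
      if (!is.null(record$concretizes) && !record$concretizes %in% names(kb$ices))
        v <- c(v, sprintf("representation %s concretizes undeclared ICE %s",
                          record$id, record$concretizes))
      if (identical(record$kind, "cognitive")) {
        part <- kb$relations[kb$relations$subject == record$bearer &
                               kb$relations$relation == "part_of", , drop = FALSE]
        if (nrow(part) == 0L)
          v <- c(v, sprintf("cognitive representation %s: bearer %s is not asserted part_of any cognitive system",
                            record$id, record$bearer))
      }
    }
  }
  if (inherits(record, "rt_configuration")) {
    mentioned <- unlist(lapply(record$constituent_relations, function(a) {
      if (inherits(a, "rt_instantiation")) c(a$particular, a$universal)
      else c(a$subject, a$object)
    }))
    members <- c(record$members_particulars, record$members_universals)
    missing <- setdiff(members, mentioned)
    if (length(missing))
      v <- c(v, sprintf("configuration %s: member %s referenced by no constituent relation",
                        record$id, missing))
  }
  if (inherits(record, "rt_classification")) {
    benign <- c("correct_diagnosis", "lucky_guess", "hearsay_copy",
                "justified_conclusion", "indeterminate")
    if (record$category %in% benign && length(record$failure_modes) > 0L)
      v <- c(v, sprintf("classification '%s' must carry no failure modes", record$category))
    if (record$category %in% c("misdiagnosis", "non_ice") &&
        length(record$failure_modes) == 0L)
      v <- c(v, sprintf("classification '%s' must carry at least one failure mode",
                        record$category))
  }
  if (inherits(record, "rt_verdict")) {
    if (identical(record$level, "compound") &&
        any(record$per_referent == "fails") && record$status == "holds")
      v <- c(v, "compound verdict cannot hold while a reference-level entry fails")
  }
  sort(unique(v))
}
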