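#' @title Provenance: ICE identity across concretizations
#' @description
#' An information content entity is identified by its minted identifier, not
#' by sentence text: the same sentence written by two different authors can
#' concretize two different ICEs, and copying a sentence one does not even
#' understand concretizes the original. These operations implement the two
#' ways a new representation can come into being -- copying an existing
#' concretization (no new ICE) and authoring a new ICE from one's own
#' cognitive representation -- plus the conformance relation between
#' concretizations of the same ICE.
#' @name provenance
NULL

#' Copy a concretization of an existing ICE
#'
#' The copy concretizes the same ICE as the source: the knowledge base's ICE
#' count is unchanged. No comprehension of the content is required -- one can
#' copy text one does not understand -- so no cognitive representation and no
#' re-derivation of the intended target takes place. The copy is marked with
#' its source, which the classifier uses to recognize hearsay.
#'
#' @param kb An \code{rt_kb}.
#' @param source IUI of the representation being copied; must concretize an
#'   ICE in \code{kb}.
#' @param new_bearer IUI of the declared material bearer of the copy.
#' @param kind Kind of the copy (\code{inscription_quality}, \code{digital},
#'   \code{cognitive}).
#' @param exists_during Temporal region of the copy; defaults to the
#'   source's.
#' @param id IUI for the copy; defaults to the next free IUI.
#' @return List with elements \code{kb} (updated) and \code{representation}
#'   (the new \code{rt_representation}).
#' @export
copy_concretization <- function(kb, source, new_bearer, kind,
                                exists_during = NULL, id = NULL) {
  stopifnot(inherits(kb, "rt_kb"))
  src <- kb$representations[[source]]
  if (is.null(src)) decl_err("representation", source)
  if (is.null(src$concretizes) || !src$concretizes %in% names(kb$ices))
    stop(sprintf("representation '%s' does not concretize an ICE in the knowledge base",
                 source), call. = FALSE)
  if (!new_bearer %in% names(kb$particulars)) decl_err("bearer", new_bearer)
  if (is.null(exists_during)) exists_during <- src$exists_during
  if (is.null(id)) id <- next_iui(kb)
  rep <- rt_representation(id, kind = kind, bearer = new_bearer,
                           concretizes = src$concretizes,
                           exists_during = exists_during,
                           copied_from = source)
  kb <- kb_add(kb, rep)
  ice <- kb$ices[[src$concretizes]]
  ice$concretizations <- sort(unique(c(ice$concretizations, id)))
  kb$ices[[src$concretizes]] <- ice
  kb <- kb_add(kb, rt_relation(id, "concretizes", src$concretizes, exists_during))
  list(kb = kb, representation = rep)
}

#' Author a new ICE from a first concretization
#'
#' Creating one's own representation of a portion of reality -- forming a
#' belief that it exists as represented -- brings a new ICE into being, even
#' when the resulting sentence is word-for-word identical to an existing one.
#' The knowledge base's ICE count increases by exactly one, the producing
#' process gains the ICE among its outputs, and the ICE's first
#' concretization timestamp is the representation's existence region.
#'
#' @param kb An \code{rt_kb}.
#' @param author IUI of the authoring agent (declared).
#' @param process IUI of the producing process in \code{kb}.
#' @param content The \code{\link{rt_content}} of the new ICE; must carry an
#'   intended target.
#' @param first_concretization An \code{rt_representation} whose
#'   \code{concretizes} field is unset on entry.
#' @param id IUI for the new ICE; defaults to the next free IUI.
#' @return List with elements \code{kb} (updated) and \code{ice}.
#' @export
derive_new_ice <- function(kb, author, process, content, first_concretization,
                           id = NULL) {
  stopifnot(inherits(kb, "rt_kb"),
            inherits(first_concretization, "rt_representation"))
  require_iui(kb, author)
  if (!process %in% names(kb$processes)) decl_err("process", process)
  if (!inherits(content, "rt_content") || is.null(content$intended_target))
    stop("validation error: content must carry an intended_target", call. = FALSE)
  if (!is.null(first_concretization$concretizes))
    stop(sprintf("representation '%s' already concretizes '%s'; use copy_concretization to copy",
                 first_concretization$id, first_concretization$concretizes),
         call. = FALSE)
  if (is.null(id)) id <- next_iui(kb)
  rep <- first_concretization
  rep$concretizes <- id
  ice <- rt_ice(id, content = content, concretizations = rep$id,
                produced_by = process,
                first_concretized_at = rep$exists_during)
  kb <- kb_add(kb, ice)
  kb <- kb_add(kb, rep)
  proc <- kb$processes[[process]]
  proc$outputs <- sort(unique(c(proc$outputs, id)))
  kb$processes[[process]] <- proc
  kb <- kb_add(kb, rt_relation(rep$id, "concretizes", id, rep$exists_during))
  kb <- kb_add(kb, rt_relation(id, "output_of", process, rep$exists_during))
  list(kb = kb, ice = ice)
}

#' Are two representations conformant?
#'
#' True iff both concretize the same ICE. Conformance is an equivalence
#' relation over the representations of a knowledge base that concretize
#' something.
#'
#' @param kb An \code{rt_kb}.
#' @param a,b IUIs of declared representations.
#' @return Logical.
#' @export
check_conformance <- function(kb, a, b) {
  stopifnot(inherits(kb, "rt_kb"))
  ra <- kb$representations[[a]]; rb <- kb$representations[[b]]
  if (is.null(ra)) decl_err("representation", a)
  if (is.null(rb)) decl_err("representation", b)
  !is.null(ra$concretizes) && !is.null(rb$concretizes) &&
    identical(ra$concretizes, rb$concretizes)
}
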