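#' @title Two-level aboutness evaluation
#' @description
#' A diagnostic assertion can succeed or fail in aboutness on two levels: the
#' level of reference (denoting the individual organism, disease instance and
#' disease type it mentions) and the level of compound expression (veridically
#' representing the whole configuration of those entities). Failure at the
#' level of reference implies failure at the level of compound expression,
#' because a configuration cannot consist of that which does not exist; but an
#' assertion that fails as a compound can still be about its referents
#' individually, and is then an information content entity nonetheless.
#' @name aboutness
NULL

reference_map <- function(content, kb) {
  out <- character()
  if (!is.null(content$asserted_organism)) {
    out[content$asserted_organism] <-
      if (content$asserted_organism %in% names(kb$particulars)) "holds" else "fails"
  }
  if (!is.null(content$asserted_disease)) {
    out[content$asserted_disease] <-
      if (content$asserted_disease %in% names(kb$particulars)) "holds" else "fails"
  }
  u <- kb$universals[[content$asserted_type]]
  out[content$asserted_type] <-
    if (!is.null(u) && isTRUE(u$exists_flag)) "holds" else "fails"
  out
}

#' Evaluate aboutness at the level of reference
#'
#' Each mentioned referent holds when it denotes something that exists in the
#' knowledge base's closed world: a declared particular, or a declared
#' universal flagged as existing. The verdict's status holds when at least
#' one referent holds -- an assertion about \emph{something} is an information
#' content entity even if it misrepresents the whole.
#'
#' @param content An \code{\link{rt_content}}.
#' @param kb An \code{rt_kb}.
#' @return An \code{\link{rt_verdict}} with \code{level = "reference"}.
#' @export
evaluate_reference <- function(content, kb) {
  stopifnot(inherits(content, "rt_content"), inherits(kb, "rt_kb"))
  per <- reference_map(content, kb)
  status <- if (any(per == "holds")) "holds" else "fails"
  rt_verdict("reference", per, status)
}

compound_components <- function(content, kb) {
  per <- reference_map(content, kb)
  all_ref <- !is.null(content$asserted_organism) &&
    !is.null(content$asserted_disease) && length(per) == 3L &&
    all(per == "holds")
  inherence <- all_ref &&
    nrow(kb$relations[kb$relations$subject == content$asserted_disease &
                        kb$relations$relation == "inheres_in" &
                        kb$relations$object == content$asserted_organism, ,
                      drop = FALSE]) > 0L
  instantiation <- all_ref &&
    nrow(kb$instantiations[kb$instantiations$particular == content$asserted_disease &
                             kb$instantiations$universal == content$asserted_type, ,
                           drop = FALSE]) > 0L
  cfg <- kb$configurations[[content$intended_target]]
  timing <- if (is.null(cfg)) "fails"
  else entails_intersects(kb, content$asserted_anchor, cfg$anchor)
  list(per = per, all_ref = all_ref, inherence = inherence,
       instantiation = instantiation, timing = timing)
}

#' Evaluate aboutness at the level of compound expression
#'
#' Holds iff (a) every mentioned referent holds at the level of reference,
#' (b) the knowledge base entails that the asserted disease inheres in the
#' asserted organism and instantiates the asserted type, and (c) the
#' assertion's temporal anchor is entailed to pick out part of the time
#' occupied by the intended configuration. Fails when any component fails;
#' indeterminate only when (a) and (b) hold and the timing condition is
#' undecided by the constraint network.
#'
#' @inheritParams evaluate_reference
#' @return An \code{\link{rt_verdict}} with \code{level = "compound"}.
#' @export
evaluate_compound <- function(content, kb) {
  stopifnot(inherits(content, "rt_content"), inherits(kb, "rt_kb"))
  cc <- compound_components(content, kb)
  status <- if (!cc$all_ref || !cc$inherence || !cc$instantiation ||
                cc$timing == "fails") "fails"
  else if (cc$timing == "indeterminate") "indeterminate"
  else "holds"
  rt_verdict("compound", cc$per, status)
}

#' Derive is-about and is-misrepresentation-of assertions
#'
#' For a representation concretizing an information content entity in the
#' knowledge base, emits \code{is_about} toward every referent that holds at
#' the level of reference; \code{is_about} toward the intended configuration
#' when compound aboutness holds; and \code{is_misrepresentation_of} toward
#' the intended configuration when it fails (a misrepresentation is a
#' representation intended to be about a portion of reality that is not about
#' it). When the compound verdict is indeterminate, neither relation toward
#' the target is emitted. The definition precludes misrepresentation of any
#' configuration other than the intended one.
#'
#' @param kb An \code{rt_kb}.
#' @param representation IUI of a representation in \code{kb}.
#' @return Data frame of derived assertions (columns subject, relation,
#'   object, at), canonically ordered.
#' @export
infer_aboutness_relations <- function(kb, representation) {
  stopifnot(inherits(kb, "rt_kb"))
  rep <- kb$representations[[representation]]
  if (is.null(rep)) decl_err("representation", representation)
  if (is.null(rep$concretizes) || !rep$concretizes %in% names(kb$ices))
    stop(sprintf("declaration error: representation '%s' has a dangling concretizes reference",
                 representation), call. = FALSE)
  content <- kb$ices[[rep$concretizes]]$content
  ref <- evaluate_reference(content, kb)
  comp <- evaluate_compound(content, kb)
  rows <- empty_relations_df()
  for (r in names(ref$per_referent)) {
    if (ref$per_referent[[r]] == "holds")
      rows <- rbind(rows, data.frame(subject = representation,
                                     relation = "is_about", object = r,
                                     at = rep$exists_during,
                                     stringsAsFactors = FALSE))
  }
  if (comp$status == "holds") {
    rows <- rbind(rows, data.frame(subject = representation,
                                   relation = "is_about",
                                   object = content$intended_target,
                                   at = rep$exists_during,
                                   stringsAsFactors = FALSE))
  } else if (comp$status == "fails") {
    rows <- rbind(rows, data.frame(subject = representation,
                                   relation = "is_misrepresentation_of",
                                   object = content$intended_target,
                                   at = rep$exists_during,
                                   stringsAsFactors = FALSE))
  }
  rows <- unique(rows)
  rows <- rows[do.call(order, rows), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
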