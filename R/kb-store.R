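#' @title Knowledge base: tuple store and temporal entailment
#' @description
#' Holds all assertions of one scenario, answers temporally indexed queries,
#' and entails consequences of qualitative temporal constraints under a
#' three-valued regime (holds / fails / indeterminate). The store is
#' closed-world over particulars: a scenario knowledge base is taken to
#' enumerate all relevant particulars, so reference-level existence checks are
#' decidable; only temporal entailment may be indeterminate.
#' @name kb-store
NULL

empty_relations_df <- function() {
  data.frame(subject = character(), relation = character(),
             object = character(), at = character(), stringsAsFactors = FALSE)
}

#' Create an empty knowledge base
#'
#' @return An object of class \code{rt_kb} with empty collections for
#'   particulars, universals, temporal regions and constraints,
#'   instantiation/relation/negative assertions, configurations, ICEs,
#'   representations, processes, clinical pictures and knowledge aggregates.
#' @export
rt_kb <- function() {
  structure(list(
    particulars = list(),
    universals = list(),
    temporal_regions = list(),
    temporal_constraints = data.frame(subject = character(),
                                      relation = character(),
                                      object = character(),
                                      stringsAsFactors = FALSE),
    instantiations = data.frame(particular = character(),
                                universal = character(), at = character(),
                                stringsAsFactors = FALSE),
    relations = empty_relations_df(),
    negatives = data.frame(particular = character(), relation = character(),
                           universal = character(), during = character(),
                           stringsAsFactors = FALSE),
    configurations = list(),
    ices = list(),
    representations = list(),
    processes = list(),
    clinical_pictures = list(),
    knowledge_aggregates = list(),
    metadata = list()
  ), class = "rt_kb")
}

#' @export
print.rt_kb <- function(x, ...) {
  cat("<rt_kb>",
      sprintf("%d particulars, %d universals, %d temporal regions",
              length(x$particulars), length(x$universals),
              length(x$temporal_regions)),
      sprintf("%d constraints, %d instantiations, %d relations, %d negatives",
              nrow(x$temporal_constraints), nrow(x$instantiations),
              nrow(x$relations), nrow(x$negatives)),
      sprintf("%d configurations, %d ICEs, %d representations, %d processes",
              length(x$configurations), length(x$ices),
              length(x$representations), length(x$processes)),
      sep = "\n  ")
  cat("\n")
  invisible(x)
}

kb_known_iuis <- function(kb) {
  unique(c(names(kb$particulars), names(kb$configurations), names(kb$ices),
           names(kb$representations), names(kb$processes),
           names(kb$clinical_pictures), names(kb$knowledge_aggregates)))
}

next_iui <- function(kb) {
  ids <- kb_known_iuis(kb)
  n <- if (length(ids)) max(as.integer(sub("^IUI-", "", ids))) else 0L
  sprintf("IUI-%d", n + 1L)
}

decl_err <- function(kind, id) {
  stop(sprintf("declaration error: %s '%s' is not declared", kind, id),
       call. = FALSE)
}

require_iui <- function(kb, id) if (!id %in% kb_known_iuis(kb)) decl_err("particular", id)
require_uui <- function(kb, id) if (!id %in% names(kb$universals)) decl_err("universal", id)
require_tid <- function(kb, id) if (!id %in% names(kb$temporal_regions)) decl_err("temporal region", id)

add_keyed <- function(kb, slot, key, record) {
  old <- kb[[slot]][[key]]
  if (!is.null(old) && !identical(old, record))
    stop(sprintf("identifier collision: '%s' already declared with different content", key),
         call. = FALSE)
  kb[[slot]][[key]] <- record
  kb[[slot]] <- kb[[slot]][order(names(kb[[slot]]))]
  kb
}

add_row_dedup <- function(df, row) {
  df <- rbind(df, row)
  df <- unique(df)
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Add a record or assertion to a knowledge base
#'
#' Referential closure is enforced at insertion: every identifier an
#' assertion mentions must already be declared. Adding an identical record
#' twice is silently idempotent; adding a different record under an existing
#' identifier is an error. Insertion order never affects any later
#' evaluation.
#'
#' @param kb An \code{rt_kb}.
#' @param record Any \code{rt_*} record, or an unnamed list of them (added in
#'   order).
#' @return The updated knowledge base.
#' @export
kb_add <- function(kb, record) {
  stopifnot(inherits(kb, "rt_kb"))
  if (is.list(record) && !inherits(record, "rt_record")) {
    for (r in record) kb <- kb_add(kb, r)
    return(kb)
  }
  UseMethod("kb_add", record)
}

#' @export
kb_add.rt_particular <- function(kb, record) {
  require_tid(kb, record$existence_interval)
  add_keyed(kb, "particulars", record$iui, record)
}

#' @export
kb_add.rt_universal <- function(kb, record) {
  add_keyed(kb, "universals", record$uui, record)
}

#' @export
kb_add.rt_region <- function(kb, record) {
  add_keyed(kb, "temporal_regions", record$tid, record)
}

#' @export
kb_add.rt_constraint <- function(kb, record) {
  require_tid(kb, record$subject); require_tid(kb, record$object)
  kb$temporal_constraints <- add_row_dedup(
    kb$temporal_constraints,
    data.frame(subject = record$subject, relation = record$relation,
               object = record$object, stringsAsFactors = FALSE))
  kb
}

#' @export
kb_add.rt_instantiation <- function(kb, record) {
  require_iui(kb, record$particular); require_uui(kb, record$universal)
  require_tid(kb, record$at)
  kb$instantiations <- add_row_dedup(
    kb$instantiations,
    data.frame(particular = record$particular, universal = record$universal,
               at = record$at, stringsAsFactors = FALSE))
  kb
}

#' @export
kb_add.rt_relation <- function(kb, record) {
  require_iui(kb, record$subject)
  if (grepl("^UUI-", record$object)) require_uui(kb, record$object)
  else require_iui(kb, record$object)
  require_tid(kb, record$at)
  kb$relations <- add_row_dedup(
    kb$relations,
    data.frame(subject = record$subject, relation = record$relation,
               object = record$object, at = record$at, stringsAsFactors = FALSE))
  kb
}

#' @export
kb_add.rt_negative <- function(kb, record) {
  require_iui(kb, record$particular); require_uui(kb, record$universal)
  require_tid(kb, record$during)
  kb$negatives <- add_row_dedup(
    kb$negatives,
    data.frame(particular = record$particular, relation = record$relation,
               universal = record$universal, during = record$during,
               stringsAsFactors = FALSE))
  kb
}

#' @export
kb_add.rt_configuration <- function(kb, record) {
  for (p in record$members_particulars) require_iui(kb, p)
  for (u in record$members_universals) require_uui(kb, u)
  require_tid(kb, record$anchor)
  add_keyed(kb, "configurations", record$id, record)
}

#' @export
kb_add.rt_ice <- function(kb, record) {
  require_tid(kb, record$first_concretized_at)
  add_keyed(kb, "ices", record$id, record)
}

#' @export
kb_add.rt_representation <- function(kb, record) {
  if (!record$bearer %in% names(kb$particulars)) decl_err("bearer", record$bearer)
  require_tid(kb, record$exists_during)
  add_keyed(kb, "representations", record$id, record)
}

#' @export
kb_add.rt_process <- function(kb, record) {
  require_iui(kb, record$agent)
  for (x in c(record$inputs, record$outputs)) require_iui(kb, x)
  require_tid(kb, record$occupies)
  add_keyed(kb, "processes", record$id, record)
}

#' @export
kb_add.rt_clinical_picture <- function(kb, record) {
  require_iui(kb, record$subject)
  for (x in record$inferred_from) require_iui(kb, x)
  require_tid(kb, record$exists_during)
  add_keyed(kb, "clinical_pictures", record$id, record)
}

#' @export
kb_add.rt_aggregate <- function(kb, record) {
  require_iui(kb, record$owner)
  for (u in c(record$disease_types, record$phenotype_types)) require_uui(kb, u)
  add_keyed(kb, "knowledge_aggregates", record$id, record)
}

#' Query assertions by pattern
#'
#' Exact-match filtering over the relation assertions (instantiations appear
#' with relation \code{"instance_of"}); \code{"*"} matches anything. The
#' result is a canonically ordered data frame with no duplicates, invariant
#' under insertion order and serialization round-trips.
#'
#' @param kb An \code{rt_kb}.
#' @param subject,relation,object,at Identifier or \code{"*"}.
#' @return Data frame with columns subject, relation, object, at.
#' @export
kb_query <- function(kb, subject = "*", relation = "*", object = "*", at = "*") {
  stopifnot(inherits(kb, "rt_kb"))
  inst <- kb$instantiations
  rows <- rbind(kb$relations,
                data.frame(subject = inst$particular,
                           relation = rep_len("instance_of", nrow(inst)),
                           object = inst$universal, at = inst$at,
                           stringsAsFactors = FALSE))
  keep <- rep(TRUE, nrow(rows))
  if (subject != "*") keep <- keep & rows$subject == subject
  if (relation != "*") keep <- keep & rows$relation == relation
  if (object != "*") keep <- keep & rows$object == object
  if (at != "*") keep <- keep & rows$at == at
  rows <- unique(rows[keep, , drop = FALSE])
  rows <- rows[do.call(order, rows), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}

## ---- qualitative temporal reasoning -------------------------------------
##
## Each named interval relation is translated to endpoint constraints in the
## point algebra over {<, <=, =}; entailment is decided on the strictness-
## tracking transitive closure of the endpoint graph. This fragment is convex,
## so the closure is complete (verified against a brute-force enumeration
## oracle in the test suite).

## point constraints for "a REL b"; each row: x, op, y  meaning x OP y,
## endpoints written "<tid>-" (start) and "<tid>+" (end)
point_constraints <- function(a, relation, b) {
  s <- function(t) paste0(t, "-"); e <- function(t) paste0(t, "+")
  switch(relation,
    equals   = list(c(s(a), "=",  s(b)), c(e(a), "=",  e(b))),
    during   = list(c(s(b), "<=", s(a)), c(e(a), "<=", e(b))),
    contains = list(c(s(a), "<=", s(b)), c(e(b), "<=", e(a))),
    ends     = list(c(e(a), "=",  e(b)), c(s(b), "<",  s(a))),
    starts   = list(c(s(a), "=",  s(b)), c(e(a), "<",  e(b))),
    before   = list(c(e(a), "<",  s(b))),
    overlaps = list(c(s(a), "<",  s(b)), c(s(b), "<",  e(a)),
                    c(e(a), "<",  e(b))),
    stop(sprintf("unknown temporal relation '%s'", relation), call. = FALSE)
  )
}

## closure matrix codes: 0 = no info, 1 = <=, 2 = <
point_closure <- function(nodes, cons) {
  n <- length(nodes)
  M <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  diag(M) <- 1L
  put <- function(M, x, y, code) {
    i <- match(x, nodes); j <- match(y, nodes)
    M[i, j] <- max(M[i, j], code)
    M
  }
  for (cn in cons) {
    x <- cn[1]; op <- cn[2]; y <- cn[3]
    if (op == "=") { M <- put(M, x, y, 1L); M <- put(M, y, x, 1L) }
    else M <- put(M, x, y, if (op == "<") 2L else 1L)
  }
  for (k in seq_len(n)) {
    ik <- M[, k]; kj <- M[k, ]
    reach_i <- which(ik > 0L)
    reach_j <- which(kj > 0L)
    if (!length(reach_i) || !length(reach_j)) next
    block <- outer(ik[reach_i] == 2L, kj[reach_j] == 2L, "|")
    cand <- matrix(1L, length(reach_i), length(reach_j))
    cand[block] <- 2L
    M[reach_i, reach_j] <- pmax(M[reach_i, reach_j, drop = FALSE], cand)
  }
  M
}

kb_point_network <- function(kb, extra = list()) {
  tids <- names(kb$temporal_regions)
  nodes <- as.vector(rbind(paste0(tids, "-"), paste0(tids, "+")))
  cons <- list()
  for (t in tids) cons[[length(cons) + 1L]] <- c(paste0(t, "-"), "<", paste0(t, "+"))
  tc <- kb$temporal_constraints
  for (i in seq_len(nrow(tc)))
    cons <- c(cons, point_constraints(tc$subject[i], tc$relation[i], tc$object[i]))
  cons <- c(cons, extra)
  list(nodes = nodes, cons = cons, M = point_closure(nodes, cons))
}

closure_inconsistent <- function(net) {
  bad <- which(diag(net$M) == 2L)
  if (!length(bad)) return(NULL)
  i <- bad[1]
  partners <- which(net$M[i, ] > 0L & net$M[, i] > 0L)
  unique(sub("[-+]$", "", net$nodes[unique(c(i, partners))]))
}

stop_if_inconsistent <- function(net) {
  cyc <- closure_inconsistent(net)
  if (!is.null(cyc))
    stop(sprintf("inconsistent temporal constraint network: violating cycle involves {%s}",
                 paste(cyc, collapse = ", ")), call. = FALSE)
}

entailed_point <- function(M, x, op, y) {
  i <- match(x, rownames(M)); j <- match(y, colnames(M))
  switch(op,
         "<"  = M[i, j] == 2L,
         "<=" = M[i, j] >= 1L,
         "="  = M[i, j] >= 1L && M[j, i] >= 1L)
}

possible_with <- function(net, extra) {
  M2 <- point_closure(net$nodes, c(net$cons, extra))
  all(diag(M2) != 2L)
}

#' Three-valued temporal entailment
#'
#' Decides whether the declared constraint network entails, refutes, or
#' leaves open that region \code{a} stands in \code{relation} to region
#' \code{b}. Returns \code{"holds"} when entailed, \code{"fails"} when the
#' negation is entailed (the relation is impossible in every model of the
#' network), and \code{"indeterminate"} otherwise. Declared constraints are
#' closed under composition at the endpoint level; distinct identifiers may
#' still denote the same period, so \code{equals} is never assumed from
#' distinctness.
#'
#' @param kb An \code{rt_kb} with both regions declared.
#' @param a,b Temporal-region identifiers.
#' @param relation One of the seven named relations; see
#'   \code{\link{rt_constraint}}.
#' @return \code{"holds"}, \code{"fails"} or \code{"indeterminate"}.
#' @export
entails_temporal <- function(kb, a, relation, b) {
  stopifnot(inherits(kb, "rt_kb"))
  require_tid(kb, a); require_tid(kb, b)
  net <- kb_point_network(kb)
  stop_if_inconsistent(net)
  cons <- point_constraints(a, relation, b)
  all_hold <- all(vapply(cons, function(cn)
    entailed_point(net$M, cn[1], cn[2], cn[3]), logical(1)))
  if (all_hold) return("holds")
  if (!possible_with(net, cons)) return("fails")
  "indeterminate"
}

#' Entailed temporal intersection
#'
#' Decides whether two regions are entailed to share more than a boundary
#' instant (\code{"holds"}), entailed disjoint (\code{"fails"}), or neither
#' (\code{"indeterminate"}). This is the timing condition used by compound
#' aboutness: an assertion's anchor must pick out some part, not necessarily
#' the entirety, of the time occupied by the configuration.
#'
#' @param kb An \code{rt_kb}.
#' @param a,b Temporal-region identifiers.
#' @return \code{"holds"}, \code{"fails"} or \code{"indeterminate"}.
#' @export
entails_intersects <- function(kb, a, b) {
  stopifnot(inherits(kb, "rt_kb"))
  require_tid(kb, a); require_tid(kb, b)
  net <- kb_point_network(kb)
  stop_if_inconsistent(net)
  cons <- list(c(paste0(a, "-"), "<", paste0(b, "+")),
               c(paste0(b, "-"), "<", paste0(a, "+")))
  all_hold <- all(vapply(cons, function(cn)
    entailed_point(net$M, cn[1], cn[2], cn[3]), logical(1)))
  if (all_hold) return("holds")
  if (!possible_with(net, cons)) return("fails")
  "indeterminate"
}

#' Check a knowledge base for internal inconsistencies
#'
#' Reports, without raising: (a) relation and instantiation assertions whose
#' temporal index is entailed to fall outside a relatum's existence interval;
#' (b) clashes between a positive assertion and a negative assertion over an
#' entailed-overlapping region (identical identifiers are not required, since
#' distinct identifiers may denote the same period); (c) inconsistent
#' temporal constraint networks; (d) dangling references from ICEs,
#' representations and configurations, plus record-level invariant breaches.
#'
#' @param kb An \code{rt_kb}.
#' @return Character vector of violation descriptors; empty when consistent.
#' @export
check_consistency <- function(kb) {
  stopifnot(inherits(kb, "rt_kb"))
  v <- character()

  net <- kb_point_network(kb)
  cyc <- closure_inconsistent(net)
  if (!is.null(cyc)) {
    return(sprintf("temporal inconsistency: violating cycle involves {%s}",
                   paste(cyc, collapse = ", ")))
  }

  intersects <- function(a, b) {
    cons <- list(c(paste0(a, "-"), "<", paste0(b, "+")),
                 c(paste0(b, "-"), "<", paste0(a, "+")))
    if (all(vapply(cons, function(cn)
      entailed_point(net$M, cn[1], cn[2], cn[3]), logical(1)))) return("holds")
    if (!possible_with(net, cons)) return("fails")
    "indeterminate"
  }

  existence_of <- function(id) {
    p <- kb$particulars[[id]]
    if (!is.null(p)) p$existence_interval else NULL
  }

  rows <- kb_query(kb)
  for (i in seq_len(nrow(rows))) {
    for (side in c("subject", "object")) {
      id <- rows[[side]][i]
      ex <- existence_of(id)
      if (is.null(ex)) next
      if (intersects(rows$at[i], ex) == "fails")
        v <- c(v, sprintf("assertion '%s %s %s at %s': region %s is entailed disjoint from %s's existence interval %s",
                          rows$subject[i], rows$relation[i], rows$object[i],
                          rows$at[i], rows$at[i], id, ex))
    }
  }

  neg <- kb$negatives
  for (i in seq_len(nrow(neg))) {
    if (neg$relation[i] == "instance_of") {
      pos <- kb$instantiations[kb$instantiations$particular == neg$particular[i] &
                                 kb$instantiations$universal == neg$universal[i], ,
                               drop = FALSE]
      ats <- pos$at
    } else {
      pos <- kb$relations[kb$relations$subject == neg$particular[i] &
                            kb$relations$relation == neg$relation[i], , drop = FALSE]
      ats <- character()
      for (j in seq_len(nrow(pos))) {
        obj <- pos$object[j]
        inst <- kb$instantiations[kb$instantiations$particular == obj &
                                    kb$instantiations$universal == neg$universal[i], ,
                                  drop = FALSE]
        if (nrow(inst) > 0L) ats <- c(ats, pos$at[j])
      }
    }
    for (at in ats) {
      if (intersects(at, neg$during[i]) == "holds")
        v <- c(v, sprintf("clash: positive assertion at %s contradicts negative assertion that %s stands in %s to no instance of %s during %s",
                          at, neg$particular[i], neg$relation[i],
                          neg$universal[i], neg$during[i]))
    }
  }

  known <- kb_known_iuis(kb)
  for (ice in kb$ices) {
    for (r in ice$concretizations) {
      if (!r %in% names(kb$representations))
        v <- c(v, sprintf("ICE %s lists undeclared concretization %s", ice$id, r))
    }
    if (!is.null(ice$produced_by) && !ice$produced_by %in% names(kb$processes))
      v <- c(v, sprintf("ICE %s produced by undeclared process %s",
                        ice$id, ice$produced_by))
  }
  for (rep in kb$representations) {
    if (!is.null(rep$concretizes) && !rep$concretizes %in% names(kb$ices))
      v <- c(v, sprintf("representation %s concretizes undeclared ICE %s",
                        rep$id, rep$concretizes))
  }
  for (cfg in kb$configurations) {
    for (m in cfg$members_particulars)
      if (!m %in% known)
        v <- c(v, sprintf("configuration %s has undeclared member %s", cfg$id, m))
  }

  v <- c(v, validate_record(unname(c(kb$particulars, kb$universals,
                                     kb$configurations, kb$ices,
                                     kb$representations, kb$processes,
                                     kb$clinical_pictures,
                                     kb$knowledge_aggregates)), kb = kb))
  sort(unique(v))
}
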