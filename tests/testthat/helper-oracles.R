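# Independent brute-force oracles.
#
# The temporal oracle enumerates every assignment of interval endpoints on an
# integer timeline of length 2n (enough values to realize every ordering of
# 2n endpoints) and evaluates constraints and queries by direct arithmetic
# comparison -- no shared code with the package's point-algebra closure.

# all (s, e) pairs with s < e on 1..T
oracle_pairs <- function(T) {
  g <- expand.grid(s = seq_len(T), e = seq_len(T))
  as.matrix(g[g$s < g$e, , drop = FALSE])
}

# direct semantics of the seven named relations on concrete endpoints
oracle_sat <- function(relation, as, ae, bs, be) {
  switch(relation,
         equals   = as == bs & ae == be,
         during   = bs <= as & ae <= be,
         contains = as <= bs & be <= ae,
         ends     = ae == be & bs < as,
         starts   = as == bs & ae < be,
         before   = ae < bs,
         overlaps = as < bs & bs < ae & ae < be,
         stop("unknown relation"))
}

# enumerate all models of a constraint network over intervals `tids`
# (data.frame subject/relation/object); returns matrices of satisfying
# endpoint assignments (one row per model). Intervals are joined one at a
# time, applying every constraint whose endpoints are already placed, so the
# enumeration is pruned as it grows.
oracle_models <- function(tids, constraints, T = 2L * length(tids)) {
  pairs <- oracle_pairs(T)
  S <- matrix(integer(), 1L, 0L); E <- matrix(integer(), 1L, 0L)
  placed <- character()
  for (t in tids) {
    reps <- nrow(pairs)
    S <- cbind(S[rep(seq_len(nrow(S)), each = reps), , drop = FALSE],
               rep(pairs[, "s"], times = max(1L, nrow(S))))
    E <- cbind(E[rep(seq_len(nrow(E)), each = reps), , drop = FALSE],
               rep(pairs[, "e"], times = max(1L, nrow(E))))
    placed <- c(placed, t)
    colnames(S) <- placed; colnames(E) <- placed
    cc <- constraints[constraints$subject %in% placed &
                        constraints$object %in% placed &
                        (constraints$subject == t | constraints$object == t), ,
                      drop = FALSE]
    keep <- rep(TRUE, nrow(S))
    for (i in seq_len(nrow(cc))) {
      a <- cc$subject[i]; b <- cc$object[i]
      keep <- keep & oracle_sat(cc$relation[i], S[, a], E[, a], S[, b], E[, b])
    }
    S <- S[keep, , drop = FALSE]; E <- E[keep, , drop = FALSE]
    if (!nrow(S)) break
  }
  list(S = S, E = E)
}

# three-valued verdict for "a relation b" across all models
oracle_entails <- function(models, a, relation, b) {
  sat <- oracle_sat(relation, models$S[, a], models$E[, a],
                    models$S[, b], models$E[, b])
  if (all(sat)) "holds" else if (!any(sat)) "fails" else "indeterminate"
}

# three-valued verdict for strict temporal intersection across all models
oracle_intersects <- function(models, a, b) {
  sat <- models$S[, a] < models$E[, b] & models$S[, b] < models$E[, a]
  if (all(sat)) "holds" else if (!any(sat)) "fails" else "indeterminate"
}

# a random constraint network as (kb, tids, constraints); may be inconsistent
random_network <- function(n, m = n) {
  tids <- sprintf("t%d", seq_len(n))
  kb <- rt_kb()
  for (t in tids) kb <- kb_add(kb, rt_region(t))
  cons <- data.frame(subject = character(), relation = character(),
                     object = character(), stringsAsFactors = FALSE)
  rels <- c("equals", "during", "contains", "ends", "starts", "before",
            "overlaps")
  for (i in seq_len(m)) {
    ab <- sample(tids, 2L)
    r <- sample(rels, 1L)
    cons <- rbind(cons, data.frame(subject = ab[1], relation = r,
                                   object = ab[2], stringsAsFactors = FALSE))
  }
  cons <- unique(cons)
  for (i in seq_len(nrow(cons)))
    kb <- kb_add(kb, rt_constraint(cons$subject[i], cons$relation[i],
                                   cons$object[i]))
  list(kb = kb, tids = tids, constraints = cons)
}

# ---- compound-aboutness oracle -------------------------------------------
#
# Exhaustive configuration matching: walks every configuration in the KB and
# tests the structural match directly from the raw assertion tables, with the
# timing condition decided by endpoint enumeration restricted to the
# constraint component containing the two anchors.

component_of <- function(kb, seeds) {
  tc <- kb$temporal_constraints
  comp <- unique(seeds)
  repeat {
    grow <- unique(c(tc$subject[tc$object %in% comp],
                     tc$object[tc$subject %in% comp]))
    new <- setdiff(grow, comp)
    if (!length(new)) break
    comp <- c(comp, new)
  }
  sort(comp)
}

oracle_timing <- function(kb, a, b) {
  comp <- component_of(kb, c(a, b))
  tc <- kb$temporal_constraints
  tc <- tc[tc$subject %in% comp & tc$object %in% comp, , drop = FALSE]
  models <- oracle_models(comp, tc)
  stopifnot(nrow(models$S) > 0L)  # scenario networks are consistent
  oracle_intersects(models, a, b)
}

oracle_compound <- function(content, kb) {
  org <- content$asserted_organism; dis <- content$asserted_disease
  typ <- content$asserted_type
  ref_ok <- !is.null(org) && org %in% names(kb$particulars) &&
    !is.null(dis) && dis %in% names(kb$particulars) &&
    typ %in% names(kb$universals) && kb$universals[[typ]]$exists_flag
  if (!ref_ok) return("fails")
  match_cfg <- function(cfg) {
    ok_members <- all(c(org, dis) %in% cfg$members_particulars) &&
      typ %in% cfg$members_universals
    has_inh <- FALSE; has_inst <- FALSE
    for (cr in cfg$constituent_relations) {
      if (inherits(cr, "rt_relation") && cr$relation == "inheres_in" &&
          cr$subject == dis && cr$object == org) has_inh <- TRUE
      if (inherits(cr, "rt_instantiation") && cr$particular == dis &&
          cr$universal == typ) has_inst <- TRUE
    }
    ok_members && has_inh && has_inst
  }
  target <- kb$configurations[[content$intended_target]]
  if (is.null(target) || !match_cfg(target)) return("fails")
  oracle_timing(kb, content$asserted_anchor, target$anchor)
}

# random KB stocked with contents whose compound verdicts the oracle decides;
# scale kept under 20 declared particulars
random_compound_kb <- function(seed) {
  fr <- c(0, 0.5, 1)[(seed %% 3) + 1]
  random_scenario(seed, n_particulars = 3L + (seed %% 6L), fault_rate = fr)
}
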