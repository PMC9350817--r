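# Forward-chaining reasoner: naive, negation-free evaluation to the unique
# least fixpoint, with full derivation tracking for explainability.

#' Match a triple pattern against a triple under a binding
#'
#' Attempts to extend `binding` (a named character vector mapping variable
#' names like `"?p"` to constants) so that `pattern` grounds to `triple`.
#'
#' @param pattern character vector `c(subject, predicate, object)`; terms
#'   starting with `?` are variables.
#' @param triple character vector `c(subject, predicate, object)`.
#' @param binding named character vector (possibly empty).
#' @return The extended binding, or `NULL` on failure.
#' @export
match_pattern <- function(pattern, triple, binding = character()) {
  for (k in 1:3) {
    term <- pattern[k]
    if (.is_var(term)) {
      bound <- binding[term]
      if (is.na(bound)) binding[term] <- triple[k]
      else if (bound != triple[k]) return(NULL)
    } else if (term != triple[k]) {
      return(NULL)
    }
  }
  binding
}

#' Evaluate a numeric guard against a binding
#'
#' The guard's variable must be bound to a typed-literal node of the graph;
#' its value is compared against the threshold.
#'
#' @param kg a `knowledge_graph`.
#' @param guard `list(var, op, value)` with `op` one of `>=`, `<=`, `>`, `<`.
#' @param binding named character vector from [match_pattern()].
#' @return Logical: `TRUE` iff the bound literal satisfies the comparison.
#' @export
eval_guard <- function(kg, guard, binding) {
  node <- binding[guard$var]
  if (is.na(node)) return(FALSE)
  v <- literal_value(kg, node)
  if (is.na(v)) return(FALSE)
  get(guard$op)(v, guard$value)
}

# Candidate triple indices for a pattern: filter on constant positions.
.candidates <- function(tr, pattern, binding) {
  ground <- vapply(pattern, function(term) {
    if (.is_var(term)) {
      b <- binding[term]
      if (is.na(b)) NA_character_ else unname(b)
    } else term
  }, "")
  keep <- rep(TRUE, nrow(tr))
  if (!is.na(ground[1])) keep <- keep & tr$subject == ground[1]
  if (!is.na(ground[2])) keep <- keep & tr$predicate == ground[2]
  if (!is.na(ground[3])) keep <- keep & tr$object == ground[3]
  which(keep)
}

# All (binding, antecedent-ids) pairs satisfying a rule over the triple set,
# enumerated in triple-id order for deterministic derivation choice.
.rule_matches <- function(kg, rule) {
  tr <- kg$triples
  states <- list(list(binding = character(), ants = character()))
  for (pat in rule$antecedents) {
    nxt <- list()
    for (st in states) {
      for (i in .candidates(tr, pat, st$binding)) {
        b <- match_pattern(pat, c(tr$subject[i], tr$predicate[i], tr$object[i]),
                           st$binding)
        if (!is.null(b)) {
          nxt[[length(nxt) + 1]] <- list(binding = b,
                                         ants = c(st$ants, tr$id[i]))
        }
      }
    }
    states <- nxt
    if (!length(states)) return(states)
  }
  if (length(rule$guards)) {
    ok <- vapply(states, function(st) {
      all(vapply(rule$guards, eval_guard, TRUE, kg = kg, binding = st$binding))
    }, TRUE)
    states <- states[ok]
  }
  states
}

.instantiate <- function(pattern, binding) {
  vapply(pattern, function(term) {
    if (.is_var(term)) unname(binding[term]) else term
  }, "")
}

#' Forward-chain a rule library over a knowledge graph
#'
#' Repeatedly applies all rules to the triple set until no rule adds a new
#' triple (the least fixpoint; unique because the rules are negation-free).
#' Every derived triple gets `provenance = "inferred"` and a derivation
#' naming the rule and the ids of the antecedent triples it matched; input
#' triples are preserved. When a triple is derivable in several ways, the
#' first derivation under (rule-order, triple-id-order) iteration is kept,
#' which is what makes the output stable; the triple *set* is independent of
#' rule order.
#'
#' @param kg a `knowledge_graph`.
#' @param rules list of [rule_axiom()] objects, e.g. [default_rules()].
#' @param max_rounds maximum number of rounds before declaring
#'   non-termination (>= 1).
#' @return The enriched `knowledge_graph`.
#' @export
forward_chain <- function(kg, rules, max_rounds = 50L) {
  stopifnot(inherits(kg, "knowledge_graph"), max_rounds >= 1)
  for (round in seq_len(max_rounds)) {
    before <- nrow(kg$triples)
    for (rule in rules) {
      if (!length(rule$antecedents)) {
        kg <- add_triples(kg, triples(rule$consequent[1], rule$consequent[2],
                                      rule$consequent[3], "inferred",
                                      rule = rule$id,
                                      antecedents = list(character())))
        next
      }
      for (st in .rule_matches(kg, rule)) {
        fact <- .instantiate(rule$consequent, st$binding)
        kg <- add_triples(kg, triples(fact[1], fact[2], fact[3], "inferred",
                                      rule = rule$id,
                                      antecedents = list(st$ants)))
      }
    }
    if (nrow(kg$triples) == before) return(kg)
  }
  # one extra check: did the last round close?
  before <- nrow(kg$triples)
  for (rule in rules) {
    if (!length(rule$antecedents)) next
    for (st in .rule_matches(kg, rule)) {
      fact <- .instantiate(rule$consequent, st$binding)
      key <- paste(fact, collapse = "\r")
      keys <- paste(kg$triples$subject, kg$triples$predicate,
                    kg$triples$object, sep = "\r")
      if (!key %in% keys) {
        stop("fixpoint not reached within ", max_rounds, " rounds",
             call. = FALSE)
      }
    }
  }
  kg
}

#' Replay the derivation of an inferred triple
#'
#' Walks the stored derivation records down to the triples they ground in.
#'
#' @param kg a `knowledge_graph`.
#' @param triple_id id of a triple in the graph.
#' @return A list with `rules` (character vector of rule ids used, outermost
#'   first) and `facts` (ids of the non-inferred triples the chain bottoms
#'   out in).
#' @export
replay_derivation <- function(kg, triple_id) {
  tr <- kg$triples
  i <- match(triple_id, tr$id)
  if (is.na(i)) stop("unknown triple id: ", triple_id, call. = FALSE)
  rules <- character(); facts <- character()
  walk <- function(j) {
    if (tr$provenance[j] != "inferred") {
      facts <<- unique(c(facts, tr$id[j]))
      return(invisible())
    }
    rules <<- unique(c(rules, tr$rule[j]))
    for (a in tr$antecedents[[j]]) walk(match(a, tr$id))
  }
  walk(i)
  list(rules = rules, facts = facts)
}
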