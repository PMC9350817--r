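# Build the population knowledge graph from the concept scheme and tract
# data, then enrich it with reasoner inferences and ML-derived predictor
# edges.

# Ground domain axioms asserted into every built graph: the measures links
# from metric concepts to the risk factors they quantify, the lack-of-
# physical-activity -> obesity causal axiom, the prevalence-metric health
# indicator link, and the obesity -> diabetes risk link.
.domain_axioms <- function() {
  vi <- .upho_variables[!is.na(.upho_variables$measures), ]
  rbind(
    triples(vi$metric, "measures", vi$measures, "asserted"),
    triples("COPE:LackOfPhysicalActivity", "leadsTo", "DO:Obesity", "asserted"),
    triples("HIO:%ObesityPrevalence", "isHealthIndicatorFor", "DO:Obesity",
            "asserted"),
    triples("DO:Obesity", "isRiskFactorOf", "DO:Diabetes", "asserted")
  )
}

.literal_node <- function(geoid, metric) paste0("lit:", geoid, ":", metric)

#' Construct the population knowledge graph
#'
#' The graph contains the scheme's `isA` edges and ground domain axioms
#' (provenance `asserted`); one node per tract (`isA` census tract) with a
#' one-per-tract neighborhood node (`representsA`); a `has` edge from each
#' tract to a typed literal node for every tract variable, carrying the value
#' as weight (provenance `data`); `hasPhysicalCharacteristic` edges from the
#' neighborhood to physical-characteristic concepts its metrics quantify; and
#' the focus individual or population with its `livesIn` edges.
#'
#' @param scheme a [concept_scheme()].
#' @param table tract data.frame (may have zero rows).
#' @param focus `NULL`, or `list(individual = id, geoid = g)` for a
#'   patient-level graph, or `list(population = id, geoids = c(...))` for a
#'   population-level graph. Focus geoids must be present in the table.
#' @return A `knowledge_graph`.
#' @export
build_graph <- function(scheme = default_scheme(), table = NULL, focus = NULL) {
  kg <- knowledge_graph(scheme)

  has_parent <- vapply(scheme$concepts, function(cp) length(cp$parents) > 0, TRUE)
  kids <- names(scheme$concepts)[has_parent]
  isa <- do.call(rbind, lapply(kids, function(cu) {
    triples(cu, "isA", scheme$concepts[[cu]]$parents, "asserted")
  }))
  kg <- add_triples(kg, isa)
  kg <- add_triples(kg, .domain_axioms())

  if (!is.null(table) && nrow(table)) {
    validate_tracts(table)
    vars <- intersect(.upho_variables$feature, names(table))
    info <- .var_info(vars)
    phys <- info$measures[!is.na(info$measures) & vapply(
      info$measures, function(m)
        !is.na(m) && is_subtype(scheme, m, "COPE:PhysicalCharacteristic"),
      TRUE)]
    rows <- list()
    for (i in seq_len(nrow(table))) {
      g <- table$geoid[i]
      nb <- paste0("nbhd:", g)
      rows[[length(rows) + 1]] <- triples(
        c(g, g, nb), c("isA", "representsA", "isA"),
        c("GISO:CensusTract", nb, "GISO:Neighborhood"), "data")
      if (length(phys)) {
        rows[[length(rows) + 1]] <-
          triples(nb, "hasPhysicalCharacteristic", phys, "data")
      }
      lit <- .literal_node(g, info$metric)
      rows[[length(rows) + 1]] <- triples(g, "has", lit, "data",
                                          weight = as.numeric(table[i, vars]))
      rows[[length(rows) + 1]] <- triples(lit, "isA", info$metric, "data")
      for (k in seq_along(vars)) {
        kg <- add_literal(kg, lit[k], as.numeric(table[[vars[k]]][i]),
                          info$metric[k])
      }
    }
    kg <- add_triples(kg, do.call(rbind, rows))
  }

  if (!is.null(focus)) {
    if (!is.null(focus$individual)) {
      g <- focus$geoid
      if (is.null(g) || !g %in% table$geoid) {
        stop("focus geoid not present in table: ",
             if (is.null(g)) "<missing>" else g, call. = FALSE)
      }
      kg <- add_triples(kg, rbind(
        triples(focus$individual, "isA", "UPHO:Individual", "data"),
        triples(focus$individual, "livesIn", g, "data")))
    } else if (!is.null(focus$population)) {
      gs <- focus$geoids
      bad <- setdiff(gs, table$geoid)
      if (length(bad)) {
        stop("focus geoid not present in table: ", bad[1], call. = FALSE)
      }
      kg <- add_triples(kg, rbind(
        triples(focus$population, "isA", "UPHO:Population", "data"),
        triples(focus$population, "livesIn", gs, "data")))
    } else {
      stop("focus must name an individual or a population", call. = FALSE)
    }
  }
  kg
}

#' Enrich a graph with ML-derived predictor edges
#'
#' Adds `isPredictorOf` edges (provenance `ml`) from the metric concepts of
#' the `top_k` most important features to the outcome prevalence metric
#' concept, weighted by scaled importance / 100. Prediction edges sit at the
#' population level (between metric concepts, not tract-specific literals).
#'
#' @param kg a `knowledge_graph`.
#' @param importance data.frame from [importance()] (columns `feature`,
#'   `scaled`).
#' @param top_k number of features to link (default 5; clamped with a warning
#'   when it exceeds the available features).
#' @param outcome_metric curie of the outcome metric concept.
#' @return The enriched graph.
#' @export
enrich_with_ml <- function(kg, importance, top_k = 5,
                           outcome_metric = "HIO:%ObesityPrevalence") {
  if (top_k > nrow(importance)) {
    warning("top_k exceeds available features; clamped to ", nrow(importance))
    top_k <- nrow(importance)
  }
  if (top_k <= 0) return(kg)
  ord <- order(-importance$scaled, importance$feature)
  top <- importance[ord[seq_len(top_k)], , drop = FALSE]
  metrics <- .var_info(top$feature)$metric
  add_triples(kg, triples(metrics, "isPredictorOf", outcome_metric, "ml",
                          weight = top$scaled / 100))
}

#' Enrich a graph to its inferential stable state
#'
#' Alternates forward chaining passes until no pass adds a triple. With the
#' negation-free built-in rules a single chaining pass already reaches the
#' fixpoint, so the second pass is a verification that the state is stable.
#'
#' @param kg a `knowledge_graph`.
#' @param rules rule library (default [default_rules()]).
#' @param max_passes maximum enrichment passes before declaring
#'   non-termination.
#' @return The stable enriched graph.
#' @export
enrich_with_inference <- function(kg, rules = default_rules(), max_passes = 10L) {
  for (pass in seq_len(max_passes)) {
    before <- nrow(kg$triples)
    kg <- forward_chain(kg, rules)
    if (nrow(kg$triples) == before) return(kg)
  }
  stop("graph did not stabilize within ", max_passes, " passes", call. = FALSE)
}
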