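# Causal pathway tracing on the enriched graph, plus the textual explanation
# and recommendation rendering that stands in for the dashboard.

#' The registered metapath templates
#'
#' A pathway must follow one of these predicate sequences from the focus
#' individual/population to the disease. Typed literal nodes add an explicit
#' `isA` hop between a tract's metric value and its metric concept.
#' \describe{
#'   \item{semantic_exposure}{livesIn, has, isA, measures, leadsTo — the
#'     tract's metric value exposes the resident to a risk factor that leads
#'     to the disease.}
#'   \item{neighborhood_characteristic}{livesIn, representsA,
#'     hasPhysicalCharacteristic, leadsTo — the canonical
#'     individual/tract/neighborhood/characteristic/disease template.}
#'   \item{statistical_prediction}{livesIn, has, isA, isPredictorOf,
#'     isHealthIndicatorFor — the ML-derived predictor route to the disease
#'     through its prevalence metric.}
#' }
#'
#' @return Named list of predicate sequences.
#' @export
default_metapaths <- function() {
  list(
    semantic_exposure =
      c("livesIn", "has", "isA", "measures", "leadsTo"),
    neighborhood_characteristic =
      c("livesIn", "representsA", "hasPhysicalCharacteristic", "leadsTo"),
    statistical_prediction =
      c("livesIn", "has", "isA", "isPredictorOf", "isHealthIndicatorFor")
  )
}

.pathway_score <- function(edges) {
  w <- ifelse(edges$provenance == "ml" & !is.na(edges$weight), edges$weight, 1)
  prod(w)
}

.pathway_evidence <- function(edges) {
  ml <- any(edges$provenance == "ml")
  other <- any(edges$provenance != "ml")
  if (ml && other) "both" else if (ml) "statistical" else "semantic"
}

#' Trace scored causal pathways from a source entity to a disease
#'
#' Depth-first enumeration of edge sequences starting at `source` whose
#' predicate sequence matches a registered metapath template and whose final
#' node is `outcome`. Each pathway is scored by the product of its
#' ML-edge weights (semantic edges count as 1), and labelled by its evidence
#' type (`semantic`, `statistical`, or `both` when ML and
#' asserted/data/inferred edges mix). Results are sorted by score descending
#' with ties broken by the lexicographic node-id sequence.
#'
#' @param kg a `knowledge_graph`.
#' @param source entity id present in the graph (individual or population).
#' @param outcome disease curie, e.g. `"DO:Obesity"`.
#' @param max_len maximum pathway length in edges (default 6); templates
#'   longer than this are skipped.
#' @param metapaths named list of predicate sequences
#'   (default [default_metapaths()]).
#' @return List of `upho_pathway` objects (possibly empty), each with
#'   `nodes`, `edges`, `score`, `evidence`, `template`.
#' @export
trace_pathways <- function(kg, source, outcome, max_len = 6,
                           metapaths = default_metapaths()) {
  tr <- kg$triples
  if (!source %in% c(tr$subject, tr$object)) {
    stop("unknown source entity: ", source, call. = FALSE)
  }
  out <- list()
  for (tname in names(metapaths)) {
    preds <- metapaths[[tname]]
    if (length(preds) > max_len) next
    stack <- list(list(node = source, edges = integer()))
    step <- function(state, depth) {
      if (depth > length(preds)) {
        if (state$node == outcome) {
          e <- tr[state$edges, , drop = FALSE]
          out[[length(out) + 1]] <<- structure(list(
            nodes = c(source, e$object), edges = e,
            score = .pathway_score(e), evidence = .pathway_evidence(e),
            template = tname), class = "upho_pathway")
        }
        return(invisible())
      }
      nxt <- which(tr$subject == state$node & tr$predicate == preds[depth])
      for (i in nxt) {
        if (tr$object[i] %in% c(source, tr$object[state$edges])) next # simple
        step(list(node = tr$object[i], edges = c(state$edges, i)), depth + 1)
      }
    }
    step(stack[[1]], 1)
  }
  if (!length(out)) return(out)
  keys <- vapply(out, function(p) paste(p$nodes, collapse = " "), "")
  scores <- vapply(out, `[[`, 0, "score")
  out[order(-scores, keys)]
}

#' @export
print.upho_pathway <- function(x, ...) {
  cat(sprintf("<pathway %s> score %.3f (%s)\n  %s\n", x$template, x$score,
              x$evidence, paste(x$nodes, collapse = " -> ")))
  invisible(x)
}

.fmt1 <- function(v) formatC(v, format = "f", digits = 1)

#' Explain a node or edge of the knowledge graph
#'
#' Renders the hover-style explanation text for a graph element:
#' \itemize{
#'   \item a typed metric literal node is compared against the reference
#'     average computed from `reference_table` ("60.8% of the population
#'     ... compared to the city average of 28.6%");
#'   \item an `ml` edge cites its scaled importance score;
#'   \item an `inferred` edge cites the deriving rule and the facts its
#'     derivation chain grounds in (derivation replay);
#'   \item asserted/data structural edges and concept nodes get definitional
#'     text with no numbers.
#' }
#' Numbers are rendered to one decimal place and every number appearing in
#' the text is recorded in `values`.
#'
#' @param kg a `knowledge_graph`.
#' @param target a node id or a triple id.
#' @param reference_table optional tract data.frame providing the reference
#'   averages for metric explanations.
#' @param region_label label of the reference region (default `"city"`).
#' @return An object of class `upho_explanation`: `target`, `text`, `values`.
#' @export
explain <- function(kg, target, reference_table = NULL, region_label = "city") {
  tr <- kg$triples
  ei <- match(target, tr$id)

  if (!is.na(ei)) { # edge
    prov <- tr$provenance[ei]
    if (prov == "ml") {
      score <- tr$weight[ei] * 100
      text <- sprintf(
        "%s was identified by the regression model as a predictor of %s, with a scaled importance score of %s out of 100.",
        .node_label(kg, tr$subject[ei]), .node_label(kg, tr$object[ei]),
        .fmt1(score))
      values <- c(importance_score = as.numeric(.fmt1(score)), scale_max = 100)
    } else if (prov == "inferred") {
      d <- replay_derivation(kg, target)
      text <- sprintf(
        "'%s %s %s' was inferred by rule %s; its derivation grounds in facts %s.",
        .node_label(kg, tr$subject[ei]), tr$predicate[ei],
        .node_label(kg, tr$object[ei]), paste(d$rules, collapse = ", "),
        paste(d$facts, collapse = ", "))
      values <- numeric()
      attr(values, "derivation") <- d
    } else {
      text <- sprintf("%s %s %s (background knowledge).",
                      .node_label(kg, tr$subject[ei]), tr$predicate[ei],
                      .node_label(kg, tr$object[ei]))
      values <- numeric()
    }
    return(structure(list(target = target, text = text, values = values),
                     class = "upho_explanation"))
  }

  li <- match(target, kg$literals$node)
  if (!is.na(li)) { # metric literal node
    value <- kg$literals$value[li]
    metric <- kg$literals$metric[li]
    vi <- .upho_variables[match(metric, .upho_variables$metric), ]
    geoid <- sub("^lit:([^:]+):.*$", "\\1", target)
    unit <- if (!is.na(vi$kind) && vi$kind == "percent") "%" else ""
    label <- if (is.na(vi$label)) metric else vi$label
    values <- c(value = as.numeric(.fmt1(value)))
    if (!is.null(reference_table) && !is.na(vi$feature) &&
        vi$feature %in% names(reference_table)) {
      ref <- mean(reference_table[[vi$feature]])
      text <- sprintf(
        "In tract %s, %s%s of the population falls under '%s', compared to the %s average of %s%s.",
        geoid, .fmt1(value), unit, label, region_label, .fmt1(ref), unit)
      values <- c(values, reference_mean = as.numeric(.fmt1(ref)))
    } else {
      text <- sprintf("In tract %s, the metric '%s' takes the value %s%s.",
                      geoid, label, .fmt1(value), unit)
    }
    return(structure(list(target = target, text = text, values = values),
                     class = "upho_explanation"))
  }

  if (target %in% names(kg$scheme$concepts)) {
    cp <- kg$scheme$concepts[[target]]
    text <- if (length(cp$parents)) {
      sprintf("%s (%s) is a subtype of %s.", cp$label, target,
              paste(vapply(cp$parents, function(p)
                kg$scheme$concepts[[p]]$label, ""), collapse = ", "))
    } else sprintf("%s (%s) is a top-level concept.", cp$label, target)
    return(structure(list(target = target, text = text, values = numeric()),
                     class = "upho_explanation"))
  }

  if (target %in% c(tr$subject, tr$object)) { # plain entity node
    types <- tr$object[tr$subject == target & tr$predicate == "isA"]
    text <- sprintf("%s is an entity of type %s.", target,
                    paste(vapply(types, function(x) .node_label(kg, x), ""),
                          collapse = ", "))
    return(structure(list(target = target, text = text, values = numeric()),
                     class = "upho_explanation"))
  }
  stop("unknown explanation target: ", target, call. = FALSE)
}

#' @export
print.upho_explanation <- function(x, ...) {
  cat(x$text, "\n")
  invisible(x)
}

#' Summarize recommendations from the enriched graph and traced pathways
#'
#' One recommendation per inferred `shouldBeScreenedFor` triple, plus one
#' intervention recommendation per pathway (framed on the pathway's risk
#' factor / predictor), deduplicated, in deterministic order: screening
#' recommendations first, then pathway recommendations by score descending.
#'
#' @param kg a `knowledge_graph`.
#' @param pathways list of pathways from [trace_pathways()].
#' @return Character vector of recommendation sentences (possibly empty).
#' @export
summarize_recommendations <- function(kg, pathways = list()) {
  tr <- kg$triples
  scr <- which(tr$predicate == "shouldBeScreenedFor")
  scr <- scr[order(tr$subject[scr], tr$object[scr])]
  recs <- sprintf("Screening: %s should be screened for %s.",
                  tr$subject[scr],
                  vapply(tr$object[scr], function(o) .node_label(kg, o), ""))
  for (p in pathways) {
    last <- p$edges[nrow(p$edges), ]
    rf <- if (last$predicate %in% c("leadsTo", "isHealthIndicatorFor")) {
      # risk factor = the node the final causal/indicator edge leaves from,
      # or the predictor metric for the statistical template
      if (last$predicate == "isHealthIndicatorFor" && nrow(p$edges) >= 2) {
        p$edges$subject[nrow(p$edges) - 1]
      } else last$subject
    } else last$object
    recs <- c(recs, sprintf(
      "Intervention: address %s along the traced %s pathway to reduce %s.",
      .node_label(kg, rf), p$evidence, .node_label(kg, p$nodes[length(p$nodes)])))
  }
  unique(recs)
}

#' Export pathways to JSON
#'
#' @param pathways list of pathways from [trace_pathways()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
pathways_to_json <- function(pathways, path) {
  out <- lapply(pathways, function(p) list(
    template = p$template, score = p$score, evidence = p$evidence,
    nodes = p$nodes,
    edges = data.frame(subject = p$edges$subject, predicate = p$edges$predicate,
                       object = p$edges$object, provenance = p$edges$provenance,
                       weight = p$edges$weight, stringsAsFactors = FALSE)))
  jsonlite::write_json(out, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Render pathways and recommendations as markdown
#'
#' @param kg a `knowledge_graph`.
#' @param pathways list of pathways from [trace_pathways()].
#' @param reference_table optional tract table for metric explanations.
#' @return Character vector of markdown lines.
#' @export
pathways_to_markdown <- function(kg, pathways, reference_table = NULL) {
  lines <- c("## Causal pathways", "")
  if (!length(pathways)) {
    lines <- c(lines, "No pathway matching a registered metapath was found.", "")
  }
  for (p in pathways) {
    lines <- c(lines, sprintf("- **%s** (score %.3f, evidence: %s): `%s`",
                              p$template, p$score, p$evidence,
                              paste(p$nodes, collapse = " -> ")))
    for (i in seq_len(nrow(p$edges))) {
      ex <- explain(kg, p$edges$id[i], reference_table)
      lines <- c(lines, sprintf("    - %s", ex$text))
    }
  }
  recs <- summarize_recommendations(kg, pathways)
  c(lines, "", "## Recommendations", "",
    if (length(recs)) paste0("- ", recs) else "(none)")
}
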