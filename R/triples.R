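# Knowledge graph container: a set of subject-predicate-object triples with
# provenance (asserted / data / ml / inferred), optional weights, typed
# literal nodes, and derivation records for inferred triples.

.empty_triples <- function() {
  data.frame(id = character(), subject = character(), predicate = character(),
             object = character(), provenance = character(), weight = numeric(),
             rule = character(), antecedents = I(list()),
             stringsAsFactors = FALSE)
}

#' Create an empty knowledge graph over a concept scheme
#'
#' @param scheme a [concept_scheme()]; defaults to [default_scheme()].
#' @return An object of class `knowledge_graph` holding a triple set (with
#'   set semantics on subject/predicate/object), a typed-literal table, and
#'   the scheme.
#' @export
knowledge_graph <- function(scheme = default_scheme()) {
  structure(list(
    scheme = scheme,
    triples = .empty_triples(),
    literals = data.frame(node = character(), value = numeric(),
                          metric = character(), stringsAsFactors = FALSE),
    next_id = 1L
  ), class = "knowledge_graph")
}

.is_curie <- function(x) grepl("^(DO|COPE|GISO|HIO|ACESO|UPHO):", x)

#' Build triple rows
#'
#' Vectorized constructor for triple records to pass to [add_triples()].
#'
#' @param subject,predicate,object character vectors (recycled to a common
#'   length). Terms that look like curies must resolve in the graph's scheme
#'   when added.
#' @param provenance one of `"asserted"`, `"data"`, `"ml"`, `"inferred"`.
#' @param weight optional numeric weight (only for `ml` or `data` triples).
#' @param rule,antecedents derivation record (rule id and antecedent triple
#'   ids), required iff `provenance == "inferred"`.
#' @return A data.frame of triple records.
#' @export
triples <- function(subject, predicate, object, provenance = "asserted",
                    weight = NA_real_, rule = NA_character_,
                    antecedents = NULL) {
  n <- max(length(subject), length(predicate), length(object))
  df <- data.frame(id = NA_character_,
                   subject = rep_len(as.character(subject), n),
                   predicate = rep_len(as.character(predicate), n),
                   object = rep_len(as.character(object), n),
                   provenance = rep_len(provenance, n),
                   weight = rep_len(as.numeric(weight), n),
                   rule = rep_len(as.character(rule), n),
                   stringsAsFactors = FALSE)
  df$antecedents <- if (is.null(antecedents)) rep(list(character()), n)
                    else rep_len(antecedents, n)
  df
}

#' Add triples to a knowledge graph
#'
#' Enforces set semantics: a triple whose (subject, predicate, object) is
#' already present is skipped regardless of provenance, so the first
#' derivation found is the one kept. Curies must resolve in the scheme;
#' provenance/weight/derivation invariants are checked.
#'
#' @param kg a `knowledge_graph`.
#' @param df triple records from [triples()].
#' @return The updated graph.
#' @export
add_triples <- function(kg, df) {
  stopifnot(inherits(kg, "knowledge_graph"))
  if (!nrow(df)) return(kg)
  ok_prov <- df$provenance %in% c("asserted", "data", "ml", "inferred")
  if (!all(ok_prov)) {
    stop("unknown provenance: ", df$provenance[!ok_prov][1], call. = FALSE)
  }
  bad_w <- !is.na(df$weight) & !df$provenance %in% c("ml", "data")
  if (any(bad_w)) {
    stop("weight is only allowed on ml or data triples", call. = FALSE)
  }
  has_deriv <- !is.na(df$rule)
  if (any(has_deriv != (df$provenance == "inferred"))) {
    stop("derivation must be present iff provenance is 'inferred'", call. = FALSE)
  }
  terms <- unique(c(df$subject, df$object))
  curies <- terms[.is_curie(terms)]
  unknown <- setdiff(curies, names(kg$scheme$concepts))
  if (length(unknown)) {
    stop("curie does not resolve in the scheme: ", unknown[1], call. = FALSE)
  }
  key_new <- paste(df$subject, df$predicate, df$object, sep = "\r")
  key_old <- paste(kg$triples$subject, kg$triples$predicate,
                   kg$triples$object, sep = "\r")
  keep <- !key_new %in% key_old & !duplicated(key_new)
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) return(kg)
  df$id <- sprintf("t%d", kg$next_id + seq_len(nrow(df)) - 1L)
  kg$next_id <- kg$next_id + nrow(df)
  kg$triples <- rbind(kg$triples, df)
  rownames(kg$triples) <- NULL
  kg
}

#' Register a typed literal node
#'
#' Literal nodes carry a numeric value tagged with the metric concept it
#' instantiates (e.g. the value 49 tagged as a lack-of-physical-activity
#' percentage). They are keyed by node id so equal values in different tracts
#' do not collide.
#'
#' @param kg a `knowledge_graph`.
#' @param node literal node id.
#' @param value numeric value.
#' @param metric curie of the metric concept the value instantiates.
#' @return The updated graph.
#' @export
add_literal <- function(kg, node, value, metric) {
  i <- match(node, kg$literals$node)
  row <- data.frame(node = node, value = value, metric = metric,
                    stringsAsFactors = FALSE)
  if (is.na(i)) kg$literals <- rbind(kg$literals, row) else kg$literals[i, ] <- row
  kg
}

#' Look up the numeric value of a literal node
#'
#' @param kg a `knowledge_graph`.
#' @param node literal node id.
#' @return Numeric value, or `NA` if `node` is not a literal.
#' @export
literal_value <- function(kg, node) {
  kg$literals$value[match(node, kg$literals$node)]
}

#' @export
print.knowledge_graph <- function(x, ...) {
  tab <- table(factor(x$triples$provenance,
                      levels = c("asserted", "data", "ml", "inferred")))
  cat("<knowledge_graph> ", nrow(x$triples), " triples (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
      "), ", nrow(x$literals), " literal nodes\n", sep = "")
  invisible(x)
}

# ---- serialization ---------------------------------------------------------

#' Serialize / parse triples in a line-oriented text format
#'
#' One record per line: `subject predicate object provenance [weight]
#' [rule|ant1,ant2]`; literal nodes are written as `LITERAL node value
#' metric` header lines. Terms contain no whitespace so the format
#' round-trips exactly.
#'
#' @param kg a `knowledge_graph`.
#' @param path file to write / read.
#' @param scheme scheme for the parsed graph.
#' @return `write_triples` returns `path` invisibly; `read_triples` returns a
#'   `knowledge_graph`.
#' @export
write_triples <- function(kg, path) {
  lit <- sprintf("LITERAL %s %.17g %s", kg$literals$node, kg$literals$value,
                 kg$literals$metric)
  tr <- kg$triples
  lines <- vapply(seq_len(nrow(tr)), function(i) {
    s <- sprintf("%s %s %s %s", tr$subject[i], tr$predicate[i], tr$object[i],
                 tr$provenance[i])
    if (!is.na(tr$weight[i])) s <- sprintf("%s %.17g", s, tr$weight[i])
    if (!is.na(tr$rule[i])) {
      s <- sprintf("%s %s|%s", s, tr$rule[i],
                   paste(tr$antecedents[[i]], collapse = ","))
    }
    s
  }, "")
  writeLines(c(lit, lines), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_triples
#' @export
read_triples <- function(path, scheme = default_scheme()) {
  kg <- knowledge_graph(scheme)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (parts[1] == "LITERAL") {
      kg <- add_literal(kg, parts[2], as.numeric(parts[3]), parts[4])
      next
    }
    weight <- NA_real_; rule <- NA_character_; ants <- character()
    for (extra in parts[-(1:4)]) {
      if (grepl("\\|", extra)) {
        bits <- strsplit(extra, "\\|")[[1]]
        rule <- bits[1]
        if (length(bits) > 1 && nzchar(bits[2])) {
          ants <- strsplit(bits[2], ",")[[1]]
        }
      } else weight <- as.numeric(extra)
    }
    kg <- add_triples(kg, triples(parts[1], parts[2], parts[3], parts[4],
                                  weight, rule, list(ants)))
  }
  kg
}

# All node ids appearing in the graph, sorted for deterministic exports.
.kg_nodes <- function(kg) {
  sort(unique(c(kg$triples$subject, kg$triples$object)))
}

.node_type <- function(kg, id) {
  if (id %in% names(kg$scheme$concepts)) "concept"
  else if (id %in% kg$literals$node) "literal"
  else "entity"
}

#' Convert a knowledge graph to / from node-link form
#'
#' The node-link form (nodes with id/label/type and literal values, links
#' with predicate/provenance/weight/derivation) is what [write_graph_json()]
#' serializes; `kg_from_node_link` inverts it.
#'
#' @param kg a `knowledge_graph`.
#' @param nl a node-link list as produced by `kg_to_node_link`.
#' @param scheme scheme for the reconstructed graph.
#' @return A list with `nodes` and `links` data.frames, or a
#'   `knowledge_graph`.
#' @export
kg_to_node_link <- function(kg) {
  ids <- .kg_nodes(kg)
  nodes <- data.frame(
    id = ids,
    label = vapply(ids, function(i) .node_label(kg, i), ""),
    type = vapply(ids, function(i) .node_type(kg, i), ""),
    value = kg$literals$value[match(ids, kg$literals$node)],
    metric = kg$literals$metric[match(ids, kg$literals$node)],
    stringsAsFactors = FALSE)
  tr <- kg$triples
  ord <- order(tr$subject, tr$predicate, tr$object)
  links <- data.frame(
    source = tr$subject[ord], target = tr$object[ord],
    predicate = tr$predicate[ord], provenance = tr$provenance[ord],
    weight = tr$weight[ord], rule = tr$rule[ord], stringsAsFactors = FALSE)
  links$antecedents <- I(tr$antecedents[ord])
  list(nodes = nodes, links = links)
}

#' @rdname kg_to_node_link
#' @export
kg_from_node_link <- function(nl, scheme = default_scheme()) {
  kg <- knowledge_graph(scheme)
  lit <- nl$nodes[nl$nodes$type == "literal", , drop = FALSE]
  for (i in seq_len(nrow(lit))) {
    kg <- add_literal(kg, lit$id[i], lit$value[i], lit$metric[i])
  }
  lk <- nl$links
  ants <- lk$antecedents
  if (is.null(ants)) ants <- rep(list(character()), nrow(lk))
  ants <- lapply(ants, function(a) if (length(a)) as.character(a) else character())
  add_triples(kg, triples(lk$source, lk$predicate, lk$target, lk$provenance,
                          lk$weight, lk$rule, ants))
}

#' Write / read a knowledge graph as node-link JSON
#'
#' @param kg a `knowledge_graph`.
#' @param path JSON file path.
#' @param scheme scheme for the parsed graph.
#' @return `write_graph_json` returns `path` invisibly; `read_graph_json`
#'   returns a `knowledge_graph`.
#' @export
write_graph_json <- function(kg, path) {
  nl <- kg_to_node_link(kg)
  nl$links$antecedents <- lapply(nl$links$antecedents, as.character)
  jsonlite::write_json(nl, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path, scheme = default_scheme()) {
  nl <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (is.null(nl$nodes$value)) nl$nodes$value <- NA_real_
  if (is.null(nl$nodes$metric)) nl$nodes$metric <- NA_character_
  if (is.null(nl$links$weight)) nl$links$weight <- NA_real_
  nl$links$weight <- as.numeric(nl$links$weight)
  if (is.null(nl$links$rule)) nl$links$rule <- NA_character_
  nl$links$rule <- as.character(nl$links$rule)
  kg_from_node_link(nl, scheme)
}

#' Export a knowledge graph to GraphML
#'
#' Nodes are sorted by id and edges by (subject, predicate, object), so the
#' output is deterministic for a given graph.
#'
#' @param kg a `knowledge_graph`.
#' @param path output `.graphml` path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(kg, path) {
  nl <- kg_to_node_link(kg)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = nl$links$source, to = nl$links$target,
                   predicate = nl$links$predicate,
                   provenance = nl$links$provenance,
                   weight = ifelse(is.na(nl$links$weight), 1, nl$links$weight),
                   stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nl$nodes$id, label = nl$nodes$label,
                          type = nl$nodes$type, stringsAsFactors = FALSE))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
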