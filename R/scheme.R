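# Concept scheme: a minimal, namespaced isA hierarchy standing in for the
# five source ontologies (DO, COPE, GISO, HIO, ACESO) plus a UPHO namespace
# for entities (patients, populations) those ontologies do not define.

.upho_prefixes <- c(
  DO = "disease concepts",
  COPE = "childhood obesity prevention enterprise: SDoH and behavioural concepts",
  GISO = "geographical information system concepts",
  HIO = "health indicator (metric) concepts",
  ACESO = "adverse childhood experiences: risk factor and intervention concepts",
  UPHO = "population-health observatory entities"
)

#' Create a concept
#'
#' @param curie compact identifier `"PREFIX:LocalName"` with a known prefix.
#' @param label human-readable label.
#' @param parents character vector of parent curies (`isA` targets).
#' @return A list of class `upho_concept`.
#' @export
concept <- function(curie, label = curie, parents = character()) {
  stopifnot(is.character(curie), length(curie) == 1)
  prefix <- sub(":.*$", "", curie)
  if (!prefix %in% names(.upho_prefixes)) {
    stop("unknown namespace prefix in curie: ", curie, call. = FALSE)
  }
  structure(list(curie = curie, label = label,
                 parents = as.character(parents)),
            class = "upho_concept")
}

#' Assemble a concept scheme
#'
#' Validates that every parent reference resolves within the scheme and that
#' the `isA` graph is acyclic.
#'
#' @param concepts list of [concept()] objects.
#' @return An object of class `concept_scheme`.
#' @export
concept_scheme <- function(concepts) {
  curies <- vapply(concepts, `[[`, "", "curie")
  if (anyDuplicated(curies)) {
    stop("duplicate concept curie: ", curies[duplicated(curies)][1], call. = FALSE)
  }
  names(concepts) <- curies
  for (cp in concepts) {
    missing <- setdiff(cp$parents, curies)
    if (length(missing)) {
      stop("parent concept not in scheme: ", missing[1], " (child ",
           cp$curie, ")", call. = FALSE)
    }
  }
  scheme <- structure(list(concepts = concepts, prefixes = .upho_prefixes),
                      class = "concept_scheme")
  # cycle check: DFS colouring over parent links
  state <- setNames(rep(0L, length(curies)), curies) # 0 new, 1 open, 2 done
  visit <- function(cu) {
    if (state[[cu]] == 1L) stop("isA cycle through concept ", cu, call. = FALSE)
    if (state[[cu]] == 2L) return(invisible())
    state[[cu]] <<- 1L
    for (p in concepts[[cu]]$parents) visit(p)
    state[[cu]] <<- 2L
  }
  for (cu in curies) visit(cu)
  scheme
}

#' The default concept scheme
#'
#' The minimal hierarchy the pipeline uses: diseases (obesity, diabetes with
#' `DO:Disease` as root), risk factors (`ACESO:RiskFactor` over the
#' `COPE:SDoH` subtypes and physical characteristics), one health-indicator
#' metric concept per tract variable under `HIO:Metric`, geographic regions,
#' and the `UPHO:Individual` / `UPHO:Population` entity types.
#'
#' @return A `concept_scheme`.
#' @export
default_scheme <- function() {
  metric_concepts <- lapply(seq_len(nrow(.upho_variables)), function(i) {
    concept(.upho_variables$metric[i],
            paste("metric:", .upho_variables$label[i]),
            "HIO:Metric")
  })
  concept_scheme(c(list(
    concept("DO:Disease", "disease"),
    concept("DO:Obesity", "obesity", "DO:Disease"),
    concept("DO:Diabetes", "diabetes", "DO:Disease"),
    concept("ACESO:RiskFactor", "risk factor"),
    concept("COPE:SDoH", "social determinant of health", "ACESO:RiskFactor"),
    concept("COPE:LackOfTransportation", "lack of transportation", "COPE:SDoH"),
    concept("COPE:FoodDesert", "food desert", "COPE:SDoH"),
    concept("COPE:Income", "income", "COPE:SDoH"),
    concept("COPE:Poverty", "poverty", "COPE:SDoH"),
    concept("COPE:Unemployment", "unemployment", "COPE:SDoH"),
    concept("COPE:LowEducation", "low education", "COPE:SDoH"),
    concept("COPE:PhysicalCharacteristic", "physical characteristic",
            "ACESO:RiskFactor"),
    concept("COPE:LackOfPhysicalActivity", "lack of physical activity",
            "COPE:PhysicalCharacteristic"),
    concept("HIO:Metric", "health indicator metric"),
    concept("GISO:GeographicRegion", "geographic region"),
    concept("GISO:ZipCode", "zip code", "GISO:GeographicRegion"),
    concept("GISO:CensusTract", "census tract", "GISO:GeographicRegion"),
    concept("GISO:Neighborhood", "neighborhood", "GISO:GeographicRegion"),
    concept("UPHO:Individual", "individual"),
    concept("UPHO:Population", "population")
  ), metric_concepts))
}

#' Subtype test over the concept hierarchy
#'
#' `is_subtype(scheme, a, b)` is `TRUE` iff `b` is reachable from `a` via
#' zero or more parent (`isA`) links; the relation is reflexive and
#' transitive.
#'
#' @param scheme a `concept_scheme`.
#' @param a,b concept curies present in the scheme.
#' @return Logical scalar.
#' @export
is_subtype <- function(scheme, a, b) {
  stopifnot(inherits(scheme, "concept_scheme"))
  for (cu in c(a, b)) {
    if (!cu %in% names(scheme$concepts)) {
      stop("unknown concept curie: ", cu, call. = FALSE)
    }
  }
  frontier <- a
  seen <- character()
  while (length(frontier)) {
    if (b %in% frontier) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- setdiff(
      unique(unlist(lapply(scheme$concepts[frontier], `[[`, "parents"))),
      seen)
  }
  FALSE
}

#' @export
print.concept_scheme <- function(x, ...) {
  cat("<concept_scheme> ", length(x$concepts), " concepts in namespaces: ",
      paste(names(x$prefixes), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Label helper: concept label, literal description, or the raw id.
.node_label <- function(kg, id) {
  if (id %in% names(kg$scheme$concepts)) return(kg$scheme$concepts[[id]]$label)
  i <- match(id, kg$literals$node)
  if (!is.na(i)) {
    return(sprintf("%s = %g", .node_label(kg, kg$literals$metric[i]),
                   kg$literals$value[i]))
  }
  id
}
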