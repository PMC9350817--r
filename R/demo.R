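# A small hand-built scenario graph: one patient living in a tract with an
# elevated lack-of-physical-activity metric, used throughout the tests and
# the documentation to exercise the reasoner and the pathway tracer on a
# graph whose derivations can be checked by hand.

#' The worked demonstration scenario graph
#'
#' A patient (`individual:Patient`) lives in census tract `10300`, which
#' carries four metric values: 49% lacking physical activity, 21% without a
#' high-school diploma, 60% below the poverty line, and an obesity prevalence
#' of 46%. A machine-learned edge marks the physical-activity metric as a
#' predictor of obesity prevalence. Together with the built-in rule library
#' ([default_rules()]), forward chaining derives that the patient is exposed
#' to lack of physical activity, is therefore at risk of obesity, and should
#' be screened for diabetes.
#'
#' Only the physical-activity metric carries a `measures` typing link here:
#' the scenario derives exposure from that metric alone, so the other metrics
#' stay untyped evidence.
#'
#' @param scheme concept scheme (default [default_scheme()]).
#' @return A `knowledge_graph` with the scenario facts (not yet enriched).
#' @examples
#' kg <- forward_chain(demo_scenario_graph(), default_rules())
#' subset(kg$triples, provenance == "inferred")[, c("subject", "predicate", "object")]
#' @export
demo_scenario_graph <- function(scheme = default_scheme()) {
  kg <- knowledge_graph(scheme)
  tract <- "10300"
  pa <- "HIO:%PopWLackOfPhysicalActivity"
  metrics <- c(pa, "HIO:%PopNoHighSchoolDiploma", "HIO:%UnderPovertyLine",
               "HIO:%ObesityPrevalence")
  vals <- c(49, 21, 60, 46)
  lits <- paste0("lit:", tract, ":", metrics)

  kg <- add_triples(kg, rbind(
    # facts: residence and the tract's metric values
    triples("individual:Patient", "livesIn", tract, "data"),
    triples(tract, "has", lits, "data", weight = vals),
    triples(lits, "isA", metrics, "data"),
    # metric typing used by the exposure derivation
    triples(pa, "measures", "COPE:LackOfPhysicalActivity", "asserted"),
    # feature-engineered predictor edge (scaled importance 100/100)
    triples(pa, "isPredictorOf", "HIO:%ObesityPrevalence", "ml", weight = 1)
  ))
  for (i in seq_along(lits)) kg <- add_literal(kg, lits[i], vals[i], metrics[i])
  kg
}
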