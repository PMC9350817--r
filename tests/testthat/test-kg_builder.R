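# Graph construction from tract tables, ML enrichment, inference enrichment,
# determinism and provenance bookkeeping.

box1_table <- function() {
  data.frame(geoid = "47157010300", obesity_prev = 46,
             lack_physical_activity = 49, no_hs_diploma = 21, poverty = 60,
             stringsAsFactors = FALSE)
}

test_that("tract metric values become weighted data triples", {
  kg <- build_graph(default_scheme(), box1_table(),
                    focus = list(individual = "individual:patient",
                                 geoid = "47157010300"))
  tr <- kg$triples
  has <- tr[tr$predicate == "has" & tr$subject == "47157010300", ]
  expect_setequal(has$weight, c(46, 49, 21, 60))
  expect_true(all(has$provenance == "data"))
  # each literal node is typed by its metric concept and holds its value
  pa_lit <- "lit:47157010300:HIO:%PopWLackOfPhysicalActivity"
  expect_true(any(tr$subject == pa_lit & tr$predicate == "isA" &
                  tr$object == "HIO:%PopWLackOfPhysicalActivity"))
  expect_equal(literal_value(kg, pa_lit), 49)
  expect_true(any(tr$subject == "individual:patient" &
                  tr$predicate == "livesIn" & tr$object == "47157010300"))
})

test_that("an empty table yields only the scheme and domain axioms", {
  sc <- default_scheme()
  kg <- build_graph(sc, NULL)
  n_isa <- sum(vapply(sc$concepts, function(cp) length(cp$parents), 0L))
  n_axioms <- sum(!is.na(upho:::.upho_variables$measures)) + 3
  expect_equal(nrow(kg$triples), n_isa + n_axioms)
  expect_true(all(kg$triples$provenance == "asserted"))
})

test_that("a two-tract toy table produces the hand-enumerated counts", {
  tab <- manual_tracts(2) # geoid + outcome + 3 features
  sc <- default_scheme()
  kg <- build_graph(sc, tab)
  n_isa <- sum(vapply(sc$concepts, function(cp) length(cp$parents), 0L))
  n_axioms <- sum(!is.na(upho:::.upho_variables$measures)) + 3
  # per tract: tract isA + representsA + neighborhood isA (3),
  # hasPhysicalCharacteristic (1), has (4 vars), literal isA (4 vars)
  per_tract <- 3 + 1 + 4 + 4
  expect_equal(nrow(kg$triples), n_isa + n_axioms + 2 * per_tract)
  # deterministic construction
  expect_identical(build_graph(sc, tab)$triples, kg$triples)
})

test_that("unknown focus geoids are rejected", {
  expect_error(build_graph(default_scheme(), manual_tracts(2),
                           focus = list(individual = "i", geoid = "99999999999")),
               "not present")
  expect_error(build_graph(default_scheme(), manual_tracts(2),
                           focus = list(population = "p",
                                        geoids = c("47157000001", "00000000000"))),
               "not present")
})

test_that("ML enrichment adds top-k predictor edges with scaled weights", {
  kg <- build_graph(default_scheme(), manual_tracts(3))
  imp <- data.frame(
    feature = c("lack_physical_activity", "poverty", "no_hs_diploma",
                "unemployment", "pct_black", "low_access_supermarket",
                "crime_rate"),
    raw = c(7, 5, 4.5, 4.2, 4, 1, 0.1),
    scaled = c(100, 78.6, 73.41, 70.16, 68.2, 4.39, 0),
    stringsAsFactors = FALSE)

  out <- enrich_with_ml(kg, imp, top_k = 5)
  ml <- out$triples[out$triples$provenance == "ml", ]
  expect_equal(nrow(ml), 5)
  expect_true(all(ml$predicate == "isPredictorOf"))
  expect_true(all(ml$object == "HIO:%ObesityPrevalence"))
  expect_equal(sort(ml$weight),
               sort(c(100, 78.6, 73.41, 70.16, 68.2) / 100))
  expect_true(all(ml$weight >= 0 & ml$weight <= 1))

  expect_identical(enrich_with_ml(kg, imp, top_k = 0)$triples, kg$triples)
  expect_warning(all_in <- enrich_with_ml(kg, imp, top_k = 99), "clamped")
  expect_equal(sum(all_in$triples$provenance == "ml"), nrow(imp))
})

test_that("inference enrichment reaches the naive-closure stable state", {
  kg <- build_graph(default_scheme(), box1_table(),
                    focus = list(individual = "individual:patient",
                                 geoid = "47157010300"))
  stable <- enrich_with_inference(kg, default_rules())
  expect_true(any(stable$triples$predicate == "isExposedTo"))
  expect_true(any(stable$triples$predicate == "shouldBeScreenedFor"))
  # already-stable graph returned unchanged
  expect_identical(enrich_with_inference(stable, default_rules())$triples,
                   stable$triples)
  # triple count equals one exhaustive naive closure of the same rules
  facts <- lapply(seq_len(nrow(kg$triples)), function(i)
    c(kg$triples$subject[i], kg$triples$predicate[i], kg$triples$object[i]))
  want <- oracle_chain(facts, default_rules())
  expect_equal(nrow(stable$triples), length(want))
  # enrichment is monotone and provenance partitions are preserved
  expect_true(all(triple_keys(kg) %in% triple_keys(stable)))
  new_rows <- !stable$triples$id %in% kg$triples$id
  expect_true(all(stable$triples$provenance[new_rows] == "inferred"))
})

test_that("graph exports are valid and deterministic", {
  kg <- enrich_with_inference(
    enrich_with_ml(build_graph(default_scheme(), manual_tracts(2)),
                   data.frame(feature = c("poverty", "no_hs_diploma"),
                              raw = c(2, 1), scaled = c(100, 0)), top_k = 2),
    default_rules())
  f1 <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(kg, f1)
  g <- igraph::read_graph(f1, format = "graphml")
  expect_equal(igraph::gorder(g), length(upho:::.kg_nodes(kg)))
  expect_equal(igraph::gsize(g), nrow(kg$triples))

  j1 <- withr::local_tempfile(fileext = ".json")
  j2 <- withr::local_tempfile(fileext = ".json")
  write_graph_json(kg, j1); write_graph_json(kg, j2)
  expect_identical(readLines(j1), readLines(j2))
})
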