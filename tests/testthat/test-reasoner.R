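# Pattern matching, guard semantics, forward chaining to the least fixpoint,
# derivation tracking, and the Datalog properties.

test_that("pattern matching binds variables consistently", {
  f1 <- c("individual:Patient", "livesIn", "10300")
  b <- match_pattern(c("?p", "livesIn", "?t"), f1)
  expect_identical(unname(b["?p"]), "individual:Patient")
  expect_identical(unname(b["?t"]), "10300")
  # pre-bound conflicting variable fails
  expect_null(match_pattern(c("?p", "livesIn", "?t"), f1,
                            binding = c("?t" = "10400")))
  # constants must match literally
  expect_null(match_pattern(c("?p", "worksIn", "?t"), f1))
  # repeated variable must bind to one constant
  expect_null(match_pattern(c("?x", "livesIn", "?x"), f1))
})

test_that("numeric guards compare typed literal values", {
  kg <- demo_scenario_graph() # physical-activity literal holds 49
  lit <- "lit:10300:HIO:%PopWLackOfPhysicalActivity"
  g50 <- list(var = "?m", op = ">=", value = 50)
  g40 <- list(var = "?m", op = ">=", value = 40)
  expect_false(eval_guard(kg, g50, c("?m" = lit)))
  expect_true(eval_guard(kg, g40, c("?m" = lit)))
  expect_false(eval_guard(kg, g40, c("?m" = "not-a-literal")))

  # and through the rule library: a 50% exposure threshold suppresses the
  # demo derivations, a 40% threshold admits them
  kg50 <- forward_chain(kg, default_rules(exposure_threshold = 50))
  expect_false("isExposedTo" %in% kg50$triples$predicate)
  kg40 <- forward_chain(kg, default_rules(exposure_threshold = 40))
  expect_true("isExposedTo" %in% kg40$triples$predicate)
})

test_that("the demonstration scenario derives exposure and screening", {
  kg0 <- demo_scenario_graph()
  kg <- forward_chain(kg0, default_rules())
  inf <- kg$triples[kg$triples$provenance == "inferred", ]

  expect_true(any(inf$subject == "individual:Patient" &
                  inf$predicate == "isExposedTo" &
                  inf$object == "COPE:LackOfPhysicalActivity"))
  scr <- inf[inf$predicate == "shouldBeScreenedFor", ]
  expect_identical(scr$subject, "individual:Patient")
  expect_identical(scr$object, "DO:Diabetes")

  # derivation chains bottom out in non-inferred facts of the fixture
  d <- replay_derivation(kg, scr$id)
  expect_true(all(c("RB1", "RB2", "RB3") %in% d$rules))
  prov <- kg$triples$provenance[match(d$facts, kg$triples$id)]
  expect_true(all(prov %in% c("asserted", "data", "ml")))
  # monotone: all input triples preserved
  expect_true(all(triple_keys(kg0) %in% triple_keys(kg)))
})

test_that("an empty rule library leaves the graph unchanged", {
  kg <- demo_scenario_graph()
  expect_identical(forward_chain(kg, list())$triples, kg$triples)
})

test_that("forward chaining equals a naive exhaustive closure on random graphs", {
  trans <- rule_axiom("T", list(c("?a", "isA", "?b"), c("?b", "isA", "?c")),
                      c("?a", "isA", "?c"))
  for (seed in c(1, 2)) {
    set.seed(seed)
    nodes <- sprintf("n%02d", 1:12)
    kg <- knowledge_graph()
    df <- unique(data.frame(s = sample(nodes, 50, TRUE),
                            o = sample(nodes, 50, TRUE)))
    df <- df[df$s != df$o, ]
    kg <- add_triples(kg, triples(df$s, "isA", df$o, "data"))

    out <- forward_chain(kg, list(trans), max_rounds = 50)
    facts <- lapply(seq_len(nrow(kg$triples)), function(i)
      c(kg$triples$subject[i], kg$triples$predicate[i], kg$triples$object[i]))
    want <- oracle_chain(facts, list(trans))
    want_keys <- sort(vapply(want, paste, "", collapse = " "))
    got_keys <- sort(paste(out$triples$subject, out$triples$predicate,
                           out$triples$object))
    expect_identical(got_keys, want_keys)

    # idempotence and rule-order independence on the same graph
    expect_identical(triple_keys(forward_chain(out, list(trans))),
                     triple_keys(out))
  }
})

test_that("the triple set is independent of rule order", {
  kg <- demo_scenario_graph()
  rules <- default_rules()
  base <- triple_keys(forward_chain(kg, rules))
  set.seed(3)
  for (i in 1:4) {
    expect_identical(triple_keys(forward_chain(kg, sample(rules))), base)
  }
})

test_that("exceeding max_rounds reports non-termination", {
  kg <- knowledge_graph()
  kg <- add_triples(kg, triples(sprintf("c%d", 1:5), "isA",
                                sprintf("c%d", 2:6), "data"))
  trans <- rule_axiom("T", list(c("?a", "isA", "?b"), c("?b", "isA", "?c")),
                      c("?a", "isA", "?c"))
  expect_error(forward_chain(kg, list(trans), max_rounds = 1),
               "fixpoint not reached within 1")
  expect_silent(forward_chain(kg, list(trans), max_rounds = 5))
})

test_that("rules are range-restricted by construction", {
  expect_error(rule_axiom("bad", list(c("?a", "isA", "?b")),
                          c("?a", "isA", "?c")), "range-restricted")
  expect_error(rule_axiom("bad2", list(c("?a", "isA", "?b")),
                          c("?a", "isA", "?b"),
                          guards = list(list(var = "?m", op = ">=", value = 1))),
               "range-restricted")
})

test_that("the shipped rule file parses to the built-in library", {
  path <- system.file("extdata", "default_rules.txt", package = "upho")
  parsed <- read_rules(path)
  builtin <- default_rules()
  expect_identical(vapply(parsed, `[[`, "", "id"),
                   vapply(builtin, `[[`, "", "id"))
  for (i in seq_along(parsed)) {
    expect_identical(parsed[[i]]$antecedents, builtin[[i]]$antecedents)
    expect_identical(parsed[[i]]$consequent, builtin[[i]]$consequent)
  }
  # guards round-trip through the text format
  f <- withr::local_tempfile(fileext = ".txt")
  write_rules(default_rules(exposure_threshold = 50), f)
  again <- read_rules(f)
  expect_identical(again[[4]]$guards,
                   list(list(var = "?m", op = ">=", value = 50)))
})
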