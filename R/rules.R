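# Rule axioms: variable-bearing antecedent patterns with optional numeric
# guards on literal values, plus one consequent pattern. Negation-free and
# range-restricted, so forward chaining has a unique least fixpoint.

.is_var <- function(term) startsWith(term, "?")

#' Create a rule axiom
#'
#' @param id rule identifier.
#' @param antecedents list of patterns, each a character vector
#'   `c(subject, predicate, object)`; terms starting with `?` are variables.
#'   May be empty, in which case the rule is a ground axiom whose consequent
#'   is asserted unconditionally.
#' @param consequent a single pattern; every variable in it (and in any
#'   guard) must appear in an antecedent (range restriction).
#' @param guards list of numeric guards, each
#'   `list(var = "?m", op = ">=", value = 50)`, comparing the literal value
#'   bound to `var` against a threshold.
#' @return An object of class `rule_axiom`.
#' @export
rule_axiom <- function(id, antecedents, consequent, guards = list()) {
  stopifnot(is.character(id), length(id) == 1)
  antecedents <- lapply(antecedents, as.character)
  consequent <- as.character(consequent)
  if (length(consequent) != 3 ||
      any(vapply(antecedents, length, 0L) != 3)) {
    stop("patterns must have exactly subject, predicate, object", call. = FALSE)
  }
  ante_vars <- unique(unlist(lapply(antecedents, function(p) p[.is_var(p)])))
  need <- unique(c(consequent[.is_var(consequent)],
                   vapply(guards, `[[`, "", "var")))
  free <- setdiff(need, ante_vars)
  if (length(free)) {
    stop("rule ", id, " is not range-restricted: variable ", free[1],
         " does not appear in an antecedent", call. = FALSE)
  }
  structure(list(id = id, antecedents = antecedents, guards = guards,
                 consequent = consequent), class = "rule_axiom")
}

#' The built-in rule library
#'
#' Three ground domain axioms and three bridging rules:
#' \describe{
#'   \item{R1}{lack of physical activity `leadsTo` obesity (ground axiom).}
#'   \item{R2}{the obesity-prevalence metric `isHealthIndicatorFor` obesity.}
#'   \item{R3}{obesity `isRiskFactorOf` diabetes.}
#'   \item{RB1}{exposure: a person living in a tract that `has` a metric
#'     value typed by a metric concept that `measures` a risk factor is
#'     `isExposedTo` that risk factor. An optional numeric guard on the
#'     metric value can be supplied via `exposure_threshold`.}
#'   \item{RB2}{risk: exposure to a risk factor that `leadsTo` a disease puts
#'     the person `atRiskOf` that disease.}
#'   \item{RB3}{screening: being at risk of a disease that `isRiskFactorOf` a
#'     second disease means the person `shouldBeScreenedFor` the latter.}
#' }
#'
#' @param exposure_threshold optional numeric; when given, RB1 only fires
#'   for metric values `>=` the threshold (by default exposure follows from
#'   the mere presence of the metric).
#' @return A list of [rule_axiom()] objects.
#' @export
default_rules <- function(exposure_threshold = NULL) {
  rb1_guards <- if (is.null(exposure_threshold)) list() else
    list(list(var = "?m", op = ">=", value = exposure_threshold))
  list(
    rule_axiom("R1", list(),
               c("COPE:LackOfPhysicalActivity", "leadsTo", "DO:Obesity")),
    rule_axiom("R2", list(),
               c("HIO:%ObesityPrevalence", "isHealthIndicatorFor", "DO:Obesity")),
    rule_axiom("R3", list(),
               c("DO:Obesity", "isRiskFactorOf", "DO:Diabetes")),
    rule_axiom("RB1",
               list(c("?p", "livesIn", "?t"),
                    c("?t", "has", "?m"),
                    c("?m", "isA", "?mc"),
                    c("?mc", "measures", "?rf")),
               c("?p", "isExposedTo", "?rf"),
               guards = rb1_guards),
    rule_axiom("RB2",
               list(c("?p", "isExposedTo", "?rf"),
                    c("?rf", "leadsTo", "?d")),
               c("?p", "atRiskOf", "?d")),
    rule_axiom("RB3",
               list(c("?p", "atRiskOf", "?d"),
                    c("?d", "isRiskFactorOf", "?d2")),
               c("?p", "shouldBeScreenedFor", "?d2"))
  )
}

# ---- rule file format ------------------------------------------------------
# RULE <id>: <pat> & <pat> [& value(?m) >= 50] => <pat>
# where <pat> is `subject predicate object`; a rule with no antecedents is
# written `RULE <id>: => subject predicate object`.

.format_rule <- function(rule) {
  pats <- vapply(rule$antecedents, paste, "", collapse = " ")
  guards <- vapply(rule$guards, function(g)
    sprintf("value(%s) %s %g", g$var, g$op, g$value), "")
  lhs <- paste(c(pats, guards), collapse = " & ")
  sprintf("RULE %s: %s => %s", rule$id, lhs, paste(rule$consequent, collapse = " "))
}

#' Write / read rule libraries in the line-oriented text format
#'
#' One rule per line: `RULE <id>: <pat> & <pat> [& value(?v) >= x] => <pat>`,
#' with patterns written as whitespace-separated `subject predicate object`
#' and `?`-prefixed variables. Lines starting with `#` and blank lines are
#' ignored on read.
#'
#' @param rules list of [rule_axiom()] objects.
#' @param path file path.
#' @return `write_rules` returns `path` invisibly; `read_rules` returns a
#'   list of `rule_axiom` objects.
#' @export
write_rules <- function(rules, path) {
  writeLines(vapply(rules, .format_rule, ""), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    m <- regmatches(ln, regexec("^RULE[[:space:]]+([^:]+):(.*)=>(.*)$", ln))[[1]]
    if (length(m) != 4) stop("malformed rule line: ", ln, call. = FALSE)
    id <- trimws(m[2])
    lhs <- trimws(m[3])
    consequent <- strsplit(trimws(m[4]), "[[:space:]]+")[[1]]
    antecedents <- list(); guards <- list()
    if (nzchar(lhs)) {
      for (part in trimws(strsplit(lhs, "&", fixed = TRUE)[[1]])) {
        g <- regmatches(part, regexec(
          "^value\\((\\?[^)]+)\\)[[:space:]]*(>=|<=|>|<)[[:space:]]*([-0-9.eE+]+)$",
          part))[[1]]
        if (length(g) == 4) {
          guards[[length(guards) + 1]] <-
            list(var = g[2], op = g[3], value = as.numeric(g[4]))
        } else {
          antecedents[[length(antecedents) + 1]] <-
            strsplit(part, "[[:space:]]+")[[1]]
        }
      }
    }
    rule_axiom(id, antecedents, consequent, guards)
  })
}
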