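# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closures are computed by set iteration on string
# keys, Shapley values by exhaustive coalition enumeration, p-values by full
# permutation, and paths by unconstrained DFS.

# Brute-force reflexive-transitive closure of a parent map (named list of
# character vectors). Returns a logical matrix closure[a, b].
oracle_closure <- function(parents) {
  nodes <- names(parents)
  M <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  diag(M) <- TRUE
  for (a in nodes) M[a, parents[[a]]] <- TRUE
  repeat {
    M2 <- M | (M %*% M > 0)
    if (identical(M2, M)) return(M)
    M <- M2
  }
}

# Naive exhaustive forward-chaining closure over (s, p, o) string triples:
# iterate every rule against every tuple combination until no change.
# Rules are upho rule_axiom objects but are interpreted here from scratch.
oracle_chain <- function(facts, rules) {
  key <- function(t) paste(t, collapse = "\r")
  store <- setNames(facts, vapply(facts, key, ""))
  bind_one <- function(pat, tri, b) {
    for (k in 1:3) {
      if (startsWith(pat[k], "?")) {
        if (!is.null(b[[pat[k]]])) {
          if (b[[pat[k]]] != tri[k]) return(NULL)
        } else b[[pat[k]]] <- tri[k]
      } else if (pat[k] != tri[k]) return(NULL)
    }
    b
  }
  repeat {
    added <- FALSE
    for (rule in rules) {
      bindings <- list(list())
      for (pat in rule$antecedents) {
        nxt <- list()
        for (b in bindings) for (tri in store) {
          b2 <- bind_one(pat, tri, b)
          if (!is.null(b2)) nxt[[length(nxt) + 1]] <- b2
        }
        bindings <- nxt
      }
      for (b in bindings) {
        fact <- vapply(rule$consequent, function(term) {
          if (startsWith(term, "?")) b[[term]] else term
        }, "")
        k <- key(fact)
        if (is.null(store[[k]])) {
          store[[k]] <- fact
          added <- TRUE
        }
      }
    }
    if (!added) return(unname(store))
  }
}

# Exhaustive interventional Shapley values for a linear model f(x) = w.x + b
# with independent features imputed at the background mean: enumerate all
# coalitions with the usual combinatorial weights.
oracle_shapley <- function(w, x, bg_mean) {
  p <- length(w)
  f <- function(mask) sum(w * ifelse(mask, x, bg_mean))
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  for (j in seq_len(p)) {
    for (r in seq_len(nrow(subsets))) {
      S <- as.logical(subsets[r, ])
      if (S[j]) next
      s <- sum(S)
      wgt <- factorial(s) * factorial(p - s - 1) / factorial(p)
      Sj <- S; Sj[j] <- TRUE
      phi[j] <- phi[j] + wgt * (f(Sj) - f(S))
    }
  }
  phi
}

# Exact two-sided permutation p-value for the Spearman statistic on small n:
# all n! permutations of y's ranks.
oracle_perm_spearman_p <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1) return(matrix(v, 1))
    out <- NULL
    for (i in seq_along(v)) {
      sub <- perms(v[-i])
      out <- rbind(out, cbind(v[i], sub))
    }
    out
  }
  rx <- rank(x); ry <- rank(y)
  n <- length(rx)
  obs <- cor(rx, ry)
  P <- perms(ry)
  num <- P %*% (rx - mean(rx))
  denom <- sd(rx) * sd(ry) * (n - 1)
  rhos <- as.numeric(num) / denom # mean term cancels against centred rx
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# Unconstrained enumeration of simple paths from `source` up to max_len
# edges; returns each path's node sequence and predicate sequence.
oracle_paths <- function(kg, source, max_len) {
  tr <- kg$triples
  out <- list()
  walk <- function(node, nodes, preds) {
    if (length(preds) >= max_len) return(invisible())
    nxt <- which(tr$subject == node)
    for (i in nxt) {
      if (tr$object[i] %in% nodes) next
      nodes2 <- c(nodes, tr$object[i])
      preds2 <- c(preds, tr$predicate[i])
      out[[length(out) + 1]] <<- list(nodes = nodes2, preds = preds2)
      walk(tr$object[i], nodes2, preds2)
    }
  }
  walk(source, source, character())
  out
}

# Compact key for a triple set: sorted subject|predicate|object strings.
triple_keys <- function(kg) {
  sort(paste(kg$triples$subject, kg$triples$predicate, kg$triples$object))
}

# Small valid tract table built by hand (no generator involvement).
manual_tracts <- function(n = 6, seed = 99) {
  set.seed(seed)
  data.frame(
    geoid = sprintf("47157%06d", seq_len(n)),
    obesity_prev = runif(n, 20, 50),
    lack_physical_activity = runif(n, 20, 50),
    poverty = runif(n, 5, 60),
    no_hs_diploma = runif(n, 2, 30),
    stringsAsFactors = FALSE)
}
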