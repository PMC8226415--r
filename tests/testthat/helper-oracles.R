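# Shared fixtures and independent oracles for the suite.
# Oracles deliberately avoid the package's own graph/tree code: reachability
# is boolean matrix transitive closure, tree comparisons are flat path sets.

REG <- make_fixture_registries()

# Boolean transitive closure of an n x n adjacency matrix (one or more
# steps), by repeated squaring-free accumulation: R = A + A^2 + ... + A^n.
closure_oracle <- function(adj) {
  n <- nrow(adj)
  reach <- adj
  step <- adj
  for (k in seq_len(n)) {
    step <- (step %*% adj) > 0
    new <- reach | step
    if (identical(new, reach)) break
    reach <- new
  }
  reach
}

# Flatten a document into "path=value" strings for set-style comparison.
flat_fields <- function(doc) {
  walk <- function(x, prefix) {
    if (is.list(x)) {
      if (length(x) == 0L) return(character(0))  # empty containers are
                                                 # transparent to the diff
      nm <- names(x)
      unlist(lapply(seq_along(x), function(i) {
        key <- if (is.null(nm) || nm[i] == "") as.character(i) else nm[i]
        walk(x[[i]], paste0(prefix, "/", key))
      }))
    } else {
      paste0(prefix, "=", paste(format(x), collapse = ","))
    }
  }
  sort(walk(doc, ""))
}

# Paths only (no values).
flat_paths <- function(doc) sort(unique(sub("=.*$", "", flat_fields(doc))))

# Unique rule kinds present in a report.
report_kinds <- function(report) {
  sort(unique(vapply(report$issues, `[[`, "", "rule_kind")))
}

# Build a random DAG snapshot (edges only from higher to lower index, so
# acyclic by construction) plus its adjacency matrix; used to cross-check
# is_descendant against the closure oracle.
random_dag_snapshot <- function(seed, n = 50, p = 0.08) {
  set.seed(seed)
  iris <- sprintf("https://onto.invalid/RND_%07d", seq_len(n))
  adj <- matrix(FALSE, n, n)
  parents <- character(n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    k <- which(stats::runif(i - 1L) < p)
    if (length(k) == 0L && stats::runif(1) < 0.7) k <- sample.int(i - 1L, 1L)
    adj[i, k] <- TRUE
    parents[i] <- paste(iris[k], collapse = "|")
  }
  terms <- data.frame(iri = iris, label = paste("term", seq_len(n)),
                      parents = parents, stringsAsFactors = FALSE)
  list(snapshot = new_ontology_snapshot("rnd", "0", terms), adj = adj,
       iris = iris)
}
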