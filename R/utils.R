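# Shared helpers: conditions, canonical JSON, nested access, seeded RNG.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a trackmeta error condition
#'
#' All package errors carry class `trackmeta_error` plus a kind-specific
#' class `trackmeta_<kind>` so callers can condition on the failure mode.
#'
#' @param kind short error kind, e.g. "curie_syntax".
#' @param message human-readable message.
#' @param ... extra condition fields.
#' @noRd
tm_error <- function(kind, message, ...) {
  cond <- structure(
    class = c(paste0("trackmeta_", kind), "trackmeta_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), kind = kind, ...)
  )
  stop(cond)
}

is_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

# A JSON value parsed with simplifyVector = FALSE: named lists are objects,
# unnamed lists are arrays, scalars are length-1 vectors.  Canonical form
# sorts object keys (C-locale radix order) at every level; array order is
# preserved.  Attributes other than names are dropped.
canonical_sort <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm)) {
      if (anyDuplicated(nm)) {
        tm_error("structure", "duplicate keys in object")
      }
      o <- order(nm, method = "radix")
      out <- lapply(unclass(x)[o], canonical_sort)
      names(out) <- nm[o]
      out
    } else {
      lapply(unclass(x), canonical_sort)
    }
  } else {
    x
  }
}

# Canonical serialization used for documents, schemas and reports:
# sorted keys, 2-space indent, UTF-8, trailing newline.
canonical_json <- function(x) {
  txt <- jsonlite::toJSON(canonical_sort(x), auto_unbox = TRUE, pretty = 2,
                          null = "null", na = "null", digits = NA)
  paste0(as.character(txt), "\n")
}

# Get / set a node in a nested list by an index path (names or integers).
doc_get <- function(x, idx) {
  for (i in idx) {
    if (is.null(x)) return(NULL)
    x <- if (is.numeric(i)) {
      if (i > length(x)) NULL else x[[i]]
    } else {
      x[[i]]
    }
  }
  x
}

doc_set <- function(x, idx, value) {
  if (length(idx) == 0L) return(value)
  i <- idx[[1]]
  rest <- idx[-1]
  sub <- if (is.numeric(i) && i > length(x)) NULL else x[[i]]
  x[[i]] <- doc_set(sub %||% list(), rest, value)
  x
}

# JSON-pointer style path string; indices are zero-based as in a pointer.
path_str <- function(idx) {
  parts <- vapply(idx, function(i) {
    if (is.numeric(i)) as.character(i - 1L) else as.character(i)
  }, character(1))
  paste0("/", paste(parts, collapse = "/"))
}

# Run code with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Flatten a document tree into leaf paths and values, used by tree-diff
# style checks and the converters.
leaf_paths <- function(x, prefix = character()) {
  if (is.list(x)) {
    if (length(x) == 0L) {
      out <- list(list(path = prefix, value = x))
      return(out)
    }
    nm <- names(x)
    out <- list()
    for (i in seq_along(x)) {
      key <- if (is.null(nm) || nm[i] == "") i else nm[i]
      out <- c(out, leaf_paths(x[[i]], c(prefix, key)))
    }
    out
  } else {
    list(list(path = prefix, value = x))
  }
}
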