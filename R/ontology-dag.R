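# Internal representation of an ontology DAG
# ------------------------------------------
# Terms are indexed 1..n; parents/children are lists of integer vectors,
# parent_rel holds the relation label of each parent edge, parallel to
# parents[[i]]. The topological order and longest-path levels are computed
# once at construction so downstream code can rely on them.

OBO_NAMESPACES <- c(biological_process = "BP",
                    molecular_function = "MF",
                    cellular_component = "CC")

#' Build an ontology DAG from an edge list
#'
#' Constructs and validates a rooted directed acyclic graph of ontology terms
#' with typed edges (`is_a` / `part_of`). Roots are the terms without parents;
#' levels are longest-path depths from the roots (roots at 0), so a term is
#' always at a strictly greater level than each of its parents.
#'
#' @param edges a data.frame with columns `parent`, `child` and optionally
#'   `relation` (default `"is_a"`), or `NULL` for a graph without edges.
#' @param terms optional character vector of term identifiers to include even
#'   if they appear in no edge (e.g. an isolated root).
#' @param namespaces optional named character vector mapping term identifiers
#'   to `"BP"`, `"MF"`, `"CC"` or `"other"`; unmapped terms inherit the
#'   namespace of their root, or `"other"`.
#' @return an object of class `ontology_dag`.
#' @examples
#' dag <- build_dag(data.frame(parent = c("C", "B"), child = c("B", "A")))
#' dag_roots(dag)
#' @export
build_dag <- function(edges = NULL, terms = NULL, namespaces = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(parent = character(), child = character(),
                        relation = character())
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("parent", "child") %in% names(edges)))
    stop("`edges` must have columns `parent` and `child`")
  if (is.null(edges$relation)) edges$relation <- rep("is_a", nrow(edges))
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  edges$relation <- as.character(edges$relation)

  key <- paste(edges$parent, edges$child, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate parent/child edge(s) removed")
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  if (any(edges$parent == edges$child))
    stop("cycle detected: term ", edges$parent[edges$parent == edges$child][1],
         " is its own parent")

  ids <- unique(c(as.character(terms), edges$parent, edges$child))
  if (length(ids) == 0L) stop("empty DAG: no terms declared")
  if (any(!nzchar(ids))) stop("empty term identifier")
  n <- length(ids)
  pi <- match(edges$parent, ids)
  ci <- match(edges$child, ids)

  parents <- split_indices(pi, ci, n)        # parents[[child]]
  parent_rel <- split_values(edges$relation, ci, n)
  children <- split_indices(ci, pi, n)       # children[[parent]]

  ord <- kahn_order(ids, parents, children)

  level <- integer(n)
  for (i in ord) {
    ps <- parents[[i]]
    level[i] <- if (length(ps)) max(level[ps]) + 1L else 0L
  }
  roots <- which(lengths(parents) == 0L)

  ns <- rep(NA_character_, n)
  if (!is.null(namespaces)) {
    hit <- match(ids, names(namespaces))
    ns[!is.na(hit)] <- unname(namespaces[hit[!is.na(hit)]])
  }
  # inherit root namespace down the graph where unset
  for (i in ord) {
    if (is.na(ns[i])) {
      ps <- parents[[i]]
      pns <- unique(ns[ps])
      pns <- pns[!is.na(pns)]
      ns[i] <- if (length(pns) == 1L) pns else "other"
    }
  }

  structure(list(terms = ids, parents = parents, parent_rel = parent_rel,
                 children = children, roots = roots, order = ord,
                 level = level, namespace = ns),
            class = "ontology_dag")
}

split_indices <- function(values, by, n) {
  out <- rep(list(integer()), n)
  if (length(by)) {
    sp <- split(values, by)
    out[as.integer(names(sp))] <- lapply(sp, as.integer)
  }
  out
}

split_values <- function(values, by, n) {
  out <- rep(list(character()), n)
  if (length(by)) {
    sp <- split(values, by)
    out[as.integer(names(sp))] <- sp
  }
  out
}

# Kahn's algorithm; errors with one member of a cycle if the graph is cyclic.
kahn_order <- function(ids, parents, children) {
  n <- length(ids)
  indeg <- lengths(parents)
  queue <- which(indeg == 0L)
  if (n > 0L && length(queue) == 0L)
    stop("cycle detected involving term ", ids[1])
  ord <- integer(n)
  k <- 0L
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    k <- k + 1L
    ord[k] <- i
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (k < n) {
    left <- setdiff(seq_len(n), ord[seq_len(k)])
    stop("cycle detected involving term ", ids[left[1]])
  }
  ord
}

term_index <- function(dag, t) {
  i <- match(t, dag$terms)
  if (anyNA(i)) stop("unknown term: ", paste(t[is.na(i)], collapse = ", "))
  i
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", length(x$terms), "terms,",
      sum(lengths(x$parents)), "edges,", length(x$roots), "root(s)\n")
  cat("  roots:", paste(x$terms[x$roots], collapse = ", "), "\n")
  cat("  max level:", max(x$level), "\n")
  invisible(x)
}

#' Roots of a DAG
#' @param dag an `ontology_dag`.
#' @return character vector of parentless term identifiers.
#' @export
dag_roots <- function(dag) dag$terms[dag$roots]

#' Self-inclusive ancestors of a term
#'
#' All terms lying on any directed path from a root down to `t`, plus `t`
#' itself (the set conventionally written T_t).
#'
#' @param dag an `ontology_dag`.
#' @param t a term identifier.
#' @return character vector of term identifiers (unordered).
#' @export
ancestors_self_inclusive <- function(dag, t) {
  i <- term_index(dag, t)
  seen <- logical(length(dag$terms))
  stack <- i
  while (length(stack)) {
    j <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (!seen[j]) {
      seen[j] <- TRUE
      stack <- c(stack, dag$parents[[j]][!seen[dag$parents[[j]]]])
    }
  }
  dag$terms[seen]
}

# Ancestor index sets for every term at once (self-inclusive), accumulated in
# topological order. Used by the similarity layer and the Wang IC.
all_ancestor_sets <- function(dag) {
  anc <- vector("list", length(dag$terms))
  for (i in dag$order) {
    ps <- dag$parents[[i]]
    anc[[i]] <- if (length(ps)) unique(c(i, unlist(anc[ps]))) else i
  }
  anc
}

#' Longest-path levels of all terms
#'
#' The level of a term is the length of the longest path from a root down to
#' it; roots sit at level 0, so a child is always at least one level below
#' each of its parents.
#'
#' @param dag an `ontology_dag`.
#' @return named integer vector of levels.
#' @export
term_levels <- function(dag) stats::setNames(dag$level, dag$terms)

#' Topological order of the terms
#'
#' Every parent precedes all of its children; this is the evaluation order of
#' the recursive topological-position product.
#'
#' @param dag an `ontology_dag`.
#' @return character vector of term identifiers.
#' @export
topological_order <- function(dag) dag$terms[dag$order]

#' Parse an OBO 1.2 flat file into an ontology DAG
#'
#' Reads `[Term]` stanzas, keeping `is_a` and (by default) `part_of`
#' relationship edges and dropping the regulates family. Obsolete terms are
#' excluded; terms referenced as parents but lacking a stanza are materialised
#' as bare terms with a warning, so truncated extracts still load.
#'
#' @param path path to an OBO file, or a character vector of its lines via
#'   `text`.
#' @param keep_relations relationship types to retain as edges.
#' @param text optional character vector of OBO lines (overrides `path`).
#' @return an `ontology_dag`.
#' @export
parse_obo <- function(path = NULL, keep_relations = c("is_a", "part_of"),
                      text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  stanzas <- list()
  start_line <- 0L
  flush <- function(cur) {
    if (!is.null(cur)) {
      if (is.null(cur$id))
        stop("malformed stanza starting at line ", cur$line, ": missing id")
      stanzas[[length(stanzas) + 1L]] <<- cur
    }
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "[Term]") {
      flush(cur)
      cur <- list(line = ln, parents = character(), rel = character())
      in_term <- TRUE
    } else if (grepl("^\\[", line)) {         # [Typedef] etc.
      flush(cur)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(line) && !startsWith(line, "!")) {
      if (!grepl(":", line, fixed = TRUE))
        stop("malformed stanza at line ", ln, ": ", line)
      tag <- sub(":.*$", "", line)
      val <- sub("!.*$", "", sub("^[^:]+:\\s*", "", line))
      val <- trimws(val)
      val <- unname(val)
      if (tag == "id") cur$id <- val
      else if (tag == "namespace") cur$namespace <- val
      else if (tag == "is_obsolete") cur$obsolete <- isTRUE(val == "true")
      else if (tag == "is_a") {
        cur$parents <- c(cur$parents, val)
        cur$rel <- c(cur$rel, "is_a")
      } else if (tag == "relationship") {
        bits <- strsplit(val, "\\s+")[[1]]
        if (length(bits) < 2L)
          stop("malformed relationship at line ", ln, ": ", line)
        cur$parents <- c(cur$parents, bits[2])
        cur$rel <- c(cur$rel, bits[1])
      }
    }
  }
  flush(cur)
  if (!length(stanzas)) stop("no [Term] stanzas found")

  stanzas <- Filter(function(s) !isTRUE(s$obsolete), stanzas)
  ids <- vapply(stanzas, `[[`, "", "id")
  ns <- vapply(stanzas, function(s) {
    raw <- s$namespace
    if (is.null(raw)) "other"
    else if (raw %in% names(OBO_NAMESPACES)) OBO_NAMESPACES[[raw]]
    else "other"
  }, "")
  edges <- do.call(rbind, lapply(stanzas, function(s) {
    keep <- s$rel %in% keep_relations & s$parents %in% ids
    miss <- s$rel %in% keep_relations & !(s$parents %in% ids)
    if (any(miss)) {
      # parent referenced without a stanza: keep as a bare term
      keep <- keep | miss
    }
    if (!any(keep)) return(NULL)
    data.frame(parent = s$parents[keep], child = rep(s$id, sum(keep)),
               relation = s$rel[keep], stringsAsFactors = FALSE)
  }))
  if (!is.null(edges)) {
    bare <- setdiff(edges$parent, ids)
    if (length(bare))
      warning("materialised ", length(bare),
              " referenced term(s) without a stanza: ",
              paste(utils::head(bare, 3), collapse = ", "))
  }
  build_dag(edges, terms = ids, namespaces = stats::setNames(ns, ids))
}

#' Serialise a DAG to OBO 1.2 text
#'
#' Inverse of [parse_obo()] for the tags this package consumes; round-trips
#' terms, namespaces and kept edges.
#'
#' @param dag an `ontology_dag`.
#' @param path output path; if `NULL` the lines are returned invisibly.
#' @return invisibly, the character vector of OBO lines.
#' @export
write_obo <- function(dag, path = NULL) {
  rev_ns <- stats::setNames(names(OBO_NAMESPACES), OBO_NAMESPACES)
  out <- c("format-version: 1.2", "")
  for (i in seq_along(dag$terms)) {
    out <- c(out, "[Term]", paste0("id: ", dag$terms[i]))
    if (dag$namespace[i] %in% names(rev_ns))
      out <- c(out, paste0("namespace: ", rev_ns[[dag$namespace[i]]]))
    ps <- dag$parents[[i]]
    rel <- dag$parent_rel[[i]]
    for (k in seq_along(ps)) {
      out <- c(out, if (rel[k] == "is_a")
        paste0("is_a: ", dag$terms[ps[k]])
        else paste0("relationship: ", rel[k], " ", dag$terms[ps[k]]))
    }
    out <- c(out, "")
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Read an edge-list TSV (`parent<TAB>child[<TAB>relation]`)
#'
#' Lines starting with `#` are comments; a header line naming the columns is
#' detected and skipped.
#'
#' @param path input path.
#' @return a data.frame suitable for [build_dag()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) && grepl("^parent\\b", lines[1])) lines <- lines[-1]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(parent = vapply(parts, `[`, "", 1),
             child = vapply(parts, `[`, "", 2),
             relation = vapply(parts, function(p)
               if (length(p) >= 3) p[3] else "is_a", ""),
             stringsAsFactors = FALSE)
}

#' Write a DAG's edges as an edge-list TSV
#' @param dag an `ontology_dag`.
#' @param path output path.
#' @export
write_edge_list <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("parent\tchild\trelation", con)
  for (i in seq_along(dag$terms)) {
    ps <- dag$parents[[i]]
    for (k in seq_along(ps))
      writeLines(paste(dag$terms[ps[k]], dag$terms[i],
                       dag$parent_rel[[i]][k], sep = "\t"), con)
  }
  invisible(path)
}
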