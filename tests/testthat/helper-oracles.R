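# Independent brute-force oracles used across the test files. These work
# from the raw edge list, never through the package's graph structures.

# edge data.frame -> list term -> self-inclusive ancestor set, by repeated
# parent expansion to a fixed point
bf_ancestors <- function(edges, terms) {
  anc <- stats::setNames(as.list(terms), terms)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      p <- edges$parent[k]
      c0 <- edges$child[k]
      add <- setdiff(anc[[p]], anc[[c0]])
      if (length(add)) {
        anc[[c0]] <- c(anc[[c0]], add)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lapply(anc, sort)
}

# longest path from any root by exhaustive path enumeration (small DAGs only)
bf_level <- function(edges, term, roots) {
  if (term %in% roots) return(0L)
  ps <- edges$parent[edges$child == term]
  if (!length(ps)) return(0L)
  1L + max(vapply(ps, bf_level, 0L, edges = edges, roots = roots))
}

# all root->leaf path counts passing through each term (Zhang count oracle)
bf_leaf_paths <- function(edges, term) {
  ch <- edges$child[edges$parent == term]
  if (!length(ch)) return(1L)
  sum(vapply(ch, bf_leaf_paths, 0L, edges = edges))
}

edge_df <- function(dag) {
  do.call(rbind, lapply(seq_along(dag$terms), function(i) {
    ps <- dag$parents[[i]]
    if (!length(ps)) return(NULL)
    data.frame(parent = dag$terms[ps], child = dag$terms[i],
               relation = dag$parent_rel[[i]])
  }))
}

obo_lines <- function(...) unlist(list("format-version: 1.2", "", ...))

term_stanza <- function(id, parents = character(), rel = "is_a",
                        ns = "biological_process", obsolete = FALSE) {
  c("[Term]", paste0("id: ", id), paste0("namespace: ", ns),
    unlist(mapply(function(p, r) {
      if (r == "is_a") paste0("is_a: ", p)
      else paste0("relationship: ", r, " ", p)
    }, parents, rep_len(rel, length(parents)), SIMPLIFY = FALSE)),
    if (obsolete) "is_obsolete: true", "")
}
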