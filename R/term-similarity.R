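# Pairwise term similarity.
#
# The candidate ancestor set A(x, y) for every measure is the intersection of
# the two self-inclusive ancestor sets (so a parent is itself a candidate for
# its child). The GO-universal score divides the shared information -ln(mu_s)
# of the most informative common ancestor (smallest mu) by the larger of the
# two term ICs; roots carry zero information so any pair involving a root
# scores 0, and cross-namespace pairs score 0 with a warning.

# log10(mu) for ordering; works for injected, non-normalised mantissas too
mu_log10 <- function(mu, idx) log10(mu$alpha[idx]) + mu$beta[idx]

common_ancestors <- function(dag, x, y) {
  intersect(ancestors_self_inclusive(dag, x), ancestors_self_inclusive(dag, y))
}

check_pair <- function(dag, x, y) {
  i <- term_index(dag, c(x, y))
  if (dag$namespace[i[1]] != dag$namespace[i[2]]) {
    warning("terms ", x, " and ", y, " are in different namespaces; ",
            "similarity is 0")
    return(FALSE)
  }
  TRUE
}

#' Shared topological position of two terms
#'
#' Finds the common self-inclusive ancestor with the smallest topological
#' position mu_s(x, y); the shared information is -ln(mu_s). Ties on mu are
#' broken by greater level, then lexicographic identifier (the score is
#' unaffected, only the reported ancestor). Terms in disjoint namespaces
#' share no informative ancestor and get shared IC 0.
#'
#' @param dag an `ontology_dag`.
#' @param mu a `topo_position` for `dag` (computed or injected).
#' @param x,y term identifiers.
#' @return a list with `best_ancestor`, `mu_s` (alpha/beta pair) and
#'   `shared_ic` in nats.
#' @export
shared_position <- function(dag, mu, x, y) {
  cand <- common_ancestors(dag, x, y)
  if (!length(cand)) {
    return(list(best_ancestor = NA_character_,
                mu_s = c(alpha = 1, beta = 0), shared_ic = 0))
  }
  lg <- mu_log10(mu, cand)
  best <- cand[lg == min(lg)]
  if (length(best) > 1) {
    lev <- dag$level[term_index(dag, best)]
    best <- best[lev == max(lev)]
    best <- sort(best)[1]
  }
  a <- mu$alpha[[best]]
  b <- mu$beta[[best]]
  list(best_ancestor = best, mu_s = c(alpha = a, beta = b),
       shared_ic = max(0, -log(a) - b * LN10))
}

#' GO-universal term similarity
#'
#' S(x, y) = shared IC / max(IC(x), IC(y)). Synonym pairs (identical mu joined
#' by a directed path) and identical terms score exactly 1; pairs where both
#' ICs are 0 (roots) or whose namespaces differ score 0.
#'
#' @param dag an `ontology_dag`.
#' @param ic an `ic_table` of method `"universal"` (its `aux$mu` supplies the
#'   topological positions).
#' @param x,y term identifiers.
#' @return similarity score in \[0, 1\].
#' @export
sim_universal <- function(dag, ic, x, y) {
  stopifnot(inherits(ic, "ic_table"), ic$method == "universal")
  if (!check_pair(dag, x, y)) return(0)
  mu <- ic$aux$mu
  if (is.null(mu)) stop("universal ic_table lacks the mu payload")
  if (identical(x, y)) return(1)
  icx <- ic_lookup(ic, x)
  icy <- ic_lookup(ic, y)
  i <- term_index(dag, c(x, y))
  if (mu$alpha[[x]] == mu$alpha[[y]] && mu$beta[[x]] == mu$beta[[y]] &&
      connected_by_path(dag, i[1], i[2]))
    return(1)
  mx <- max(icx, icy)
  if (mx == 0) return(0)
  sp <- shared_position(dag, mu, x, y)
  min(1, sp$shared_ic / mx)
}

# directed path in either orientation
connected_by_path <- function(dag, i, j) {
  ai <- ancestors_idx(dag, i)
  if (j %in% ai) return(TRUE)
  i %in% ancestors_idx(dag, j)
}

ancestors_idx <- function(dag, i) {
  seen <- logical(length(dag$terms))
  stack <- i
  while (length(stack)) {
    k <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (!seen[k]) {
      seen[k] <- TRUE
      stack <- c(stack, dag$parents[[k]][!seen[dag$parents[[k]]]])
    }
  }
  which(seen)
}

ic_lookup <- function(ic, t) {
  v <- ic$values[t]
  if (anyNA(v)) stop("term missing from IC table: ",
                     paste(t[is.na(v)], collapse = ", "))
  unname(v)
}

#' GO-universal term distance
#'
#' d(x, y) = 1 - S(x, y); symmetric, zero exactly on synonym pairs and
#' identical terms, and satisfies the triangle inequality.
#'
#' @inheritParams sim_universal
#' @return distance in \[0, 1\].
#' @export
dist_universal <- function(dag, ic, x, y) 1 - sim_universal(dag, ic, x, y)

#' Wang term similarity
#'
#' Sum over the common self-inclusive ancestors of S_x(t) + S_y(t), divided by
#' IC_W(x) + IC_W(y); both S-value maps use the self-inclusive ancestor
#' convention.
#'
#' @param dag an `ontology_dag`.
#' @param ic an `ic_table` of method `"wang"` from [wang_ic()].
#' @param x,y term identifiers.
#' @return similarity score in (0, 1\].
#' @export
sim_wang <- function(dag, ic, x, y) {
  stopifnot(inherits(ic, "ic_table"), ic$method == "wang")
  if (!check_pair(dag, x, y)) return(0)
  sx <- ic$aux$svalues[[x]]
  sy <- ic$aux$svalues[[y]]
  if (is.null(sx) || is.null(sy)) stop("term missing from Wang S-values")
  common <- intersect(names(sx), names(sy))
  if (!length(common)) return(0)
  sum(sx[common] + sy[common]) / (ic_lookup(ic, x) + ic_lookup(ic, y))
}

#' Zhang term similarity (uniform-Resnik or Lin scaling)
#'
#' `uniform_resnik`: the maximum IC_Zu over the common self-inclusive
#' ancestors. `lin`: the maximum of 2*IC_Z(a) / (IC_Z(x) + IC_Z(y)) over the
#' same set.
#'
#' @param dag an `ontology_dag`.
#' @param ic for `scaling = "lin"` an `ic_table` of method `"zhang"`; for
#'   `"uniform_resnik"` one of method `"zhang_uniform"`.
#' @param x,y term identifiers.
#' @param scaling `"lin"` or `"uniform_resnik"`.
#' @return similarity score in \[0, 1\].
#' @export
sim_zhang <- function(dag, ic, x, y, scaling = c("lin", "uniform_resnik")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(ic, "ic_table"))
  if (!check_pair(dag, x, y)) return(0)
  cand <- common_ancestors(dag, x, y)
  if (!length(cand)) return(0)
  ica <- ic_lookup(ic, cand)
  if (scaling == "uniform_resnik") {
    stopifnot(ic$method == "zhang_uniform")
    return(max(ica))
  }
  stopifnot(ic$method == "zhang")
  denom <- ic_lookup(ic, x) + ic_lookup(ic, y)
  if (denom == 0) return(if (identical(x, y)) 1 else 0)
  min(1, max(2 * ica / denom))
}

#' Term-to-set similarity
#'
#' The best match of a term against a set: max over s in S of sim(t, s),
#' equivalently 1 minus the minimum distance from t to the set.
#'
#' @param dag an `ontology_dag`.
#' @param ic an `ic_table` matching `measure`.
#' @param t a term identifier.
#' @param set non-empty character vector of term identifiers.
#' @param measure `"universal"`, `"wang"`, `"zhang_lin"` or
#'   `"zhang_uniform_resnik"`.
#' @return the best-match similarity in \[0, 1\].
#' @export
sim_term_to_set <- function(dag, ic, t, set,
                            measure = c("universal", "wang", "zhang_lin",
                                        "zhang_uniform_resnik")) {
  measure <- match.arg(measure)
  if (!length(set)) stop("empty term set")
  max(vapply(set, function(s) pair_sim(dag, ic, t, s, measure), 0))
}

pair_sim <- function(dag, ic, x, y, measure) {
  switch(measure,
         universal = sim_universal(dag, ic, x, y),
         wang = sim_wang(dag, ic, x, y),
         zhang_lin = sim_zhang(dag, ic, x, y, "lin"),
         zhang_uniform_resnik = sim_zhang(dag, ic, x, y, "uniform_resnik"),
         stop("unknown measure: ", measure))
}

#' Batch term similarity
#'
#' Scores a table of term pairs under one measure, returning one tidy row per
#' pair. Unknown terms yield an `NA` score with a warning rather than
#' aborting the batch.
#'
#' @param dag an `ontology_dag`.
#' @param ic an `ic_table` matching `measure`.
#' @param pairs data.frame with columns `term_a`, `term_b` (or first two
#'   columns used positionally).
#' @param measure as in [sim_term_to_set()].
#' @return data.frame `term_a`, `term_b`, `measure`, `score`.
#' @export
term_sim <- function(dag, ic, pairs, measure = "universal") {
  pairs <- as.data.frame(pairs)
  if (!all(c("term_a", "term_b") %in% names(pairs)))
    names(pairs)[1:2] <- c("term_a", "term_b")
  score <- vapply(seq_len(nrow(pairs)), function(k) {
    tryCatch(pair_sim(dag, ic, pairs$term_a[k], pairs$term_b[k], measure),
             error = function(e) {
               warning("pair (", pairs$term_a[k], ", ", pairs$term_b[k],
                       ") skipped: ", conditionMessage(e))
               NA_real_
             })
  }, 0)
  data.frame(term_a = pairs$term_a, term_b = pairs$term_b,
             measure = measure, score = score)
}
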