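# Topological position characteristic mu and information content tables.
#
# mu(root) = 1; mu(z) = prod over parents x of mu(x)/C(x), with C(x) the
# number of children of x. The product tails off exponentially with depth,
# far past the double-precision underflow limit on realistic ontologies, so
# every mu is held as a normalised base-10 mantissa/exponent pair (alpha,
# beta): mu = alpha * 10^beta with 0.1 <= alpha < 1 (alpha = 1 only for
# mu = 1), beta <= 0 an exact integer. IC is then -ln(alpha) - beta*ln(10),
# never materialising mu as a dense float.

LN10 <- log(10)

new_topo_position <- function(alpha, beta, terms) {
  structure(list(alpha = stats::setNames(alpha, terms),
                 beta = stats::setNames(beta, terms)),
            class = "topo_position")
}

# renormalise a single (alpha, beta) so alpha is in [0.1, 1) (or exactly 1)
norm_ab <- function(a, b) {
  if (a == 1) return(c(a, b))
  while (a < 0.1) { a <- a * 10; b <- b - 1 }
  while (a >= 1) { a <- a / 10; b <- b + 1 }
  c(a, b)
}

#' Topological position characteristic of every term
#'
#' Evaluates the recursive reachability measure mu over the DAG in topological
#' order: mu(root) = 1 and mu(z) is the product over the distinct parents x of
#' z of mu(x) divided by the number of children of x. Each partial product is
#' immediately renormalised to mantissa/exponent form, so arbitrarily deep and
#' dense graphs evaluate without floating-point underflow.
#'
#' @param dag an `ontology_dag`.
#' @return a `topo_position` object holding named vectors `alpha` and `beta`
#'   with mu = alpha * 10^beta per term.
#' @examples
#' fx <- fixture_walkthrough()
#' mu <- compute_mu(fx$dag)
#' mu_value(mu)[c("1", "4", "5")]  # 1/2, 1/24, 1/6
#' @export
compute_mu <- function(dag) {
  n <- length(dag$terms)
  alpha <- numeric(n)
  beta <- numeric(n)
  nch <- lengths(dag$children)
  for (i in dag$order) {
    ps <- dag$parents[[i]]
    if (!length(ps)) {
      alpha[i] <- 1
      beta[i] <- 0
    } else {
      a <- 1
      b <- 0
      for (p in ps) {
        a <- a * alpha[p] / nch[p]
        b <- b + beta[p]
        ab <- norm_ab(a, b)
        a <- ab[1]
        b <- ab[2]
      }
      alpha[i] <- a
      beta[i] <- b
    }
  }
  new_topo_position(alpha, beta, dag$terms)
}

#' Dense numeric value of mu (underflows for deep terms)
#'
#' Convenience accessor for shallow graphs; returns 0 where the true value is
#' below the double-precision range.
#' @param mu a `topo_position`.
#' @return named numeric vector alpha * 10^beta.
#' @export
mu_value <- function(mu) mu$alpha * 10^mu$beta

# natural log of mu, exact in the mantissa/exponent representation
mu_log <- function(mu) log(mu$alpha) + mu$beta * LN10

#' Parse mantissa/exponent mu strings
#'
#' Accepts strings of the form `"0.1278292e-116"` meaning
#' mantissa * 10^exponent. Mantissas are kept exactly as printed (they are not
#' renormalised), so published tables round-trip.
#'
#' @param x character vector of mu strings, optionally named by term.
#' @param terms optional term names (overrides `names(x)`).
#' @return a `topo_position`.
#' @export
parse_mu <- function(x, terms = names(x)) {
  m <- regmatches(x, regexec("^\\s*([0-9.]+)e([+-]?[0-9]+)\\s*$", x))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) stop("unparseable mu string: ", x[bad][1])
  alpha <- vapply(m, function(g) as.numeric(g[2]), 0)
  beta <- vapply(m, function(g) as.numeric(g[3]), 0)
  new_topo_position(alpha, beta, terms)
}

#' Format mu as mantissa/exponent strings
#' @param mu a `topo_position`.
#' @param digits mantissa digits.
#' @return named character vector like `"0.1278292e-116"`.
#' @export
format_mu <- function(mu, digits = 7) {
  stats::setNames(sprintf("%.*fe%+d", digits, mu$alpha, as.integer(mu$beta)),
                  names(mu$alpha))
}

#' @export
print.topo_position <- function(x, ...) {
  cat("topo_position for", length(x$alpha), "terms\n")
  show <- utils::head(format_mu(x), 6)
  cat(paste0("  ", names(show), ": ", show, collapse = "\n"), "\n")
  invisible(x)
}

#' Construct an information-content table
#'
#' Container pairing per-term IC values (in nats) with the producing method
#' and any method-specific payload (the mu map for the universal method, the
#' D values for Zhang, S-value maps for Wang, propagated frequencies for the
#' annotation method).
#'
#' @param method one of `"universal"`, `"zhang"`, `"zhang_uniform"`,
#'   `"wang"`, `"annotation"`.
#' @param values named numeric vector, term -> IC in nats (all >= 0).
#' @param aux optional method-specific payload list.
#' @return an object of class `ic_table`.
#' @export
ic_table <- function(method, values, aux = list()) {
  method <- match.arg(method,
                      c("universal", "zhang", "zhang_uniform", "wang",
                        "annotation"))
  if (is.null(names(values))) stop("`values` must be named by term")
  if (any(values < -1e-9)) stop("negative IC value")
  structure(list(method = method, values = values, aux = aux),
            class = "ic_table")
}

#' @export
print.ic_table <- function(x, ...) {
  cat("ic_table (", x$method, "): ", length(x$values), " terms, IC range [",
      sprintf("%.4f", min(x$values)), ", ",
      sprintf("%.4f", max(x$values)), "] nats\n", sep = "")
  invisible(x)
}

#' Topological (GO-universal) information content
#'
#' IC(z) = -ln(mu(z)) computed as -ln(alpha) - beta*ln(10) directly from the
#' mantissa/exponent pair; the root has IC 0.
#'
#' @param mu a `topo_position` from [compute_mu()] or [parse_mu()].
#' @return an `ic_table` of method `"universal"` with the mu map in `aux$mu`.
#' @export
ic_universal <- function(mu) {
  ic <- -log(mu$alpha) - mu$beta * LN10 + 0   # + 0 clears negative zero
  ic[ic < 0 & ic > -1e-12] <- 0
  ic_table("universal", ic, aux = list(mu = mu))
}

#' Serialise an IC table to TSV with an (alpha, beta) sidecar
#'
#' Writes `term<TAB>ic<TAB>method`; for the universal method a sidecar file
#' `<path>.mu.tsv` holds the mantissa/exponent strings.
#'
#' @param ic an `ic_table`.
#' @param path output TSV path.
#' @export
write_ic_table <- function(ic, path) {
  utils::write.table(
    data.frame(term = names(ic$values), ic = sprintf("%.6f", ic$values),
               method = ic$method),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (ic$method == "universal" && !is.null(ic$aux$mu)) {
    utils::write.table(
      data.frame(term = names(ic$aux$mu$alpha), mu = format_mu(ic$aux$mu)),
      paste0(path, ".mu.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Zhang D values and information content
#'
#' Bottom-up path-count construction: every leaf has count 1 and a non-leaf's
#' count is the sum of its direct children's counts (the number of paths from
#' the term to leaves below it). Leaves take D = 1 / count(root of their
#' namespace); every other term's D is the sum of its children's D, so
#' D(root) = 1. IC_Z = -ln(D); the uniform variant divides by ln(N) with N
#' the number of terms in the namespace.
#'
#' @param dag an `ontology_dag`.
#' @return a list of two `ic_table`s, `zhang` (IC_Z) and `zhang_uniform`
#'   (IC_Zu); `aux` carries the D values, counts and N.
#' @export
zhang_ic <- function(dag) {
  n <- length(dag$terms)
  count <- numeric(n)
  rev_ord <- rev(dag$order)
  for (i in rev_ord) {
    ch <- dag$children[[i]]
    count[i] <- if (length(ch)) sum(count[ch]) else 1
  }
  # root (hence leaf baseline) is resolved per namespace
  root_of_ns <- stats::setNames(dag$roots, dag$namespace[dag$roots])
  d <- numeric(n)
  for (i in rev_ord) {
    ch <- dag$children[[i]]
    if (length(ch)) {
      d[i] <- sum(d[ch])
    } else {
      r <- root_of_ns[[dag$namespace[i]]]
      if (is.null(r)) stop("no root found for namespace ", dag$namespace[i])
      d[i] <- 1 / count[r]
    }
  }
  icz <- stats::setNames(-log(d), dag$terms)
  icz[icz < 0 & icz > -1e-12] <- 0
  nsize <- table(dag$namespace)
  iczu <- icz / log(as.numeric(nsize[dag$namespace]))
  iczu[!is.finite(iczu)] <- 0   # single-term namespace
  aux <- list(d = stats::setNames(d, dag$terms),
              count = stats::setNames(count, dag$terms),
              n_terms = as.list(nsize))
  list(zhang = ic_table("zhang", icz, aux = aux),
       zhang_uniform = ic_table("zhang_uniform", iczu, aux = aux))
}

#' Wang S-values and semantic value (IC_W)
#'
#' For each term z, the semantic contribution S_z(t) of each self-inclusive
#' ancestor t is 1 at z itself and otherwise the maximum over t's children
#' inside z's ancestor sub-DAG of the edge's semantic factor times the child's
#' S-value. IC_W(z) is the sum of S_z over that sub-DAG. Only the
#' ancestor-induced sub-DAG of z is materialised.
#'
#' @param dag an `ontology_dag`.
#' @param weights named numeric semantic contribution factors per relation.
#' @return an `ic_table` of method `"wang"`; `aux$svalues` holds each term's
#'   S-value map (named by ancestor term id).
#' @export
wang_ic <- function(dag, weights = c(is_a = 0.8, part_of = 0.6)) {
  anc <- all_ancestor_sets(dag)
  pos <- integer(length(dag$terms))
  pos[dag$order] <- seq_along(dag$order)   # topological rank
  svalues <- vector("list", length(dag$terms))
  names(svalues) <- dag$terms
  ic <- numeric(length(dag$terms))
  for (z in seq_along(dag$terms)) {
    sub <- anc[[z]]
    sub <- sub[order(pos[sub], decreasing = TRUE)]  # children before parents
    s <- stats::setNames(numeric(length(sub)), sub)
    s[as.character(z)] <- 1
    in_sub <- stats::setNames(rep(TRUE, length(sub)), sub)
    for (t in sub) {
      if (t == z) next
      best <- 0
      ch <- dag$children[[t]]
      for (c0 in ch) {
        if (!length(sub) || is.na(in_sub[as.character(c0)])) next
        k <- match(t, dag$parents[[c0]])
        w <- weights[[dag$parent_rel[[c0]][k]]]
        if (is.null(w)) w <- 0
        cand <- w * s[as.character(c0)]
        if (cand > best) best <- cand
      }
      s[as.character(t)] <- best
    }
    names(s) <- dag$terms[as.integer(names(s))]
    svalues[[z]] <- s
    ic[z] <- sum(s)
  }
  ic_table("wang", stats::setNames(ic, dag$terms),
           aux = list(svalues = svalues, weights = weights))
}

#' Annotation-frequency information content
#'
#' Maximum-likelihood corpus estimator with true-path propagation: a protein
#' annotated to a term counts for every ancestor of that term, frequencies are
#' distinct-protein counts, and IC(t) = -ln(freq(t) / freq(root of t's
#' namespace)). Terms with zero propagated frequency are absent from the
#' table.
#'
#' @param dag an `ontology_dag`.
#' @param annotations an `annotation_set` bound to `dag`.
#' @return an `ic_table` of method `"annotation"`; `aux$freq` holds the
#'   propagated distinct-protein counts.
#' @export
annotation_ic <- function(dag, annotations) {
  df <- annotations$entries
  if (nrow(df) == 0L) stop("empty annotation corpus")
  anc <- all_ancestor_sets(dag)
  ti <- term_index(dag, df$term)
  prop <- unique(do.call(rbind, lapply(seq_len(nrow(df)), function(r)
    cbind(protein = df$protein[r], term = anc[[ti[r]]]))))
  freq <- table(factor(as.integer(prop[, "term"]),
                       levels = seq_along(dag$terms)))
  freq <- as.numeric(freq)
  root_of_ns <- stats::setNames(dag$roots, dag$namespace[dag$roots])
  present <- which(freq > 0)
  ic <- vapply(present, function(i) {
    r <- root_of_ns[[dag$namespace[i]]]
    -log(freq[i] / freq[r])
  }, 0)
  ic[ic < 0 & ic > -1e-12] <- 0
  ic_table("annotation", stats::setNames(ic, dag$terms[present]),
           aux = list(freq = stats::setNames(freq[present],
                                             dag$terms[present])))
}

#' Synonym (topologically identical) classes
#'
#' Two terms are synonyms when their mu values are exactly equal (identical
#' mantissa/exponent pairs) and one is reachable from the other by a directed
#' path. Since mu never increases along an edge, equality along a path forces
#' equality at every intermediate step, so the classes are the transitive
#' closure of synonym edges. Synonym terms carry identical IC and similarity 1.
#'
#' @param dag an `ontology_dag`.
#' @param mu a `topo_position` for `dag`.
#' @return named integer vector of class ids (same id = same class), with the
#'   list of non-trivial classes in attribute `"classes"`.
#' @export
synonym_classes <- function(dag, mu) {
  n <- length(dag$terms)
  parent_id <- seq_len(n)
  find <- function(i) {
    while (parent_id[i] != i) {
      parent_id[i] <<- parent_id[parent_id[i]]
      i <- parent_id[i]
    }
    i
  }
  a <- mu$alpha[dag$terms]
  b <- mu$beta[dag$terms]
  for (i in seq_len(n)) {
    for (p in dag$parents[[i]]) {
      if (a[i] == a[p] && b[i] == b[p]) {
        ri <- find(i)
        rp <- find(p)
        if (ri != rp) parent_id[ri] <- rp
      }
    }
  }
  cls <- vapply(seq_len(n), find, 0L)
  ids <- match(cls, unique(cls))
  out <- stats::setNames(ids, dag$terms)
  groups <- split(dag$terms, ids)
  attr(out, "classes") <- unname(groups[lengths(groups) > 1])
  out
}
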