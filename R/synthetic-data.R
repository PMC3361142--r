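# Worked-example fixtures, seeded random generators and the exact oracle.
#
# The twelve-node illustration DAG pins down the recursive
# mu walkthrough; only its textually forced core is encoded (root 0 with
# children 1 and 2; 1 -> {3, 4}; 2 -> {4, 5} plus one dummy child standing in
# for the unprinted third child of 2, which fixes C(2) = 3). The GO BP
# subgraph fixture ships as TSV files: its 14 parent-child edges plus the
# published per-term mu strings and IC columns, with the expected pairwise
# similarity scores. Absolute mu values of that subgraph cannot be recomputed
# because the upstream ontology context is not part of the fixture, so mu is
# injected and only the similarity layer is exercised on it.

#' Worked-example DAG for the recursive mu walkthrough
#'
#' A single-root DAG (root `"0"`) in which node 4 has two parents (one with
#' two children, one with three), giving mu(1) = mu(2) = 1/2, mu(3) = 1/4,
#' mu(4) = 1/24 and mu(5) = 1/6.
#'
#' @return a list of class `fixture_bundle` with elements `dag` and
#'   `expected` (columns `term`, `mu_num`, `mu_den`, `ic`).
#' @export
fixture_walkthrough <- function() {
  edges <- data.frame(
    parent = c("0", "0", "1", "1", "2", "2", "2"),
    child  = c("1", "2", "3", "4", "4", "5", "d6"),
    relation = "is_a")
  expected <- data.frame(
    term = c("0", "1", "2", "3", "4", "5"),
    mu_num = 1,
    mu_den = c(1, 2, 2, 4, 24, 6))
  expected$ic <- -log(expected$mu_num / expected$mu_den)
  structure(list(dag = build_dag(edges), injected_mu = NULL,
                 expected = expected),
            class = "fixture_bundle")
}

#' GO BP subgraph fixture with published topological positions
#'
#' Builds the DNA-damage-response subgraph of the biological-process ontology
#' from its 14 parent-child edges and injects the published mantissa/exponent
#' mu value and Zhang IC of each of the 12 terms, together with the expected
#' per-pair similarity scores. GO:0042770 is the subgraph's sole root (it has
#' 4 children here); its true ancestors are outside the fixture, which is why
#' mu is injected rather than recomputed.
#'
#' @return a list of class `fixture_bundle` with elements `dag`,
#'   `injected_mu` (a `topo_position`), `terms` (per-term expected values:
#'   level, mu string, IC_T, IC_Z, IC_Zu) and `pairs` (per-pair expected
#'   scores: s_go, s_w, s_zur, s_zl).
#' @export
fixture_subgraph <- function() {
  ext <- function(f) {
    p <- system.file("extdata", f, package = "GOuniversal")
    if (!nzchar(p)) p <- file.path("inst", "extdata", f)
    p
  }
  terms <- utils::read.delim(ext("subgraph_terms.tsv"), comment.char = "#",
                             colClasses = c(mu = "character"))
  pairs <- utils::read.delim(ext("subgraph_pairs.tsv"), comment.char = "#")
  edges <- data.frame(parent = pairs$parent, child = pairs$child,
                      relation = "is_a")
  ns <- stats::setNames(rep("BP", nrow(terms)), terms$go_id)
  dag <- build_dag(edges, namespaces = ns)
  mu <- parse_mu(stats::setNames(terms$mu, terms$go_id))
  structure(list(dag = dag, injected_mu = mu, terms = terms, pairs = pairs),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat("fixture_bundle:", length(x$dag$terms), "terms;",
      if (is.null(x$injected_mu)) "computed mu" else "injected mu", "\n")
  invisible(x)
}

#' Seeded random rooted DAG generator
#'
#' Grows a single-root DAG term by term: each new term picks 1 to
#' `max_parents` parents among existing terms, the first with probability
#' weight (1 + level)^2 so that the graph develops depth, extras uniformly.
#' A short root chain guarantees a level spread of at least 3 once
#' `n_terms >= 5`. Edges are `is_a` with probability `p_is_a`, else
#' `part_of`. Identical seeds give identical graphs.
#'
#' @param n_terms number of terms (>= 1).
#' @param max_parents maximum parents per term.
#' @param p_extra_parent probability of each additional parent beyond the
#'   first.
#' @param p_is_a probability that an edge is `is_a`.
#' @param seed integer seed.
#' @return an `ontology_dag` with terms `"t001"`, `"t002"`, ...
#' @export
generate_random_dag <- function(n_terms, max_parents = 3,
                                p_extra_parent = 0.3, p_is_a = 0.85,
                                seed = 1) {
  stopifnot(n_terms >= 1, max_parents >= 1)
  ids <- sprintf("t%03d", seq_len(n_terms))
  if (n_terms == 1) return(build_dag(NULL, terms = ids))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  level <- c(0L, rep(NA_integer_, n_terms - 1))
  parent <- character()
  child <- character()
  for (i in 2:n_terms) {
    if (i <= min(4, n_terms)) {
      ps <- i - 1L                          # backbone chain -> level spread
    } else {
      extra <- stats::rbinom(1, max_parents - 1, p_extra_parent)
      k <- min(1L + extra, i - 1L)
      w <- (1 + level[seq_len(i - 1)])^2
      first <- sample.int(i - 1L, 1, prob = w)
      rest <- if (k > 1) sample(setdiff(seq_len(i - 1L), first),
                                k - 1L) else integer()
      ps <- c(first, rest)
    }
    level[i] <- max(level[ps]) + 1L
    parent <- c(parent, ids[ps])
    child <- c(child, rep(ids[i], length(ps)))
  }
  rel <- ifelse(stats::runif(length(parent)) < p_is_a, "is_a", "part_of")
  build_dag(data.frame(parent = parent, child = child, relation = rel),
            terms = ids)
}

#' Seeded random annotation-corpus generator
#'
#' Emulates GOA-style direct annotations: each protein receives
#' 1 + Poisson(`mean_terms` - 1) direct terms drawn with depth-biased
#' probability (weight 1 + level, so deeper, more specific terms are
#' preferred), with evidence codes sampled from `evidence_weights`.
#'
#' @param dag an `ontology_dag`.
#' @param n_proteins number of proteins (0 gives an empty set).
#' @param mean_terms mean direct annotations per protein (>= 1).
#' @param evidence_weights named sampling weights over evidence codes.
#' @param seed integer seed.
#' @return an `annotation_set` with proteins `"P001"`, `"P002"`, ...
#' @export
generate_annotations <- function(dag, n_proteins, mean_terms = 3,
                                 evidence_weights = c(EXP = 0.2, IDA = 0.3,
                                                      IEA = 0.4, ISS = 0.1),
                                 seed = 1) {
  if (n_proteins == 0) {
    return(annotation_set(data.frame(protein = character(),
                                     term = character()), dag))
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  w <- 1 + dag$level
  rows <- do.call(rbind, lapply(seq_len(n_proteins), function(p) {
    k <- min(1 + stats::rpois(1, max(0, mean_terms - 1)), length(dag$terms))
    terms <- dag$terms[sample.int(length(dag$terms), k, prob = w)]
    data.frame(protein = sprintf("P%03d", p), term = terms,
               evidence = sample(names(evidence_weights), k, replace = TRUE,
                                 prob = evidence_weights),
               source = "synthetic")
  }))
  annotation_set(rows, dag)
}

local_seed <- function(seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed",
                                               envir = .GlobalEnv)
  } else assign(".Random.seed", old, envir = .GlobalEnv)
  invisible()
}

# ---------------------------------------------------------------------------
# Exact big-integer oracle for mu.
#
# Because mu(root) = 1 and every recursion step multiplies unit fractions,
# every mu is exactly 1/D with D a positive integer:
# D(z) = prod over parents x of D(x) * C(x). D is carried as an exact
# big integer (little-endian base-1e4 limbs, plain R numerics), so the oracle
# is independent of the mantissa/exponent engine it checks.

big_from_int <- function(n) {
  stopifnot(n >= 1, n == floor(n))
  out <- numeric(0)
  while (n > 0) {
    out <- c(out, n %% 1e4)
    n <- n %/% 1e4
  }
  out
}

big_carry <- function(x) {
  repeat {
    q <- x %/% 1e4
    if (!any(q > 0)) break
    x <- c(x - q * 1e4, 0)
    x[-1] <- x[-1] + q
  }
  while (length(x) > 1 && x[length(x)] == 0) x <- x[-length(x)]
  x
}

big_mul <- function(a, b) {
  res <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    idx <- i:(i + length(b) - 1)
    res[idx] <- res[idx] + a[i] * b
  }
  big_carry(res)
}

# natural log of a big integer: top limbs give ~13 significant digits
big_log <- function(x) {
  k <- length(x)
  top <- x[max(1, k - 3):k]
  mant <- sum(top * 1e4^(seq_along(top) - 1))
  log(mant) + (max(1, k - 3) - 1) * log(1e4)
}

big_to_string <- function(x) {
  k <- length(x)
  paste0(x[k], paste(sprintf("%04d", rev(x[-k])), collapse = ""))
}

#' Exact rational oracle for the topological position
#'
#' Recomputes every mu by exact big-integer arithmetic: mu(z) = 1/D(z) with
#' D(z) the product over parents x of D(x) times the child count of x. Meant
#' as an independent check of the mantissa/exponent engine on small graphs.
#'
#' @param dag an `ontology_dag` (intended for up to ~1000 terms).
#' @return a list with `log_mu` (named numeric, exact natural log of mu) and
#'   `denominator` (named character, the exact integer D as a decimal
#'   string).
#' @export
oracle_mu_exact <- function(dag) {
  n <- length(dag$terms)
  nch <- lengths(dag$children)
  dens <- vector("list", n)
  for (i in dag$order) {
    ps <- dag$parents[[i]]
    if (!length(ps)) {
      dens[[i]] <- big_from_int(1)
    } else {
      acc <- big_from_int(1)
      for (p in ps) {
        acc <- big_mul(acc, dens[[p]])
        acc <- big_mul(acc, big_from_int(nch[p]))
      }
      dens[[i]] <- acc
    }
  }
  list(log_mu = stats::setNames(-vapply(dens, big_log, 0), dag$terms),
       denominator = stats::setNames(vapply(dens, big_to_string, ""),
                                     dag$terms))
}

#' Maximum log-space discrepancy between engine and oracle
#'
#' Compares ln(mu) from the mantissa/exponent engine against the exact
#' big-integer oracle and returns the maximum relative discrepancy
#' (absolute where the exact log is near zero).
#'
#' @param mu a `topo_position` from [compute_mu()].
#' @param oracle result of [oracle_mu_exact()] on the same DAG.
#' @return the maximum discrepancy over all terms.
#' @export
mu_oracle_gap <- function(mu, oracle) {
  lf <- mu_log(mu)[names(oracle$log_mu)]
  le <- oracle$log_mu
  max(abs(lf - le) / pmax(1, abs(le)))
}
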