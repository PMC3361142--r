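# Protein functional similarity from GO annotations.
#
# Pairwise combinations (BMA / Avg / Max) operate on DIRECT annotation sets;
# the set-wise Jaccard family (SimGIC / SimUIC / SimUI / SimDIC / SimUIX)
# operates on ancestor-closed sets (true-path rule), where root terms carry
# IC 0 and so only affect the unweighted SimUI. Empty annotation sets yield
# an NA sentinel that downstream statistics exclude rather than treat as 0.

GO_EVIDENCE_CODES <- c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "HTP",
                       "HDA", "HMP", "HGI", "HEP", "IBA", "IBD", "IKR",
                       "IRD", "ISS", "ISO", "ISA", "ISM", "IGC", "RCA",
                       "TAS", "NAS", "IC", "ND", "IEA")

#' Evidence-code filter
#'
#' Either excludes the listed codes (e.g. `exclude = "IEA"` or
#' `c("IEA", "ISS")`) or retains only the listed codes.
#'
#' @param exclude evidence codes to drop (mode `"exclude"`).
#' @param include_only evidence codes to keep (mode `"include-only"`);
#'   mutually exclusive with `exclude`.
#' @return an object of class `evidence_filter`.
#' @export
evidence_filter <- function(exclude = NULL, include_only = NULL) {
  if (!is.null(exclude) && !is.null(include_only))
    stop("give either `exclude` or `include_only`, not both")
  mode <- if (is.null(include_only)) "exclude" else "include-only"
  codes <- if (mode == "exclude") exclude else include_only
  structure(list(mode = mode, codes = as.character(codes)),
            class = "evidence_filter")
}

apply_evidence_filter <- function(df, filter) {
  if (is.null(filter)) return(df)
  stopifnot(inherits(filter, "evidence_filter"))
  keep <- if (filter$mode == "exclude") !(df$evidence %in% filter$codes)
          else df$evidence %in% filter$codes
  df[keep, , drop = FALSE]
}

#' Construct an annotation set
#'
#' Binds a protein -> term annotation table to an ontology; every term must
#' exist in the DAG and the namespace column is filled from the DAG when
#' omitted.
#'
#' @param df data.frame with columns `protein`, `term` and optionally
#'   `evidence`, `source`, `namespace`.
#' @param dag the `ontology_dag` the terms live in.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(df, dag) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(c("protein", "term") %in% names(df)))
  i <- term_index(dag, df$term)    # errors on unknown terms
  if (is.null(df$evidence)) df$evidence <- rep("EXP", nrow(df))
  if (is.null(df$source)) df$source <- rep("unknown", nrow(df))
  df$namespace <- dag$namespace[i]
  df <- df[!duplicated(df[c("protein", "term")]), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(entries = df[c("protein", "term", "namespace", "evidence",
                                "source")],
                 dag = dag),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(unique(x$entries$protein)), "proteins,",
      nrow(x$entries), "annotations\n")
  print(table(x$entries$namespace))
  invisible(x)
}

#' Direct annotation terms of a protein
#' @param annotations an `annotation_set`.
#' @param protein protein identifier.
#' @param namespace `"BP"`, `"MF"`, `"CC"` or `"other"`.
#' @return character vector of directly annotated terms (possibly empty).
#' @export
annotation_terms <- function(annotations, protein, namespace) {
  df <- annotations$entries
  unique(df$term[df$protein == protein & df$namespace == namespace])
}

#' Parse a GAF 2.x annotation file
#'
#' Reads tab-separated GAF rows (comment lines start with `!`), dropping
#' NOT-qualified rows, rows whose term is absent from the DAG (counted in a
#' warning) and rows removed by the evidence filter. Malformed rows are
#' skipped with a warning count.
#'
#' @param path GAF file path, or lines via `text`.
#' @param dag the `ontology_dag` annotations refer to.
#' @param filter optional [evidence_filter()].
#' @param text optional character vector of GAF lines.
#' @return an `annotation_set`.
#' @export
parse_gaf <- function(path = NULL, dag, filter = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(parts, length, 0L) >= 15L
  if (any(!ok))
    warning(sum(!ok), " malformed GAF row(s) skipped")
  parts <- parts[ok]
  if (!length(parts)) {
    return(annotation_set(data.frame(protein = character(),
                                     term = character()), dag))
  }
  df <- data.frame(
    protein = vapply(parts, `[`, "", 2),
    qualifier = vapply(parts, `[`, "", 4),
    term = vapply(parts, `[`, "", 5),
    evidence = vapply(parts, `[`, "", 7),
    source = vapply(parts, `[`, "", 15),
    stringsAsFactors = FALSE)
  notq <- grepl("(^|\\|)NOT($|\\|)", df$qualifier)
  df <- df[!notq, , drop = FALSE]
  known <- df$term %in% dag$terms
  if (any(!known))
    warning(sum(!known), " annotation(s) to unknown/obsolete terms dropped")
  df <- df[known, , drop = FALSE]
  df <- apply_evidence_filter(df, filter)
  annotation_set(df[c("protein", "term", "evidence", "source")], dag)
}

#' Serialise an annotation set as GAF 2.2
#' @param annotations an `annotation_set`.
#' @param path output path; if `NULL`, lines are returned invisibly.
#' @return invisibly, the GAF lines.
#' @export
write_gaf <- function(annotations, path = NULL) {
  df <- annotations$entries
  aspect <- c(BP = "P", MF = "F", CC = "C", other = "P")[df$namespace]
  rows <- paste("DB", df$protein, df$protein, "", df$term, "REF:0000001",
                df$evidence, "", aspect, "", "", "protein", "taxon:0000",
                "20120101", df$source, "", "", sep = "\t")
  out <- c("!gaf-version: 2.2", rows)
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}

#' Czekanowski-Dice annotation overlap
#'
#' 2|A n B| / (|A u B| + |A n B|) on the DIRECT term sets of the two proteins
#' (no true-path propagation): the set-matching baseline that credits only
#' exactly shared terms.
#'
#' @param annotations an `annotation_set`.
#' @param p1,p2 protein identifiers.
#' @param namespace ontology namespace.
#' @return score in \[0, 1\], or `NA` if either protein has no annotations in
#'   the namespace.
#' @export
czekanowski_dice <- function(annotations, p1, p2, namespace) {
  t1 <- annotation_terms(annotations, p1, namespace)
  t2 <- annotation_terms(annotations, p2, namespace)
  if (!length(t1) || !length(t2)) return(NA_real_)
  ni <- length(intersect(t1, t2))
  nu <- length(union(t1, t2))
  2 * ni / (nu + ni)
}

#' Pairwise protein functional similarity (BMA / Avg / Max)
#'
#' Scores all cross pairs between the two proteins' direct term sets with the
#' chosen term measure and combines them: `bma` averages each protein's
#' best-match scores and then averages the two directions; `avg` is the mean
#' over all cross pairs; `max` the maximum cross pair.
#'
#' @param dag an `ontology_dag`.
#' @param ic an `ic_table` matching `measure`.
#' @param annotations an `annotation_set`.
#' @param p1,p2 protein identifiers.
#' @param namespace ontology namespace.
#' @param measure term measure as in [sim_term_to_set()].
#' @param combine `"bma"`, `"avg"` or `"max"`.
#' @return score in \[0, 1\], or `NA` if either direct set is empty.
#' @export
funsim_pairwise <- function(dag, ic, annotations, p1, p2, namespace,
                            measure = "universal",
                            combine = c("bma", "avg", "max")) {
  combine <- match.arg(combine)
  t1 <- annotation_terms(annotations, p1, namespace)
  t2 <- annotation_terms(annotations, p2, namespace)
  if (!length(t1) || !length(t2)) return(NA_real_)
  m <- matrix(0, length(t1), length(t2))
  for (i in seq_along(t1))
    for (j in seq_along(t2))
      m[i, j] <- pair_sim(dag, ic, t1[i], t2[j], measure)
  switch(combine,
         bma = (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2,
         avg = mean(m),
         max = max(m))
}

# ancestor-closed term set of a protein (self-inclusive closure of the
# direct annotations)
closure_terms <- function(dag, annotations, protein, namespace) {
  direct <- annotation_terms(annotations, protein, namespace)
  if (!length(direct)) return(character())
  unique(unlist(lapply(direct, function(t) ancestors_self_inclusive(dag, t))))
}

#' Set-wise protein functional similarity (SimGIC family)
#'
#' Both proteins' direct term sets are first closed under the true-path rule
#' (self-inclusive ancestors). With W(S) the summed IC of a set:
#' `simgic`/`simuic` = W(inter) / W(union) (Jaccard index weighted by IC —
#' SimUIC is this form driven by topological rather than annotation IC),
#' `simdic` = 2 W(inter) / (W(A) + W(B)) (Dice), `simuix` = W(inter) /
#' max(W(A), W(B)) (universal index), and `simui` = |inter| / |union|
#' (unweighted). Terms missing from the IC table (and roots, with IC 0)
#' contribute no weight.
#'
#' @inheritParams funsim_pairwise
#' @param variant one of `"simgic"`, `"simuic"`, `"simui"`, `"simdic"`,
#'   `"simuix"`.
#' @return score in \[0, 1\], or `NA` if either closure is empty.
#' @export
funsim_setwise <- function(dag, ic, annotations, p1, p2, namespace,
                           variant = c("simgic", "simuic", "simui",
                                       "simdic", "simuix")) {
  variant <- match.arg(variant)
  c1 <- closure_terms(dag, annotations, p1, namespace)
  c2 <- closure_terms(dag, annotations, p2, namespace)
  if (!length(c1) || !length(c2)) return(NA_real_)
  inter <- intersect(c1, c2)
  uni <- union(c1, c2)
  if (variant == "simui") return(length(inter) / length(uni))
  w <- function(s) {
    v <- ic$values[s]
    sum(v[!is.na(v)])
  }
  wi <- w(inter)
  w1 <- w(c1)
  w2 <- w(c2)
  if (w1 + w2 == 0) return(if (setequal(c1, c2)) 1 else 0)
  switch(variant,
         simgic = ,
         simuic = wi / w(uni),
         simdic = 2 * wi / (w1 + w2),
         simuix = wi / max(w1, w2))
}

#' Batch protein functional similarity
#'
#' Scores a list of protein pairs under one configuration, one row per pair.
#' Unknown proteins or empty annotation sets produce `NA` sentinel rows and
#' the run continues.
#'
#' @param dag an `ontology_dag`.
#' @param ic an `ic_table`.
#' @param annotations an `annotation_set`.
#' @param pairs data.frame with columns `protein_a`, `protein_b` (or first
#'   two columns positionally).
#' @param namespace ontology namespace.
#' @param method `"pairwise"` (uses `measure` + `combine`), `"setwise"` (uses
#'   `variant`) or `"czekanowski_dice"`.
#' @param measure,combine,variant passed to [funsim_pairwise()] /
#'   [funsim_setwise()].
#' @return data.frame `protein_a`, `protein_b`, `measure`, `ontology`,
#'   `score`, in input order.
#' @export
funsim_matrix <- function(dag, ic, annotations, pairs, namespace,
                          method = c("pairwise", "setwise",
                                     "czekanowski_dice"),
                          measure = "universal", combine = "bma",
                          variant = "simgic") {
  method <- match.arg(method)
  pairs <- as.data.frame(pairs)
  if (!all(c("protein_a", "protein_b") %in% names(pairs)))
    names(pairs)[1:2] <- c("protein_a", "protein_b")
  label <- switch(method,
                  pairwise = paste(measure, combine, sep = "_"),
                  setwise = variant,
                  czekanowski_dice = "czekanowski_dice")
  score <- vapply(seq_len(nrow(pairs)), function(k) {
    tryCatch(
      switch(method,
             pairwise = funsim_pairwise(dag, ic, annotations,
                                        pairs$protein_a[k], pairs$protein_b[k],
                                        namespace, measure, combine),
             setwise = funsim_setwise(dag, ic, annotations,
                                      pairs$protein_a[k], pairs$protein_b[k],
                                      namespace, variant),
             czekanowski_dice = czekanowski_dice(annotations,
                                                 pairs$protein_a[k],
                                                 pairs$protein_b[k],
                                                 namespace)),
      error = function(e) NA_real_)
  }, 0)
  data.frame(protein_a = pairs$protein_a, protein_b = pairs$protein_b,
             measure = label, ontology = namespace, score = score)
}
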