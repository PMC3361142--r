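# Shared fixture: a two-branch DAG under one root plus a detached second
# root, with four proteins covering identical, overlapping, unrelated and
# cross-root annotation patterns.
psim_dag <- build_dag(data.frame(
  parent = c("r", "r", "a1", "a1", "b1", "r2"),
  child  = c("a1", "b1", "a2", "a3", "b2", "q1")),
  namespaces = c(r = "BP", r2 = "BP"))
psim_ic <- ic_universal(compute_mu(psim_dag))
psim_ann <- annotation_set(data.frame(
  protein = c("p1", "p1", "p2", "p2", "p3", "p4"),
  term    = c("a2", "a3", "a2", "a3", "b2", "q1")), psim_dag)

test_that("GAF parsing honours qualifiers, evidence filters and round-trips", {
  gaf <- c("!gaf-version: 2.2",
           paste("DB", "p1", "p1", "", "a2", "REF:1", "IDA", "", "P", "", "",
                 "protein", "taxon:1", "20120101", "SRC", "", "", sep = "\t"),
           paste("DB", "p1", "p1", "", "a3", "REF:1", "IEA", "", "P", "", "",
                 "protein", "taxon:1", "20120101", "SRC", "", "", sep = "\t"),
           paste("DB", "p2", "p2", "NOT", "a2", "REF:1", "IDA", "", "P", "",
                 "", "protein", "taxon:1", "20120101", "SRC", "", "",
                 sep = "\t"))
  ann <- parse_gaf(text = gaf, dag = psim_dag,
                   filter = evidence_filter(exclude = "IEA"))
  expect_equal(nrow(ann$entries), 1L)
  expect_equal(ann$entries$term, "a2")

  # NOT row dropped even without a filter; unknown terms counted
  ann2 <- parse_gaf(text = gaf, dag = psim_dag)
  expect_false("p2" %in% ann2$entries$protein)
  expect_warning(parse_gaf(text = c(gaf, sub("a2", "NOPE", gaf[2])),
                           dag = psim_dag), "unknown")

  # serialize/parse identity on a generated corpus
  dag <- generate_random_dag(20, seed = 11)
  ann3 <- generate_annotations(dag, 8, seed = 12)
  back <- parse_gaf(text = write_gaf(ann3), dag = dag)
  a <- ann3$entries[order(ann3$entries$protein, ann3$entries$term), ]
  b <- back$entries[order(back$entries$protein, back$entries$term), ]
  expect_equal(a$term, b$term)
  expect_equal(a$evidence, b$evidence)
})

test_that("evidence filter modes are exclusive and typed", {
  expect_error(evidence_filter(exclude = "IEA", include_only = "EXP"),
               "not both")
  f <- evidence_filter(include_only = c("EXP", "IDA"))
  expect_equal(f$mode, "include-only")
})

test_that("Czekanowski-Dice works on direct sets with sentinels", {
  expect_equal(czekanowski_dice(psim_ann, "p1", "p2", "BP"), 1)
  expect_equal(czekanowski_dice(psim_ann, "p1", "p3", "BP"), 0)
  expect_true(is.na(czekanowski_dice(psim_ann, "p1", "nobody", "BP")))
  # {a,b} vs {b,c} -> 2*1/(3+1)
  ann <- annotation_set(data.frame(protein = c("x", "x", "y", "y"),
                                   term = c("a2", "a3", "a3", "b2")),
                        psim_dag)
  expect_equal(czekanowski_dice(ann, "x", "y", "BP"), 0.5)
})

test_that("pairwise combinations match a brute-force double loop", {
  t1 <- annotation_terms(psim_ann, "p1", "BP")
  t3 <- c("a2", "b2")
  ann <- annotation_set(data.frame(protein = c("p1", "p1", "px", "px"),
                                   term = c(t1, t3)), psim_dag)
  m <- outer(t1, t3, Vectorize(function(x, y)
    sim_universal(psim_dag, psim_ic, x, y)))
  bma <- (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
  expect_equal(funsim_pairwise(psim_dag, psim_ic, ann, "p1", "px", "BP"),
               bma)
  expect_equal(funsim_pairwise(psim_dag, psim_ic, ann, "p1", "px", "BP",
                               combine = "avg"), mean(m))
  expect_equal(funsim_pairwise(psim_dag, psim_ic, ann, "p1", "px", "BP",
                               combine = "max"), max(m))
})

test_that("identical sets score 1 and unrelated sets score 0 everywhere", {
  expect_equal(funsim_pairwise(psim_dag, psim_ic, psim_ann, "p1", "p2", "BP"),
               1)
  for (v in c("simgic", "simuic", "simui", "simdic", "simuix"))
    expect_equal(funsim_setwise(psim_dag, psim_ic, psim_ann, "p1", "p2",
                                "BP", v), 1, info = v)
  # p4 lives under a detached root: no shared ancestor at all
  expect_equal(funsim_pairwise(psim_dag, psim_ic, psim_ann, "p1", "p4", "BP"),
               0)
  for (v in c("simgic", "simuic", "simui", "simdic", "simuix"))
    expect_equal(funsim_setwise(psim_dag, psim_ic, psim_ann, "p1", "p4",
                                "BP", v), 0, info = v)
  # same root, different branches: weighted variants 0 (root carries IC 0)
  expect_equal(funsim_pairwise(psim_dag, psim_ic, psim_ann, "p1", "p3", "BP"),
               0)
  for (v in c("simgic", "simuic", "simdic", "simuix"))
    expect_equal(funsim_setwise(psim_dag, psim_ic, psim_ann, "p1", "p3",
                                "BP", v), 0, info = v)
  # the unweighted variant still sees the shared root
  expect_gt(funsim_setwise(psim_dag, psim_ic, psim_ann, "p1", "p3", "BP",
                           "simui"), 0)
})

test_that("set-wise variants respect nesting and denominator ordering", {
  # nested closures: p_sub's closure is a subset of p_all's
  ann <- annotation_set(data.frame(protein = c("ps", "pa", "pa"),
                                   term = c("a1", "a2", "a3")), psim_dag)
  w <- function(s) sum(psim_ic$values[s])
  cs <- closure <- c("r", "a1")
  ca <- c("r", "a1", "a2", "a3")
  expect_equal(funsim_setwise(psim_dag, psim_ic, ann, "ps", "pa", "BP",
                              "simuic"), w(cs) / w(ca))
  # union >= max >= mean denominators => simgic <= simuix <= simdic
  for (s in 1:5) {
    dag <- generate_random_dag(25, seed = s + 700)
    ic <- ic_universal(compute_mu(dag))
    ann2 <- generate_annotations(dag, 6, seed = s + 701)
    prots <- unique(ann2$entries$protein)
    for (k in 1:5) {
      pq <- sample(prots, 2)
      g <- funsim_setwise(dag, ic, ann2, pq[1], pq[2], "other", "simgic")
      xx <- funsim_setwise(dag, ic, ann2, pq[1], pq[2], "other", "simuix")
      d <- funsim_setwise(dag, ic, ann2, pq[1], pq[2], "other", "simdic")
      if (!is.na(g)) {
        expect_lte(g, xx + 1e-12)
        expect_lte(xx, d + 1e-12)
      }
    }
  }
})

test_that("true-path-closed set matching is blind to term content while the
           similarity-based score is not", {
  # two structurally identical annotation patterns (p2 = p1 plus one child
  # of the deepest shared term): a "wide" DAG where the extra child is one
  # of 100 siblings, and a "narrow" one where it is one of 2
  closed_cd <- function(dag, ann) {
    cl <- function(p) unique(unlist(lapply(
      annotation_terms(ann, p, "other"), function(t)
        ancestors_self_inclusive(dag, t))))
    ni <- length(intersect(cl("p1"), cl("p2")))
    2 * ni / (length(union(cl("p1"), cl("p2"))) + ni)
  }
  make <- function(n_children) {
    dag <- build_dag(data.frame(
      parent = c("r", "r", rep("c1", n_children)),
      child = c("c1", "s", "c2", sprintf("x%02d", seq_len(n_children - 1)))))
    ann <- annotation_set(data.frame(protein = c("p1", "p2", "p2"),
                                     term = c("c1", "c1", "c2")), dag)
    list(dag = dag, ann = ann, ic = ic_universal(compute_mu(dag)))
  }
  wide <- make(100)
  narrow <- make(2)
  # closure forces |union| = |intersection| + 1 in both cases: same score,
  # independent of how informative the differing term is
  expect_equal(closed_cd(wide$dag, wide$ann), 0.8)
  expect_equal(closed_cd(narrow$dag, narrow$ann), 0.8)
  # the similarity-based score distinguishes them and sits below the
  # content-blind set score in the wide case
  bma_wide <- funsim_pairwise(wide$dag, wide$ic, wide$ann, "p1", "p2",
                              "other")
  bma_narrow <- funsim_pairwise(narrow$dag, narrow$ic, narrow$ann, "p1",
                                "p2", "other")
  expect_lt(bma_wide, 0.8)
  expect_gt(bma_narrow, bma_wide + 0.05)
  # direct-set Czekanowski-Dice does not inflate: 2*1/(2+1)
  expect_equal(czekanowski_dice(wide$ann, "p1", "p2", "other"), 2 / 3)
})

test_that("pairwise scores are symmetric, bounded, BMA <= Max, self = 1", {
  dag <- generate_random_dag(30, seed = 900)
  ic <- ic_universal(compute_mu(dag))
  ann <- generate_annotations(dag, 10, seed = 901)
  prots <- unique(ann$entries$protein)
  for (k in 1:15) {
    pq <- sample(prots, 2)
    b <- funsim_pairwise(dag, ic, ann, pq[1], pq[2], "other")
    b2 <- funsim_pairwise(dag, ic, ann, pq[2], pq[1], "other")
    mx <- funsim_pairwise(dag, ic, ann, pq[1], pq[2], "other",
                          combine = "max")
    expect_equal(b, b2)
    expect_lte(b, mx + 1e-12)
    expect_true(b >= 0 && b <= 1)
  }
  p <- prots[1]
  expect_equal(funsim_pairwise(dag, ic, ann, p, p, "other"), 1)
  for (v in c("simgic", "simuic", "simui", "simdic", "simuix"))
    expect_equal(funsim_setwise(dag, ic, ann, p, p, "other", v), 1)
})

test_that("batch scoring equals per-pair calls and tolerates unknowns", {
  dag <- generate_random_dag(25, seed = 950)
  ic <- ic_universal(compute_mu(dag))
  ann <- generate_annotations(dag, 8, seed = 951)
  prots <- unique(ann$entries$protein)
  pairs <- expand.grid(protein_a = prots[1:4], protein_b = prots[5:8],
                       stringsAsFactors = FALSE)
  out <- funsim_matrix(dag, ic, ann, pairs, "other")
  per <- vapply(seq_len(nrow(pairs)), function(k)
    funsim_pairwise(dag, ic, ann, pairs$protein_a[k], pairs$protein_b[k],
                    "other"), 0)
  expect_equal(out$score, per)
  self <- funsim_matrix(dag, ic, ann,
                        data.frame(protein_a = prots, protein_b = prots),
                        "other")
  expect_true(all(self$score == 1))
  ghost <- funsim_matrix(dag, ic, ann,
                         data.frame(protein_a = "missing",
                                    protein_b = prots[1]), "other")
  expect_true(is.na(ghost$score))
})
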