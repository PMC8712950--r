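test_that("overlap score follows the squared-intersection formula", {
  expect_equal(overlap_score(c("p1", "p2", "p3"), c("p2", "p3", "p4", "p5")), 4 / 12)
  expect_equal(overlap_score(c("a", "b"), c("a", "b")), 1)
  expect_equal(overlap_score(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_score(c("a", "b", "c"), c("b", "c")),
               overlap_score(c("b", "c"), c("a", "b", "c")))
  expect_error(overlap_score(character(), c("a")), "empty")
})

test_that("precision/recall/F count matches at the OS threshold", {
  std <- complex_set(list(c("a", "b", "c"), c("d", "e", "f")))
  expect_equal(unlist(f_measure(std, std)[c("precision", "recall", "f_measure")]),
               c(precision = 1, recall = 1, f_measure = 1))
  none <- complex_set(list(c("x", "y", "z")))
  expect_equal(f_measure(none, std)$f_measure, 0)
  det <- complex_set(list(c("a", "b", "c"), c("q", "r", "s")))
  fm <- f_measure(det, std)
  expect_equal(fm$precision, 0.5)
  expect_equal(fm$recall, 0.5)
  expect_equal(fm$f_measure, 0.5)
})

test_that("coverage rate sums best per-standard overlaps", {
  std <- complex_set(list(c("a", "b", "c", "d")))
  det <- complex_set(list(c("a", "b"), c("c", "e")))
  expect_equal(coverage_rate(det, std), 0.5)
  expect_equal(coverage_rate(std, std), 1)
  expect_equal(coverage_rate(structure(list(), class = "complex_set"), std), 0)
})

test_that("Sn/PPV/ACC follow the clustering-wise contingency table", {
  std <- complex_set(list(c("a", "b", "c"), c("d", "e", "f")))
  r <- sn_ppv_acc(std, std)
  expect_equal(unlist(r), c(sn = 1, ppv = 1, acc = 1))
  half <- complex_set(list(c("a", "b")))
  r2 <- sn_ppv_acc(half, complex_set(list(c("a", "b", "c", "d"))))
  expect_equal(r2$sn, 0.5)
  expect_equal(r2$ppv, 1)
  expect_equal(r2$acc, sqrt(0.5))
  r3 <- sn_ppv_acc(complex_set(list(c("x", "y"))), std)
  expect_equal(unlist(r3), c(sn = 0, ppv = 0, acc = 0))
})

test_that("MMR equals the hand-enumerated optimal matching", {
  std <- complex_set(list(c("a", "b", "c"), c("d", "e", "f")))
  det <- complex_set(list(c("a", "b", "c"), c("d", "e", "g")))
  expect_equal(mmr(det, std), (1 + 4 / 9) / 2)
  expect_equal(mmr(std, std), 1)
  # a standard complex split in two: the one-to-one mapping uses one part
  split_det <- complex_set(list(c("a", "b"), c("c", "d")))
  expect_equal(mmr(split_det, complex_set(list(c("a", "b", "c", "d")))), 0.5)
})

test_that("MMR matches exhaustive matching enumeration on random instances", {
  set.seed(701)
  alphabet <- sprintf("p%02d", 1:12)
  for (rep in 1:25) {
    det <- random_complexes(sample(1:6, 1L), alphabet)
    std <- random_complexes(sample(1:6, 1L), alphabet)
    os <- outer(seq_along(det), seq_along(std),
                Vectorize(function(i, j) overlap_score(det[[i]], std[[j]])))
    expect_equal(mmr(det, std), oracle_matching_weight(os) / length(std),
                 tolerance = 1e-9)
  }
})

test_that("Jaccard aggregates per-side best matches harmonically", {
  std <- complex_set(list(c("a", "b", "c")))
  expect_equal(unlist(jaccard_metric(std, std)),
               c(jaccard_c = 1, jaccard_g = 1, jaccard = 1))
  jm <- jaccard_metric(complex_set(list(c("a", "b", "c"))),
                       complex_set(list(c("b", "c", "d"))))
  expect_equal(unlist(jm), c(jaccard_c = 0.5, jaccard_g = 0.5, jaccard = 0.5))
  jm0 <- jaccard_metric(complex_set(list(c("x", "y"))), std)
  expect_equal(jm0$jaccard, 0)
})

test_that("total score sums the five headline metrics", {
  expect_equal(total_score(list(f_measure = 0.5, cr = 0.5, acc = 0.5,
                                mmr = 0.5, jaccard = 0.5)), 2.5)
  expect_equal(total_score(list(f_measure = 0, cr = 0, acc = 0, mmr = 0, jaccard = 0)), 0)
})

test_that("hypergeometric p-values are exact and validated", {
  expect_equal(hypergeometric_pvalue(10, 5, 3, 3), choose(5, 3) / choose(10, 3))
  expect_equal(hypergeometric_pvalue(10, 5, 3, 0), 1)
  expect_error(hypergeometric_pvalue(10, 5, 3, 4), "impossible")
  expect_error(hypergeometric_pvalue(10, 12, 3, 1), "impossible")
  set.seed(702)
  for (rep in 1:50) {
    N <- sample(5:25, 1L)
    F_ann <- sample(0:N, 1L)
    C <- sample(1:N, 1L)
    K <- sample(0:min(F_ann, C), 1L)
    expect_equal(hypergeometric_pvalue(N, F_ann, C, K),
                 oracle_hyper_p(N, F_ann, C, K), tolerance = 1e-12)
  }
})

test_that("enrichment takes the best term per complex over the universe", {
  universe <- sprintf("p%d", 1:10)
  ann <- stats::setNames(rep(list("T1"), 5L), universe[1:5])
  det <- complex_set(list(universe[1:3], universe[8:10]))
  e <- enrichment(det, ann, universe = universe)
  expect_equal(e$p_values[[1L]], choose(5, 3) / choose(10, 3))
  expect_equal(e$p_values[[2L]], 1) # unannotated complex
  expect_equal(unname(e$counts[[1L]]), 0) # nothing below 1e-2 here
})

test_that("co-localization scores the dominant compartment fraction", {
  det <- complex_set(list(c("p1", "p2", "p3"), c("p4", "p5")))
  locs <- list(p1 = "nucleus", p2 = "nucleus", p3 = "cytoplasm",
               p4 = "mitochondrion", p5 = "mitochondrion")
  r <- colocalization(det, locs)
  expect_equal(r$cl, 0.8)
  expect_equal(unname(r$per_complex), c(2 / 3, 1))
  expect_equal(colocalization(det, list())$cl, 0) # nothing localized
  all_same <- lapply(stats::setNames(nm = unlist(det)), function(p) "vacuole")
  expect_equal(colocalization(det, all_same)$cl, 1)
})

test_that("a perfect prediction maximizes every metric in the report", {
  std <- complex_set(list(c("a", "b", "c"), c("d", "e", "f"), c("g", "h", "i")))
  rep <- evaluate_complexes(std, std)
  for (m in c("precision", "recall", "f_measure", "cr", "sn", "ppv", "acc",
              "mmr", "jaccard_c", "jaccard_g", "jaccard")) {
    expect_equal(rep[[m]], 1)
  }
  expect_equal(rep$total_score, 5)
})

test_that("all aggregate metrics stay within their ranges", {
  set.seed(703)
  alphabet <- sprintf("p%02d", 1:15)
  for (rep in 1:20) {
    det <- random_complexes(sample(1:5, 1L), alphabet)
    std <- random_complexes(sample(1:5, 1L), alphabet)
    r <- evaluate_complexes(det, std)
    for (m in c("precision", "recall", "f_measure", "cr", "sn", "ppv", "acc",
                "mmr", "jaccard")) {
      expect_gte(r[[m]], 0)
      expect_lte(r[[m]], 1)
    }
    expect_gte(r$total_score, 0)
    expect_lte(r$total_score, 5)
  }
})
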