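# Operator-level contracts for the memetic search. Probabilistic claims use
# seeded Monte-Carlo with generous tolerances.

two_triangles <- function() {
  suppressMessages(ppi_network(
    rbind(c("a", "b"), c("a", "c"), c("b", "c"),
          c("x", "y"), c("x", "z"), c("y", "z")),
    weights = rep(1, 6)
  ))
}

test_that("binary tournament prefers the fitter individual at rate 3/4", {
  net <- two_triangles()
  weak <- new_individual(net, list(c("a", "b")))       # fitness < 4
  strong <- new_individual(net, list(c("a", "b", "c"))) # fitness 4
  pop <- list(weak, strong)
  set.seed(601)
  wins <- mean(replicate(4000, binary_tournament(pop)$fitness == strong$fitness))
  expect_equal(wins, 0.75, tolerance = 0.03)
  expect_identical(binary_tournament(list(weak))$clusters, weak$clusters)
})

test_that("population initialization filters, pads and truncates", {
  net <- two_triangles()
  cfg <- ima_config(pop_size = 4L, min_cluster_size = 3L)
  cs <- complex_set(list(c("a", "b", "c"), c("x", "y", "z")))
  pop <- init_population(cs, net, cfg)
  expect_length(pop, 4L)
  expect_true(all(vapply(pop, `[[`, numeric(1L), "fitness") == 8))

  # members absent from the network are dropped before scoring
  cs2 <- complex_set(list(c("a", "b", "c", "GHOST"), c("x", "y")))
  pop2 <- init_population(cs2, net, cfg)
  expect_identical(pop2[[1L]]$clusters, list(c("a", "b", "c")))
  # nothing usable at all -> error
  expect_error(init_population(complex_set(list(c("a", "GHOST"))), net, cfg),
               "no usable clusters")
})

test_that("recombination respects length bounds and composite membership", {
  net <- two_triangles()
  p1 <- new_individual(net, list(c("a", "b", "c")))
  p2 <- new_individual(net, list(c("a", "b", "c"), c("x", "y", "z"),
                                 c("a", "b"), c("x", "y"), c("b", "c")))
  composite_keys <- unique(vapply(c(p1$clusters, p2$clusters),
                                  function(m) paste(sort(m), collapse = ","),
                                  character(1L)))
  set.seed(602)
  lens <- integer()
  for (rep in 1:200) {
    kids <- recombine(p1, p2)
    for (k in kids) {
      lens <- c(lens, length(k$clusters))
      keys <- vapply(k$clusters, function(m) paste(sort(m), collapse = ","),
                     character(1L))
      expect_true(all(keys %in% composite_keys))
      expect_false(anyDuplicated(keys) > 0)
      expect_equal(k$fitness, sum(k$ff))
    }
  }
  expect_true(all(lens >= 1L & lens <= 5L))
  expect_setequal(unique(lens), 1:5)

  # identical parents: children are subsets of the shared clusters at full length
  kids <- recombine(p2, p2)
  expect_true(all(lengths(lapply(kids, `[[`, "clusters")) == 5L))
})

test_that("recombination tournaments favour the dominant-FF cluster", {
  net <- two_triangles()
  # one maximal-FF cluster among weak fragments
  p1 <- new_individual(net, list(c("a", "b", "c"), c("a", "b"), c("x", "y")))
  p2 <- new_individual(net, list(c("b", "c"), c("y", "z"), c("x", "z")))
  set.seed(603)
  hits <- matrix(0, nrow = 1000, ncol = 6)
  keys_all <- vapply(c(p1$clusters, p2$clusters),
                     function(m) paste(sort(m), collapse = ","), character(1L))
  for (rep in 1:1000) {
    kid <- recombine(p1, p2)[[1L]]
    keys <- vapply(kid$clusters, function(m) paste(sort(m), collapse = ","),
                   character(1L))
    hits[rep, ] <- keys_all %in% keys
  }
  freq <- colMeans(hits)
  expect_equal(which.max(freq), 1L) # the triangle appears most often
})

test_that("local optimization sheds a weak pendant and fixes optima", {
  net <- suppressMessages(ppi_network(
    rbind(c("a", "b"), c("a", "c"), c("b", "c"), c("c", "d")),
    weights = c(1, 1, 1, 0.1)
  ))
  cfg <- ima_config()
  ind <- new_individual(net, list(c("a", "b", "c", "d")))
  opt <- local_optimize(ind, net, cfg)
  expect_identical(opt$clusters, list(c("a", "b", "c")))
  expect_gt(opt$fitness, ind$fitness)

  # already-optimal cluster is a fixed point
  tri <- new_individual(net, list(c("a", "b", "c")))
  expect_identical(local_optimize(tri, net, cfg)$clusters, tri$clusters)
})

test_that("local optimization never lowers fitness", {
  set.seed(604)
  for (rep in 1:15) {
    inst <- random_weighted_instance(sample(6:12, 1L), p = 0.4)
    clusters <- lapply(seq_len(sample(1:3, 1L)), function(i) {
      sample(inst$nodes, sample(2:5, 1L))
    })
    ind <- new_individual(inst$net, clusters)
    opt <- local_optimize(ind, inst$net, ima_config())
    expect_gte(opt$fitness, ind$fitness)
  }
})

test_that("terminal clusters are fixed points of the single-move oracle", {
  set.seed(605)
  for (rep in 1:15) {
    inst <- random_weighted_instance(sample(5:10, 1L), p = 0.5)
    ind <- new_individual(inst$net, list(sample(inst$nodes, sample(2:4, 1L))))
    opt <- local_optimize(ind, inst$net, ima_config())
    members <- opt$clusters[[1L]]
    ff0 <- oracle_ff(inst$edges, members)
    # no single removal of a connected member improves FF
    if (length(members) > 1L) {
      for (v in members) {
        connected <- any(inst$edges$u == v | inst$edges$v == v)
        if (connected) expect_lte(oracle_ff(inst$edges, setdiff(members, v)), ff0)
      }
    }
    # no single boundary addition improves FF
    boundary <- setdiff(unique(c(
      inst$edges$v[inst$edges$u %in% members],
      inst$edges$u[inst$edges$v %in% members]
    )), members)
    for (v in boundary) {
      expect_lte(oracle_ff(inst$edges, c(members, v)), ff0)
    }
  }
})

test_that("roulette update keeps size and favours a dominant child", {
  net <- two_triangles()
  weak <- new_individual(net, list(c("a", "b")))
  strong <- new_individual(net, list(c("a", "b", "c"), c("x", "y", "z")))
  pop <- replicate(6, weak, simplify = FALSE)

  set.seed(606)
  survived <- replicate(300, {
    newpop <- roulette_update(pop, strong)
    expect_length(newpop, 6L)
    any(vapply(newpop, `[[`, numeric(1L), "fitness") == strong$fitness)
  })
  expect_gt(mean(survived), 0.95)

  # equal fitnesses: every pool member survives with probability 6/7
  pop_eq <- replicate(6, strong, simplify = FALSE)
  newpop <- roulette_update(pop_eq, strong)
  expect_length(newpop, 6L)
})

test_that("full runs are deterministic with monotone best-ever fitness", {
  sb <- small_benchmark()
  inits <- lapply(1:4, function(k) {
    suppressMessages(perturb_gold(sb$bench$gold, 0.3, sb$bench$network,
                                  rng_seed = 700 + k))
  })
  cfg <- ima_config(max_iter = 15L, pop_size = 8L, rng_seed = 99L)
  r1 <- run_ima(sb$weighted, inits, cfg)
  r2 <- run_ima(sb$weighted, inits, cfg)
  expect_identical(r1$complexes, r2$complexes)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace$best_fitness) >= 0))
  expect_true(all(lengths(r1$complexes) >= cfg$min_cluster_size))
})

test_that("an already-optimal population is a fixed point of the search", {
  net <- two_triangles()
  inits <- complex_set(list(c("a", "b", "c"), c("x", "y", "z")))
  res <- run_ima(net, inits, ima_config(max_iter = 10L, pop_size = 4L, rng_seed = 1L))
  expect_true(all(res$trace$best_fitness == 8))
  expect_equal(res$fitness, 8)
  canon <- sort(vapply(res$complexes, function(m) paste(sort(m), collapse = ","),
                       character(1L)))
  expect_identical(canon, c("a,b,c", "x,y,z"))
})
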