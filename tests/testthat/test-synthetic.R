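test_that("minimal motif quotas produce the canonical 3-gene structures", {
  net <- simulate_network(3, density = 0, motifs = c(single_input = 1, chain = 0),
                          seed = 1)
  expect_equal(nrow(net$edges), 2)
  expect_equal(length(unique(net$edges$regulator)), 1)  # one regulator, 2 targets

  net2 <- simulate_network(3, density = 0, motifs = c(single_input = 0, chain = 1),
                           seed = 2)
  expect_equal(nrow(net2$edges), 2)
  mid <- intersect(net2$edges$regulator, net2$edges$target)
  expect_length(mid, 1)                                 # X -> A -> Y

  expect_error(simulate_network(2, motifs = c(single_input = 1, chain = 0)),
               "infeasible")
})

test_that("planted motifs are re-detectable in the edge list across seeds", {
  for (s in 1:50) {
    net <- simulate_network(10, density = 0.15,
                            motifs = c(single_input = 2, chain = 2),
                            seed = sub_seed(400, s))
    key <- paste(net$edges$regulator, net$edges$target)
    for (mo in net$motifs) {
      if (mo$kind == "single_input") {
        expect_true(all(paste(mo$members[1], mo$members[2:3]) %in% key))
      } else {
        expect_true(all(c(paste(mo$members[1], mo$members[2]),
                          paste(mo$members[2], mo$members[3])) %in% key))
      }
    }
    # acyclicity: every edge points forward in the id (topological) order
    expect_true(all(match(net$edges$regulator, net$gene_ids) <
                      match(net$edges$target, net$gene_ids)))
  }
})

test_that("steady-state sampling approaches determinism as noise vanishes", {
  net <- structure(list(
    gene_ids = c("A", "X"),
    edges = data.frame(regulator = "A", target = "X", effect = 1),
    basal = c(A = 1, X = 1), motifs = list(), n = 2),
    class = "true_network")
  # the regulator keeps its variability; the target's own noise vanishes
  em <- simulate_steady_state(net, 200, noise_sd = c(1, 1e-5), seed = 3)
  expect_gt(cor(em$values["A", ], em$values["X", ]), 0.999)
})

test_that("an empty network yields independent columns that order-0 inference clears", {
  empty <- structure(list(gene_ids = sprintf("G%02d", 1:10),
                          edges = data.frame(regulator = character(),
                                             target = character(),
                                             effect = numeric()),
                          basal = stats::setNames(runif(10, 1, 3),
                                                  sprintf("G%02d", 1:10)),
                          motifs = list(), n = 10),
                     class = "true_network")
  fp <- numeric(20)
  for (s in 1:20) {
    em <- simulate_steady_state(empty, 500, seed = sub_seed(410, s))
    fit <- rpni(em, theta = 0.03)
    fp[s] <- n_edges(fit$network)
  }
  # false-positive control: out of 45 possible edges, almost none survive
  expect_lt(mean(fp), 2)
})

test_that("chains are screened off by their intermediate", {
  net <- structure(list(
    gene_ids = c("X", "A", "Y"),
    edges = data.frame(regulator = c("X", "A"), target = c("A", "Y"),
                       effect = c(1, 1)),
    basal = c(X = 1, A = 1, Y = 1), motifs = list(), n = 3),
    class = "true_network")
  em <- simulate_steady_state(net, 2000, seed = 4)
  v <- em$values
  pcor <- (cor(v["X", ], v["Y", ]) -
             cor(v["X", ], v["A", ]) * cor(v["A", ], v["Y", ])) /
    sqrt((1 - cor(v["X", ], v["A", ])^2) * (1 - cor(v["A", ], v["Y", ])^2))
  expect_lt(abs(pcor), 0.05)
})

test_that("knockout compendium matches the interventional means at zero noise", {
  net <- simulate_network(8, density = 0.25, seed = 5)
  em <- simulate_knockouts(net, noise_sd = 0, seed = 6)
  expect_equal(em$wild_type, "wt")
  expect_length(em$knockout_of, 8)

  sinks <- setdiff(net$gene_ids, net$edges$regulator)
  for (k in sinks) {
    others <- setdiff(net$gene_ids, k)
    expect_equal(em$values[others, k], em$values[others, "wt"])
    expect_equal(unname(em$values[k, k]), 0)
  }

  # knocking out a chain head shifts all its descendants
  heads <- intersect(net$edges$regulator, setdiff(net$gene_ids,
                                                  net$edges$target))
  for (k in heads) {
    desc <- character(0); frontier <- k
    while (length(frontier)) {
      nxt <- net$edges$target[net$edges$regulator %in% frontier]
      frontier <- setdiff(nxt, desc)
      desc <- union(desc, nxt)
    }
    for (d in setdiff(desc, k))
      expect_false(isTRUE(all.equal(em$values[d, k], em$values[d, "wt"])))
  }
})

test_that("corruption models have their conservation properties", {
  net <- simulate_network(6, density = 0.3, seed = 7)
  em <- simulate_steady_state(net, 50, seed = 8)

  expect_equal(corrupt_expression(em, "outlier", fraction = 0, seed = 1)$values,
               em$values)
  expect_equal(corrupt_expression(em, "permute", fraction = 0, seed = 1)$values,
               em$values)

  # permute conserves the value multiset exactly, at any fraction
  p1 <- corrupt_expression(em, "permute", fraction = 1, seed = 2)
  expect_equal(sort(p1$values), sort(em$values))
  p2 <- corrupt_expression(em, "permute", fraction = 0.1, seed = 3)
  expect_equal(sort(p2$values), sort(em$values))

  # outlier changes exactly floor(fraction * n * m) cells
  o1 <- corrupt_expression(em, "outlier", fraction = 0.1, seed = 4)
  expect_equal(sum(o1$values != em$values), floor(0.1 * length(em$values)))

  expect_error(corrupt_expression(em, "outlier", fraction = 1.2), "fraction")

  # identical seeds give identical corruptions
  expect_identical(corrupt_expression(em, "outlier", fraction = 0.2, seed = 9),
                   corrupt_expression(em, "outlier", fraction = 0.2, seed = 9))
})

test_that("gaussian corruption doubles per-gene variance in expectation", {
  net <- simulate_network(5, density = 0.3, seed = 10)
  em <- simulate_steady_state(net, 5000, seed = 11)
  noisy <- corrupt_expression(em, "gaussian", seed = 12)
  ratio <- apply(noisy$values, 1, var) / apply(em$values, 1, var)
  expect_true(all(abs(ratio - 2) < 0.2))
})

test_that("generators are byte-for-byte reproducible under a fixed seed", {
  n1 <- simulate_network(9, density = 0.25, seed = 13)
  n2 <- simulate_network(9, density = 0.25, seed = 13)
  expect_identical(n1, n2)
  expect_identical(simulate_steady_state(n1, 40, seed = 14)$values,
                   simulate_steady_state(n2, 40, seed = 14)$values)
  expect_identical(simulate_knockouts(n1, seed = 15)$values,
                   simulate_knockouts(n2, seed = 15)$values)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_network(as_gene_network(n1), f1)
  write_network(as_gene_network(n2), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("robustness aggregation collapses for a zero-noise specification", {
  net <- simulate_network(7, density = 0.25, seed = 16)
  rb <- robustness_experiment(net, m = 80,
                              specs = list(list(kind = "none")),
                              repeats = 3, theta_grid = c(0.01, 0.05, 0.2),
                              seed = 17)
  expect_equal(colnames(rb$auc), "clean")
  # each repeat is a fresh draw, but within a repeat the clean spec is the data
  # itself: the per-theta spread reflects only between-repeat variation
  expect_true(all(rb$per_theta$tpr_min <= rb$per_theta$median_tpr))
  expect_true(all(rb$per_theta$tpr_max >= rb$per_theta$median_tpr))
  expect_equal(nrow(rb$per_theta), 3)
})
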