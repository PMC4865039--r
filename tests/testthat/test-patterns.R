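make_hints <- function(pairs) {
  structure(list(pairs = data.frame(regulator = vapply(pairs, `[[`, "", 1),
                                    target = vapply(pairs, `[[`, "", 2),
                                    stringsAsFactors = FALSE),
                 alpha = 0.05, z_scores = NULL),
            class = "direction_hints")
}

test_that("z-tests emit no pairs for a knockout identical to wild type", {
  net <- simulate_network(6, density = 0.3, seed = 2)
  em <- simulate_knockouts(net, noise_sd = 0, seed = 3)
  # a sink gene's knockout leaves every other gene at its wild-type level,
  # so no readout passes; restrict to a compendium of just that strain
  sinks <- setdiff(net$gene_ids, net$edges$regulator)
  skip_if(length(sinks) == 0)
  k <- sinks[1]
  sub <- expression_matrix(em$values[, c("wt", k)],
                           knockout_of = stats::setNames(k, k),
                           wild_type = "wt")
  h <- suppressWarnings(infer_directions(sub, alpha = 0.05))
  expect_equal(nrow(h$pairs), 0)
})

test_that("alpha = 0 always yields an empty hint set", {
  net <- simulate_network(6, density = 0.3, seed = 4)
  em <- simulate_knockouts(net, noise_sd = 1, seed = 5)
  expect_equal(nrow(infer_directions(em, alpha = 0)$pairs), 0)
})

test_that("knockout z-tests recover strong direct regulations", {
  # over 20 seeds, the fraction of true regulator->target pairs (adjacent in
  # the network) recovered by the z-test must exceed 0.9
  hit <- tot <- 0
  for (s in 1:20) {
    net <- simulate_network(8, density = 0.25, seed = sub_seed(40, s))
    em <- simulate_knockouts(net, noise_sd = 0.1, seed = sub_seed(41, s))
    h <- infer_directions(em, alpha = 0.05)
    key <- paste(h$pairs$regulator, h$pairs$target)
    want <- paste(net$edges$regulator, net$edges$target)
    hit <- hit + sum(want %in% key)
    tot <- tot + length(want)
  }
  expect_gt(hit / tot, 0.9)
})

test_that("infer_directions requires knockout annotations and flags constant genes", {
  em <- expression_matrix(matrix(rnorm(20), 4, 5))
  expect_error(infer_directions(em), "no knockout annotations")
  net <- simulate_network(5, density = 0.3, seed = 6)
  em2 <- simulate_knockouts(net, noise_sd = 0.5, seed = 7)
  em2$values[3, ] <- 1  # constant readout
  expect_warning(infer_directions(em2, alpha = 0.05), "constant gene")
})

test_that("common neighbors are the shared adjacencies, sorted, endpoints excluded", {
  net <- gene_network(c("i", "j", "a", "b", "c"), data.frame(
    gene_a = c("i", "i", "j", "i", "j", "c"),
    gene_b = c("j", "a", "a", "c", "c", "b")))
  expect_equal(common_neighbors(net, "i", "j"), c("a", "c"))
  expect_equal(common_neighbors(net, "a", "b"), character(0))
  expect_error(common_neighbors(net, "i", "zz"), "not in network")
})

test_that("pattern classification follows the hint structure", {
  tri <- gene_network(c("i", "j", "a"), data.frame(
    gene_a = c("i", "i", "j"), gene_b = c("j", "a", "a")))

  # co-regulation: a is upstream of both endpoints
  p <- classify_patterns(tri, make_hints(list(c("a", "i"), c("a", "j"))), "i", "j")
  expect_equal(p$co_regulators, "a")
  expect_equal(p$chain_intermediates, character(0))
  expect_equal(p$T, 1)

  # indirect regulation: i -> a -> j chain
  p <- classify_patterns(tri, make_hints(list(c("i", "a"), c("a", "j"))), "i", "j")
  expect_equal(p$chain_intermediates, "a")
  expect_equal(p$co_regulators, character(0))
  expect_equal(p$T, 1)

  # mix: both roles at once, counted once in T
  p <- classify_patterns(tri, make_hints(list(c("a", "i"), c("a", "j"),
                                              c("i", "a"))), "i", "j")
  expect_equal(p$co_regulators, "a")
  expect_equal(p$chain_intermediates, "a")
  expect_equal(p$mixed, "a")
  expect_equal(p$T, 1)

  # no hints: fallback governs
  p <- classify_patterns(tri, NULL, "i", "j", fallback = "neighbors")
  expect_equal(p$co_regulators, "a")
  expect_equal(p$chain_intermediates, "a")
  p <- classify_patterns(tri, NULL, "i", "j", fallback = "none")
  expect_equal(p$T, 0)

  # partial evidence completing no pattern excludes the neighbor ...
  p <- classify_patterns(tri, make_hints(list(c("a", "i"))), "i", "j",
                         fallback = "neighbors")
  expect_equal(p$T, 0)
  # ... while a fully unoriented neighbor falls back to candidacy
  p <- classify_patterns(tri, make_hints(list(c("i", "j"))), "i", "j",
                         fallback = "neighbors")
  expect_equal(p$mixed, "a")
})

test_that("candidates are always common neighbors and grow monotonically with hints", {
  set.seed(50)
  for (rep in 1:10) {
    net <- simulate_network(8, density = 0.4, seed = sub_seed(60, rep))
    skel <- as_gene_network(net)
    ed <- network_edges(skel)
    g <- net$gene_ids
    # random hint set, then an enlarged superset
    all_pairs <- expand.grid(a = g, b = g, stringsAsFactors = FALSE)
    all_pairs <- all_pairs[all_pairs$a != all_pairs$b, ]
    pick <- sample(nrow(all_pairs), 10)
    more <- union(pick, sample(nrow(all_pairs), 10))
    h1 <- make_hints(lapply(pick, function(i) unlist(all_pairs[i, ])))
    h2 <- make_hints(lapply(more, function(i) unlist(all_pairs[i, ])))
    for (r in seq_len(min(nrow(ed), 5))) {
      i <- ed$gene_a[r]; j <- ed$gene_b[r]
      cn <- common_neighbors(skel, i, j)
      p1 <- classify_patterns(skel, h1, i, j, fallback = "none")
      p2 <- classify_patterns(skel, h2, i, j, fallback = "none")
      expect_true(all(p1$mixed %in% cn))
      expect_false(i %in% p1$mixed || j %in% p1$mixed)
      expect_true(all(p1$mixed %in% p2$mixed))  # more hints never shrink T
      expect_equal(p1$T, length(union(p1$co_regulators, p1$chain_intermediates)))
    }
  }
})

test_that("planted motifs are recognized from knockout-derived hints", {
  # on networks planted with a single-input module and a chain, the motif
  # genes must be classified into the matching candidate list
  ok <- n <- 0
  for (s in 1:20) {
    net <- simulate_network(9, density = 0.15,
                            motifs = c(single_input = 1, chain = 1),
                            seed = sub_seed(70, s))
    em <- simulate_knockouts(net, noise_sd = 0.05, seed = sub_seed(71, s))
    h <- infer_directions(em, alpha = 0.05)
    skel <- complete_network(net$gene_ids)  # order-1 graph: all pairs present
    for (mo in net$motifs) {
      n <- n + 1
      if (mo$kind == "single_input") {
        p <- classify_patterns(skel, h, mo$members[2], mo$members[3],
                               fallback = "none")
        ok <- ok + (mo$members[1] %in% p$co_regulators)
      } else {
        p <- classify_patterns(skel, h, mo$members[1], mo$members[3],
                               fallback = "none")
        ok <- ok + (mo$members[2] %in% p$chain_intermediates)
      }
    }
  }
  expect_gte(ok / n, 0.95)
})
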