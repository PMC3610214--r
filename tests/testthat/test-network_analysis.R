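test_that("duplicate pairs merge into one edge with the best category", {
  ints <- dplyr::bind_rows(make_interactions("C"), make_interactions("D"))
  ints$bait_protein <- c("DYSF", "SNAPIN")
  ints$prey_protein <- c("SNAPIN", "DYSF")
  ints$screens <- c("S001", "S002")
  net <- build_network(ints)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$pbs, "C")
  expect_equal(net$edges$screens, "S001;S002")
})

test_that("disjoint pairs, self-loops and exclusions build as specified", {
  ints <- make_interactions(c("A", "B", "C"))
  net <- build_network(ints)
  expect_equal(length(net$nodes), 6L)
  expect_equal(nrow(net$edges), 3L)

  homo <- make_interactions("D")
  homo$prey_protein <- homo$bait_protein
  loop_net <- build_network(homo)
  expect_equal(nrow(loop_net$edges), 1L)
  expect_equal(loop_net$edges$protein_a, loop_net$edges$protein_b)

  excl <- make_interactions(c("A", "excluded"))
  expect_equal(nrow(build_network(excl)$edges), 1L)
})

test_that("merging order of screens does not change the network", {
  set.seed(14)
  ints <- make_interactions(sample(c("A", "C", "D"), 30, replace = TRUE))
  shuffled <- ints[sample.int(nrow(ints)), ]
  expect_equal(build_network(shuffled)$edges, build_network(ints)$edges)
})

test_that("topology metrics are exact on closed-form graphs", {
  tri <- build_network(dplyr::bind_rows(
    lapply(list(c("A", "B"), c("B", "C"), c("A", "C")), function(p) {
      dplyr::mutate(make_interactions("A"), bait_protein = p[1],
                    prey_protein = p[2])
    })))
  ts <- topology_summary(tri)
  expect_equal(ts$mean_degree, 2)
  expect_equal(ts$mean_shortest_path, 1)
  expect_equal(ts$heterogeneity, 0)
  expect_equal(ts$density, 1)

  star <- build_network(dplyr::bind_rows(lapply(paste0("leaf", 1:4), function(l) {
    dplyr::mutate(make_interactions("A"), bait_protein = "hub", prey_protein = l)
  })))
  expect_equal(topology_summary(star)$heterogeneity, 0.75)
})

test_that("self-loops add two to degree but are ignored in density and paths", {
  ints <- dplyr::bind_rows(make_interactions("A"), make_interactions("B"))
  ints$bait_protein <- c("A", "A")
  ints$prey_protein <- c("B", "A") # one edge A-B plus a self-loop on A
  ts <- topology_summary(build_network(ints))
  expect_equal(ts$mean_degree, 2) # degrees 3 and 1
  expect_equal(ts$density, 1)     # only A-B among 2 nodes
  expect_equal(ts$mean_shortest_path, 1)
})

test_that("topology metrics match brute-force BFS and variance oracles", {
  set.seed(8)
  nodes <- sprintf("v%02d", 1:50)
  a <- sample(nodes, 70, replace = TRUE)
  b <- sample(nodes, 70, replace = TRUE)
  pairs <- unique(data.frame(a = pmin(a, b), b = pmax(a, b)))
  pairs <- pairs[pairs$a != pairs$b, ]
  ints <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
    dplyr::mutate(make_interactions("C"), bait_protein = pairs$a[i],
                  prey_protein = pairs$b[i])
  }))
  net <- build_network(ints)
  ts <- topology_summary(net)

  deg <- table(factor(c(net$edges$protein_a, net$edges$protein_b),
                      levels = net$nodes))
  expect_equal(ts$mean_degree, mean(deg))
  expect_equal(ts$heterogeneity, sqrt(mean((deg - mean(deg))^2)) / mean(deg))
  expect_equal(ts$density, 2 * nrow(net$edges) /
                 (length(net$nodes) * (length(net$nodes) - 1)))

  d <- oracle_bfs_distances(net$nodes, net$edges$protein_a, net$edges$protein_b)
  finite <- is.finite(d)
  comp_sizes <- table(apply(finite, 1, function(r) paste(which(r), collapse = ",")))
  members <- which(finite[which.max(rowSums(finite)), ])
  sub <- d[members, members]
  expect_equal(ts$mean_shortest_path, mean(sub[upper.tri(sub)]))
})

test_that("single-node networks report an undefined path length", {
  homo <- make_interactions("D")
  homo$prey_protein <- homo$bait_protein
  expect_true(is.na(topology_summary(build_network(homo))$mean_shortest_path))
})

hc_fixture <- function() {
  ints <- make_interactions(c("B", "D", "D", "D", "E"))
  net <- build_network(ints)
  evidence <- tibble::tibble(
    protein_a = net$edges$protein_a[-1],
    protein_b = net$edges$protein_b[-1],
    literature_support = c(FALSE, FALSE, FALSE, TRUE),
    experimental_support = FALSE,
    shares_bp = c(FALSE, FALSE, FALSE, FALSE),
    shares_cc = c(TRUE, TRUE, FALSE, FALSE),
    shares_mf = c(FALSE, TRUE, FALSE, FALSE),
    nmd_prey = FALSE
  )
  list(net = net, evidence = evidence)
}

test_that("the HC filter keeps A-C and admits D/E only on evidence", {
  fx <- hc_fixture()
  hc <- hc_filter(fx$net, fx$evidence)
  # kept: the B edge, the CC+MF-sharing D edge, the literature E edge;
  # dropped: CC-only and evidence-free D edges
  expect_equal(nrow(hc$edges), 3L)
  expect_setequal(hc$edges$hc_rules, c("pbs_abc", "go", "literature"))
  expect_true(all(hc$edges$pbs[hc$edges$hc_rules == "pbs_abc"] == "B"))
})

test_that("the HC filter is idempotent and never drops A-C edges", {
  fx <- hc_fixture()
  hc1 <- hc_filter(fx$net, fx$evidence)
  hc2 <- hc_filter(hc1, fx$evidence)
  expect_equal(hc2$edges[names(fx$net$edges)], hc1$edges[names(fx$net$edges)])
  keys_in <- paste(fx$net$edges$protein_a, fx$net$edges$protein_b)
  keys_hc <- paste(hc1$edges$protein_a, hc1$edges$protein_b)
  expect_true(all(keys_hc %in% keys_in))
  abc <- fx$net$edges$pbs %in% c("A", "B", "C")
  expect_true(all(keys_in[abc] %in% keys_hc))
})

test_that("missing evidence for a D/E edge is an error naming the pair", {
  fx <- hc_fixture()
  expect_error(hc_filter(fx$net, fx$evidence[-1, ]), fx$evidence$protein_a[1])
})

test_that("network comparison reports identical columns for identical inputs", {
  net <- build_network(make_interactions(c("A", "B", "C", "D")))
  cmp <- compare_networks(list(one = net, two = net))
  expect_equal(cmp$n_ppis, c(4L, 4L))
  expect_equal(cmp$mean_degree[1], cmp$mean_degree[2])

  fx <- hc_fixture()
  hc <- hc_filter(fx$net, fx$evidence)
  cmp2 <- compare_networks(list(original = fx$net, hc = hc))
  expect_lte(cmp2$n_ppis[2], cmp2$n_ppis[1])
  expect_lte(cmp2$n_proteins[2], cmp2$n_proteins[1])
})

test_that("literature overlap matches pairs after identifier normalization", {
  ints <- make_interactions(c("A", "D"))
  ints$bait_protein <- c("DYSF", "TCAP")
  ints$prey_protein <- c("SNAPIN", "MYOM1")
  net <- build_network(ints)
  known <- tibble::tibble(protein_a = "snapin.2", protein_b = "Dysf")
  ov <- literature_overlap(net, known)
  expect_equal(ov$n_known, 1L)
  expect_equal(ov$fraction, 0.5)
  expect_equal(ov$by_category$n_known[ov$by_category$pbs == "A"], 1L)
})
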