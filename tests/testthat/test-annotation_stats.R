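pair_net <- function(pairs, pbs = "A") {
  ints <- dplyr::bind_rows(lapply(seq_along(pairs), function(i) {
    dplyr::mutate(make_interactions(pbs[min(i, length(pbs))]),
                  bait_protein = pairs[[i]][1], prey_protein = pairs[[i]][2])
  }))
  build_network(ints)
}

test_that("pairs share an aspect iff their cluster sets intersect", {
  net <- pair_net(list(c("A", "B"), c("C", "D"), c("E", "F")))
  clusters <- tibble::tibble(
    protein = c("A", "B", "B", "C", "D", "E"),
    aspect = c("BP", "BP", "BP", "MF", "MF", "BP"),
    cluster_id = c("c1", "c1", "c2", "m1", "m2", "c9")
  )
  sp <- shared_pairs(net, clusters)
  got <- sp$pairs[order(sp$pairs$protein_a), ]
  expect_equal(got$shares_bp, c(TRUE, FALSE, FALSE))
  expect_equal(got$shares_any, c(TRUE, FALSE, FALSE))
  expect_equal(sp$summary$fraction[sp$summary$aspect == "any"], 1 / 3)
})

test_that("shared-pair flags are symmetric in the two proteins", {
  clusters <- tibble::tibble(protein = c("A", "B"), aspect = "CC",
                             cluster_id = "k1")
  n1 <- pair_net(list(c("A", "B")))
  n2 <- pair_net(list(c("B", "A")))
  expect_equal(shared_pairs(n1, clusters)$summary,
               shared_pairs(n2, clusters)$summary)
})

test_that("a ten-edge network with three sharing pairs reports 30%", {
  pairs <- lapply(1:10, function(i) c(sprintf("L%02d", i), sprintf("R%02d", i)))
  net <- pair_net(pairs)
  clusters <- dplyr::bind_rows(lapply(1:3, function(i) {
    tibble::tibble(protein = c(sprintf("L%02d", i), sprintf("R%02d", i)),
                   aspect = "BP", cluster_id = sprintf("c%d", i))
  }))
  sp <- shared_pairs(net, clusters)
  expect_equal(sp$summary$fraction[sp$summary$aspect == "any"], 0.3)
})

test_that("the sharing background expectation follows the stated ratio", {
  # two baits each sharing a cluster with half of a 10-protein proteome
  proteome <- tibble::tibble(
    protein = sprintf("q%02d", 1:10),
    aspect = "BP",
    cluster_id = rep(c("left", "right"), each = 5)
  )
  bg <- sharing_background(c("q01", "q06"), proteome, proteome_size = 10)
  expect_equal(bg$per_bait$shared_i, c(5L, 5L))
  expect_equal(bg$per_bait$nonshared_i, c(5L, 5L))
  expect_equal(bg$expected_frequency, 0.5)
})

test_that("chi-square is zero with p = 1 when observed equals expected", {
  proteome <- tibble::tibble(protein = sprintf("q%02d", 1:10), aspect = "BP",
                             cluster_id = rep(c("a", "b"), each = 5))
  bg <- sharing_background(c("q01", "q06"), proteome, proteome_size = 10,
                           observed_shared = 50, observed_pairs = 100)
  expect_equal(bg$chisq$statistic, 0)
  expect_equal(bg$chisq$p_value, 1)
})

test_that("the chi-square statistic equals the direct O/E formula", {
  set.seed(23)
  proteome <- tibble::tibble(
    protein = rep(sprintf("q%02d", 1:20), each = 2),
    aspect = sample(c("BP", "CC", "MF"), 40, replace = TRUE),
    cluster_id = sample(sprintf("c%d", 1:6), 40, replace = TRUE)
  )
  bg <- sharing_background(c("q01", "q02", "q03"), proteome, proteome_size = 20,
                           observed_shared = 17, observed_pairs = 60)
  e <- bg$expected_frequency * 60
  want <- (17 - e)^2 / e + ((60 - 17) - (60 - e))^2 / (60 - e)
  expect_equal(bg$chisq$statistic, want)
  expect_equal(bg$chisq$p_value,
               stats::pchisq(want, df = 1, lower.tail = FALSE))
})

test_that("baits missing from the proteome cluster table are an error", {
  proteome <- tibble::tibble(protein = "q01", aspect = "BP", cluster_id = "c")
  expect_error(sharing_background(c("q01", "zz9"), proteome, 10), "zz9")
})

test_that("EASE decrements the overlap so single-gene overlaps never enrich", {
  proteome <- sprintf("g%02d", 1:20)
  res <- ease_enrichment("g01", list(term1 = "g01"), proteome)
  expect_equal(res$ease_p, 1)
  # overlap 10 of 10 against a 10-protein term in a 20-protein universe:
  # EASE equals the hypergeometric tail at overlap 9 with margins unchanged
  res2 <- ease_enrichment(proteome[1:10], list(t = proteome[1:10]), proteome)
  expect_equal(res2$ease_p, oracle_hyper_upper(9, 10, 20, 10), tolerance = 1e-12)
  expect_equal(res2$fisher_p, oracle_hyper_upper(10, 10, 20, 10), tolerance = 1e-12)
  # a term absent from the gene set is never enriched
  res3 <- ease_enrichment(proteome[1:5], list(t = proteome[6:10]), proteome)
  expect_equal(res3$ease_p, 1)
  expect_equal(nrow(ease_enrichment(character(), list(t = "g01"), proteome)), 0L)
})

test_that("the EASE p-value never undercuts the classical Fisher p-value", {
  set.seed(41)
  proteome <- sprintf("g%03d", 1:60)
  for (i in 1:20) {
    gene_set <- sample(proteome, sample(3:20, 1))
    term <- list(t = sample(proteome, sample(3:30, 1)))
    res <- ease_enrichment(gene_set, term, proteome)
    expect_gte(res$ease_p, res$fisher_p - 1e-12)
    k <- res$n_overlap
    expect_equal(res$fisher_p,
                 oracle_hyper_upper(k, res$n_term, 60, length(gene_set)),
                 tolerance = 1e-9)
    expect_equal(res$ease_p,
                 oracle_hyper_upper(max(k - 1, 0), res$n_term, 60, length(gene_set)),
                 tolerance = 1e-9)
  }
})

test_that("disease overlays count records and proteins separately", {
  net <- pair_net(list(c("A", "B"), c("B", "C"), c("C", "D"), c("E", "F")))
  ann <- tibble::tibble(
    protein = c("A", "A", "B", "C", "Z"),
    class = c("myopathy", "cardiomyopathy", "neuropathy", "non-NMD", "myopathy")
  )
  ov <- disease_overlay(net, ann)
  cc <- setNames(ov$class_counts$n_records, ov$class_counts$class)
  expect_equal(unname(cc["myopathy"]), 1L) # Z is not in the network
  expect_equal(sum(ov$class_counts$n_records), 4L)
  expect_equal(ov$n_disease_proteins, 3L)
  expect_equal(ov$n_nmd_proteins, 2L)
  # induced subgraph on {A, B, C}: edges A-B and B-C survive
  expect_equal(nrow(ov$subnetwork$edges), 2L)
  expect_setequal(ov$subnetwork$nodes, c("A", "B", "C"))
})

test_that("empty disease annotations give all-zero overlays", {
  net <- pair_net(list(c("A", "B")))
  ov <- disease_overlay(net, tibble::tibble(protein = character(),
                                            class = character()))
  expect_true(all(ov$class_counts$n_records == 0L))
  expect_equal(nrow(ov$subnetwork$edges), 0L)
})

test_that("class over-representation uses one-sided exact tails", {
  ann <- tibble::tibble(protein = sprintf("m%02d", 1:5), class = "myopathy")
  background <- c(sprintf("m%02d", 1:5), sprintf("x%03d", 1:100))
  res <- class_overrepresentation(sprintf("m%02d", 1:5), ann, background)
  myo <- res[res$class == "myopathy", ]
  expect_lt(myo$p_value, 0.05)
  expect_equal(myo$p_value, oracle_hyper_upper(5, 5, 105, 5), tolerance = 1e-9)
  expect_equal(res$p_value[res$class == "neuropathy"], 1)

  # enrichment direction inverts when the partner set avoids the class
  res2 <- class_overrepresentation(sprintf("x%03d", 1:5), ann, background)
  expect_gt(res2$p_value[res2$class == "myopathy"],
            myo$p_value)
})

test_that("locus candidates intersect locus genes with the network", {
  loci <- tibble::tibble(
    locus_id = c(rep("LGMD1F", 20), rep("LGMD1E", 5), rep("LGMD1G", 3)),
    gene = c(sprintf("f%02d", 1:19), "FLNC", sprintf("e%02d", 1:5),
             c("SEC31A", "AAA1", "AAA2"))
  )
  res <- locus_candidates(loci, c("FLNC", "SEC31A", "AAA1", "AAA2", "TTN"))
  res <- res[order(res$locus_id), ]
  expect_equal(res$n_candidates[res$locus_id == "LGMD1E"], 0L)
  expect_equal(res$candidates[res$locus_id == "LGMD1F"], "FLNC")
  expect_true(res$unique_candidate[res$locus_id == "LGMD1F"])
  expect_equal(res$n_candidates[res$locus_id == "LGMD1G"], 3L)
  expect_false(res$unique_candidate[res$locus_id == "LGMD1G"])
})
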