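# Minimal interaction evidence rows for rule tests.
evidence_row <- function(bait, prey, screens = "S1", support = 3L,
                         singleton = FALSE, promiscuity = 1L) {
  tibble::tibble(bait_protein = bait, prey_protein = prey, screens = screens,
                 sid_starts = "10", sid_stops = "100", n_sids = 1L,
                 n_clones = support, n_distinct_fragments = support,
                 support_score = as.integer(support),
                 all_singleton = singleton, reciprocal = FALSE,
                 in_cycle = FALSE, promiscuity = as.integer(promiscuity))
}

test_that("reciprocal detection requires both orientations and two proteins", {
  ints <- dplyr::bind_rows(evidence_row("X", "Y"), evidence_row("Y", "X"),
                           evidence_row("X", "Z"), evidence_row("W", "W"))
  expect_equal(detect_reciprocal(ints), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("triangle membership flags exactly the cycle edges", {
  tri <- dplyr::bind_rows(evidence_row("A", "B"), evidence_row("B", "C"),
                          evidence_row("C", "A"))
  expect_true(all(detect_cycles(tri)))
  path <- dplyr::bind_rows(evidence_row("A", "B"), evidence_row("B", "C"))
  expect_false(any(detect_cycles(path)))
})

test_that("triangle flags match exhaustive enumeration on random graphs", {
  for (seed in 1:4) {
    set.seed(seed)
    nodes <- sprintf("n%02d", 1:30)
    a <- sample(nodes, 60, replace = TRUE)
    b <- sample(nodes, 60, replace = TRUE)
    pairs <- unique(data.frame(a = pmin(a, b), b = pmax(a, b)))
    pairs <- pairs[pairs$a != pairs$b, ]
    ints <- dplyr::bind_rows(lapply(seq_len(nrow(pairs)), function(i) {
      evidence_row(pairs$a[i], pairs$b[i])
    }))
    got <- detect_cycles(ints)
    want <- oracle_triangle_edges(tolower(pairs$a), tolower(pairs$b))
    expect_equal(got, want)
  }
})

test_that("promiscuity counts distinct bait proteins, not bait domains", {
  registry <- tibble::tibble(
    screen_id = sprintf("S%02d", 1:14),
    bait_protein = c(sprintf("bait%02d", 1:12), "bait01", "bait02"),
    prey_protein = "sticky",
    sid_start = 40L, sid_stop = 120L,
    n_clones = 1L, n_distinct_fragments = 1L, singleton = TRUE
  )
  expect_equal(promiscuity_count("sticky", 50L, 100L, registry), 12L)
  # two screens (bait domains) of the same protein count once
  same_bait <- registry[registry$bait_protein == "bait01", ]
  expect_equal(promiscuity_count("sticky", 50L, 100L, same_bait), 1L)
  # non-overlapping SIDs do not count
  expect_equal(promiscuity_count("sticky", 300L, 400L, registry), 0L)
})

test_that("the category rules apply in strict precedence order", {
  cfg <- y2h_config(false_positive_preys = "HSP70")
  rows <- dplyr::bind_rows(
    dplyr::mutate(evidence_row("X", "HSP70", promiscuity = 20), reciprocal = TRUE),
    evidence_row("X", "sticky", promiscuity = 11),
    evidence_row("X", "solo", support = 1L, singleton = TRUE),
    dplyr::mutate(evidence_row("X", "Y"), reciprocal = TRUE),
    evidence_row("X", "strong", support = 6L),
    evidence_row("X", "mid", support = 4L),
    evidence_row("X", "weak", support = 2L),
    dplyr::mutate(evidence_row("X", "cyc", support = 2L), in_cycle = TRUE)
  )
  expect_equal(assign_pbs(rows, cfg),
               c("excluded", "E", "D", "A", "A", "B", "C", "B"))
})

test_that("a promiscuous reciprocal interaction is demoted to E with a note", {
  rows <- dplyr::mutate(evidence_row("X", "sticky", promiscuity = 15),
                        reciprocal = TRUE)
  expect_message(pbs <- assign_pbs(rows, y2h_config()), "demoted")
  expect_equal(pbs, "E")
})

test_that("raising the promiscuity threshold never moves interactions into E", {
  set.seed(5)
  rows <- dplyr::bind_rows(lapply(1:40, function(i) {
    evidence_row("X", sprintf("p%02d", i), support = sample(1:8, 1),
                 singleton = sample(c(TRUE, FALSE), 1),
                 promiscuity = sample(1:20, 1))
  }))
  rows$all_singleton <- rows$all_singleton & rows$support_score == 1L
  low <- assign_pbs(rows, y2h_config(promiscuity_threshold = 8))
  high <- assign_pbs(rows, y2h_config(promiscuity_threshold = 15))
  expect_true(all(!(high == "E" & low != "E")))
})

test_that("an independent confirming screen never demotes a category", {
  base <- evidence_row("X", "Y", screens = "S1", support = 3L)
  more <- evidence_row("X", "Y", screens = "S1;S2", support = 5L)
  expect_lte(match(assign_pbs(more, y2h_config()), c("A", "B", "C", "D", "E")),
             match(assign_pbs(base, y2h_config()), c("A", "B", "C", "D", "E")))
})

test_that("a pluggable p-value scorer honours the printed cutoffs", {
  rows <- dplyr::bind_rows(evidence_row("X", "p1"), evidence_row("X", "p2"),
                           evidence_row("X", "p3"), evidence_row("X", "p4"))
  pv <- c(1e-12, 1e-7, 1e-3, 0.5)
  got <- assign_pbs(rows, y2h_config(), pvalue_fn = function(ints) {
    pv[match(ints$prey_protein, rows$prey_protein)]
  })
  expect_equal(got, c("A", "B", "C", "D"))
})

test_that("category tables report counts, A-E fractions and exclusions", {
  ints <- make_interactions(c(rep("A", 3), rep("D", 6), "excluded"))
  tab <- category_table(ints)
  expect_equal(tab$n[tab$pbs == "A"], 3L)
  expect_equal(sum(tab$fraction[tab$pbs %in% c("A", "B", "C", "D", "E")]), 1)
  expect_true(is.na(tab$fraction[tab$pbs == "excluded"]))
  expect_equal(nrow(category_table(make_interactions(character()))), 0L)
})

test_that("scoring a screen set is exhaustive and preserves clone provenance", {
  sim <- simulate_screen_set(sim_config(n_baits = 5, n_proteins = 60, n_promiscuous_preys = 0,
                                        n_true_ppis = 10, rng_seed = 3))
  ints <- score_interactions(sim$screen_data)
  expect_true(all(ints$pbs %in% c("A", "B", "C", "D", "E", "excluded")))
  expect_equal(sum(ints$n_clones), nrow(sim$screen_data$fragments))
})

test_that("known false-positive preys are excluded with a warning", {
  screens <- tibble::tibble(screen_id = "S1", bait_protein = "DYSF",
                            bait_start = 1L, bait_stop = 100L)
  frags <- tibble::tibble(screen_id = "S1", prey_protein = c("HSP70", "TTN"),
                          clone_id = c("c1", "c2"),
                          frag_start = 1L, frag_stop = 50L)
  expect_warning(
    ints <- score_interactions(list(screens = screens, fragments = frags),
                               y2h_config(false_positive_preys = "HSP70")),
    "excluded")
  expect_equal(ints$pbs[ints$prey_protein == "HSP70"], "excluded")
  expect_equal(ints$pbs[ints$prey_protein == "TTN"], "D")
})
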