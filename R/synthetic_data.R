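#' Simulation configuration for synthetic screen sets
#'
#' Defaults emulate the screening campaign the pipeline was designed for:
#' random-primed cDNA fragments averaging ~600 bp (200 aa) with spread
#' sd = mean/3 and a 30 aa floor, an average of 155 processed positive
#' clones per bait screen, saturation screening approximated by a 0.9
#' per-screen detection probability for true interactions, plus singleton
#' noise clones and promiscuous ("sticky") preys recurring across unrelated
#' bait screens.
#'
#' @param n_baits Number of bait proteins (one full-size screen each).
#' @param n_proteins Proteome size of the simulated library.
#' @param protein_length_range Min/max protein length (aa).
#' @param mean_fragment_length Mean prey fragment length in aa (default 200,
#'   i.e. ~600 bp of coding sequence).
#' @param clones_per_screen Mean number of processed positive clones per
#'   screen (default 155).
#' @param n_true_ppis Number of planted true interactions.
#' @param noise_singletons_per_screen Spurious single-clone preys per screen.
#' @param n_promiscuous_preys Number of sticky preys.
#' @param promiscuous_breadth Screens (distinct baits) in which each sticky
#'   prey shows up.
#' @param detection_prob Per-screen probability that a planted interaction
#'   of the screened bait is detected at all.
#' @param rng_seed Integer seed; every simulation is reproducible under it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_baits = 15L, n_proteins = 300L,
                       protein_length_range = c(200L, 1500L),
                       mean_fragment_length = 200L,
                       clones_per_screen = 155L,
                       n_true_ppis = 60L,
                       noise_singletons_per_screen = 20L,
                       n_promiscuous_preys = 2L,
                       promiscuous_breadth = 12L,
                       detection_prob = 0.9,
                       rng_seed = 1L) {
  cfg <- list(n_baits = as.integer(n_baits), n_proteins = as.integer(n_proteins),
              protein_length_range = as.integer(protein_length_range),
              mean_fragment_length = as.integer(mean_fragment_length),
              clones_per_screen = as.integer(clones_per_screen),
              n_true_ppis = as.integer(n_true_ppis),
              noise_singletons_per_screen = as.integer(noise_singletons_per_screen),
              n_promiscuous_preys = as.integer(n_promiscuous_preys),
              promiscuous_breadth = as.integer(promiscuous_breadth),
              detection_prob = detection_prob, rng_seed = as.integer(rng_seed))
  assert_that(all(vapply(cfg[c("n_baits", "n_proteins", "n_true_ppis",
                               "noise_singletons_per_screen",
                               "n_promiscuous_preys")], `>=`, logical(1), 0)),
              "counts must be >= 0")
  assert_that(length(cfg$protein_length_range) == 2 &&
                cfg$protein_length_range[1] <= cfg$protein_length_range[2],
              "protein_length_range must be min <= max")
  assert_that(cfg$mean_fragment_length < cfg$protein_length_range[2],
              "mean_fragment_length must be below the max protein length")
  assert_that(cfg$detection_prob > 0 && cfg$detection_prob <= 1,
              "detection_prob must be in (0, 1]")
  assert_that(cfg$n_promiscuous_preys == 0 || cfg$promiscuous_breadth <= cfg$n_baits,
              "promiscuous_breadth cannot exceed n_baits")
  structure(cfg, class = "sim_config")
}

# Fragment lengths: truncated normal, sd = mean/3, floored at 30 aa and at
# `at_least` (so a clone can always cover its planted domain), capped at the
# protein length.
draw_fragment_length <- function(n, cfg, at_least = 30L, at_most = Inf) {
  len <- round(stats::rnorm(n, cfg$mean_fragment_length,
                            cfg$mean_fragment_length / 3))
  as.integer(pmin(pmax(len, 30L, at_least), at_most))
}

#' Simulate a proteome with annotations
#'
#' Generates protein lengths (uniform over the configured range), GO
#' cluster memberships per aspect, domain annotations and disease classes,
#' reproducibly under the configuration seed.
#'
#' @param cfg A [sim_config()].
#' @param n_go_clusters,n_domain_accs Pool sizes for cluster and domain
#'   accessions.
#' @param go_prob Probability that a protein carries an annotation in a
#'   given aspect.
#' @param disease_probs Named probabilities for the disease classes; the
#'   remainder is non-diseased.
#' @return List of tibbles: `proteins` (`protein`, `length`), `go_clusters`
#'   (`protein`, `aspect`, `cluster_id`), `domains` (`protein`,
#'   `domain_acc`, `start`, `stop`), `diseases` (`protein`, `class`).
#' @export
simulate_proteome <- function(cfg, n_go_clusters = 40L, n_domain_accs = 30L,
                              go_prob = 0.8,
                              disease_probs = c(myopathy = 0.04,
                                                cardiomyopathy = 0.02,
                                                neuropathy = 0.02,
                                                metabolic = 0.01,
                                                excitation = 0.005,
                                                unclassified = 0.005,
                                                `non-NMD` = 0.1)) {
  set.seed(cfg$rng_seed)
  n <- cfg$n_proteins
  empty <- function(...) tibble::tibble(...)
  if (n == 0) {
    return(list(proteins = empty(protein = character(), length = integer()),
                go_clusters = empty(protein = character(), aspect = character(),
                                    cluster_id = character()),
                domains = empty(protein = character(), domain_acc = character(),
                                start = integer(), stop = integer()),
                diseases = empty(protein = character(), class = character())))
  }
  proteins <- tibble::tibble(
    protein = sprintf("P%04d", seq_len(n)),
    length = sample(cfg$protein_length_range[1]:cfg$protein_length_range[2],
                    n, replace = TRUE)
  )
  go <- purrr::map_dfr(GO_ASPECTS, function(aspect) {
    has <- stats::runif(n) < go_prob
    k <- sample(1:3, sum(has), replace = TRUE)
    tibble::tibble(
      protein = rep(proteins$protein[has], k),
      aspect = aspect,
      cluster_id = sprintf("%s%02d", tolower(aspect),
                           sample.int(n_go_clusters, sum(k), replace = TRUE))
    ) |> dplyr::distinct()
  })
  n_dom <- stats::rpois(n, 1.2)
  dom_rows <- rep(seq_len(n), n_dom)
  dom_len <- pmin(sample(40:120, length(dom_rows), replace = TRUE),
                  proteins$length[dom_rows])
  dom_start <- vapply(seq_along(dom_rows), function(i) {
    sample.int(proteins$length[dom_rows[i]] - dom_len[i] + 1L, 1)
  }, integer(1))
  domains <- tibble::tibble(
    protein = proteins$protein[dom_rows],
    domain_acc = sprintf("IPR%06d", sample.int(n_domain_accs, length(dom_rows),
                                               replace = TRUE)),
    start = dom_start,
    stop = dom_start + dom_len - 1L
  )
  cls <- sample(c(names(disease_probs), "none"), n, replace = TRUE,
                prob = c(disease_probs, 1 - sum(disease_probs)))
  diseases <- tibble::tibble(protein = proteins$protein, class = cls) |>
    dplyr::filter(.data$class != "none")
  list(proteins = proteins, go_clusters = go, domains = domains,
       diseases = diseases)
}

#' Plant the ground truth of a simulated screen campaign
#'
#' Samples the bait panel, the true interactions (each with an interaction
#' domain on its prey that every supporting clone must cover) and the sticky
#' preys with the unrelated bait screens they will recur in.
#'
#' @param cfg A [sim_config()].
#' @param proteome Output of [simulate_proteome()].
#' @return List of class `ground_truth`: `baits`, `true_ppis` (`bait`,
#'   `prey`, `domain_start`, `domain_stop`), `sticky_preys` (`prey`,
#'   `core_start`, `core_stop`, `baits`), `noise_records` (filled in by
#'   [simulate_screens()]).
#' @export
simulate_truth <- function(cfg, proteome) {
  set.seed(cfg$rng_seed + 1L)
  prot <- proteome$proteins
  assert_that(nrow(prot) >= cfg$n_baits + cfg$n_promiscuous_preys + 1,
              "proteome too small for the requested bait/sticky counts")
  baits <- sample(prot$protein, cfg$n_baits)
  non_bait <- setdiff(prot$protein, baits)
  sticky <- sample(non_bait, cfg$n_promiscuous_preys)
  candidates <- setdiff(prot$protein, sticky)
  pairs <- expand.grid(bait = baits, prey = candidates,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$bait != pairs$prey, , drop = FALSE]
  pick <- pairs[sample.int(nrow(pairs), min(cfg$n_true_ppis, nrow(pairs))), ]
  plen <- setNames(prot$length, prot$protein)
  dlen <- pmin(sample(30:100, nrow(pick), replace = TRUE), plen[pick$prey])
  dstart <- vapply(seq_len(nrow(pick)), function(i) {
    sample.int(plen[pick$prey[i]] - dlen[i] + 1L, 1)
  }, integer(1))
  true_ppis <- tibble::tibble(bait = pick$bait, prey = pick$prey,
                              domain_start = dstart,
                              domain_stop = dstart + dlen - 1L)
  sticky_preys <- tibble::tibble(
    prey = sticky,
    core_start = 1L,
    core_stop = pmin(150L, plen[sticky]),
    baits = lapply(seq_along(sticky), function(i) {
      sample(baits, cfg$promiscuous_breadth)
    })
  )
  structure(list(baits = baits, true_ppis = true_ppis,
                 sticky_preys = sticky_preys,
                 noise_records = NULL),
            class = "ground_truth")
}

#' Simulate the clone-level output of all screens
#'
#' For each bait screen: every planted interaction of the bait is detected
#' with probability `detection_prob`, contributing clones whose fragments
#' all cover the planted interaction domain (fragment lengths from the
#' configured distribution, positions uniform subject to coverage); noise
#' preys are emitted as single clones at random positions; sticky preys are
#' emitted in their assigned screens. The per-screen clone budget
#' (`clones_per_screen`) is split evenly among the detected true preys
#' after noise and sticky clones are allocated.
#'
#' @param cfg A [sim_config()].
#' @param proteome Output of [simulate_proteome()].
#' @param truth Output of [simulate_truth()].
#' @return List: `screen_data` (`screens` + `fragments`, the same shape
#'   [read_screen_table()] returns) and `truth` with `noise_records`
#'   (tibble `screen_id`, `bait`, `prey`) filled in.
#' @export
simulate_screens <- function(cfg, proteome, truth) {
  set.seed(cfg$rng_seed + 2L)
  plen <- setNames(proteome$proteins$length, proteome$proteins$protein)
  baits <- truth$baits
  infeasible <- truth$true_ppis$domain_stop > plen[truth$true_ppis$prey]
  if (any(infeasible)) {
    stop("config error: planted domain extends beyond its prey for pair(s) ",
         paste(truth$true_ppis$bait[infeasible], truth$true_ppis$prey[infeasible],
               sep = "-", collapse = ", "))
  }
  # detection draws come from their own stream so that screen sets simulated
  # from the same seed share the detection pattern regardless of clone budget
  detect_rng <- local({
    set.seed(cfg$rng_seed + 3L)
    u <- stats::runif(nrow(truth$true_ppis))
    set.seed(cfg$rng_seed + 2L)
    setNames(u < cfg$detection_prob,
             paste(truth$true_ppis$bait, truth$true_ppis$prey))
  })
  cover_clone <- function(prey, d_start, d_stop) {
    L <- draw_fragment_length(1, cfg, at_least = d_stop - d_start + 1L,
                              at_most = plen[[prey]])
    lo <- max(1L, d_stop - L + 1L)
    start <- if (lo >= d_start) lo else sample(lo:d_start, 1)
    as.integer(c(start, min(start + L - 1L, plen[[prey]])))
  }
  frag_list <- list()
  noise_list <- list()
  screens <- tibble::tibble(
    screen_id = sprintf("S%03d", seq_along(baits)),
    bait_protein = baits,
    bait_start = 1L,
    bait_stop = as.integer(pmin(400L, plen[baits])),
    tested_diploids = 103000000L
  )
  for (i in seq_along(baits)) {
    sid <- screens$screen_id[i]
    bait <- baits[i]
    rows <- list()
    sticky_here <- truth$sticky_preys[
      vapply(truth$sticky_preys$baits, function(b) bait %in% b, logical(1)), ,
      drop = FALSE]
    planted <- truth$true_ppis[truth$true_ppis$bait == bait, , drop = FALSE]
    detected <- planted[detect_rng[paste(planted$bait, planted$prey)], ,
                        drop = FALSE]
    budget <- max(0L, cfg$clones_per_screen - cfg$noise_singletons_per_screen -
                    nrow(sticky_here))
    if (nrow(detected)) {
      per_prey <- max(2L, budget %/% nrow(detected))
      for (j in seq_len(nrow(detected))) {
        ints <- t(vapply(seq_len(per_prey), function(k) {
          cover_clone(detected$prey[j], detected$domain_start[j],
                      detected$domain_stop[j])
        }, integer(2)))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          prey_protein = detected$prey[j],
          frag_start = ints[, 1], frag_stop = ints[, 2])
      }
    }
    if (nrow(sticky_here)) {
      for (j in seq_len(nrow(sticky_here))) {
        int <- cover_clone(sticky_here$prey[j], sticky_here$core_start[j],
                           sticky_here$core_stop[j])
        rows[[length(rows) + 1L]] <- tibble::tibble(
          prey_protein = sticky_here$prey[j],
          frag_start = int[1], frag_stop = int[2])
      }
    }
    # noise records stay disjoint from planted and sticky pairs by
    # construction: spurious clones never land on those preys
    noise_pool <- setdiff(names(plen),
                          c(truth$sticky_preys$prey, planted$prey))
    if (cfg$noise_singletons_per_screen > 0 && length(noise_pool)) {
      preys <- sample(noise_pool, cfg$noise_singletons_per_screen,
                      replace = TRUE)
      L <- draw_fragment_length(length(preys), cfg, at_most = plen[preys])
      start <- vapply(seq_along(preys), function(k) {
        sample.int(plen[[preys[k]]] - L[k] + 1L, 1)
      }, integer(1))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        prey_protein = preys, frag_start = start, frag_stop = start + L - 1L)
      noise_list[[length(noise_list) + 1L]] <- tibble::tibble(
        screen_id = sid, bait = bait, prey = preys)
    }
    if (length(rows)) {
      sf <- dplyr::bind_rows(rows)
      sf$screen_id <- sid
      sf$clone_id <- sprintf("%s_c%04d", sid, seq_len(nrow(sf)))
      frag_list[[length(frag_list) + 1L]] <- sf
    }
  }
  fragments <- if (length(frag_list)) {
    dplyr::bind_rows(frag_list)[, c("screen_id", "prey_protein", "clone_id",
                                    "frag_start", "frag_stop")]
  } else {
    tibble::tibble(screen_id = character(), prey_protein = character(),
                   clone_id = character(), frag_start = integer(),
                   frag_stop = integer())
  }
  fragments$frag_start <- as.integer(fragments$frag_start)
  fragments$frag_stop <- as.integer(fragments$frag_stop)
  screens$processed_clones <- as.integer(
    table(factor(fragments$screen_id, levels = screens$screen_id)))
  truth$noise_records <- if (length(noise_list)) {
    dplyr::bind_rows(noise_list)
  } else {
    tibble::tibble(screen_id = character(), bait = character(),
                   prey = character())
  }
  list(screen_data = list(screens = screens, fragments = fragments),
       truth = truth)
}

#' Simulate a full screen set (proteome, ground truth, clone tables)
#'
#' Orchestrates [simulate_proteome()], [simulate_truth()] and
#' [simulate_screens()] under one configuration; deterministic given the
#' configuration seed.
#'
#' @param cfg A [sim_config()].
#' @return List: `proteome`, `truth`, `screen_data`.
#' @export
simulate_screen_set <- function(cfg = sim_config()) {
  proteome <- simulate_proteome(cfg)
  truth <- simulate_truth(cfg, proteome)
  sim <- simulate_screens(cfg, proteome, truth)
  list(proteome = proteome, truth = sim$truth, screen_data = sim$screen_data)
}

#' Parameter-recovery report against planted ground truth
#'
#' Compares the scored interactions of a simulated screen set with the
#' planted truth: per-origin confusion counts over PBS categories, the
#' headline recall (fraction of planted interactions landing in PBS A-C),
#' the analogous rate for injected singleton noise, and the PBS-E rate for
#' sticky preys.
#'
#' @param interactions Scored interaction tibble ([score_interactions()]).
#' @param truth Ground truth with `noise_records` filled in.
#' @return List with `confusion` (tibble origin x category, including
#'   `missed`), `recall_abc` (`NA` when nothing was planted),
#'   `noise_abc_rate`, `sticky_e_rate` and `sticky_misses` (sticky bait-prey
#'   pairs not categorized E).
#' @export
recovery_report <- function(interactions, truth) {
  int_key <- pair_key(interactions$bait_protein, interactions$prey_protein)
  cat_of <- function(keys) {
    idx <- match(keys, int_key)
    ifelse(is.na(idx), "missed", interactions$pbs[idx])
  }
  planted_key <- unique(pair_key(truth$true_ppis$bait, truth$true_ppis$prey))
  sticky_key <- unique(unlist(purrr::map2(
    truth$sticky_preys$prey, truth$sticky_preys$baits,
    function(p, bs) pair_key(bs, rep(p, length(bs))))))
  noise_key <- unique(pair_key(truth$noise_records$bait,
                               truth$noise_records$prey))
  noise_key <- setdiff(noise_key, c(planted_key, sticky_key))
  cats <- list(planted = cat_of(planted_key),
               noise = cat_of(noise_key),
               sticky = cat_of(sticky_key))
  lv <- c(PBS_LEVELS, "excluded", "missed")
  confusion <- purrr::imap_dfr(cats, function(x, origin) {
    tibble::tibble(origin = origin, category = lv,
                   n = as.integer(table(factor(x, levels = lv))))
  })
  abc_rate <- function(x) if (length(x)) mean(x %in% c("A", "B", "C")) else NA_real_
  e_rate <- function(x) if (length(x)) mean(x == "E") else NA_real_
  list(confusion = confusion,
       recall_abc = abc_rate(cats$planted),
       noise_abc_rate = abc_rate(cats$noise),
       sticky_e_rate = e_rate(cats$sticky),
       sticky_misses = sticky_key[cats$sticky != "E"])
}
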