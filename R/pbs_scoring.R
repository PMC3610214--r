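#' Aggregate SIDs into bait-prey interactions
#'
#' Collapses a SID table to one row per ordered (bait protein, prey protein)
#' pair, pooling evidence across all screens of that bait: supporting
#' screens, SID coordinates, clone counts, and the fragment-support score
#' (the number of distinct fragment intervals summed over SIDs). An
#' interaction whose every supporting SID is a singleton is marked
#' `all_singleton`.
#'
#' @param sids SID tibble from [compute_sids()].
#' @return Interaction tibble (one row per ordered pair) with evidence
#'   columns; `reciprocal`, `in_cycle`, `promiscuity` and `pbs` are added by
#'   the scoring steps.
#' @export
build_interactions <- function(sids) {
  if (!nrow(sids)) {
    return(tibble::tibble(bait_protein = character(), prey_protein = character(),
                          screens = character(), sid_starts = character(),
                          sid_stops = character(), n_sids = integer(),
                          n_clones = integer(), n_distinct_fragments = integer(),
                          support_score = integer(), all_singleton = logical()))
  }
  sids |>
    dplyr::group_by(.data$bait_protein, .data$prey_protein) |>
    dplyr::summarise(
      screens = paste(sort(unique(.data$screen_id)), collapse = ";"),
      sid_starts = paste(.data$sid_start, collapse = ";"),
      sid_stops = paste(.data$sid_stop, collapse = ";"),
      n_sids = dplyr::n(),
      n_clones = as.integer(sum(.data$n_clones)),
      n_distinct_fragments = as.integer(sum(.data$n_distinct_fragments)),
      support_score = as.integer(sum(.data$n_distinct_fragments)),
      all_singleton = all(.data$singleton),
      .groups = "drop"
    )
}

#' Flag reciprocally detected interactions
#'
#' An interaction is reciprocal when its unordered pair was found with each
#' partner serving as bait in some screen (X as bait finding Y, and Y as
#' bait finding X). A homodimer found in a single orientation is not
#' reciprocal.
#'
#' @param interactions Interaction tibble with `bait_protein` and
#'   `prey_protein` columns.
#' @return Logical vector along the rows of `interactions`.
#' @export
detect_reciprocal <- function(interactions) {
  if (!nrow(interactions)) return(logical())
  fwd <- paste(normalize_protein_id(interactions$bait_protein),
               normalize_protein_id(interactions$prey_protein))
  rev <- paste(normalize_protein_id(interactions$prey_protein),
               normalize_protein_id(interactions$bait_protein))
  rev %in% fwd &
    normalize_protein_id(interactions$bait_protein) !=
      normalize_protein_id(interactions$prey_protein)
}

#' Flag interactions lying on a triangle (interaction cycle X-Y, Y-Z, X-Z)
#'
#' The network is taken as unordered and deduplicated; self-loops never form
#' triangles.
#'
#' @param interactions Interaction tibble with `bait_protein` and
#'   `prey_protein` columns.
#' @return Logical vector: TRUE where the interaction's edge is part of at
#'   least one triangle.
#' @export
detect_cycles <- function(interactions) {
  if (!nrow(interactions)) return(logical())
  a <- normalize_protein_id(interactions$bait_protein)
  b <- normalize_protein_id(interactions$prey_protein)
  keep <- a != b
  keys <- unique(pair_key(a[keep], b[keep]))
  if (!length(keys)) return(rep(FALSE, nrow(interactions)))
  ends <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
  # an edge is on a triangle iff its endpoints share a common neighbour
  # (self-loops were removed, so the endpoints themselves never qualify)
  nbr <- lapply(split(c(ends[, 2], ends[, 1]), c(ends[, 1], ends[, 2])), unique)
  on_tri <- setNames(vapply(seq_len(nrow(ends)), function(i) {
    length(intersect(nbr[[ends[i, 1]]], nbr[[ends[i, 2]]])) > 0
  }, logical(1)), keys)
  flags <- rep(FALSE, nrow(interactions))
  flags[keep] <- unname(on_tri[pair_key(a[keep], b[keep])])
  flags
}

#' Count unrelated bait proteins detecting an overlapping prey SID
#'
#' Promiscuity of a prey SID: the number of *distinct bait proteins* (not
#' bait domains — two domains of one protein are related) whose screens, in
#' the supplied registry, yielded a SID on the same prey overlapping the
#' query SID by at least one residue.
#'
#' @param prey_protein Prey protein identifier.
#' @param sid_start,sid_stop Query SID coordinates.
#' @param registry SID tibble spanning all screens ([compute_sids()] output).
#' @return Integer count of distinct bait proteins.
#' @export
promiscuity_count <- function(prey_protein, sid_start, sid_stop, registry) {
  hit <- normalize_protein_id(registry$prey_protein) ==
    normalize_protein_id(prey_protein) &
    intervals_overlap(registry$sid_start, registry$sid_stop, sid_start, sid_stop)
  dplyr::n_distinct(normalize_protein_id(registry$bait_protein[hit]))
}

interaction_promiscuity <- function(interactions, registry) {
  if (!nrow(interactions)) return(integer())
  vapply(seq_len(nrow(interactions)), function(i) {
    starts <- as.integer(strsplit(interactions$sid_starts[i], ";")[[1]])
    stops <- as.integer(strsplit(interactions$sid_stops[i], ";")[[1]])
    max(vapply(seq_along(starts), function(j) {
      promiscuity_count(interactions$prey_protein[i], starts[j], stops[j], registry)
    }, integer(1)))
  }, integer(1))
}

#' Assign PBS categories
#'
#' Applies the category decision rules in strict precedence order:
#' \enumerate{
#'   \item prey on the known-false-positive exclusion list: `excluded`;
#'   \item promiscuity count strictly above `config$promiscuity_threshold`:
#'     `E` (stickiness dominates even reciprocal detection; such conflicts
#'     are reported in a message);
#'   \item singleton SID evidence in every supporting screen: `D`;
#'   \item otherwise `A`/`B`/`C` from the fragment-support score
#'     (`config$pbs_fragment_thresholds`; defaults: score >= 6 is A, >= 4
#'     is B, >= 2 is C), with reciprocal detection forcing `A` and triangle
#'     membership upgrading one level (capped at A).
#' }
#' An optional p-value scorer replaces the fragment-count score: it receives
#' the interaction tibble and returns a p-value per row, mapped through
#' `config$pbs_pvalue_thresholds` (below the A cutoff is A, etc.; at or
#' above the C cutoff falls to D).
#'
#' @param interactions Interaction tibble carrying `prey_protein`,
#'   `all_singleton`, `reciprocal`, `in_cycle`, `support_score`,
#'   `promiscuity`.
#' @param config A [y2h_config()].
#' @param pvalue_fn Optional function `interactions -> numeric p-values`.
#' @return Character vector of categories in `A, B, C, D, E, excluded`.
#' @export
assign_pbs <- function(interactions, config = y2h_config(), pvalue_fn = NULL) {
  n <- nrow(interactions)
  if (!n) return(character())
  pbs <- rep(NA_character_, n)

  excluded <- normalize_protein_id(interactions$prey_protein) %in%
    normalize_protein_id(config$false_positive_preys)
  pbs[excluded] <- "excluded"

  sticky <- !excluded & interactions$promiscuity > config$promiscuity_threshold
  pbs[sticky] <- "E"
  conflict <- sticky & interactions$reciprocal
  if (any(conflict)) {
    message(sum(conflict), " reciprocal interaction(s) demoted to PBS-E by promiscuity: ",
            paste(interactions$bait_protein[conflict],
                  interactions$prey_protein[conflict],
                  sep = "-", collapse = ", "))
  }

  singleton <- is.na(pbs) & interactions$all_singleton
  pbs[singleton] <- "D"

  open <- is.na(pbs)
  if (any(open)) {
    if (is.null(pvalue_fn)) {
      thr <- config$pbs_fragment_thresholds
      score <- interactions$support_score[open]
      base <- ifelse(score >= thr[["A"]], "A",
                     ifelse(score >= thr[["B"]], "B",
                            ifelse(score >= thr[["C"]], "C", "D")))
    } else {
      pv <- pvalue_fn(interactions[open, , drop = FALSE])
      thr <- config$pbs_pvalue_thresholds
      base <- ifelse(pv < thr[["A"]], "A",
                     ifelse(pv < thr[["B"]], "B",
                            ifelse(pv < thr[["C"]], "C", "D")))
    }
    base[interactions$reciprocal[open]] <- "A"
    upgrade <- interactions$in_cycle[open] & base %in% c("B", "C")
    base[upgrade] <- PBS_LEVELS[pbs_rank(base[upgrade]) - 1L]
    pbs[open] <- base
  }
  assert_that(!anyNA(pbs), "internal defect: unassignable PBS state")
  pbs
}

#' Score a screen set end to end
#'
#' Driver for the scoring stage: derives SIDs, aggregates them into
#' interactions, computes reciprocity, triangle and promiscuity flags, and
#' assigns PBS categories. Exclusions (known false-positive preys) are
#' reported with counts.
#'
#' @param screen_data List with `screens` and `fragments`.
#' @param config A [y2h_config()].
#' @param pvalue_fn Optional p-value scorer passed to [assign_pbs()].
#' @return Interaction tibble with a `pbs` column.
#' @export
#' @examples
#' sim <- simulate_screen_set(sim_config(n_baits = 4, n_proteins = 40,
#'                                       n_true_ppis = 6,
#'                                       n_promiscuous_preys = 0, rng_seed = 7))
#' ints <- score_interactions(sim$screen_data)
#' category_table(ints)
score_interactions <- function(screen_data, config = y2h_config(), pvalue_fn = NULL) {
  sids <- compute_sids(screen_data)
  interactions <- build_interactions(sids)
  interactions$reciprocal <- detect_reciprocal(interactions)
  interactions$in_cycle <- detect_cycles(interactions)
  interactions$promiscuity <- interaction_promiscuity(interactions, sids)
  interactions$pbs <- assign_pbs(interactions, config, pvalue_fn)
  n_excl <- sum(interactions$pbs == "excluded")
  if (n_excl) {
    warning(n_excl, " interaction(s) excluded (known false-positive preys)")
  }
  interactions
}

#' Tabulate PBS categories
#'
#' @param interactions Interaction tibble with a `pbs` column.
#' @return Tibble with one row per category present: `pbs`, `n`, `fraction`.
#'   Fractions are taken over the A-E interactions and sum to 1; excluded
#'   interactions are reported as a separate row with `fraction = NA`.
#' @export
category_table <- function(interactions) {
  if (!nrow(interactions)) {
    return(tibble::tibble(pbs = character(), n = integer(), fraction = double()))
  }
  counts <- interactions |>
    dplyr::count(pbs = factor(.data$pbs, levels = c(PBS_LEVELS, "excluded")),
                 .drop = FALSE) |>
    dplyr::mutate(pbs = as.character(.data$pbs))
  total <- sum(counts$n[counts$pbs %in% PBS_LEVELS])
  counts |>
    dplyr::mutate(fraction = dplyr::if_else(.data$pbs %in% PBS_LEVELS,
                                            .data$n / total, NA_real_)) |>
    dplyr::filter(.data$pbs %in% PBS_LEVELS | .data$n > 0)
}
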