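#' Assemble overlapping prey fragments into families
#'
#' Groups positive-clone fragments on one prey protein into families
#' (contigs) that admit a non-empty common core, the prerequisite for a
#' selected interacting domain. Fragments are sorted canonically by
#' `(frag_start, frag_stop, clone_id)`; the first unassigned fragment seeds
#' a family and each subsequent unassigned fragment joins iff it intersects
#' the family's running core (the intersection of all members so far,
#' overlap meaning at least one shared residue). The scan restarts until
#' every fragment is assigned, so the partition is deterministic and
#' independent of the input row order.
#'
#' @param fragments Tibble of fragments for a single prey protein with
#'   columns `prey_protein`, `clone_id`, `frag_start`, `frag_stop` (and
#'   optionally `screen_id`).
#' @return The input tibble with an integer `family` column; rows sorted
#'   canonically. Zero rows in, zero rows out.
#' @export
#' @examples
#' frags <- tibble::tibble(prey_protein = "P1",
#'                         clone_id = c("c1", "c2", "c3"),
#'                         frag_start = c(10L, 50L, 140L),
#'                         frag_stop = c(100L, 150L, 200L))
#' assemble_families(frags)
assemble_families <- function(fragments) {
  if (!nrow(fragments)) {
    fragments$family <- integer()
    return(fragments)
  }
  assert_that(length(unique(fragments$prey_protein)) == 1,
              "assemble_families expects fragments of a single prey protein")
  assert_that(all(fragments$frag_start <= fragments$frag_stop),
              "fragment invariant violated: frag_stop < frag_start")
  ord <- order(fragments$frag_start, fragments$frag_stop, fragments$clone_id)
  fragments <- fragments[ord, , drop = FALSE]
  n <- nrow(fragments)
  family <- integer(n)
  fam_id <- 0L
  while (any(family == 0L)) {
    fam_id <- fam_id + 1L
    core <- c(NA_integer_, NA_integer_)
    for (i in which(family == 0L)) {
      s <- fragments$frag_start[i]
      e <- fragments$frag_stop[i]
      if (is.na(core[1])) {
        core <- c(s, e)
        family[i] <- fam_id
      } else if (intervals_overlap(core[1], core[2], s, e)) {
        core <- c(max(core[1], s), min(core[2], e))
        family[i] <- fam_id
      }
    }
  }
  fragments$family <- family
  fragments
}

#' Compute the selected interacting domain (SID) of a fragment family
#'
#' The SID is the common core shared by every member fragment: the
#' intersection of all member intervals. A SID is a *singleton* when it is
#' supported by a single distinct fragment interval — either one clone, or
#' several clones bearing identical start and stop positions.
#'
#' @param family Tibble of fragments forming one family (all on the same
#'   prey, non-empty common intersection).
#' @return One-row tibble: `prey_protein`, `sid_start`, `sid_stop`,
#'   `n_clones`, `n_distinct_fragments`, `singleton`.
#' @export
compute_sid <- function(family) {
  assert_that(nrow(family) >= 1, "empty fragment family")
  assert_that(length(unique(family$prey_protein)) == 1,
              "family invariant violated: multiple prey proteins")
  start <- max(family$frag_start)
  stop <- min(family$frag_stop)
  assert_that(start <= stop,
              "family invariant violated: empty common intersection")
  n_distinct <- nrow(unique(family[c("frag_start", "frag_stop")]))
  tibble::tibble(
    prey_protein = family$prey_protein[1],
    sid_start = as.integer(start),
    sid_stop = as.integer(stop),
    n_clones = nrow(family),
    n_distinct_fragments = as.integer(n_distinct),
    singleton = n_distinct == 1L
  )
}

#' Derive all SIDs of a screen set
#'
#' Runs [assemble_families()] and [compute_sid()] per `(screen_id,
#' prey_protein)` group — families are built within a screen; cross-screen
#' comparison happens downstream in promiscuity scoring — and attaches the
#' bait protein of each screen.
#'
#' @param screen_data List with `screens` and `fragments` as returned by
#'   [read_screen_table()].
#' @return Tibble with one row per SID: `screen_id`, `bait_protein`,
#'   `prey_protein`, `sid_start`, `sid_stop`, `n_clones`,
#'   `n_distinct_fragments`, `singleton`.
#' @export
compute_sids <- function(screen_data) {
  frags <- screen_data$fragments
  if (!nrow(frags)) {
    return(tibble::tibble(screen_id = character(), bait_protein = character(),
                          prey_protein = character(), sid_start = integer(),
                          sid_stop = integer(), n_clones = integer(),
                          n_distinct_fragments = integer(), singleton = logical()))
  }
  sids <- frags |>
    dplyr::group_by(.data$screen_id, .data$prey_protein) |>
    dplyr::group_modify(function(g, key) {
      g$prey_protein <- key$prey_protein
      fam <- assemble_families(g)
      fam |>
        dplyr::group_by(.data$family) |>
        dplyr::group_modify(~ compute_sid(dplyr::mutate(.x, prey_protein = key$prey_protein))) |>
        dplyr::ungroup() |>
        dplyr::select(-"family", -"prey_protein")
    }) |>
    dplyr::ungroup()
  sids |>
    dplyr::left_join(dplyr::select(screen_data$screens, "screen_id", "bait_protein"),
                     by = "screen_id") |>
    dplyr::select("screen_id", "bait_protein", "prey_protein", dplyr::everything())
}

#' Summarise a SID table
#'
#' @param sids SID tibble from [compute_sids()].
#' @param n_screens Optional number of screens for the per-screen mean;
#'   defaults to the number of distinct `screen_id`s present.
#' @return One-row tibble: `n_sids`, `mean_length` (inclusive amino-acid
#'   length, `stop - start + 1`), `n_screens`, `mean_sids_per_screen`.
#' @export
sid_summary <- function(sids, n_screens = NULL) {
  assert_that(nrow(sids) >= 1, "sid_summary needs at least one SID")
  n_screens <- n_screens %||%
    (if ("screen_id" %in% names(sids)) dplyr::n_distinct(sids$screen_id) else NA_integer_)
  tibble::tibble(
    n_sids = nrow(sids),
    mean_length = mean(interval_length(sids$sid_start, sids$sid_stop)),
    n_screens = as.integer(n_screens),
    mean_sids_per_screen = nrow(sids) / n_screens
  )
}
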