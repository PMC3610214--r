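#' Pipeline configuration
#'
#' Bundles every tunable threshold of the scoring pipeline. All values can be
#' overridden; the defaults reproduce the screening facility's published
#' operating points.
#'
#' @param promiscuity_threshold Number of unrelated bait proteins beyond
#'   which a prey SID is considered promiscuous ("sticky") and its
#'   interactions demoted to PBS-E. An interaction is demoted when the count
#'   is *strictly greater* than this value (default 10, i.e. 11+ baits).
#' @param pbs_pvalue_thresholds Named numeric vector of decreasing p-value
#'   cutoffs for categories A, B and C, used when a pluggable p-value scorer
#'   is supplied (defaults `1e-10`, `1e-5`, `10^-2.5`).
#' @param pbs_fragment_thresholds Named integer vector of minimal
#'   fragment-support scores for categories A, B and C under the default
#'   fragment-count score (defaults 6, 4, 2); see [assign_pbs()].
#' @param pla_ratio_threshold Mean PPI/prey spot-count ratio that a proximity
#'   ligation assay must *strictly exceed* to validate an interaction
#'   (default 0.2).
#' @param coloc_thresholds Two strictly increasing Pearson-correlation cut
#'   points separating low / medium / strong colocalization
#'   (defaults 0.25 and 0.5).
#' @param proteome_size Number of protein-coding genes used as the
#'   background universe for sharing statistics (default 19220).
#' @param false_positive_preys Character vector of prey identifiers known to
#'   be technical false positives of the two-hybrid system; their
#'   interactions are excluded before scoring.
#' @param rng_seed Integer seed; mandatory for any stochastic operation.
#'
#' @return A list of class `y2h_config`.
#' @export
#' @examples
#' cfg <- y2h_config(promiscuity_threshold = 12)
#' cfg$promiscuity_threshold
y2h_config <- function(promiscuity_threshold = 10L,
                       pbs_pvalue_thresholds = c(A = 1e-10, B = 1e-5, C = 10^-2.5),
                       pbs_fragment_thresholds = c(A = 6L, B = 4L, C = 2L),
                       pla_ratio_threshold = 0.2,
                       coloc_thresholds = c(low = 0.25, medium = 0.5),
                       proteome_size = 19220L,
                       false_positive_preys = character(),
                       rng_seed = 1L) {
  assert_that(promiscuity_threshold > 0, "promiscuity_threshold must be positive")
  assert_that(all(pbs_pvalue_thresholds > 0) &&
                all(diff(unname(pbs_pvalue_thresholds)) > 0),
              "pbs_pvalue_thresholds must be positive and loosen from A to C")
  assert_that(all(pbs_fragment_thresholds > 0) && all(diff(unname(pbs_fragment_thresholds)) < 0),
              "pbs_fragment_thresholds must decrease from A to C")
  assert_that(pla_ratio_threshold > 0, "pla_ratio_threshold must be positive")
  assert_that(length(coloc_thresholds) == 2 && diff(unname(coloc_thresholds)) > 0 &&
                all(coloc_thresholds > 0),
              "coloc_thresholds must be two strictly increasing positive cut points")
  assert_that(proteome_size >= 1, "proteome_size must be >= 1")
  structure(
    list(
      promiscuity_threshold = as.integer(promiscuity_threshold),
      pbs_pvalue_thresholds = pbs_pvalue_thresholds,
      pbs_fragment_thresholds = pbs_fragment_thresholds,
      pla_ratio_threshold = pla_ratio_threshold,
      coloc_thresholds = coloc_thresholds,
      proteome_size = as.integer(proteome_size),
      false_positive_preys = as.character(false_positive_preys),
      rng_seed = as.integer(rng_seed)
    ),
    class = "y2h_config"
  )
}

#' Read a pipeline configuration from a flat key-value file
#'
#' The file holds one `key = value` pair per line (`#` comments allowed);
#' vector-valued keys use comma-separated values. Unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A `y2h_config` list.
#' @export
read_y2h_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, `[`, "", 2))
  args <- formals(y2h_config)
  unknown <- setdiff(keys, names(args))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  parsed <- lapply(seq_along(keys), function(i) {
    parts <- trimws(strsplit(vals[[i]], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (anyNA(num)) parts else num
  })
  do.call(y2h_config, setNames(parsed, keys))
}

SCREEN_TABLE_COLS <- c("screen_id", "bait_protein", "bait_start", "bait_stop",
                       "prey_protein", "clone_id", "frag_start", "frag_stop")

#' Read a clone-level screen table
#'
#' Parses a TSV with one row per sequenced positive clone. Required columns:
#' `screen_id`, `bait_protein`, `bait_start`, `bait_stop`, `prey_protein`,
#' `clone_id`, `frag_start`, `frag_stop` (amino-acid coordinates, 1-based,
#' inclusive). Optional per-screen columns `tested_diploids` and
#' `processed_clones` are carried into the screen registry.
#'
#' Rows with missing required fields are dropped with a warning that lists
#' their line numbers; a clone whose `frag_stop` precedes `frag_start` is a
#' validation error naming the clone.
#'
#' @param path Path to the TSV file.
#' @return A list with components `screens` (one row per screen: `screen_id`,
#'   `bait_protein`, `bait_start`, `bait_stop`, optional counts) and
#'   `fragments` (one row per clone).
#' @export
read_screen_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing_cols <- setdiff(SCREEN_TABLE_COLS, names(tbl))
  if (length(missing_cols)) {
    stop("screen table format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("bait_start", "bait_stop", "frag_start", "frag_stop",
                intersect(c("tested_diploids", "processed_clones"), names(tbl)))) {
    val <- suppressWarnings(as.integer(tbl[[col]]))
    if (any(!is.na(tbl[[col]]) & is.na(val))) {
      stop("screen table format error: non-integer values in column ", col)
    }
    tbl[[col]] <- val
  }
  incomplete <- !stats::complete.cases(tbl[SCREEN_TABLE_COLS])
  if (any(incomplete)) {
    # +1 for the header line so reported numbers match the file
    warning(sum(incomplete), " malformed row(s) dropped (line ",
            paste(which(incomplete) + 1L, collapse = ", "), ")")
    tbl <- tbl[!incomplete, , drop = FALSE]
  }
  validate_fragments(tbl)

  screens <- tbl |>
    dplyr::distinct(dplyr::across(dplyr::any_of(
      c("screen_id", "bait_protein", "bait_start", "bait_stop",
        "tested_diploids", "processed_clones"))))
  if (anyDuplicated(screens$screen_id)) {
    dup <- unique(screens$screen_id[duplicated(screens$screen_id)])
    stop("validation error: conflicting bait definitions for screen(s) ",
         paste(dup, collapse = ", "))
  }
  if (nrow(screens) &&
      any(screens$bait_start < 1 | screens$bait_stop < screens$bait_start)) {
    stop("validation error: invalid bait domain coordinates")
  }
  fragments <- tbl |>
    dplyr::select(dplyr::all_of(c("screen_id", "prey_protein", "clone_id",
                                  "frag_start", "frag_stop")))
  list(screens = screens, fragments = fragments)
}

validate_fragments <- function(tbl) {
  if (!nrow(tbl)) return(invisible(TRUE))
  bad <- tbl$frag_stop < tbl$frag_start | tbl$frag_start < 1
  if (any(bad)) {
    stop("validation error: frag_stop < frag_start (or start < 1) for clone(s) ",
         paste(tbl$clone_id[bad], collapse = ", "))
  }
  key <- paste(tbl$screen_id, tbl$clone_id)
  if (anyDuplicated(key)) {
    stop("validation error: duplicate (screen_id, clone_id): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  invisible(TRUE)
}

#' Write a clone-level screen table
#'
#' Inverse of [read_screen_table()]; writing then re-reading is lossless.
#'
#' @param screen_data List with `screens` and `fragments` as returned by
#'   [read_screen_table()] or [simulate_screens()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(screen_data, path) {
  tbl <- screen_data$fragments |>
    dplyr::left_join(screen_data$screens, by = "screen_id") |>
    dplyr::select(dplyr::all_of(SCREEN_TABLE_COLS),
                  dplyr::any_of(c("tested_diploids", "processed_clones")))
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

INTERACTION_TSV_COLS <- c("bait_protein", "prey_protein", "pbs", "screens",
                          "sid_starts", "sid_stops", "n_sids", "n_clones",
                          "n_distinct_fragments", "support_score",
                          "reciprocal", "in_cycle", "promiscuity")

#' Write scored interactions as PSI-MITAB 2.5 plus an extended TSV
#'
#' Emits a tab-delimited PSI-MITAB 2.5-style file (15 columns; the
#' confidence column carries `pbs:<A-E>`) in which duplicate unordered
#' bait-prey pairs found by several screens are merged into one record
#' listing all supporting screens, together with an extended TSV preserving
#' SID coordinates and scoring evidence. The extended TSV round-trips
#' losslessly through [read_interactions_tsv()].
#'
#' @param interactions Interaction table from [score_interactions()].
#' @param path Output path for the MITAB file.
#' @param tsv_path Output path for the extended TSV; defaults to `path` with
#'   a `.tsv` extension appended.
#' @return `path`, invisibly.
#' @export
write_mitab <- function(interactions, path, tsv_path = paste0(path, ".tsv")) {
  if (!nrow(interactions)) {
    writeLines(character(), path)
    readr::write_tsv(interactions[INTERACTION_TSV_COLS], tsv_path, progress = FALSE)
    return(invisible(path))
  }
  if (anyNA(interactions$pbs) || !all(interactions$pbs %in% c(PBS_LEVELS, "excluded"))) {
    stop("refusing to write: interaction(s) without a PBS category")
  }
  merged <- interactions |>
    dplyr::mutate(.key = pair_key(.data$bait_protein, .data$prey_protein)) |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      id_a = min(.data$bait_protein, .data$prey_protein),
      id_b = max(.data$bait_protein, .data$prey_protein),
      pbs = PBS_LEVELS[min(pbs_rank(.data$pbs))],
      screens = paste(sort(unique(unlist(strsplit(.data$screens, ";")))),
                      collapse = ";"),
      .groups = "drop"
    )
  fields <- c("uniprotkb:%s", "uniprotkb:%s", "-", "-", "-", "-",
              'psi-mi:"MI:0018"(two hybrid)', "-", "-",
              "taxid:9606(human)", "taxid:9606(human)",
              'psi-mi:"MI:0407"(direct interaction)', "-", "-", "pbs:%s")
  lines <- sprintf(paste(fields, collapse = "\t"),
                   merged$id_a, merged$id_b, merged$pbs)
  writeLines(lines, path)
  readr::write_tsv(interactions[INTERACTION_TSV_COLS], tsv_path, progress = FALSE)
  invisible(path)
}

#' Read back the extended interaction TSV written by [write_mitab()]
#'
#' @param path Path to the extended TSV.
#' @return An interaction tibble with the same columns and types as produced
#'   by [score_interactions()].
#' @export
read_interactions_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    bait_protein = readr::col_character(),
    prey_protein = readr::col_character(),
    pbs = readr::col_character(),
    screens = readr::col_character(),
    sid_starts = readr::col_character(),
    sid_stops = readr::col_character(),
    n_sids = readr::col_integer(),
    n_clones = readr::col_integer(),
    n_distinct_fragments = readr::col_integer(),
    support_score = readr::col_integer(),
    reciprocal = readr::col_logical(),
    in_cycle = readr::col_logical(),
    promiscuity = readr::col_integer()
  ), progress = FALSE)
}
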