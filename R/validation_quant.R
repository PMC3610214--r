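#' Proximity ligation assay (PLA) validation of one interaction
#'
#' Per cell, the signal ratio is the PPI spot count divided by the
#' prey-alone control spot count; cells with zero prey spots are excluded
#' from the mean and counted as inconclusive. The compartment mean ratio
#' validates the interaction when it *strictly exceeds* the configured
#' threshold (default 0.2 — the interaction recruits more than 20% of the
#' partner in that compartment); a mean of exactly the threshold does not
#' validate. The overall verdict is positive if any compartment validates,
#' `"inconclusive"` if every cell of every compartment was inconclusive.
#'
#' @param measurements Tibble for one PPI: `cell_id`, `compartment`
#'   (`membrane` or `cytoplasm`), `ppi_spots`, `prey_spots`.
#' @param config A [y2h_config()] supplying `pla_ratio_threshold`.
#' @return List with `per_compartment` (tibble: `compartment`, `n_cells`,
#'   `n_inconclusive`, `mean_ratio`, `validated`), `verdict`
#'   (`"validated"`, `"not_validated"` or `"inconclusive"`) and
#'   `validated_compartments`.
#' @export
#' @examples
#' m <- tibble::tibble(cell_id = 1:3, compartment = "membrane",
#'                     ppi_spots = c(5, 6, 7), prey_spots = c(20, 20, 20))
#' pla_validate(m)$verdict
pla_validate <- function(measurements, config = y2h_config()) {
  assert_that(all(measurements$compartment %in% c("membrane", "cytoplasm")),
              "compartment must be 'membrane' or 'cytoplasm'")
  assert_that(all(measurements$ppi_spots >= 0 & measurements$prey_spots >= 0),
              "spot counts must be non-negative")
  per <- measurements |>
    dplyr::group_by(.data$compartment) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      n_inconclusive = sum(.data$prey_spots == 0),
      mean_ratio = if (all(.data$prey_spots == 0)) NA_real_ else {
        mean((.data$ppi_spots / .data$prey_spots)[.data$prey_spots > 0])
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(validated = !is.na(.data$mean_ratio) &
                    .data$mean_ratio > config$pla_ratio_threshold)
  verdict <- if (any(per$validated)) {
    "validated"
  } else if (all(is.na(per$mean_ratio))) {
    "inconclusive"
  } else {
    "not_validated"
  }
  list(per_compartment = per, verdict = verdict,
       validated_compartments = per$compartment[per$validated])
}

#' Pearson colocalization classifier
#'
#' Computes the Pearson correlation between the paired pixel intensities of
#' the two channels and classifies it on half-open intervals: low for
#' `R <= 0.25`, medium for `0.25 < R <= 0.5`, strong for `0.5 < R <= 1`
#' (cut points configurable). A channel with zero variance has no defined
#' correlation and yields `NA`.
#'
#' @param channel_a,channel_b Numeric vectors of paired pixel intensities
#'   (same length, >= 2).
#' @param config A [y2h_config()] supplying `coloc_thresholds`.
#' @return List with `pearson_r` and `klass` (`"low"`, `"medium"`,
#'   `"strong"`, or `NA`).
#' @export
pearson_coloc <- function(channel_a, channel_b, config = y2h_config()) {
  assert_that(length(channel_a) == length(channel_b) && length(channel_a) >= 2,
              "need >= 2 paired intensity samples")
  if (stats::sd(channel_a) == 0 || stats::sd(channel_b) == 0) {
    return(list(pearson_r = NA_real_, klass = NA_character_))
  }
  r <- stats::cor(channel_a, channel_b)
  list(pearson_r = r, klass = classify_coloc(r, config))
}

#' Classify a Pearson coefficient into colocalization strength
#'
#' @param r Numeric vector of Pearson coefficients in `[-1, 1]`.
#' @param config A [y2h_config()].
#' @return Character vector: `"low"`, `"medium"` or `"strong"`.
#' @export
classify_coloc <- function(r, config = y2h_config()) {
  assert_that(all(r >= -1 & r <= 1, na.rm = TRUE), "Pearson r must be in [-1, 1]")
  lo <- config$coloc_thresholds[[1]]
  hi <- config$coloc_thresholds[[2]]
  dplyr::case_when(is.na(r) ~ NA_character_,
                   r <= lo ~ "low",
                   r <= hi ~ "medium",
                   TRUE ~ "strong")
}

#' Roll validation verdicts up into per-interaction experimental evidence
#'
#' Combines co-immunoprecipitation, colocalization and PLA verdicts per
#' unordered protein pair: experimental support is TRUE when any technique
#' is positive; inconclusive techniques are ignored; an interaction whose
#' every available technique is inconclusive is flagged as such.
#' Colocalization counts as positive above the low cut point (medium or
#' strong). Conflicting duplicate rows within one technique are an error.
#'
#' @param coip Optional tibble `protein_a`, `protein_b`, `verdict`
#'   (`"positive"`, `"negative"`, `"inconclusive"`).
#' @param coloc Optional tibble `protein_a`, `protein_b`, `pearson_r` (or a
#'   precomputed `klass`).
#' @param pla Optional tibble `protein_a`, `protein_b`, `verdict` (from
#'   [pla_validate()]: `"validated"`, `"not_validated"`, `"inconclusive"`).
#' @param config A [y2h_config()].
#' @return Tibble `protein_a`, `protein_b`, per-technique verdicts,
#'   `experimental_support`, `inconclusive`, plus a `summary` attribute with
#'   `n_tested`, `n_supported` and `fraction_supported`.
#' @export
validation_rollup <- function(coip = NULL, coloc = NULL, pla = NULL,
                              config = y2h_config()) {
  norm_verdicts <- function(tbl, value, technique) {
    if (is.null(tbl) || !nrow(tbl)) return(NULL)
    out <- tibble::tibble(.key = pair_key(tbl$protein_a, tbl$protein_b),
                          protein_a = pmin(tbl$protein_a, tbl$protein_b),
                          protein_b = pmax(tbl$protein_a, tbl$protein_b),
                          verdict = value)
    dup <- out |>
      dplyr::distinct(.data$.key, .data$verdict) |>
      dplyr::count(.data$.key) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup)) {
      stop("conflicting duplicate ", technique, " rows for pair(s): ",
           paste(dup$.key, collapse = ", "))
    }
    dplyr::distinct(out, .data$.key, .keep_all = TRUE)
  }
  coip_v <- if (!is.null(coip)) {
    assert_that(all(coip$verdict %in% c("positive", "negative", "inconclusive")),
                "co-IP verdicts must be positive/negative/inconclusive")
    norm_verdicts(coip, coip$verdict, "co-IP")
  }
  coloc_v <- if (!is.null(coloc)) {
    klass <- if ("klass" %in% names(coloc)) coloc$klass else {
      classify_coloc(coloc$pearson_r, config)
    }
    v <- dplyr::case_when(is.na(klass) ~ "inconclusive",
                          klass %in% c("medium", "strong") ~ "positive",
                          TRUE ~ "negative")
    norm_verdicts(coloc, v, "colocalization")
  }
  pla_v <- if (!is.null(pla)) {
    assert_that(all(pla$verdict %in% c("validated", "not_validated", "inconclusive")),
                "PLA verdicts must be validated/not_validated/inconclusive")
    v <- dplyr::case_when(pla$verdict == "validated" ~ "positive",
                          pla$verdict == "not_validated" ~ "negative",
                          TRUE ~ "inconclusive")
    norm_verdicts(pla, v, "PLA")
  }
  techniques <- list(coip = coip_v, coloc = coloc_v, pla = pla_v)
  techniques <- techniques[!vapply(techniques, is.null, logical(1))]
  assert_that(length(techniques) >= 1, "at least one verdict table required")
  all_pairs <- dplyr::bind_rows(lapply(techniques, function(t) {
    t[c(".key", "protein_a", "protein_b")]
  })) |> dplyr::distinct(.data$.key, .keep_all = TRUE)
  for (nm in names(techniques)) {
    idx <- match(all_pairs$.key, techniques[[nm]]$.key)
    all_pairs[[nm]] <- techniques[[nm]]$verdict[idx]
  }
  vmat <- as.matrix(all_pairs[names(techniques)])
  all_pairs$experimental_support <- apply(vmat, 1, function(v) {
    any(v == "positive", na.rm = TRUE)
  })
  all_pairs$inconclusive <- apply(vmat, 1, function(v) {
    all(is.na(v) | v == "inconclusive")
  })
  out <- dplyr::select(all_pairs, -".key")
  tested <- !out$inconclusive
  attr(out, "summary") <- list(
    n_tested = sum(tested),
    n_supported = sum(out$experimental_support),
    fraction_supported = sum(out$experimental_support) / max(1L, nrow(out))
  )
  out
}
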