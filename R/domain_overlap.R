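OVERLAP_CLASSES <- c("sid_within_domain", "domain_within_sid",
                     "partial_overlap", "none")

#' Classify the relation between a SID and an annotated domain
#'
#' Both intervals are 1-based inclusive amino-acid coordinates on the same
#' protein. `sid_within_domain` when the domain contains the SID (non-strict:
#' identical intervals resolve to this class), `domain_within_sid` for the
#' reverse containment, `partial_overlap` when the intervals intersect
#' without containment, `none` otherwise.
#'
#' @param sid One-row tibble/list with `prey_protein` (or `protein`),
#'   `sid_start`, `sid_stop`.
#' @param domain One-row tibble/list with `protein`, `start`, `stop`.
#' @return One of `"sid_within_domain"`, `"domain_within_sid"`,
#'   `"partial_overlap"`, `"none"`.
#' @export
#' @examples
#' classify_overlap(list(prey_protein = "P1", sid_start = 30, sid_stop = 60),
#'                  list(protein = "P1", start = 20, stop = 80))
classify_overlap <- function(sid, domain) {
  sid_prot <- sid$prey_protein %||% sid$protein
  assert_that(normalize_protein_id(sid_prot) == normalize_protein_id(domain$protein),
              "classify_overlap: SID and domain are on different proteins")
  assert_that(domain$start <= domain$stop, "invalid domain interval")
  classify_overlap_vec(sid$sid_start, sid$sid_stop, domain$start, domain$stop)
}

classify_overlap_vec <- function(ss, se, ds, de) {
  dplyr::case_when(
    ds <= ss & se <= de ~ "sid_within_domain",
    ss <= ds & de <= se ~ "domain_within_sid",
    ss <= de & ds <= se ~ "partial_overlap",
    TRUE ~ "none"
  )
}

#' Per-domain SID association counts
#'
#' Crosses a SID table with protein domain annotations and counts, for each
#' domain family, the SIDs with at least one *containment* relation
#' (SID within domain, or domain within SID); partial overlaps are computed
#' but segregated. Accession groups (e.g. the several immunoglobulin-fold
#' accessions) can be aggregated through `groups`.
#'
#' @param sids SID tibble (`prey_protein`, `sid_start`, `sid_stop`);
#'   restrict upstream to the high-confidence categories when emulating the
#'   published analysis.
#' @param annotations Tibble `protein`, `domain_acc`, `start`, `stop`.
#' @param groups Optional named character vector mapping `domain_acc` to a
#'   family label; unmapped accessions keep their own accession.
#' @return List with `relations` (one row per SID x domain pair that
#'   overlaps, with its class), `per_domain` (domain family, `n_sids` with a
#'   containment relation, `fraction` of all SIDs), and `n_associated`
#'   (distinct SIDs with >= 1 containment relation).
#' @export
domain_frequency_table <- function(sids, annotations, groups = NULL) {
  empty <- list(
    relations = tibble::tibble(sid_id = integer(), prey_protein = character(),
                               domain_acc = character(), family = character(),
                               class = character()),
    per_domain = tibble::tibble(family = character(), n_sids = integer(),
                                fraction = double()),
    n_associated = 0L
  )
  if (!nrow(sids) || !nrow(annotations)) return(empty)
  sids <- dplyr::mutate(sids, sid_id = dplyr::row_number(),
                        .norm = normalize_protein_id(.data$prey_protein))
  ann <- dplyr::mutate(annotations, .norm = normalize_protein_id(.data$protein))
  rel <- dplyr::inner_join(sids, ann, by = ".norm",
                           relationship = "many-to-many") |>
    dplyr::mutate(class = classify_overlap_vec(.data$sid_start, .data$sid_stop,
                                               .data$start, .data$stop)) |>
    dplyr::filter(.data$class != "none")
  if (!nrow(rel)) return(empty)
  fam <- unname((groups %||% character())[rel$domain_acc])
  rel$family <- ifelse(is.na(fam), rel$domain_acc, fam)
  rel <- dplyr::select(rel, "sid_id", "prey_protein", "domain_acc",
                       "family", "class")
  contained <- dplyr::filter(rel, .data$class != "partial_overlap")
  per_domain <- contained |>
    dplyr::distinct(.data$family, .data$sid_id) |>
    dplyr::count(.data$family, name = "n_sids") |>
    dplyr::mutate(fraction = .data$n_sids / nrow(sids)) |>
    dplyr::arrange(dplyr::desc(.data$n_sids))
  list(relations = rel, per_domain = per_domain,
       n_associated = dplyr::n_distinct(contained$sid_id))
}

#' Domain over-representation against a proteome background
#'
#' For each domain family, builds the 2x2 table contrasting SIDs carrying
#' the domain vs not against proteome proteins carrying it vs not, and runs
#' a two-sided exact Fisher (hypergeometric) test; Benjamini-Hochberg
#' adjusted p-values are reported alongside the raw ones. Degenerate tables
#' with a zero margin give p = 1 by convention.
#'
#' @param observed Tibble `family`, `n_sids` (e.g. `per_domain` from
#'   [domain_frequency_table()]).
#' @param background Tibble `family` (or `domain_acc`), `proteome_count`,
#'   and either a `proteome_total` column or the `proteome_total` argument.
#' @param total_sids Total number of SIDs analysed (the SID-side margin).
#' @param proteome_total Number of proteins in the background proteome.
#' @return Tibble: `family`, `n_sids`, `proteome_count`, `p_value`,
#'   `p_adjusted`, sorted by `p_value`.
#' @export
domain_enrichment <- function(observed, background, total_sids,
                              proteome_total = NULL) {
  if ("domain_acc" %in% names(background) && !"family" %in% names(background)) {
    background <- dplyr::rename(background, family = "domain_acc")
  }
  proteome_total <- proteome_total %||% background$proteome_total[1]
  assert_that(!is.null(proteome_total) && proteome_total >= 1,
              "proteome_total required")
  tbl <- dplyr::inner_join(observed, background[c("family", "proteome_count")],
                           by = "family")
  if (!nrow(tbl)) {
    return(tibble::tibble(family = character(), n_sids = integer(),
                          proteome_count = integer(), p_value = double(),
                          p_adjusted = double()))
  }
  tbl$p_value <- vapply(seq_len(nrow(tbl)), function(i) {
    k <- tbl$n_sids[i]
    K <- tbl$proteome_count[i]
    m <- matrix(c(k, total_sids - k, K, proteome_total - K), nrow = 2)
    if (any(m < 0)) stop("counts exceed their totals for family ", tbl$family[i])
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) return(1)
    stats::fisher.test(m, alternative = "two.sided")$p.value
  }, double(1))
  tbl$p_adjusted <- stats::p.adjust(tbl$p_value, method = "BH")
  dplyr::arrange(tbl, .data$p_value)
}
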