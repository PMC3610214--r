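GO_ASPECTS <- c("BP", "CC", "MF")

# protein -> list of cluster-id sets per aspect, from a long cluster table
cluster_sets <- function(clusters, aspect) {
  sub <- clusters[clusters$aspect == aspect, , drop = FALSE]
  split(as.character(sub$cluster_id), normalize_protein_id(sub$protein))
}

#' Shared-GO-cluster statistics over network pairs
#'
#' A pair of interacting proteins shares a GO aspect (BP, CC or MF) when
#' their cluster-id sets for that aspect intersect; unannotated proteins
#' share nothing. The fraction denominator is all network PPIs.
#'
#' @param network A `ppi_network`.
#' @param clusters Long tibble `protein`, `aspect` (BP/CC/MF), `cluster_id`.
#' @return List with `pairs` (per-edge logicals `shares_bp`, `shares_cc`,
#'   `shares_mf`, `shares_any`) and `summary` (per-aspect and any-aspect
#'   counts and fractions with the denominator reported).
#' @export
shared_pairs <- function(network, clusters) {
  assert_that(all(clusters$aspect %in% GO_ASPECTS),
              "cluster aspects must be BP, CC or MF")
  edges <- network$edges
  pairs <- tibble::tibble(protein_a = edges$protein_a,
                          protein_b = edges$protein_b)
  for (aspect in GO_ASPECTS) {
    sets <- cluster_sets(clusters, aspect)
    shared <- vapply(seq_len(nrow(pairs)), function(i) {
      sa <- sets[[normalize_protein_id(pairs$protein_a[i])]]
      sb <- sets[[normalize_protein_id(pairs$protein_b[i])]]
      length(intersect(sa, sb)) > 0
    }, logical(1))
    pairs[[paste0("shares_", tolower(aspect))]] <- shared
  }
  pairs$shares_any <- pairs$shares_bp | pairs$shares_cc | pairs$shares_mf
  n <- nrow(pairs)
  summary <- tibble::tibble(
    aspect = c(GO_ASPECTS, "any"),
    n_shared = c(sum(pairs$shares_bp), sum(pairs$shares_cc),
                 sum(pairs$shares_mf), sum(pairs$shares_any)),
    n_pairs = n
  )
  summary$fraction <- summary$n_shared / max(1L, n)
  list(pairs = pairs, summary = summary)
}

#' Proteome background for GO sharing and chi-square comparison
#'
#' For each bait, counts the proteome proteins with which it shares a
#' cluster (`Shared_i`; `NonShared_i = proteome_size - Shared_i`). The
#' expected sharing frequency is `sum(Shared_i) / (n_baits * proteome_size)`.
#' The observed sharing fraction among network pairs is compared to this
#' expectation by a 1-df Pearson chi-square test without continuity
#' correction.
#'
#' @param baits Character vector of bait protein identifiers.
#' @param proteome_clusters Long cluster tibble covering the proteome
#'   (`protein`, `aspect`, `cluster_id`); every bait must appear.
#' @param proteome_size Number of proteome proteins (the pairing universe
#'   per bait).
#' @param observed_shared,observed_pairs Observed shared-pair count and
#'   total pair count from the network (e.g. [shared_pairs()] summary);
#'   omit to get the background alone.
#' @param aspect Restrict sharing to one aspect, or `"any"` (default).
#' @return List with `per_bait` (Shared_i / NonShared_i), `expected_frequency`,
#'   and when observations are supplied `chisq` (`statistic`, `p_value`,
#'   `observed_frequency`).
#' @export
sharing_background <- function(baits, proteome_clusters, proteome_size,
                               observed_shared = NULL, observed_pairs = NULL,
                               aspect = "any") {
  norm_baits <- normalize_protein_id(baits)
  aspects <- if (aspect == "any") GO_ASPECTS else match.arg(aspect, GO_ASPECTS)
  sets <- lapply(GO_ASPECTS, function(a) cluster_sets(proteome_clusters, a))
  names(sets) <- GO_ASPECTS
  annotated <- unique(unlist(lapply(sets, names)))
  missing <- setdiff(norm_baits, annotated)
  if (length(missing)) {
    stop("bait(s) absent from proteome cluster table: ",
         paste(missing, collapse = ", "))
  }
  proteome_proteins <- unique(normalize_protein_id(proteome_clusters$protein))
  shared_i <- vapply(norm_baits, USE.NAMES = FALSE, function(b) {
    sum(vapply(proteome_proteins, function(p) {
      any(vapply(aspects, function(a) {
        length(intersect(sets[[a]][[b]], sets[[a]][[p]])) > 0
      }, logical(1)))
    }, logical(1)))
  }, integer(1))
  per_bait <- tibble::tibble(bait = baits, shared_i = shared_i,
                             nonshared_i = as.integer(proteome_size) - shared_i)
  expected <- sum(shared_i) / (length(baits) * proteome_size)
  out <- list(per_bait = per_bait, expected_frequency = expected)
  if (!is.null(observed_shared)) {
    assert_that(!is.null(observed_pairs), "observed_pairs required with observed_shared")
    exp_counts <- c(shared = expected * observed_pairs,
                    nonshared = (1 - expected) * observed_pairs)
    obs_counts <- c(shared = observed_shared,
                    nonshared = observed_pairs - observed_shared)
    stat <- sum((obs_counts - exp_counts)^2 / exp_counts)
    out$chisq <- list(statistic = stat,
                      p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                      observed_frequency = observed_shared / observed_pairs)
  }
  out
}

# One-sided enrichment p-value P(X >= k) for overlap k, term size K,
# universe N, set size n; EASE decrements k by one (floor 0) first.
hyper_upper_tail <- function(k, K, N, n) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' EASE-score term enrichment
#'
#' Conservative variant of the one-sided Fisher exact test used by DAVID:
#' the overlap count between the gene set and each term is decremented by
#' one (floor 0, with margins unchanged) before taking the hypergeometric
#' upper tail, so single-gene overlaps can never appear enriched. Terms
#' with EASE p below `alpha` are flagged.
#'
#' @param gene_set Character vector of proteins of interest (subset of the
#'   proteome).
#' @param background_sets Named list mapping term id to the proteome
#'   proteins annotated with the term.
#' @param proteome Character vector: the background universe.
#' @param alpha Significance level for the `enriched` flag (default 0.01).
#' @return Tibble `term`, `n_overlap`, `n_term`, `ease_p`, `fisher_p`,
#'   `enriched`, sorted by `ease_p`. Empty gene set gives an empty table.
#' @export
ease_enrichment <- function(gene_set, background_sets, proteome, alpha = 0.01) {
  gene_set <- unique(normalize_protein_id(gene_set))
  proteome <- unique(normalize_protein_id(proteome))
  assert_that(all(gene_set %in% proteome), "gene_set must be within the proteome")
  if (!length(gene_set) || !length(background_sets)) {
    return(tibble::tibble(term = character(), n_overlap = integer(),
                          n_term = integer(), ease_p = double(),
                          fisher_p = double(), enriched = logical()))
  }
  N <- length(proteome)
  n <- length(gene_set)
  rows <- purrr::imap_dfr(background_sets, function(members, term) {
    members <- intersect(unique(normalize_protein_id(members)), proteome)
    k <- length(intersect(gene_set, members))
    K <- length(members)
    tibble::tibble(term = term, n_overlap = k, n_term = K,
                   ease_p = hyper_upper_tail(max(k - 1L, 0L), K, N, n),
                   fisher_p = hyper_upper_tail(k, K, N, n))
  })
  rows$enriched <- rows$ease_p < alpha
  dplyr::arrange(rows, .data$ease_p)
}

DISEASE_CLASSES <- c("myopathy", "cardiomyopathy", "neuropathy", "metabolic",
                     "excitation", "unclassified", "non-NMD")

#' Overlay disease annotations on a network
#'
#' Counts disease records per class (a protein may carry several classes,
#' so record counts and protein counts are reported separately) and
#' extracts the sub-network induced on disease-annotated proteins with edge
#' categories retained.
#'
#' @param network A `ppi_network`.
#' @param annotations Tibble `protein`, `class` (controlled vocabulary:
#'   myopathy, cardiomyopathy, neuropathy, metabolic, excitation,
#'   unclassified, non-NMD), optional `omim`.
#' @return List: `class_counts` (records per class), `n_disease_proteins`,
#'   `n_nmd_proteins` (classes other than non-NMD), and `subnetwork`
#'   (`ppi_network` induced on disease proteins present in the network).
#' @export
disease_overlay <- function(network, annotations) {
  assert_that(all(annotations$class %in% DISEASE_CLASSES),
              "unknown disease class in annotations")
  in_net <- normalize_protein_id(annotations$protein) %in%
    normalize_protein_id(network$nodes)
  ann <- annotations[in_net, , drop = FALSE]
  class_counts <- ann |>
    dplyr::count(class = factor(.data$class, levels = DISEASE_CLASSES),
                 name = "n_records", .drop = FALSE) |>
    dplyr::mutate(class = as.character(class))
  disease_prot <- unique(normalize_protein_id(ann$protein))
  nmd_prot <- unique(normalize_protein_id(ann$protein[ann$class != "non-NMD"]))
  edges <- network$edges
  keep <- normalize_protein_id(edges$protein_a) %in% disease_prot &
    normalize_protein_id(edges$protein_b) %in% disease_prot
  list(class_counts = class_counts,
       n_disease_proteins = length(disease_prot),
       n_nmd_proteins = length(nmd_prot),
       subnetwork = new_ppi_network(edges[keep, , drop = FALSE]))
}

#' Disease-class over-representation among interaction partners
#'
#' One-sided Fisher exact test per class: are proteins of the class
#' over-represented in `partner_set` relative to `background_set`?
#'
#' @param partner_set Character vector (subset of `background_set`).
#' @param annotations Disease annotation tibble (`protein`, `class`).
#' @param background_set Character vector: the comparison universe.
#' @return Tibble `class`, `n_partners`, `n_background`, `p_value`.
#' @export
class_overrepresentation <- function(partner_set, annotations, background_set) {
  partner_set <- unique(normalize_protein_id(partner_set))
  background_set <- unique(normalize_protein_id(background_set))
  assert_that(all(partner_set %in% background_set),
              "partner_set must be within background_set")
  N <- length(background_set)
  n <- length(partner_set)
  purrr::map_dfr(setdiff(DISEASE_CLASSES, "non-NMD"), function(cl) {
    members <- unique(normalize_protein_id(
      annotations$protein[annotations$class == cl]))
    members <- intersect(members, background_set)
    k <- length(intersect(partner_set, members))
    tibble::tibble(class = cl, n_partners = k, n_background = length(members),
                   p_value = hyper_upper_tail(k, length(members), N, n))
  })
}

#' Candidate genes for disease loci
#'
#' Intersects each locus gene list with the network's proteins; a locus
#' with exactly one candidate is flagged as having a unique candidate.
#'
#' @param loci Tibble `locus_id`, `gene` (one row per gene) or list mapping
#'   locus id to gene vectors.
#' @param network_proteins Character vector of network protein identifiers.
#' @return Tibble `locus_id`, `n_genes`, `candidates` (";"-joined),
#'   `n_candidates`, `unique_candidate`.
#' @export
locus_candidates <- function(loci, network_proteins) {
  if (!is.data.frame(loci)) {
    loci <- tibble::tibble(locus_id = rep(names(loci), lengths(loci)),
                           gene = unlist(loci, use.names = FALSE))
  }
  assert_that(nrow(loci) >= 1, "loci must be non-empty")
  net <- unique(normalize_protein_id(network_proteins))
  loci |>
    dplyr::group_by(.data$locus_id) |>
    dplyr::summarise(
      n_genes = dplyr::n_distinct(.data$gene),
      candidates = paste(sort(unique(
        .data$gene[normalize_protein_id(.data$gene) %in% net])), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_candidates = dplyr::if_else(nzchar(.data$candidates),
                                    lengths(strsplit(.data$candidates, ";")), 0L),
      unique_candidate = .data$n_candidates == 1L
    )
}
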