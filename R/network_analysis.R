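#' Assemble the protein-protein interaction network
#'
#' Merges scored interactions into an undirected, deduplicated network.
#' Duplicate bait-prey pairs found by multiple bait domains, screens or
#' orientations collapse into one edge carrying all evidence; the merged
#' edge takes the best category among its constituents (A < B < C < D < E).
#' Excluded interactions never enter the network. Homodimers become
#' self-loop edges.
#'
#' @param interactions Interaction tibble with `pbs` assigned.
#' @return A `ppi_network`: list with `edges` (one row per unordered pair:
#'   `protein_a`, `protein_b`, `pbs`, `screens`, `baits`, `n_screens`),
#'   `nodes` (character vector of endpoint identifiers) and
#'   `category_counts`.
#' @export
build_network <- function(interactions) {
  scored <- interactions[interactions$pbs %in% PBS_LEVELS, , drop = FALSE]
  if (!nrow(scored)) {
    edges <- tibble::tibble(protein_a = character(), protein_b = character(),
                            pbs = character(), screens = character(),
                            baits = character(), n_screens = integer())
    return(new_ppi_network(edges))
  }
  edges <- scored |>
    dplyr::mutate(
      .key = pair_key(.data$bait_protein, .data$prey_protein),
      protein_a = pmin(.data$bait_protein, .data$prey_protein),
      protein_b = pmax(.data$bait_protein, .data$prey_protein)
    ) |>
    dplyr::group_by(.data$.key) |>
    dplyr::summarise(
      protein_a = .data$protein_a[1],
      protein_b = .data$protein_b[1],
      pbs = PBS_LEVELS[min(pbs_rank(.data$pbs))],
      screens = paste(sort(unique(unlist(strsplit(.data$screens, ";")))),
                      collapse = ";"),
      baits = paste(sort(unique(.data$bait_protein)), collapse = ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_screens = lengths(strsplit(.data$screens, ";"))) |>
    dplyr::select(-".key") |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
  new_ppi_network(edges)
}

new_ppi_network <- function(edges) {
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b)))
  counts <- table(factor(edges$pbs, levels = PBS_LEVELS))
  structure(
    list(edges = edges, nodes = nodes,
         category_counts = setNames(as.integer(counts), PBS_LEVELS)),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network> ", length(x$nodes), " proteins, ", nrow(x$edges),
      " interactions\n", sep = "")
  cat("  PBS: ", paste(names(x$category_counts), x$category_counts,
                       sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Convert a ppi_network to an igraph graph
#'
#' @param network A `ppi_network`.
#' @param drop_loops Remove self-loop edges (default FALSE).
#' @return An undirected igraph graph whose edges carry the `pbs` attribute.
#' @export
as_igraph <- function(network, drop_loops = FALSE) {
  edges <- network$edges
  if (drop_loops) edges <- edges[edges$protein_a != edges$protein_b, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edges[c("protein_a", "protein_b", "pbs")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes)
  )
  g
}

#' Topology summary of a PPI network
#'
#' Degrees count self-loops twice (so `mean_degree = 2 * n_edges / n_nodes`
#' exactly); the mean shortest path is averaged over unordered node pairs of
#' the largest connected component of the loop-free graph; heterogeneity is
#' the coefficient of variation of the degree sequence (population standard
#' deviation over mean degree), reflecting the tendency to contain hubs;
#' density is `2E / (N(N-1))` ignoring self-loops.
#'
#' @param network A `ppi_network`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `mean_degree`,
#'   `mean_shortest_path`, `heterogeneity`, `density`. With a single node
#'   (or empty largest component) the path length is `NA`.
#' @export
topology_summary <- function(network) {
  edges <- network$edges
  n_nodes <- length(network$nodes)
  assert_that(n_nodes >= 1, "topology_summary needs at least one node")
  n_edges <- nrow(edges)
  deg <- setNames(rep(0L, n_nodes), network$nodes)
  ends <- c(edges$protein_a, edges$protein_b) # loops appear twice: degree +2
  tab <- table(ends)
  deg[names(tab)] <- as.integer(tab)
  mean_degree <- mean(deg)
  het <- if (mean_degree > 0) {
    sqrt(mean((deg - mean_degree)^2)) / mean_degree
  } else NA_real_
  simple <- edges[edges$protein_a != edges$protein_b, , drop = FALSE]
  density <- if (n_nodes > 1) 2 * nrow(simple) / (n_nodes * (n_nodes - 1)) else 0
  g <- as_igraph(network, drop_loops = TRUE)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  members <- igraph::V(g)[comp$membership == big]
  msp <- if (length(members) >= 2) {
    sub <- igraph::induced_subgraph(g, members)
    d <- igraph::distances(sub)
    mean(d[upper.tri(d)])
  } else NA_real_
  tibble::tibble(
    n_nodes = n_nodes, n_edges = n_edges, mean_degree = mean_degree,
    mean_shortest_path = msp, heterogeneity = het, density = density
  )
}

#' Flag network edges reported in a literature interaction table
#'
#' Matches the network's unordered protein pairs against a table of known
#' pairs (e.g. literature-curated direct interactions) after identifier
#' normalization (case-fold, strip version suffixes).
#'
#' @param network A `ppi_network`.
#' @param known_pairs Tibble/data frame with columns `protein_a`,
#'   `protein_b` (any order within a pair).
#' @return List with `flags` (logical per edge), `n_known`, `fraction`
#'   (over all network edges) and `by_category` (per-PBS counts and
#'   fractions).
#' @export
literature_overlap <- function(network, known_pairs) {
  keys <- pair_key(network$edges$protein_a, network$edges$protein_b)
  known <- unique(pair_key(known_pairs$protein_a, known_pairs$protein_b))
  flags <- keys %in% known
  by_cat <- tibble::tibble(pbs = network$edges$pbs, known = flags) |>
    dplyr::group_by(.data$pbs) |>
    dplyr::summarise(n = dplyr::n(), n_known = sum(.data$known),
                     fraction = sum(.data$known) / dplyr::n(), .groups = "drop")
  list(flags = flags, n_known = sum(flags),
       fraction = sum(flags) / max(1L, length(flags)), by_category = by_cat)
}

HC_RULES <- c("pbs_abc", "literature", "experimental", "go", "nmd_prey")

#' Extract the high-confidence (HC) sub-network
#'
#' Keeps every PBS A-C edge unconditionally and rescues a PBS D/E edge when
#' at least one of four evidence rules admits it: (1) the pair is reported
#' in the literature; (2) the interaction was confirmed experimentally
#' (co-immunoprecipitation, colocalization or proximity ligation); (3) the
#' two proteins share a biological-process GO cluster, or share both a
#' cellular-component and a molecular-function cluster; (4) the prey is a
#' neuromuscular-disorder protein. Every admitted D/E edge is labeled with
#' its admitting rule(s). Applying the filter twice with the same evidence
#' is idempotent.
#'
#' @param network A `ppi_network`.
#' @param evidence Tibble with one row per D/E edge (any pair order):
#'   `protein_a`, `protein_b`, `literature_support`, `experimental_support`,
#'   `shares_bp`, `shares_cc`, `shares_mf`, `nmd_prey` (logicals). A D/E
#'   edge without an evidence row is an error listing the missing pairs.
#' @return A `ppi_network` whose edges carry an `hc_rules` column
#'   (";"-separated admitting rules) and whose nodes are the endpoints of
#'   the surviving edges.
#' @export
hc_filter <- function(network, evidence) {
  edges <- network$edges
  if (!nrow(edges)) return(network)
  is_de <- edges$pbs %in% c("D", "E")
  ev <- evidence |>
    dplyr::mutate(.key = pair_key(.data$protein_a, .data$protein_b)) |>
    dplyr::distinct(.data$.key, .keep_all = TRUE)
  keys <- pair_key(edges$protein_a, edges$protein_b)
  missing <- is_de & !(keys %in% ev$.key)
  if (any(missing)) {
    stop("missing evidence rows for D/E edge(s): ",
         paste(edges$protein_a[missing], edges$protein_b[missing],
               sep = "-", collapse = ", "))
  }
  idx <- match(keys, ev$.key)
  rules <- character(nrow(edges))
  rules[!is_de] <- "pbs_abc"
  if (any(is_de)) {
    e <- ev[idx[is_de], , drop = FALSE]
    go_rule <- e$shares_bp | (e$shares_cc & e$shares_mf)
    rule_mat <- cbind(literature = e$literature_support,
                      experimental = e$experimental_support,
                      go = go_rule,
                      nmd_prey = e$nmd_prey)
    rules[is_de] <- apply(rule_mat, 1, function(r) {
      paste(colnames(rule_mat)[which(r)], collapse = ";")
    })
  }
  keep <- nzchar(rules)
  hc_edges <- edges[keep, , drop = FALSE]
  hc_edges$hc_rules <- rules[keep]
  new_ppi_network(hc_edges)
}

#' Compare networks side by side
#'
#' @param networks Named list of `ppi_network` objects (at least two).
#' @param baits Optional character vector of bait protein identifiers; when
#'   given, the mean number of interactions per bait present in each
#'   network is reported.
#' @return Tibble with one row per network: protein/PPI counts, mean
#'   partners per bait, and the connectivity metrics of
#'   [topology_summary()].
#' @export
compare_networks <- function(networks, baits = NULL) {
  assert_that(length(networks) >= 2, "compare_networks needs at least two networks")
  nm <- names(networks) %||% paste0("network", seq_along(networks))
  purrr::imap_dfr(setNames(networks, nm), function(net, name) {
    ts <- topology_summary(net)
    partners <- NA_real_
    if (!is.null(baits)) {
      b <- intersect(normalize_protein_id(baits), normalize_protein_id(net$nodes))
      hits <- normalize_protein_id(net$edges$protein_a) %in% b |
        normalize_protein_id(net$edges$protein_b) %in% b
      partners <- if (length(b)) sum(hits) / length(b) else NA_real_
    }
    dplyr::bind_cols(tibble::tibble(network = name,
                                    n_proteins = length(net$nodes),
                                    n_ppis = nrow(net$edges),
                                    mean_partners_per_bait = partners),
                     ts[c("mean_degree", "mean_shortest_path",
                          "heterogeneity", "density")])
  })
}
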