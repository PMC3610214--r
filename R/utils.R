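#' @importFrom rlang .data %||%
#' @importFrom stats setNames
NULL

# Ordered PBS levels, best first. "excluded" never enters a network.
PBS_LEVELS <- c("A", "B", "C", "D", "E")

pbs_rank <- function(pbs) match(pbs, PBS_LEVELS)

#' Normalize a protein identifier for cross-table matching
#'
#' Case-folds the identifier and strips a trailing numeric version suffix
#' (e.g. `"Q9Y4G6.2"` becomes `"q9y4g6"`). Used whenever identifiers from
#' different sources (screen tables, literature interaction tables,
#' annotation tables) are compared; no alias resolution is attempted.
#'
#' @param x Character vector of protein identifiers.
#' @return Character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_protein_id(c("DysF", "Q9Y4G6.2"))
normalize_protein_id <- function(x) {
  sub("\\.[0-9]+$", "", tolower(trimws(as.character(x))))
}

# Canonical unordered pair key: normalized ids, sorted, "|"-joined.
pair_key <- function(a, b) {
  a <- normalize_protein_id(a)
  b <- normalize_protein_id(b)
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

# Inclusive amino-acid interval length.
interval_length <- function(start, stop) stop - start + 1L

# TRUE when closed intervals [s1, e1] and [s2, e2] share >= 1 residue.
intervals_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
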