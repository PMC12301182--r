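#' Enumerate co-acquisitions at one stringency level
#'
#' A co-acquisition is an unordered pair of genes from two different families
#' inferred to be gained on the same terminal branch, with both genes on the
#' same chromosome. Gains on internal branches are ignored (gene positions
#' exist only in extant genomes), and chromosomes with fewer than
#' `min_chrom_genes` genes are excluded to limit small-number effects. Every
#' cross-family pair of member genes counts as a separate co-acquisition when
#' families have several copies.
#'
#' The co-transfer flag is "yes" when both genes' gain events name the same
#' donor branch, "no" when both name donors that differ, and "unknown" when
#' either event carries no donor.
#'
#' @param events Gain-event tibble restricted to one stringency level.
#' @param orders Gene-order tibble for the extant taxa.
#' @param tree Optional [species_tree]; its leaf set defines the terminal
#'   branches (defaults to the taxa present in `orders`).
#' @param t Maximum number of intervening genes for two genes to be called
#'   neighbors (default 1).
#' @param min_chrom_genes Chromosome-size filter (default 1000).
#' @return An object of class `coacq_table`: `$pairs` (one row per pair with
#'   `intervening` and `cotransfer`), `$tallies` (per chromosome with pairs:
#'   `c_i` pairs and `g_i` genes), `$t`, `$n_pairs`.
#' @export
enumerate_coacquisitions <- function(events, orders, tree = NULL, t = 1,
                                     min_chrom_genes = 1000) {
  stopifnot(t >= 0)
  if (length(unique(events$stringency)) > 1)
    stop("events span several stringency levels; filter to one first")
  leaves <- if (is.null(tree)) unique(orders$taxon) else tree_leaves(tree)
  known_taxa <- unique(orders$taxon)
  ev <- events[events$recipient_branch %in% leaves, ]
  lost <- setdiff(unique(ev$recipient_branch), known_taxa)
  if (length(lost)) {
    message("taxa with events but no annotation skipped: ",
            paste(lost, collapse = ", "))
    ev <- ev[!ev$recipient_branch %in% lost, ]
  }

  empty <- structure(list(
    pairs = tibble::tibble(taxon = character(), chromosome = character(),
                           gene_a = character(), gene_b = character(),
                           family_a = character(), family_b = character(),
                           intervening = integer(),
                           cotransfer = character()),
    tallies = tibble::tibble(taxon = character(), chromosome = character(),
                             c_i = integer(), g_i = integer()),
    t = t, n_pairs = 0L), class = "coacq_table")
  if (nrow(ev) == 0) return(empty)

  # one donor per (taxon, family); conflicting donors degrade to unknown
  donors <- ev |>
    dplyr::distinct(.data$recipient_branch, .data$family_id,
                    .data$donor_branch) |>
    dplyr::group_by(.data$recipient_branch, .data$family_id) |>
    dplyr::summarise(donor = if (dplyr::n() == 1) .data$donor_branch[1]
                     else NA_character_, .groups = "drop")

  chrom_sizes <- orders |>
    dplyr::count(.data$taxon, .data$chromosome, name = "g_i")

  members <- orders |>
    dplyr::inner_join(donors, by = c(taxon = "recipient_branch",
                                     family_id = "family_id")) |>
    dplyr::inner_join(chrom_sizes, by = c("taxon", "chromosome")) |>
    dplyr::filter(.data$g_i >= min_chrom_genes) |>
    dplyr::select("taxon", "chromosome", "position", "gene_id",
                  "family_id", "donor", "g_i")
  if (nrow(members) == 0) return(empty)

  pairs <- members |>
    dplyr::inner_join(members, by = c("taxon", "chromosome", "g_i"),
                      suffix = c("_a", "_b"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$position_a < .data$position_b,
                  .data$family_id_a != .data$family_id_b) |>
    dplyr::mutate(
      intervening = .data$position_b - .data$position_a - 1L,
      cotransfer = dplyr::case_when(
        is.na(.data$donor_a) | is.na(.data$donor_b) ~ "unknown",
        .data$donor_a == .data$donor_b ~ "yes",
        TRUE ~ "no")) |>
    dplyr::select("taxon", "chromosome",
                  gene_a = "gene_id_a", gene_b = "gene_id_b",
                  family_a = "family_id_a", family_b = "family_id_b",
                  "intervening", "cotransfer")
  if (nrow(pairs) == 0) return(empty)

  tallies <- pairs |>
    dplyr::count(.data$taxon, .data$chromosome, name = "c_i") |>
    dplyr::inner_join(chrom_sizes, by = c("taxon", "chromosome"))

  structure(list(pairs = pairs, tallies = tallies, t = t,
                 n_pairs = nrow(pairs)), class = "coacq_table")
}

#' @export
print.coacq_table <- function(x, ...) {
  cat("Co-acquisition table:", x$n_pairs, "pairs on", nrow(x$tallies),
      "chromosome(s); t =", x$t, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy coacq_table
#' @export
tidy.coacq_table <- function(x, ...) x$pairs

#' @method glance coacq_table
#' @export
glance.coacq_table <- function(x, ...) {
  tibble::tibble(
    n_pairs = x$n_pairs,
    n_chromosomes = nrow(x$tallies),
    t = x$t,
    pct_neighbors = if (x$n_pairs > 0) percent_neighbors(x) else NA_real_,
    expected_pct_neighbors = if (x$n_pairs > 0)
      expected_neighbor_percent(x) else NA_real_)
}

#' Observed percentage of neighboring co-acquisitions
#'
#' Two genes are neighbors when separated by at most `t` intervening genes
#' on the same chromosome.
#'
#' @param table A `coacq_table` with at least one pair.
#' @return Percentage in [0, 100].
#' @export
percent_neighbors <- function(table) {
  stopifnot(inherits(table, "coacq_table"))
  if (table$n_pairs == 0) stop("no co-acquisitions; percentage undefined")
  100 * mean(table$pairs$intervening <= table$t)
}

#' Expected percentage of neighboring co-acquisitions under the null model
#'
#' Null model: the two gains of each pair arose independently, so for a gene
#' on a chromosome of g_i genes the chance that a second gene lands within t
#' intervening genes is 2(t+1)/g_i (t+1 neighboring slots on either side,
#' approximating for boundary genes). With c_i co-acquisitions on chromosome
#' i, the expected percentage is
#'   100 * 2 * sum_i (t+1) (c_i / g_i) / sum_i c_i,
#' which for a single chromosome reduces to 100 * 2(t+1)/g.
#'
#' @param table A `coacq_table` with at least one pair.
#' @return Percentage in [0, 100].
#' @export
expected_neighbor_percent <- function(table) {
  stopifnot(inherits(table, "coacq_table"))
  tl <- table$tallies
  if (nrow(tl) == 0 || sum(tl$c_i) == 0)
    stop("no co-acquisitions; expectation undefined")
  if (any(tl$g_i == 0)) stop("chromosome with zero genes")
  t <- table$t
  100 * 2 * sum((t + 1) * tl$c_i / tl$g_i) / sum(tl$c_i)
}

#' Co-transfer percentages among co-acquisitions
#'
#' Both percentages use all co-acquisitions as the denominator: the percent
#' of pairs whose two genes share an inferred donor branch (co-transfers),
#' and the percent that additionally are neighbors.
#'
#' @param table A `coacq_table`. Errors when no pair carries donor
#'   information (implicit and parametric methods provide no donors).
#' @return A one-row tibble: `pct_cotransfers`, `pct_neighbor_cotransfers`.
#' @export
cotransfer_stats <- function(table) {
  stopifnot(inherits(table, "coacq_table"))
  p <- table$pairs
  if (nrow(p) == 0) stop("no co-acquisitions")
  if (all(p$cotransfer == "unknown"))
    stop("method provides no donors; co-transfer statistics undefined")
  yes <- p$cotransfer == "yes"
  tibble::tibble(
    pct_cotransfers = 100 * sum(yes) / nrow(p),
    pct_neighbor_cotransfers =
      100 * sum(yes & p$intervening <= table$t) / nrow(p))
}

#' Evaluate an inference set across its stringency sweep
#'
#' One row per (method, stringency) level: the number of co-acquisitions (the
#' comparability axis across methods), the observed and null-expected percent
#' of neighboring co-acquisitions, and — when the method reports donors — the
#' co-transfer percentages. Levels with fewer than `min_pairs`
#' co-acquisitions are marked excluded.
#'
#' @param events Gain-event tibble (any number of methods/stringencies).
#' @param orders Gene-order tibble.
#' @param tree Optional [species_tree].
#' @param t Neighbor definition: max intervening genes (default 1).
#' @param min_pairs Exclusion threshold on the co-acquisition count
#'   (default 20).
#' @param min_chrom_genes Chromosome-size filter (default 1000).
#' @return A tibble of class `hgt_eval` with columns method, stringency,
#'   n_coacquisitions, pct_neighbors, expected_pct_neighbors,
#'   pct_cotransfers, pct_neighbor_cotransfers, excluded, exclude_reason.
#' @export
stringency_sweep <- function(events, orders, tree = NULL, t = 1,
                             min_pairs = 20, min_chrom_genes = 1000) {
  levels <- dplyr::distinct(events, .data$method, .data$stringency)
  rows <- purrr::pmap_dfr(levels, function(method, stringency) {
    ev <- events[events$method == method & events$stringency == stringency, ]
    tab <- enumerate_coacquisitions(ev, orders, tree, t = t,
                                    min_chrom_genes = min_chrom_genes)
    n <- tab$n_pairs
    has_donor <- n > 0 && any(tab$pairs$cotransfer != "unknown")
    ct <- if (has_donor) cotransfer_stats(tab) else
      tibble::tibble(pct_cotransfers = NA_real_,
                     pct_neighbor_cotransfers = NA_real_)
    tibble::tibble(
      method = method, stringency = stringency, n_coacquisitions = n,
      pct_neighbors = if (n > 0) percent_neighbors(tab) else NA_real_,
      expected_pct_neighbors = if (n > 0) expected_neighbor_percent(tab)
        else NA_real_,
      pct_cotransfers = ct$pct_cotransfers,
      pct_neighbor_cotransfers = ct$pct_neighbor_cotransfers,
      excluded = n < min_pairs,
      exclude_reason = dplyr::case_when(n == 0 ~ "no-pairs",
                                        n < min_pairs ~ "min-pairs",
                                        TRUE ~ NA_character_))
  })
  rows <- dplyr::arrange(rows, .data$method, .data$stringency)
  class(rows) <- c("hgt_eval", class(rows))
  rows
}
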