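#' Read ordered gene annotations from a gene-order TSV
#'
#' The file must carry the header columns `taxon`, `chromosome`, `position`,
#' `gene_id`, `family_id` and optionally `strand`; unknown columns are kept.
#' Gene positions are 0-based, consecutive integers within each chromosome, so
#' the number of intervening genes between positions p < q is q - p - 1.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble of gene orders (one row per gene), sorted by taxon,
#'   chromosome and position, validated with [validate_gene_orders()].
#' @export
read_gene_orders <- function(path) {
  orders <- readr::read_tsv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              position = readr::col_integer(),
                              .default = readr::col_guess()))
  validate_gene_orders(orders)
}

#' Validate a gene-order tibble
#'
#' Checks the gene-order invariants: required columns present, gene ids unique
#' within a taxon, and positions forming a gapless 0..n-1 sequence per
#' (taxon, chromosome).
#'
#' @param orders A data frame of gene orders.
#' @return The validated tibble, sorted by taxon, chromosome, position.
#' @export
validate_gene_orders <- function(orders) {
  required <- c("taxon", "chromosome", "position", "gene_id", "family_id")
  missing <- setdiff(required, names(orders))
  if (length(missing))
    stop("gene orders missing columns: ", paste(missing, collapse = ", "))
  orders <- dplyr::arrange(tibble::as_tibble(orders),
                           .data$taxon, .data$chromosome, .data$position)
  dup <- orders |>
    dplyr::count(.data$taxon, .data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup))
    stop("duplicate gene_id within taxon: ",
         paste(utils::head(dup$gene_id, 3), collapse = ", "))
  bad <- orders |>
    dplyr::group_by(.data$taxon, .data$chromosome) |>
    dplyr::summarise(ok = identical(as.integer(.data$position),
                                    seq(0L, dplyr::n() - 1L)),
                     .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad))
    stop("non-consecutive positions on chromosome(s): ",
         paste(utils::head(paste(bad$taxon, bad$chromosome, sep = "/"), 3),
               collapse = ", "))
  orders
}

#' Read a gain-event TSV into an inference set
#'
#' Expected header: `method`, `stringency`, `family_id`, `recipient_branch`,
#' `donor_branch`, `confidence`. An empty or "." donor means the method does
#' not report a donor (implicit/parametric methods).
#'
#' @param path Path to a tab-separated file.
#' @param tree Optional [species_tree]; if given, recipient and donor labels
#'   are validated against the tree's node labels.
#' @return A tibble of gain events, one row per (stringency, event).
#' @export
read_gain_events <- function(path, tree = NULL) {
  ev <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          method = readr::col_character(),
                          stringency = readr::col_double(),
                          family_id = readr::col_character(),
                          recipient_branch = readr::col_character(),
                          donor_branch = readr::col_character(),
                          confidence = readr::col_double()))
  ev$donor_branch[!is.na(ev$donor_branch) & ev$donor_branch == "."] <- NA_character_
  validate_gain_events(ev, tree)
}

#' Validate a gain-event tibble
#'
#' @param events A data frame of gain events.
#' @param tree Optional [species_tree] for branch validation.
#' @return The validated tibble.
#' @export
validate_gain_events <- function(events, tree = NULL) {
  required <- c("method", "stringency", "family_id", "recipient_branch",
                "donor_branch", "confidence")
  missing <- setdiff(required, names(events))
  if (length(missing))
    stop("gain events missing columns: ", paste(missing, collapse = ", "))
  events <- tibble::as_tibble(events)
  same <- !is.na(events$donor_branch) &
    events$donor_branch == events$recipient_branch
  if (any(same))
    stop("donor equal to recipient for family ",
         events$family_id[which(same)[1]])
  if (!is.null(tree)) {
    labs <- tree$labels
    bad <- setdiff(events$recipient_branch, labs)
    if (length(bad))
      stop("recipient branch not in tree: ", paste(bad, collapse = ", "))
    badd <- setdiff(stats::na.omit(events$donor_branch), labs)
    if (length(badd))
      stop("donor branch not in tree: ", paste(badd, collapse = ", "))
  }
  events
}

#' Write gain events in the TSV dialect accepted by [read_gain_events()]
#'
#' @param events A gain-event tibble.
#' @param path Output path. Missing donors are written as empty fields.
#' @export
write_gain_events <- function(events, path) {
  required <- c("method", "stringency", "family_id", "recipient_branch",
                "donor_branch", "confidence")
  readr::write_tsv(events[required], path, na = "")
  invisible(path)
}

#' Family-by-taxon presence/absence (copy-number) matrix from gene orders
#'
#' @param orders A gene-order tibble.
#' @return An integer matrix, families as rows and taxa as columns, holding
#'   gene copy counts. Use `matrix > 0` for the binary phyletic-pattern view.
#' @export
presence_absence_from_orders <- function(orders) {
  orders <- validate_gene_orders(orders)
  tab <- table(factor(orders$family_id), factor(orders$taxon))
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}
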