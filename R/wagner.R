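#' Asymmetric Wagner parsimony for one gene family
#'
#' Sankoff dynamic program over presence states {0, 1} on the species tree,
#' with transition costs cost(0 -> 1) = `ratio` (a gain), cost(1 -> 0) = 1 (a
#' loss) and zero for no change. Presence at the root is charged as one stem
#' gain (cost `ratio`, reported with the root label as recipient) so gain
#' totals are comparable across families: every present family is gained
#' somewhere. Among minimum-cost labelings, ties are broken by preferring
#' absence (state 0) during the top-down traceback — the conservative
#' fewest-presence convention.
#'
#' @param tree A [species_tree].
#' @param presence Named logical/0-1 vector over all leaf labels; at least one
#'   leaf present.
#' @param ratio Gain/loss penalty ratio r > 0 (loss cost fixed at 1). Higher
#'   r = higher stringency = fewer inferred gains.
#' @return A list: `$gains` and `$losses` (character vectors of branch ids;
#'   `$gains` may contain the root label for a stem gain), `$cost` (the
#'   minimum total cost including any stem-gain charge), and `$states` (the
#'   reconstructed 0/1 state per node label).
#' @export
infer_family_gains <- function(tree, presence, ratio) {
  stopifnot(inherits(tree, "species_tree"), ratio > 0)
  leaves <- tree_leaves(tree)
  missing <- setdiff(leaves, names(presence))
  if (length(missing))
    stop("presence missing for leaf: ", paste(missing, collapse = ", "))
  pres <- as.integer(as.logical(presence[leaves]))
  names(pres) <- leaves
  if (!any(pres == 1)) stop("family absent from every leaf")

  trans <- matrix(c(0, ratio, 1, 0), nrow = 2, byrow = TRUE)  # [from+1, to+1]
  labels <- tree$labels
  cost <- matrix(NA_real_, nrow = length(labels), ncol = 2,
                 dimnames = list(labels, NULL))

  for (node in rev(tree$preorder)) {          # postorder
    if (node %in% leaves) {
      s <- pres[[node]]
      cost[node, ] <- c(Inf, Inf)
      cost[node, s + 1] <- 0
    } else {
      kids <- tree$children[[node]]
      for (s in 0:1) {
        tot <- 0
        for (k in kids)
          tot <- tot + min(cost[k, 1] + trans[s + 1, 1],
                           cost[k, 2] + trans[s + 1, 2])
        cost[node, s + 1] <- tot
      }
    }
  }

  root <- tree$root
  # stem-gain charge: root presence costs one gain
  root_tot <- c(cost[root, 1], cost[root, 2] + ratio)
  root_state <- which.min(root_tot) - 1L      # which.min prefers 0 on ties

  states <- stats::setNames(integer(length(labels)), labels)
  states[root] <- root_state
  gains <- character(0)
  losses <- character(0)
  if (root_state == 1L) gains <- root

  for (node in tree$preorder) {
    if (node %in% leaves || is.null(tree$children[[node]])) next
    s <- states[[node]]
    for (k in tree$children[[node]]) {
      opts <- c(cost[k, 1] + trans[s + 1, 1], cost[k, 2] + trans[s + 1, 2])
      ks <- which.min(opts) - 1L              # tie -> state 0
      states[[k]] <- ks
      if (s == 0L && ks == 1L) gains <- c(gains, k)
      if (s == 1L && ks == 0L) losses <- c(losses, k)
    }
  }

  list(gains = gains, losses = losses,
       cost = unname(min(root_tot)), states = states)
}

#' Sweep the gain/loss penalty ratio over a presence/absence matrix
#'
#' Runs [infer_family_gains()] for every family and every ratio in the sweep;
#' the ratio is the stringency axis of the resulting inference set. Families
#' sharing a phyletic pattern are reconstructed once per ratio and the result
#' reused.
#'
#' @param tree A [species_tree].
#' @param pa_matrix Family-by-taxon count (or binary) matrix, as from
#'   [presence_absence_from_orders()]; columns must cover the tree's leaves.
#' @param ratios Numeric vector of gain/loss penalty ratios (default 1..8).
#' @return A gain-event tibble (method "wagner_mp", stringency = ratio,
#'   donors absent, confidence 1). Families absent everywhere yield no
#'   events.
#' @export
sweep_ratios <- function(tree, pa_matrix, ratios = 1:8) {
  stopifnot(is.matrix(pa_matrix))
  leaves <- tree_leaves(tree)
  missing <- setdiff(leaves, colnames(pa_matrix))
  if (length(missing))
    stop("matrix missing taxa: ", paste(missing, collapse = ", "))
  bin <- pa_matrix[, leaves, drop = FALSE] > 0

  keep <- rowSums(bin) > 0
  bin <- bin[keep, , drop = FALSE]
  if (nrow(bin) == 0)
    return(tibble::tibble(method = character(), stringency = double(),
                          family_id = character(),
                          recipient_branch = character(),
                          donor_branch = character(), confidence = double()))

  pattern <- apply(bin, 1, paste, collapse = "")
  fams_by_pattern <- split(rownames(bin), pattern)

  purrr::map_dfr(ratios, function(r) {
    purrr::map_dfr(fams_by_pattern, function(fams) {
      pres <- bin[fams[1], ]
      res <- infer_family_gains(tree, pres, r)
      if (!length(res$gains)) return(NULL)
      tidyr::expand_grid(family_id = fams, recipient_branch = res$gains) |>
        dplyr::mutate(method = "wagner_mp", stringency = r,
                      donor_branch = NA_character_, confidence = 1,
                      .before = 1) |>
        dplyr::select("method", "stringency", "family_id",
                      "recipient_branch", "donor_branch", "confidence")
    })
  })
}
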