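# Independent oracles and fixture builders used across the suite.

# Exhaustive minimum-cost asymmetric Wagner parsimony: enumerate every 0/1
# labeling of the internal nodes, cost = sum of branch transitions
# (gain = r, loss = 1) plus a stem-gain charge r when the root is present.
brute_force_wagner_cost <- function(tree, presence, r) {
  internals <- setdiff(tree$labels, tree_leaves(tree))
  pres <- as.integer(as.logical(presence[tree_leaves(tree)]))
  names(pres) <- tree_leaves(tree)
  best <- Inf
  for (mask in 0:(2^length(internals) - 1)) {
    bits <- bitwAnd(bitwShiftR(mask, seq_along(internals) - 1L), 1L)
    st <- c(pres, stats::setNames(bits, internals))
    cost <- if (st[[tree$root]] == 1L) r else 0
    for (b in setdiff(tree$labels, tree$root)) {
      ps <- st[[tree$parent[[b]]]]
      cs <- st[[b]]
      cost <- cost + if (ps == 0L && cs == 1L) r else
        if (ps == 1L && cs == 0L) 1 else 0
    }
    best <- min(best, cost)
  }
  best
}

# Monte-Carlo null: place c gained genes uniformly at random (distinct
# positions) on a g-gene chromosome and record the fraction of gene pairs
# separated by at most t intervening genes.
mc_neighbor_fraction <- function(g, c, t, reps, seed) {
  set.seed(seed)
  tot <- c * (c - 1) / 2
  fr <- vapply(seq_len(reps), function(i) {
    p <- sort.int(sample.int(g, c))
    cnt <- 0L
    for (j in 1:(c - 1)) {
      d <- p[(1 + j):c] - p[1:(c - j)]
      cnt <- cnt + sum(d <= t + 1L)
      if (min(d) > t + 1L) break  # shift-j minimum gap is non-decreasing in j
    }
    cnt / tot
  }, numeric(1))
  list(mean = mean(fr), se = stats::sd(fr) / sqrt(reps))
}

# Synthetic co-acquisition table built directly from per-chromosome tallies
# and a vector of intervening distances (for arithmetic-level tests).
make_coacq_table <- function(intervening, t = 1, g = 1000,
                             cotransfer = rep("unknown", length(intervening))) {
  n <- length(intervening)
  structure(list(
    pairs = tibble::tibble(
      taxon = "tx", chromosome = "chr1",
      gene_a = paste0("a", seq_len(n)), gene_b = paste0("b", seq_len(n)),
      family_a = paste0("FA", seq_len(n)), family_b = paste0("FB", seq_len(n)),
      intervening = as.integer(intervening), cotransfer = cotransfer),
    tallies = tibble::tibble(taxon = "tx", chromosome = "chr1",
                             c_i = n, g_i = as.integer(g)),
    t = t, n_pairs = n), class = "coacq_table")
}

# Tallies-only table for the analytic null formula (multi-chromosome).
make_tally_table <- function(c_i, g_i, t = 1) {
  structure(list(
    pairs = tibble::tibble(intervening = integer(), cotransfer = character()),
    tallies = tibble::tibble(taxon = "tx",
                             chromosome = paste0("chr", seq_along(c_i)),
                             c_i = as.integer(c_i), g_i = as.integer(g_i)),
    t = t, n_pairs = sum(c_i)), class = "coacq_table")
}

# One-taxon gene-order tibble: n background genes with unique families;
# `gained` is a named character vector position -> family id overriding the
# background family at that 0-based position.
make_orders <- function(taxon = "tx", n = 1200, gained = character(0),
                        chromosome = "chr1") {
  fams <- paste0("BG", seq_len(n))
  if (length(gained))
    fams[as.integer(names(gained)) + 1L] <- unname(gained)
  tibble::tibble(taxon = taxon, chromosome = chromosome,
                 position = 0:(n - 1), gene_id = paste0(taxon, "_g", 1:n),
                 family_id = fams, strand = "+")
}

make_events <- function(families, recipient, donors = NA_character_,
                        method = "m", stringency = 1, confidence = 1) {
  tibble::tibble(method = method, stringency = stringency,
                 family_id = families, recipient_branch = recipient,
                 donor_branch = donors, confidence = confidence)
}

# Orders for a standalone genome with implanted terminal-branch acquisitions
# at random positions (for Wn end-to-end tests); fraction `implant_frac`.
make_wn_orders <- function(n = 1000, implant_frac = 0.05, taxon = "tx",
                           seed = 1) {
  set.seed(seed)
  imp <- sample.int(n, round(implant_frac * n))
  tibble::tibble(taxon = taxon, chromosome = "chr1", position = 0:(n - 1),
                 gene_id = paste0(taxon, "_g", 1:n),
                 family_id = paste0("F", 1:n), strand = "+",
                 origin_branch = ifelse(seq_len(n) %in% imp, taxon,
                                        NA_character_),
                 event_id = NA_integer_)
}

read_tree_text <- function(text) {
  tf <- withr::local_tempfile(fileext = ".nwk",
                              .local_envir = parent.frame())
  writeLines(text, tf)
  read_species_tree(tf)
}
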