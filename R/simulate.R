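#' Parameters for the genome-evolution simulator
#'
#' Defaults describe a single circular-free (linear) chromosome of 1,200 gene
#' families evolving under per-branch gene loss, segmental horizontal transfer
#' and occasional translocation. The root genome size is set above 1,000 so
#' that, under the default loss rate, extant chromosomes stay above the
#' 1,000-gene threshold used by the co-acquisition evaluation.
#'
#' @param root_size Number of gene families in the root genome (single
#'   chromosome).
#' @param p_loss Per-branch, per-gene loss probability.
#' @param hgt_rate Expected number of HGT events per unit branch length
#'   (Poisson).
#' @param p_seg Success probability of the geometric segment-length
#'   distribution (support >= 1); `p_seg` is also the fraction of single-gene
#'   transfers.
#' @param rearr_rate Expected number of translocations per unit branch length.
#' @param p_novel Probability that an HGT event introduces brand-new families
#'   (influx from outside the sampled taxa) instead of copying a donor
#'   segment.
#' @param seed Integer random seed.
#' @return A list of class `evolution_params`.
#' @export
evolution_params <- function(root_size = 1200, p_loss = 0.02, hgt_rate = 15,
                             p_seg = 0.3, rearr_rate = 1, p_novel = 0.1,
                             seed = 1) {
  stopifnot(root_size >= 1,
            p_loss >= 0, p_loss <= 1,
            hgt_rate >= 0, rearr_rate >= 0,
            p_seg > 0, p_seg <= 1,
            p_novel >= 0, p_novel <= 1)
  structure(list(root_size = as.integer(root_size), p_loss = p_loss,
                 hgt_rate = hgt_rate, p_seg = p_seg, rearr_rate = rearr_rate,
                 p_novel = p_novel, seed = as.integer(seed)),
            class = "evolution_params")
}

#' Simulate a Yule species tree with depth normalized to 1
#'
#' @param n_taxa Number of leaves (>= 2).
#' @param seed Integer random seed; identical seeds give identical trees.
#' @return A [species_tree] with leaves `t1..tn` and auto-labeled internal
#'   nodes.
#' @export
simulate_species_tree <- function(n_taxa, seed = 1) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  phy <- ape::rphylo(n_taxa, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length / depth
  phy$node.label <- NULL
  as_species_tree(phy)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# geometric segment length with support >= 1, truncated at `max_len`
.rgeom1 <- function(p, max_len = Inf) {
  min(stats::rgeom(1, p) + 1L, max_len)
}

#' Evolve genomes along a species tree with segmental HGT
#'
#' The root genome is one chromosome of `root_size` families, F0001.. in
#' order. Along each branch in preorder: (1) each gene is lost independently
#' with probability `p_loss` (the order closes the gap); (2) a Poisson number
#' of HGT events insert a contiguous donor segment (geometric length) at a
#' uniform position — with probability `p_novel` the segment consists of
#' brand-new families; (3) a Poisson number of translocations excise a
#' geometric-length segment and reinsert it elsewhere. Genes carry their
#' origin branch so terminal-branch acquisitions can be located in the leaf
#' annotations.
#'
#' Donor branches are sampled uniformly among branches off the recipient's
#' root path; the transferred segment is read from the genome of the deepest
#' already-evolved node on the donor's own root path (at minimum the root), so
#' segments are always contiguous in a concrete donor-lineage genome.
#'
#' @param tree A [species_tree].
#' @param params An [evolution_params] object.
#' @return A list with `$orders` (leaf gene-order tibble, with extra columns
#'   `origin_branch` and `event_id` recording provenance) and `$truth` (a
#'   `truth_log`: `$transfers`, `$losses`, `$gains`).
#' @export
evolve_genomes <- function(tree, params) {
  stopifnot(inherits(tree, "species_tree"), inherits(params, "evolution_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  G <- params$root_size
  wid <- max(4L, nchar(as.character(G)))
  root_fams <- sprintf(paste0("F%0", wid, "d"), seq_len(G))
  state <- list()
  state[[tree$root]] <- list(fam = root_fams,
                             origin = rep(NA_character_, G),
                             event = rep(NA_integer_, G))
  branches <- tree_branches(tree)
  novel_counter <- 0L
  event_counter <- 0L
  transfers <- list()
  losses <- list()

  # deepest already-evolved node on `label`'s root path
  donor_genome <- function(label) {
    for (lab in root_path(tree, label)) {
      if (!is.null(state[[lab]])) return(state[[lab]])
    }
    state[[tree$root]]
  }

  for (node in tree$preorder) {
    if (node == tree$root) next
    par <- tree$parent[[node]]
    bl <- tree$branch_length[[node]]
    g <- state[[par]]

    # (1) losses
    if (params$p_loss > 0 && length(g$fam) > 0) {
      keep <- stats::runif(length(g$fam)) >= params$p_loss
      if (any(!keep))
        losses[[length(losses) + 1L]] <-
          tibble::tibble(family_id = g$fam[!keep], branch = node)
      g <- lapply(g, `[`, keep)
    }
    if (length(g$fam) == 0)
      stop("empty genome at branch ", node)

    # (2) segmental HGT
    n_hgt <- stats::rpois(1, params$hgt_rate * bl)
    if (n_hgt > 0) {
      path <- root_path(tree, node)
      candidates <- setdiff(branches, path)
      for (i in seq_len(n_hgt)) {
        donor_br <- if (length(candidates)) sample(candidates, 1) else NA_character_
        if (stats::runif(1) < params$p_novel || is.na(donor_br)) {
          len <- .rgeom1(params$p_seg)
          seg <- sprintf(paste0("X%0", wid, "d"), novel_counter + seq_len(len))
          novel_counter <- novel_counter + len
        } else {
          dg <- donor_genome(donor_br)$fam
          start <- sample.int(length(dg), 1)
          len <- .rgeom1(params$p_seg, max_len = length(dg) - start + 1L)
          seg <- dg[start:(start + len - 1L)]
        }
        event_counter <- event_counter + 1L
        transfers[[event_counter]] <- tibble::tibble(
          event_id = event_counter, donor_branch = donor_br,
          recipient_branch = node, families = list(seg))
        at <- sample.int(length(g$fam) + 1L, 1) - 1L  # insert after `at` genes
        g <- list(fam = append(g$fam, seg, after = at),
                  origin = append(g$origin, rep(node, length(seg)), after = at),
                  event = append(g$event, rep(event_counter, length(seg)),
                                 after = at))
      }
    }

    # (3) translocations
    n_re <- stats::rpois(1, params$rearr_rate * bl)
    for (i in seq_len(n_re)) {
      n <- length(g$fam)
      if (n < 2) break
      start <- sample.int(n, 1)
      len <- .rgeom1(params$p_seg, max_len = n - start + 1L)
      block <- start:(start + len - 1L)
      rest <- setdiff(seq_len(n), block)
      at <- sample.int(length(rest) + 1L, 1) - 1L
      reorder <- append(rest, block, after = at)
      g <- lapply(g, `[`, reorder)
    }

    state[[node]] <- g
  }

  orders <- purrr::map_dfr(tree$leaves, function(leaf) {
    g <- state[[leaf]]
    tibble::tibble(taxon = leaf, chromosome = "chr1",
                   position = seq_along(g$fam) - 1L,
                   gene_id = paste0(leaf, "_g", seq_along(g$fam)),
                   family_id = g$fam, strand = "+",
                   origin_branch = g$origin, event_id = g$event)
  })

  transfers <- if (length(transfers)) dplyr::bind_rows(transfers) else
    tibble::tibble(event_id = integer(), donor_branch = character(),
                   recipient_branch = character(), families = list())
  losses <- if (length(losses)) dplyr::bind_rows(losses) else
    tibble::tibble(family_id = character(), branch = character())
  gains <- if (nrow(transfers)) {
    tidyr::unnest(
      dplyr::mutate(transfers, family_id = .data$families),
      "family_id")[, c("event_id", "family_id", "recipient_branch",
                       "donor_branch")]
  } else {
    tibble::tibble(event_id = integer(), family_id = character(),
                   recipient_branch = character(), donor_branch = character())
  }

  truth <- structure(list(transfers = transfers, losses = losses,
                          gains = gains), class = "truth_log")
  list(orders = orders, truth = truth)
}

#' @export
print.truth_log <- function(x, ...) {
  cat("Truth log:", nrow(x$transfers), "transfer events,",
      nrow(x$gains), "gained genes,", nrow(x$losses), "losses\n")
  invisible(x)
}

#' Ground-truth inference set from a simulator truth log
#'
#' One gain event per gained (family, recipient branch) pair, carrying the
#' true donor and confidence 1, at a single stringency level.
#'
#' @param log A `truth_log` from [evolve_genomes()].
#' @return A gain-event tibble (method "truth", stringency 1).
#' @export
truth_inference <- function(log) {
  stopifnot(inherits(log, "truth_log"))
  g <- dplyr::distinct(log$gains, .data$family_id, .data$recipient_branch,
                       .keep_all = TRUE)
  tibble::tibble(method = "truth", stringency = 1,
                 family_id = g$family_id,
                 recipient_branch = g$recipient_branch,
                 donor_branch = g$donor_branch,
                 confidence = 1)
}

#' Corrupt a ground-truth inference set with false negatives and positives
#'
#' Each true event is dropped with probability `fnr`. False events are added
#' as uniformly random (family, terminal branch) pairs absent from the truth;
#' their count is `fpr / (1 - fpr)` times the retained-truth count, so `fpr`
#' is the expected false fraction of the output. Confidences are drawn
#' Beta(8, 2) for true and Beta(2, 8) for false events, and stringency levels
#' 1..10 are the deciles of the confidence distribution (level d keeps events
#' with confidence at or above the d-th decile), so thresholding the
#' confidence enacts a stringency sweep with rising precision.
#'
#' @param truth A single-level gain-event tibble (e.g. from
#'   [truth_inference()]).
#' @param fpr,fnr False-positive and false-negative rates in [0, 1).
#' @param tree The [species_tree] (terminal branches host false events).
#' @param families Character vector: the family universe to draw false events
#'   from.
#' @param seed Integer random seed.
#' @return A gain-event tibble with 10 nested stringency levels; false events
#'   carry no donor.
#' @export
corrupt_inference <- function(truth, fpr, fnr, tree, families, seed = 1) {
  stopifnot(fpr >= 0, fpr < 1, fnr >= 0, fnr < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  keep <- stats::runif(nrow(truth)) >= fnr
  kept <- truth[keep, ]
  n_false <- round(fpr / (1 - fpr) * nrow(kept))

  ev <- tibble::tibble(family_id = kept$family_id,
                       recipient_branch = kept$recipient_branch,
                       donor_branch = kept$donor_branch,
                       confidence = stats::rbeta(nrow(kept), 8, 2))
  if (n_false > 0) {
    leaves <- tree_leaves(tree)
    universe <- tidyr::expand_grid(family_id = unique(families),
                                   recipient_branch = leaves)
    truth_keys <- paste(truth$family_id, truth$recipient_branch)
    pool <- universe[!paste(universe$family_id, universe$recipient_branch)
                     %in% truth_keys, ]
    if (nrow(pool) < n_false)
      stop("family/branch universe too small for requested fpr")
    fake <- pool[sample.int(nrow(pool), n_false), ]
    ev <- dplyr::bind_rows(ev, tibble::tibble(
      family_id = fake$family_id,
      recipient_branch = fake$recipient_branch,
      donor_branch = NA_character_,
      confidence = stats::rbeta(n_false, 2, 8)))
  }

  cuts <- stats::quantile(ev$confidence, probs = seq(0, 0.9, by = 0.1),
                          names = FALSE)
  method <- sprintf("corrupt_fpr%g_fnr%g", fpr, fnr)
  purrr::map_dfr(seq_along(cuts), function(d) {
    lv <- ev[ev$confidence >= cuts[d], ]
    tibble::tibble(method = method, stringency = d,
                   family_id = lv$family_id,
                   recipient_branch = lv$recipient_branch,
                   donor_branch = lv$donor_branch,
                   confidence = lv$confidence)
  })
}

#' Simulate per-gene nucleotide sequences with a compositional HGT signal
#'
#' Each taxon receives a genome-specific order-0 nucleotide composition with
#' GC content drawn uniformly from [0.35, 0.65]; native genes are sampled
#' i.i.d. from it. Genes acquired on the taxon's terminal branch (per the
#' `origin_branch` column written by [evolve_genomes()]) are sampled from a
#' composition whose GC content is displaced by `shift` toward the farther
#' GC boundary (clamped to [0.05, 0.95]), giving transferred genes an
#' atypical oligonucleotide signature of controlled magnitude.
#'
#' @param orders Leaf gene-order tibble from [evolve_genomes()] (must carry
#'   `origin_branch`).
#' @param shift GC displacement of transferred genes, in [0, 0.5].
#' @param gene_len Length of every simulated gene (>= 100).
#' @param seed Integer random seed.
#' @return A named list (by taxon) of [Biostrings::DNAStringSet], one record
#'   per gene id.
#' @export
simulate_sequences <- function(orders, shift = 0.3, gene_len = 300, seed = 1) {
  stopifnot(shift >= 0, shift <= 0.5, gene_len >= 100)
  if (!"origin_branch" %in% names(orders))
    stop("`orders` must carry the simulator's origin_branch column")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  bases <- c("A", "C", "G", "T")
  gc_probs <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

  taxa <- unique(orders$taxon)
  out <- lapply(taxa, function(tx) {
    ann <- orders[orders$taxon == tx, ]
    gc <- stats::runif(1, 0.35, 0.65)
    gc_t <- if (gc < 0.5) gc + shift else gc - shift
    gc_t <- min(max(gc_t, 0.05), 0.95)
    transferred <- !is.na(ann$origin_branch) & ann$origin_branch == tx
    seqs <- vapply(seq_len(nrow(ann)), function(i) {
      p <- if (transferred[i]) gc_probs(gc_t) else gc_probs(gc)
      paste(sample(bases, gene_len, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    Biostrings::DNAStringSet(stats::setNames(seqs, ann$gene_id))
  })
  stats::setNames(out, taxa)
}

#' Write per-taxon gene sequences to FASTA files
#'
#' @param seqs Named list of [Biostrings::DNAStringSet] as returned by
#'   [simulate_sequences()].
#' @param dir Output directory; one `<taxon>.fasta` file per taxon.
#' @export
write_taxon_fasta <- function(seqs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tx in names(seqs)) {
    Biostrings::writeXStringSet(seqs[[tx]], file.path(dir, paste0(tx, ".fasta")))
  }
  invisible(dir)
}
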