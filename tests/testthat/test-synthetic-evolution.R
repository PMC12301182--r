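test_that("Yule trees are deterministic, depth-normalized, right-sized", {
  tr1 <- simulate_species_tree(50, seed = 11)
  tr2 <- simulate_species_tree(50, seed = 11)
  expect_identical(ape::write.tree(tr1$phy), ape::write.tree(tr2$phy))
  expect_length(tree_leaves(tr1), 50)
  expect_equal(max(ape::node.depth.edgelength(tr1$phy)), 1, tolerance = 1e-9)
  expect_error(simulate_species_tree(1), "n_taxa")

  cherry <- simulate_species_tree(2, seed = 1)
  expect_length(tree_branches(cherry), 2)
})

test_that("evolution without loss, transfer or rearrangement is the identity", {
  tr <- simulate_species_tree(6, seed = 2)
  p <- evolution_params(root_size = 50, p_loss = 0, hgt_rate = 0,
                        rearr_rate = 0, seed = 1)
  sim <- evolve_genomes(tr, p)
  for (tx in tree_leaves(tr)) {
    fams <- sim$orders$family_id[sim$orders$taxon == tx]
    expect_identical(fams, sprintf("F%04d", 1:50))
  }
  expect_equal(nrow(sim$truth$transfers), 0)
  expect_equal(nrow(truth_inference(sim$truth)), 0)
})

test_that("evolution is seed-deterministic and conserves gene counts", {
  tr <- simulate_species_tree(8, seed = 4)
  p <- evolution_params(root_size = 100, p_loss = 0.05, hgt_rate = 10,
                        rearr_rate = 2, seed = 9)
  sim1 <- evolve_genomes(tr, p)
  sim2 <- evolve_genomes(tr, p)
  expect_equal(sim1$orders, sim2$orders)

  # every gain in the derived list maps to exactly one transfer event, and
  # total gains equal the summed segment lengths
  expect_equal(nrow(sim1$truth$gains),
               sum(lengths(sim1$truth$transfers$families)))
  expect_true(all(sim1$truth$gains$event_id %in%
                    sim1$truth$transfers$event_id))

  # leaf genome size = root size - losses + gains along the root path
  for (tx in tree_leaves(tr)) {
    path <- root_path(tr, tx, include_self = TRUE)
    n_loss <- sum(sim1$truth$losses$branch %in% path)
    n_gain <- sum(sim1$truth$gains$recipient_branch %in% path)
    expect_equal(sum(sim1$orders$taxon == tx), 100 - n_loss + n_gain)
  }
})

test_that("multi-gene transfers onto terminal branches stay contiguous
           without rearrangement", {
  tr <- simulate_species_tree(8, seed = 6)
  p <- evolution_params(root_size = 120, p_loss = 0, hgt_rate = 12,
                        rearr_rate = 0, seed = 5)
  sim <- evolve_genomes(tr, p)
  term <- sim$truth$transfers[
    sim$truth$transfers$recipient_branch %in% tree_leaves(tr) &
      lengths(sim$truth$transfers$families) > 1, ]
  expect_gt(nrow(term), 0)
  for (i in seq_len(nrow(term))) {
    tx <- term$recipient_branch[i]
    ann <- sim$orders[sim$orders$taxon == tx, ]
    # a later transfer may insert inside an earlier block; contiguity holds
    # after setting aside genes gained by later events on the same branch
    keep <- is.na(ann$event_id) | ann$event_id <= term$event_id[i]
    ranks <- which(!is.na(ann$event_id[keep]) &
                     ann$event_id[keep] == term$event_id[i])
    expect_identical(ranks, seq(min(ranks), max(ranks)))
  }
})

test_that("truth inference keeps one event per gained family with its donor", {
  tr <- simulate_species_tree(6, seed = 3)
  p <- evolution_params(root_size = 80, p_loss = 0, hgt_rate = 8,
                        p_seg = 0.25, seed = 7)
  sim <- evolve_genomes(tr, p)
  ti <- truth_inference(sim$truth)
  expect_true(all(ti$confidence == 1))
  expect_equal(anyDuplicated(paste(ti$family_id, ti$recipient_branch)), 0)

  seg3 <- sim$truth$transfers[lengths(sim$truth$transfers$families) >= 3, ]
  expect_gt(nrow(seg3), 0)
  fams <- seg3$families[[1]]
  sub <- ti[ti$family_id %in% fams &
              ti$recipient_branch == seg3$recipient_branch[1], ]
  expect_equal(dplyr::n_distinct(sub$donor_branch), 1)

  # round-trip through the gain-event TSV dialect
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_gain_events(ti, tf)
  expect_equal(read_gain_events(tf, tr), ti)
})

test_that("corruption keeps truth at fpr=fnr=0 and obeys the false-count
           formula", {
  tr <- simulate_species_tree(10, seed = 5)
  p <- evolution_params(root_size = 150, hgt_rate = 10, seed = 2)
  sim <- evolve_genomes(tr, p)
  truth <- truth_inference(sim$truth)
  fams <- unique(sim$orders$family_id)

  clean <- corrupt_inference(truth, 0, 0, tr, fams, seed = 1)
  lvl1 <- clean[clean$stringency == 1, ]
  expect_setequal(paste(lvl1$family_id, lvl1$recipient_branch),
                  paste(truth$family_id, truth$recipient_branch))

  half <- corrupt_inference(truth, 0.5, 0, tr, fams, seed = 1)
  h1 <- half[half$stringency == 1, ]
  n_false <- sum(is.na(h1$donor_branch) &
                   !paste(h1$family_id, h1$recipient_branch) %in%
                     paste(truth$family_id, truth$recipient_branch))
  expect_equal(nrow(h1) - n_false, nrow(truth))   # all truth retained
  expect_equal(n_false, nrow(truth))              # fpr/(1-fpr) = 1
})

test_that("confidence thresholds enact a stringency sweep with rising
           precision", {
  tr <- simulate_species_tree(10, seed = 8)
  p <- evolution_params(root_size = 150, hgt_rate = 10, seed = 3)
  sim <- evolve_genomes(tr, p)
  truth <- truth_inference(sim$truth)
  fams <- unique(sim$orders$family_id)
  truth_keys <- paste(truth$family_id, truth$recipient_branch)

  prec_gain <- vapply(1:20, function(seed) {
    cor <- corrupt_inference(truth, 0.4, 0.1, tr, fams, seed = seed)
    prec <- vapply(c(1, 10), function(d) {
      lv <- cor[cor$stringency == d, ]
      mean(paste(lv$family_id, lv$recipient_branch) %in% truth_keys)
    }, numeric(1))
    prec[2] - prec[1]
  }, numeric(1))
  expect_gt(mean(prec_gain), 0)
})

test_that("simulated sequences have the requested length, alphabet and GC
           displacement", {
  orders <- make_wn_orders(n = 200, implant_frac = 0.25, seed = 10)
  seqs <- simulate_sequences(orders, shift = 0.3, gene_len = 400, seed = 21)
  expect_setequal(names(seqs$tx), orders$gene_id)
  expect_true(all(Biostrings::width(seqs$tx) == 400))
  expect_true(all(Biostrings::alphabetFrequency(seqs$tx)[, -(1:4)] == 0))

  gc <- Biostrings::letterFrequency(seqs$tx, "GC", as.prob = TRUE)[, 1]
  imp <- !is.na(orders$origin_branch)
  expect_equal(abs(mean(gc[imp]) - mean(gc[!imp])), 0.3, tolerance = 0.02)

  # shift 0: native and transferred indistinguishable in GC
  seqs0 <- simulate_sequences(orders, shift = 0, gene_len = 400, seed = 21)
  gc0 <- Biostrings::letterFrequency(seqs0$tx, "GC", as.prob = TRUE)[, 1]
  expect_lt(abs(mean(gc0[imp]) - mean(gc0[!imp])), 0.02)
})
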