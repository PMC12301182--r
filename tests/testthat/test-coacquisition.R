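test_that("adjacent gains on a large chromosome form one neighboring pair", {
  orders <- make_orders(n = 1200, gained = c(`3` = "F1", `4` = "F2"))
  ev <- make_events(c("F1", "F2"), "tx")
  tab <- enumerate_coacquisitions(ev, orders, t = 1)
  expect_equal(tab$n_pairs, 1)
  expect_equal(tab$pairs$intervening, 0L)
  expect_equal(percent_neighbors(tab), 100)
  expect_equal(tab$tallies$c_i, 1L)
  expect_equal(tab$tallies$g_i, 1200L)
})

test_that("chromosomes under 1,000 genes are excluded", {
  orders <- make_orders(n = 800, gained = c(`3` = "F1", `4` = "F2"))
  ev <- make_events(c("F1", "F2"), "tx")
  tab <- enumerate_coacquisitions(ev, orders, t = 1)
  expect_equal(tab$n_pairs, 0)
})

test_that("pairs require the same chromosome and different families", {
  orders <- dplyr::bind_rows(
    make_orders(n = 1100, gained = c(`5` = "F1"), chromosome = "c1"),
    make_orders(n = 1100, gained = c(`5` = "F2"), chromosome = "c2") |>
      dplyr::mutate(gene_id = paste0("c2_", gene_id),
                    family_id = sub("^BG", "BH", family_id)))
  ev <- make_events(c("F1", "F2"), "tx")
  expect_equal(enumerate_coacquisitions(ev, orders, t = 1)$n_pairs, 0)

  # same family twice never forms a pair; multi-copy families expand fully
  orders2 <- make_orders(n = 1100, gained = c(`2` = "F1", `5` = "F1",
                                              `9` = "F2"))
  ev2 <- make_events(c("F1", "F2"), "tx")
  tab2 <- enumerate_coacquisitions(ev2, orders2, t = 1)
  expect_equal(tab2$n_pairs, 2)  # each F1 copy against F2, not F1-F1
})

test_that("internal-branch gains and unannotated taxa are ignored", {
  tr <- read_tree_text("((A:1,B:1)N1:1,C:2)N0;")
  orders <- make_orders(taxon = "A", n = 1100,
                        gained = c(`1` = "F1", `2` = "F2"))
  ev <- make_events(c("F1", "F2", "F1", "F2"), c("A", "A", "N1", "N1"))
  tab <- enumerate_coacquisitions(ev, orders, tr, t = 1)
  expect_equal(tab$n_pairs, 1)

  ev_b <- make_events(c("F1", "F2"), "B")  # leaf without annotation
  expect_message(tab_b <- enumerate_coacquisitions(ev_b, orders, tr, t = 1),
                 "skipped")
  expect_equal(tab_b$n_pairs, 0)
})

test_that("neighbor percentage follows the intervening-gene cutoff", {
  expect_equal(percent_neighbors(make_coacq_table(c(0L))), 100)
  expect_equal(percent_neighbors(make_coacq_table(c(2L))), 0)
  expect_equal(percent_neighbors(make_coacq_table(c(0L, 1L, 5L))), 200 / 3,
               tolerance = 1e-10)
  expect_error(percent_neighbors(make_coacq_table(integer(0))), "undefined")
})

test_that("the analytic null reduces to 2(t+1)/g on one chromosome", {
  expect_equal(expected_neighbor_percent(make_tally_table(10, 1000, t = 1)),
               0.4)
  expect_equal(expected_neighbor_percent(make_tally_table(10, 1000, t = 0)),
               0.2)
  # two chromosomes, evaluated by hand from the printed expression
  expect_equal(expected_neighbor_percent(
    make_tally_table(c(10, 30), c(1000, 2000), t = 1)), 0.25)
})

test_that("the analytic null matches Monte-Carlo random gene placement", {
  for (par in list(c(1000, 10, 1), c(2000, 50, 0))) {
    mc <- mc_neighbor_fraction(par[1], par[2], par[3], reps = 20000,
                               seed = sum(par))
    form <- expected_neighbor_percent(
      make_tally_table(par[2], par[1], t = par[3]))
    expect_lt(abs(form - 100 * mc$mean), 3 * 100 * mc$se)
  }
})

test_that("co-transfer percentages use all co-acquisitions as denominator", {
  tab <- make_coacq_table(c(0L, 4L), cotransfer = c("yes", "no"))
  st <- cotransfer_stats(tab)
  expect_equal(st$pct_cotransfers, 50)
  expect_equal(st$pct_neighbor_cotransfers, 50)

  tab2 <- make_coacq_table(c(4L), cotransfer = "yes")
  st2 <- cotransfer_stats(tab2)
  expect_equal(st2$pct_cotransfers, 100)
  expect_equal(st2$pct_neighbor_cotransfers, 0)

  expect_error(cotransfer_stats(make_coacq_table(c(0L, 1L))), "no donors")
})

test_that("stringency sweeps mark sparse levels excluded and stay monotone
           for threshold sets", {
  tr <- simulate_species_tree(12, seed = 13)
  p <- evolution_params(root_size = 1100, hgt_rate = 12, seed = 13)
  sim <- evolve_genomes(tr, p)
  truth <- truth_inference(sim$truth)
  cor <- corrupt_inference(truth, 0.3, 0.1, tr,
                           unique(sim$orders$family_id), seed = 4)
  eval <- stringency_sweep(cor, sim$orders, tr, t = 1)
  expect_s3_class(eval, "hgt_eval")
  expect_true(all(diff(eval$n_coacquisitions) <= 0))  # nested decile levels
  expect_true(all(eval$pct_neighbors[!eval$excluded] >= 0))

  # a level with almost no events is excluded with a reason
  tiny <- make_events("F1", sim$orders$taxon[1], method = "tiny")
  orders1 <- sim$orders
  ev_tiny <- stringency_sweep(tiny, orders1, tr, t = 1)
  expect_true(ev_tiny$excluded[1])
  expect_match(ev_tiny$exclude_reason[1], "pairs")
})

test_that("true segmental-transfer inferences beat the null expectation", {
  hits <- vapply(1:5, function(seed) {
    tr <- simulate_species_tree(15, seed = seed)
    p <- evolution_params(root_size = 1100, hgt_rate = 12, rearr_rate = 0,
                          p_loss = 0, seed = seed)
    sim <- evolve_genomes(tr, p)
    tab <- enumerate_coacquisitions(truth_inference(sim$truth), sim$orders,
                                    tr, t = 1)
    percent_neighbors(tab) > expected_neighbor_percent(tab)
  }, logical(1))
  expect_true(all(hits))
})

test_that("tidy and glance summarize a co-acquisition table", {
  tab <- make_coacq_table(c(0L, 3L))
  expect_equal(nrow(tidy(tab)), 2)
  g <- glance(tab)
  expect_equal(g$n_pairs, 2)
  expect_equal(g$pct_neighbors, 50)
})
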