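test_that("receptor promiscuity index is the agonist fraction", {
  ds <- activity_dataset(toy_compounds()[1:4, ], toy_activation()[1:4, ])
  expect_equal(unname(receptor_promiscuity_index(ds, "TAS2R14")), 0.5)
  expect_equal(unname(receptor_promiscuity_index(ds, "TAS2R50")), 0)
  idx <- receptor_promiscuity_index(ds)
  expect_length(idx, 25)
  expect_true(all(idx >= 0 & idx <= 1))
  expect_error(receptor_promiscuity_index(ds, "TAS2R99"),
               class = "bitterspace_validation_error")
})

test_that("promiscuity index recovers the generating activation probability", {
  cfg <- generator_config(n_compounds = 500,
                          p = c(TAS2R14 = 0.3, TAS2R1 = 0.4),
                          promiscuous_prob = 0, seed = 42)
  comp <- data.frame(compound_id = sprintf("c%03d", 1:500), name = "x",
                     smiles = "c1ccccc1", superclass = "Benzenoids",
                     is_food = TRUE, tested_all_receptors = TRUE)
  ds <- generate_activity(comp, cfg)
  # conditioning on >=1 activation inflates the marginal slightly; compare
  # against the truncated-joint expectation by simulation-free bound: the
  # estimate must sit within 3 binomial SE of p after deconditioning via the
  # untruncated draw (resampling affects only all-zero rows, ~42% here, so
  # test on the receptor-wise ratio of the two columns instead)
  est <- unname(receptor_promiscuity_index(ds, "TAS2R14"))
  se <- sqrt(0.3 * 0.7 / 500)
  # truncation correction: P(active | row not all zero) = p / (1 - (1-p1)(1-p2))
  p_any <- 1 - 0.7 * 0.6
  expect_lt(abs(est - 0.3 / p_any), 3 * se / p_any)
})

test_that("scaffold promiscuity index uses the explicit denominator", {
  comp <- data.frame(compound_id = c("a", "b", "c"), name = c("a", "b", "c"),
                     smiles = c("Cc1ccccc1", "CCc1ccccc1", "C1CCOCC1"),
                     superclass = "Benzenoids", is_food = TRUE,
                     tested_all_receptors = TRUE)
  act <- matrix(0L, 3, 2, dimnames = list(NULL, c("TAS2R14", "TAS2R39")))
  act[, "TAS2R14"] <- c(1L, 1L, 0L)   # two agonists, one shared scaffold
  act[3, "TAS2R39"] <- 1L
  ds <- activity_dataset(comp, act)
  expect_equal(scaffold_promiscuity_index(ds, "TAS2R14", 10), 0.1)
  expect_equal(scaffold_promiscuity_index(ds, "TAS2R50", 10), 0)
  expect_error(scaffold_promiscuity_index(ds, "TAS2R14", 0),
               class = "bitterspace_validation_error")
})

test_that("a scaffold-rich receptor can out-rank a compound-rich one (profile inversion)", {
  # receptor A: 2 chemically complex agonists (many scaffolds);
  # receptor B: 3 agonists sharing one benzene scaffold
  comp <- data.frame(
    compound_id = paste0("m", 1:5), name = paste0("m", 1:5),
    smiles = c("c1ccc(CC2CCC(Cc3ccccn3)CC2)cc1",       # 6 scaffolds
               "c1ccc(CC2CCCCO2)cc1",                  # 3 scaffolds
               "Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1"),
    superclass = "x", is_food = TRUE, tested_all_receptors = TRUE)
  act <- matrix(0L, 5, 2, dimnames = list(NULL, c("TAS2R39", "TAS2R14")))
  act[1:2, "TAS2R39"] <- 1L
  act[3:5, "TAS2R14"] <- 1L
  ds <- activity_dataset(comp, act)
  ci <- receptor_promiscuity_index(ds)
  expect_lt(ci[["TAS2R39"]], ci[["TAS2R14"]])
  si_A <- scaffold_promiscuity_index(ds, "TAS2R39", 10)
  si_B <- scaffold_promiscuity_index(ds, "TAS2R14", 10)
  expect_gt(si_A, si_B)
})

test_that("compound promiscuity counts receptors per compound", {
  ds <- promiscuous_agonist_dataset()
  expect_equal(unname(compound_promiscuity(ds, "quinine")), 9)
  expect_equal(unname(compound_promiscuity(ds, "amarogentin")), 7)
  expect_equal(unname(compound_promiscuity(ds, "EGCG")), 6)
  expect_equal(unname(compound_promiscuity(ds, "caffeine")), 5)
  expect_error(compound_promiscuity(ds, "nonesuch"),
               class = "bitterspace_validation_error")
  ds0 <- toy_dataset()
  ds0$activation["c2", ] <- 0L
  expect_equal(unname(compound_promiscuity(ds0, "c2")), 0)
})

test_that("promiscuity bins map counts deterministically with a configurable boundary", {
  expect_equal(as.character(promiscuity_bin(c(1, 2, 3, 4, 5, 9))),
               c("1", "2", "3", "4", "5+", "5+"))
  expect_equal(as.character(promiscuity_bin(5, boundary = 6)), "5")
  expect_equal(levels(promiscuity_bin(1)), c("1", "2", "3", "4", "5+"))
  expect_error(promiscuity_bin(0), class = "bitterspace_domain_error")
})

test_that("receptor summary table reports counts, scaffolds, ratio and median MW", {
  comp <- data.frame(compound_id = c("a", "b"), name = c("toluene", "ethylbenzene"),
                     smiles = c("Cc1ccccc1", "CCc1ccccc1"),
                     superclass = "Benzenoids", is_food = TRUE,
                     tested_all_receptors = TRUE)
  act <- matrix(c(1L, 1L), 2, 1, dimnames = list(NULL, "TAS2R14"))
  tab <- receptor_summary_table(activity_dataset(comp, act))
  expect_equal(nrow(tab), 1)
  expect_equal(tab$n_compounds, 2)
  expect_equal(tab$n_unique_scaffolds, 1)
  expect_equal(tab$scaffold_per_compound, 0.50)
  # even-sized set: mean of the central pair (92.14, 106.17) -> 99
  expect_equal(tab$median_mw, 99)
  # all-zero dataset -> empty table
  empty <- activity_dataset(comp, matrix(0L, 2, 1, dimnames = list(NULL, "TAS2R14")))
  expect_equal(nrow(receptor_summary_table(empty)), 0)
})

test_that("summary ratios always equal the ratio operation (generated data)", {
  out <- synthesize_dataset(generator_config(n_compounds = 25, seed = 8))
  tab <- receptor_summary_table(out$dataset)
  expect_gt(nrow(tab), 0)
  expect_equal(tab$scaffold_per_compound,
               scaffold_per_compound(tab$n_unique_scaffolds, tab$n_compounds))
})

test_that("superclass-receptor matrix counts activation pairs by class", {
  comp <- toy_compounds()[1:4, ]
  act <- toy_activation()[1:4, ]
  ds <- activity_dataset(comp, act)
  m <- superclass_receptor_matrix(ds)
  expect_equal(m["TAS2R14", "Benzenoids"], 2L)
  expect_equal(m["TAS2R30", "Organic oxygen compounds"], 1L)
  # a compound activating 3 receptors contributes 3 counts but is 1 compound
  comp5 <- toy_compounds()
  ds5 <- activity_dataset(comp5, toy_activation())
  expect_warning(m5 <- superclass_receptor_matrix(ds5), "superclass")
  expect_equal(sum(m5), sum(ds5$activation[!is.na(comp5$superclass), ]))
  # receptor with k agonists from k distinct superclasses has k nonzeros
  compk <- data.frame(compound_id = paste0("k", 1:3), name = paste0("k", 1:3),
                      smiles = "c1ccccc1",
                      superclass = c("A", "B", "C"), is_food = TRUE,
                      tested_all_receptors = TRUE)
  compk$smiles <- c("c1ccccc1", "C1CCCCC1", "c1ccncc1")
  dsk <- activity_dataset(compk, matrix(1L, 3, 1, dimnames = list(NULL, "TAS2R38")))
  mk <- superclass_receptor_matrix(dsk)
  expect_equal(sum(mk["TAS2R38", ] > 0), 3)
})

test_that("double-counting identity holds on generated datasets", {
  for (seed in c(1, 5)) {
    out <- synthesize_dataset(generator_config(n_compounds = 40, seed = seed))
    ds <- out$dataset
    expect_equal(sum(compound_promiscuity(ds)),
                 sum(receptor_promiscuity_index(ds) * n_compounds(ds)))
  }
})
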