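test_that("default founders are 9 european men, 12 polynesian women, 3 immigrants", {
  ped <- simulate_pedigree(simulation_config(seed = 1))
  founders <- pedigree_founders(ped)
  fo <- ped[match(founders, ped$id), ]
  expect_equal(sum(fo$sex == "male" & fo$origin == "european" &
                     fo$generation == 0), 9)
  expect_equal(sum(fo$sex == "female" & fo$origin == "polynesian"), 12)
  # the three later male settlers arrive during the first three generations
  imm <- fo[fo$generation > 0, ]
  expect_equal(nrow(imm), 3)
  expect_true(all(imm$sex == "male" & imm$origin == "european"))
  expect_true(all(imm$generation %in% 1:3))
})

test_that("zero generations yields founders only", {
  ped <- simulate_pedigree(simulation_config(seed = 1, generations = 0))
  expect_equal(nrow(ped), 21)
  expect_setequal(pedigree_founders(ped), ped$id)
})

test_that("identical seeds give byte-identical PED output", {
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_pedigree(simulate_pedigree(simulation_config(seed = 77)), f1)
  write_pedigree(simulate_pedigree(simulation_config(seed = 77)), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- withr::local_tempfile()
  write_pedigree(simulate_pedigree(simulation_config(seed = 78)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("the population cap binds without being mistaken for extinction", {
  ped <- simulate_pedigree(simulation_config(seed = 5, max_pop = 200))
  expect_lte(nrow(ped), 200)
  expect_true(attr(ped, "capped"))
  expect_false(attr(ped, "extinct"))
})

test_that("die-out before the requested horizon is flagged", {
  cfg <- simulation_config(seed = 2, offspring_rate = 0, immigrants = NULL)
  ped <- simulate_pedigree(cfg)
  expect_true(attr(ped, "extinct"))
  expect_equal(nrow(ped), 21)
})

test_that("expected generation growth matches couples x offspring rate", {
  # one generation from balanced founders: E[size] = couples * rate
  rate <- 2
  n_rep <- 200
  sizes <- vapply(seq_len(n_rep), function(s) {
    cfg <- simulation_config(seed = 7000 + s, n_male_founders = 10,
                             n_female_founders = 10, generations = 1,
                             offspring_rate = rate, max_pop = 10000,
                             immigrants = NULL)
    sum(simulate_pedigree(cfg)$generation == 1)
  }, numeric(1))
  expected <- 10 * rate
  se <- sqrt(10 * rate / n_rep)  # total is Poisson(couples * rate)
  expect_lt(abs(mean(sizes) - expected), 3 * se)
})

test_that("founder haplogroups are drawn from the configured clade pools", {
  mt <- fixture_mt_tree()
  yt <- fixture_y_tree()
  b4_tips <- intersect(tree_tips(mt), tree_descendants(mt, "B4"))
  h_tips <- intersect(tree_tips(mt), tree_descendants(mt, "H"))
  f_tips <- intersect(tree_tips(yt), tree_descendants(yt, "F"))

  # deterministic pools at the probability extremes
  cfg1 <- simulation_config(seed = 9, polynesian_B_prob = 1,
                            y_outlier_prob = 0)
  ped <- simulate_pedigree(cfg1)
  fh <- assign_founder_haplotypes(ped, mt, yt, cfg1)
  expect_true(all(fh$mt_haplogroup[fh$origin == "polynesian"] %in% b4_tips))
  expect_true(all(fh$mt_haplogroup[fh$origin == "european"] %in% h_tips))
  expect_true(all(fh$y_haplogroup[fh$sex == "male"] %in%
                    setdiff(f_tips, "O")))
  expect_true(all(is.na(fh$y_haplogroup[fh$sex == "female"])))

  # same seed, same map
  fh2 <- assign_founder_haplotypes(ped, mt, yt, cfg1)
  expect_identical(fh, fh2)

  # B4 membership rate across seeds stays within binomial bounds of 0.9
  n_b4 <- 0; n_pol <- 0
  for (s in 1:15) {
    cfg <- simulation_config(seed = s)
    peds <- simulate_pedigree(cfg)
    fhs <- assign_founder_haplotypes(peds, mt, yt, cfg)
    pol <- fhs$mt_haplogroup[fhs$origin == "polynesian"]
    n_pol <- n_pol + length(pol)
    n_b4 <- n_b4 + sum(pol %in% b4_tips)
  }
  p_hat <- n_b4 / n_pol
  expect_lt(abs(p_hat - 0.9), 3 * sqrt(0.9 * 0.1 / n_pol))
})

test_that("noise-free profiles equal the cumulative sets and recall the truth", {
  sim <- simulate_norfolk(simulation_config(seed = 31, generations = 6,
                                            max_pop = 300))
  leaves <- pedigree_leaves(sim$ped)
  prof <- generate_variant_profiles(sim$assign, sim$mt_tree, seed = 32,
                                    ids = leaves)
  expect_equal(length(prof), length(leaves))
  truth <- sim$assign$mt_haplotype[match(leaves, sim$assign$id)]
  for (i in seq_along(prof)) {
    expect_setequal(prof[[i]]$variants,
                    cumulative_variants(sim$mt_tree, truth[i]))
  }
  calls <- call_haplogroups(prof, sim$mt_tree)
  expect_identical(calls$haplogroup, truth)
})

test_that("dropout removes the binomially expected share of variants", {
  sim <- simulate_norfolk(simulation_config(seed = 33))
  prof0 <- generate_variant_profiles(sim$assign, sim$mt_tree, seed = 34)
  planted <- sum(lengths(lapply(prof0, `[[`, "variants")))
  expect_gte(planted, 1000)
  prof5 <- generate_variant_profiles(sim$assign, sim$mt_tree,
                                     dropout_rate = 0.5, seed = 34)
  kept <- sum(lengths(lapply(prof5, `[[`, "variants")))
  drop_frac <- 1 - kept / planted
  expect_lt(abs(drop_frac - 0.5), 3 * sqrt(0.25 / planted))
})

test_that("false positives are private and absent at rate zero", {
  sim <- simulate_norfolk(simulation_config(seed = 35, generations = 5,
                                            max_pop = 150))
  prof <- generate_variant_profiles(sim$assign, sim$mt_tree,
                                    false_positive_rate = 0, seed = 36)
  for (p in prof) {
    hap <- sim$assign$mt_haplotype[match(p$sample_id, sim$assign$id)]
    expect_setequal(p$variants, cumulative_variants(sim$mt_tree, hap))
  }
  noisy <- generate_variant_profiles(sim$assign, sim$mt_tree,
                                     false_positive_rate = 2, seed = 36)
  extra <- vapply(noisy, function(p) {
    hap <- sim$assign$mt_haplotype[match(p$sample_id, sim$assign$id)]
    length(setdiff(p$variants, cumulative_variants(sim$mt_tree, hap)))
  }, numeric(1))
  expect_gt(mean(extra), 1)  # Poisson(2) additions on average
})

test_that("sequence editing matches its constructive oracles", {
  expect_identical(apply_variants_to_sequence("ACGTACGT", character(0)),
                   "ACGTACGT")
  one <- apply_variants_to_sequence("ACGTACGT", "C2T")
  expect_equal(sum(strsplit(one, "")[[1]] !=
                     strsplit("ACGTACGT", "")[[1]]), 1)
  # wildcard substitutes the transition partner
  expect_identical(apply_variants_to_sequence("AAAA", "2"), "AGAA")
  expect_identical(apply_variants_to_sequence("ACGTACGT", "4-6d"), "ACGGT")
  expect_identical(apply_variants_to_sequence("ACGT", "2.1TT"), "ACTTGT")
  del9 <- apply_variants_to_sequence(synthetic_mt_reference(), "8281-8289d")
  expect_equal(nchar(del9), 16569 - 9)
  expect_error(apply_variants_to_sequence("ACGT", "A9G"), "out of range")
  expect_error(apply_variants_to_sequence("ACGTACGT", c("2-4d", "A3G")),
               "overlapping")
  expect_error(apply_variants_to_sequence("ACGT", "P293"), "non-positional")
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(), "seed")
  expect_error(simulation_config(seed = 1, dropout_rate = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(seed = 1, offspring_rate = -1))
})
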