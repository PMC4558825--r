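# small hand-built pedigree: 2 of the 5 leaves trace their matriline to a
# polynesian founder
mixed_pedigree <- function() {
  as_pedigree(data.frame(
    fam = "T",
    id = c("pf", "ef", "em1", "em2", "d1", "d2", "s1", "s2", "s3"),
    father = c(NA, NA, NA, NA, "em1", "em1", "em2", "em2", "em2"),
    mother = c(NA, NA, NA, NA, "pf", "pf", "ef", "ef", "ef"),
    sex = c("female", "female", "male", "male", "female", "female",
            "male", "male", "male"),
    origin = c("polynesian", "european", "european", "european",
               rep("unknown", 5)),
    stringsAsFactors = FALSE))
}

mixed_assignment <- function(ped) {
  founders <- pedigree_founders(ped)
  sex <- ped$sex[match(founders, ped$id)]
  propagate_lineages(ped, data.frame(
    id = founders, mt_haplogroup = paste0("MT", seq_along(founders)),
    y_haplogroup = ifelse(sex == "male", "R1b", NA_character_),
    stringsAsFactors = FALSE))
}

test_that("ancestry fractions are exhaustive counts over the subset", {
  ped <- mixed_pedigree()
  assign <- mixed_assignment(ped)
  fr <- ancestry_fractions(assign, ped)  # leaves: d1 d2 s1 s2 s3
  expect_equal(fr$maternal[["polynesian"]], 2 / 5)
  expect_equal(fr$maternal[["european"]], 3 / 5)
  expect_equal(sum(fr$maternal), 1)
  expect_equal(fr$paternal[["european"]], 1)
  expect_equal(fr$n, 5)
  expect_error(ancestry_fractions(assign, ped, character(0)), "empty")
  expect_error(ancestry_fractions(assign, ped, "ghost"), "not in pedigree")
})

test_that("a female-only subset leaves the paternal map undefined", {
  ped <- mixed_pedigree()
  assign <- mixed_assignment(ped)
  fr <- ancestry_fractions(assign, ped, subset = c("d1", "d2"))
  expect_null(fr$paternal)
  expect_equal(fr$maternal[["polynesian"]], 1)
  expect_error(gender_bias_index(fr, "polynesian"), "undefined")
})

test_that("an all-polynesian-founder matriline gives fraction 1", {
  ped <- as_pedigree(data.frame(
    fam = "T", id = c("f1", "f2"), father = NA, mother = NA,
    sex = "female", origin = "polynesian", stringsAsFactors = FALSE))
  assign <- propagate_lineages(ped, data.frame(
    id = c("f1", "f2"), mt_haplogroup = "B4a1a1m", y_haplogroup = NA))
  fr <- ancestry_fractions(assign, ped, subset = ped$id)
  expect_equal(fr$maternal[["polynesian"]], 1)
})

test_that("bootstrap CIs replay an independent resampling loop exactly", {
  set.seed(501)
  ped <- random_pedigree(160, n_founders = 30)
  assign <- propagate_lineages(ped, local({
    founders <- pedigree_founders(ped)
    sex <- ped$sex[match(founders, ped$id)]
    data.frame(id = founders, mt_haplogroup = "MT",
               y_haplogroup = ifelse(sex == "male", "Y", NA_character_))
  }))
  subset <- pedigree_leaves(ped)
  got <- bootstrap_ci(assign, ped, subset, origin = "polynesian",
                      line = "maternal", reps = 400, seed = 99)
  # independent replay: same RNG recipe, own indicator construction
  founder_of <- vapply(subset, function(id) or_trace(ped, id, "maternal"),
                       character(1))
  ind <- as.numeric(ped$origin[match(founder_of, ped$id)] == "polynesian")
  set.seed(99)
  stats <- vapply(seq_len(400), function(r) {
    mean(ind[sample(length(ind), replace = TRUE)])
  }, numeric(1))
  want <- stats::quantile(stats, c(0.025, 0.975), type = 7, names = FALSE)
  expect_identical(got, want)
  expect_error(bootstrap_ci(assign, ped, subset, reps = 0, seed = 1),
               "reps")
  expect_error(bootstrap_ci(assign, ped, subset, reps = 10), "seed")
})

test_that("zero-variance cohorts give a degenerate (1, 1) interval", {
  ped <- mixed_pedigree()
  assign <- mixed_assignment(ped)
  ci <- bootstrap_ci(assign, ped, subset = c("s1", "s2", "s3"),
                     origin = "european", line = "maternal",
                     reps = 200, seed = 3)
  expect_equal(ci, c(1, 1))
})

test_that("lineage survival counts distinct surviving founder lines", {
  ped <- mixed_pedigree()
  assign <- mixed_assignment(ped)
  # both female founders leave matriline descendants among the leaves
  expect_equal(lineage_survival(assign, ped, line = "maternal"), 2)
  expect_equal(lineage_survival(assign, ped, line = "maternal",
                                origin = "polynesian"), 1)
  # em1's sons are absent: only em2's patriline survives into the leaves
  expect_equal(lineage_survival(assign, ped, line = "paternal"), 1)
})

test_that("extinct matrilines drop out of the survival count", {
  # 6 polynesian founders; the matrilines of 2 leave no descendants
  n <- 6
  founders <- sprintf("pf%d", 1:n)
  kids <- sprintf("k%d", 1:4)
  ped <- as_pedigree(data.frame(
    fam = "T", id = c(founders, "m", kids),
    father = c(rep(NA, n + 1), rep("m", 4)),
    mother = c(rep(NA, n + 1), founders[1:4]),
    sex = c(rep("female", n), "male", rep("female", 4)),
    origin = c(rep("polynesian", n), "european", rep("unknown", 4)),
    stringsAsFactors = FALSE))
  assign <- propagate_lineages(ped, data.frame(
    id = c(founders, "m"),
    mt_haplogroup = "B4a1a1m",
    y_haplogroup = c(rep(NA, n), "R1b"), stringsAsFactors = FALSE))
  expect_equal(lineage_survival(assign, ped, subset = kids,
                                line = "maternal", origin = "polynesian"),
               4)
  # set-cardinality oracle
  expect_equal(lineage_survival(assign, ped, subset = kids, "maternal"),
               length(unique(vapply(kids, function(k)
                 or_trace(ped, k, "maternal"), character(1)))))
})

test_that("the gender-bias index is the maternal-paternal difference", {
  est <- list(maternal = c(polynesian = 0.45, european = 0.55),
              paternal = c(european = 1))
  expect_equal(gender_bias_index(est, "polynesian"), 0.45)
  est2 <- list(maternal = c(polynesian = 0.3), paternal = c(polynesian = 0.3))
  expect_equal(gender_bias_index(est2, "polynesian"), 0)
  est3 <- list(maternal = c(european = 1), paternal = c(polynesian = 1))
  expect_equal(gender_bias_index(est3, "polynesian"), -1)
})

test_that("the estimator object is coherent and its CIs bracket the point", {
  ped <- mixed_pedigree()
  assign <- mixed_assignment(ped)
  est <- admixture_estimate(assign, ped, reps = 300, seed = 11)
  expect_s3_class(est, "admixture_estimate")
  expect_equal(sum(est$maternal), 1)
  expect_equal(sum(est$paternal), 1)
  for (o in names(est$maternal)) {
    expect_lte(est$ci$maternal["lo", o], est$maternal[[o]])
    expect_gte(est$ci$maternal["hi", o], est$maternal[[o]])
  }
  expect_equal(est$bias_index[["polynesian"]], 0.4)
  expect_equal(est$matriline_survivors, 2)
  co <- coef(est)
  expect_equal(co[["maternal.polynesian"]], 0.4)
  expect_output(print(est), "gender-bias index")
  expect_output(summary(est), "bootstrap")
  expect_error(admixture_estimate(assign, ped, reps = 10), "seed")
})

test_that("more bootstrap replicates keep the point inside the interval", {
  set.seed(502)
  ped <- random_pedigree(200, n_founders = 40)
  founders <- pedigree_founders(ped)
  sex <- ped$sex[match(founders, ped$id)]
  assign <- propagate_lineages(ped, data.frame(
    id = founders, mt_haplogroup = "MT",
    y_haplogroup = ifelse(sex == "male", "Y", NA_character_)))
  subset <- pedigree_leaves(ped)
  point <- ancestry_fractions(assign, ped, subset)$maternal
  for (o in names(point)) {
    for (reps in c(100, 1000)) {
      ci <- bootstrap_ci(assign, ped, subset, origin = o, line = "maternal",
                         reps = reps, seed = 7)
      expect_lte(ci[1], point[[o]])
      expect_gte(ci[2], point[[o]])
    }
  }
})
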