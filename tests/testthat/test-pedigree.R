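founding_cohort_file <- function(path) {
  # the 21-founder cohort: 9 european men, 12 polynesian women
  males <- sprintf("M%02d\t0\t0\t1\teuropean", 1:9)
  females <- sprintf("F%02d\t0\t0\t2\tpolynesian", 1:12)
  writeLines(paste("NI", c(males, females), sep = "\t"), path)
  path
}

test_that("a founders-only PED file loads as 21 founders", {
  f <- withr::local_tempfile()
  ped <- read_pedigree(founding_cohort_file(f))
  expect_equal(nrow(ped), 21)
  expect_setequal(pedigree_founders(ped), ped$id)
  expect_equal(sum(ped$sex == "male" & ped$origin == "european"), 9)
  expect_equal(sum(ped$sex == "female" & ped$origin == "polynesian"), 12)
})

test_that("write-then-read round-trip is field-identical", {
  set.seed(301)
  for (i in 1:5) {
    ped <- random_pedigree(sample(30:200, 1))
    f <- withr::local_tempfile()
    write_pedigree(ped, f)
    back <- read_pedigree(f)
    for (col in c("fam", "id", "father", "mother", "sex", "origin")) {
      expect_identical(back[[col]], ped[[col]])
    }
  }
})

test_that("validation rejects sex-inconsistent parents, bad refs and cycles", {
  f <- withr::local_tempfile()
  writeLines(c("T A 0 0 1 0", "T B 0 A 2 0"), f)  # mother A is male
  expect_error(read_pedigree(f), "not female")
  writeLines(c("T A 0 0 2 0", "T B A 0 1 0"), f)  # father A is female
  expect_error(read_pedigree(f), "not male")
  writeLines(c("T A 0 0 1 0", "T B 0 Z 2 0"), f)
  expect_error(read_pedigree(f), "unresolved mother reference 'Z' \\(row 2")
  writeLines(c("T A B 0 1 0", "T B A 0 1 0"), f)  # A and B father each other
  expect_error(read_pedigree(f), "cycle")
  writeLines(c("T A 0 0 1 0", "T A 0 0 1 0"), f)
  expect_error(read_pedigree(f), "duplicate")
  writeLines("T A 0 0 3 0", f)
  expect_error(read_pedigree(f), "invalid sex code")
  writeLines("T A 0 0 1", f)
  expect_error(read_pedigree(f), "6 columns")
})

test_that("uniparental tracing follows the stated conventions", {
  ped <- as_pedigree(data.frame(
    fam = "T", id = c("gma", "mum", "kid", "dad"),
    father = c(NA, NA, "dad", NA), mother = c(NA, "gma", "mum", NA),
    sex = c("female", "female", "female", "male"),
    origin = c("polynesian", "unknown", "unknown", "european")))
  expect_identical(uniparental_founder(ped, "gma", "maternal"), "gma")
  expect_identical(uniparental_founder(ped, "kid", "maternal"), "gma")
  # paternal line of a female is undefined
  expect_true(is.na(uniparental_founder(ped, "kid", "paternal")))
  expect_identical(uniparental_founder(ped, "dad", "paternal"), "dad")
  expect_error(uniparental_founder(ped, "nope"), "unknown individual")
})

test_that("tracing agrees with the independent path-walking oracle", {
  set.seed(302)
  for (i in 1:10) {
    ped <- random_pedigree(sample(50:400, 1))
    for (id in sample(ped$id, 25)) {
      expect_identical(uniparental_founder(ped, id, "maternal"),
                       or_trace(ped, id, "maternal"))
      expect_identical(uniparental_founder(ped, id, "paternal"),
                       or_trace(ped, id, "paternal"))
    }
  }
})

founder_map_for <- function(ped) {
  founders <- pedigree_founders(ped)
  sex <- ped$sex[match(founders, ped$id)]
  data.frame(id = founders,
             mt_haplogroup = paste0("MT", seq_along(founders)),
             y_haplogroup = ifelse(sex == "male",
                                   paste0("Y", seq_along(founders)),
                                   NA_character_),
             stringsAsFactors = FALSE)
}

test_that("propagation equals uniparental tracing plus founder lookup", {
  set.seed(303)
  for (i in 1:5) {
    ped <- random_pedigree(sample(50:300, 1))
    fh <- founder_map_for(ped)
    assign <- propagate_lineages(ped, fh)
    expect_identical(assign$id, ped$id)
    for (id in sample(ped$id, 20)) {
      row <- assign[assign$id == id, ]
      mat <- or_trace(ped, id, "maternal")
      expect_identical(row$matriline_founder, mat)
      expect_identical(row$mt_haplotype,
                       fh$mt_haplogroup[match(mat, fh$id)])
      pat <- or_trace(ped, id, "paternal")
      expect_identical(row$patriline_founder, pat)
      if (!is.na(pat)) {
        expect_identical(row$y_haplotype, fh$y_haplogroup[match(pat, fh$id)])
      }
    }
    # females never carry a Y
    expect_true(all(is.na(assign$y_haplotype[ped$sex == "female"])))
  }
})

test_that("all-founder pedigrees keep their own haplotypes", {
  f <- withr::local_tempfile()
  ped <- read_pedigree(founding_cohort_file(f))
  fh <- founder_map_for(ped)
  assign <- propagate_lineages(ped, fh)
  expect_identical(assign$matriline_founder, ped$id)
  expect_identical(assign$mt_haplotype, fh$mt_haplogroup)
})

test_that("propagation demands complete founder haplotypes", {
  set.seed(304)
  ped <- random_pedigree(60)
  fh <- founder_map_for(ped)
  expect_error(propagate_lineages(ped, fh[-1, ]), "missing founder mtDNA")
  fh2 <- fh
  male_founder <- which(!is.na(fh2$y_haplogroup))[1]
  fh2$y_haplogroup[male_founder] <- NA
  expect_error(propagate_lineages(ped, fh2), "missing founder Y")
})

test_that("matrilines are constant along mother chains and bounded in number", {
  set.seed(305)
  ped <- random_pedigree(300)
  fh <- founder_map_for(ped)
  assign <- propagate_lineages(ped, fh)
  has_mum <- !is.na(ped$mother)
  expect_identical(
    assign$matriline_founder[has_mum],
    assign$matriline_founder[match(ped$mother[has_mum], ped$id)])
  # distinct matriline founders never exceed matriline terminals
  terminals <- sum(is.na(ped$mother))
  expect_lte(length(unique(assign$matriline_founder)), terminals)
})

test_that("propagation is invariant to row order", {
  set.seed(306)
  ped <- random_pedigree(150)
  fh <- founder_map_for(ped)
  a1 <- propagate_lineages(ped, fh)
  shuffled <- as_pedigree(ped[sample(nrow(ped)), ])
  a2 <- propagate_lineages(shuffled, fh)
  a2 <- a2[match(a1$id, a2$id), ]
  rownames(a2) <- NULL
  expect_equal(a1, a2, ignore_attr = TRUE)
})

test_that("concordance counts collapsed agreement and lists mismatches", {
  mt <- fixture_mt_tree()
  ids <- sprintf("s%02d", 1:10)
  assign <- data.frame(id = ids, matriline_founder = ids,
                       patriline_founder = NA, mt_haplotype = "B4a1a1m",
                       y_haplotype = NA, stringsAsFactors = FALSE)
  calls <- data.frame(sample_id = ids, haplogroup = "B4a1a1m",
                      stringsAsFactors = FALSE)
  expect_equal(lineage_concordance(assign, calls, mt)$concordance, 1)
  # flip k of n to a different clade -> (n - k) / n
  k <- 3
  calls$haplogroup[seq_len(k)] <- "H1"
  cc <- lineage_concordance(assign, calls, mt)
  expect_equal(cc$concordance, (10 - k) / 10)
  expect_equal(nrow(cc$mismatches), k)
  # collapsing to a shallow level forgives within-clade disagreement
  calls$haplogroup <- c(rep("B4a1a1a14", 5), rep("B4a1a1c", 5))
  expect_equal(lineage_concordance(assign, calls, mt, level = 8)$concordance,
               1)
  calls$sample_id <- paste0("x", calls$sample_id)
  expect_error(lineage_concordance(assign, calls, mt), "no overlapping")
})
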