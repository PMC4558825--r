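#' Simulation configuration for a founder-isolate pedigree
#'
#' Defaults encode the historical founding scenario: 9 European male and 12
#' Polynesian female founders, 11 non-overlapping generations growing to a
#' cap of about 1400 individuals, and 3 later European male immigrants
#' arriving during the first three generations. Polynesian founders carry a
#' haplogroup-B4 mitochondrial lineage with probability `polynesian_B_prob`
#' (0.9 by default, matching the clade's predominance among Polynesian
#' mtDNA); European founders carry haplogroup-H mtDNA and F-branch Y
#' lineages, with a small probability `y_outlier_prob` of the rare E1b1a1
#' outlier.
#'
#' @param n_male_founders,n_female_founders founding counts (defaults 9, 12).
#' @param male_founder_origin,female_founder_origin origin labels.
#' @param generations number of non-overlapping generations (default 11).
#' @param offspring_rate mean of the per-couple Poisson offspring
#'   distribution (default 3.0, calibrated so 21 founders reach a cumulative
#'   pedigree near `max_pop` over 11 generations; couples are limited by the
#'   scarcer sex within each generation, so realised growth is well below
#'   `offspring_rate / 2` per generation).
#' @param max_pop cumulative pedigree-size cap (default 1400).
#' @param immigrants data.frame with columns `generation`, `sex`, `origin`,
#'   `count`: new founders inserted into the pairing pool of that generation.
#' @param dropout_rate,false_positive_rate per-profile genotyping noise rates
#'   in `[0, 1]` (defaults 0).
#' @param polynesian_B_prob probability a Polynesian founder's mtDNA is in
#'   clade B4 (default 0.9).
#' @param y_outlier_prob probability a European male founder carries the
#'   E1b1a1 Y outlier (default 0.01).
#' @param seed RNG seed (mandatory).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_male_founders = 9, n_female_founders = 12,
                              male_founder_origin = "european",
                              female_founder_origin = "polynesian",
                              generations = 11, offspring_rate = 3.0,
                              max_pop = 1400,
                              immigrants = data.frame(
                                generation = 1:3, sex = "male",
                                origin = "european", count = 1),
                              dropout_rate = 0, false_positive_rate = 0,
                              polynesian_B_prob = 0.9, y_outlier_prob = 0.01,
                              seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_male_founders >= 0, n_female_founders >= 0, generations >= 0,
            offspring_rate >= 0, max_pop >= 1)
  for (r in c(dropout_rate, false_positive_rate, polynesian_B_prob,
              y_outlier_prob)) {
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_male_founders = n_male_founders,
    n_female_founders = n_female_founders,
    male_founder_origin = male_founder_origin,
    female_founder_origin = female_founder_origin,
    generations = generations, offspring_rate = offspring_rate,
    max_pop = max_pop, immigrants = immigrants,
    dropout_rate = dropout_rate, false_positive_rate = false_positive_rate,
    polynesian_B_prob = polynesian_B_prob, y_outlier_prob = y_outlier_prob,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate a founder-isolate pedigree
#'
#' Forward-time simulation with non-overlapping generations: each
#' generation's unmarried adults (natives of the previous generation plus any
#' immigrants configured for it) are paired at random and monogamously, each
#' couple draws a Poisson number of offspring, offspring sex is a fair coin,
#' and production stops when the cumulative pedigree reaches `max_pop`.
#' Output is identical for identical seeds. If the population dies out before
#' the requested number of generations the result is flagged (attribute
#' `extinct`), not silently truncated.
#'
#' @param cfg a [simulation_config()].
#' @return A `pedigree` with a `generation` column and attributes `extinct`,
#'   `capped` and `generations_realised`.
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  counter <- 0L
  new_ids <- function(n) {
    ids <- sprintf("I%05d", counter + seq_len(n))
    counter <<- counter + n
    ids
  }
  founders_m <- new_ids(cfg$n_male_founders)
  founders_f <- new_ids(cfg$n_female_founders)
  cols <- list(
    id = c(founders_m, founders_f),
    father = rep(NA_character_, length(founders_m) + length(founders_f)),
    mother = rep(NA_character_, length(founders_m) + length(founders_f)),
    sex = c(rep("male", length(founders_m)),
            rep("female", length(founders_f))),
    origin = c(rep(cfg$male_founder_origin, length(founders_m)),
               rep(cfg$female_founder_origin, length(founders_f))),
    generation = rep(0L, length(founders_m) + length(founders_f))
  )
  gen_members <- list(`0` = cols$id)
  extinct <- FALSE
  capped <- FALSE
  realised <- 0L

  imm <- cfg$immigrants
  add_immigrants <- function(g) {
    if (is.null(imm) || nrow(imm) == 0) return(character(0))
    rows <- imm[imm$generation == g, , drop = FALSE]
    ids <- character(0)
    for (k in seq_len(nrow(rows))) {
      nk <- rows$count[k]
      if (nk < 1) next
      idk <- new_ids(nk)
      cols$id <<- c(cols$id, idk)
      cols$father <<- c(cols$father, rep(NA_character_, nk))
      cols$mother <<- c(cols$mother, rep(NA_character_, nk))
      cols$sex <<- c(cols$sex, rep(rows$sex[k], nk))
      cols$origin <<- c(cols$origin, rep(rows$origin[k], nk))
      cols$generation <<- c(cols$generation, rep(as.integer(g), nk))
      ids <- c(ids, idk)
    }
    ids
  }

  for (g in seq_len(cfg$generations)) {
    pool <- c(gen_members[[as.character(g - 1L)]], add_immigrants(g - 1L))
    sex_pool <- cols$sex[match(pool, cols$id)]
    males <- pool[sex_pool == "male"]
    females <- pool[sex_pool == "female"]
    nc <- min(length(males), length(females))
    kids <- character(0)
    if (nc > 0 && length(cols$id) < cfg$max_pop) {
      males <- if (length(males) > 1) sample(males) else males
      females <- if (length(females) > 1) sample(females) else females
      noff <- stats::rpois(nc, cfg$offspring_rate)
      budget <- cfg$max_pop - length(cols$id)
      if (sum(noff) > budget) {
        capped <- TRUE
        # truncate couple by couple so the cap is exact
        cum <- cumsum(noff)
        noff <- pmin(noff, pmax(0L, budget - c(0L, cum[-nc])))
      }
      for (ci in seq_len(nc)) {
        if (noff[ci] < 1) next
        idk <- new_ids(noff[ci])
        cols$id <- c(cols$id, idk)
        cols$father <- c(cols$father, rep(males[ci], noff[ci]))
        cols$mother <- c(cols$mother, rep(females[ci], noff[ci]))
        cols$sex <- c(cols$sex,
                      sample(c("male", "female"), noff[ci], replace = TRUE))
        cols$origin <- c(cols$origin, rep("unknown", noff[ci]))
        cols$generation <- c(cols$generation, rep(as.integer(g), noff[ci]))
        kids <- c(kids, idk)
      }
    }
    gen_members[[as.character(g)]] <- kids
    if (length(kids) == 0 && g < cfg$generations) {
      if (capped || length(cols$id) >= cfg$max_pop) {
        # population hit the cap, not died out
        break
      }
      # still allow late immigrants to found new lines; extinct only if the
      # remaining generations also stay empty
      if (is.null(imm) || !any(imm$generation >= g)) {
        extinct <- TRUE
        realised <- g - 1L
        break
      }
    }
    if (length(kids) > 0) realised <- g
  }

  ped <- as_pedigree(data.frame(fam = "SIM", id = cols$id,
                                father = cols$father, mother = cols$mother,
                                sex = cols$sex, origin = cols$origin,
                                generation = cols$generation,
                                stringsAsFactors = FALSE))
  attr(ped, "extinct") <- extinct
  attr(ped, "capped") <- capped
  attr(ped, "generations_realised") <- realised
  ped
}

#' Assign haplogroups to pedigree founders
#'
#' Draws each founder's mtDNA haplogroup from their origin's clade pool on
#' the reference tree — Polynesian founders from the B4-descendant tips with
#' probability `polynesian_B_prob` (otherwise from non-B4, non-H tips),
#' European founders from the H-descendant tips, others uniformly over all
#' tips — and gives each male founder a Y haplogroup from the F-branch tips
#' (excluding the O sub-branch), with probability `y_outlier_prob` of the
#' E1b1a1 outlier instead.
#'
#' @param ped a `pedigree`.
#' @param mt_tree,y_tree `reference_tree`s containing the configured clades.
#' @param cfg a [simulation_config()].
#' @return A data.frame with columns `id`, `origin`, `sex`, `mt_haplogroup`,
#'   `y_haplogroup` (NA for females), one row per founder.
#' @export
assign_founder_haplotypes <- function(ped, mt_tree, y_tree, cfg) {
  set.seed(cfg$seed + 1L)
  founders <- pedigree_founders(ped)
  fi <- match(founders, ped$id)
  tips <- tree_tips(mt_tree)
  pool_B <- intersect(tips, tree_descendants(mt_tree, "B4"))
  pool_H <- intersect(tips, tree_descendants(mt_tree, "H"))
  pool_other <- setdiff(tips, c(pool_B, pool_H))
  ytips <- tree_tips(y_tree)
  pool_F <- intersect(ytips, tree_descendants(y_tree, "F"))
  if ("O" %in% y_tree$nodes$name) {
    pool_F <- setdiff(pool_F, tree_descendants(y_tree, "O"))
  }
  pool_nonF <- setdiff(ytips, c(pool_F, "E1b1a1"))
  for (p in list(pool_B, pool_H, pool_other, pool_F)) {
    if (length(p) == 0) stop("empty clade pool on reference tree",
                             call. = FALSE)
  }
  pick <- function(pool) pool[sample.int(length(pool), 1)]
  mt <- character(length(founders))
  yh <- rep(NA_character_, length(founders))
  for (k in seq_along(founders)) {
    o <- ped$origin[fi[k]]
    mt[k] <- if (o == "polynesian") {
      if (stats::runif(1) < cfg$polynesian_B_prob) pick(pool_B)
      else pick(pool_other)
    } else if (o == "european") {
      pick(pool_H)
    } else {
      pick(tips)
    }
    if (ped$sex[fi[k]] == "male") {
      yh[k] <- if (o == "european") {
        if (stats::runif(1) < cfg$y_outlier_prob) "E1b1a1" else pick(pool_F)
      } else if (length(pool_nonF) > 0) {
        pick(pool_nonF)
      } else {
        pick(ytips)
      }
    }
  }
  data.frame(id = founders, origin = ped$origin[fi], sex = ped$sex[fi],
             mt_haplogroup = mt, y_haplogroup = yh, stringsAsFactors = FALSE)
}

#' Write / read a founder-haplotype table
#'
#' @param founders data.frame from [assign_founder_haplotypes()].
#' @param path file path.
#' @param header optional `#`-prefixed header lines.
#' @return `path` (write) or the data.frame (read).
#' @export
write_founder_haplotypes <- function(founders, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0) writeLines(paste0("# ", header), con)
  utils::write.table(founders, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_founder_haplotypes
#' @export
read_founder_haplotypes <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' Generate noisy variant profiles from propagated haplotypes
#'
#' Each individual's profile starts as the cumulative variant set of their
#' propagated haplogroup; every variant is then independently dropped with
#' probability `dropout_rate`, and `Poisson(false_positive_rate)` private
#' false-positive variants are added at random positions not already in the
#' profile (for Y profiles, as private opaque marker labels).
#'
#' @param assign a `lineage_assignment` from [propagate_lineages()].
#' @param tree the matching `reference_tree`.
#' @param dropout_rate,false_positive_rate noise rates in `[0, 1]`.
#' @param seed RNG seed (mandatory).
#' @param marker `"mtDNA"` (uses `mt_haplotype`, all individuals) or `"Y"`
#'   (uses `y_haplotype`, males only).
#' @param ids optional subset of individuals to profile.
#' @param genome_length coordinate range for false-positive positions
#'   (default 16569, the mtDNA reference length).
#' @return A list of `variant_profile` objects.
#' @export
generate_variant_profiles <- function(assign, tree, dropout_rate = 0,
                                      false_positive_rate = 0, seed,
                                      marker = c("mtDNA", "Y"), ids = NULL,
                                      genome_length = 16569) {
  marker <- match.arg(marker)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate > 1 || false_positive_rate < 0) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  hap_col <- if (marker == "mtDNA") "mt_haplotype" else "y_haplotype"
  rows <- assign[!is.na(assign[[hap_col]]), ]
  if (!is.null(ids)) rows <- rows[rows$id %in% ids, ]
  cum_cache <- new.env(parent = emptyenv())
  lapply(seq_len(nrow(rows)), function(i) {
    hap <- rows[[hap_col]][i]
    if (is.null(cum_cache[[hap]])) {
      cum_cache[[hap]] <- cumulative_variants(tree, hap)
    }
    toks <- cum_cache[[hap]]
    if (dropout_rate > 0 && length(toks) > 0) {
      toks <- toks[stats::runif(length(toks)) >= dropout_rate]
    }
    nfp <- stats::rpois(1, false_positive_rate)
    if (nfp > 0) {
      if (marker == "mtDNA") {
        used <- variant_positions(toks)
        pos <- sample(setdiff(seq_len(genome_length), used), nfp)
        toks <- c(toks, paste0(pos, sample(c("A", "C", "G", "T"), nfp,
                                           replace = TRUE)))
      } else {
        toks <- c(toks, sprintf("FP%d", sample.int(1e6, nfp)))
      }
    }
    variant_profile(rows$id[i], toks, marker)
  })
}

#' Apply variants to a reference sequence
#'
#' Edits a reference DNA sequence with a set of positional variants:
#' substitutions replace the base in place (a wildcard allele substitutes the
#' transition partner of the reference base), deletions remove their range
#' with downstream coordinates shifting left, and insertions add bases after
#' their anchor position. Edits must not overlap; non-positional (opaque)
#' tokens cannot be applied.
#'
#' @param reference a DNA sequence (character or [Biostrings::DNAString]).
#' @param variants character vector of variant tokens.
#' @return The edited sequence as a character string; its length is the
#'   input length minus deleted plus inserted bases.
#' @examples
#' apply_variants_to_sequence("ACGTACGT", c("A1G", "4-5d"))
#' @export
apply_variants_to_sequence <- function(reference, variants) {
  seq <- toupper(as.character(reference))
  if (length(variants) == 0) return(seq)
  pv <- parse_variants(variants)
  if (any(pv$kind == "opaque")) {
    stop("cannot apply non-positional variant(s): ",
         paste(pv$token[pv$kind == "opaque"], collapse = ", "),
         call. = FALSE)
  }
  if (any(pv$end > nchar(seq)) || any(pv$position < 1)) {
    stop("variant position out of range for reference of length ",
         nchar(seq), call. = FALSE)
  }
  pv <- pv[order(pv$position), ]
  if (nrow(pv) > 1) {
    lap <- pv$position[-1] <= pv$end[-nrow(pv)]
    if (any(lap)) {
      stop("overlapping edits at position ", pv$position[-1][lap][1],
           call. = FALSE)
    }
  }
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  # apply right-to-left so earlier coordinates stay valid
  for (i in rev(seq_len(nrow(pv)))) {
    p <- pv$position[i]
    if (pv$kind[i] == "substitution") {
      base <- pv$derived[i]
      if (base == "*") base <- transition[[substr(seq, p, p)]]
      substr(seq, p, p) <- base
    } else if (pv$kind[i] == "deletion") {
      seq <- paste0(substr(seq, 1, p - 1),
                    substr(seq, pv$end[i] + 1, nchar(seq)))
    } else {  # insertion
      seq <- paste0(substr(seq, 1, p), pv$derived[i],
                    substr(seq, p + 1, nchar(seq)))
    }
  }
  seq
}

#' Synthetic mitochondrial reference sequence
#'
#' A seeded random 16,569-base sequence with the mtDEL primer binding sites
#' and the CCCCCTCTA x2 tandem repeat implanted at offsets homologous to the
#' human mtDNA reference frame (forward primer at 8196-8217, repeat copies
#' at 8272-8280 and 8281-8289, reverse-primer complement at 8307-8328), so
#' the 9-bp-deletion fragment-length screen produces the expected 133-bp
#' product — and 124 bp after applying the `8281-8289d` deletion. This is a
#' synthetic stand-in sequence, not the real rCRS; only the assay-relevant
#' geometry is reproduced.
#'
#' @param seed seed for the random background sequence (default 1); the
#'   caller's RNG state is preserved.
#' @return A character string of length 16,569.
#' @export
synthetic_mt_reference <- function(seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), 16569, replace = TRUE),
               collapse = "")
  pr <- mtdel_primers()
  implant <- function(seq, at, what) {
    substr(seq, at, at + nchar(what) - 1) <- what
    seq
  }
  seq <- implant(seq, 8196, pr$fwd)
  seq <- implant(seq, 8272, "CCCCCTCTACCCCCTCTA")
  rev_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(pr$rev)))
  implant(seq, 8307, rev_rc)
}

#' Run the founding-event simulation end to end
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [assign_founder_haplotypes()] and [propagate_lineages()] on the bundled
#' reference trees (or user-supplied ones).
#'
#' @param cfg a [simulation_config()].
#' @param mt_tree,y_tree optional `reference_tree`s; defaults to the bundled
#'   toy mtDNA and Y skeleton trees.
#' @return A list with `ped`, `founders`, `assign`, `mt_tree`, `y_tree`,
#'   `cfg`.
#' @export
simulate_norfolk <- function(cfg, mt_tree = NULL, y_tree = NULL) {
  if (is.null(mt_tree)) {
    mt_tree <- read_reference_tree(uniparental_example("mt_tree.tsv"), "mtDNA")
  }
  if (is.null(y_tree)) {
    y_tree <- read_reference_tree(uniparental_example("y_tree.tsv"), "Y")
  }
  ped <- simulate_pedigree(cfg)
  founders <- assign_founder_haplotypes(ped, mt_tree, y_tree, cfg)
  assign <- propagate_lineages(ped, founders)
  list(ped = ped, founders = founders, assign = assign,
       mt_tree = mt_tree, y_tree = y_tree, cfg = cfg)
}
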