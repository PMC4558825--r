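#' Read a flat key-value pipeline configuration
#'
#' One `key: value` pair per line; `#` lines are comments. Values are kept
#' as strings and interpreted by [run_pipeline()].
#'
#' @param path config file path.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  stats::setNames(as.list(vals), keys)
}

# stable, dependency-free config fingerprint (31-ary polynomial hash mod a
# Mersenne prime; stays in exact double range throughout)
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v),
             collapse = ","), character(1)), sep = "=", collapse = ";")
  h <- 17
  for (b in utf8ToInt(s)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

pipeline_default_stages <- c("simulate", "assign", "propagate", "profiles",
                             "call", "assay", "concordance", "estimate",
                             "tree")

#' Run the uniparental-ancestry pipeline
#'
#' Executes the enabled stages in dependency order with flat-file handoffs,
#' so that any stage can be re-run in isolation from its on-disk inputs:
#' `simulate` (pedigree), `assign` (founder haplogroups), `propagate`
#' (lineage table), `profiles` (noisy variant profiles for the evaluation
#' subset), `call` (haplogroup calls), `assay` (9-bp-deletion screen on
#' sequences built from the synthetic reference), `concordance`
#' (propagated-vs-called agreement), `estimate` (admixture estimate) and
#' `tree` (NJ tree of the profiles). Tabular outputs carry `#` header lines
#' recording the seed and a config fingerprint; identical config and seed
#' give byte-identical outputs.
#'
#' @param config a named list (string values allowed, as from
#'   [read_pipeline_config()]) or a path to a flat key-value config file.
#'   Recognised keys: `outdir`, `seed`, `stages` (comma-separated subset of
#'   the defaults), `mt_tree`, `y_tree`, `ped`, `founders`, `lineages`,
#'   `profiles`, `reps`, `subset`, and `sim_*` overrides for
#'   [simulation_config()] fields (e.g. `sim_generations`,
#'   `sim_offspring_rate`, `sim_max_pop`, `sim_dropout_rate`,
#'   `sim_false_positive_rate`).
#' @return A run report: named list of per-stage record counts and output
#'   paths, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config) && length(config) == 1) {
    read_pipeline_config(config)
  } else {
    config
  }
  need_key <- function(key, stage) {
    if (is.null(cfg[[key]])) {
      stop("configuration error: stage '", stage, "' requires key '", key,
           "'", call. = FALSE)
    }
    cfg[[key]]
  }
  outdir <- need_key("outdir", "all")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (is.null(cfg$stages)) pipeline_default_stages else {
    trimws(strsplit(paste(cfg$stages, collapse = ","), ",")[[1]])
  }
  bad <- setdiff(stages, pipeline_default_stages)
  if (length(bad) > 0) {
    stop("configuration error: unknown stage(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  stages <- pipeline_default_stages[pipeline_default_stages %in% stages]
  stochastic <- c("simulate", "assign", "profiles", "estimate")
  if (any(stages %in% stochastic) && is.null(cfg$seed)) {
    stop("configuration error: key 'seed' is mandatory when stochastic ",
         "stages are enabled", call. = FALSE)
  }
  seed <- if (is.null(cfg$seed)) 0L else as.integer(cfg$seed)
  # fingerprint of the logical configuration; the output location is not
  # part of what the run computes
  hash <- config_hash(cfg[sort(setdiff(names(cfg), "outdir"))])
  hdr <- c(paste0("seed=", seed), paste0("config_hash=", hash))
  out <- function(f) file.path(outdir, f)
  num <- function(key, default) {
    if (is.null(cfg[[key]])) default else as.numeric(cfg[[key]])
  }
  report <- list(seed = seed, config_hash = hash,
                 package_version = as.character(utils::packageVersion("uniparental")))
  ped_path <- cfg$ped %||% out("sim.ped")
  founders_path <- cfg$founders %||% out("founders.tsv")
  lineages_path <- cfg$lineages %||% out("lineages.tsv")
  profiles_path <- cfg$profiles %||% out("profiles.tsv")
  mask <- if (is.null(cfg$mask)) integer(0) else {
    as.integer(trimws(strsplit(paste(cfg$mask, collapse = ","), ",")[[1]]))
  }
  sim_cfg <- function() {
    simulation_config(
      n_male_founders = num("sim_n_male_founders", 9),
      n_female_founders = num("sim_n_female_founders", 12),
      generations = num("sim_generations", 11),
      offspring_rate = num("sim_offspring_rate", 3.0),
      max_pop = num("sim_max_pop", 1400),
      dropout_rate = num("sim_dropout_rate", 0),
      false_positive_rate = num("sim_false_positive_rate", 0),
      polynesian_B_prob = num("sim_polynesian_B_prob", 0.9),
      y_outlier_prob = num("sim_y_outlier_prob", 0.01),
      seed = seed)
  }
  load_tree <- function(key, stage, marker) {
    read_reference_tree(need_key(key, stage), marker)
  }
  subset_ids <- function(ped) {
    if (is.null(cfg$subset) || identical(cfg$subset, "leaves")) {
      pedigree_leaves(ped)
    } else {
      trimws(strsplit(paste(cfg$subset, collapse = ","), ",")[[1]])
    }
  }

  run_stage <- function(stage) {
    switch(stage,
      simulate = {
        ped <- simulate_pedigree(sim_cfg())
        write_pedigree(ped, out("sim.ped"), header = hdr)
        ped_path <<- out("sim.ped")
        nrow(ped)
      },
      assign = {
        ped <- read_pedigree(ped_path)
        mt <- load_tree("mt_tree", "assign", "mtDNA")
        yt <- load_tree("y_tree", "assign", "Y")
        f <- assign_founder_haplotypes(ped, mt, yt, sim_cfg())
        write_founder_haplotypes(f, out("founders.tsv"), header = hdr)
        founders_path <<- out("founders.tsv")
        nrow(f)
      },
      propagate = {
        ped <- read_pedigree(ped_path)
        f <- read_founder_haplotypes(founders_path)
        a <- propagate_lineages(ped, f)
        write_lineages(a, out("lineages.tsv"), header = hdr)
        lineages_path <<- out("lineages.tsv")
        nrow(a)
      },
      profiles = {
        ped <- read_pedigree(ped_path)
        a <- read_lineages(lineages_path)
        mt <- load_tree("mt_tree", "profiles", "mtDNA")
        p <- generate_variant_profiles(
          a, mt, dropout_rate = num("sim_dropout_rate", 0),
          false_positive_rate = num("sim_false_positive_rate", 0),
          seed = seed + 2L, ids = subset_ids(ped))
        write_variant_profiles(p, out("profiles.tsv"))
        profiles_path <<- out("profiles.tsv")
        length(p)
      },
      call = {
        mt <- load_tree("mt_tree", "call", "mtDNA")
        p <- read_variant_profiles(profiles_path)
        calls <- call_haplogroups(p, mt, mask = mask)
        write_haplogroup_calls(calls, out("calls.tsv"), header = hdr)
        nrow(calls)
      },
      assay = {
        p <- read_variant_profiles(profiles_path)
        ref <- if (is.null(cfg$reference)) synthetic_mt_reference() else {
          as.character(Biostrings::readDNAStringSet(cfg$reference)[[1]])
        }
        seqs <- vapply(p, function(pr) {
          pv <- pr$variants[parse_variants(pr$variants)$kind != "opaque"]
          apply_variants_to_sequence(ref, pv)
        }, character(1))
        names(seqs) <- vapply(p, `[[`, character(1), "sample_id")
        res <- run_deletion_assay(seqs)
        con <- file(out("assay.tsv"), "w")
        writeLines(paste0("# ", hdr), con)
        utils::write.table(res, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        close(con)
        nrow(res)
      },
      concordance = {
        a <- read_lineages(lineages_path)
        calls <- utils::read.table(out("calls.tsv"), header = TRUE,
                                   sep = "\t", comment.char = "#",
                                   stringsAsFactors = FALSE)
        mt <- load_tree("mt_tree", "concordance", "mtDNA")
        cc <- lineage_concordance(a, calls, mt)
        con <- file(out("concordance.tsv"), "w")
        writeLines(c(paste0("# ", hdr),
                     paste0("concordance\t", format(cc$concordance)),
                     paste0("n_overlap\t", cc$n_overlap)), con)
        close(con)
        cc$n_overlap
      },
      estimate = {
        ped <- read_pedigree(ped_path)
        a <- read_lineages(lineages_path)
        est <- admixture_estimate(a, ped, subset = subset_ids(ped),
                                  reps = num("reps", 1000),
                                  seed = seed + 3L,
                                  subset_label = cfg$subset %||% "leaves")
        jsonlite::write_json(
          list(seed = seed, config_hash = hash, subset = est$subset,
               n = est$n, maternal = as.list(est$maternal),
               paternal = as.list(est$paternal),
               ci = est$ci,
               matriline_survivors = est$matriline_survivors,
               patriline_survivors = est$patriline_survivors,
               bias_index = as.list(est$bias_index)),
          out("estimate.json"), auto_unbox = TRUE, digits = NA)
        est$n
      },
      tree = {
        p <- read_variant_profiles(profiles_path)
        nwk <- if (length(p) >= 2) {
          neighbor_joining(hamming_distance_matrix(p, mask = mask))
        } else {
          paste0(p[[1]]$sample_id, ";")
        }
        writeLines(nwk, out("tree.nwk"))
        length(p)
      })
  }

  for (stage in stages) {
    n <- tryCatch(run_stage(stage), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report[[stage]] <- n
    message("stage ", stage, ": ", n, " records")
  }
  manifest <- c(paste0("# uniparental run manifest"),
                paste0("seed\t", seed), paste0("config_hash\t", hash),
                paste0("package_version\t", report$package_version),
                vapply(stages, function(s) paste0(s, "\t", report[[s]]),
                       character(1)))
  writeLines(manifest, out("run_manifest.txt"))
  invisible(report)
}

#' Read a lineage table written by [write_lineages()]
#'
#' @param path input path.
#' @return A `lineage_assignment` data.frame.
#' @export
read_lineages <- function(path) {
  a <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         stringsAsFactors = FALSE, na.strings = "NA",
                         colClasses = "character")
  class(a) <- c("lineage_assignment", "data.frame")
  a
}
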