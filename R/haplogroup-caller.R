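#' Create a variant profile
#'
#' A variant profile is the set of variants observed in one sample relative to
#' the marker's reference sequence — the per-sample reduction of a consensus
#' sequence or genotyping panel.
#'
#' @param sample_id non-empty sample identifier.
#' @param variants character vector of variant tokens (see [parse_variants()]).
#' @param marker_type `"mtDNA"` or `"Y"`.
#' @return An object of class `variant_profile`.
#' @export
variant_profile <- function(sample_id, variants, marker_type = c("mtDNA", "Y")) {
  marker_type <- match.arg(marker_type)
  if (!is.character(sample_id) || length(sample_id) != 1 || !nzchar(sample_id)) {
    stop("sample_id must be a non-empty string", call. = FALSE)
  }
  variants <- unique(as.character(variants))
  parse_variants(variants)  # grammar check
  structure(list(sample_id = sample_id, variants = variants,
                 marker_type = marker_type),
            class = "variant_profile")
}

#' @export
print.variant_profile <- function(x, ...) {
  cat("Variant profile '", x$sample_id, "' (", x$marker_type, "): ",
      length(x$variants), " variants\n", sep = "")
  invisible(x)
}

#' Read variant profiles from TSV
#'
#' Expects two tab-separated columns, `sample_id` and a comma-separated list
#' of variant tokens (possibly empty). `#` lines are comments.
#'
#' @param path input path.
#' @param marker_type `"mtDNA"` or `"Y"`.
#' @return A list of `variant_profile` objects.
#' @export
read_variant_profiles <- function(path, marker_type = c("mtDNA", "Y")) {
  marker_type <- match.arg(marker_type)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    toks <- if (length(f) >= 2 && nzchar(trimws(f[2]))) {
      trimws(strsplit(f[2], ",", fixed = TRUE)[[1]])
    } else {
      character(0)
    }
    variant_profile(trimws(f[1]), toks, marker_type)
  })
}

#' Write variant profiles to TSV
#'
#' @param profiles list of `variant_profile` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_profiles <- function(profiles, path) {
  rows <- vapply(profiles, function(p) {
    paste(p$sample_id, paste(p$variants, collapse = ","), sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

# Canonical matching key per parsed token: substitutions by position+allele,
# deletions by range, insertions/opaque by body string.
variant_match_keys <- function(p) {
  ifelse(p$kind == "substitution",
         paste0("s", p$position, ":", p$derived),
         ifelse(p$kind == "deletion",
                paste0("d", p$position, "-", p$end),
                paste0("o", sub("!$", "", p$token))))
}

# Pre-parsed token set with cached keys and size, the unit the scorer works on.
parsed_set <- function(tokens) {
  p <- parse_variants(tokens)
  list(p = p, key = variant_match_keys(p), n = nrow(p))
}

# Parsed cumulative variant sets (with keys) for every node of a tree,
# computed once per calling batch in a single root-to-tips sweep.
tree_cumulative_parsed <- function(tree, mask = integer(0)) {
  lapply(all_cumulative_tokens(tree), function(toks) {
    parsed_set(mask_variants(toks, mask))
  })
}

# Kulczynski-style symmetric score on pre-parsed sets.
score_parsed_sets <- function(es, os) {
  m <- match_parsed_sets(es, os)
  e <- es$n
  o <- os$n
  te <- if (e == 0) 1 else m / e
  to <- if (o == 0) 1 else m / o
  list(score = (te + to) / 2, matched = m, expected = e, observed = o)
}

# |M| on pre-parsed sets: exact token classes match by canonical key
# (vectorised), then a small second pass pairs remaining substitutions whose
# alleles are compatible through the bare-position wildcard. One-to-one
# throughout, so |M| <= min(|E|, |O|).
match_parsed_sets <- function(es, os) {
  ne <- es$n; no <- os$n
  if (ne == 0 || no == 0) return(0L)
  ekey <- es$key; okey <- os$key
  ein <- ekey %in% okey
  if (anyDuplicated(ekey) || anyDuplicated(okey)) {
    te <- table(ekey); to <- table(okey)
    common <- intersect(names(te), names(to))
    m <- sum(pmin(as.integer(te[common]), as.integer(to[common])))
  } else {
    m <- sum(ein)
  }
  # wildcard pass only when both sides still have unmatched tokens
  if (m < ne && m < no) {
    ep <- es$p; op <- os$p
    eu <- which(!ein & ep$kind == "substitution")
    ou <- which(!(okey %in% ekey) & op$kind == "substitution")
    if (length(eu) > 0 && length(ou) > 0) {
      used <- rep(FALSE, length(ou))
      for (i in eu) {
        hit <- which(!used & op$position[ou] == ep$position[i] &
                       (ep$derived[i] == "*" | op$derived[ou] == "*"))
        if (length(hit) > 0) {
          used[hit[1]] <- TRUE
          m <- m + 1L
        }
      }
    }
  }
  as.integer(m)
}

#' Score a profile against one haplogroup
#'
#' Compares the sample's observed variants `O` with the haplogroup's expected
#' cumulative variants `E` (root-to-node, positions in `mask` removed from
#' both sides) and returns the symmetric Kulczynski-style mean
#' `(|M|/|E| + |M|/|O|) / 2`, where `M` is the matched set and a term with an
#' empty denominator counts as 1. Bare-position tokens match any allele at
#' their position.
#'
#' @param profile a `variant_profile`.
#' @param tree a `reference_tree`.
#' @param node a node name.
#' @param mask integer vector of positions to exclude (default none).
#' @return A list with `score` in `[0, 1]`, `matched`, `expected`, `observed`.
#' @examples
#' tree <- read_reference_tree(uniparental_example("mt_tree.tsv"))
#' p <- variant_profile("s1", cumulative_variants(tree, "B4a1"))
#' score_profile_against_node(p, tree, "B4a1")
#' @export
score_profile_against_node <- function(profile, tree, node, mask = integer(0)) {
  if (!(node %in% tree$nodes$name)) {
    stop("unknown node '", node, "'", call. = FALSE)
  }
  es <- parsed_set(mask_variants(cumulative_variants(tree, node), mask))
  os <- parsed_set(mask_variants(profile$variants, mask))
  score_parsed_sets(es, os)
}

#' Call the best-matching haplogroup for a profile
#'
#' Scores the profile against every node of the reference tree and returns
#' the maximiser. Ties are broken in favour of the deeper (more specific)
#' node, then lexicographically by name, so output is deterministic.
#'
#' @inheritParams score_profile_against_node
#' @param n_runners_up number of runner-up nodes to report (default 5).
#' @return An object of class `haplogroup_call` with fields `sample_id`,
#'   `best_node`, `score`, `matched`, `expected`, `observed` and a
#'   `runners_up` data.frame (`node`, `score`).
#' @examples
#' tree <- read_reference_tree(uniparental_example("mt_tree.tsv"))
#' p <- variant_profile("s1", cumulative_variants(tree, "B4a1a1a14"))
#' call_haplogroup(p, tree)
#' @export
call_haplogroup <- function(profile, tree, mask = integer(0),
                            n_runners_up = 5) {
  if (nrow(tree$nodes) == 0) stop("empty tree", call. = FALSE)
  if (!identical(profile$marker_type, tree$marker_type)) {
    stop("profile marker_type '", profile$marker_type,
         "' does not match tree marker_type '", tree$marker_type, "'",
         call. = FALSE)
  }
  cum <- tree_cumulative_parsed(tree, mask)
  depths <- vapply(tree$nodes$name, function(nd) node_depth(tree, nd),
                   integer(1))
  call_one(profile, tree, cum, depths, mask, n_runners_up)
}

call_one <- function(profile, tree, cum, depths, mask, n_runners_up) {
  os <- parsed_set(mask_variants(profile$variants, mask))
  nodes <- tree$nodes$name
  nn <- length(cum)
  mvec <- integer(nn)
  evec <- integer(nn)
  for (k in seq_len(nn)) {
    mvec[k] <- match_parsed_sets(cum[[k]], os)
    evec[k] <- cum[[k]]$n
  }
  te <- ifelse(evec == 0L, 1, mvec / evec)
  to <- if (os$n == 0L) rep(1, nn) else mvec / os$n
  scores <- (te + to) / 2
  ord <- order(-scores, -depths, nodes)
  best <- ord[1]
  ru <- ord[-1][seq_len(min(n_runners_up, length(ord) - 1))]
  structure(list(
    sample_id = profile$sample_id,
    best_node = nodes[best],
    score = scores[[best]],
    matched = mvec[best],
    expected = evec[best],
    observed = os$n,
    runners_up = data.frame(node = nodes[ru], score = unname(scores[ru]),
                            stringsAsFactors = FALSE)
  ), class = "haplogroup_call")
}

#' @export
print.haplogroup_call <- function(x, ...) {
  cat(sprintf("%s -> %s (score %.4f; |M|=%d |E|=%d |O|=%d)\n",
              x$sample_id, x$best_node, x$score, x$matched, x$expected,
              x$observed))
  invisible(x)
}

#' Call haplogroups for a set of profiles
#'
#' Batch interface over [call_haplogroup()]. Identical variant sets are
#' scored once and the call reused, which matters on noise-free simulated
#' cohorts where many samples share a haplotype.
#'
#' @param profiles list of `variant_profile` objects.
#' @param tree a `reference_tree`.
#' @param mask integer vector of masked positions.
#' @return A data.frame with columns `sample_id`, `haplogroup`, `score`,
#'   `matched`, `expected`, `observed`.
#' @export
call_haplogroups <- function(profiles, tree, mask = integer(0)) {
  if (length(profiles) == 0) stop("empty profile list", call. = FALSE)
  cum <- tree_cumulative_parsed(tree, mask)
  depths <- vapply(tree$nodes$name, function(nd) node_depth(tree, nd),
                   integer(1))
  keys <- vapply(profiles, function(p) {
    paste0("k:", paste(sort(p$variants), collapse = ";"))
  }, character(1))
  cache <- new.env(parent = emptyenv())
  calls <- lapply(seq_along(profiles), function(i) {
    k <- keys[i]
    if (is.null(cache[[k]])) {
      if (!identical(profiles[[i]]$marker_type, tree$marker_type)) {
        stop("profile marker_type mismatch for sample '",
             profiles[[i]]$sample_id, "'", call. = FALSE)
      }
      cache[[k]] <- call_one(profiles[[i]], tree, cum, depths, mask, 5)
    }
    c0 <- cache[[k]]
    data.frame(sample_id = profiles[[i]]$sample_id, haplogroup = c0$best_node,
               score = c0$score, matched = c0$matched, expected = c0$expected,
               observed = c0$observed, stringsAsFactors = FALSE)
  })
  do.call(rbind, calls)
}

#' Write haplogroup calls to TSV
#'
#' @param calls data.frame from [call_haplogroups()].
#' @param path output path.
#' @param header optional character vector of `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_haplogroup_calls <- function(calls, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0) writeLines(paste0("# ", header), con)
  utils::write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse haplogroup calls into clade frequency bins
#'
#' Bins each call as `"<ancestor>[x]"` when its haplogroup lies at or below
#' `ancestor`, and otherwise by its own top-level clade (the depth-1 ancestor
#' on the reference tree). This is the bookkeeping behind summaries such as
#' the fraction of a cohort falling in a focal clade.
#'
#' @param calls data.frame from [call_haplogroups()] (or any data.frame with
#'   a `haplogroup` column), or a character vector of haplogroup names.
#' @param ancestor focal clade name.
#' @param tree a `reference_tree`.
#' @return A data.frame with columns `bin`, `count`, `frequency`; frequencies
#'   sum to 1.
#' @examples
#' tree <- read_reference_tree(uniparental_example("mt_tree.tsv"))
#' collapse_haplogroup_frequencies(c("H1", "B4a1a1m", "B4a1a1a14"), "B4a1", tree)
#' @export
collapse_haplogroup_frequencies <- function(calls, ancestor, tree) {
  hg <- if (is.character(calls)) calls else calls$haplogroup
  if (length(hg) == 0) stop("empty call list", call. = FALSE)
  if (!(ancestor %in% tree$nodes$name)) {
    stop("unknown ancestor '", ancestor, "'", call. = FALSE)
  }
  bins <- vapply(hg, function(nd) {
    path <- node_path(tree, nd)
    if (ancestor %in% path) {
      paste0(ancestor, "[x]")
    } else if (length(path) >= 2) {
      path[2]
    } else {
      path[1]
    }
  }, character(1))
  tab <- table(bins)
  data.frame(bin = names(tab), count = as.integer(tab),
             frequency = as.numeric(tab) / length(bins),
             stringsAsFactors = FALSE, row.names = NULL)
}
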