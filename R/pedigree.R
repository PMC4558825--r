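#' Construct and validate a pedigree
#'
#' A pedigree is a table of individuals with parent links, sex and (for
#' founders) a population-of-origin label. Validation enforces: unique ids,
#' resolvable parent references, fathers male, mothers female, and an acyclic
#' parent-child graph. A founder is an individual with both parents missing;
#' `origin` is meaningful for founders and is `"unknown"` elsewhere.
#'
#' @param df data.frame with columns `fam`, `id`, `father`, `mother` (`NA`
#'   for missing), `sex` (`"male"`/`"female"`) and `origin` (`"european"`,
#'   `"polynesian"`, `"other"` or `"unknown"`); an optional `generation`
#'   column is kept.
#' @return The validated data.frame with class `pedigree`.
#' @export
as_pedigree <- function(df) {
  need <- c("fam", "id", "father", "mother", "sex", "origin")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df$id <- as.character(df$id)
  df$father <- as.character(df$father)
  df$mother <- as.character(df$mother)
  dup <- which(duplicated(df$id))
  if (length(dup) > 0) {
    stop("duplicate individual id '", df$id[dup[1]], "' (row ", dup[1], ")",
         call. = FALSE)
  }
  if (!all(df$sex %in% c("male", "female"))) {
    bad <- which(!(df$sex %in% c("male", "female")))[1]
    stop("invalid sex '", df$sex[bad], "' (row ", bad, ")", call. = FALSE)
  }
  idx <- stats::setNames(seq_len(nrow(df)), df$id)
  for (col in c("father", "mother")) {
    ref <- df[[col]]
    bad <- which(!is.na(ref) & !(ref %in% df$id))
    if (length(bad) > 0) {
      stop("unresolved ", col, " reference '", ref[bad[1]], "' (row ",
           bad[1], ")", call. = FALSE)
    }
    want <- if (col == "father") "male" else "female"
    bad <- which(!is.na(ref) & df$sex[idx[ref]] != want)
    if (length(bad) > 0) {
      stop(col, " '", ref[bad[1]], "' of individual '", df$id[bad[1]],
           "' is not ", want, " (row ", bad[1], ")", call. = FALSE)
    }
  }
  # acyclicity: walking up either parent line must terminate
  fi <- match(df$father, df$id)
  mi <- match(df$mother, df$id)
  for (start in seq_len(nrow(df))) {
    cur <- start
    steps <- 0L
    while (TRUE) {
      nxt <- if (!is.na(mi[cur])) mi[cur] else fi[cur]
      if (is.na(nxt)) break
      cur <- nxt
      steps <- steps + 1L
      if (steps > nrow(df)) {
        stop("cycle detected in pedigree involving individual '",
             df$id[start], "' (row ", start, ")", call. = FALSE)
      }
    }
  }
  class(df) <- c("pedigree", "data.frame")
  df
}

#' Read a PED-like pedigree file
#'
#' Six whitespace-delimited columns: family id, individual id, father id,
#' mother id, sex (1 = male, 2 = female), origin (`european`, `polynesian`,
#' `other`, or `0` = unknown). `0` in a parent column means missing. `#`
#' lines are comments. The origin label occupies the slot a classic PED file
#' uses for the phenotype.
#'
#' @param path input path.
#' @return A validated `pedigree`.
#' @seealso [write_pedigree()], its exact inverse.
#' @export
read_pedigree <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(fields) != 6)
  if (length(bad) > 0) {
    stop("expected 6 columns, got ", length(fields[[bad[1]]]), " (row ",
         bad[1], ")", call. = FALSE)
  }
  m <- do.call(rbind, fields)
  sex_code <- m[, 5]
  if (!all(sex_code %in% c("1", "2"))) {
    bad <- which(!(sex_code %in% c("1", "2")))[1]
    stop("invalid sex code '", sex_code[bad], "' (row ", bad, ")",
         call. = FALSE)
  }
  origin <- m[, 6]
  origin[origin == "0"] <- "unknown"
  ok <- origin %in% c("european", "polynesian", "other", "unknown")
  if (!all(ok)) {
    stop("invalid origin '", origin[which(!ok)[1]], "' (row ", which(!ok)[1],
         ")", call. = FALSE)
  }
  as_pedigree(data.frame(
    fam = m[, 1], id = m[, 2],
    father = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = ifelse(sex_code == "1", "male", "female"),
    origin = origin, stringsAsFactors = FALSE))
}

#' Write a pedigree in PED-like format
#'
#' @param ped a `pedigree`.
#' @param path output path.
#' @param header optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, header = character(0)) {
  rows <- paste(ped$fam, ped$id,
                ifelse(is.na(ped$father), "0", ped$father),
                ifelse(is.na(ped$mother), "0", ped$mother),
                ifelse(ped$sex == "male", "1", "2"),
                ifelse(ped$origin == "unknown", "0", ped$origin),
                sep = "\t")
  if (length(header) > 0) rows <- c(paste0("# ", header), rows)
  writeLines(rows, path)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  f <- pedigree_founders(x)
  cat("Pedigree: ", nrow(x), " individuals (", sum(x$sex == "male"),
      " male / ", sum(x$sex == "female"), " female), ", length(f),
      " founders, ", length(pedigree_leaves(x)), " leaves\n", sep = "")
  invisible(x)
}

#' Pedigree subsets
#'
#' `pedigree_founders()` returns the ids of individuals with both parents
#' missing; `pedigree_leaves()` the ids of individuals with no recorded
#' children (the default stand-in for the present-day cohort).
#'
#' @param ped a `pedigree`.
#' @return Character vector of ids.
#' @name pedigree_subsets
#' @export
pedigree_founders <- function(ped) {
  ped$id[is.na(ped$father) & is.na(ped$mother)]
}

#' @rdname pedigree_subsets
#' @export
pedigree_leaves <- function(ped) {
  setdiff(ped$id, c(ped$father[!is.na(ped$father)],
                    ped$mother[!is.na(ped$mother)]))
}

#' Trace an individual's uniparental founder
#'
#' Follows mother links (`line = "maternal"`) or father links
#' (`line = "paternal"`) until the corresponding parent is missing and
#' returns that individual's id — possibly the query itself. An individual
#' with only one recorded parent terminates the missing side's line at
#' themselves. The paternal line of a female is undefined and returns `NA`.
#'
#' @param ped a `pedigree`.
#' @param id individual id.
#' @param line `"maternal"` or `"paternal"`.
#' @return A founder id, or `NA` for a female's paternal line.
#' @export
uniparental_founder <- function(ped, id, line = c("maternal", "paternal")) {
  line <- match.arg(line)
  i <- match(id, ped$id)
  if (is.na(i)) stop("unknown individual '", id, "'", call. = FALSE)
  if (line == "paternal" && ped$sex[i] == "female") return(NA_character_)
  parent <- if (line == "maternal") ped$mother else ped$father
  pidx <- match(parent, ped$id)
  while (!is.na(pidx[i])) i <- pidx[i]
  ped$id[i]
}

#' Propagate founder haplotypes through a pedigree
#'
#' Assigns every individual their matrilineal founder, patrilineal founder
#' (males only), and the mtDNA / Y haplogroups inherited along those lines:
#' mtDNA passes from mother to all children, the Y from father to sons.
#' Lineage founders absent from `founder_haplotypes` (for example half-known
#' individuals whose missing parent side makes them a lineage terminal)
#' propagate `NA` haplotypes.
#'
#' @param ped a `pedigree`.
#' @param founder_haplotypes data.frame with columns `id`, `mt_haplogroup`
#'   and `y_haplogroup` (e.g. from [assign_founder_haplotypes()]). Every true
#'   founder must have an mtDNA haplogroup and every male founder a Y
#'   haplogroup.
#' @return A data.frame of class `lineage_assignment` with columns `id`,
#'   `matriline_founder`, `patriline_founder`, `mt_haplotype`, `y_haplotype`.
#' @export
propagate_lineages <- function(ped, founder_haplotypes) {
  fh <- founder_haplotypes
  founders <- pedigree_founders(ped)
  fsex <- ped$sex[match(founders, ped$id)]
  miss_mt <- setdiff(founders, fh$id[!is.na(fh$mt_haplogroup)])
  if (length(miss_mt) > 0) {
    stop("missing founder mtDNA haplotype for: ",
         paste(utils::head(miss_mt, 5), collapse = ", "), call. = FALSE)
  }
  miss_y <- setdiff(founders[fsex == "male"],
                    fh$id[!is.na(fh$y_haplogroup)])
  if (length(miss_y) > 0) {
    stop("missing founder Y haplotype for: ",
         paste(utils::head(miss_y, 5), collapse = ", "), call. = FALSE)
  }
  n <- nrow(ped)
  mi <- match(ped$mother, ped$id)
  fi <- match(ped$father, ped$id)
  # vectorised chain-following: repeatedly replace each index by its parent
  matri <- seq_len(n)
  repeat {
    nxt <- mi[matri]
    has <- !is.na(nxt)
    if (!any(has)) break
    matri[has] <- nxt[has]
  }
  patri <- seq_len(n)
  repeat {
    nxt <- fi[patri]
    has <- !is.na(nxt)
    if (!any(has)) break
    patri[has] <- nxt[has]
  }
  mt <- fh$mt_haplogroup[match(ped$id[matri], fh$id)]
  yh <- fh$y_haplogroup[match(ped$id[patri], fh$id)]
  pat <- ped$id[patri]
  female <- ped$sex == "female"
  pat[female] <- NA_character_
  yh[female] <- NA_character_
  out <- data.frame(id = ped$id, matriline_founder = ped$id[matri],
                    patriline_founder = pat, mt_haplotype = mt,
                    y_haplotype = yh, stringsAsFactors = FALSE)
  class(out) <- c("lineage_assignment", "data.frame")
  out
}

#' Write a lineage assignment table
#'
#' @param assign a `lineage_assignment`.
#' @param path output path.
#' @param header optional `#`-prefixed header lines.
#' @return `path`, invisibly.
#' @export
write_lineages <- function(assign, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0) writeLines(paste0("# ", header), con)
  utils::write.table(assign, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# Ancestor of `node` at the requested depth (the node itself if shallower).
collapse_to_depth <- function(tree, node, level) {
  path <- node_path(tree, node)
  path[min(level + 1L, length(path))]
}

#' Concordance between propagated and observed haplogroups
#'
#' Compares pedigree-propagated haplotypes with observed haplogroup calls on
#' the overlapping samples, after collapsing both to a clade level (ancestor
#' at the given depth on the reference tree). Mismatches flag candidate
#' pedigree errors or unrecognised founders.
#'
#' @param assign a `lineage_assignment` (uses `mt_haplotype`).
#' @param calls data.frame from [call_haplogroups()].
#' @param tree the `reference_tree` both label sets live on.
#' @param level collapse depth (root = 0); default `Inf` compares exact
#'   haplogroup labels.
#' @return A list with `concordance` (fraction in `[0, 1]`), `n_overlap`,
#'   and `mismatches` (data.frame of discordant samples).
#' @export
lineage_concordance <- function(assign, calls, tree, level = Inf) {
  common <- intersect(assign$id, calls$sample_id)
  if (length(common) == 0) {
    stop("no overlapping sample ids between assignment and calls",
         call. = FALSE)
  }
  exp_hg <- assign$mt_haplotype[match(common, assign$id)]
  obs_hg <- calls$haplogroup[match(common, calls$sample_id)]
  coll <- function(h) {
    if (is.na(h)) return(NA_character_)
    if (is.finite(level)) collapse_to_depth(tree, h, level) else h
  }
  expc <- vapply(exp_hg, coll, character(1))
  obsc <- vapply(obs_hg, coll, character(1))
  agree <- !is.na(expc) & !is.na(obsc) & expc == obsc
  mism <- data.frame(id = common[!agree], expected = expc[!agree],
                     observed = obsc[!agree], stringsAsFactors = FALSE)
  list(concordance = mean(agree), n_overlap = length(common),
       mismatches = mism)
}
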