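#' Read a haplogroup reference tree
#'
#' Reads an annotated haplogroup phylogeny (a Phylotree-style mtDNA tree or a
#' minimal skeleton Y tree) from a three-column tab-separated file:
#' `node <TAB> parent <TAB> comma-separated variant tokens`. The root row has
#' an empty parent field. Lines starting with `#` are comments.
#'
#' @param path path to the tree file.
#' @param marker_type `"mtDNA"` or `"Y"`; recorded on the returned tree and
#'   checked against profiles at calling time.
#' @return An object of class `reference_tree`: a list with elements `nodes`
#'   (data.frame of `name`, `parent`), `variants` (named list of token
#'   vectors) and `marker_type`.
#' @seealso [cumulative_variants()], [induced_subtree_newick()],
#'   [write_reference_tree()]
#' @examples
#' tree <- read_reference_tree(uniparental_example("mt_tree.tsv"))
#' tree
#' @export
read_reference_tree <- function(path, marker_type = c("mtDNA", "Y")) {
  marker_type <- match.arg(marker_type)
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) stop("tree file is empty: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  name <- vapply(fields, function(f) trimws(f[1]), character(1))
  parent <- vapply(fields, function(f) {
    if (length(f) >= 2) trimws(f[2]) else ""
  }, character(1))
  vartok <- vapply(fields, function(f) {
    if (length(f) >= 3) trimws(f[3]) else ""
  }, character(1))
  variants <- lapply(vartok, function(v) {
    if (!nzchar(v)) character(0) else trimws(strsplit(v, ",", fixed = TRUE)[[1]])
  })
  names(variants) <- name
  new_reference_tree(name, ifelse(nzchar(parent), parent, NA_character_),
                     variants, marker_type)
}

#' Construct and validate a reference tree
#'
#' Low-level constructor used by [read_reference_tree()] and by the
#' simulator's random-tree helpers. Validates the haplogroup graph: unique
#' names, resolvable parents, exactly one root, no cycles.
#'
#' @param name character vector of node names.
#' @param parent character vector of parent names (`NA` for the root).
#' @param variants named list of defining-variant token vectors.
#' @param marker_type `"mtDNA"` or `"Y"`.
#' @return A `reference_tree` object.
#' @export
new_reference_tree <- function(name, parent, variants, marker_type = "mtDNA") {
  dup <- name[duplicated(name)]
  if (length(dup) > 0) {
    stop("duplicate node name(s) in tree: ", paste(unique(dup), collapse = ", "),
         " (row ", which(name %in% dup)[2], ")", call. = FALSE)
  }
  roots <- which(is.na(parent))
  if (length(roots) == 0) stop("tree has no root row (empty parent field)",
                               call. = FALSE)
  if (length(roots) > 1) {
    stop("tree has multiple roots: ", paste(name[roots], collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.na(parent) & !(parent %in% name))
  if (length(bad) > 0) {
    stop("unresolvable parent '", parent[bad[1]], "' for node '",
         name[bad[1]], "' (row ", bad[1], ")", call. = FALSE)
  }
  # cycle check: walk to root from every node, bounded by node count
  pmap <- stats::setNames(parent, name)
  for (i in seq_along(name)) {
    cur <- name[i]
    steps <- 0L
    while (!is.na(pmap[[cur]])) {
      cur <- pmap[[cur]]
      steps <- steps + 1L
      if (steps > length(name)) {
        stop("cycle detected in tree at node '", name[i], "' (row ", i, ")",
             call. = FALSE)
      }
    }
  }
  for (v in variants) parse_variants(v)  # token grammar check
  structure(list(
    nodes = data.frame(name = name, parent = parent, stringsAsFactors = FALSE),
    variants = variants[name],
    marker_type = marker_type
  ), class = "reference_tree")
}

#' Write a reference tree
#'
#' Serialises a `reference_tree` back to the three-column TSV format;
#' [read_reference_tree()] of the result reproduces the node set and variant
#' tokens exactly.
#'
#' @param tree a `reference_tree`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_tree <- function(tree, path) {
  stopifnot(inherits(tree, "reference_tree"))
  rows <- vapply(seq_len(nrow(tree$nodes)), function(i) {
    paste(tree$nodes$name[i],
          ifelse(is.na(tree$nodes$parent[i]), "", tree$nodes$parent[i]),
          paste(tree$variants[[tree$nodes$name[i]]], collapse = ","),
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' @export
print.reference_tree <- function(x, ...) {
  cat("Haplogroup reference tree (", x$marker_type, "), ",
      nrow(x$nodes), " nodes, root '", tree_root(x), "'\n", sep = "")
  nv <- sum(lengths(x$variants))
  cat("  ", nv, " defining variant tokens; ", length(tree_tips(x)),
      " tips\n", sep = "")
  invisible(x)
}

#' @rdname tree_queries
#' @export
tree_root <- function(tree) {
  tree$nodes$name[is.na(tree$nodes$parent)]
}

#' Reference-tree queries
#'
#' Small query helpers over a `reference_tree`: the root name, the root-to-node
#' path, node depth (root = 0), tips, and the descendant set of a node.
#'
#' @param tree a `reference_tree`.
#' @param node a node name.
#' @param include_self for `tree_descendants()`, whether `node` itself is
#'   included (default `TRUE`).
#' @return Character vectors of node names (`node_path`, `tree_tips`,
#'   `tree_descendants`) or an integer depth (`node_depth`).
#' @name tree_queries
#' @export
node_path <- function(tree, node) {
  pmap <- stats::setNames(tree$nodes$parent, tree$nodes$name)
  if (!(node %in% names(pmap))) {
    stop("unknown node '", node, "'", call. = FALSE)
  }
  path <- node
  while (!is.na(pmap[[path[1]]])) path <- c(pmap[[path[1]]], path)
  path
}

#' @rdname tree_queries
#' @export
node_depth <- function(tree, node) {
  length(node_path(tree, node)) - 1L
}

#' @rdname tree_queries
#' @export
tree_tips <- function(tree) {
  setdiff(tree$nodes$name, tree$nodes$parent)
}

#' @rdname tree_queries
#' @export
tree_descendants <- function(tree, node, include_self = TRUE) {
  if (!(node %in% tree$nodes$name)) {
    stop("unknown node '", node, "'", call. = FALSE)
  }
  kids <- split(tree$nodes$name, tree$nodes$parent)
  out <- character(0)
  frontier <- node
  while (length(frontier) > 0) {
    out <- c(out, frontier)
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  if (include_self) out else setdiff(out, node)
}

# ancestor (or equal) test used for clade collapsing
is_within_clade <- function(tree, node, ancestor) {
  ancestor %in% node_path(tree, node)
}

#' Cumulative variants of a haplogroup
#'
#' Accumulates defining variants along the root-to-node path, the way a
#' Phylotree haplotype is defined: each node's tokens are added in path order,
#' and a back-mutation token (suffix `"!"`) removes the previously gained
#' variant at its position (or, for named markers, the matching token) instead
#' of adding one.
#'
#' @param tree a `reference_tree`.
#' @param node a node name.
#' @return Character vector of variant tokens (path order, back mutations
#'   resolved).
#' @examples
#' tree <- read_reference_tree(uniparental_example("mt_tree.tsv"))
#' cumulative_variants(tree, "B4a1a1a14")
#' @export
cumulative_variants <- function(tree, node) {
  path <- node_path(tree, node)
  acc <- character(0)
  for (nd in path) {
    acc <- accumulate_tokens(acc, tree$variants[[nd]])
  }
  acc
}

# add one node's defining tokens to an accumulated set, resolving back
# mutations
accumulate_tokens <- function(acc, toks) {
  if (length(toks) == 0) return(acc)
  pv <- parse_variants(toks)
  for (i in seq_len(nrow(pv))) {
    if (pv$back[i]) {
      if (pv$kind[i] == "opaque") {
        acc <- acc[sub("!$", "", acc) != sub("!$", "", pv$token[i])]
      } else {
        keep <- is.na(variant_positions(acc)) |
          variant_positions(acc) != pv$position[i]
        acc <- acc[keep]
      }
    } else {
      acc <- c(acc, pv$token[i])
    }
  }
  acc
}

# cumulative token sets for every node in one root-to-tips sweep
all_cumulative_tokens <- function(tree) {
  kids <- split(tree$nodes$name, tree$nodes$parent)
  root <- tree_root(tree)
  acc <- vector("list", nrow(tree$nodes))
  names(acc) <- tree$nodes$name
  acc[[root]] <- accumulate_tokens(character(0), tree$variants[[root]])
  queue <- root
  while (length(queue) > 0) {
    nd <- queue[1]
    queue <- queue[-1]
    for (ch in kids[[nd]] %||% character(0)) {
      acc[[ch]] <- accumulate_tokens(acc[[nd]], tree$variants[[ch]])
      queue <- c(queue, ch)
    }
  }
  acc
}

#' Export an induced subtree as Newick
#'
#' Builds the minimal subtree of the reference phylogeny spanning a set of
#' node names, suppressing unary internal nodes that were not requested, and
#' renders it as a Newick string. With `annotate = TRUE` each retained node
#' carries the defining variant tokens of the branch above it (including any
#' suppressed intermediate nodes) as a square-bracket comment, mirroring
#' figure-style variant-labelled haplogroup trees; leave it `FALSE` for strict
#' Newick parsers.
#'
#' @param tree a `reference_tree`.
#' @param names character vector of node names to span (must be non-empty and
#'   present in the tree).
#' @param annotate logical; attach branch variant annotations.
#' @return A Newick string terminated by `";"`.
#' @examples
#' tree <- read_reference_tree(uniparental_example("mt_tree.tsv"))
#' induced_subtree_newick(tree, c("H", "B4a1a1", "B4a1a1a14"))
#' @export
induced_subtree_newick <- function(tree, names, annotate = FALSE) {
  if (length(names) == 0) stop("empty name set", call. = FALSE)
  unknown <- setdiff(names, tree$nodes$name)
  if (length(unknown) > 0) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  keep <- unique(unlist(lapply(names, function(n) node_path(tree, n))))
  kids <- split(tree$nodes$name, tree$nodes$parent)

  render <- function(nd, pending) {
    own <- c(pending, tree$variants[[nd]])
    kept_kids <- intersect(kids[[nd]] %||% character(0), keep)
    retained <- nd %in% names || length(kept_kids) >= 2
    if (!retained && length(kept_kids) == 1) {
      return(render(kept_kids, own))  # suppress unary, merge branch variants
    }
    # labels stay unquoted: characters Newick reserves are replaced
    label <- gsub("[^A-Za-z0-9_.+-]", "_", nd)
    if (annotate && length(own) > 0) {
      label <- paste0(label, "[", paste(own, collapse = ","), "]")
    }
    if (length(kept_kids) == 0) return(label)
    parts <- vapply(kept_kids, render, character(1), pending = character(0))
    paste0("(", paste(parts, collapse = ","), ")", label)
  }
  paste0(render(tree_root(tree), character(0)), ";")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to a bundled example file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
uniparental_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "uniparental")
  if (is.null(file)) list.files(dir) else file.path(dir, file)
}
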