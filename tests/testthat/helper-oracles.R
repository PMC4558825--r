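# Fixtures and independent oracles used across the suite. The oracles
# deliberately re-implement the checked quantities from scratch (own token
# parser, own scorer, own path walker) so they share no code with the package
# internals they validate.

fixture_mt_tree <- function() {
  read_reference_tree(uniparental_example("mt_tree.tsv"), "mtDNA")
}

fixture_y_tree <- function() {
  read_reference_tree(uniparental_example("y_tree.tsv"), "Y")
}

# --- random instances -------------------------------------------------------

# Random reference tree with globally unique variant positions, so every
# node's cumulative set is distinct and self-consistency is well defined.
random_reference_tree <- function(n_nodes, marker_type = "mtDNA") {
  name <- paste0("N", sprintf("%02d", seq_len(n_nodes)))
  parent <- c(NA_character_,
              vapply(seq_len(n_nodes - 1), function(i) {
                name[sample.int(i, 1)]
              }, character(1)))
  pool <- sample.int(16569, n_nodes * 3)
  used <- 0L
  bases <- c("A", "C", "G", "T")
  variants <- lapply(seq_len(n_nodes), function(i) {
    if (i == 1) return(character(0))
    k <- sample.int(3, 1)
    pos <- pool[used + seq_len(k)]
    used <<- used + k
    vapply(pos, function(p) {
      if (stats::runif(1) < 0.25) {
        as.character(p)  # bare-position token
      } else {
        paste0(sample(bases, 1), p, sample(bases, 1))
      }
    }, character(1))
  })
  names(variants) <- name
  new_reference_tree(name, parent, variants, marker_type)
}

# Random valid pedigree: parents always precede children, so acyclic by
# construction; some single-parent individuals.
random_pedigree <- function(n, n_founders = max(4, round(n / 10))) {
  sex <- sample(c("male", "female"), n, replace = TRUE)
  sex[1:2] <- c("male", "female")
  id <- sprintf("P%04d", seq_len(n))
  father <- rep(NA_character_, n)
  mother <- rep(NA_character_, n)
  origin <- rep("unknown", n)
  origin[seq_len(n_founders)] <- sample(
    c("european", "polynesian", "other", "unknown"), n_founders,
    replace = TRUE)
  males <- which(sex[seq_len(n_founders)] == "male")
  females <- which(sex[seq_len(n_founders)] == "female")
  for (i in seq.int(n_founders + 1, n)) {
    if (length(males) > 0 && stats::runif(1) > 0.15) {
      father[i] <- id[males[sample.int(length(males), 1)]]
    }
    if (length(females) > 0 && stats::runif(1) > 0.15) {
      mother[i] <- id[females[sample.int(length(females), 1)]]
    }
    if (sex[i] == "male") males <- c(males, i) else females <- c(females, i)
  }
  as_pedigree(data.frame(fam = "T", id = id, father = father, mother = mother,
                         sex = sex, origin = origin, stringsAsFactors = FALSE))
}

# --- independent scorer oracle ---------------------------------------------

# Minimal token reader independent of parse_variants().
or_token <- function(tok) {
  body <- sub("!$", "", tok)
  if (grepl("^[0-9]+$", body)) {
    list(type = "s", pos = as.numeric(body), allele = "*")
  } else if (grepl("^[ACGTNacgtn]?[0-9]+[ACGTNacgtn]$", body)) {
    list(type = "s",
         pos = as.numeric(gsub("[^0-9]", "", body)),
         allele = toupper(substr(body, nchar(body), nchar(body))))
  } else if (grepl("^[0-9]+(-[0-9]+)?[dD]$", body)) {
    rng <- as.numeric(strsplit(sub("[dD]$", "", body), "-")[[1]])
    if (length(rng) == 1) rng <- c(rng, rng)
    list(type = "d", pos = rng[1], end = rng[2])
  } else {
    list(type = "o", str = body)
  }
}

or_match_count <- function(expected, observed) {
  eo <- lapply(expected, or_token)
  oo <- lapply(observed, or_token)
  taken <- rep(FALSE, length(oo))
  m <- 0
  for (e in eo) {
    for (j in seq_along(oo)) {
      if (taken[j]) next
      o <- oo[[j]]
      hit <- if (e$type != o$type) {
        FALSE
      } else if (e$type == "s") {
        e$pos == o$pos && (e$allele == "*" || o$allele == "*" ||
                           e$allele == o$allele)
      } else if (e$type == "d") {
        e$pos == o$pos && e$end == o$end
      } else {
        e$str == o$str
      }
      if (hit) { taken[j] <- TRUE; m <- m + 1; break }
    }
  }
  m
}

or_score <- function(expected, observed) {
  m <- or_match_count(expected, observed)
  t1 <- if (length(expected) == 0) 1 else m / length(expected)
  t2 <- if (length(observed) == 0) 1 else m / length(observed)
  (t1 + t2) / 2
}

# Hand-walked cumulative set: climb parent links collecting tokens root-first,
# then resolve back mutations front to back.
or_cumulative <- function(tree, node) {
  pmap <- stats::setNames(tree$nodes$parent, tree$nodes$name)
  chain <- node
  while (!is.na(pmap[[chain[1]]])) chain <- c(pmap[[chain[1]]], chain)
  toks <- unlist(tree$variants[chain], use.names = FALSE)
  out <- character(0)
  for (tok in toks) {
    if (grepl("!$", tok)) {
      t0 <- or_token(tok)
      keep <- vapply(out, function(x) {
        x0 <- or_token(x)
        if (t0$type == "o") x0$type != "o" || x0$str != t0$str
        else is.null(x0$pos) || x0$pos != t0$pos
      }, logical(1))
      out <- out[keep]
    } else {
      out <- c(out, tok)
    }
  }
  out
}

# Exhaustive best-node search with the same declared tie-break (depth, name).
or_best_node <- function(tree, observed, mask = integer(0)) {
  drop_masked <- function(toks) {
    keep <- vapply(toks, function(tok) {
      t0 <- or_token(tok)
      is.null(t0$pos) || !(t0$pos %in% mask)
    }, logical(1))
    toks[keep]
  }
  obs <- drop_masked(observed)
  pmap <- stats::setNames(tree$nodes$parent, tree$nodes$name)
  depth_of <- function(nd) {
    d <- 0
    while (!is.na(pmap[[nd]])) { nd <- pmap[[nd]]; d <- d + 1 }
    d
  }
  nodes <- tree$nodes$name
  score <- vapply(nodes, function(nd) {
    or_score(drop_masked(or_cumulative(tree, nd)), obs)
  }, numeric(1))
  depth <- vapply(nodes, depth_of, numeric(1))
  nodes[order(-score, -depth, nodes)[1]]
}

# --- pedigree oracles -------------------------------------------------------

or_trace <- function(ped, id, line) {
  col <- if (line == "maternal") "mother" else "father"
  if (line == "paternal" && ped$sex[match(id, ped$id)] == "female") {
    return(NA_character_)
  }
  repeat {
    parent <- ped[[col]][match(id, ped$id)]
    if (is.na(parent)) return(id)
    id <- parent
  }
}

# --- induced-subtree oracle -------------------------------------------------

# Brute-force reduced parent map of the spanning subtree: the retained nodes
# are the requested names plus nodes where >= 2 retained lineages meet, and
# each retained node's reduced parent is its nearest retained proper ancestor.
or_reduced_edges <- function(tree, names) {
  pmap <- stats::setNames(tree$nodes$parent, tree$nodes$name)
  ancestors <- function(nd) {
    out <- character(0)
    while (!is.na(pmap[[nd]])) { nd <- pmap[[nd]]; out <- c(out, nd) }
    out
  }
  closure <- unique(c(names, unlist(lapply(names, ancestors))))
  n_kids <- table(unlist(lapply(closure, function(nd) {
    p <- pmap[[nd]]
    if (!is.na(p)) p else NULL
  })))
  retained <- union(names,
                    names(n_kids)[n_kids >= 2])
  edges <- NULL
  for (nd in retained) {
    anc <- ancestors(nd)
    ranc <- anc[anc %in% retained]
    if (length(ranc) > 0) {
      edges <- rbind(edges, c(parent = ranc[1], child = nd))
    }
  }
  edges
}
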