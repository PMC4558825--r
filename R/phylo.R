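#' Hamming distance matrix between variant profiles
#'
#' Pairwise distance between samples defined as the size of the symmetric
#' difference of their (masked) variant sets — the number of variants
#' private to either profile. Symmetric with a zero diagonal.
#'
#' @param profiles list of `variant_profile` objects sharing a marker type.
#' @param mask integer vector of positions to exclude.
#' @return A symmetric numeric matrix with sample ids as dimnames.
#' @export
hamming_distance_matrix <- function(profiles, mask = integer(0)) {
  if (length(profiles) < 2) stop("need at least 2 profiles", call. = FALSE)
  mt <- unique(vapply(profiles, `[[`, character(1), "marker_type"))
  if (length(mt) > 1) stop("mixed marker types", call. = FALSE)
  sets <- lapply(profiles, function(p) unique(mask_variants(p$variants, mask)))
  ids <- vapply(profiles, `[[`, character(1), "sample_id")
  n <- length(sets)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- length(setdiff(sets[[i]], sets[[j]])) +
        length(setdiff(sets[[j]], sets[[i]]))
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Agglomerative neighbor joining on a symmetric distance matrix, returning
#' an unrooted tree as a Newick string. Negative branch lengths, which NJ can
#' produce on non-additive input, are clamped to zero with a warning. The
#' two- and three-taxon cases are handled by their closed forms (for three
#' taxa, `x = (d12 + d13 - d23) / 2` and cyclic permutations).
#'
#' @param d symmetric numeric matrix with zero diagonal and labelled rows.
#' @return A Newick string.
#' @examples
#' d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' neighbor_joining(d)
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be square and symmetric", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero",
                              call. = FALSE)
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(d)))
  n <- nrow(d)
  if (n < 2) stop("need at least 2 taxa", call. = FALSE)
  if (n == 2) {
    return(sprintf("(%s:%g,%s:%g);", labs[1], d[1, 2] / 2, labs[2],
                   d[1, 2] / 2))
  }
  if (n == 3) {
    x <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    y <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    z <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    v <- clamp_negative(c(x, y, z))
    return(sprintf("(%s:%g,%s:%g,%s:%g);", labs[1], v[1], labs[2], v[2],
                   labs[3], v[3]))
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length <- clamp_negative(tr$edge.length)
  ape::write.tree(tr)
}

clamp_negative <- function(x) {
  if (any(x < 0)) {
    warning("clamping ", sum(x < 0), " negative branch length(s) to 0",
            call. = FALSE)
    x[x < 0] <- 0
  }
  x
}
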