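#' Parse variant tokens
#'
#' Parses Phylotree-style variant tokens into a structured table. The grammar
#' accepts four token classes:
#'
#' * substitutions, with or without the ancestral base: `"A1692G"`, `"1692G"`;
#' * bare positions, the shorthand used in the haplogroup literature:
#'   `"1692"` — the derived allele is a wildcard that matches any base
#'   observed at that position;
#' * deletions: `"8281-8289d"` (range) or `"3107d"` (single base);
#' * insertions: `"573.1C"` (base(s) inserted after the reference position);
#' * anything else (for example named Y-SNP labels such as `"P293"`) is kept
#'   as an opaque token matched by exact string identity.
#'
#' A trailing `"!"` marks a back mutation: when accumulating variants along a
#' root-to-node path, a back-mutation token removes the previously gained
#' variant at its position instead of adding a new one.
#'
#' @param tokens character vector of variant tokens.
#' @return A data.frame with one row per token and columns `token`, `kind`
#'   (`"substitution"`, `"deletion"`, `"insertion"` or `"opaque"`), `position`
#'   (1-based start, `NA` for opaque tokens), `end` (deletion end, otherwise
#'   equal to `position`), `ancestral`, `derived` (`"*"` for wildcards) and
#'   `back` (logical back-mutation flag).
#' @examples
#' parse_variants(c("A1692G", "1692", "8281-8289d", "573.1C", "P293", "152!"))
#' @export
parse_variants <- function(tokens) {
  tokens <- as.character(tokens)
  n <- length(tokens)
  kind <- character(n)
  position <- rep(NA_integer_, n)
  end <- rep(NA_integer_, n)
  ancestral <- rep(NA_character_, n)
  derived <- rep(NA_character_, n)
  back <- grepl("!$", tokens)
  body <- sub("!$", "", tokens)

  re_sub  <- "^([ACGTNacgtn])?([0-9]+)([ACGTNacgtn])$"
  re_bare <- "^([0-9]+)$"
  re_del  <- "^([0-9]+)(-([0-9]+))?[dD]$"
  re_ins  <- "^([0-9]+)\\.([0-9]+)([ACGTNacgtn]+)$"

  if (any(!nzchar(body))) stop("empty variant token", call. = FALSE)
  kind[] <- "opaque"
  is_sub <- grepl(re_sub, body)
  is_bare <- !is_sub & grepl(re_bare, body)
  is_del <- !is_sub & !is_bare & grepl(re_del, body)
  is_ins <- !is_sub & !is_bare & !is_del & grepl(re_ins, body)
  if (any(is_sub)) {
    kind[is_sub] <- "substitution"
    anc <- toupper(sub(re_sub, "\\1", body[is_sub]))
    ancestral[is_sub] <- ifelse(nzchar(anc), anc, NA_character_)
    position[is_sub] <- as.integer(sub(re_sub, "\\2", body[is_sub]))
    end[is_sub] <- position[is_sub]
    derived[is_sub] <- toupper(sub(re_sub, "\\3", body[is_sub]))
  }
  if (any(is_bare)) {
    kind[is_bare] <- "substitution"
    position[is_bare] <- as.integer(body[is_bare])
    end[is_bare] <- position[is_bare]
    derived[is_bare] <- "*"
  }
  if (any(is_del)) {
    kind[is_del] <- "deletion"
    position[is_del] <- as.integer(sub(re_del, "\\1", body[is_del]))
    e <- sub(re_del, "\\3", body[is_del])
    end[is_del] <- ifelse(nzchar(e), suppressWarnings(as.integer(e)),
                          position[is_del])
    if (any(end[is_del] < position[is_del])) {
      stop("deletion range end before start in token '",
           tokens[is_del][which(end[is_del] < position[is_del])[1]], "'",
           call. = FALSE)
    }
  }
  if (any(is_ins)) {
    kind[is_ins] <- "insertion"
    position[is_ins] <- as.integer(sub(re_ins, "\\1", body[is_ins]))
    end[is_ins] <- position[is_ins]
    derived[is_ins] <- toupper(sub(re_ins, "\\3", body[is_ins]))
  }
  if (any(!is.na(position) & position < 1)) {
    stop("variant position must be >= 1 in token '",
         tokens[which(!is.na(position) & position < 1)[1]], "'",
         call. = FALSE)
  }
  # built by hand: this runs once per token set in tight calling loops and
  # data.frame() overhead dominates otherwise
  structure(list(token = tokens, kind = kind, position = position, end = end,
                 ancestral = ancestral, derived = derived, back = back),
            names = c("token", "kind", "position", "end", "ancestral",
                      "derived", "back"),
            row.names = c(NA, -n), class = "data.frame")
}

#' Render parsed variants back to tokens
#'
#' The inverse of [parse_variants()]: rendering a parsed token reproduces the
#' input string exactly.
#'
#' @param vars a data.frame as returned by [parse_variants()].
#' @return character vector of tokens.
#' @export
format_variants <- function(vars) {
  vapply(seq_len(nrow(vars)), function(i) {
    v <- vars[i, ]
    body <- switch(v$kind,
      substitution = if (identical(v$derived, "*")) {
        as.character(v$position)
      } else {
        paste0(if (!is.na(v$ancestral)) v$ancestral else "", v$position,
               v$derived)
      },
      deletion = if (v$end > v$position) {
        paste0(v$position, "-", v$end, "d")
      } else {
        paste0(v$position, "d")
      },
      insertion = sub("!$", "", v$token),
      opaque = sub("!$", "", v$token)
    )
    paste0(body, if (v$back) "!" else "")
  }, character(1))
}

# Position used for back-mutation bookkeeping and masking. Opaque tokens have
# no coordinate; masks never remove them.
variant_positions <- function(tokens) {
  parse_variants(tokens)$position
}

# Drop variants whose position falls in `mask` (a vector of positions).
mask_variants <- function(tokens, mask) {
  if (length(mask) == 0 || length(tokens) == 0) return(tokens)
  pos <- variant_positions(tokens)
  tokens[is.na(pos) | !(pos %in% as.integer(mask))]
}

# |M|: number of expected variants matched one-to-one by observed variants.
# Substitutions match on position with the wildcard "*" matching any base;
# deletions match on their exact range; insertions and opaque tokens match by
# string identity. |M| <= min(|E|, |O|) by construction.
match_variant_sets <- function(expected, observed) {
  if (length(expected) == 0 || length(observed) == 0) return(0L)
  match_parsed_sets(parsed_set(expected), parsed_set(observed))
}
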