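#' mtDEL primer pair for the COII/tRNA-Lys 9-bp deletion screen
#'
#' The published forward/reverse primer pair targeting the mitochondrial
#' COII/tRNA-Lys intergenic region that contains the 9-bp (CCCCCTCTA) tandem
#' repeat. On a template carrying two repeat copies the amplicon is 133 bp;
#' loss of one copy (the Polynesian-motif deletion diagnostic of haplogroup B
#' carriers) shortens it to 124 bp.
#'
#' @return A list with elements `fwd` and `rev` (5'→3' primer sequences).
#' @export
mtdel_primers <- function() {
  list(fwd = "AGGGCCCGTATTTACCCTATAG",
       rev = "ATTTAGTTGGGGCATTTCACTG")
}

#' Locate a PCR amplicon on a template
#'
#' In-silico PCR: finds the forward primer on the plus strand and the
#' reverse complement of the reverse primer downstream of it, each with at
#' most `max_mismatch` mismatches, and returns the shortest such product.
#' Mismatches in the 3'-terminal 3 bases of either primer are disallowed
#' (polymerase extension requires a matched 3' end). Fragment length is
#' end-to-end, both primers included. mtDNA is circular; the linear search is
#' the default, and `origin_window > 0` appends that many leading bases to
#' the end of the template so origin-spanning products can be found.
#'
#' @param template a DNA sequence (character string or
#'   [Biostrings::DNAString]).
#' @param fwd_primer,rev_primer primer sequences, 5'→3'.
#' @param max_mismatch maximum mismatches per primer site (default 1).
#' @param origin_window bases of the template start to append at the end for
#'   circular templates (default 0 = linear).
#' @param max_product products longer than this are ignored when warning
#'   about multiple products (default 2000 bp).
#' @return A list of class `amplicon_result` with `fwd_start`, `rev_end`
#'   (1-based inclusive template coordinates) and `fragment_length`
#'   (`rev_end - fwd_start + 1`).
#' @examples
#' ref <- synthetic_mt_reference()
#' pr <- mtdel_primers()
#' find_amplicon(ref, pr$fwd, pr$rev)$fragment_length  # 133
#' @export
find_amplicon <- function(template, fwd_primer, rev_primer, max_mismatch = 1,
                          origin_window = 0, max_product = 2000) {
  if (!nzchar(fwd_primer) || !nzchar(rev_primer)) {
    stop("primers must be non-empty", call. = FALSE)
  }
  tmpl <- as.character(template)
  if (nchar(tmpl) < nchar(fwd_primer) + nchar(rev_primer)) {
    stop("template shorter than the combined primer lengths", call. = FALSE)
  }
  if (origin_window > 0) {
    tmpl <- paste0(tmpl, substr(tmpl, 1, origin_window))
  }
  subj <- Biostrings::DNAString(tmpl)
  fwd <- toupper(fwd_primer)
  rev_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(toupper(rev_primer))))

  hits_ok <- function(pattern, three_prime_left) {
    m <- Biostrings::matchPattern(pattern, subj, max.mismatch = max_mismatch)
    st <- Biostrings::start(m)
    en <- Biostrings::end(m)
    keep <- vapply(seq_along(st), function(i) {
      if (three_prime_left) {
        # reverse primer: its 3' end maps to the left end of the rc match
        substr(tmpl, st[i], st[i] + 2) == substr(pattern, 1, 3)
      } else {
        substr(tmpl, en[i] - 2, en[i]) ==
          substr(pattern, nchar(pattern) - 2, nchar(pattern))
      }
    }, logical(1))
    list(start = st[keep], end = en[keep])
  }
  fh <- hits_ok(fwd, three_prime_left = FALSE)
  rh <- hits_ok(rev_rc, three_prime_left = TRUE)
  if (length(fh$start) == 0 || length(rh$start) == 0) {
    stop("no amplicon: primer site not found on template", call. = FALSE)
  }
  products <- do.call(rbind, lapply(seq_along(fh$start), function(i) {
    ok <- rh$start > fh$end[i]
    if (!any(ok)) return(NULL)
    data.frame(fwd_start = fh$start[i], rev_end = rh$end[ok])
  }))
  if (is.null(products) || nrow(products) == 0) {
    stop("no amplicon: no reverse site downstream of a forward site",
         call. = FALSE)
  }
  products$fragment_length <- products$rev_end - products$fwd_start + 1
  small <- products[products$fragment_length <= max_product, , drop = FALSE]
  if (nrow(small) > 1) {
    warning("multiple products (", nrow(small), ") under ", max_product,
            " bp; reporting the shortest", call. = FALSE)
  }
  best <- products[which.min(products$fragment_length), ]
  structure(list(fwd_start = best$fwd_start, rev_end = best$rev_end,
                 fragment_length = best$fragment_length),
            class = "amplicon_result")
}

#' @export
print.amplicon_result <- function(x, ...) {
  cat(sprintf("Amplicon %d..%d (%d bp)\n", x$fwd_start, x$rev_end,
              x$fragment_length))
  invisible(x)
}

#' Classify the 9-bp deletion genotype from a fragment length
#'
#' Exact-match fragment-length interpretation of the COII/tRNA-Lys screen:
#' 133 bp means both repeat copies are present (`deletion_absent`), 124 bp
#' means one copy was lost (`deletion_present`), and any other length — or a
#' failed amplification (`NA`) — is `unknown`. Tolerance is zero; `unknown`
#' is a value, not an error.
#'
#' @param length fragment length in bp, or `NA` for no amplicon. Vectorised.
#' @return Character vector with values `"deletion_absent"`,
#'   `"deletion_present"` or `"unknown"`.
#' @examples
#' classify_9bp_genotype(c(133, 124, 130, NA))
#' @export
classify_9bp_genotype <- function(length) {
  out <- rep("unknown", base::length(length))
  out[!is.na(length) & length == 133] <- "deletion_absent"
  out[!is.na(length) & length == 124] <- "deletion_present"
  out
}

#' Run the 9-bp deletion screen over a set of templates
#'
#' @param templates a named character vector of DNA sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @param fwd_primer,rev_primer primer pair; defaults to [mtdel_primers()].
#' @param ... further arguments passed to [find_amplicon()].
#' @return A data.frame with columns `sample_id`, `fragment_length` (`NA`
#'   when no amplicon forms) and `genotype`.
#' @export
run_deletion_assay <- function(templates,
                               fwd_primer = mtdel_primers()$fwd,
                               rev_primer = mtdel_primers()$rev, ...) {
  if (is.character(templates) && length(templates) == 1 &&
      file.exists(templates)) {
    templates <- Biostrings::readDNAStringSet(templates)
  }
  ids <- names(templates)
  seqs <- as.character(templates)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  lens <- vapply(seqs, function(s) {
    tryCatch(find_amplicon(s, fwd_primer, rev_primer, ...)$fragment_length,
             error = function(e) NA_integer_)
  }, numeric(1))
  data.frame(sample_id = ids, fragment_length = as.integer(lens),
             genotype = classify_9bp_genotype(lens),
             stringsAsFactors = FALSE, row.names = NULL)
}
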