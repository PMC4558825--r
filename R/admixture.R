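#' Maternal and paternal ancestry fractions
#'
#' For an evaluation subset (by default the pedigree leaves, standing in for
#' the present-day cohort), computes the fraction of individuals whose
#' matriline founder has each population origin, and analogously the
#' paternal fractions over the subset's males. Fractions per line sum to 1
#' over the origin bins (`european`, `polynesian`, `other`, `unknown`);
#' lineages terminating in an unlabelled individual count in `unknown` and
#' are never redistributed. With no males in the subset the paternal map is
#' undefined (`NULL`), not zero.
#'
#' @param assign a `lineage_assignment` from [propagate_lineages()].
#' @param ped the `pedigree` (supplies founder origin labels).
#' @param subset ids to evaluate; default [pedigree_leaves()].
#' @return A list with `maternal` (named fractions), `paternal` (named
#'   fractions or `NULL`), `n`, `n_males`.
#' @export
ancestry_fractions <- function(assign, ped, subset = NULL) {
  if (is.null(subset)) subset <- pedigree_leaves(ped)
  if (length(subset) == 0) stop("empty evaluation subset", call. = FALSE)
  unknown <- setdiff(subset, ped$id)
  if (length(unknown) > 0) {
    stop("subset id(s) not in pedigree: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  a <- assign[match(subset, assign$id), ]
  founder_origin <- function(ids) {
    o <- ped$origin[match(ids, ped$id)]
    o[is.na(o)] <- "unknown"
    o
  }
  mat <- founder_origin(a$matriline_founder)
  maternal <- prop.table(table(mat))
  males <- !is.na(a$patriline_founder)
  paternal <- if (any(males)) {
    prop.table(table(founder_origin(a$patriline_founder[males])))
  } else {
    NULL
  }
  list(maternal = c(maternal), paternal = if (is.null(paternal)) NULL else
         c(paternal),
       n = length(subset), n_males = sum(males))
}

#' Percentile bootstrap CI for an ancestry fraction
#'
#' Resamples individuals of the evaluation subset with replacement `reps`
#' times and returns the 2.5/97.5 percentile interval of the fraction whose
#' line founder has the requested origin. Fully reproducible: the generator
#' is seeded with `seed` and each replicate draws one `sample(n, replace =
#' TRUE)`.
#'
#' @inheritParams ancestry_fractions
#' @param origin origin bin (e.g. `"polynesian"`).
#' @param line `"maternal"` or `"paternal"`.
#' @param reps number of bootstrap replicates (>= 1).
#' @param seed RNG seed (mandatory).
#' @return Numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(assign, ped, subset = NULL, origin = "polynesian",
                         line = c("maternal", "paternal"), reps = 1000,
                         seed) {
  line <- match.arg(line)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  ind <- ancestry_indicator(assign, ped, subset, origin, line)
  if (length(ind) == 0) {
    stop("no individuals with a defined ", line, " line in subset",
         call. = FALSE)
  }
  set.seed(seed)
  stats <- numeric(reps)
  n <- length(ind)
  for (r in seq_len(reps)) {
    stats[r] <- mean(ind[sample(n, replace = TRUE)])
  }
  stats::quantile(stats, c(0.025, 0.975), type = 7, names = FALSE)
}

# Per-individual 0/1 indicator: does the line founder have `origin`?
ancestry_indicator <- function(assign, ped, subset, origin, line) {
  if (is.null(subset)) subset <- pedigree_leaves(ped)
  if (length(subset) == 0) stop("empty evaluation subset", call. = FALSE)
  a <- assign[match(subset, assign$id), ]
  fid <- if (line == "maternal") a$matriline_founder else a$patriline_founder
  fid <- fid[!is.na(fid)]
  o <- ped$origin[match(fid, ped$id)]
  o[is.na(o)] <- "unknown"
  as.numeric(o == origin)
}

#' Count surviving founder lineages
#'
#' The number of distinct founder lineages of the requested line with at
#' least one member in the evaluation subset — i.e. how many founding
#' matrilines (or patrilines) persist into the present-day cohort —
#' optionally restricted to founders of a given origin.
#'
#' @inheritParams ancestry_fractions
#' @param line `"maternal"` or `"paternal"`.
#' @param origin optional origin restriction on the founders counted.
#' @return Integer count.
#' @export
lineage_survival <- function(assign, ped, subset = NULL,
                             line = c("maternal", "paternal"),
                             origin = NULL) {
  line <- match.arg(line)
  if (is.null(subset)) subset <- pedigree_leaves(ped)
  if (length(subset) == 0) stop("empty evaluation subset", call. = FALSE)
  a <- assign[match(subset, assign$id), ]
  fid <- if (line == "maternal") a$matriline_founder else a$patriline_founder
  fid <- unique(fid[!is.na(fid)])
  if (!is.null(origin)) {
    fid <- fid[ped$origin[match(fid, ped$id)] %in% origin]
  }
  length(fid)
}

#' Gender-bias index
#'
#' The signed difference between the maternal and paternal ancestry
#' fractions for one origin, in `[-1, 1]`. In a founder isolate settled by
#' men of one population and women of another, the index approaches +1 for
#' the maternal-side origin and -1 for the paternal-side one.
#'
#' @param est an `admixture_estimate` (or a list with `maternal` and
#'   `paternal` named fraction vectors).
#' @param origin origin bin.
#' @return Numeric scalar in `[-1, 1]`.
#' @export
gender_bias_index <- function(est, origin = "polynesian") {
  if (is.null(est$paternal)) {
    stop("paternal fraction undefined (no males with a defined patriline)",
         call. = FALSE)
  }
  m <- if (origin %in% names(est$maternal)) est$maternal[[origin]] else 0
  p <- if (origin %in% names(est$paternal)) est$paternal[[origin]] else 0
  m - p
}

#' Estimate gender-biased admixture from uniparental lineages
#'
#' The package's top-level estimator: combines [ancestry_fractions()],
#' per-origin percentile [bootstrap_ci()]s, [lineage_survival()] counts and
#' the [gender_bias_index()] into one classed object with `print()`,
#' `summary()` and `coef()` methods.
#'
#' @inheritParams ancestry_fractions
#' @param reps bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap (mandatory).
#' @param subset_label description of the evaluated cohort for printing.
#' @return An object of class `admixture_estimate` with elements `subset`,
#'   `maternal`, `paternal`, `ci` (list with `maternal`/`paternal` matrices
#'   of `lo`/`hi` per origin), `matriline_survivors`,
#'   `patriline_survivors`, `bias_index` (named by origin), `n`, `n_males`.
#' @examples
#' cfg <- simulation_config(seed = 7, generations = 5, max_pop = 200)
#' sim <- simulate_norfolk(cfg)
#' admixture_estimate(sim$assign, sim$ped, reps = 100, seed = 7)
#' @export
admixture_estimate <- function(assign, ped, subset = NULL, reps = 1000,
                               seed, subset_label = NULL) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(subset)) {
    subset <- pedigree_leaves(ped)
    if (is.null(subset_label)) subset_label <- "pedigree leaves"
  }
  if (is.null(subset_label)) subset_label <- "explicit id list"
  fr <- ancestry_fractions(assign, ped, subset)
  ci_for <- function(line, fracs) {
    if (is.null(fracs)) return(NULL)
    out <- sapply(names(fracs), function(o) {
      bootstrap_ci(assign, ped, subset, origin = o, line = line,
                   reps = reps, seed = seed)
    })
    rownames(out) <- c("lo", "hi")
    out
  }
  origins <- union(names(fr$maternal), names(fr$paternal))
  bias <- if (is.null(fr$paternal)) NULL else {
    stats::setNames(vapply(origins, function(o) gender_bias_index(fr, o),
                           numeric(1)), origins)
  }
  structure(list(
    subset = subset_label,
    ids = subset,
    maternal = fr$maternal,
    paternal = fr$paternal,
    ci = list(maternal = ci_for("maternal", fr$maternal),
              paternal = ci_for("paternal", fr$paternal)),
    matriline_survivors = lineage_survival(assign, ped, subset, "maternal"),
    patriline_survivors = lineage_survival(assign, ped, subset, "paternal"),
    bias_index = bias,
    n = fr$n, n_males = fr$n_males,
    reps = reps, seed = seed
  ), class = "admixture_estimate")
}

#' @export
print.admixture_estimate <- function(x, ...) {
  cat("Gender-biased admixture estimate (", x$subset, ", n = ", x$n,
      ")\n", sep = "")
  fmt_line <- function(label, fr, ci) {
    if (is.null(fr)) {
      cat("  ", label, ": undefined (no individuals with this line)\n",
          sep = "")
      return(invisible())
    }
    for (o in names(fr)) {
      cat(sprintf("  %s %-11s %5.1f%%  [%.1f%%, %.1f%%]\n", label, o,
                  100 * fr[[o]], 100 * ci["lo", o], 100 * ci["hi", o]))
    }
  }
  fmt_line("maternal", x$maternal, x$ci$maternal)
  fmt_line("paternal", x$paternal, x$ci$paternal)
  cat("  surviving matrilines: ", x$matriline_survivors,
      "; surviving patrilines: ", x$patriline_survivors, "\n", sep = "")
  if (!is.null(x$bias_index)) {
    b <- x$bias_index[which.max(abs(x$bias_index))]
    cat(sprintf("  gender-bias index (%s): %+.3f\n", names(b), b))
  }
  invisible(x)
}

#' @export
summary.admixture_estimate <- function(object, ...) {
  print(object)
  cat("  bootstrap: ", object$reps, " replicates, seed ", object$seed,
      "; males in subset: ", object$n_males, "\n", sep = "")
  invisible(object)
}

#' @export
coef.admixture_estimate <- function(object, ...) {
  out <- stats::setNames(as.numeric(object$maternal),
                         paste0("maternal.", names(object$maternal)))
  if (!is.null(object$paternal)) {
    out <- c(out, stats::setNames(as.numeric(object$paternal),
                                  paste0("paternal.", names(object$paternal))))
  }
  out
}
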