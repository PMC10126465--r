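# amino-acid alphabet accepted by the aligner; X marks unknown residues
.AA_X <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch/Gotoh global alignment with affine gap costs: a gap of
#' length L costs `gap_open + L * gap_extend`, so `gap_open = 0` gives the
#' linear-gap model.  The traceback is deterministic (ties prefer the
#' diagonal move, then the vertical, then the horizontal).
#'
#' Percent identity is the number of identical aligned residue pairs over
#' the number of aligned columns excluding terminal-gap columns (columns
#' lying before the first or after the last residue of either sequence);
#' leaving terminal gaps out of the denominator keeps length-mismatched
#' Duf421 vs 2Duf comparisons from being deflated mechanically.  Query
#' coverage is the percentage of `a`'s residues falling in non-terminal
#' columns.
#'
#' @param a query sequence (character string over the 20 amino acids plus
#'   X).
#' @param b subject sequence.
#' @param substitution a substitution matrix with residue dimnames, or the
#'   name of one shipped with Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap parameters (defaults 10 and 0.5).
#' @return a list of class `pairwise_alignment`: `score`, `aligned_a`,
#'   `aligned_b` (gapped strings), `percent_identity`, `query_coverage`,
#'   `n_columns`.
#' @export
global_align <- function(a, b, substitution = "BLOSUM62",
                         gap_open = 10, gap_extend = 0.5) {
  stopifnot(is.character(a), is.character(b), nchar(a) > 0, nchar(b) > 0)
  sub <- if (is.character(substitution) &&
             identical(substitution, "BLOSUM62")) .blosum62()
         else substitution
  stopifnot(is.matrix(sub), !is.null(rownames(sub)))

  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  bad <- setdiff(unique(c(ca, cb)), intersect(.AA_X, rownames(sub)))
  if (length(bad) > 0)
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  ia <- match(ca, rownames(sub)) - 1L
  ib <- match(cb, rownames(sub)) - 1L

  res <- .align_global(ia, ib, sub, gap_open, gap_extend)
  apos <- res$a_pos; bpos <- res$b_pos
  achr <- ifelse(apos > 0, ca[pmax(apos, 1)], "-")
  bchr <- ifelse(bpos > 0, cb[pmax(bpos, 1)], "-")

  ra <- which(apos > 0); rb <- which(bpos > 0)
  lo <- max(min(ra), min(rb)); hi <- min(max(ra), max(rb))
  if (lo <= hi) {
    core <- lo:hi
    matches <- sum(apos[core] > 0 & bpos[core] > 0 &
                     achr[core] == bchr[core])
    identity <- 100 * matches / length(core)
    coverage <- 100 * sum(apos[core] > 0) / length(ca)
  } else {
    identity <- 0; coverage <- 0
  }
  structure(list(score = res$score,
                 aligned_a = paste(achr, collapse = ""),
                 aligned_b = paste(bchr, collapse = ""),
                 percent_identity = identity,
                 query_coverage = coverage,
                 n_columns = length(apos)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment: score %.1f, identity %.1f%%, coverage %.1f%%\n",
              x$score, x$percent_identity, x$query_coverage))
  invisible(x)
}

#' Length-based Duf421-family classification
#'
#' Homologs split cleanly into two molecular-weight groups: proteins with
#' only a Duf421 domain (YetF-like) and proteins carrying both Duf421 and
#' Duf1657 domains (2Duf-like).  Default ranges cover the observed homolog
#' lengths: 210-253 residues for YetF-like and 285-290 for 2Duf-like.
#'
#' @param length residue count(s); vectorized.
#' @param ranges list with inclusive integer ranges `yetf` and `duf2`;
#'   they must not overlap.
#' @return character vector: `"YetF-like"`, `"2Duf-like"` or
#'   `"unclassified"`.
#' @export
classify_length <- function(length,
                            ranges = list(yetf = c(210, 253),
                                          duf2 = c(285, 290))) {
  stopifnot(all(length > 0))
  y <- ranges$yetf; d <- ranges$duf2
  stopifnot(length(y) == 2, length(d) == 2, y[1] <= y[2], d[1] <= d[2])
  if (y[1] <= d[2] && d[1] <= y[2])
    stop("classification length ranges overlap")
  ifelse(length >= y[1] & length <= y[2], "YetF-like",
         ifelse(length >= d[1] & length <= d[2], "2Duf-like",
                "unclassified"))
}

#' Align records to the class prototypes and classify
#'
#' For each protein: assigns the length-based class, aligns the matching
#' query prototype (YetF query for YetF-like, 2Duf query for 2Duf-like;
#' unclassified records are scored against whichever query aligns with
#' higher identity) and records the query label, percent identity and
#' query coverage.
#'
#' @param records a `data.frame` with `id`, `species`, `sequence` (and
#'   optionally `length`; recomputed if absent).
#' @param queries named character vector of query sequences; default
#'   [duf_prototypes()].
#' @param ranges passed to [classify_length()].
#' @param ... alignment parameters passed to [global_align()].
#' @return a `data.frame` of homolog calls: `id`, `species`, `length`,
#'   `class`, `query`, `percent_identity`, `query_coverage`.
#' @export
call_homologs <- function(records, queries = duf_prototypes(),
                          ranges = list(yetf = c(210, 253),
                                        duf2 = c(285, 290)), ...) {
  stopifnot(all(c("id", "species", "sequence") %in% names(records)))
  len <- if ("length" %in% names(records)) records$length
         else nchar(records$sequence)
  cls <- classify_length(len, ranges)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    q <- switch(cls[i],
                "YetF-like" = "yetf",
                "2Duf-like" = "duf2",
                NA_character_)
    if (is.na(q)) {
      al_y <- global_align(queries[["yetf"]], records$sequence[i], ...)
      al_d <- global_align(queries[["duf2"]], records$sequence[i], ...)
      if (al_y$percent_identity >= al_d$percent_identity) {
        q <- "yetf"; al <- al_y
      } else {
        q <- "duf2"; al <- al_d
      }
    } else {
      al <- global_align(queries[[q]], records$sequence[i], ...)
    }
    data.frame(id = records$id[i], species = records$species[i],
               length = len[i], class = cls[i],
               query = c(yetf = "YetF", duf2 = "2Duf")[[q]],
               percent_identity = al$percent_identity,
               query_coverage = al$query_coverage,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-species census of YetF-like and 2Duf-like homologs
#'
#' Applies the hit filter and tabulates passing calls per species and
#' class, selecting a best hit per species and query class.  When an
#' external hit table with E-values is supplied, the filter is
#' `evalue < evalue_threshold` and `coverage > coverage_threshold`
#' (defaults 1e-30 and 85); without E-values the identity/coverage
#' thresholds apply.  The best hit is the passing call with the smallest
#' (most significant) E-value - `best_hit = "literal_max"` selects the
#' numerically largest instead - or, absent E-values, the highest percent
#' identity; ties break by identity and then by id.
#'
#' @param calls a [call_homologs()] table.
#' @param hits optional `data.frame` with columns `id`, `evalue` (and
#'   optionally `coverage`, overriding the alignment coverage).
#' @param evalue_threshold,coverage_threshold,identity_threshold filter
#'   settings.
#' @param best_hit `"most_significant"` (default) or `"literal_max"`.
#' @return a list of class `homolog_census` with `calls` (the input plus
#'   `evalue` and `passes_filter`), `by_species` (a `data.frame` with
#'   `species`, `n_yetf_like`, `n_2duf_like`, `n_unclassified`),
#'   `totals` (named counts over all species) and `best_hits` (best
#'   passing call per species and query class).
#' @export
census <- function(calls, hits = NULL, evalue_threshold = 1e-30,
                   coverage_threshold = 85, identity_threshold = 20,
                   best_hit = c("most_significant", "literal_max")) {
  best_hit <- match.arg(best_hit)
  calls$evalue <- NA_real_
  if (!is.null(hits)) {
    m <- match(calls$id, hits$id)
    calls$evalue <- hits$evalue[m]
    if ("coverage" %in% names(hits)) {
      ext <- hits$coverage[m]
      calls$query_coverage <- ifelse(is.na(ext), calls$query_coverage, ext)
    }
  }
  classified <- calls$class != "unclassified"
  calls$passes_filter <- classified &
    calls$query_coverage > coverage_threshold &
    (if (is.null(hits)) calls$percent_identity >= identity_threshold
     else !is.na(calls$evalue) & calls$evalue < evalue_threshold)

  passing <- calls[calls$passes_filter, , drop = FALSE]
  species <- sort(unique(calls$species))
  by_species <- data.frame(
    species = species,
    n_yetf_like = vapply(species, function(s)
      sum(passing$species == s & passing$class == "YetF-like"), 0L),
    n_2duf_like = vapply(species, function(s)
      sum(passing$species == s & passing$class == "2Duf-like"), 0L),
    n_unclassified = vapply(species, function(s)
      sum(calls$species == s & calls$class == "unclassified"), 0L),
    stringsAsFactors = FALSE)
  rownames(by_species) <- NULL

  best_rows <- list()
  if (nrow(passing) > 0) {
    for (s in unique(passing$species)) {
      for (q in unique(passing$query[passing$species == s])) {
        sub <- passing[passing$species == s & passing$query == q, ,
                       drop = FALSE]
        if (all(!is.na(sub$evalue))) {
          key <- if (best_hit == "most_significant") sub$evalue
                 else -sub$evalue
          ord <- order(key, -sub$percent_identity, sub$id)
        } else {
          ord <- order(-sub$percent_identity, sub$id)
        }
        best_rows[[paste(s, q)]] <- sub[ord[1], , drop = FALSE]
      }
    }
  }
  best_hits <- if (length(best_rows)) do.call(rbind, best_rows) else
    passing[0, , drop = FALSE]
  rownames(best_hits) <- NULL

  structure(list(calls = calls, by_species = by_species,
                 totals = c(n_yetf_like = sum(by_species$n_yetf_like),
                            n_2duf_like = sum(by_species$n_2duf_like),
                            n_unclassified = sum(by_species$n_unclassified)),
                 best_hits = best_hits),
            class = "homolog_census")
}

#' @export
print.homolog_census <- function(x, ...) {
  cat("homolog_census:", x$totals["n_yetf_like"], "YetF-like,",
      x$totals["n_2duf_like"], "2Duf-like,",
      x$totals["n_unclassified"], "unclassified across",
      nrow(x$by_species), "species\n")
  invisible(x)
}
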