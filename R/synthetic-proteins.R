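# Synthetic reference prototypes for the two Duf421-family classes.  These
# are NOT natural sequences: they are fixed random amino-acid strings with a
# membrane-protein-like composition, built once so that identity/coverage
# arithmetic is reproducible without any external database.  The 2Duf-like
# prototype shares its first 231 residues with the YetF-like prototype at
# ~30% identity and carries a 55-residue C-terminal extension, mirroring
# the Duf421 + Duf1657 domain architecture (231 vs 286 residues).
.proto_yetf <- paste0(
  "VVDYRPHLFQVNFCLMAFPAQLLGFLQAQYVGDNKVIFIKYDKVIVNIGLSVPYFNMDFV",
  "PSRLKLEYIFTDQAGRERAMMNPFTQIAWHGTVASMRISNDHVIQWTSILRPSLIDESVI",
  "STLVLVIIFGIYWGPFIVYTVITAASGGDRTKTGRFRAHTFKGIKIKVPRADDVAESFHQ",
  "ISDTVVTMVFGRDLLLFMGEAYIAPADRILNILIGSYMAILAAGNMPLRVT")
.proto_duf2 <- paste0(
  "HERNQPSPAQVGECLMNFGGLITGALQAQSIGFNEAILIKIQIKIKMIEIGGKYAGDDGI",
  "PNMLRIEAIKTGFVDRAFAMFFELTIVAPIGITINVQISNTIIADRVNKLKLQYCGKTPK",
  "YARYWMTMAGNYELDFGIIQEASITSFGDTEITIIVLYKERKKVKPLIPFAGDASVIHLQ",
  "IFDIVKTHTGGRALKLTFDNPYVLIIVRILVIIKNMVVVISAEGNVPPRVYIMVEYGNGS",
  "LATAAVCLIYGGQSRFDNGNRVSTSMFKPDDELGGASVTMRDPFLA")

.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Synthetic Duf421-family prototype sequences
#'
#' Returns the two embedded synthetic prototypes used as alignment queries:
#' `yetf` (231 residues, Duf421 only) and `duf2` (286 residues, Duf421 +
#' Duf1657-like extension).
#'
#' @return named character vector of length 2.
#' @export
duf_prototypes <- function() c(yetf = .proto_yetf, duf2 = .proto_duf2)

#' Generate a labeled synthetic protein set
#'
#' Builds sequences in the three census classes by controlled mutation of
#' the embedded prototypes.  YetF-like sequences get lengths drawn
#' uniformly in `yetf_lengths` and the 2Duf-like in `duf2_lengths`
#' (defaults cover the observed homolog length ranges 210-253 and
#' 285-290); length changes are made by random internal deletions or
#' insertions, then point substitutions are applied so that the
#' alignment-measured identity to the prototype lands near
#' `target_identity`.  "Other" sequences are unrelated random strings with
#' lengths outside both class ranges.
#'
#' @param n_yetf_like,n_2duf_like,n_other class counts (>= 0).
#' @param target_identity requested fractional identity to the prototype
#'   for the two homolog classes (default 0.6); controlled to within about
#'   +/- 5 percentage points as measured by [global_align()].
#' @param yetf_lengths,duf2_lengths inclusive length ranges for the two
#'   classes.
#' @param seed integer RNG seed.
#' @return a `data.frame` with columns `id`, `species`, `sequence`,
#'   `length`, `true_class` (`"YetF-like"`, `"2Duf-like"` or `"other"`)
#'   and `target_identity`.
#' @export
generate_protein_set <- function(n_yetf_like, n_2duf_like, n_other,
                                 target_identity = 0.6,
                                 yetf_lengths = c(210, 253),
                                 duf2_lengths = c(285, 290),
                                 seed = 1L) {
  stopifnot(n_yetf_like >= 0, n_2duf_like >= 0, n_other >= 0,
            target_identity > 0, target_identity <= 1)
  with_seed(seed, {
    recs <- list()
    add <- function(seqs, cls) {
      k <- length(recs)
      for (j in seq_along(seqs)) {
        i <- k + j
        recs[[i]] <<- data.frame(
          id = sprintf("prot_%03d", i),
          species = sprintf("species_%03d", i),
          sequence = seqs[j],
          length = nchar(seqs[j]),
          true_class = cls,
          target_identity = if (cls == "other") NA_real_ else
            target_identity,
          stringsAsFactors = FALSE)
      }
    }
    if (n_yetf_like > 0)
      add(vapply(seq_len(n_yetf_like), function(i)
        .mutate_to(.proto_yetf, .sample_range(yetf_lengths),
                   target_identity), ""), "YetF-like")
    if (n_2duf_like > 0)
      add(vapply(seq_len(n_2duf_like), function(i)
        .mutate_to(.proto_duf2, .sample_range(duf2_lengths),
                   target_identity), ""), "2Duf-like")
    if (n_other > 0) {
      lens <- sample(c(120:200, 300:400), n_other, replace = TRUE)
      add(vapply(lens, function(L)
        paste(sample(.AA, L, replace = TRUE), collapse = ""), ""), "other")
    }
    out <- do.call(rbind, recs)
    rownames(out) <- NULL
    out
  })
}

# uniform draw from an inclusive integer range (safe for single-value ranges)
.sample_range <- function(r) r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L

# derive a sequence of length `target_len` at ~`identity` to `proto`:
# internal deletions/insertions first, then point substitutions budgeted so
# that matches / alignment-columns ~ identity under the designed alignment
.mutate_to <- function(proto, target_len, identity) {
  s <- strsplit(proto, "")[[1]]
  L <- length(s)
  d <- 0L; ins <- 0L
  if (target_len < L) {
    d <- L - target_len
    s <- s[-sort(sample(L, d))]
  } else if (target_len > L) {
    ins <- target_len - L
    for (j in seq_len(ins)) {
      p <- sample(length(s) + 1L, 1)
      s <- append(s, sample(.AA, 1), after = p - 1L)
    }
  }
  # designed alignment: columns ~ L (deletions become gap columns) or
  # L + ins (insertions add gap columns); matches = kept residues - subs
  kept <- min(L, target_len)
  cols <- if (target_len <= L) L else L + ins
  n_sub <- max(0L, round(kept - identity * cols))
  n_sub <- min(n_sub, kept)
  if (n_sub > 0) {
    idx <- sample(length(s), n_sub)
    for (i in idx) s[i] <- sample(setdiff(.AA, s[i]), 1)
  }
  paste(s, collapse = "")
}

#' Write / read protein sets as FASTA
#'
#' Record ids are written as `species|protein_id`; [read_protein_fasta()]
#' parses them back into `species` and `id` columns.
#'
#' @param proteins a protein table as from [generate_protein_set()].
#' @param path file path.
#' @return `write_protein_fasta` returns `path` invisibly;
#'   `read_protein_fasta` returns a `data.frame` with `id`, `species`,
#'   `sequence`, `length`.
#' @export
write_protein_fasta <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(proteins$sequence)
  names(seqs) <- paste(proteins$species, proteins$id, sep = "|")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_protein_fasta
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- names(seqs)
  has_species <- grepl("|", ids, fixed = TRUE)
  species <- ifelse(has_species, sub("\\|.*$", "", ids), NA_character_)
  id <- ifelse(has_species, sub("^[^|]*\\|", "", ids), ids)
  data.frame(id = id, species = species,
             sequence = as.character(seqs),
             length = Biostrings::width(seqs),
             stringsAsFactors = FALSE)
}
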