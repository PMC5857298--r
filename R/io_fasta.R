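#' Read a protein FASTA file into a record table
#'
#' Reads amino-acid sequences and derives a locus identifier from each
#' sequence identifier, so that alternative isoforms of one gene locus can be
#' grouped later by [select_primary()]. Trailing stop-codon characters (`*`)
#' are stripped before lengths are computed.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @param locus_regex Regular expression removed from the end of each
#'   `protein_id` to obtain `locus_id`. The default strips a trailing
#'   dot-separated isoform index (Phytozome-style headers, e.g.
#'   `"AT1G01010.2"` becomes `"AT1G01010"`). Identifiers without a match keep
#'   their full id as locus id. Pass `NULL` to use the identifier verbatim.
#'
#' @return A `data.frame` with columns `protein_id`, `locus_id`, `sequence`
#'   and `length` (one row per FASTA entry; `length` counts residues after
#'   `*`-stripping).
#'
#' @details Sequences may contain the 20 standard amino-acid letters plus the
#'   unknown-residue code `X`; anything else is a validation error. Entries
#'   with an empty sequence are rejected, naming the offending header.
#'
#' @seealso [select_primary()], [exclude_unknown()], [build_proteome()]
#' @export
read_fasta <- function(path, locus_regex = "\\.\\d+$") {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  seqs <- as.character(aa)
  names(seqs) <- NULL
  seqs <- gsub("\\*+$", "", toupper(seqs))
  if (any(!nzchar(seqs))) {
    bad <- ids[!nzchar(seqs)]
    stop("empty sequence for FASTA entr", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "))
  }
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX*]*$", seqs)
  if (any(!ok)) {
    stop("non-amino-acid characters in entr",
         if (sum(!ok) > 1) "ies: " else "y: ",
         paste(ids[!ok], collapse = ", "))
  }
  # internal '*' (translated internal stops) are not residues either
  if (any(grepl("\\*", seqs))) {
    stop("internal stop codon '*' in entr",
         if (sum(grepl("\\*", seqs)) > 1) "ies: " else "y: ",
         paste(ids[grepl("\\*", seqs)], collapse = ", "))
  }
  locus <- if (is.null(locus_regex)) ids else sub(locus_regex, "", ids)
  data.frame(protein_id = ids, locus_id = locus, sequence = seqs,
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write a record table back to FASTA
#'
#' @param records A record table as returned by [read_fasta()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- records$protein_id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Keep only the primary protein at each gene locus
#'
#' The primary protein of a locus is its longest isoform. When two isoforms
#' tie for maximal length the lexicographically smallest `protein_id` is kept,
#' so the selection is deterministic. The input is not modified; the number of
#' alternative isoforms removed is `nrow(records) - nrow(result)`.
#'
#' @param records A record table ([read_fasta()]).
#' @return The record table restricted to one row per `locus_id`.
#' @export
select_primary <- function(records) {
  if (nrow(records) == 0) {
    return(records)
  }
  ord <- order(records$locus_id, -records$length, records$protein_id)
  sorted <- records[ord, , drop = FALSE]
  keep <- !duplicated(sorted$locus_id)
  out <- sorted[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove proteins containing unknown residues
#'
#' Proteins with one or more `X` residues have an unknown local sequence and
#' cannot be scored for disorder; they are excluded from disorder statistics.
#'
#' @param records A record table.
#' @return A list with `records` (the X-free rows) and `n_excluded`.
#' @export
exclude_unknown <- function(records) {
  has_x <- grepl("X", records$sequence, fixed = TRUE)
  out <- records[!has_x, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, n_excluded = sum(has_x))
}

#' Assemble a proteome from a FASTA file or record table
#'
#' Applies the standard preparation order: all sequences are read, the primary
#' (longest) isoform is selected at each locus, and then proteins containing
#' unknown `X` residues are set aside. Length statistics are computed over all
#' primary proteins, while disorder statistics use only the X-free subset, so
#' both views are kept.
#'
#' @param name Proteome label (used in summaries, fingerprints and trees).
#' @param x A FASTA path or a record table from [read_fasta()].
#' @param scores Optional: a score-file path (see [read_score_file()]), the
#'   string `"proxy"` to score sequences with [proxy_scores()], or a named
#'   list of numeric vectors keyed by `protein_id`.
#' @param locus_regex Passed to [read_fasta()] when `x` is a path.
#' @param proxy_window Smoothing window for the proxy scorer.
#'
#' @return An object of class `proteome`: a list with elements
#'   \describe{
#'     \item{name}{label}
#'     \item{records}{primary, X-free record table (the disorder view)}
#'     \item{records_all}{all primary proteins, including X-containing ones
#'       (the length-statistics view)}
#'     \item{scores}{named list of per-residue disorder scores for `records`}
#'     \item{n_total_loaded, n_excluded_x, n_alternative_removed}{provenance
#'       counts; `nrow(records) == n_total_loaded - n_excluded_x -
#'       n_alternative_removed`}
#'     \item{score_source}{`"external"`, `"proxy"` or `"none"`}
#'   }
#' @export
build_proteome <- function(name, x, scores = NULL, locus_regex = "\\.\\d+$",
                           proxy_window = 21L) {
  records_raw <- if (is.character(x) && length(x) == 1) {
    read_fasta(x, locus_regex = locus_regex)
  } else {
    x
  }
  stopifnot(is.data.frame(records_raw),
            all(c("protein_id", "locus_id", "sequence", "length") %in%
                  names(records_raw)))
  if (anyDuplicated(records_raw$protein_id)) {
    stop("duplicate protein_id in proteome '", name, "'")
  }
  n_total <- nrow(records_raw)
  primary <- select_primary(records_raw)
  n_alt <- n_total - nrow(primary)
  ex <- exclude_unknown(primary)

  p <- structure(list(
    name = name,
    records = ex$records,
    records_all = primary,
    scores = NULL,
    n_total_loaded = n_total,
    n_excluded_x = ex$n_excluded,
    n_alternative_removed = n_alt,
    score_source = "none"
  ), class = "proteome")

  if (is.null(scores)) {
    return(p)
  }
  if (identical(scores, "proxy")) {
    sc <- lapply(p$records$sequence, proxy_scores, window = proxy_window)
    names(sc) <- p$records$protein_id
    p$scores <- sc
    p$score_source <- "proxy"
  } else if (is.character(scores)) {
    p <- load_scores(p, scores)
  } else {
    p <- attach_scores(p, scores)
  }
  p
}

#' @export
print.proteome <- function(x, ...) {
  cat("<proteome> ", x$name, "\n", sep = "")
  cat("  loaded: ", x$n_total_loaded,
      "  alternative isoforms removed: ", x$n_alternative_removed,
      "  X-containing excluded: ", x$n_excluded_x, "\n", sep = "")
  cat("  primary proteins: ", nrow(x$records_all),
      "  disorder view (X-free): ", nrow(x$records), "\n", sep = "")
  cat("  score source: ", x$score_source, "\n", sep = "")
  invisible(x)
}

#' Read a per-residue disorder score file
#'
#' Two plain-text dialects are accepted, covering common disorder-predictor
#' outputs:
#' \itemize{
#'   \item one protein per line: the identifier followed by whitespace- or
#'     comma-separated per-residue values;
#'   \item FASTA-like blocks: a `>id` header line followed by lines of
#'     `position score` (or bare score) pairs, one residue per line.
#' }
#'
#' @param path Score file path.
#' @return A named list of numeric vectors, one per protein.
#' @export
read_score_file <- function(path) {
  if (!file.exists(path)) {
    stop("score file not found: ", path)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(list())
  }
  if (startsWith(trimws(lines[[1]]), ">")) {
    idx <- cumsum(startsWith(trimws(lines), ">"))
    blocks <- split(lines, idx)
    out <- lapply(blocks, function(b) {
      vals <- unlist(lapply(b[-1], function(l) {
        f <- strsplit(trimws(l), "[,\\s]+", perl = TRUE)[[1]]
        # 'position score' pairs keep the last field; bare scores keep the only one
        as.numeric(f[[length(f)]])
      }))
      vals
    })
    names(out) <- vapply(blocks, function(b) sub("^>\\s*", "", trimws(b[[1]])),
                         character(1))
  } else {
    fields <- strsplit(trimws(lines), "[,\\s]+", perl = TRUE)
    out <- lapply(fields, function(f) as.numeric(f[-1]))
    names(out) <- vapply(fields, `[[`, character(1), 1L)
  }
  bad <- vapply(out, function(v) anyNA(v) || any(v < 0 | v > 1), logical(1))
  if (any(bad)) {
    stop("scores outside [0,1] (or unparseable) for: ",
         paste(names(out)[bad], collapse = ", "))
  }
  out
}

#' Attach per-residue disorder scores to a proteome
#'
#' @param proteome A `proteome`.
#' @param path Path to a score file in one of the [read_score_file()] dialects.
#' @return The proteome with `scores` filled in for every matched record.
#'   Records without a score entry remain unscored and are listed in the
#'   `unscored` attribute of the result (and reported via a message).
#' @export
load_scores <- function(proteome, path) {
  attach_scores(proteome, read_score_file(path), source = "external")
}

attach_scores <- function(proteome, score_list, source = "external") {
  stopifnot(inherits(proteome, "proteome"))
  ids <- proteome$records$protein_id
  hit <- ids[ids %in% names(score_list)]
  lens <- proteome$records$length[match(hit, ids)]
  got <- lengths(score_list[hit])
  if (any(got != lens)) {
    bad <- hit[got != lens]
    stop("score count does not match sequence length for: ",
         paste(bad, collapse = ", "))
  }
  rng_bad <- vapply(score_list[hit],
                    function(v) any(v < 0 | v > 1), logical(1))
  if (any(rng_bad)) {
    stop("scores outside [0,1] for: ", paste(hit[rng_bad], collapse = ", "))
  }
  sc <- stats::setNames(vector("list", length(ids)), ids)
  sc[hit] <- score_list[hit]
  proteome$scores <- sc
  proteome$score_source <- source
  unscored <- ids[!ids %in% hit]
  if (length(unscored) > 0) {
    message(length(unscored), " record(s) without scores in '",
            proteome$name, "'")
  }
  attr(proteome, "unscored") <- unscored
  proteome
}

#' Write per-residue scores in the one-line-per-protein dialect
#'
#' @param scores Named list of numeric vectors.
#' @param path Output path.
#' @param digits Significant digits written (text round-trip precision).
#' @return `path`, invisibly.
#' @export
write_score_file <- function(scores, path, digits = 6) {
  lines <- vapply(seq_along(scores), function(i) {
    paste(c(names(scores)[[i]],
            formatC(scores[[i]], digits = digits, format = "g")),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# scored, X-free records with their scores; errors if any record lacks scores
scored_view <- function(proteome, what = "this operation") {
  stopifnot(inherits(proteome, "proteome"))
  if (is.null(proteome$scores)) {
    stop("proteome '", proteome$name, "' carries no disorder scores; ",
         what, " needs them (see build_proteome(scores=))")
  }
  missing <- proteome$records$protein_id[
    vapply(proteome$scores[proteome$records$protein_id], is.null, logical(1))]
  if (length(missing) > 0) {
    stop("records without scores in '", proteome$name, "': ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ...")
  }
  proteome
}
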