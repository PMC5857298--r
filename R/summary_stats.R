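#' Proteome summary statistics
#'
#' One-row summary in the style of a proteome survey table: gene number and
#' length statistics are computed over *all* primary proteins (including those
#' with unknown `X` residues), whereas the two disorder percentages use only
#' the scored, X-free subset — unknown residues cannot be scored, but they do
#' have a length. The median uses the standard mid-point convention (mean of
#' the two central order statistics for even counts). The median is generally
#' preferred over the average for cross-proteome length comparison because a
#' handful of giant proteins (titin-scale) inflate the mean.
#'
#' @param proteome A scored `proteome`.
#' @return A one-row `data.frame`: `name`, `gene_number`, `ave_L`, `med_L`,
#'   `max_L`, `min_L`, `pct_idp` (percentage of proteins with
#'   `id_pep >= 0.5`), `pct_id_res` (100 times the proteome [id_res()]).
#' @export
summarize_proteome <- function(proteome) {
  stopifnot(inherits(proteome, "proteome"))
  L_all <- proteome$records_all$length
  if (length(L_all) == 0) {
    stop("summarize_proteome: empty proteome '", proteome$name, "'")
  }
  dt <- disorder_table(proteome)
  data.frame(
    name = proteome$name,
    gene_number = length(L_all),
    ave_L = mean(L_all),
    med_L = stats::median(L_all),
    max_L = max(L_all),
    min_L = min(L_all),
    pct_idp = 100 * mean(dt$is_idp),
    pct_id_res = 100 * id_res(proteome),
    stringsAsFactors = FALSE
  )
}

#' Summarize several proteomes into one table
#'
#' @param proteomes List of scored `proteome` objects.
#' @return Row-bound [summarize_proteome()] results.
#' @export
summarize_proteomes <- function(proteomes) {
  do.call(rbind, lapply(proteomes, summarize_proteome))
}

#' Correlation between ln(length) and disorder content
#'
#' Pearson and Spearman correlation coefficients between per-protein
#' `ln(L)` and `id_pep`, over the scored X-free view. The two fingerprint
#' axes are intended to be (nearly) independent attributes; these coefficients
#' quantify how far a given proteome departs from that. Spearman uses
#' mid-ranks for ties. If either variable has zero variance the correlation is
#' undefined; this is reported explicitly (`defined = FALSE`) rather than as a
#' silent `NA`.
#'
#' @param proteome A scored `proteome` (at least 3 scored proteins).
#' @return A list: `pearson`, `spearman`, `n`, `defined`, and `reason` when
#'   undefined.
#' @export
ld_correlation <- function(proteome) {
  dt <- disorder_table(scored_view(proteome, "ld_correlation"))
  if (nrow(dt) < 3) {
    stop("ld_correlation: need at least 3 scored proteins")
  }
  x <- log(dt$length)
  y <- dt$id_pep
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(pearson = NA_real_, spearman = NA_real_, n = nrow(dt),
                defined = FALSE,
                reason = if (stats::sd(x) == 0) "ln(L) has zero variance"
                         else "id_pep has zero variance"))
  }
  list(pearson = stats::cor(x, y, method = "pearson"),
       spearman = stats::cor(x, y, method = "spearman"),
       n = nrow(dt), defined = TRUE)
}

#' Correlation table over several proteomes
#'
#' @param proteomes List of scored `proteome` objects.
#' @return A `data.frame` with `name`, `n`, `pearson`, `spearman`
#'   (`NA` where undefined).
#' @export
ld_correlation_table <- function(proteomes) {
  rows <- lapply(proteomes, function(p) {
    cc <- ld_correlation(p)
    data.frame(name = p$name, n = cc$n, pearson = cc$pearson,
               spearman = cc$spearman, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a summary table as TSV
#'
#' Percentages and length averages are displayed to one decimal place;
#' underlying computations keep full precision.
#'
#' @param x A `data.frame` from [summarize_proteomes()] or
#'   [ld_correlation_table()].
#' @param path Output path.
#' @param digits Decimal places for non-integer columns.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(x, path, digits = 1) {
  out <- x
  num <- vapply(out, function(col) {
    is.numeric(col) && !all(col == round(col), na.rm = TRUE)
  }, logical(1))
  out[num] <- lapply(out[num], function(c) formatC(c, format = "f", digits = digits))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
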