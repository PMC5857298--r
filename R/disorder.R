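#' Per-residue disorder propensity scale used by the proxy scorer
#'
#' A fixed per-residue disorder propensity table in the TOP-IDP style
#' (order-promoting residues negative, disorder-promoting positive), frozen in
#' the package so that proxy scores are reproducible across versions. Proline
#' carries the maximal propensity (0.987) and tryptophan the minimal
#' (-0.884); [proxy_scores()] min-max rescales smoothed propensities to [0,1]
#' with exactly these two constants.
#'
#' @return Named numeric vector over the 20 standard amino-acid letters.
#' @export
disorder_propensity_scale <- function() {
  c(A =  0.060, C =  0.020, D =  0.192, E =  0.736, F = -0.697,
    G =  0.166, H =  0.303, I = -0.486, K =  0.586, L = -0.326,
    M = -0.397, N =  0.007, P =  0.987, Q =  0.318, R =  0.180,
    S =  0.341, T =  0.059, V = -0.121, W = -0.884, Y = -0.510)
}

#' Per-protein disorder content
#'
#' A residue is in the disordered state when its score is greater than or
#' equal to 0.5 (the threshold is inclusive). The per-protein disorder content
#' is the fraction of disordered residues, `id_pep = N_D / L`, ranging from 0
#' (fully ordered) to 1 (fully disordered). A protein is classified as an
#' intrinsically disordered protein (IDP) when `id_pep >= 0.5`.
#'
#' @param scores Numeric vector of per-residue disorder scores in [0,1].
#' @return A list with `id_pep`, `n_disordered` and `is_idp`.
#' @export
id_pep <- function(scores) {
  if (length(scores) == 0) {
    stop("id_pep: empty score vector")
  }
  if (anyNA(scores) || any(scores < 0 | scores > 1)) {
    stop("id_pep: scores must be in [0,1]")
  }
  nd <- sum(scores >= 0.5)
  frac <- nd / length(scores)
  list(id_pep = frac, n_disordered = nd, is_idp = frac >= 0.5)
}

#' Proteome-wide average disorder per residue
#'
#' The mean of the raw per-residue scores over every residue in the scored,
#' X-free view of the proteome: `sum(D_i) / X`, where `X` is the total residue
#' count. Unlike [id_pep()], no threshold is applied.
#'
#' @param proteome A scored `proteome`.
#' @return A single value in [0,1].
#' @export
id_res <- function(proteome) {
  p <- scored_view(proteome, "id_res")
  sc <- p$scores[p$records$protein_id]
  sum(vapply(sc, sum, numeric(1))) / sum(lengths(sc))
}

#' Per-protein disorder table
#'
#' @param proteome A scored `proteome`.
#' @return A `data.frame` with one row per X-free primary protein:
#'   `protein_id`, `length`, `n_disordered`, `id_pep`, `is_idp`.
#' @export
disorder_table <- function(proteome) {
  p <- scored_view(proteome, "disorder_table")
  sc <- p$scores[p$records$protein_id]
  nd <- vapply(sc, function(v) sum(v >= 0.5), numeric(1))
  frac <- nd / p$records$length
  data.frame(protein_id = p$records$protein_id,
             length = p$records$length,
             n_disordered = as.integer(nd),
             id_pep = frac,
             is_idp = frac >= 0.5,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Built-in propensity-based proxy disorder scorer
#'
#' A deterministic stand-in score source for self-contained runs: each
#' residue's propensity from [disorder_propensity_scale()] is averaged over a
#' centred sliding window (truncated at the sequence ends) and min-max
#' rescaled to [0,1] using the scale's fixed extremes. The proxy is *not* a
#' trained disorder predictor; pipelines record which score source was used so
#' proxy-based results are never mistaken for predictor output.
#'
#' @param sequence Amino-acid string over the 20 standard letters.
#' @param window Odd positive window width. A window larger than the sequence
#'   is clamped to the sequence length (this is the documented behaviour for
#'   very short proteins, not an error).
#' @return Numeric vector of per-residue scores in [0,1], one per residue.
#' @export
proxy_scores <- function(sequence, window = 21L) {
  stopifnot(length(sequence) == 1, is.character(sequence))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be an odd positive integer")
  }
  scale <- disorder_propensity_scale()
  res <- strsplit(toupper(sequence), "")[[1]]
  if (!all(res %in% names(scale))) {
    stop("proxy_scores: sequence contains non-standard residues: ",
         paste(unique(res[!res %in% names(scale)]), collapse = ""))
  }
  prop <- unname(scale[res])
  L <- length(prop)
  w <- min(window, L)
  half <- (w - 1L) %/% 2L
  # truncated centred moving average via cumulative sums
  cs <- c(0, cumsum(prop))
  lo <- pmax(seq_len(L) - half, 1L)
  hi <- pmin(seq_len(L) + half, L)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  (sm - min(scale)) / (max(scale) - min(scale))
}
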