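#' Construct an LD-space partition
#'
#' The LD space is the plane spanned by `ln(L)` (natural-log protein length)
#' and `ID` (per-protein disorder content). A partition divides it into
#' `M x N` rectangular blocks. Bins are half-open `[lo, hi)` on both axes,
#' with the final bin of each axis closed above, so every `(L, ID)` pair maps
#' to exactly one block.
#'
#' @param ln_edges Ascending numeric vector of `M+1` ln-length edges, starting
#'   at 0 and ending at `Inf`.
#' @param id_edges Ascending numeric vector of `N+1` disorder edges spanning
#'   `[0, 1]`.
#' @return An object of class `ld_partition` with `ln_edges`, `id_edges`,
#'   `M`, `N`.
#' @seealso [default_partition()] for the standard grid.
#' @export
ld_partition <- function(ln_edges, id_edges) {
  if (length(ln_edges) < 3 || length(id_edges) < 3) {
    stop("need at least 2 bins on each axis")
  }
  if (any(diff(ln_edges) <= 0) || any(diff(id_edges) <= 0)) {
    stop("bin edges must be strictly ascending")
  }
  if (ln_edges[[1]] != 0 || !is.infinite(ln_edges[[length(ln_edges)]])) {
    stop("ln edges must start at 0 and end at Inf")
  }
  if (id_edges[[1]] != 0 || id_edges[[length(id_edges)]] != 1) {
    stop("id edges must span [0, 1]")
  }
  structure(list(ln_edges = as.numeric(ln_edges),
                 id_edges = as.numeric(id_edges),
                 M = length(ln_edges) - 1L,
                 N = length(id_edges) - 1L),
            class = "ld_partition")
}

#' Default M x N partition of the LD space
#'
#' For `M = N = 10` this is the reference grid: ln-length edges
#' `0, 4.6, 4.9, 5.2, ..., 7.0, Inf` (open-ended first and last bins, interior
#' edges in steps of 0.3) and disorder edges `0, 0.1, ..., 1.0`. For other
#' `M`, the interior ln edges are spread uniformly over `[4.6, 7.0]` — the
#' natural generalization of the reference grid's uniform interior spacing —
#' and the `N` disorder bins are equal-width on `[0, 1]`.
#'
#' @param M,N Number of blocks on the ln-length and disorder axes (each >= 2).
#' @return An `ld_partition`.
#' @export
default_partition <- function(M = 10L, N = 10L) {
  M <- as.integer(M); N <- as.integer(N)
  if (M < 2L || N < 2L) {
    stop("M and N must each be at least 2")
  }
  ln_int <- if (M == 2L) 5.8 else seq(4.6, 7.0, length.out = M - 1L)
  ld_partition(c(0, ln_int, Inf), seq(0, 1, length.out = N + 1L))
}

#' @export
print.ld_partition <- function(x, ...) {
  cat("<ld_partition> ", x$M, " x ", x$N, " blocks\n", sep = "")
  cat("  ln(L) edges: ", paste(signif(x$ln_edges, 4), collapse = ", "), "\n",
      sep = "")
  cat("  ID edges:    ", paste(signif(x$id_edges, 4), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Integer length bound of an ln-length bin edge
#'
#' The smallest integer length whose natural log reaches the edge,
#' `ceiling(exp(b))`: lengths below the bound fall strictly under the edge.
#' This reproduces the printed integer bounds of the reference grid (e.g.
#' edge 4.6 -> 100, 4.9 -> 135, 7.0 -> 1097) and the display-clamping bounds
#' 4.3 -> 74 and 7.3 -> 1481.
#'
#' @param b ln-length edge value(s).
#' @return Integer bound(s).
#' @export
length_bound <- function(b) {
  as.integer(ceiling(exp(b)))
}

#' Map proteins to LD-space blocks
#'
#' Block `i` on the ln axis is the unique bin with
#' `ln_edges[i] <= ln(L) < ln_edges[i+1]`; likewise `j` for `id_pep`, with the
#' top disorder bin closed at 1.0. Vectorized over proteins.
#'
#' @param L Positive integer length(s).
#' @param id Disorder content(s) in [0,1].
#' @param partition An `ld_partition`.
#' @return A two-column integer matrix of block indices `(i, j)`.
#' @export
bin_protein <- function(L, id, partition) {
  stopifnot(inherits(partition, "ld_partition"))
  if (any(L < 1) || any(id < 0 | id > 1)) {
    stop("bin_protein: need L >= 1 and id in [0,1]")
  }
  i <- findInterval(log(L), partition$ln_edges)        # [lo, hi) by default
  j <- pmin(findInterval(id, partition$id_edges), partition$N)  # 1.0 closed
  cbind(i = i, j = j)
}

#' Compute a proteome fingerprint
#'
#' Bins every protein of the scored, X-free view into the partition and
#' normalizes the block counts by the total: `X_ij = n_ij / n_tot`. The
#' density grid sums to 1 by construction and is the proteome's fingerprint
#' in LD space.
#'
#' @param proteome A scored `proteome`, or a `data.frame` with columns
#'   `length` and `id_pep` (e.g. a [disorder_table()]).
#' @param partition An `ld_partition` (default 10 x 10).
#' @param name Label override (defaults to the proteome's name).
#' @return An object of class `ld_fingerprint`: `name`, `partition`,
#'   `counts` (M x N integer), `density` (M x N, sums to 1), `n_tot`.
#' @export
compute_fingerprint <- function(proteome, partition = default_partition(),
                                name = NULL) {
  if (inherits(proteome, "proteome")) {
    dt <- disorder_table(proteome)
    if (is.null(name)) name <- proteome$name
  } else {
    dt <- proteome
    stopifnot(all(c("length", "id_pep") %in% names(dt)))
    if (is.null(name)) name <- "fingerprint"
  }
  if (nrow(dt) == 0) {
    stop("compute_fingerprint: no scored proteins to bin")
  }
  ij <- bin_protein(dt$length, dt$id_pep, partition)
  counts <- matrix(0L, partition$M, partition$N)
  tab <- tabulate((ij[, "j"] - 1L) * partition$M + ij[, "i"],
                  nbins = partition$M * partition$N)
  counts[] <- tab
  n_tot <- nrow(dt)
  structure(list(name = name, partition = partition, counts = counts,
                 density = counts / n_tot, n_tot = n_tot),
            class = "ld_fingerprint")
}

#' @export
print.ld_fingerprint <- function(x, ...) {
  cat("<ld_fingerprint> ", x$name, ": ", x$partition$M, " x ", x$partition$N,
      " blocks over ", x$n_tot, " proteins\n", sep = "")
  invisible(x)
}

same_partition <- function(a, b, tol = 1e-9) {
  a$M == b$M && a$N == b$N &&
    all(abs(a$ln_edges - b$ln_edges) < tol | (is.infinite(a$ln_edges) &
                                                is.infinite(b$ln_edges))) &&
    all(abs(a$id_edges - b$id_edges) < tol)
}

#' Differential fingerprint
#'
#' Cell-wise density difference `a - b` between two fingerprints on the same
#' partition; positive cells mark LD-space regions where proteome `a` is
#' enriched relative to `b`. The grid sums to 0 (both inputs are normalized).
#'
#' @param a,b `ld_fingerprint` objects sharing a partition.
#' @return An M x N numeric matrix with attributes `partition` and `names`.
#' @export
fingerprint_differential <- function(a, b) {
  stopifnot(inherits(a, "ld_fingerprint"), inherits(b, "ld_fingerprint"))
  if (!same_partition(a$partition, b$partition)) {
    stop("fingerprints use different partitions")
  }
  d <- a$density - b$density
  attr(d, "partition") <- a$partition
  attr(d, "names_ab") <- c(a$name, b$name)
  d
}

#' Count proteins in a joint length/disorder category
#'
#' Counts proteins of the scored X-free view satisfying both a length
#' predicate and a disorder predicate — e.g. "short" (`L < 100`, i.e.
#' `ln(L) < 4.6`) and "disordered". Two disorder conventions are in use for
#' such category counts: the strict `id_pep > 0.5` (used when contrasting
#' short/long disordered protein counts between proteomes) and the inclusive
#' `id_pep >= 0.5` IDP classification; pass the one you mean.
#'
#' @param proteome A scored `proteome`.
#' @param l_rule Function of the length vector returning a logical vector.
#' @param d_rule Function of the `id_pep` vector returning a logical vector.
#' @return Integer count.
#' @examples
#' \dontrun{
#' count_category(p, l_rule = function(L) L < 100,
#'                   d_rule = function(id) id > 0.5)   # short disordered
#' }
#' @export
count_category <- function(proteome, l_rule, d_rule) {
  dt <- disorder_table(proteome)
  sum(l_rule(dt$length) & d_rule(dt$id_pep))
}

#' Serialize a fingerprint (or differential grid) as annotated TSV
#'
#' A `#`-prefixed header block records the label, the total protein count and
#' the bin edges; the body is the M x N density matrix (rows = ln-length
#' bins, columns = disorder bins).
#'
#' @param x An `ld_fingerprint` or a differential grid from
#'   [fingerprint_differential()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint_tsv <- function(x, path) {
  if (inherits(x, "ld_fingerprint")) {
    part <- x$partition
    header <- c(paste0("# fingerprint\t", x$name),
                paste0("# n_tot\t", x$n_tot))
    mat <- x$density
  } else {
    part <- attr(x, "partition")
    nm <- attr(x, "names_ab")
    header <- paste0("# differential\t", nm[[1]], "\t", nm[[2]])
    mat <- unclass(x)
    attributes(mat) <- list(dim = dim(x))
  }
  header <- c(header,
              paste0("# ln_edges\t", paste(part$ln_edges, collapse = "\t")),
              paste0("# id_edges\t", paste(part$id_edges, collapse = "\t")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(mat, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
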