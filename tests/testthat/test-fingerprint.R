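test_that("the default 10x10 partition reproduces the reference grid", {
  part <- default_partition(10, 10)
  expect_equal(part$ln_edges,
               c(0, 4.6, 4.9, 5.2, 5.5, 5.8, 6.1, 6.4, 6.7, 7.0, Inf))
  expect_equal(part$id_edges, seq(0, 1, by = 0.1))
  expect_equal(part$M, 10L)
  expect_equal(part$N, 10L)

  # N = 2 halves the disorder axis
  expect_equal(default_partition(10, 2)$id_edges, c(0, 0.5, 1))
  expect_error(default_partition(1, 10), "at least 2")
  expect_error(ld_partition(c(0, 5, 4, Inf), c(0, 0.5, 1)), "ascending")
  expect_error(ld_partition(c(1, 5, Inf), c(0, 0.5, 1)), "start at 0")
})

test_that("integer length bounds follow the smallest-integer-at-least-exp(b) rule", {
  # independent oracle: linear search for the smallest integer whose ln
  # reaches the edge
  oracle <- function(b) {
    n <- 1L
    while (log(n) < b) n <- n + 1L
    n
  }
  edges <- c(4.3, 4.6, 4.9, 7.0, 7.3)
  expect_equal(length_bound(edges), vapply(edges, oracle, integer(1)))
  # the printed bounds these edges correspond to
  expect_equal(length_bound(edges), c(74L, 100L, 135L, 1097L, 1481L))
})

test_that("bin_protein places boundary cases in the right half-open bins", {
  part <- default_partition(10, 10)
  # ln(100) = 4.605 >= 4.6: second length bin
  expect_equal(unname(bin_protein(100, 0.05, part)[1, ]), c(2L, 1L))
  # ln(99) < 4.6: first (open-ended) bin
  expect_equal(unname(bin_protein(99, 0.05, part)[1, ]), c(1L, 1L))
  # top disorder edge is closed
  expect_equal(unname(bin_protein(100, 1.0, part)[1, "j"]), 10L)
  expect_equal(unname(bin_protein(100, 0.1, part)[1, "j"]), 2L)  # [0.1, 0.2)
  # giant protein lands in the open-ended last length bin
  expect_equal(unname(bin_protein(34350, 0.5, part)[1, "i"]), 10L)
  expect_error(bin_protein(0, 0.5, part), "L >= 1")
})

test_that("binning partitions the LD space: every point in exactly one block", {
  part <- default_partition(10, 10)
  # dense lattice over lengths and disorder values, including the edges
  L <- rep(c(1:5, seq(6, 2000, by = 7), 50000), times = 21)
  id <- rep(seq(0, 1, by = 0.05), each = length(L) / 21)
  ij <- bin_protein(L, id, part)
  expect_true(all(ij[, "i"] >= 1 & ij[, "i"] <= 10))
  expect_true(all(ij[, "j"] >= 1 & ij[, "j"] <= 10))
  # occupancies are exhaustive: block totals sum to the number of points
  counts <- table(factor(ij[, "i"], 1:10), factor(ij[, "j"], 1:10))
  expect_equal(sum(counts), length(L))
})

test_that("grid totals match a brute-force per-protein double-loop binner", {
  set.seed(41)
  n <- 10000
  L <- sample(5:3000, n, replace = TRUE)
  id <- runif(n)
  part <- default_partition(10, 10)
  fp <- compute_fingerprint(data.frame(length = L, id_pep = id), part)

  oracle <- matrix(0L, 10, 10)
  lnL <- log(L)
  for (k in seq_len(n)) {
    i <- 10L; j <- 10L
    for (b in 1:10) {
      if (lnL[k] >= part$ln_edges[b] && lnL[k] < part$ln_edges[b + 1]) i <- b
      if (id[k] >= part$id_edges[b] &&
          (id[k] < part$id_edges[b + 1] || b == 10)) j <- b
    }
    oracle[i, j] <- oracle[i, j] + 1L
  }
  expect_equal(fp$counts, oracle)
  expect_equal(fp$density, oracle / n)
  expect_equal(fp$n_tot, n)
})

test_that("fingerprints are normalized and order-invariant", {
  # single protein: all mass in one block
  fp1 <- compute_fingerprint(data.frame(length = 150L, id_pep = 0.25))
  expect_equal(sum(fp1$density), 1)
  expect_equal(fp1$density[3, 3], 1)       # ln(150)=5.01 in [4.9,5.2); id bin 3

  set.seed(43)
  dt <- data.frame(length = sample(10:2000, 500, TRUE), id_pep = runif(500))
  a <- compute_fingerprint(dt)
  b <- compute_fingerprint(dt[sample(nrow(dt)), ])
  expect_equal(a$density, b$density)
  expect_equal(abs(sum(a$density) - 1) < 1e-12, TRUE)
})

test_that("a merged proteome's fingerprint is the count-weighted mixture", {
  set.seed(47)
  for (rep in 1:10) {
    na <- sample(50:400, 1); nb <- sample(50:400, 1)
    da <- data.frame(length = sample(10:2000, na, TRUE), id_pep = runif(na))
    db <- data.frame(length = sample(10:2000, nb, TRUE), id_pep = runif(nb))
    fa <- compute_fingerprint(da); fb <- compute_fingerprint(db)
    fm <- compute_fingerprint(rbind(da, db))
    expect_equal(fm$density,
                 (na * fa$density + nb * fb$density) / (na + nb),
                 tolerance = 1e-12)
  }
})

test_that("nested coarsening: summing sibling blocks equals direct computation", {
  fine <- ld_partition(c(0, 4.6, 5.2, 5.8, 6.4, 7.0, Inf),
                       seq(0, 1, by = 0.25))
  coarse <- ld_partition(c(0, 5.2, 6.4, Inf), c(0, 0.5, 1))  # every other edge
  set.seed(53)
  dt <- data.frame(length = sample(5:3000, 2000, TRUE), id_pep = runif(2000))
  ff <- compute_fingerprint(dt, fine)
  fc <- compute_fingerprint(dt, coarse)
  agg <- matrix(0, 3, 2)
  for (i in 1:3) for (j in 1:2) {
    agg[i, j] <- sum(ff$density[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  }
  expect_equal(fc$density, agg, tolerance = 1e-12)
})

test_that("differential grids subtract cell-wise and sum to zero", {
  set.seed(59)
  a <- random_fingerprint("a")
  b <- random_fingerprint("b")
  d <- fingerprint_differential(a, b)
  expect_equal(unclass(d)[seq_along(d)], (a$density - b$density)[seq_along(d)])
  expect_lt(abs(sum(d)), 1e-12)
  # self-difference and antisymmetry
  expect_true(all(fingerprint_differential(a, a) == 0))
  expect_equal(unclass(fingerprint_differential(b, a))[seq_len(100)],
               -unclass(d)[seq_len(100)])
  # partition mismatch
  c5 <- random_fingerprint("c", default_partition(5, 5))
  expect_error(fingerprint_differential(a, c5), "partition")
})

test_that("a planted density shift appears only where constructed", {
  part <- default_partition(10, 10)
  base <- data.frame(length = rep(c(120L, 400L), each = 100),
                     id_pep = rep(c(0.15, 0.65), each = 100))
  shifted <- base
  shifted$id_pep[1:20] <- 0.95               # move 20 proteins to block (2,10)
  d <- fingerprint_differential(compute_fingerprint(shifted, part),
                                compute_fingerprint(base, part))
  expect_equal(d[2, 10], 0.1)
  expect_equal(d[2, 2], -0.1)
  expect_equal(sum(d != 0), 2)
})

test_that("count_category supports both disorder threshold conventions", {
  p <- proteome_from_truth(rep(50L, 10), rep(0.9, 10))
  short <- function(L) L < 100
  expect_equal(count_category(p, short, function(id) id > 0.5), 10)

  # proteins at exactly 0.5 disorder: counted by >=, not by >
  q <- proteome_from_truth(rep(50L, 4), rep(0.5, 4))
  expect_equal(count_category(q, short, function(id) id >= 0.5), 4)
  expect_equal(count_category(q, short, function(id) id > 0.5), 0)

  # planted short-disordered count recovered exactly
  set.seed(61)
  n_sd <- 37
  L <- c(sample(10:99, n_sd, TRUE), sample(150:900, 200, TRUE))
  ids <- c(runif(n_sd, 0.6, 0.9), runif(200, 0, 0.45))
  r <- proteome_from_truth(L, ids)
  expect_equal(count_category(r, short, function(id) id > 0.5), n_sd)
})

test_that("fingerprint TSV serialization records edges and densities", {
  set.seed(67)
  fp <- random_fingerprint("ser")
  path <- tempfile(fileext = ".tsv")
  write_fingerprint_tsv(fp, path)
  lines <- readLines(path)
  expect_match(lines[1], "ser")
  expect_match(lines[3], "4.6")
  body <- read.delim(path, comment.char = "#", header = FALSE)
  expect_equal(as.matrix(body), fp$density, ignore_attr = TRUE,
               tolerance = 1e-10)
})
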