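test_that("fingerprint distance has its analytic values and oracle agreement", {
  part <- default_partition(10, 10)
  a <- fp_from_counts(matrix(c(100L, rep(0L, 99)), 10, 10), part, "a")
  b <- fp_from_counts(matrix(c(0L, 50L, rep(0L, 98)), 10, 10), part, "b")
  expect_equal(fingerprint_distance(a, a), 0)
  # disjointly supported unit masses: the sqrt(2) maximum
  expect_equal(fingerprint_distance(a, b), sqrt(2))

  set.seed(71)
  for (rep in 1:20) {
    x <- random_fingerprint("x"); y <- random_fingerprint("y")
    acc <- 0
    for (i in 1:10) for (j in 1:10) {
      acc <- acc + (x$density[i, j] - y$density[i, j])^2
    }
    expect_equal(fingerprint_distance(x, y), sqrt(acc), tolerance = 1e-12)
  }

  c5 <- random_fingerprint("c", default_partition(5, 5))
  expect_error(fingerprint_distance(a, c5), "partition")
})

test_that("the fingerprint distance is a bounded metric on random triples", {
  set.seed(73)
  for (rep in 1:50) {
    f <- lapply(c("a", "b", "c"), random_fingerprint)
    dab <- fingerprint_distance(f[[1]], f[[2]])
    dba <- fingerprint_distance(f[[2]], f[[1]])
    dac <- fingerprint_distance(f[[1]], f[[3]])
    dbc <- fingerprint_distance(f[[2]], f[[3]])
    expect_identical(dab, dba)
    expect_gte(dab, 0)
    expect_lte(dab, sqrt(2) + 1e-12)
    expect_lte(dac, dab + dbc + 1e-12)
  }
})

test_that("distance matrices satisfy their invariants", {
  set.seed(79)
  fps <- lapply(letters[1:8], random_fingerprint)
  dm <- fingerprint_distance_matrix(fps)
  expect_equal(rownames(dm), letters[1:8])
  expect_equal(unclass(dm), t(unclass(dm)), ignore_attr = TRUE)
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm >= 0 & dm <= sqrt(2)))
  # element-wise pairwise oracle
  for (i in 1:8) for (j in 1:8) {
    expect_equal(dm[i, j], fingerprint_distance(fps[[i]], fps[[j]]))
  }
  expect_error(fingerprint_distance_matrix(fps[c(1, 1)]), "duplicate")
  expect_error(fingerprint_distance_matrix(fps[1]), "at least 2")
})

test_that("three taxa give the closed-form star tree", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  # closed form: v_a = (d_ab + d_ac - d_bc)/2 etc.
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
})

test_that("NJ recovers a 4-taxon additive tree exactly, with branch lengths", {
  # known tree: ((a:1, b:2):1.5, c:0.7, d:1.2)
  true <- ape::read.tree(text = "((a:1,b:2):1.5,c:0.7,d:1.2);")
  d <- ape::cophenetic.phylo(true)
  tr <- nj_tree(d)
  expect_equal(phangorn::RF.dist(ape::unroot(true), ape::unroot(tr)), 0)
  # additive input: branch length multiset is recovered
  expect_equal(sort(tr$edge.length), sort(true$edge.length), tolerance = 1e-9)
})

test_that("NJ recovers random additive topologies and matches a reference NJ", {
  set.seed(83)
  for (rep in 1:25) {
    ntax <- sample(6:12, 1)
    true <- ape::rtree(ntax, rooted = FALSE,
                       br = function(n) runif(n, 0.05, 1))
    d <- ape::cophenetic.phylo(true)
    tr <- nj_tree(d)
    expect_equal(phangorn::RF.dist(tr, true), 0)
  }

  # noisy fingerprint-derived matrices: topology identical to ape::nj
  for (rep in 1:10) {
    fps <- lapply(letters[1:7], random_fingerprint)
    dm <- fingerprint_distance_matrix(fps)
    expect_equal(phangorn::RF.dist(nj_tree(dm), ape::nj(as.dist(dm))), 0)
  }
})

test_that("NJ output is deterministic and free of negative branch lengths", {
  set.seed(89)
  fps <- lapply(letters[1:9], random_fingerprint)
  dm <- fingerprint_distance_matrix(fps)
  f1 <- tempfile(); f2 <- tempfile()
  write_newick(nj_tree(dm), f1)
  write_newick(nj_tree(dm), f2)
  expect_identical(readLines(f1), readLines(f2))

  for (rep in 1:20) {
    n <- sample(5:10, 1)
    # strongly non-additive random matrices exercise the clamping path
    m <- matrix(runif(n * n, 0.01, 1), n, n)
    m <- m + t(m); diag(m) <- 0
    rownames(m) <- colnames(m) <- paste0("t", 1:n)
    tr <- nj_tree(m)
    expect_true(all(tr$edge.length >= 0))
    expect_setequal(tr$tip.label, rownames(m))
  }

  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
  bad <- unclass(dm); bad[1, 2] <- bad[2, 1] <- NaN
  expect_error(nj_tree(bad), "non-finite")
})

test_that("tie-breaking joins the lexicographically smallest label pair", {
  # four equidistant taxa: every Q is tied; the a-b pair must be joined first,
  # making {a,b} (equivalently {c,d}) a clade of the result
  d <- matrix(1, 4, 4); diag(d) <- 0
  rownames(d) <- colnames(d) <- c("d", "c", "b", "a")  # scrambled order
  tr <- nj_tree(d)
  expect_true(clade_check(tr, c("a", "b")))
})

test_that("clade_check detects exactly the bipartitions of the tree", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  expect_true(clade_check(tr, c("a", "b")))
  expect_true(clade_check(tr, c("c", "d")))
  expect_false(clade_check(tr, c("a", "c")))
  expect_true(clade_check(tr, c("a", "b", "e")))   # complement of {c,d}
  expect_true(clade_check(tr, "a"))                # pendant edge
  expect_error(clade_check(tr, c("a", "b", "c", "d", "e")), "proper")
  expect_error(clade_check(tr, character(0)), "proper")
  expect_error(clade_check(tr, c("a", "zz")), "absent")
})

test_that("well-separated fingerprint mixtures form clades end-to-end", {
  set.seed(97)
  part <- default_partition(10, 10)
  make_group <- function(prefix, base_block) {
    lapply(1:4, function(k) {
      w <- matrix(0.01, 10, 10)
      w[base_block[1], base_block[2]] <- 5    # group-specific density peak
      counts <- matrix(as.integer(rmultinom(1, 800, w)), 10, 10)
      fp_from_counts(counts, part, paste0(prefix, k))
    })
  }
  fps <- c(make_group("left", c(2, 8)), make_group("right", c(8, 2)))
  tr <- nj_tree(fingerprint_distance_matrix(fps))
  expect_true(clade_check(tr, paste0("left", 1:4)))
  expect_true(clade_check(tr, paste0("right", 1:4)))
})

test_that("distance matrices serialize to PHYLIP and TSV", {
  set.seed(101)
  dm <- fingerprint_distance_matrix(lapply(c("aa", "bb", "cc"),
                                           random_fingerprint))
  phy <- tempfile(); tsv <- tempfile()
  write_phylip(dm, phy)
  lines <- readLines(phy)
  expect_equal(as.integer(trimws(lines[1])), 3)
  expect_equal(length(lines), 4)
  write_distance_tsv(dm, tsv)
  back <- read.delim(tsv)
  expect_equal(as.matrix(back[, -1]), unclass(dm), ignore_attr = TRUE,
               tolerance = 1e-9)
})
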