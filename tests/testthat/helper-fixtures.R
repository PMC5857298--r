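# shared fixture builders and independent oracles

# build an ld_fingerprint directly from a count grid (bypasses binning so the
# distance/metric tests do not depend on the binner under test)
fp_from_counts <- function(counts, partition = default_partition(), name = "fp") {
  structure(list(name = name, partition = partition,
                 counts = counts, density = counts / sum(counts),
                 n_tot = sum(counts)),
            class = "ld_fingerprint")
}

random_fingerprint <- function(name = "fp", partition = default_partition(),
                               n_tot = 500) {
  w <- stats::runif(partition$M * partition$N)^3  # sparse-ish support
  counts <- matrix(as.integer(stats::rmultinom(1, n_tot, w)),
                   partition$M, partition$N)
  fp_from_counts(counts, partition, name)
}

# minimal independent FASTA parser (line-by-line state machine)
naive_fasta_parse <- function(path) {
  lines <- readLines(path)
  ids <- character(0); seqs <- character(0); cur <- NULL
  for (l in lines) {
    if (startsWith(l, ">")) {
      ids <- c(ids, sub("\\s.*$", "", sub("^>", "", l)))
      seqs <- c(seqs, ""); cur <- length(seqs)
    } else if (!is.null(cur)) {
      seqs[cur] <- paste0(seqs[cur], gsub("\\s", "", l))
    }
  }
  list(id = ids, seq = gsub("\\*+$", "", toupper(seqs)))
}

write_tiny_fasta <- function(seqs, path = withr::local_tempfile(fileext = ".fa",
                                                .local_envir = parent.frame())) {
  lines <- unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]])))
  writeLines(as.character(lines %||% character(0)), path)
  path
}

# proteome straight from (length, id_pep) pairs, with planted block scores
proteome_from_truth <- function(lengths, ids, name = "truth") {
  nd <- as.integer(round(ids * lengths))
  pid <- sprintf("%s_g%04d.1", name, seq_along(lengths))
  recs <- data.frame(protein_id = pid, locus_id = sub("\\.1$", "", pid),
                     sequence = vapply(lengths, function(L)
                       paste(rep("A", L), collapse = ""), character(1)),
                     length = as.integer(lengths), stringsAsFactors = FALSE)
  sc <- lapply(seq_along(lengths), function(i)
    rep(c(0.9, 0.1), c(nd[[i]], lengths[[i]] - nd[[i]])))
  names(sc) <- pid
  p <- build_proteome(name, recs)
  attach_scores(p, sc, source = "planted")
}

two_group_specs <- function(seed_base, n = 1000L) {
  c(lapply(1:4, function(i)
      synth_preset("eukaryote", paste0("euk", i), seed = seed_base + i,
                   n_proteins = n)),
    lapply(1:4, function(i)
      synth_preset("prokaryote", paste0("prok", i), seed = seed_base + 50 + i,
                   n_proteins = n)))
}
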