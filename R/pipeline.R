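#' Read a run configuration
#'
#' A single declarative YAML file names the proteomes and fixes every
#' convention the method leaves open, so a run is fully described by its
#' config:
#'
#' ```yaml
#' proteomes:
#'   - name: human_like
#'     fasta: human_like.fasta
#'     scores: human_like.scores     # a score file, or "proxy"
#' M: 10
#' N: 10
#' # optional explicit partition override:
#' # ln_edges: [0, 4.6, ..., .inf]
#' # id_edges: [0, 0.1, ..., 1]
#' id_threshold_convention: ge       # "ge" (IDP: id >= 0.5) or "gt"
#' out_dir: results
#' seed: 1
#' ```
#'
#' @param path YAML file path. Relative fasta/score paths are resolved
#'   against the config file's directory.
#' @return A validated config list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (i in seq_along(cfg$proteomes)) {
    for (f in c("fasta", "scores")) {
      v <- cfg$proteomes[[i]][[f]]
      if (!is.null(v) && !identical(v, "proxy") && !file.exists(v)) {
        cfg$proteomes[[i]][[f]] <- file.path(base, v)
      }
    }
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$proteomes) || length(cfg$proteomes) < 1) {
    stop("config: at least one proteome entry is required")
  }
  nms <- vapply(cfg$proteomes, function(p) p$name, character(1))
  if (anyDuplicated(nms)) {
    stop("config: duplicate proteome names")
  }
  cfg$M <- if (is.null(cfg$M)) 10L else as.integer(cfg$M)
  cfg$N <- if (is.null(cfg$N)) 10L else as.integer(cfg$N)
  if (cfg$M < 2 || cfg$N < 2) {
    stop("config: M and N must each be at least 2")
  }
  cfg$id_threshold_convention <-
    match.arg(cfg$id_threshold_convention %||% "ge", c("ge", "gt"))
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  cfg$out_dir <- cfg$out_dir %||% "ldspace_out"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_partition <- function(cfg) {
  if (!is.null(cfg$ln_edges) || !is.null(cfg$id_edges)) {
    dflt <- default_partition(cfg$M, cfg$N)
    ld_partition(as.numeric(cfg$ln_edges %||% dflt$ln_edges),
                 as.numeric(cfg$id_edges %||% dflt$id_edges))
  } else {
    default_partition(cfg$M, cfg$N)
  }
}

#' Run the full fingerprint-to-phylogeny workflow
#'
#' Executes the standard flow: load and prepare each proteome (primary-isoform
#' selection, X exclusion, disorder scores) -> per-proteome summaries ->
#' fingerprints on the configured partition -> length-disorder correlation
#' table -> pairwise distance matrix -> neighbor-joining tree; plus a
#' machine-readable run log capturing the package version, seed and every
#' active convention. With a single proteome the distance and tree stages are
#' skipped with a notice. Reruns of the same config are byte-identical.
#'
#' @param config A config list ([read_run_config()]) or a YAML path.
#' @param out_dir Output directory override.
#' @return Invisibly, a list with the in-memory `proteomes`, `summaries`,
#'   `correlations`, `fingerprints`, `distance`, `tree` and the written
#'   `files`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  out <- out_dir %||% cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "fingerprints"), showWarnings = FALSE)

  stage <- "load"
  result <- tryCatch({
    proteomes <- lapply(cfg$proteomes, function(p) {
      build_proteome(p$name, p$fasta, scores = p$scores %||% "proxy",
                     locus_regex = cfg$locus_regex %||% "\\.\\d+$")
    })
    names(proteomes) <- vapply(proteomes, function(p) p$name, character(1))

    stage <- "summaries"
    summaries <- summarize_proteomes(proteomes)
    write_summary_tsv(summaries, file.path(out, "summary.tsv"))

    stage <- "fingerprints"
    part <- config_partition(cfg)
    fps <- lapply(proteomes, compute_fingerprint, partition = part)
    for (f in fps) {
      write_fingerprint_tsv(f, file.path(out, "fingerprints",
                                         paste0(f$name, ".tsv")))
    }

    stage <- "correlations"
    cc <- ld_correlation_table(proteomes)
    write_summary_tsv(cc, file.path(out, "correlations.tsv"), digits = 4)

    dmat <- NULL; tree <- NULL
    if (length(fps) >= 2) {
      stage <- "distance"
      dmat <- fingerprint_distance_matrix(fps)
      write_phylip(dmat, file.path(out, "distance.phy"))
      write_distance_tsv(dmat, file.path(out, "distance.tsv"))
    } else {
      message("single proteome: distance and tree stages skipped")
    }
    if (length(fps) >= 3) {
      stage <- "tree"
      tree <- nj_tree(dmat)
      write_newick(tree, file.path(out, "tree.nwk"))
    } else if (length(fps) == 2) {
      message("two proteomes: tree stage skipped (needs >= 3)")
    }

    stage <- "runlog"
    log <- list(
      package = "ldspace",
      version = as.character(utils::packageVersion("ldspace")),
      seed = cfg$seed,
      M = cfg$M, N = cfg$N,
      ln_edges = part$ln_edges, id_edges = part$id_edges,
      id_threshold_convention = cfg$id_threshold_convention,
      score_sources = stats::setNames(
        lapply(proteomes, function(p) p$score_source), names(proteomes)),
      provenance = stats::setNames(lapply(proteomes, function(p) {
        list(n_total_loaded = p$n_total_loaded,
             n_alternative_removed = p$n_alternative_removed,
             n_excluded_x = p$n_excluded_x)
      }), names(proteomes))
    )
    jsonlite::write_json(log, file.path(out, "runlog.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    files <- list.files(out, recursive = TRUE, full.names = TRUE)
    list(proteomes = proteomes, summaries = summaries, correlations = cc,
         fingerprints = fps, distance = dmat, tree = tree, files = files)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

#' Render a fingerprint or differential grid as a contour/heat map
#'
#' Displays the density grid with ln(L) on the x axis and disorder content on
#' the y axis. For display only, the open-ended outer length bins are clamped
#' to finite bounds (default `ln(L) = 4.3` and `7.3`, i.e. `L = 74` and
#' `1481`); clamping never affects the underlying binning. Differential grids
#' use a symmetric diverging palette centred at zero.
#'
#' @param x An `ld_fingerprint` or differential grid
#'   ([fingerprint_differential()]).
#' @param file Output image path (`.png` or `.svg` chosen by extension).
#' @param clamp Length-2 display bounds for the ln-length axis.
#' @param width,height Device size in pixels (png) or inches (svg).
#' @return `file`, invisibly.
#' @export
render_contour <- function(x, file, clamp = c(4.3, 7.3),
                           width = 800, height = 700) {
  if (length(clamp) != 2 || !all(is.finite(clamp)) || clamp[[1]] >= clamp[[2]]) {
    stop("clamp must be two finite increasing ln-length bounds")
  }
  if (inherits(x, "ld_fingerprint")) {
    part <- x$partition
    z <- x$density
    main <- paste("Fingerprint:", x$name)
    diverging <- FALSE
  } else {
    part <- attr(x, "partition")
    nm <- attr(x, "names_ab")
    z <- unclass(x); attributes(z) <- list(dim = dim(x))
    main <- paste("Differential:", nm[[1]], "-", nm[[2]])
    diverging <- TRUE
  }
  ln <- part$ln_edges
  ln[[1]] <- min(clamp[[1]], ln[[2]] - 0.1)
  ln[[length(ln)]] <- max(clamp[[2]], ln[[length(ln) - 1]] + 0.1)

  ext <- tolower(tools::file_ext(file))
  if (ext == "svg") {
    grDevices::svg(file, width = width / 100, height = height / 100)
  } else {
    grDevices::png(file, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  if (diverging) {
    lim <- max(abs(z), 1e-12)
    breaks <- seq(-lim, lim, length.out = 22)
    pal <- grDevices::hcl.colors(21, "Blue-Red 2")
  } else {
    breaks <- seq(0, max(z, 1e-12), length.out = 22)
    pal <- grDevices::hcl.colors(21, "YlOrRd", rev = TRUE)
  }
  graphics::image(ln, part$id_edges, z, breaks = breaks, col = pal,
                  xlab = "ln(L)", ylab = "ID", main = main, useRaster = FALSE)
  graphics::box()
  invisible(file)
}
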