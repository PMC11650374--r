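#' Read grouped observations from a delimited file
#'
#' Expects a header row with a `group` column of integer labels followed by
#' one or more numeric feature columns. Comma- and tab-separated files are
#' detected automatically. Observation order within a group is the file
#' order.
#'
#' @param path file path.
#' @return a [grouped_data()].
#' @export
read_grouped_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (nrow(df) == 0L) stop("no observations in ", path)
  if (!"group" %in% names(df)) stop("missing `group` column in ", path)
  feat <- df[setdiff(names(df), "group")]
  if (ncol(feat) < 1L) stop("no feature columns in ", path)
  if (!all(vapply(feat, is.numeric, TRUE))) stop("non-numeric feature columns")
  grouped_data(as.matrix(feat), df$group)
}

#' Write grouped observations to CSV
#'
#' Columns: `group`, then `x1..xd`. Round-trips through
#' [read_grouped_csv()] losslessly at full double precision.
#'
#' @param data a [grouped_data()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_grouped_csv <- function(data, path) {
  df <- data.frame(group = data$group,
                   format(data$x, digits = 17, trim = TRUE, scientific = TRUE))
  names(df) <- c("group", paste0("x", seq_len(data$d)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a group DAG from a JSON or edge-list file
#'
#' JSON files use `{"nodes": [...], "edges": [[u, v], ...],
#' "observed": {"id": bool}}` (`nodes` and `observed` optional). Plain-text
#' files are read as a two-column whitespace- or comma-separated edge list
#' with all nodes observed.
#'
#' @param path file path; `.json` selects the JSON reader.
#' @inheritParams group_dag
#' @return a [group_dag()].
#' @export
read_dag <- function(path, auto_augment = TRUE) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::fromJSON(path)
    edges <- if (!is.null(spec$edges) && length(spec$edges) > 0L) {
      matrix(as.integer(as.matrix(spec$edges)), ncol = 2L)
    } else NULL
    observed <- if (!is.null(spec$observed)) {
      stats::setNames(as.logical(unlist(spec$observed)), names(spec$observed))
    } else NULL
    nodes <- if (!is.null(spec$nodes)) as.integer(unlist(spec$nodes)) else NULL
    group_dag(edges, nodes = nodes, observed = observed,
              auto_augment = auto_augment)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- do.call(rbind, lapply(strsplit(lines, "[,[:space:]]+"), as.integer))
    group_dag(parts[, 1:2, drop = FALSE], auto_augment = auto_augment)
  }
}

#' Write fit results to a directory
#'
#' Emits everything needed to reproduce and inspect a run: estimated labels
#' (`labels.csv`: group, row, cluster), the posterior similarity matrix
#' (`psm.csv`), the retained log-likelihood trace (`loglik.csv`), evaluation
#' metrics (`metrics.json`), and a configuration echo with the seed
#' (`run_config.json`).
#'
#' @param outdir output directory (created if missing).
#' @param samples a `gdp_samples`.
#' @param clustering a `gdp_clustering` from [dahl_estimate()].
#' @param metrics named list of metrics (e.g. from [internal_validation()]),
#'   or `NULL` for an empty object.
#' @return character vector of the files written, invisibly.
#' @export
write_gdp_results <- function(outdir, samples, clustering, metrics = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  row_in_group <- stats::ave(seq_along(samples$group), samples$group,
                             FUN = seq_along)
  labels <- data.frame(group = samples$group, row = row_in_group,
                       cluster = clustering$labels)
  files <- file.path(outdir, c("labels.csv", "psm.csv", "loglik.csv",
                               "metrics.json", "run_config.json"))
  utils::write.csv(labels, files[1L], row.names = FALSE)
  utils::write.table(clustering$psm, files[2L], sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(draw = seq_along(samples$loglik),
                              loglik = samples$loglik),
                   files[3L], row.names = FALSE)
  jsonlite::write_json(if (is.null(metrics)) structure(list(), names = character(0)) else metrics,
                       files[4L], auto_unbox = TRUE, digits = NA)
  cfg <- samples$config
  cfg$alpha0 <- samples$alpha0
  cfg$L <- samples$L
  jsonlite::write_json(unclass(cfg), files[5L], auto_unbox = TRUE, digits = NA)
  invisible(files)
}
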