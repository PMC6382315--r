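#' Write a fibril population as a plain-text trace table
#'
#' One vertex per row with columns `fibril_id`, `vertex_index`, `x_nm`,
#' `y_nm` — the same layout as coordinate exports of fibril-tracing software,
#' so generated and traced populations go through the same reader.
#' Coordinates are written with 17 significant digits, enough to round-trip
#' IEEE doubles exactly.
#'
#' @param fibrils list of [fibril_chain()] objects.
#' @param path output file; `.tsv` extension selects tab separation,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_population <- function(fibrils, path) {
  if (length(fibrils) == 0L) stop("empty population", call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  rows <- lapply(seq_along(fibrils), function(i) {
    f <- fibrils[[i]]
    v <- f$vertices
    id <- if (is.na(f$id)) i else f$id
    data.frame(fibril_id = id, vertex_index = seq_len(nrow(v)),
               x_nm = sprintf("%.17g", v[, 1]),
               y_nm = sprintf("%.17g", v[, 2]))
  })
  utils::write.table(do.call(rbind, rows), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fibril population from a trace table
#'
#' Accepts the format written by [write_population()] and equivalent
#' coordinate exports from tracing software. Vertices must be consecutive
#' (1, 2, 3, ...) within each fibril; violations are reported with the file
#' line number. Kink annotation is not stored in the table; use
#' [detect_kinks()] (or `annotate = TRUE` here) to recover it.
#'
#' @param path input file (`.tsv` tab-separated, otherwise comma).
#' @param annotate if TRUE, annotate kinks by [detect_kinks()] at
#'   `threshold`.
#' @param threshold kink visibility threshold in degrees when annotating.
#' @return list of [fibril_chain()] objects.
#' @export
read_population <- function(path, annotate = FALSE, threshold = 20) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      colClasses = c(NA, NA, "numeric", "numeric")),
    error = function(e)
      stop(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
           call. = FALSE))
  need <- c("fibril_id", "vertex_index", "x_nm", "y_nm")
  if (!all(need %in% names(tab)))
    stop(sprintf("'%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (any(!is.finite(tab$x_nm)) || any(!is.finite(tab$y_nm))) {
    bad <- which(!is.finite(tab$x_nm) | !is.finite(tab$y_nm))[1]
    stop(sprintf("non-numeric coordinate at line %d of '%s'", bad + 1L, path),
         call. = FALSE)
  }
  ids <- unique(tab$fibril_id)
  lapply(ids, function(id) {
    rows <- which(tab$fibril_id == id)
    vi <- tab$vertex_index[rows]
    if (!identical(as.integer(vi), seq_along(rows)))
      stop(sprintf(
        "fibril '%s': vertex_index not consecutive from 1 (near line %d)",
        id, rows[which(as.integer(vi) != seq_along(rows))[1]] + 1L),
        call. = FALSE)
    v <- cbind(tab$x_nm[rows], tab$y_nm[rows])
    if (annotate) {
      k <- detect_kinks(v, threshold)
      fibril_chain(v, kink_indices = k$index, kink_angles = k$angle,
                   signs = k$sign, id = id)
    } else {
      fibril_chain(v, id = id)
    }
  })
}

#' Read a model / run configuration file
#'
#' YAML or JSON (selected by extension), with keys matching the arguments of
#' [fibril_model()] (`length_law`, `kink_pmf`, `kink_angle_law`,
#' `partition_law`, `persistence_p`) plus optional run keys (`ratios`,
#' `mean_L`, `n_accept`, `seed`, analysis parameters).
#'
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' not found", path), call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_config
#' @param config named list to serialize.
#' @return `write_config`: `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(config, path)
  else
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  invisible(path)
}

#' Build a fibril model from a configuration list
#'
#' @param config list as returned by [read_config()].
#' @return a [fibril_model()].
#' @export
model_from_config <- function(config) {
  pick <- function(key, default) {
    val <- config[[key]]
    if (is.null(val)) default else val
  }
  fibril_model(
    length_law = as.list(pick("length_law",
                              list(type = "uniform", min = 550, max = 650))),
    kink_pmf = pick("kink_pmf", c(0.21, 0.45, 0.26, 0.05, 0.03)),
    kink_angle_law = as.list(pick("kink_angle_law",
                                  list(type = "fixed", value = 65))),
    partition_law = pick("partition_law", "random"),
    persistence_p = pick("persistence_p", 0.65))
}

#' Write run metadata next to simulation outputs
#'
#' JSON sidecar recording the seed, configuration hash, counts and
#' acceptance fractions of a run, so that every output table can be
#' regenerated from its sidecar alone.
#'
#' @param meta named list of run metadata.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(meta, path) {
  meta$written <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Export a morphology summary
#'
#' Writes the scalar fields as a two-column TSV, the full structure
#' (including the orientation histogram and per-fibril table) as JSON.
#'
#' @param summary a `morphology_summary` from [conformation_summary()].
#' @param dir output directory (created if missing).
#' @param prefix file name prefix.
#' @return character vector of written paths, invisibly.
#' @export
write_summary <- function(summary, dir, prefix = "morphology") {
  stopifnot(inherits(summary, "morphology_summary"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
    message("created output directory ", dir)
  }
  scalars <- c(n_fibrils = summary$n_fibrils, mean_L = summary$mean_L,
               mean_nk = summary$mean_nk,
               mean_kink_angle = summary$mean_kink_angle,
               mean_inverse_kink_density = summary$mean_inverse_kink_density,
               mean_segment_length = summary$mean_segment_length,
               mean_rg_norm_sq = summary$mean_rg_norm_sq, s2d = summary$s2d)
  tsv <- file.path(dir, paste0(prefix, "_summary.tsv"))
  utils::write.table(
    data.frame(statistic = names(scalars), value = unname(scalars)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  od <- file.path(dir, paste0(prefix, "_od.tsv"))
  utils::write.table(summary$od, od, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  per <- file.path(dir, paste0(prefix, "_per_fibril.tsv"))
  utils::write.table(summary$per_fibril, per, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  js <- file.path(dir, paste0(prefix, "_summary.json"))
  jsonlite::write_json(unclass(summary), js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null",
                       dataframe = "columns")
  invisible(c(tsv, od, per, js))
}
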