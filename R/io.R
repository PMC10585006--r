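# File I/O for every format the pipeline touches: TSV count matrices,
# CSV design/survival/fiber/caliper tables, GMT gene sets, YAML config.
# Readers validate schemas and report the offending row; writers round-trip
# losslessly.

#' Read a gene x sample count matrix from TSV
#'
#' First column is the gene id, remaining columns are samples.
#'
#' @param path TSV file path.
#' @return validated integer matrix with dimnames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("count TSV needs a gene column plus >= 2 samples")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  validate_counts(m)
}

#' Write a count matrix to TSV
#' @param counts genes x samples matrix.
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a factorial design table from CSV
#' @param path CSV with columns sample, x_A, x_B (optionally time,
#'   replicate).
#' @return validated design data.frame.
#' @export
read_design_csv <- function(path) {
  validate_design(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read a survival table from CSV
#' @param path CSV with columns sample, time, event.
#' @return validated survival data.frame.
#' @export
read_survival_csv <- function(path) {
  validate_survival(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read gene sets from a GMT file
#'
#' Standard dialect: tab-separated lines `name<TAB>description<TAB>gene...`.
#'
#' @param path GMT file path.
#' @return named list of character vectors; descriptions kept in the
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  attr(sets, "descriptions") <- vapply(fields, `[[`, character(1), 2L)
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector (recycled "na" if absent).
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(k)
    paste(c(names(sets)[k], descriptions[k], sets[[k]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read fiber structures from CSV
#'
#' Long format: one row per segment, columns fiber_id, segment_index,
#' color (red/green), length_um, and optionally condition, replicate.
#'
#' @param path CSV file path.
#' @return list of `fiber_structure`s, one per fiber id.
#' @export
read_fiber_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fiber_id", "segment_index", "color", "length_um")
  if (!all(need %in% names(df)))
    stop("fiber CSV needs columns fiber_id, segment_index, color, length_um")
  bad <- which(!df$color %in% c("red", "green"))
  if (length(bad))
    stop(sprintf("fiber CSV row %d: unknown color '%s'", bad[1],
                 df$color[bad[1]]))
  lapply(split(df, df$fiber_id), function(d) {
    d <- d[order(d$segment_index), , drop = FALSE]
    fiber_structure(d$color, d$length_um, fiber_id = d$fiber_id[1],
                    condition = (d$condition %||% NA_character_)[1],
                    replicate = as.character((d$replicate %||%
                                                NA_character_)[1]))
  })
}

#' Write fiber structures to CSV
#' @param structures list of `fiber_structure`s.
#' @param path output path.
#' @export
write_fiber_csv <- function(structures, path) {
  rows <- lapply(structures, function(s)
    data.frame(fiber_id = s$fiber_id,
               segment_index = seq_along(s$colors), color = s$colors,
               length_um = s$lengths_um, condition = s$condition,
               replicate = s$replicate, stringsAsFactors = FALSE))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write a generic table as TSV
#' @param df data.frame.
#' @param path output path.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load a YAML pipeline configuration
#'
#' Single YAML document with per-stage sections (simulate, de, signature,
#' score, fibers); returns it as a nested list, with an empty list for a
#' missing file section.
#'
#' @param path YAML file path.
#' @return nested list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path) %||% list()
}
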