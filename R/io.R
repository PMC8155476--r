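#' Read and write feature tables as delimited text
#'
#' Feature tables are stored as comma-separated text with a header row of
#' canonical feature names, an optional leading `record_id` column and a
#' final `label` column.  `read_feature_table()` restores the label factor
#' in the canonical (N, A, O, ~) order, so a written table round-trips
#' unchanged.
#'
#' @param table A feature table (tibble with feature columns and `label`).
#' @param path File path.
#' @return `read_feature_table()` returns the tibble;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if ("label" %in% names(out)) {
    out$label <- as_rhythm_factor(out$label)
  }
  tibble::as_tibble(out)
}

#' Write RR-interval records with a label manifest
#'
#' Writes one plain-text file per record (one interval per line, seconds)
#' into `dir`, plus a `manifest.csv` mapping `record_id` to `label`.
#'
#' @param records A named list of RR-interval vectors (names are record
#'   ids).
#' @param labels Character or factor vector of labels, one per record.
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_rr_records <- function(records, labels, dir) {
  stopifnot(length(records) == length(labels), !is.null(names(records)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (id in names(records)) {
    writeLines(format(records[[id]], digits = 15, scientific = FALSE),
      file.path(dir, paste0(id, ".rr"))
    )
  }
  manifest <- tibble::tibble(
    record_id = names(records),
    label = as.character(labels)
  )
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' @rdname write_rr_records
#' @export
read_rr_records <- function(dir) {
  manifest <- readr::read_csv(file.path(dir, "manifest.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  records <- lapply(manifest$record_id, function(id) {
    as.numeric(readLines(file.path(dir, paste0(id, ".rr"))))
  })
  names(records) <- manifest$record_id
  list(records = records, labels = as_rhythm_factor(manifest$label))
}

#' Extract a feature table from stored RR records
#'
#' Reads RR records written by [write_rr_records()] and computes the
#' rhythm feature table, one row per record.
#'
#' @param dir Directory holding `*.rr` files and `manifest.csv`.
#' @return A tibble with `record_id`, the 21 rhythm features and `label`.
#' @export
extract_rr_feature_table <- function(dir) {
  x <- read_rr_records(dir)
  feats <- dplyr::bind_rows(
    purrr::imap(x$records, function(rr, id) rr_features(rr, record_id = id))
  )
  dplyr::mutate(feats, label = x$labels)
}
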