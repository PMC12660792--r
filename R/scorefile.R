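#' Read a docking score table
#'
#' Parses a whitespace-separated score table (the layout of a Rosetta score
#' file) into a tibble of decoy records.  Scores are in Rosetta Energy Units
#' (REU) for the total score and the interface binding-energy estimate
#' (`dg_binding`), and in Angstrom^2 for the buried interface area (`dsasa`).
#' Rows whose score fields do not parse as numbers are dropped with a single
#' warning giving the count; the count is also attached as the
#' `n_rejected` attribute.
#'
#' @param path Path to the table.
#' @param columns Named character vector mapping the required record fields
#'   (`decoy_id`, `total_score`, `dg_binding`, `dsasa`) to column names in the
#'   file header.
#' @return A tibble with columns `decoy_id`, `total_score`, `dg_binding`,
#'   `dsasa`, plus `structure_path` and `cluster_id` when present in the file.
#' @export
read_scorefile <- function(path,
                           columns = c(decoy_id = "decoy_id",
                                       total_score = "total_score",
                                       dg_binding = "dg_binding",
                                       dsasa = "dsasa")) {
  required <- c("decoy_id", "total_score", "dg_binding", "dsasa")
  if (!all(required %in% names(columns))) {
    abort(paste0("columns must name: ", paste(required, collapse = ", ")))
  }
  tab <- readr::read_table(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  for (field in required) {
    if (!columns[[field]] %in% names(tab)) {
      abort(sprintf("score table is missing mandatory column '%s'", columns[[field]]))
    }
  }
  out <- tibble(
    decoy_id = tab[[columns[["decoy_id"]]]],
    total_score = suppressWarnings(as.numeric(tab[[columns[["total_score"]]]])),
    dg_binding = suppressWarnings(as.numeric(tab[[columns[["dg_binding"]]]])),
    dsasa = suppressWarnings(as.numeric(tab[[columns[["dsasa"]]]]))
  )
  if ("structure_path" %in% names(tab)) out$structure_path <- tab$structure_path
  if ("cluster_id" %in% names(tab)) {
    out$cluster_id <- suppressWarnings(as.integer(tab$cluster_id))
  }
  bad <- !stats::complete.cases(out[, c("total_score", "dg_binding", "dsasa")])
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    warn(sprintf("dropped %d row(s) with non-numeric scores", n_rejected))
    out <- out[!bad, , drop = FALSE]
  }
  if (any(out$dsasa < 0)) abort("dsasa must be non-negative")
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Write a docking score table
#'
#' Inverse of [read_scorefile()]: writes a whitespace-separated table that
#' round-trips exactly through the reader.
#'
#' @param decoys Tibble of decoy records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scorefile <- function(decoys, path) {
  cols <- intersect(
    c("decoy_id", "total_score", "dg_binding", "dsasa", "structure_path", "cluster_id"),
    names(decoys)
  )
  df <- as.data.frame(decoys[, cols])
  for (nm in c("total_score", "dg_binding", "dsasa")) {
    df[[nm]] <- formatC(df[[nm]], format = "f", digits = 3)
  }
  widths <- vapply(names(df), function(nm) {
    max(nchar(c(nm, as.character(df[[nm]])))) + 2L
  }, integer(1))
  fmt_row <- function(vals) {
    paste0(mapply(formatC, as.character(vals), width = widths), collapse = "")
  }
  lines <- c(fmt_row(names(df)), apply(df, 1, fmt_row))
  writeLines(lines, path)
  invisible(path)
}
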