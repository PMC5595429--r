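#' Read and write trial-level CSV files
#'
#' The trials file is UTF-8 comma-separated with exactly the header
#' `subject_id,group,task,item_class,response,confidence,attribution,encoding_depth`
#' and one trial per row; absent fields (confidence outside the ROC task,
#' attribution outside RKG "yes" responses) are empty strings. The groups
#' sheet has header `subject_id,group,subgroup` with `subgroup` one of
#' `dMTT`, `iMTT` or empty.
#'
#' @param path File path.
#' @return `read_trials()` and `read_groups()` return data frames;
#'   the writers return `path` invisibly.
#' @name trials_io
NULL

trials_header <- c("subject_id", "group", "task", "item_class", "response",
                   "confidence", "attribution", "encoding_depth")

#' @rdname trials_io
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(df), trials_header))
    stop("trials file must have exact header: ",
         paste(trials_header, collapse = ","))
  df$confidence <- suppressWarnings(as.integer(df$confidence))
  for (col in c("attribution", "encoding_depth"))
    df[[col]][!nzchar(df[[col]]) | is.na(df[[col]])] <- NA_character_
  df
}

#' @rdname trials_io
#' @param trials Data frame of trial records.
#' @export
write_trials <- function(trials, path) {
  df <- trials[trials_header]
  df$confidence <- ifelse(is.na(df$confidence), "", df$confidence)
  for (col in c("attribution", "encoding_depth"))
    df[[col]][is.na(df[[col]])] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname trials_io
#' @export
read_groups <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("subject_id", "group", "subgroup")
  if (!all(need %in% names(df)))
    stop("groups file must have columns: ", paste(need, collapse = ","))
  df$subgroup[is.na(df$subgroup)] <- ""
  df[need]
}

#' @rdname trials_io
#' @param groups Data frame with `subject_id`, `group`, `subgroup`.
#' @export
write_groups <- function(groups, path) {
  df <- groups[c("subject_id", "group", "subgroup")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize an analysis bundle to JSON
#'
#' Writes a [run_group_analysis()] result to JSON at full double
#' precision (rounding is a presentation concern; see
#' [results_markdown()]).
#'
#' @param results A `"recmem_results"` object.
#' @param path Output file.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(unclass(results), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Markdown summary of an analysis bundle
#'
#' Renders the comparison tables as Markdown, numbers rounded to 2
#' decimals in the reported style.
#'
#' @param results A `"recmem_results"` object.
#' @return Character vector of Markdown lines.
#' @export
results_markdown <- function(results) {
  md_table <- function(df) {
    df <- format_num_df(df)
    hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    rows <- apply(df, 1L, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    c(hdr, sep, rows)
  }
  out <- c("# Recognition-memory group analysis", "",
           "## Per-task comparisons (Mann-Whitney, controls vs patients)", "",
           md_table(results$per_task), "")
  if (!is.null(results$z_comparisons))
    out <- c(out, "## Cross-task z summaries", "",
             md_table(results$z_comparisons), "")
  out <- c(out, "## zR-zF Spearman correlations", "",
           md_table(results$correlations), "")
  if (!is.null(results$subgroup))
    out <- c(out, "## Subgroup permutation contrasts", "",
             md_table(results$subgroup), "")
  out
}
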