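#' Read a feature matrix from CSV or TSV
#'
#' Expects a header row of unique feature names and a numeric body, with an
#' optional leading column of sample identifiers. The delimiter is chosen
#' from the file extension (`.tsv`/`.tab`/`.txt` are tab-separated,
#' anything else comma-separated).
#'
#' @param path Path to the file.
#' @param sample_id_col If `TRUE`, the first column holds sample IDs and is
#'   used as row names rather than data.
#' @param na_policy What to do with missing values: `"reject"` (default,
#'   error), `"drop_feature"` (remove any feature with a missing value), or
#'   `"mean_impute"` (replace by the feature mean).
#'
#' @return A validated numeric feature matrix.
#' @export
read_matrix <- function(path,
                        sample_id_col = FALSE,
                        na_policy = c("reject", "drop_feature", "mean_impute")) {
  na_policy <- match.arg(na_policy)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|tab|txt)$", path, ignore.case = TRUE)) "\t" else ","

  header <- strsplit(readLines(path, n = 1), sep, fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  if (sample_id_col) header <- header[-1]
  if (anyDuplicated(header)) stop("duplicate feature names", call. = FALSE)

  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  rn <- NULL
  if (sample_id_col) {
    rn <- as.character(dt[[1]])
    dt <- dt[, -1, drop = FALSE]
  }
  if (nrow(dt) < 2) stop("fewer than 2 rows", call. = FALSE)
  numeric_ok <- vapply(dt, is.numeric, logical(1))
  if (!all(numeric_ok)) {
    stop("non-numeric cell in feature(s): ",
         paste(names(dt)[!numeric_ok], collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(dt)
  colnames(x) <- header
  if (!is.null(rn)) rownames(x) <- rn

  if (anyNA(x)) {
    if (na_policy == "reject") {
      stop("feature matrix contains missing values (na_policy = \"reject\")",
           call. = FALSE)
    } else if (na_policy == "drop_feature") {
      keep <- colSums(is.na(x)) == 0
      if (!any(keep)) stop("all features contain missing values", call. = FALSE)
      x <- x[, keep, drop = FALSE]
    } else {
      for (j in which(colSums(is.na(x)) > 0)) {
        x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
      }
    }
  }
  as_feature_matrix(x)
}

#' Write a reduction result to disk
#'
#' The reduced matrix is written as CSV (header = output feature names,
#' values formatted to 10 significant digits) and the surjective mapping as
#' JSON: a list of `{name, members, information, n_members}` records plus a
#' `run` block with the configuration, input/output feature counts, the
#' percent reduction `100 * (1 - out/in)`, and a summary of the
#' super-partition trace when present.
#'
#' @param result A `partition_result`.
#' @param out_matrix_path Path for the reduced CSV matrix.
#' @param out_mapping_path Path for the JSON mapping.
#'
#' @return Invisibly, the paths written.
#' @export
write_result <- function(result, out_matrix_path, out_mapping_path) {
  stopifnot(inherits(result, "partition_result"))
  reduced <- as.data.frame(result$reduced_data, check.names = FALSE)
  reduced[] <- lapply(reduced, signif, digits = 10)
  data.table::fwrite(reduced, out_matrix_path)

  n_in <- sum(result$mapping$n_members)
  n_out <- nrow(result$mapping)
  mapping <- lapply(seq_len(n_out), function(i) {
    list(
      name = result$mapping$name[i],
      members = I(result$mapping$members[[i]]),
      information = result$mapping$information[i],
      n_members = result$mapping$n_members[i]
    )
  })
  run <- list(
    config = unclass(result$config),
    input_n_features = n_in,
    output_n_features = n_out,
    percent_reduction = 100 * (1 - n_out / n_in)
  )
  if (!is.null(result$superpartition)) {
    run$trace <- result$superpartition$trace
    run$n_superclusters <- length(result$superpartition$sizes)
  }
  jsonlite::write_json(list(mapping = mapping, run = run), out_mapping_path,
                       auto_unbox = TRUE, digits = 10, dataframe = "rows")
  invisible(c(out_matrix_path, out_mapping_path))
}
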