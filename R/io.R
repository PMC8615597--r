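#' Read a benefit matrix from CSV
#'
#' Expects a square table whose first column holds the row category
#' identifiers and whose header holds the column identifiers, cell `(i, j)`
#' being the benefit `b_ij`. Squareness, row/column label agreement, range
#' and unit diagonal are validated.
#'
#' @param path CSV file.
#' @param normal_label optional normal-class identifier (default: `"NSR"`
#'   when present, else the first label).
#' @return a [benefit_matrix()].
#' @export
read_benefit_csv <- function(path, normal_label = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  entries <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(entries), labels))
    stop("row and column category identifiers differ (or are reordered)")
  rownames(entries) <- labels
  benefit_matrix(entries, labels = labels, normal_label = normal_label)
}

#' Write a benefit matrix to CSV
#'
#' @param b a [benefit_matrix()].
#' @param path output CSV file.
#' @export
write_benefit_csv <- function(b, path) {
  b <- as_benefit_matrix(b)
  df <- data.frame(label = rownames(b), unclass(b), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a label or score matrix from CSV/TSV
#'
#' One row per recording; the first column is the recording identifier, the
#' remaining columns are category values (binary 0/1 for annotations,
#' numbers in `[0, 1]` for scores).
#'
#' @param path CSV (or TSV, detected from the extension) file.
#' @param binary validate entries as exactly 0/1.
#' @return numeric matrix with recording ids as rownames and categories as
#'   colnames.
#' @export
read_matrix_csv <- function(path, binary = FALSE) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  if (binary) m <- check_label_matrix(m) else m <- check_score_matrix(m)
  m
}

#' Write a label or score matrix to CSV
#'
#' @param m numeric matrix with category colnames; rownames (or `id`) supply
#'   the recording identifier column.
#' @param path output CSV file.
#' @param id optional recording identifiers.
#' @export
write_matrix_csv <- function(m, path, id = rownames(m)) {
  if (is.null(id)) id <- paste0("rec", seq_len(nrow(m)))
  df <- data.frame(record_id = id, m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Read a plain-text WFDB-style ECG record
#'
#' Reads the package's text serialization of a multi-lead record: a header
#' file (`<base>.hea`) whose first line is
#' `<record_id> <n_leads> <fs> <n_samples>`, optionally followed by a
#' `# labels: A,B` comment line, and a companion `<base>.csv` holding the
#' signal matrix (one column per lead, no header). This mirrors the layout
#' of a WFDB header + signal pair in a text-only form; binary `.dat`
#' signals are not supported.
#'
#' @param base path without extension.
#' @return an [ecg_record()].
#' @export
read_ecg_text <- function(base) {
  hea <- readLines(paste0(base, ".hea"))
  parts <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  if (length(parts) < 4) stop("malformed header line: ", hea[1])
  labels <- character()
  lab_line <- grep("^#\\s*labels:", hea, value = TRUE)
  if (length(lab_line))
    labels <- trimws(strsplit(sub("^#\\s*labels:\\s*", "", lab_line[1]),
                              ",")[[1]])
  sig <- as.matrix(utils::read.csv(paste0(base, ".csv"), header = FALSE))
  dimnames(sig) <- NULL
  n_leads <- as.integer(parts[2]); fs <- as.numeric(parts[3])
  n <- as.integer(parts[4])
  if (ncol(sig) != n_leads || nrow(sig) != n)
    stop("signal shape ", nrow(sig), "x", ncol(sig),
         " disagrees with header ", n, "x", n_leads)
  ecg_record(sig, fs = fs, labels = labels, record_id = parts[1])
}

#' Write a plain-text WFDB-style ECG record
#'
#' Companion writer for [read_ecg_text()].
#'
#' @param rec an [ecg_record()].
#' @param base output path without extension.
#' @export
write_ecg_text <- function(rec, base) {
  stopifnot(inherits(rec, "ecg_record"))
  hea <- sprintf("%s %d %g %d", rec$record_id, ncol(rec$signal), rec$fs,
                 nrow(rec$signal))
  if (length(rec$labels))
    hea <- c(hea, paste0("# labels: ", paste(rec$labels, collapse = ",")))
  writeLines(hea, paste0(base, ".hea"))
  utils::write.table(rec$signal, paste0(base, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
}
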