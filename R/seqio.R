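# Sequence and label input/output, plus the dataset-quality filters applied to
# protein sequences before modelling: removal of entries with non-standard
# residues and of entries shorter than a minimum length.

#' Construct a protein sequence dataset
#'
#' A thin data.frame-based container with columns `id`, `sequence` and `label`
#' (`NA` when unlabeled; otherwise 1 = TF, 0 = non-TF) and a `split_tag`
#' attribute marking it as a training, test, or unsplit collection.
#'
#' @param id character vector of unique record identifiers.
#' @param sequence character vector of upper-case amino-acid sequences.
#' @param label integer vector of 0/1 labels, or `NA` for unlabeled records.
#' @param split_tag one of `"train"`, `"test"`, `"unsplit"`.
#' @return A `capstf_dataset` (data.frame).
#' @export
tf_dataset <- function(id, sequence, label = NA_integer_,
                       split_tag = c("unsplit", "train", "test")) {
  split_tag <- match.arg(split_tag)
  if (anyDuplicated(id))
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  lab <- suppressWarnings(as.integer(label))
  if (any(!is.na(lab) & !(lab %in% c(0L, 1L))))
    stop("label must be 0 or 1")
  df <- data.frame(id = as.character(id), sequence = as.character(sequence),
                   label = rep_len(lab, length(id)), stringsAsFactors = FALSE)
  structure(df, class = c("capstf_dataset", "data.frame"), split_tag = split_tag)
}

#' @export
print.capstf_dataset <- function(x, ...) {
  n_lab <- sum(!is.na(x$label))
  cat(sprintf("<capstf_dataset> %d records (%s), %d labeled (%d positive)\n",
              nrow(x), attr(x, "split_tag") %||% "unsplit", n_lab,
              sum(x$label == 1L, na.rm = TRUE)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read protein sequences from a FASTA file
#'
#' Parses a (multi-line) FASTA file into a [tf_dataset()]. Sequences are
#' upper-cased and trailing stop characters (`*`) are stripped; the record id
#' is the first whitespace-delimited token of the header. Optionally, a
#' trailing `|0` / `|1` on the header is read as a class label.
#'
#' @param path path to a FASTA text file.
#' @param labels_in_header if `TRUE`, accept labels embedded as a `|<0/1>`
#'   suffix on the header token (sidecar TSV label files are the default
#'   route, see [read_labels()]).
#' @return A `capstf_dataset`; `label` is `NA` unless `labels_in_header`.
#' @export
read_fasta <- function(path, labels_in_header = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0)
    stop("empty dataset: no FASTA records in ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop(sprintf("malformed FASTA: sequence line before any header at line %d",
                 nonblank[1]))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty dataset: no FASTA records in ", path)
  headers <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  labels <- NA_integer_
  if (labels_in_header) {
    m <- regmatches(headers, regexec("^(.*)\\|([01])$", headers))
    has <- lengths(m) == 3
    labels <- rep(NA_integer_, length(headers))
    labels[has] <- as.integer(vapply(m[has], `[`, character(1), 3L))
    headers[has] <- vapply(m[has], `[`, character(1), 2L)
  }
  if (anyDuplicated(headers))
    stop("duplicate record id(s) in FASTA: ",
         paste(unique(headers[duplicated(headers)]), collapse = ", "))
  tf_dataset(headers, unname(seqs), labels)
}

#' Write a dataset to FASTA
#'
#' @param ds a `capstf_dataset`.
#' @param path output file path.
#' @param width line width for wrapped sequence lines.
#' @export
write_fasta <- function(ds, path, width = 60L) {
  set <- Biostrings::BStringSet(setNames(ds$sequence, ds$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Filter out low-quality sequence records
#'
#' Removes records containing residues outside the 20 standard amino-acid
#' letters (the non-standard codes X, B and Z, and by extension U, O, J or any
#' other character, unless allowed explicitly) and records shorter than
#' `min_len` residues ("less than `min_len`" read literally: a record of
#' exactly `min_len` residues is kept). Kept records are returned unmodified.
#'
#' @param ds a `capstf_dataset`.
#' @param min_len minimum sequence length kept (default 50).
#' @param allow_chars extra characters to tolerate beyond the 20 standard
#'   residue letters.
#' @return A list with `dataset` (the kept records, same class and split tag)
#'   and `report`, a data.frame of `id`/`reason` rows for each removed record.
#' @export
filter_records <- function(ds, min_len = 50L, allow_chars = character()) {
  allowed <- c(AA_LETTERS, toupper(allow_chars))
  reasons <- character(0)
  rm_ids <- character(0)
  keep <- logical(nrow(ds))
  for (r in seq_len(nrow(ds))) {
    chars <- unique(strsplit(ds$sequence[r], "")[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad) > 0) {
      rm_ids <- c(rm_ids, ds$id[r])
      reasons <- c(reasons, paste("illegal character", paste(sort(bad), collapse = ",")))
    } else if (nchar(ds$sequence[r]) < min_len) {
      rm_ids <- c(rm_ids, ds$id[r])
      reasons <- c(reasons, sprintf("length < %d", min_len))
    } else {
      keep[r] <- TRUE
    }
  }
  kept <- ds[keep, , drop = FALSE]
  attr(kept, "split_tag") <- attr(ds, "split_tag")
  class(kept) <- class(ds)
  list(dataset = kept,
       report = data.frame(id = rm_ids, reason = reasons, stringsAsFactors = FALSE))
}

#' Attach labels from a sidecar TSV
#'
#' Reads a two-column tab-separated file (`id<TAB>label`, no header) and
#' attaches the labels to `ds` by id. Every record of `ds` must be labeled;
#' ids present in the file but absent from `ds` produce a warning only.
#'
#' @param path path to the label TSV.
#' @param ds a `capstf_dataset`.
#' @return `ds` with its `label` column filled.
#' @export
read_labels <- function(path, ds) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                    col.names = c("id", "label"), quote = "", comment.char = "")
  if (any(!tab$label %in% c("0", "1")))
    stop("label must be 0 or 1 (offending ids: ",
         paste(tab$id[!tab$label %in% c("0", "1")], collapse = ", "), ")")
  if (anyDuplicated(tab$id))
    stop("duplicate ids in label file: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  extra <- setdiff(tab$id, ds$id)
  if (length(extra) > 0)
    warning("label file contains ids absent from the dataset: ",
            paste(extra, collapse = ", "))
  missing <- setdiff(ds$id, tab$id)
  if (length(missing) > 0)
    stop("unlabeled record(s): ", paste(missing, collapse = ", "))
  ds$label <- as.integer(tab$label[match(ds$id, tab$id)])
  ds
}

#' Write a label TSV for a labeled dataset
#' @param ds a labeled `capstf_dataset`.
#' @param path output path.
#' @export
write_labels <- function(ds, path) {
  if (any(is.na(ds$label))) stop("dataset contains unlabeled records")
  write.table(data.frame(ds$id, ds$label), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
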