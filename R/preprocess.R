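# Fixed-length model input: position windowing, closed-vocabulary tokenization
# and right padding.

#' Cut a fixed-length window from a sequence
#'
#' Sequences longer than `L` residues are cut to the first `L` (upstream), the
#' centred `L` (centre; the start offset is `floor((len - L) / 2)`, 0-based),
#' or the last `L` (downstream). Shorter sequences are returned unchanged.
#'
#' @param seq amino-acid string.
#' @param position `"upstream"`, `"centre"` or `"downstream"`.
#' @param L window length in residues (default 500).
#' @return The windowed string, of length `min(nchar(seq), L)`.
#' @export
window_sequence <- function(seq, position = c("upstream", "centre", "downstream"),
                            L = 500L) {
  position <- match.arg(position)
  if (!nzchar(seq)) stop("sequence is empty")
  if (L < 1) stop("window length must be >= 1")
  n <- nchar(seq)
  if (n <= L) return(seq)
  switch(position,
         upstream = substr(seq, 1L, L),
         centre = {
           start0 <- (n - L) %/% 2L
           substr(seq, start0 + 1L, start0 + L)
         },
         downstream = substr(seq, n - L + 1L, n))
}

#' Build a token vocabulary
#'
#' Residue mode yields a closed vocabulary of 22 tokens: padding (id 0),
#' unknown (id 1) and the 20 standard amino acids. `kmer3` mode enumerates the
#' overlapping 3-mers (stride 1) observed in a training corpus plus the two
#' special tokens.
#'
#' @param unit `"residue"` or `"kmer3"`.
#' @param corpus character vector of training sequences; required for `kmer3`.
#' @return A `capstf_vocabulary`: list with `token_to_id` (named 0-based
#'   integer ids), `pad_id` (always 0), `unk_id` (always 1), and `unit`.
#' @export
build_vocabulary <- function(unit = c("residue", "kmer3"), corpus = NULL) {
  unit <- match.arg(unit)
  toks <- if (unit == "residue") {
    AA_LETTERS
  } else {
    if (is.null(corpus)) stop("kmer3 vocabulary requires a training corpus")
    kmers <- unlist(lapply(corpus, function(s) {
      n <- nchar(s)
      if (n < 3) return(character(0))
      substring(s, 1:(n - 2), 3:n)
    }))
    sort(unique(kmers))
  }
  ids <- setNames(seq_along(toks) + 1L, toks)      # 0 = PAD, 1 = UNK
  structure(list(token_to_id = c("<pad>" = 0L, "<unk>" = 1L, ids),
                 pad_id = 0L, unk_id = 1L, unit = unit),
            class = "capstf_vocabulary")
}

#' @export
print.capstf_vocabulary <- function(x, ...) {
  cat(sprintf("<capstf_vocabulary> unit=%s, |V|=%d\n", x$unit, length(x$token_to_id)))
  invisible(x)
}

seq_units <- function(seq, unit) {
  if (unit == "residue") {
    strsplit(seq, "")[[1]]
  } else {
    n <- nchar(seq)
    if (n < 3) character(0) else substring(seq, 1:(n - 2), 3:n)
  }
}

#' Tokenize a windowed sequence
#'
#' Maps each unit of `seq` to its vocabulary id and right-pads with the pad id
#' to length `L`. Unknown units map to the unknown id (their count is kept as
#' the `n_unknown` attribute). `seq` must already be windowed to at most `L`
#' units.
#'
#' @param seq amino-acid string of at most `L` units.
#' @param vocab a [build_vocabulary()] result.
#' @param L padded length (default 500).
#' @param source_id id carried along for bookkeeping.
#' @return A `capstf_tokens`: list with integer `ids` (length `L`, 0-based),
#'   binary `mask` (1 = real token, a prefix), and `source_id`.
#' @export
tokenize <- function(seq, vocab, L = 500L, source_id = NA_character_) {
  units <- seq_units(seq, vocab$unit)
  if (length(units) > L)
    stop(sprintf("sequence has %d units but L = %d; window it first",
                 length(units), L))
  ids <- unname(vocab$token_to_id[units])
  unknown <- is.na(ids)
  ids[unknown] <- vocab$unk_id
  n <- length(ids)
  out <- structure(list(ids = c(as.integer(ids), rep(vocab$pad_id, L - n)),
                        mask = c(rep(1L, n), rep(0L, L - n)),
                        source_id = source_id),
                   class = "capstf_tokens")
  attr(out, "n_unknown") <- sum(unknown)
  out
}

#' Invert tokenization (sequences without unknowns only)
#' @param tokens a `capstf_tokens`.
#' @param vocab the vocabulary used to produce it.
#' @return The windowed sequence string.
#' @export
detokenize <- function(tokens, vocab) {
  ids <- tokens$ids[tokens$mask == 1L]
  rev_map <- setNames(names(vocab$token_to_id), vocab$token_to_id)
  toks <- rev_map[as.character(ids)]
  if (any(toks == "<unk>"))
    warning("sequence contained unknown tokens; they cannot be restored")
  if (vocab$unit == "residue") paste(toks, collapse = "")
  else paste0(paste(substr(toks[-length(toks)], 1, 1), collapse = ""),
              toks[length(toks)])
}

# Window + tokenize a whole dataset into the column-major id matrix the
# compiled model consumes (L x n, 0-based ids) plus per-record true lengths.
tokenize_dataset <- function(ds, vocab, L = 500L,
                             position = "upstream") {
  n <- nrow(ds)
  ids <- matrix(0L, nrow = L, ncol = n)
  lens <- integer(n)
  for (r in seq_len(n)) {
    w <- window_sequence(ds$sequence[r], position, L)
    tk <- tokenize(w, vocab, L, ds$id[r])
    ids[, r] <- tk$ids
    lens[r] <- sum(tk$mask)
  }
  list(ids = ids, lengths = lens, id = ds$id, L = L)
}

#' Serialize a vocabulary to JSON
#' @param vocab a `capstf_vocabulary`.
#' @param path output path.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(list(unit = vocab$unit,
                            token_to_id = as.list(vocab$token_to_id)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a vocabulary from JSON
#' @param path path written by [write_vocabulary()].
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path)
  ids <- unlist(x$token_to_id)
  structure(list(token_to_id = setNames(as.integer(ids), names(ids)),
                 pad_id = 0L, unk_id = 1L, unit = x$unit),
            class = "capstf_vocabulary")
}
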