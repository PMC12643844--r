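`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize text for matching
#'
#' Unicode NFKC normalization followed by lower-casing. All substring
#' matching in the corpus pipeline (noise filtering, deduplication, seed
#' screening) operates on this normalized form; Chinese has no case, but
#' Latin-token fixtures do.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_text <- function(x) {
  tolower(stringi::stri_trans_nfkc(as.character(x)))
}

#' Whitespace tokenizer
#'
#' @param text a single string.
#' @return character vector of tokens (no empty tokens).
#' @export
tokenize_ws <- function(text) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Read a plain-text term list
#'
#' One term per line; blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return character vector of terms.
#' @export
read_termlist <- function(path) {
  if (!file.exists(path)) stop("term list not found: ", path)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

# derive a child seed below 2^31 from a base seed and a stream label
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 1103 + h * 12289 + 49297) %% 2147483647)
}
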