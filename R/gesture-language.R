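# The four-alphabet eye-gesture language: {L, R, U, B}, fixed-length codes of
# three states, and the 64-phrase dictionary with encode/decode.

#' The four eye-state alphabets
#'
#' The language recognises exactly four eye states — Left, Right, Up and
#' Blink — each with a one-letter canonical code. Frame-level classification
#' additionally uses CENTER, CLOSED and UNKNOWN, but only these four states
#' carry linguistic meaning.
#'
#' @return A named character vector mapping state names to one-letter codes.
#' @examples
#' eye_states()
#' @export
eye_states <- function() {
  c(LEFT = "L", RIGHT = "R", UP = "U", BLINK = "B")
}

# frame-level states seen by the classifier (superset of the alphabet)
frame_states <- function() {
  c("LEFT", "RIGHT", "UP", "CENTER", "CLOSED", "UNKNOWN")
}

#' Number of expressible sentences
#'
#' A language with `n` recognised eye states and sentences of `k` states can
#' express exactly \eqn{n^k} distinct sentences. With the system's four states
#' and three-state sentences this is 64.
#'
#' @param n Number of recognised eye states (positive integer).
#' @param k Sentence length in states (positive integer).
#' @return The exact integer \eqn{n^k}.
#' @examples
#' capacity(4, 3) # 64
#' @export
capacity <- function(n, k) {
  if (!is_scalar_number(n) || !is_scalar_number(k) ||
      n < 1 || k < 1 || n != round(n) || k != round(k)) {
    abort_input("capacity() requires positive integer n and k")
  }
  out <- as.integer(round(n))^as.integer(round(k))
  if (!is.finite(out) || out > .Machine$integer.max) {
    return(round(n)^round(k))
  }
  as.integer(out)
}

#' Coerce a 3-letter gesture code
#'
#' @param code Character scalar over the alphabet `{L, R, U, B}`, or a
#'   character vector of three single letters.
#' @return A validated 3-character string.
#' @export
as_gesture_code <- function(code) {
  if (is.character(code) && length(code) == 3 && all(nchar(code) == 1)) {
    code <- paste(code, collapse = "")
  }
  if (!is.character(code) || length(code) != 1 || nchar(code) != 3) {
    abort_validation("a gesture code is exactly three letters over {L, R, U, B}")
  }
  code <- toupper(code)
  letters_ok <- strsplit(code, "")[[1]] %in% eye_states()
  if (!all(letters_ok)) {
    abort_validation(paste0("invalid gesture code '", code, "': letters must be in {L, R, U, B}"))
  }
  code
}

all_gesture_codes <- function() {
  s <- unname(eye_states())
  g <- expand.grid(a = s, b = s, c = s, stringsAsFactors = FALSE)
  sort(paste0(g$a, g$b, g$c))
}

#' Path of the bundled English dictionary
#' @return File path of the installed 64-phrase TSV.
#' @export
eyespeak_dictionary_file <- function() {
  system.file("extdata", "dictionary_en.tsv", package = "eyespeak", mustWork = TRUE)
}

#' Load and validate a gesture-phrase dictionary
#'
#' The dictionary is a two-column TSV (`code<TAB>phrase`, one header line,
#' UTF-8) mapping every one of the \eqn{4^3 = 64} three-state codes to a
#' distinct non-empty phrase. Validation names the offending row on failure.
#'
#' @param source Path to a dictionary TSV; defaults to the bundled English
#'   dictionary.
#' @param language_tag Identifier of the rendering language.
#' @return A tibble with columns `code` and `phrase`, class
#'   `phrase_dictionary`, carrying `language_tag` as an attribute.
#' @examples
#' dict <- load_dictionary()
#' nrow(dict) # 64
#' @export
load_dictionary <- function(source = eyespeak_dictionary_file(), language_tag = "en") {
  if (!file.exists(source)) abort_io(paste0("dictionary file not found: ", source))
  d <- readr::read_tsv(source, col_types = readr::cols(
    code = readr::col_character(), phrase = readr::col_character()
  ), progress = FALSE)
  if (!identical(names(d), c("code", "phrase"))) {
    abort_validation("dictionary must have exactly the columns 'code' and 'phrase'")
  }
  bad_len <- which(nchar(d$code) != 3 | !grepl("^[LRUB]{3}$", d$code))
  if (length(bad_len)) {
    abort_validation(paste0("row ", bad_len[1] + 1L, ": invalid code '", d$code[bad_len[1]],
                            "' (must be 3 letters over {L, R, U, B})"))
  }
  dup <- which(duplicated(d$code))
  if (length(dup)) {
    abort_validation(paste0("row ", dup[1] + 1L, ": duplicate code '", d$code[dup[1]], "'"))
  }
  if (nrow(d) != 64) {
    missing <- setdiff(all_gesture_codes(), d$code)
    abort_validation(paste0("dictionary has ", nrow(d), " entries, expected 64",
                            if (length(missing)) paste0(" (missing e.g. ", missing[1], ")")))
  }
  empty <- which(is.na(d$phrase) | trimws(d$phrase) == "")
  if (length(empty)) {
    abort_validation(paste0("row ", empty[1] + 1L, ": empty phrase for code '", d$code[empty[1]], "'"))
  }
  dup_p <- which(duplicated(trimws(d$phrase)))
  if (length(dup_p)) {
    abort_validation(paste0("row ", dup_p[1] + 1L, ": duplicate phrase '", d$phrase[dup_p[1]], "'"))
  }
  d <- as_tibble(d)
  d$phrase <- trimws(d$phrase)
  class(d) <- c("phrase_dictionary", class(d))
  attr(d, "language_tag") <- language_tag
  d
}

stopifnot_dictionary <- function(dict) {
  if (!inherits(dict, "phrase_dictionary")) {
    abort_validation("'dict' must be a phrase_dictionary from load_dictionary()")
  }
  invisible(dict)
}

#' Decode a gesture code to its phrase
#'
#' @param code A 3-letter gesture code (string or 3 letters).
#' @param dict A `phrase_dictionary`.
#' @return The phrase string for `code`.
#' @examples
#' decode_code("LLL", load_dictionary()) # "Water"
#' @export
decode_code <- function(code, dict = load_dictionary()) {
  stopifnot_dictionary(dict)
  code <- as_gesture_code(code)
  dict$phrase[match(code, dict$code)]
}

#' Encode a phrase back to its gesture code
#'
#' Inverse lookup; matching is exact after whitespace normalisation (phrases
#' are display strings, so case matters). Unknown phrases raise a lookup
#' error listing the nearest candidates.
#'
#' @param phrase A phrase present in the dictionary.
#' @param dict A `phrase_dictionary`.
#' @return The 3-letter gesture code.
#' @examples
#' encode_phrase("Water", load_dictionary()) # "LLL"
#' @export
encode_phrase <- function(phrase, dict = load_dictionary()) {
  stopifnot_dictionary(dict)
  if (!is.character(phrase) || length(phrase) != 1) {
    abort_input("'phrase' must be a single string")
  }
  key <- gsub("\\s+", " ", trimws(phrase))
  i <- match(key, dict$phrase)
  if (is.na(i)) {
    near <- dict$phrase[order(utils::adist(key, dict$phrase, ignore.case = TRUE))][1:3]
    abort(paste0("phrase not in dictionary: '", phrase, "'. Nearest: ",
                 paste(shQuote(near), collapse = ", ")),
          class = "eyespeak_lookup_error")
  }
  dict$code[i]
}
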