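# Pluggable translation and text-to-speech backends. The deployed system used
# cloud translation and Azure TTS; those are out of scope here, so offline
# default backends keep the interfaces testable: an identity translator and a
# TTS backend that logs the text.

the_backends <- new.env(parent = emptyenv())

#' Register a translation backend
#'
#' A backend is a function `function(phrase, target_language)` returning the
#' translated phrase, together with the set of language tags it supports.
#'
#' @param name Backend identifier.
#' @param translate Translation function.
#' @param languages Character vector of supported language tags.
#' @return `name`, invisibly.
#' @export
register_translation_backend <- function(name, translate, languages) {
  stopifnot(is.character(name), length(name) == 1, is.function(translate))
  the_backends[[paste0("translate_", name)]] <- list(fn = translate, languages = languages)
  invisible(name)
}

get_translation_backend <- function(name) {
  b <- the_backends[[paste0("translate_", name)]]
  if (is.null(b)) abort_config(paste0("unknown translation backend: '", name, "'"))
  b
}

#' Translate a phrase through a registered backend
#'
#' The default `identity` backend supports only `"en"` and returns its input
#' unchanged; a `table` backend can be registered from a named lookup for
#' offline tests of other languages.
#'
#' @param phrase Phrase text.
#' @param target_language Language tag the backend must support.
#' @param backend Backend name (default `"identity"`).
#' @return The rendered phrase.
#' @examples
#' translate_phrase("Water", "en") # "Water"
#' @export
translate_phrase <- function(phrase, target_language = "en", backend = "identity") {
  b <- get_translation_backend(backend)
  if (!target_language %in% b$languages) {
    abort_config(paste0("backend '", backend, "' does not support language '",
                        target_language, "' (supports: ",
                        paste(b$languages, collapse = ", "), ")"))
  }
  b$fn(phrase, target_language)
}

#' Register a table-based translation stub
#'
#' @param name Backend identifier.
#' @param table Named list: `table[[lang]][[phrase]] -> translation`.
#' @return `name`, invisibly.
#' @export
register_table_backend <- function(name, table) {
  register_translation_backend(name, function(phrase, lang) {
    out <- table[[lang]][[phrase]]
    if (is.null(out)) phrase else out
  }, languages = names(table))
}

#' Speak a phrase through a text-to-speech backend
#'
#' The default `log` backend emits the text as a message and records it; a
#' real synthesiser can be registered under another name with
#' [register_tts_backend()].
#'
#' @param phrase Phrase text.
#' @param backend TTS backend name.
#' @return The phrase, invisibly.
#' @export
speak_phrase <- function(phrase, backend = "log") {
  b <- the_backends[[paste0("tts_", backend)]]
  if (is.null(b)) abort_config(paste0("unknown TTS backend: '", backend, "'"))
  b(phrase)
  invisible(phrase)
}

#' Register a text-to-speech backend
#' @param name Backend identifier.
#' @param speak Function of one argument (the phrase).
#' @return `name`, invisibly.
#' @export
register_tts_backend <- function(name, speak) {
  stopifnot(is.function(speak))
  the_backends[[paste0("tts_", name)]] <- speak
  invisible(name)
}

# spoken phrases observable in tests
the_tts_log <- new.env(parent = emptyenv())
the_tts_log$lines <- character(0)

#' Retrieve (and optionally clear) the log-backend TTS transcript
#' @param clear Reset the log after reading.
#' @return Character vector of spoken phrases.
#' @export
tts_log <- function(clear = FALSE) {
  out <- the_tts_log$lines
  if (clear) the_tts_log$lines <- character(0)
  out
}

register_default_backends <- function() {
  register_translation_backend("identity", function(phrase, lang) phrase, languages = "en")
  register_tts_backend("log", function(phrase) {
    the_tts_log$lines <- c(the_tts_log$lines, phrase)
    inform(paste0("[tts] ", phrase))
  })
}

.onLoad <- function(libname, pkgname) {
  register_default_backends()
}
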