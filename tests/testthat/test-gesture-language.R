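test_that("capacity follows the n^k law and matches brute-force enumeration", {
  expect_identical(capacity(4, 3), 64L)
  expect_identical(capacity(1, 1), 1L)
  # oracle: count all length-k sequences over n symbols explicitly
  for (n in 1:5) {
    for (k in 1:4) {
      enumerated <- nrow(do.call(expand.grid, rep(list(seq_len(n)), k)))
      expect_identical(capacity(n, k), as.integer(enumerated))
    }
  }
  expect_error(capacity(0, 3), class = "eyespeak_input_error")
  expect_error(capacity(4, 2.5), class = "eyespeak_input_error")
  expect_error(capacity(-1, 1), class = "eyespeak_input_error")
})

test_that("bundled dictionary loads with 64 entries covering all codes", {
  d <- load_dictionary()
  expect_s3_class(d, "phrase_dictionary")
  expect_identical(nrow(d), 64L)
  all_codes <- sort(apply(expand.grid(c("L","R","U","B"), c("L","R","U","B"),
                                      c("L","R","U","B")), 1, paste, collapse = ""))
  expect_setequal(d$code, all_codes)
  expect_true(all(nzchar(d$phrase)))
  expect_false(any(duplicated(d$phrase)))
})

test_that("no-transition codes map to the basic-needs phrases", {
  d <- load_dictionary()
  expect_identical(decode_code("LLL", d), "Water")
  expect_identical(decode_code("RRR", d), "Food")
  expect_identical(decode_code("UUU", d), "Toilet")
  expect_identical(decode_code("BBB", d), "I am Okay")
})

test_that("dictionary validation names the offending row", {
  d <- load_dictionary()
  plain <- tibble::tibble(code = d$code, phrase = d$phrase)
  expect_error(load_dictionary(write_dict_tsv(plain[-5, ])),
               "63 entries", class = "eyespeak_validation_error")
  dup <- plain
  dup$code[10] <- "LLL"
  expect_error(load_dictionary(write_dict_tsv(dup)),
               "duplicate code 'LLL'", class = "eyespeak_validation_error")
  badlen <- plain
  badlen$code[3] <- "LLLL"
  expect_error(load_dictionary(write_dict_tsv(badlen)),
               "row 4", class = "eyespeak_validation_error")
  badletter <- plain
  badletter$code[1] <- "LLQ"
  expect_error(load_dictionary(write_dict_tsv(badletter)),
               class = "eyespeak_validation_error")
  empty_phrase <- plain
  empty_phrase$phrase[2] <- " "
  expect_error(load_dictionary(write_dict_tsv(empty_phrase)),
               "empty phrase", class = "eyespeak_validation_error")
  expect_error(load_dictionary(tempfile()), class = "eyespeak_io_error")
})

test_that("decode and encode are mutual inverses over all 64 codes", {
  d <- load_dictionary()
  for (code in d$code) {
    phrase <- decode_code(code, d)
    expect_identical(encode_phrase(phrase, d), code)
  }
  # spot values transcribed from the published tables
  expect_identical(decode_code("LRB", d), "I am not Okay")
  expect_identical(decode_code(c("B", "B", "U"), d), "Thank You")
  expect_identical(encode_phrase("Water", d), "LLL")
  expect_identical(encode_phrase("  Thank   You ", d), "BBU") # whitespace-normalised
})

test_that("unknown phrases raise a lookup error with nearest candidates", {
  d <- load_dictionary()
  err <- expect_error(encode_phrase("not a phrase", d), class = "eyespeak_lookup_error")
  expect_match(conditionMessage(err), "Nearest")
  expect_error(decode_code("LLQ", d), class = "eyespeak_validation_error")
  expect_error(decode_code("LL", d), class = "eyespeak_validation_error")
})

test_that("translation backends are pluggable with offline defaults", {
  expect_identical(translate_phrase("Water", "en"), "Water")
  expect_error(translate_phrase("Water", "xx"), class = "eyespeak_config_error")
  expect_error(translate_phrase("Water", "en", backend = "nope"),
               class = "eyespeak_config_error")
  register_table_backend("test_de", list(de = list(Water = "Wasser")))
  expect_identical(translate_phrase("Water", "de", backend = "test_de"), "Wasser")
  expect_identical(translate_phrase("Food", "de", backend = "test_de"), "Food") # stub round-trip
})

test_that("the log TTS backend records spoken phrases", {
  tts_log(clear = TRUE)
  expect_message(speak_phrase("Water"), "Water")
  expect_identical(tts_log(clear = TRUE), "Water")
  expect_error(speak_phrase("x", backend = "azure"), class = "eyespeak_config_error")
})
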