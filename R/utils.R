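# shared internal helpers

# numeric parse tolerating thousands separators inside quoted cells
# ("1,234.5" -> 1234.5); "" -> NA. Never warns.
parse_abundance <- function(x) {
  x <- stringr::str_trim(x)
  x[x == ""] <- NA_character_
  suppressWarnings(as.numeric(stringi::stri_replace_all_fixed(x, ",", "")))
}

is_numeric_like <- function(x) !is.na(parse_abundance(x))

# forward-fill blank cells with nearest non-blank value to the left
ffill_chr <- function(x) {
  last <- ""
  for (i in seq_along(x)) {
    if (!is.na(x[i]) && x[i] != "") last <- x[i] else x[i] <- last
  }
  x
}

# "sp|P12345|NAME" -> "P12345"; anything else unchanged
bare_accession <- function(token) {
  out <- token
  piped <- stringr::str_detect(token, "^[^|]+\\|[^|]+\\|")
  out[piped] <- stringr::str_split_i(token[piped], stringr::fixed("|"), 2)
  out
}

first_residue <- function(x) stringr::str_sub(x, 1L, 1L)
last_residue <- function(x) stringr::str_sub(x, -1L, -1L)

log_msg <- function(quiet, ...) if (!quiet) message(...)
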