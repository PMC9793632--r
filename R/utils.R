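# internal helpers shared across modules

# condition classes follow "nof1_error_<code>" so callers can branch on the
# specific failure (e.g. out-of-range scale value vs unknown measure)
abort_nof1 <- function(code, message, ...) {
  rlang::abort(message, class = c(paste0("nof1_error_", code), "nof1_error"), ...)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

is_nonempty_string <- function(x) is_string(x) && nzchar(trimws(x))

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x) && x >= min
}

# "HH:MM" on a 24h clock
is_hhmm <- function(x) {
  is.character(x) & !is.na(x) & grepl("^([01][0-9]|2[0-3]):[0-5][0-9]$", x)
}

hhmm_to_minutes <- function(x) {
  h <- as.integer(substr(x, 1, 2))
  m <- as.integer(substr(x, 4, 5))
  h * 60L + m
}

# timestamps are local, timezone-naive "YYYY-MM-DDTHH:MM:SS" strings
is_timestamp <- function(x) {
  is_string(x) &&
    grepl("^\\d{4}-\\d{2}-\\d{2}T\\d{2}:\\d{2}(:\\d{2})?$", x) &&
    !is.na(parse_timestamp(x))
}

parse_timestamp <- function(x) {
  as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

timestamp_date <- function(x) as.Date(substr(x, 1, 10))

now_timestamp <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%S")

new_id <- function() {
  # UUID-format random identifier (RFC 4122 layout, RNG-independent of
  # simulation streams is not required here; ids are opaque)
  bytes <- sample.int(256L, 16L, replace = TRUE) - 1L
  bytes[7] <- bitwOr(bitwAnd(bytes[7], 0x0FL), 0x40L)
  bytes[9] <- bitwOr(bitwAnd(bytes[9], 0x3FL), 0x80L)
  hex <- sprintf("%02x", bytes)
  paste0(
    paste(hex[1:4], collapse = ""), "-", paste(hex[5:6], collapse = ""), "-",
    paste(hex[7:8], collapse = ""), "-", paste(hex[9:10], collapse = ""), "-",
    paste(hex[11:16], collapse = "")
  )
}

# drop NULL entries so optional fields are absent, not null
compact_list <- function(x) x[!vapply(x, is.null, logical(1))]

`%||%` <- function(a, b) if (is.null(a)) b else a
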