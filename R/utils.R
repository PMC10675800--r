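# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding; printed
# summary tables in pharmacovigilance reports round 1.045 -> 1.05).
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Locale-independent character ordering, so output row order is identical
# across machines.
c_order <- function(...) order(..., method = "radix")

c_sort <- function(x) sort(x, method = "radix")

# Write a tibble as TSV with deterministic formatting (no quoting; NA -> "").
write_tsv_plain <- function(x, path) {
  df <- as.data.frame(x)
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      df[[j]] <- format(df[[j]], digits = 15, trim = TRUE, scientific = FALSE)
      df[[j]][df[[j]] %in% c("NA", "NaN")] <- ""
    } else {
      df[[j]] <- as.character(df[[j]])
      df[[j]][is.na(df[[j]])] <- ""
    }
  }
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df)) do.call(paste, c(unname(df), sep = "\t"))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_tsv_plain <- function(path) {
  df <- utils::read.delim(path, sep = "\t", colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  as_tibble(df)
}
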