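# shared internal helpers

# read a comma- or tab-delimited UTF-8 table, sniffing the separator from
# the header line (tab wins if present)
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, check.names = TRUE, fill = TRUE,
                    comment.char = "", fileEncoding = "UTF-8",
                    colClasses = "character")
}

# round half away from zero (printed-table convention; avoids the IEEE
# round-half-even behaviour of base round())
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
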