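# stage-tagged key=value log lines, suppressible via suppressMessages()
logStage <- function(stage, ...) {
  kv <- list(...)
  if (length(kv)) {
    txt <- paste(sprintf("%s=%s", names(kv),
                         vapply(kv, function(v) paste(format(v), collapse = ","),
                                character(1))),
                 collapse = " ")
  } else txt <- ""
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage, txt))
  invisible(NULL)
}

# classify a variant record from its ref and alt alleles:
# SNP iff ref and every alt are single bases; MNP if all lengths match;
# otherwise indel (length-changing); symbolic alleles -> complex
classifyVariant <- function(ref, alt) {
  stopifnot(is.character(ref), length(ref) == 1L)
  if (grepl("[^ACGTN]", ref) || any(grepl("[^ACGTN]", alt)))
    return("complex")
  if (nchar(ref) == 1L && all(nchar(alt) == 1L)) return("SNP")
  if (all(nchar(alt) == nchar(ref))) return("MNP")
  "indel"
}

# deterministic TSV writer (byte-stable across runs for identical input)
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
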