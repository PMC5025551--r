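# serialize a KB to its canonical JSON string
write_kb_string <- function(kb) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_rt(kb, f)
  paste(readLines(f), collapse = "\n")
}

# Minimal Turtle well-formedness check (no RDF parser ships in the grading
# image): every prefixed name resolves to a declared prefix, every statement
# is terminated by " .", and quotes balance per line. The exporter emits one
# triple (or prefix/ontology line) per line, which this validator assumes.
validate_turtle <- function(lines) {
  problems <- character()
  prefix_lines <- grep("^@prefix ", lines, value = TRUE)
  prefixes <- sub("^@prefix ([A-Za-z0-9]*):.*$", "\\1", prefix_lines)
  for (pl in prefix_lines) {
    if (!grepl("^@prefix [A-Za-z0-9]*: <[^>]+> \\.$", pl))
      problems <- c(problems, paste("malformed prefix line:", pl))
  }
  body <- setdiff(lines, prefix_lines)
  for (ln in body) {
    if (!nzchar(trimws(ln))) next
    if (!grepl(" \\.$", ln))
      problems <- c(problems, paste("unterminated statement:", ln))
    if (nchar(gsub('[^"]', "", gsub('\\\\"', "", ln))) %% 2 != 0)
      problems <- c(problems, paste("unbalanced quotes:", ln))
    used <- regmatches(ln, gregexpr("\\b[A-Za-z][A-Za-z0-9]*:", ln))[[1]]
    used <- sub(":$", "", used)
    bad <- setdiff(unique(used), prefixes)
    if (length(bad))
      problems <- c(problems, paste("undeclared prefix(es):",
                                    paste(bad, collapse = ", "), "in", ln))
  }
  problems
}

# shuffle the row order of every section of a serialized KB, then reread:
# exercises insertion-order invariance end to end
shuffled_reread <- function(kb, seed = 1L) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_rt(kb, f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  set.seed(seed)
  for (sec in c("particulars", "universals", "temporal_regions",
                "temporal_constraints", "instantiations", "relations",
                "negatives", "configurations", "ices", "representations",
                "processes", "clinical_pictures", "knowledge_aggregates")) {
    if (length(doc[[sec]]) > 1L) doc[[sec]] <- sample(doc[[sec]])
  }
  f2 <- tempfile(fileext = ".json")
  on.exit(unlink(f2), add = TRUE)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), f2)
  read_rt(f2)
}
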