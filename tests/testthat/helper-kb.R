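# Shared fixtures: the bundled knowledge base (built once per test run) and
# small helpers for running single sentences.

test_kb <- fixture_kb()

run_one <- function(text, ...) {
  run_pipeline(text, test_kb, run_options(...))
}

triples_of <- function(result) {
  df <- predications(result)
  if (!nrow(df)) return(character())
  paste(df$subj_name, df$predicate, df$obj_name, sep = "|")
}

annotate_one <- function(text, kb = test_kb, ...) {
  annotate_sentence(text, kb, run_options(...))
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
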