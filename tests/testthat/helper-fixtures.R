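# Shared study conditions for the end-to-end fixture tests: an 8-strand
# barrel with 9-residue strands, and a filter trained on 10 synthetic
# structures. Built once per test run.
fixture_config <- function(...) {
  run_config(strand_len_bounds = c(6L, 12L), max_leader = 12L,
             max_trailer = 12L, ...)
}

fixture_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      tab <<- train_block_table(make_training_set(10, seed = 42), l = 3L,
                                pseudocount = 1)
    }
    tab
  }
})

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
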