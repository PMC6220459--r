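# Small genotype tables built in code; no fixture files on disk.

gt <- function(ids, calls, chrom = "1", pos = NULL, sample_id = "S") {
  new_genotype_table(
    tibble::tibble(
      locus_id = ids,
      chromosome = rep_len(chrom, length(ids)),
      position = pos %||% seq_along(ids),
      call = calls
    ),
    sample_id = sample_id
  )
}

`%||%` <- rlang::`%||%`

# Write a canonical-dialect file with an optional preamble, returning its path.
write_fixture_file <- function(rows, preamble = character(), eol = "\n",
                               header = "ProbeName\tChromosome\tPosition\tGenotype") {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  con <- file(path, open = "wb")
  writeLines(c(preamble, header, rows), con, sep = eol, useBytes = TRUE)
  close(con)
  path
}

# Independent per-locus oracle: the filter + classification re-derived as a
# naive scalar loop, kept deliberately separate from the vectorized
# implementation it checks.
oracle_classify <- function(call_p, call_q) {
  hom <- function(x) {
    !is.na(x) && nchar(x) == 2L && substr(x, 1, 1) == substr(x, 2, 2)
  }
  if (!hom(call_p) || !hom(call_q)) return("removed")
  if (call_p == call_q) "concordant" else "discordant"
}
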