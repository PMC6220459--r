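#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
NULL

# tokens vendor exports use for a failed genotype call (compared lower-case)
.nocall_tokens <- c("nocall", "no call", "nc", "na", "")

# canonical export dialect: semantic field -> header name
.default_column_map <- c(
  locus_id   = "ProbeName",
  chromosome = "Chromosome",
  position   = "Position",
  call       = "Genotype"
)

#' Normalize genotype call strings
#'
#' Uppercases calls, maps vendor no-call tokens (`NoCall`, `NC`, `NA`, empty;
#' case-insensitive) to `NA`, and sorts the two alleles of a two-copy call so
#' `"TA"` and `"AT"` are the same genotype. Calls of length 1 or >= 3 (one- or
#' three-copy states from copy-number gains/losses) are kept verbatim apart
#' from uppercasing.
#'
#' @param call Character vector of raw genotype call strings.
#' @return Character vector of normalized calls; `NA` marks a no-call.
#' @examples
#' normalize_call(c("TA", "aa", "NoCall", "AAA"))
#' @export
normalize_call <- function(call) {
  call <- toupper(trimws(call))
  call[is.na(call) | tolower(call) %in% .nocall_tokens] <- NA_character_
  two <- !is.na(call) & nchar(call) == 2L
  if (any(two)) {
    a1 <- substr(call[two], 1L, 1L)
    a2 <- substr(call[two], 2L, 2L)
    swap <- a1 > a2
    call[two][swap] <- paste0(a2[swap], a1[swap])
  }
  call
}

#' Construct a genotype table
#'
#' A genotype table is a tibble with one row per SNP probe and columns
#' `locus_id`, `chromosome`, `position`, `call`, carrying the sample
#' identifier as an attribute. Calls are normalized with [normalize_call()]
#' and validated: a call must be `NA` (no-call) or match `[ACGT]+`, and
#' `locus_id` values must be non-empty and unique.
#'
#' @param records Data frame with at least `locus_id` and `call`; optional
#'   `chromosome` and `position`.
#' @param sample_id Identifier for the individual the table belongs to.
#' @return A `genotype_table` tibble.
#' @examples
#' new_genotype_table(
#'   data.frame(locus_id = c("rs1", "rs2"), call = c("AA", "TA")),
#'   sample_id = "NA12878"
#' )
#' @export
new_genotype_table <- function(records, sample_id = "sample") {
  records <- as_tibble(records)
  if (!all(c("locus_id", "call") %in% names(records))) {
    abort("`records` must contain `locus_id` and `call` columns.")
  }
  if (nrow(records) < 1L) {
    abort("a genotype table must contain at least one record.")
  }
  records$locus_id <- as.character(records$locus_id)
  if (anyNA(records$locus_id) || any(!nzchar(records$locus_id))) {
    abort("`locus_id` values must be non-empty.")
  }
  dup <- records$locus_id[duplicated(records$locus_id)]
  if (length(dup)) {
    abort(sprintf(
      "duplicate locus_id in genotype table: %s",
      paste(unique(dup), collapse = ", ")
    ))
  }
  records$call <- normalize_call(as.character(records$call))
  bad <- !is.na(records$call) & !grepl("^[ACGT]+$", records$call)
  if (any(bad)) {
    abort(sprintf(
      "invalid genotype call(s) at locus %s: calls must match [ACGT]+ or be a no-call token.",
      paste(utils::head(records$locus_id[bad], 5L), collapse = ", ")
    ))
  }
  if (!"chromosome" %in% names(records)) records$chromosome <- NA_character_
  records$chromosome <- as.character(records$chromosome)
  if (!"position" %in% names(records)) records$position <- NA_integer_
  records$position <- as.integer(records$position)
  if (any(!is.na(records$position) & records$position < 0L)) {
    abort("`position` must be a non-negative 1-based coordinate.")
  }
  out <- records[, c("locus_id", "chromosome", "position", "call")]
  attr(out, "sample_id") <- as.character(sample_id)
  class(out) <- c("genotype_table", class(out))
  out
}

#' Sample identifier of a genotype table
#'
#' @param table A `genotype_table`.
#' @return The sample identifier string (or `NULL` for a plain data frame).
#' @export
sample_id <- function(table) attr(table, "sample_id", exact = TRUE)

#' Read a per-sample SNP genotype export
#'
#' Reads a tab-separated genotype table as written by array analysis software:
#' any preamble lines before the header row are skipped (the header is the
#' first line containing all required column names), Windows line endings and
#' trailing whitespace are tolerated, genotype calls are uppercased, vendor
#' no-call tokens become `NA`, and the alleles of two-copy calls are sorted so
#' heterozygote detection is order-free.
#'
#' @param path Path to a tab-separated text file with one header row.
#' @param column_map Named character vector overriding the expected header
#'   names for any of `locus_id`, `chromosome`, `position`, `call`. Defaults
#'   to `ProbeName`, `Chromosome`, `Position`, `Genotype`. Only `locus_id` and
#'   `call` are required to be present in the file.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return A `genotype_table` tibble preserving file order.
#' @seealso [write_genotype_table()] for the canonical dialect writer.
#' @export
read_genotype_table <- function(path, column_map = NULL, sample_id = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("genotype file not found: %s", path))
  }
  cmap <- .default_column_map
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(cmap))
    if (length(unknown)) {
      abort(sprintf("unknown column_map field(s): %s", paste(unknown, collapse = ", ")))
    }
    cmap[names(column_map)] <- column_map
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  required <- cmap[c("locus_id", "call")]

  header_at <- NA_integer_
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    if (all(required %in% fields)) {
      header_at <- i
      header <- fields
      break
    }
  }
  if (is.na(header_at)) {
    abort(sprintf(
      "no header row found in %s: need tab-separated columns %s.",
      path, paste(sprintf("'%s'", required), collapse = " and ")
    ))
  }

  body <- lines[-seq_len(header_at)]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) {
    abort(sprintf("no data rows found in %s after the header (line %d).", path, header_at))
  }
  split_rows <- strsplit(body, "\t", fixed = TRUE)
  n_col <- length(header)
  cells <- vapply(split_rows, function(x) {
    length(x) <- n_col
    trimws(x)
  }, character(n_col))
  cells <- if (n_col == 1L) matrix(cells, nrow = 1L) else cells

  pick <- function(field) {
    j <- match(cmap[[field]], header)
    if (is.na(j)) rep(NA_character_, length(body)) else cells[j, ]
  }
  records <- tibble(
    locus_id   = pick("locus_id"),
    chromosome = pick("chromosome"),
    position   = suppressWarnings(as.integer(pick("position"))),
    call       = pick("call")
  )
  withCallingHandlers(
    new_genotype_table(records, sample_id = sample_id %||%
      sub("\\.[^.]*$", "", basename(path))),
    error = function(e) {
      abort(sprintf("while parsing %s: %s", path, conditionMessage(e)))
    }
  )
}

#' Write a genotype table in the canonical dialect
#'
#' Writes tab-separated text with columns `ProbeName`, `Chromosome`,
#' `Position`, `Genotype` and the token `NoCall` for missing calls, so that a
#' table written here and re-read with [read_genotype_table()] round-trips
#' record-by-record. Output is byte-identical across runs.
#'
#' @param table A `genotype_table`.
#' @param path Output file path or connection.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  stopifnot(is.data.frame(table), nrow(table) >= 1L)
  call <- ifelse(is.na(table$call), "NoCall", table$call)
  chrom <- ifelse(is.na(table$chromosome), "", table$chromosome)
  pos <- ifelse(is.na(table$position), "", format(table$position, scientific = FALSE, trim = TRUE))
  lines <- c(
    paste("ProbeName", "Chromosome", "Position", "Genotype", sep = "\t"),
    paste(table$locus_id, chrom, pos, call, sep = "\t")
  )
  con <- if (inherits(path, "connection")) path else {
    f <- file(path, open = "wb")
    on.exit(close(f))
    f
  }
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a verdict report
#'
#' Writes one tab-separated row per pairing with columns `proband_id`,
#' `parent_id`, `role`, `n_informative`, `n_concordant`, `n_discordant`,
#' `proportion_discordant` (fixed six-decimal formatting) and `verdict`; a
#' `trio_verdict` column (and any further columns such as `pairing` or
#' `caution`) is carried through when present. Output is byte-identical
#' across runs for identical inputs.
#'
#' @param results Tibble of pair verdicts as produced by [call_pair()], with
#'   a `role` column; optionally annotated with `trio_verdict`.
#' @param path Output file path or connection.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) < 1L) {
    abort("`results` must be a non-empty data frame of verdicts; nothing written.")
  }
  core <- c("proband_id", "parent_id", "role", "n_informative", "n_concordant",
            "n_discordant", "proportion_discordant", "verdict")
  missing <- setdiff(core, names(results))
  if (length(missing)) {
    abort(sprintf("`results` lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  extra <- intersect(c("trio_verdict", setdiff(names(results), core)), names(results))
  out <- results[, c(core, extra)]
  fmt <- function(x) {
    if (is.double(x)) {
      ifelse(is.na(x), "NA", sprintf("%.6f", x))
    } else {
      x <- as.character(x)
      ifelse(is.na(x), "NA", x)
    }
  }
  cols <- lapply(out, fmt)
  lines <- c(
    paste(names(out), collapse = "\t"),
    do.call(paste, c(cols, sep = "\t"))
  )
  con <- if (inherits(path, "connection")) path else {
    f <- file(path, open = "wb")
    on.exit(close(f))
    f
  }
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
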