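#' @importFrom stats median rbinom runif setNames
NULL

#' Is a chromosome label an autosome?
#'
#' Labels are compared case-insensitively with an optional `chr` prefix
#' stripped; `1`..`22` are autosomes, anything else (`X`, `Y`, `MT`, missing)
#' is not.
#'
#' @param chromosome Character vector of chromosome labels.
#' @return Logical vector.
#' @export
is_autosome <- function(chromosome) {
  lab <- sub("^chr", "", tolower(trimws(as.character(chromosome))))
  !is.na(lab) & grepl("^[0-9]+$", lab) & as.integer(ifelse(grepl("^[0-9]+$", lab), lab, NA)) %in% 1:22
}

#' Merge two genotype tables on locus identifier
#'
#' Inner join on `locus_id` (never on coordinates): returns exactly the loci
#' present in both tables, ordered by `locus_id` for determinism. Chromosome
#' labels are taken from the proband table, falling back to the parent's
#' where missing.
#'
#' @param proband,parent `genotype_table` tibbles (or data frames with
#'   `locus_id`, `call` and optionally `chromosome`).
#' @return Tibble with columns `locus_id`, `chromosome`, `call_proband`,
#'   `call_parent`.
#' @export
merge_on_locus <- function(proband, parent) {
  shared <- sort(intersect(proband$locus_id, parent$locus_id))
  if (!length(shared)) {
    abort("no shared loci between the two tables: incompatible array designs.")
  }
  ip <- match(shared, proband$locus_id)
  im <- match(shared, parent$locus_id)
  chrom_p <- if ("chromosome" %in% names(proband)) proband$chromosome[ip] else NA_character_
  chrom_m <- if ("chromosome" %in% names(parent)) parent$chromosome[im] else NA_character_
  tibble(
    locus_id     = shared,
    chromosome   = dplyr::coalesce(as.character(chrom_p), as.character(chrom_m)),
    call_proband = proband$call[ip],
    call_parent  = parent$call[im]
  )
}

.is_two_copy_homozygote <- function(call) {
  !is.na(call) & nchar(call) == 2L & substr(call, 1L, 1L) == substr(call, 2L, 2L)
}

#' Is a merged locus informative?
#'
#' A locus is informative when both calls are two-copy homozygotes: exactly
#' two characters long, both characters identical, neither a no-call.
#' Heterozygotes, no-calls and one- or three-copy calls (copy-number gains or
#' losses, e.g. `"A"` or `"AAA"`) in either sample disqualify the locus, as
#' does a non-autosomal chromosome when `autosomes_only` is set.
#'
#' @param call_proband,call_parent Character vectors of normalized calls
#'   (`NA` = no-call).
#' @param chromosome Chromosome labels for the loci (may be `NA`; loci with
#'   missing labels are treated as autosomal).
#' @param autosomes_only Restrict to autosomes? Default `TRUE`: hemizygous
#'   male X calls violate the two-copy assumption and would inflate
#'   father-son discordance.
#' @return Logical vector.
#' @export
is_informative <- function(call_proband, call_parent,
                           chromosome = NA_character_,
                           autosomes_only = TRUE) {
  ok <- .is_two_copy_homozygote(call_proband) & .is_two_copy_homozygote(call_parent)
  if (autosomes_only) {
    ok <- ok & (is.na(chromosome) | is_autosome(chromosome))
  }
  ok
}

#' Classify an informative locus as concordant or discordant
#'
#' Both calls must already be two-copy homozygotes (see [is_informative()]).
#' The locus is concordant when the call strings are identical and discordant
#' otherwise — a `TT` parent cannot have an `AA` child, so a discordant locus
#' is Mendelian-impossible for a true parent-child pair absent genotyping
#' error. The relation is symmetric in its arguments.
#'
#' @param call_proband,call_parent Two-copy homozygous call strings.
#' @return Character vector, `"concordant"` or `"discordant"`.
#' @export
classify_locus <- function(call_proband, call_parent) {
  if (!all(.is_two_copy_homozygote(call_proband) & .is_two_copy_homozygote(call_parent))) {
    abort("classify_locus() requires two-copy homozygous calls in both samples; filter with is_informative() first.")
  }
  ifelse(call_proband == call_parent, "concordant", "discordant")
}

#' Compare a proband against one putative parent
#'
#' The pairwise procedure: merge the two tables on locus, keep only loci
#' homozygous-in-both (dropping heterozygous, no-call and copy-number-abnormal
#' calls in either sample), classify each survivor as concordant or
#' discordant, and report counts together with the decision statistic
#' `proportion_discordant = n_discordant / n_informative`. The proportion —
#' rather than the absolute discordant count — is used downstream because the
#' number of informative loci varies with relatedness and assay quality.
#'
#' @param proband,parent `genotype_table` tibbles.
#' @param autosomes_only Restrict to autosomes (default `TRUE`). If no
#'   chromosome labels are present at all, every locus is treated as
#'   autosomal and a warning is emitted.
#' @param min_informative Evidence floor: a warning is emitted when fewer
#'   informative loci survive (the platform supplies roughly 30,000 loci, so
#'   drastic shrinkage indicates an input problem). Default 1000.
#' @return One-row tibble with `proband_id`, `parent_id`, `n_merged`,
#'   `n_informative`, `n_concordant`, `n_discordant`,
#'   `proportion_discordant` (`NA` when no locus is informative).
#' @examples
#' p <- new_genotype_table(data.frame(
#'   locus_id = c("rs1", "rs2", "rs3"), chromosome = "1",
#'   call = c("AA", "AT", "TT")), "child")
#' q <- new_genotype_table(data.frame(
#'   locus_id = c("rs1", "rs2", "rs3"), chromosome = "1",
#'   call = c("AA", "AA", "AA")), "father")
#' compare_pair(p, q, min_informative = 0)
#' @export
compare_pair <- function(proband, parent, autosomes_only = TRUE,
                         min_informative = 1000L) {
  merged <- merge_on_locus(proband, parent)
  if (autosomes_only && all(is.na(merged$chromosome))) {
    warn("no chromosome labels in either table; treating all loci as autosomal.")
  }
  info <- is_informative(merged$call_proband, merged$call_parent,
                         merged$chromosome, autosomes_only = autosomes_only)
  n_informative <- sum(info)
  n_discordant <- sum(info & merged$call_proband != merged$call_parent)
  pid <- sample_id(proband) %||% "proband"
  qid <- sample_id(parent) %||% "parent"
  if (n_informative == 0L) {
    warn(sprintf("comparison %s vs %s is uninformative: no homozygous-in-both loci.", pid, qid))
  } else if (n_informative < min_informative) {
    warn(sprintf(
      "low evidence for %s vs %s: only %d informative loci (floor %d).",
      pid, qid, n_informative, as.integer(min_informative)
    ))
  }
  tibble(
    proband_id = pid,
    parent_id = qid,
    n_merged = nrow(merged),
    n_informative = n_informative,
    n_concordant = n_informative - n_discordant,
    n_discordant = n_discordant,
    proportion_discordant = if (n_informative > 0L) n_discordant / n_informative else NA_real_
  )
}

#' Summarize a set of pair comparisons
#'
#' Median and range of the discordant proportion, discordant count and
#' concordant count across comparisons — the three quantities used to judge
#' whether matched and mismatched pairings separate. For an even number of
#' comparisons the median is the midpoint of the two central order statistics
#' (so 20 pairs can yield a median count of 39.5).
#'
#' @param comparisons Tibble of pair comparisons from [compare_pair()].
#' @return Tibble with one row per metric and columns `metric`, `median`,
#'   `min`, `max`. Uninformative comparisons (`NA` proportion) are excluded
#'   from the proportion row.
#' @export
summarize_comparisons <- function(comparisons) {
  if (!is.data.frame(comparisons) || nrow(comparisons) < 1L) {
    abort("`comparisons` must be a non-empty data frame.")
  }
  one <- function(metric) {
    x <- comparisons[[metric]]
    tibble(metric = metric,
           median = median(x, na.rm = TRUE),
           min = suppressWarnings(min(x, na.rm = TRUE)),
           max = suppressWarnings(max(x, na.rm = TRUE)))
  }
  dplyr::bind_rows(lapply(
    c("proportion_discordant", "n_discordant", "n_concordant"), one
  ))
}
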