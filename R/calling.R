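#' Call a pairing true-pair or false-pair
#'
#' Applies the clinical decision rule to one or more pair comparisons: a
#' true-pair is called only when `proportion_discordant` is strictly below
#' the threshold (default 0.015); otherwise a false-pair. A comparison with
#' no informative loci gets the verdict `"uninformative"` — never a
#' true-pair, since parentage cannot be asserted on empty evidence. Verdicts
#' additionally carry an advisory `caution` flag when the proportion falls in
#' a band between the typical true-pair and unrelated-stranger regimes
#' (default `[0.015, 0.05)`): such intermediate values can arise from close
#' relatives or degraded specimens and deserve manual review.
#'
#' @param comparisons Tibble of pair comparisons from [compare_pair()] or
#'   [cross_match_cohort()].
#' @param threshold Discordant-proportion cut-off in (0, 1); default 0.015.
#' @param caution_band Length-2 numeric `[lo, hi)` for the advisory flag, or
#'   `NULL` to disable.
#' @return `comparisons` with `verdict` (`"true-pair"`, `"false-pair"`,
#'   `"uninformative"`) and logical `caution` columns added.
#' @examples
#' call_pair(tibble::tibble(
#'   proband_id = "p", parent_id = "m", n_merged = 30000L,
#'   n_informative = 12000L, n_concordant = 11961L, n_discordant = 39L,
#'   proportion_discordant = 39 / 12000
#' ))
#' @export
call_pair <- function(comparisons, threshold = 0.015,
                      caution_band = c(0.015, 0.05)) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    abort("`threshold` must be a single number in (0, 1).")
  }
  p <- comparisons$proportion_discordant
  comparisons$verdict <- dplyr::case_when(
    comparisons$n_informative == 0L | is.na(p) ~ "uninformative",
    p < threshold ~ "true-pair",
    TRUE ~ "false-pair"
  )
  comparisons$caution <- if (is.null(caution_band)) {
    FALSE
  } else {
    !is.na(p) & p >= caution_band[[1L]] & p < caution_band[[2L]]
  }
  comparisons
}

#' Call trios from paired mother and father verdicts
#'
#' A trio is confirmed (`"true trio"`) only when both the mother-proband and
#' father-proband pairings are true-pairs; it is a `"false trio"` when either
#' is a false-pair, and `"uninformative"` when either pairing could not be
#' evaluated — an uninformative member forces re-testing rather than a
#' clinically loaded claim either way.
#'
#' @param pair_verdicts Tibble from [call_pair()] with a `role` column
#'   (`"mother"` or `"father"`); each proband must contribute exactly one
#'   verdict per role.
#' @return Tibble with one row per proband: `proband_id`, `mother_id`,
#'   `father_id`, `mother_verdict`, `father_verdict`, `trio_verdict`.
#' @export
call_trio <- function(pair_verdicts) {
  needed <- c("proband_id", "parent_id", "role", "verdict")
  missing <- setdiff(needed, names(pair_verdicts))
  if (length(missing)) {
    abort(sprintf("`pair_verdicts` lacks column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!all(pair_verdicts$role %in% c("mother", "father"))) {
    abort('`role` must be "mother" or "father".')
  }
  pair_verdicts %>%
    dplyr::group_by(.data$proband_id) %>%
    dplyr::group_modify(function(df, key) {
      m <- df[df$role == "mother", ]
      f <- df[df$role == "father", ]
      if (nrow(m) != 1L || nrow(f) != 1L) {
        abort(sprintf(
          "proband %s needs exactly one mother and one father verdict (got %d mother, %d father); check proband identifiers.",
          key$proband_id, nrow(m), nrow(f)
        ))
      }
      verdicts <- c(m$verdict, f$verdict)
      tibble(
        mother_id = m$parent_id,
        father_id = f$parent_id,
        mother_verdict = m$verdict,
        father_verdict = f$verdict,
        trio_verdict = if (any(verdicts == "uninformative")) {
          "uninformative"
        } else if (all(verdicts == "true-pair")) {
          "true trio"
        } else {
          "false trio"
        }
      )
    }) %>%
    dplyr::ungroup()
}

.as_cohort <- function(x, pedigree) {
  if (inherits(x, "simulated_cohort") ||
      (is.list(x) && !is.data.frame(x) && all(c("tables", "pedigree") %in% names(x)))) {
    list(tables = x$tables, pedigree = x$pedigree)
  } else {
    if (is.null(pedigree)) {
      abort("`pedigree` is required when `x` is a plain list of genotype tables.")
    }
    list(tables = x, pedigree = pedigree)
  }
}

#' Cross-match every proband against every parent in a cohort
#'
#' The validation design for a cohort of T putative trios: each proband is
#' compared with its own mother and father (2T matched pairings) and with
#' every parent belonging to another trio (2T(T-1) artificially mismatched
#' pairings), so every proband meets every parent exactly once (2T^2
#' comparisons in total). Matched and mismatched discordant-proportion
#' distributions are summarized separately; with a working assay they do not
#' overlap and the threshold separates them perfectly.
#'
#' @param x A `simulated_cohort`, a list with `tables` and `pedigree`
#'   elements, or a named list of `genotype_table`s (then supply `pedigree`).
#' @param pedigree Tibble with columns `trio`, `proband`, `mother`, `father`
#'   naming the tables; only needed when `x` is a plain list.
#' @param threshold,caution_band Passed to [call_pair()].
#' @param autosomes_only,min_informative Passed to [compare_pair()].
#' @return A `cross_match` object: list with `comparisons` (one row per
#'   pairing with `pairing` = matched/mismatched, `role`, verdicts),
#'   `summary` (per-pairing medians and ranges), `threshold`, `n_trios`.
#'   Use [tidy()], [glance()] and [ggplot2::autoplot()] on it.
#' @export
cross_match_cohort <- function(x, pedigree = NULL, threshold = 0.015,
                               caution_band = c(0.015, 0.05),
                               autosomes_only = TRUE, min_informative = 1000L) {
  cohort <- .as_cohort(x, pedigree)
  ped <- as_tibble(cohort$pedigree)
  tables <- cohort$tables
  t_n <- nrow(ped)
  if (is.null(t_n) || t_n < 2L) {
    abort("cross-matching needs at least 2 trios: with a single trio no mismatched pairing can be constructed.")
  }
  needed <- unique(c(ped$proband, ped$mother, ped$father))
  absent <- setdiff(needed, names(tables))
  if (length(absent)) {
    abort(sprintf("pedigree names samples with no genotype table: %s", paste(absent, collapse = ", ")))
  }

  grid <- do.call(rbind, lapply(seq_len(t_n), function(i) {
    do.call(rbind, lapply(seq_len(t_n), function(j) {
      data.frame(
        proband = ped$proband[[i]],
        parent = c(ped$mother[[j]], ped$father[[j]]),
        role = c("mother", "father"),
        pairing = if (i == j) "matched" else "mismatched",
        stringsAsFactors = FALSE
      )
    }))
  }))

  comparisons <- purrr::pmap(grid, function(proband, parent, role, pairing) {
    cmp <- compare_pair(tables[[proband]], tables[[parent]],
                        autosomes_only = autosomes_only,
                        min_informative = min_informative)
    cmp$proband_id <- proband
    cmp$parent_id <- parent
    cmp$role <- role
    cmp$pairing <- pairing
    cmp
  }) %>%
    dplyr::bind_rows() %>%
    call_pair(threshold = threshold, caution_band = caution_band)

  summary <- comparisons %>%
    dplyr::group_by(.data$pairing) %>%
    dplyr::group_modify(~ summarize_comparisons(.x)) %>%
    dplyr::ungroup()

  structure(
    list(comparisons = comparisons, summary = summary,
         threshold = threshold, n_trios = t_n),
    class = "cross_match"
  )
}

#' @export
print.cross_match <- function(x, ...) {
  cat(sprintf("Cross-match of %d trios: %d pairings (%d matched, %d mismatched), threshold %g\n",
              x$n_trios, nrow(x$comparisons),
              sum(x$comparisons$pairing == "matched"),
              sum(x$comparisons$pairing == "mismatched"),
              x$threshold))
  print(x$summary)
  invisible(x)
}

#' Tidy a cross-match result
#'
#' @param x A `cross_match` object.
#' @param ... Unused.
#' @return The per-pairing comparison tibble (one row per proband-parent
#'   pairing with counts, proportion, verdict).
#' @method tidy cross_match
#' @export
tidy.cross_match <- function(x, ...) x$comparisons

#' One-row summary of a cross-match result
#'
#' @param x A `cross_match` object.
#' @param ... Unused.
#' @return One-row tibble: pairing counts, matched/mismatched medians and
#'   extremes of the discordant proportion, the threshold, and
#'   `perfect_separation` (are all matched pairings true-pairs and all
#'   mismatched ones false-pairs?).
#' @method glance cross_match
#' @export
glance.cross_match <- function(x, ...) {
  cmp <- x$comparisons
  m <- cmp[cmp$pairing == "matched", ]
  u <- cmp[cmp$pairing == "mismatched", ]
  tibble(
    n_trios = x$n_trios,
    n_matched = nrow(m),
    n_mismatched = nrow(u),
    matched_median_proportion = median(m$proportion_discordant, na.rm = TRUE),
    matched_max_proportion = max(m$proportion_discordant, na.rm = TRUE),
    mismatched_median_proportion = median(u$proportion_discordant, na.rm = TRUE),
    mismatched_min_proportion = min(u$proportion_discordant, na.rm = TRUE),
    threshold = x$threshold,
    perfect_separation = all(m$verdict == "true-pair") && all(u$verdict == "false-pair")
  )
}

#' Plot matched vs mismatched discordant proportions
#'
#' One point per pairing, grouped by matched/mismatched, with the decision
#' threshold as a dashed line — the visual check that the two distributions
#' are disjoint.
#'
#' @param object A `cross_match` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cross_match
#' @export
autoplot.cross_match <- function(object, ...) {
  ggplot2::ggplot(object$comparisons,
                  ggplot2::aes(x = .data$pairing, y = .data$proportion_discordant)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$threshold,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL, y = "proportion of discordant loci",
                  title = sprintf("Cross-match of %d trios", object$n_trios),
                  subtitle = sprintf("dashed line: true-pair threshold %g", object$threshold)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cross_match
#' @export
plot_cross_match <- function(object, ...) autoplot.cross_match(object, ...)
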