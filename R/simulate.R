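#' Simulation parameters for synthetic genotype cohorts
#'
#' Captures the statistical regime the parentage check assumes: a panel of
#' polymorphic biallelic SNPs (the clinical platform genotypes roughly
#' 30,000), founders in Hardy-Weinberg equilibrium, and three independent
#' per-genotype noise layers emulating assay artefacts — no-calls,
#' copy-number-abnormal one- or three-copy calls, and miscalls.
#'
#' @param n_loci Number of SNP loci on the shared panel; default 30000.
#' @param maf_sampler Minor-allele-frequency sampler: either a length-2
#'   numeric range for a uniform draw (default `c(0.05, 0.5)`, i.e. common
#'   polymorphic SNPs) or a function of `n` returning `n` frequencies in
#'   (0, 0.5].
#' @param error_rate Per-genotype miscall probability; default 0.002.
#' @param nocall_rate Per-genotype no-call probability; default 0.005.
#' @param cn_abnormal_rate Per-genotype probability of a one- or three-copy
#'   call; default 0.001.
#' @param seed Integer seed applied by stream-starting generators
#'   ([draw_allele_frequencies()], [simulate_founder()],
#'   [simulate_cohort()]); `NULL` leaves the RNG state untouched.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_loci = 30000L,
                              maf_sampler = c(0.05, 0.5),
                              error_rate = 0.002,
                              nocall_rate = 0.005,
                              cn_abnormal_rate = 0.001,
                              seed = NULL) {
  n_loci <- as.integer(n_loci)
  if (is.na(n_loci) || n_loci < 1L) abort("`n_loci` must be a positive integer.")
  rates <- c(error_rate = error_rate, nocall_rate = nocall_rate,
             cn_abnormal_rate = cn_abnormal_rate)
  if (any(rates < 0) || any(rates >= 1)) abort("noise rates must lie in [0, 1).")
  if (sum(rates) >= 1) abort("error_rate + nocall_rate + cn_abnormal_rate must be < 1.")
  if (!is.function(maf_sampler)) {
    maf_sampler <- as.numeric(maf_sampler)
    if (length(maf_sampler) != 2L || any(is.na(maf_sampler)) ||
        maf_sampler[[1L]] > maf_sampler[[2L]] ||
        maf_sampler[[1L]] < 0 || maf_sampler[[2L]] > 0.5) {
      abort("`maf_sampler` must be a function or an increasing range within [0, 0.5].")
    }
  }
  structure(
    list(n_loci = n_loci, maf_sampler = maf_sampler,
         error_rate = error_rate, nocall_rate = nocall_rate,
         cn_abnormal_rate = cn_abnormal_rate, seed = seed),
    class = "simulation_config"
  )
}

.apply_seed <- function(config) {
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))
}

#' Draw per-locus minor-allele frequencies
#'
#' @param config A [simulation_config()]. With the default sampler,
#'   frequencies are uniform on `[0.05, 0.5]`; the config's seed (if any) is
#'   applied first, so identical configs give identical vectors.
#' @return Numeric vector of length `n_loci`.
#' @export
draw_allele_frequencies <- function(config = simulation_config()) {
  .apply_seed(config)
  q <- if (is.function(config$maf_sampler)) {
    config$maf_sampler(config$n_loci)
  } else {
    runif(config$n_loci, config$maf_sampler[[1L]], config$maf_sampler[[2L]])
  }
  if (length(q) != config$n_loci || any(is.na(q)) || any(q < 0 | q > 0.5)) {
    abort("the MAF sampler must return n_loci frequencies in [0, 0.5].")
  }
  q
}

# One shared panel per cohort: ids, autosomal coordinates, the biallelic
# allele pair and its three two-copy genotype strings. Draws alleles from
# the current RNG stream.
.make_locus_panel <- function(maf) {
  n <- length(maf)
  bases <- c("A", "C", "G", "T")
  major <- bases[sample.int(4L, n, replace = TRUE)]
  minor <- bases[(match(major, bases) - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L]
  lo <- pmin(major, minor)
  hi <- pmax(major, minor)
  tibble(
    locus_id = sprintf("SNP_%06d", seq_len(n)),
    chromosome = as.character(rep_len(1:22, n)),
    position = 10000L * (seq_len(n) %/% 22L + 1L),
    maf = maf,
    a_major = major,
    a_minor = minor,
    hom_major = paste0(major, major),
    het = paste0(lo, hi),
    hom_minor = paste0(minor, minor)
  )
}

# dosage = count of minor alleles (0, 1, 2); HWE founder is Binomial(2, q)
.founder_dosage <- function(panel) rbinom(nrow(panel), 2L, panel$maf)

.dosage_calls <- function(dosage, panel) {
  cbind(panel$hom_major, panel$het, panel$hom_minor)[cbind(seq_along(dosage), dosage + 1L)]
}

# Noise layers in priority order no-call > CN-abnormal > miscall, mutually
# exclusive via a single uniform per locus.
.noisy_table <- function(dosage, panel, config, sample_id) {
  n <- nrow(panel)
  call <- .dosage_calls(dosage, panel)
  u <- runif(n)
  p_nc <- config$nocall_rate
  p_cn <- config$cn_abnormal_rate
  p_er <- config$error_rate
  nocall <- u < p_nc
  cnab <- !nocall & u < p_nc + p_cn
  err <- !nocall & !cnab & u < p_nc + p_cn + p_er

  if (any(err)) {
    # replace with one of the other two two-copy genotypes at that locus
    others <- rbind(c(1L, 2L), c(0L, 2L), c(0L, 1L))
    pick <- sample.int(2L, sum(err), replace = TRUE)
    new_dosage <- others[cbind(dosage[err] + 1L, pick)]
    call[err] <- .dosage_calls(new_dosage, panel[err, , drop = FALSE])
  }
  if (any(cnab)) {
    for (i in which(cnab)) {
      alleles <- c(
        rep(panel$a_major[[i]], 2L - dosage[[i]]),
        rep(panel$a_minor[[i]], dosage[[i]])
      )
      call[[i]] <- if (runif(1L) < 0.5) {
        sample(alleles, 1L)                                   # one-copy loss
      } else {
        paste(sort(c(alleles, sample(alleles, 1L))), collapse = "")  # three-copy gain
      }
    }
  }
  call[nocall] <- NA_character_

  out <- new_genotype_table(
    tibble(locus_id = panel$locus_id, chromosome = panel$chromosome,
           position = panel$position, call = call),
    sample_id = sample_id
  )
  attr(out, "true_dosage") <- dosage
  attr(out, "locus_panel") <- panel
  out
}

.require_truth <- function(table, what) {
  dosage <- attr(table, "true_dosage", exact = TRUE)
  panel <- attr(table, "locus_panel", exact = TRUE)
  if (is.null(dosage) || is.null(panel)) {
    abort(sprintf(
      "%s must carry true genotypes (`true_dosage`/`locus_panel` attributes) as produced by the simulate_* functions.",
      what
    ))
  }
  list(dosage = dosage, panel = panel)
}

#' Simulate a founder individual
#'
#' Genotypes are drawn locus-by-locus under Hardy-Weinberg equilibrium: with
#' minor-allele frequency q the major homozygote, heterozygote and minor
#' homozygote have probabilities (1-q)^2, 2q(1-q) and q^2. Noise layers are
#' then applied per the config. The returned table carries the noise-free
#' true genotypes as attributes so children and siblings can be bred from it.
#'
#' @param frequencies Per-locus minor-allele frequencies, e.g. from
#'   [draw_allele_frequencies()].
#' @param config A [simulation_config()]; its seed (if any) is applied first.
#' @param sample_id Identifier for the simulated individual.
#' @return A `genotype_table`.
#' @export
simulate_founder <- function(frequencies, config = simulation_config(),
                             sample_id = "founder") {
  if (length(frequencies) != config$n_loci) {
    abort("`frequencies` must have length n_loci.")
  }
  .apply_seed(config)
  panel <- .make_locus_panel(frequencies)
  .noisy_table(.founder_dosage(panel), panel, config, sample_id)
}

#' Simulate a child of two simulated parents
#'
#' At each locus the child receives one allele drawn uniformly from each
#' parent's two true alleles, independently across loci (Mendelian
#' transmission); noise layers are then applied. Draws from the current RNG
#' stream so a cohort remains a single reproducible stream.
#'
#' @param mother,father `genotype_table`s carrying true genotypes (from
#'   [simulate_founder()], [simulate_child()] or [simulate_cohort()]).
#' @param config A [simulation_config()].
#' @param sample_id Identifier for the child.
#' @return A `genotype_table`.
#' @export
simulate_child <- function(mother, father, config = simulation_config(),
                           sample_id = "child") {
  m <- .require_truth(mother, "`mother`")
  f <- .require_truth(father, "`father`")
  if (!identical(m$panel$locus_id, f$panel$locus_id)) {
    abort("locus mismatch: mother and father must share the same locus panel.")
  }
  n <- length(m$dosage)
  dosage <- rbinom(n, 1L, m$dosage / 2) + rbinom(n, 1L, f$dosage / 2)
  .noisy_table(dosage, m$panel, config, sample_id)
}

#' Simulate a relative of an existing simulated individual
#'
#' Relatedness classes used to probe the method's blind spots: a full sibling
#' is a second child of the same two parents (and therefore still a true-pair
#' against each parent — the documented sample-swap the check cannot catch);
#' a half sibling shares one parent with a fresh founder; an unrelated
#' individual is a fresh founder on the same locus panel.
#'
#' @param relationship One of `"full-sibling"`, `"half-sibling"`,
#'   `"unrelated"`.
#' @param context Named list with the shared parents' tables: `mother` and
#'   `father` for a full sibling, at least one of them for a half sibling,
#'   and any one table (for the shared panel) for an unrelated individual.
#' @param config A [simulation_config()].
#' @param sample_id Identifier for the new individual.
#' @return A `genotype_table`.
#' @export
simulate_relative <- function(relationship = c("full-sibling", "half-sibling", "unrelated"),
                              context = list(), config = simulation_config(),
                              sample_id = relationship) {
  relationship <- rlang::arg_match(relationship)
  fresh_founder <- function(panel, id) {
    .noisy_table(.founder_dosage(panel), panel, config, id)
  }
  switch(relationship,
    "full-sibling" = {
      if (is.null(context$mother) || is.null(context$father)) {
        abort("a full sibling needs both `mother` and `father` in `context`.")
      }
      simulate_child(context$mother, context$father, config, sample_id)
    },
    "half-sibling" = {
      shared <- context$mother %||% context$father
      if (is.null(shared)) {
        abort("a half sibling needs `mother` or `father` in `context`.")
      }
      panel <- .require_truth(shared, "the shared parent")$panel
      other <- fresh_founder(panel, "other_parent")
      simulate_child(shared, other, config, sample_id)
    },
    "unrelated" = {
      any_table <- context$mother %||% context$father %||% context[[1L]]
      if (is.null(any_table)) {
        abort("an unrelated individual needs any context table supplying the locus panel.")
      }
      fresh_founder(.require_truth(any_table, "the context table")$panel, sample_id)
    }
  )
}

#' Re-apply assay noise to a simulated individual's true genotypes
#'
#' Independently per locus and in this priority order: with `nocall_rate`
#' the call becomes a no-call; with `cn_abnormal_rate` a one- or three-copy
#' call built from the individual's true alleles; with `error_rate` the call
#' is replaced by a genotype drawn uniformly from the other two two-copy
#' genotypes at that locus; otherwise it is the true genotype. Outcomes are
#' mutually exclusive.
#'
#' @param table A `genotype_table` carrying true genotypes.
#' @param config A [simulation_config()] supplying the rates.
#' @return A `genotype_table` with fresh noise.
#' @export
apply_noise <- function(table, config = simulation_config()) {
  truth <- .require_truth(table, "`table`")
  .noisy_table(truth$dosage, truth$panel, config, sample_id(table))
}

#' Simulate a cohort of independent trios
#'
#' Draws one shared locus panel, then for each trio an unrelated founder
#' couple and one child, with assay noise on every sample. Deterministic
#' given the config's seed: the stream order is allele frequencies, panel
#' alleles, then per trio the mother's and father's genotypes, the child's
#' transmissions, and each member's noise.
#'
#' @param n_trios Number of trios (>= 1).
#' @param config A [simulation_config()].
#' @return A `simulated_cohort`: list with `tables` (named list of 3 x
#'   n_trios `genotype_table`s, ids like `trio01_proband`), `pedigree`
#'   (tibble with `trio`, `proband`, `mother`, `father`), `loci` (the shared
#'   panel) and `config`.
#' @examples
#' cohort <- simulate_cohort(2, simulation_config(n_loci = 500, seed = 1))
#' names(cohort$tables)
#' @export
simulate_cohort <- function(n_trios, config = simulation_config()) {
  n_trios <- as.integer(n_trios)
  if (is.na(n_trios) || n_trios < 1L) abort("`n_trios` must be >= 1.")
  .apply_seed(config)
  maf <- if (is.function(config$maf_sampler)) {
    config$maf_sampler(config$n_loci)
  } else {
    runif(config$n_loci, config$maf_sampler[[1L]], config$maf_sampler[[2L]])
  }
  panel <- .make_locus_panel(maf)

  tables <- list()
  pedigree <- vector("list", n_trios)
  for (i in seq_len(n_trios)) {
    ids <- setNames(sprintf("trio%02d_%s", i, c("mother", "father", "proband")),
                    c("mother", "father", "proband"))
    dm <- .founder_dosage(panel)
    df <- .founder_dosage(panel)
    dc <- rbinom(nrow(panel), 1L, dm / 2) + rbinom(nrow(panel), 1L, df / 2)
    tables[[ids[["mother"]]]] <- .noisy_table(dm, panel, config, ids[["mother"]])
    tables[[ids[["father"]]]] <- .noisy_table(df, panel, config, ids[["father"]])
    tables[[ids[["proband"]]]] <- .noisy_table(dc, panel, config, ids[["proband"]])
    pedigree[[i]] <- tibble(trio = i, proband = ids[["proband"]],
                            mother = ids[["mother"]], father = ids[["father"]])
  }
  structure(
    list(tables = tables, pedigree = dplyr::bind_rows(pedigree),
         loci = panel, config = config),
    class = "simulated_cohort"
  )
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d trios (%d samples), %d shared loci%s\n",
              nrow(x$pedigree), length(x$tables), nrow(x$loci),
              if (is.null(x$config$seed)) "" else sprintf(", seed %d", as.integer(x$config$seed))))
  invisible(x)
}

#' MAF spectrum of a simulated cohort
#'
#' @param object A `simulated_cohort`.
#' @param ... Unused.
#' @return A ggplot histogram of the panel's minor-allele frequencies.
#' @method autoplot simulated_cohort
#' @export
autoplot.simulated_cohort <- function(object, ...) {
  ggplot2::ggplot(object$loci, ggplot2::aes(x = .data$maf)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::labs(x = "minor-allele frequency", y = "loci") +
    ggplot2::theme_minimal()
}

#' Write a simulated cohort to genotype files plus a truth manifest
#'
#' One canonical-dialect genotype file per sample plus `manifest.json`
#' recording the pedigree, the simulation parameters, the seed and the file
#' names — enough to regenerate the cohort byte-identically.
#'
#' @param cohort A `simulated_cohort`.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- setNames(paste0(names(cohort$tables), ".txt"), names(cohort$tables))
  for (id in names(cohort$tables)) {
    write_genotype_table(cohort$tables[[id]], file.path(dir, files[[id]]))
  }
  cfg <- cohort$config
  manifest <- list(
    tool = "trioconcord",
    version = as.character(utils::packageVersion("trioconcord")),
    n_trios = nrow(cohort$pedigree),
    config = list(
      n_loci = cfg$n_loci,
      maf_sampler = if (is.function(cfg$maf_sampler)) "custom-function" else cfg$maf_sampler,
      error_rate = cfg$error_rate,
      nocall_rate = cfg$nocall_rate,
      cn_abnormal_rate = cfg$cn_abnormal_rate,
      seed = cfg$seed
    ),
    pedigree = cohort$pedigree,
    files = as.list(files)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param path A cohort directory containing `manifest.json`, or the
#'   manifest path itself.
#' @return List with `tables` (named list of `genotype_table`s), `pedigree`
#'   and the parsed `manifest`; directly usable by [cross_match_cohort()].
#' @export
read_cohort <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  if (!file.exists(manifest_path)) {
    abort(sprintf("cohort manifest not found: %s", manifest_path))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  base <- dirname(manifest_path)
  files <- manifest$files
  tables <- lapply(setNames(names(files), names(files)), function(id) {
    read_genotype_table(file.path(base, files[[id]]), sample_id = id)
  })
  list(tables = tables, pedigree = as_tibble(manifest$pedigree), manifest = manifest)
}
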