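#' Load the Mediterranean-Atlantic Rajidae diversity framework
#'
#' Returns the packaged literature compilation of COI diversity statistics for
#' Rajidae populations across the Mediterranean Sea and the Atlantic Ocean:
#' 42 populations of 18 species, each with sample size, haplotype count,
#' haplotype diversity and nucleotide diversity (standard deviations where the
#' source reported them). Populations were included only when based on at
#' least 10 sequences; sub-areas without COI-based differentiation were merged
#' by their source-study haplotype networks (see [merge_subpopulations()]).
#'
#' @return A tibble with columns `species`, `basin`, `subarea`, `n`, `nh`,
#'   `h`, `h_sd`, `pi`, `pi_sd`, `source`.
#' @export
read_framework <- function() {
  path <- system.file("extdata", "rajidae_framework.tsv", package = "rajastat",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    species = "c", basin = "c", subarea = "c",
                    n = "i", nh = "i", h = "d", h_sd = "d",
                    pi = "d", pi_sd = "d", source = "c"))
}

#' Load the Balearic Rajidae diversity table
#'
#' Packaged per-species COI diversity statistics for the seven focal Balearic
#' skate species (sample size, haplotype counts, haplotypes exclusive to the
#' area, h and pi with standard deviations).
#'
#' @return A tibble with columns `species`, `n`, `nh`, `nh_a`, `h`, `h_sd`,
#'   `pi`, `pi_sd`.
#' @export
read_balearic_diversity <- function() {
  path <- system.file("extdata", "balearic_diversity.tsv", package = "rajastat",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    species = "c", n = "i", nh = "i", nh_a = "i",
                    h = "d", h_sd = "d", pi = "d", pi_sd = "d"))
}

#' Load the Balearic GenBank accession bookkeeping table
#'
#' Packaged transcription of the GenBank accession groups behind the Balearic
#' COI dataset: one row per accession block with the species and the number of
#' sequences it contributes.
#'
#' @return A tibble with columns `species`, `n`, `accessions`.
#' @export
read_genbank_table <- function() {
  path <- system.file("extdata", "balearic_genbank.tsv", package = "rajastat",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(species = "c", n = "i",
                                          accessions = "c"))
}

#' Merge sub-population records into one regional record
#'
#' When a source study found no COI-based differentiation between
#' geographically defined sub-areas, their records are merged into one
#' broader region: sample sizes are added, the merged haplotype count is
#' supplied externally (read off the source study's haplotype network, since
#' shared haplotypes make it non-additive), and the remaining statistics are
#' arithmetically averaged. Missing standard deviations stay missing.
#'
#' @param records A data frame of at least two framework records of the same
#'   species and basin (columns as in [read_framework()]).
#' @param merged_nh Integer haplotype count of the merged region.
#' @return A one-row tibble in framework-record form; `subarea` is the
#'   `" + "` concatenation of the input sub-areas.
#' @export
merge_subpopulations <- function(records, merged_nh) {
  assert_that(nrow(records) >= 2, "need at least two records to merge")
  assert_that(dplyr::n_distinct(records$species) == 1 &&
                dplyr::n_distinct(records$basin) == 1,
              "records must share species and basin")
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = FALSE)
  tibble(
    species = records$species[[1]],
    basin = records$basin[[1]],
    subarea = paste(records$subarea, collapse = " + "),
    n = sum(records$n),
    nh = as.integer(merged_nh),
    h = mean_or_na(records$h),
    h_sd = mean_or_na(records$h_sd),
    pi = mean_or_na(records$pi),
    pi_sd = mean_or_na(records$pi_sd),
    source = paste(unique(records$source), collapse = ";"))
}

#' Percentile-bootstrap median and 95% confidence interval
#'
#' Draws `B` bootstrap replicates (sampling `length(values)` items with
#' replacement), records the median of each, and summarises the replicate
#' medians by their 50th, 2.5th and 97.5th percentiles (type-7 linear
#' interpolation). This is the percentile bootstrap for the median used to
#' build the comparative diversity framework.
#'
#' @param values Non-empty numeric vector.
#' @param B Number of bootstrap replicates (default 10000).
#' @param seed Integer seed for reproducibility (RNG state is restored).
#' @param subset Label recorded in the output (e.g. basin name).
#' @return A one-row tibble: `median`, `lci`, `uci`, `sample_median` (plain
#'   median of `values`), `B`, `n`, `seed`, `subset`.
#' @export
bootstrap_median_ci <- function(values, B = 10000, seed = 1,
                                subset = "all") {
  values <- as.numeric(values)
  assert_that(length(values) >= 1, "empty values")
  assert_that(B >= 1, "B must be >= 1")
  n <- length(values)
  meds <- with_seed(seed, {
    vapply(seq_len(B),
           function(b) median(sample(values, n, replace = TRUE)),
           numeric(1))
  })
  qs <- unname(quantile(meds, c(0.5, 0.025, 0.975), type = 7))
  tibble(median = qs[1], lci = qs[2], uci = qs[3],
         sample_median = median(values),
         B = as.integer(B), n = n, seed = as.integer(seed), subset = subset)
}

#' Bootstrap the diversity framework, optionally by basin
#'
#' Filters the framework to a basin subset (or keeps all records), extracts
#' the nucleotide-diversity column and delegates to [bootstrap_median_ci()].
#'
#' @param dataset Framework tibble (defaults to the packaged compilation).
#' @param subset One of `"all"`, `"Atlantic"`, `"Mediterranean"`.
#' @inheritParams bootstrap_median_ci
#' @return A one-row tibble as from [bootstrap_median_ci()].
#' @export
#' @examples
#' build_framework(subset = "Atlantic", B = 200, seed = 1)
build_framework <- function(dataset = read_framework(),
                            subset = c("all", "Atlantic", "Mediterranean"),
                            B = 10000, seed = 1) {
  subset <- match.arg(subset)
  recs <- if (subset == "all") dataset else dplyr::filter(dataset, .data$basin == subset)
  if (nrow(recs) == 0) abort(paste0("subset '", subset, "' has no records"))
  bootstrap_median_ci(recs$pi, B = B, seed = seed, subset = subset)
}

#' Classify a population's nucleotide diversity against the framework
#'
#' A population is in a worse conservation state than the framework average
#' when its nucleotide diversity falls below the lower boundary of the
#' framework median's 95% CI. Because published diversities are rounded,
#' the boundary comparison is rounding-aware: values within `tol` of the
#' lower bound are classified `at_lci` rather than below/within. The default
#' `tol` is half of one unit in the fourth decimal place, matching tables
#' that report pi to 4 decimals.
#'
#' @param pi Non-negative nucleotide diversity of the focal population
#'   (vectorised).
#' @param summary A one-row framework summary from [build_framework()] or
#'   [bootstrap_median_ci()].
#' @param tol Absolute tolerance for the boundary class (default `5e-5`).
#' @return A tibble with columns `pi` and `status` (factor with levels
#'   `below_lci`, `at_lci`, `within_ci`, `above_uci`).
#' @export
classify_population <- function(pi, summary, tol = 5e-5) {
  assert_that(all(pi >= 0), "negative nucleotide diversity")
  lci <- summary$lci[[1]]
  uci <- summary$uci[[1]]
  status <- dplyr::case_when(
    abs(pi - lci) <= tol ~ "at_lci",
    pi < lci ~ "below_lci",
    pi <= uci ~ "within_ci",
    TRUE ~ "above_uci")
  tibble(pi = pi,
         status = factor(status, levels = c("below_lci", "at_lci",
                                            "within_ci", "above_uci")))
}

#' Classify the Balearic species table against the framework
#'
#' Convenience wrapper: classifies each species of a Balearic-style diversity
#' table (columns `species`, `pi`) against a framework bootstrap summary.
#'
#' @param diversity Tibble with columns `species` and `pi` (defaults to the
#'   packaged Balearic table).
#' @inheritParams classify_population
#' @return The input with a `status` column appended.
#' @export
classify_balearic <- function(diversity = read_balearic_diversity(),
                              summary, tol = 5e-5) {
  cls <- classify_population(diversity$pi, summary, tol = tol)
  dplyr::mutate(diversity, status = cls$status)
}

#' Plot focal populations against the framework interval
#'
#' Dot plot of focal per-species nucleotide diversity with the framework's
#' bootstrap median (solid line) and 95% CI (dashed lines).
#'
#' @param classified Output of [classify_balearic()].
#' @param summary The framework summary the classification used.
#' @return A ggplot object.
#' @export
plot_framework <- function(classified, summary) {
  ggplot2::ggplot(classified,
                  ggplot2::aes(x = .data$species, y = .data$pi,
                               colour = .data$status)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(yintercept = summary$median[[1]], colour = "red") +
    ggplot2::geom_hline(yintercept = c(summary$lci[[1]], summary$uci[[1]]),
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(pi), colour = "status") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
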