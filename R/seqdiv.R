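#' Read a COI alignment from a FASTA file
#'
#' Reads a multi-record FASTA file (wrapped or unwrapped) into an alignment
#' tibble. Sequences are upper-cased and validated: all records must have the
#' same length, and only the characters `A`, `C`, `G`, `T`, `N` and the gap
#' symbol `-` are accepted (IUPAC ambiguity codes other than `N` are rejected
#' so that haplotype identity stays unambiguous). Record order is preserved.
#'
#' Sets of sequences of unequal length (as happens when mixing barcode
#' fragments from different studies) are rejected by default; set
#' `trim_to_overlap = TRUE` to truncate every record to the shortest length
#' instead. Silent trimming is never performed.
#'
#' @param path Path to a FASTA file with at least one record.
#' @param trim_to_overlap If `TRUE`, trim all records to the length of the
#'   shortest one instead of erroring on unequal lengths.
#' @return A tibble with columns `id` and `seq`, carrying attributes
#'   `n` (number of records) and `length` (alignment length).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGTACGTAC", ">b", "ACGTACGTAC"), fa)
#' aln <- read_alignment(fa)
#' attr(aln, "n")
read_alignment <- function(path, trim_to_overlap = FALSE) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort("no records in FASTA file")
  seqs <- toupper(as.character(set))
  ids <- names(set) %||% as.character(seq_along(seqs))
  as_alignment(tibble(id = unname(ids), seq = unname(seqs)),
               trim_to_overlap = trim_to_overlap)
}

#' Construct an alignment from an id/sequence tibble
#'
#' Validation used by [read_alignment()] and the synthetic generator:
#' upper-cases sequences, enforces a common length and the `{A,C,G,T,N,-}`
#' alphabet.
#'
#' @param x A data frame with columns `id` and `seq`.
#' @inheritParams read_alignment
#' @return A validated alignment tibble (see [read_alignment()]).
#' @export
as_alignment <- function(x, trim_to_overlap = FALSE) {
  assert_that(all(c("id", "seq") %in% names(x)), "need columns id and seq")
  assert_that(nrow(x) >= 1, "no records")
  x <- as_tibble(x[c("id", "seq")])
  x$seq <- toupper(x$seq)
  lens <- nchar(x$seq)
  if (length(unique(lens)) > 1) {
    if (trim_to_overlap) {
      x$seq <- substr(x$seq, 1L, min(lens))
    } else {
      abort(paste0("sequences have unequal lengths (",
                   paste(sort(unique(lens)), collapse = ", "),
                   "); set trim_to_overlap = TRUE to truncate"))
    }
  }
  bad <- grepl("[^ACGTN-]", x$seq)
  if (any(bad)) {
    abort(paste0("disallowed characters (IUPAC ambiguity codes other than N?) in: ",
                 paste(utils::head(x$id[bad], 5), collapse = ", ")))
  }
  structure(x, n = nrow(x), length = nchar(x$seq[[1]]),
            class = c("coi_alignment", class(x)))
}

# Character matrix of an alignment, sequences in rows.
aln_matrix <- function(a) {
  m <- do.call(rbind, strsplit(a$seq, "", fixed = TRUE))
  rownames(m) <- a$id
  m
}

# Complete-deletion site filter: drop every column containing '-' or 'N'
# in any sequence. Returns the filtered matrix (possibly 0 columns).
filter_sites <- function(m) {
  keep <- colSums(m == "-" | m == "N") == 0
  m[, keep, drop = FALSE]
}

#' Collapse an alignment into a haplotype table
#'
#' Haplotypes are exact-identity classes of the sequences after complete
#' deletion of alignment columns containing a gap or an `N` in any record
#' (the usual configuration for barcode diversity summaries). Haplotypes are
#' reported in order of first appearance.
#'
#' @param a An alignment from [read_alignment()] or [as_alignment()].
#' @return A tibble with columns `haplotype` (filtered sequence), `count` and
#'   `frequency`; attributes `n` (sequences) and `n_sites` (retained sites).
#' @export
collapse_haplotypes <- function(a) {
  m <- filter_sites(aln_matrix(a))
  key <- if (ncol(m) == 0) rep("", nrow(m)) else apply(m, 1, paste, collapse = "")
  cls <- factor(key, levels = unique(key))
  counts <- as.integer(table(cls))
  out <- tibble(haplotype = levels(cls), count = counts,
                frequency = counts / sum(counts))
  structure(out, n = nrow(a), n_sites = ncol(m))
}

#' Haplotype (gene) diversity with Nei's variance
#'
#' Computes the small-sample-corrected haplotype diversity
#' \eqn{h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} where \eqn{p_i} is the
#' frequency of the i-th haplotype, together with its standard deviation from
#' Nei's (1987) variance estimator
#' \deqn{V(h) = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p_i^3 -
#'   \left(\sum p_i^2\right)^2\right] + \sum p_i^2 -
#'   \left(\sum p_i^2\right)^2\right\}.}
#'
#' @param t A haplotype table from [collapse_haplotypes()], or an integer
#'   vector of haplotype counts.
#' @return A one-row tibble with columns `h`, `h_sd`, `n`, `nh`.
#' @export
#' @examples
#' haplotype_diversity(c(29, 2))  # h = 0.1247, sd = 0.0771
haplotype_diversity <- function(t) {
  counts <- if (is.data.frame(t)) t$count else as.integer(t)
  assert_that(all(counts >= 1), "haplotype counts must be positive")
  n <- sum(counts)
  if (n < 2) abort("diversity undefined for n < 2")
  p <- counts / n
  s2 <- sum(p^2)
  s3 <- sum(p^3)
  h <- n / (n - 1) * (1 - s2)
  v <- 2 / (n * (n - 1)) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  tibble(h = h, h_sd = sqrt(max(v, 0)), n = n, nh = length(counts))
}

#' Nucleotide diversity with Nei's total variance
#'
#' Computes the small-sample-corrected per-site nucleotide diversity
#' \eqn{\pi = \frac{n}{n-1} \sum_{ij} x_i x_j \pi_{ij}} over ordered pairs of
#' distinct sequences, where \eqn{x_i} is the frequency of the i-th distinct
#' sequence and \eqn{\pi_{ij}} the proportion of differing sites. Sites are
#' filtered by complete deletion (any column carrying `-` or `N` is dropped)
#' before distances are taken, so haplotype collapsing and \eqn{\pi} see the
#' same data.
#'
#' The standard deviation uses Nei's (1987) total variance, which includes
#' both the sampling term and the stochastic (evolutionary) term:
#' \deqn{V(\pi) = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2}
#' with \eqn{L} the number of retained sites.
#'
#' @param a An alignment.
#' @return A one-row tibble with columns `pi`, `pi_sd`, `n`, `n_sites`.
#' @export
nucleotide_diversity <- function(a) {
  n <- nrow(a)
  if (n < 2) abort("diversity undefined for n < 2")
  m <- filter_sites(aln_matrix(a))
  L <- ncol(m)
  if (L == 0) abort("all sites removed by the complete-deletion filter")
  key <- apply(m, 1, paste, collapse = "")
  cls <- factor(key, levels = unique(key))
  counts <- as.integer(table(cls))
  x <- counts / n
  uniq <- do.call(rbind, strsplit(levels(cls), "", fixed = TRUE))
  k <- nrow(uniq)
  pi <- 0
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        d_ij <- sum(uniq[i, ] != uniq[j, ]) / L
        pi <- pi + 2 * x[i] * x[j] * d_ij
      }
    }
    pi <- n / (n - 1) * pi
  }
  v <- (n + 1) / (3 * (n - 1) * L) * pi +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi^2
  tibble(pi = pi, pi_sd = sqrt(max(v, 0)), n = n, n_sites = L)
}

#' Per-population diversity summary
#'
#' One-stop summary for an alignment: sample size, haplotype count, haplotype
#' diversity and nucleotide diversity with their standard deviations,
#' mirroring the columns of a barcode diversity table.
#'
#' @param a An alignment.
#' @param species Optional label prepended as a `species` column.
#' @return A one-row tibble with columns `species` (if given), `n`, `nh`,
#'   `h`, `h_sd`, `pi`, `pi_sd`.
#' @export
diversity_summary <- function(a, species = NULL) {
  ht <- collapse_haplotypes(a)
  hd <- haplotype_diversity(ht)
  nd <- nucleotide_diversity(a)
  out <- tibble(n = hd$n, nh = hd$nh, h = hd$h, h_sd = hd$h_sd,
                pi = nd$pi, pi_sd = nd$pi_sd)
  if (!is.null(species)) out <- dplyr::bind_cols(tibble(species = species), out)
  out
}

#' Haplotype sharedness across regions
#'
#' Classifies every haplotype of a focal region by which other regions carry
#' it, and counts haplotypes exclusive to each region (the `Nh_a` column of a
#' regional diversity table).
#'
#' @param regional_haplotypes Named list mapping region name to a character
#'   vector (set) of haplotype sequences.
#' @param focal Name of the focal region (must be present in the list).
#' @return A list with elements `focal_report` (tibble: `haplotype`,
#'   `regions` (list-column of other regions carrying it), `n_regions`,
#'   `unique_to_focal`) and `exclusive_counts` (tibble: `region`,
#'   `nh`, `nh_exclusive`).
#' @export
sharedness_report <- function(regional_haplotypes, focal) {
  assert_that(focal %in% names(regional_haplotypes),
              paste0("focal region '", focal, "' not in map"))
  sets <- lapply(regional_haplotypes, unique)
  if (length(sets[[focal]]) == 0) abort("empty focal haplotype set")
  others <- setdiff(names(sets), focal)
  focal_report <- purrr::map_dfr(sets[[focal]], function(hap) {
    carriers <- others[vapply(sets[others], function(s) hap %in% s, logical(1))]
    tibble(haplotype = hap, regions = list(carriers),
           n_regions = length(carriers),
           unique_to_focal = length(carriers) == 0)
  })
  exclusive_counts <- purrr::map_dfr(names(sets), function(r) {
    rest <- unique(unlist(sets[setdiff(names(sets), r)]))
    tibble(region = r, nh = length(sets[[r]]),
           nh_exclusive = sum(!sets[[r]] %in% rest))
  })
  list(focal_report = focal_report, exclusive_counts = exclusive_counts)
}
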