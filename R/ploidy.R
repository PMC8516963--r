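## Genome-QC statistics: heterozygous-site calling, allele-balance
## ploidy inference and k-mer assembly completeness.

#' Call heterozygous sites from a base-count pileup
#'
#' A site is considered when its coverage (sum of the four base counts)
#' is at least `min_cov` (default 10; lower-coverage positions are
#' ignored). A considered site is heterozygous when at least two
#' distinct bases are present with at least `min_alt_reads` reads each
#' (default 2).
#'
#' @param sites Data frame with integer columns `A`, `C`, `G`, `T`
#'   (and optionally `site`).
#' @param min_cov Minimum coverage for a site to be considered.
#' @param min_alt_reads Minimum reads per base for it to count.
#' @return Data frame: `site`, `coverage`, `n1`, `n2` (two largest base
#'   counts), `minor_fraction` (`n2 / (n1 + n2)`, NA when not
#'   heterozygous), `is_considered`, `is_heterozygous`.
#' @export
call_het_sites <- function(sites, min_cov = 10, min_alt_reads = 2) {
  cnt <- as.matrix(sites[, c("A", "C", "G", "T")])
  if (any(cnt < 0)) stop("negative base counts", call. = FALSE)
  coverage <- rowSums(cnt)
  srt <- t(apply(cnt, 1, sort, decreasing = TRUE))
  n1 <- srt[, 1]; n2 <- srt[, 2]
  is_considered <- coverage >= min_cov
  is_het <- is_considered & (rowSums(cnt >= min_alt_reads) >= 2)
  minor <- ifelse(is_het, n2 / (n1 + n2), NA_real_)
  data.frame(site = sites$site %||% seq_len(nrow(sites)),
             coverage = coverage, n1 = n1, n2 = n2,
             minor_fraction = minor,
             is_considered = is_considered, is_heterozygous = is_het)
}

#' Infer ploidy from heterozygous-site calls
#'
#' Computes the heterozygous-site fraction among considered sites and
#' the minor-allele-fraction histogram (20 bins on `[0, 0.5]`, from the
#' two most frequent bases of each heterozygous site). The verdict is
#' `diploid` when the het fraction reaches `het_frac_threshold` and the
#' histogram mode lies in `balance_window` (a true diploid shows a mode
#' near 0.5, balanced alleles); `haploid` when the het fraction is
#' below the threshold (residual heterozygous calls at 0.5% sequencing
#' error and 30x coverage are about 3e-3, which sets the default
#' threshold of 5e-3); otherwise `undetermined`.
#'
#' @param calls Output of [call_het_sites()].
#' @param het_frac_threshold Heterozygous fraction separating haploid
#'   from diploid signal (default `5e-3`).
#' @param balance_window Closed interval in which a diploid histogram
#'   mode must fall (default `c(0.4, 0.5)`).
#' @param min_sites Minimum considered sites for a verdict (default
#'   1000; fewer gives `undetermined`).
#' @return Object of class `ploidy_report`: `considered`, `het_count`,
#'   `het_fraction`, `histogram` (20-bin counts with break attributes),
#'   `mode_bin_mid`, `verdict`, `thresholds`, `reason`.
#' @export
infer_ploidy <- function(calls, het_frac_threshold = 5e-3,
                         balance_window = c(0.4, 0.5), min_sites = 1000) {
  considered <- sum(calls$is_considered)
  het <- calls[calls$is_heterozygous, , drop = FALSE]
  breaks <- seq(0, 0.5, length.out = 21)
  hcount <- if (nrow(het)) {
    bin <- pmin(pmax(ceiling(het$minor_fraction / 0.025), 1L), 20L)
    tabulate(bin, nbins = 20L)
  } else integer(20)
  mids <- (breaks[-21] + breaks[-1]) / 2

  het_fraction <- if (considered > 0) nrow(het) / considered else NA_real_
  thresholds <- list(het_frac_threshold = het_frac_threshold,
                     balance_window = balance_window,
                     min_sites = min_sites)
  if (considered < min_sites) {
    verdict <- "undetermined"
    reason <- sprintf("only %d considered sites (< %d)", considered,
                      min_sites)
    mode_mid <- NA_real_
  } else {
    ## histogram mode from a 3-bin moving average: a true diploid shows a
    ## broad folded-binomial peak near 0.5, while sequencing-error sites
    ## form a narrow spike near min_alt_reads/coverage; smoothing keeps
    ## the broad peak from being outvoted by the spike
    mode_mid <- if (sum(hcount) > 0) {
      sm <- vapply(seq_along(hcount), function(i) {
        w <- max(1, i - 1):min(length(hcount), i + 1)
        mean(hcount[w])
      }, 0)
      mids[which.max(sm)]
    } else NA_real_
    if (het_fraction < het_frac_threshold) {
      verdict <- "haploid"; reason <- "het fraction below threshold"
    } else if (!is.na(mode_mid) && mode_mid >= balance_window[1] &&
               mode_mid <= balance_window[2]) {
      verdict <- "diploid"
      reason <- "het fraction above threshold with balanced allele mode"
    } else {
      verdict <- "undetermined"
      reason <- "het fraction above threshold but allele balance unimodal away from 0.5"
    }
  }
  structure(list(considered = considered, het_count = nrow(het),
                 het_fraction = het_fraction,
                 histogram = setNames(hcount, sprintf("%.3f", mids)),
                 mode_bin_mid = mode_mid, verdict = verdict,
                 thresholds = thresholds, reason = reason),
            class = "ploidy_report")
}

#' @export
print.ploidy_report <- function(x, ...) {
  cat(sprintf("<ploidy_report> %s (het fraction %.2e over %d sites)\n",
              x$verdict, x$het_fraction, x$considered))
  invisible(x)
}

#' K-mer assembly completeness
#'
#' Reference-free completeness in the style of k-mer spectrum methods:
#' the fraction of solid read k-mers (count at or above `solid_min`,
#' filtering sequencing-error k-mers) that are found in the assembly
#' k-mer set.
#'
#' @param assembly_kmers Character vector of canonical assembly k-mers.
#' @param read_kmers Data frame `kmer`, `count` of canonical read
#'   k-mers.
#' @param solid_min Minimum read count for a solid k-mer (default 4).
#' @return Object of class `kmer_completeness`: `k`, `solid_min`,
#'   `solid`, `found`, `percent` (= 100 * found / solid).
#' @export
kmer_completeness <- function(assembly_kmers, read_kmers, solid_min = 4) {
  solid <- unique(read_kmers$kmer[read_kmers$count >= solid_min])
  if (length(solid) == 0)
    stop("undefined-completeness: no solid read k-mers", call. = FALSE)
  ka <- unique(nchar(assembly_kmers)); kr <- unique(nchar(solid))
  if (length(ka) == 1 && length(kr) == 1 && ka != kr)
    stop("assembly and read k-mer sizes differ", call. = FALSE)
  found <- sum(solid %in% assembly_kmers)
  structure(list(k = kr[1], solid_min = solid_min,
                 solid = length(solid), found = found,
                 percent = 100 * found / length(solid)),
            class = "kmer_completeness")
}

#' @export
print.kmer_completeness <- function(x, ...) {
  cat(sprintf("<kmer_completeness> %.2f%% (%d / %d solid k-mers, k=%d)\n",
              x$percent, x$found, x$solid, x$k))
  invisible(x)
}
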