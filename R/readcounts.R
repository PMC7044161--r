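#' Expected variant allele frequencies, copy-neutral case
#'
#' Under copy-neutral heterozygous SNVs the expected VAF follows the mixture
#' relationship V = 1/2 f M: the clone frequencies of all clones carrying
#' the mutant base are summed and divided by two (each carrier contributes
#' one mutant of its two copies).
#'
#' @param composition Samples-by-clones frequency matrix (rows sum to <= 1;
#'   the remainder is the normal-cell fraction).
#' @param genotypes Binary clones-by-SNVs matrix; its clone set must contain
#'   the composition's clones.
#' @return Samples-by-SNVs matrix of expected VAFs, entries in [0, 1/2].
#' @export
expected_vaf_neutral <- function(composition, genotypes) {
  check_composition(composition)
  missing <- setdiff(colnames(composition), rownames(genotypes))
  if (length(missing))
    stop("clone '", missing[1], "' in composition but not in genotypes")
  M <- genotypes[colnames(composition), , drop = FALSE]
  0.5 * composition %*% M
}

#' Expected variant allele frequencies under CNAs and LOH
#'
#' Each clone contributes its frequency times the per-site multiplier
#' mutant_copies / total_copies (e.g. 2/3 at a site with two mutant and one
#' wild-type copy); the expected SNV frequency is the sum of these
#' contributions over clones.  A clone whose total copy number at a site is
#' 0 contributes 0 there.
#'
#' @param composition Samples-by-clones frequency matrix.
#' @param copy_states A `copy_state_table` covering the composition's clones.
#' @return Samples-by-SNVs matrix of expected VAFs.
#' @export
expected_vaf_cna <- function(composition, copy_states) {
  check_composition(composition)
  clones <- colnames(composition)
  missing <- setdiff(clones, rownames(copy_states$mutant))
  if (length(missing))
    stop("clone '", missing[1], "' in composition but not in copy states")
  mut <- copy_states$mutant[clones, , drop = FALSE]
  tot <- mut + copy_states$wild[clones, , drop = FALSE]
  frac <- ifelse(tot > 0, mut / tot, 0)
  composition %*% frac
}

#' Expected sequencing depth under CNAs
#'
#' The expected total read count at a site is the sum over clones of
#' base_depth * clone frequency * total copy number / 2, plus the same
#' weighting for (diploid) normal cells at the sample's normal fraction.
#'
#' @param composition Samples-by-clones frequency matrix.
#' @param copy_states A `copy_state_table`.
#' @param base_depth Depth of a fully diploid site (default 100).
#' @return Samples-by-SNVs matrix of expected depths.
#' @export
expected_depth_cna <- function(composition, copy_states, base_depth = 100) {
  stopifnot(base_depth > 0)
  check_composition(composition)
  clones <- colnames(composition)
  tot <- copy_states$mutant[clones, , drop = FALSE] +
    copy_states$wild[clones, , drop = FALSE]
  normal <- 1 - rowSums(composition)
  base_depth * (composition %*% (tot / 2)) + base_depth * normal
}

#' Draw observed read counts under the Poisson/Binomial model
#'
#' The observed total read count at each (sample, SNV) is drawn from a
#' Poisson distribution with mean equal to the expected depth; the mutant
#' read count is then Binomial(total, expected VAF).  This counting noise is
#' the only error model; a Poisson draw of 0 total reads is kept as-is.
#'
#' @param expected_vaf Samples-by-SNVs matrix of expected VAFs in [0, 1].
#' @param expected_depth Matching matrix (or single number) of expected
#'   depths >= 0.
#' @param seed Integer seed.
#' @return An object of class `read_count_table`: list with matrices
#'   `mutant`, `total`, `expected_vaf`, `expected_depth` (samples x SNVs).
#' @export
sample_read_counts <- function(expected_vaf, expected_depth, seed) {
  if (any(expected_vaf < 0 | expected_vaf > 1)) stop("expected_vaf must lie in [0, 1]")
  if (any(expected_depth < 0)) stop("expected_depth must be >= 0")
  if (length(expected_depth) == 1L)
    expected_depth <- array(expected_depth, dim(expected_vaf), dimnames(expected_vaf))
  stopifnot(all(dim(expected_vaf) == dim(expected_depth)))
  set.seed(seed)
  n <- length(expected_vaf)
  total <- matrix(stats::rpois(n, expected_depth), nrow(expected_vaf),
                  dimnames = dimnames(expected_vaf))
  mutant <- matrix(stats::rbinom(n, total, expected_vaf), nrow(expected_vaf),
                   dimnames = dimnames(expected_vaf))
  structure(list(mutant = mutant, total = total,
                 expected_vaf = expected_vaf, expected_depth = expected_depth),
            class = "read_count_table")
}

#' @export
print.read_count_table <- function(x, ...) {
  cat("read_count_table: ", nrow(x$total), " samples x ", ncol(x$total),
      " SNVs, mean depth ", round(mean(x$total), 1), "\n", sep = "")
  invisible(x)
}

#' Regenerate read counts at an alternative sequencing depth
#'
#' Re-emits the observation layer of an existing truth (clone genotypes and
#' frequencies) at a new constant depth, e.g. to turn 200x datasets into 50x
#' ones.  Expected VAFs are unchanged; only the counting noise scales.
#'
#' @param genotypes Binary clones-by-SNVs matrix.
#' @param composition Samples-by-clones frequency matrix.
#' @param depth Constant expected depth > 0.
#' @param seed Integer seed.
#' @return A `read_count_table`.
#' @export
regenerate_at_depth <- function(genotypes, composition, depth, seed) {
  stopifnot(depth > 0)
  sample_read_counts(expected_vaf_neutral(composition, genotypes), depth, seed)
}

check_composition <- function(composition) {
  if (!is.matrix(composition) || is.null(colnames(composition)))
    stop("composition must be a samples x clones matrix with clone names")
  if (any(composition < 0))
    stop("composition entries must be >= 0")
  rs <- rowSums(composition)
  if (any(rs > 1 + 1e-8))
    stop("composition row sums must be <= 1; offending sample: ",
         rownames(composition)[rs > 1 + 1e-8][1])
  invisible(composition)
}
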