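#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Every stochastic operation in a pipeline run receives its own seed derived
#' deterministically from the master seed and a short label, so that changing
#' one stage does not perturb the random streams of the others.  The result
#' always fits in a 32-bit signed integer.
#'
#' @param seed Master seed (single integer).
#' @param label Character label naming the consumer of the sub-seed.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729 + 12345) %% 2147483646 + 1)
}

hamming <- function(a, b) sum(a != b)

# stable pair key for unordered SNV pairs
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

assert_binary_matrix <- function(m, what = "genotype matrix") {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must be a matrix with row and column names")
  bad <- apply(m, 1, function(r) any(!r %in% c(0, 1)))
  if (any(bad))
    stop(what, " entries must be 0/1; offending row: ", rownames(m)[bad][1])
  invisible(m)
}
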