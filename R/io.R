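# --- frozen TSV dialects -----------------------------------------------------
# genotype: rows = clones, columns = SNV ids, entries 0/1
# composition: rows = samples, columns = clones, entries in [0,1]
# read counts: snv_id, then per sample <sample>:ref and <sample>:alt
# copy states: clone_id, snv_id, mutant_copies, wild_copies (long form)
# mutational tree: node_id, parent_id, comma-separated mutations, root "-"
# clone tree: rooted Newick, internal labels allowed, germline tip "Normal"

write_tsv <- function(df, path, row_col = NULL) {
  if (!is.null(row_col)) {
    df <- cbind(stats::setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                                row_col), as.data.frame(df))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Read/write clone genotype matrices as TSV
#'
#' @param genotypes Binary clones-by-SNVs matrix.
#' @param path File path.
#' @return `read_genotypes` returns an integer matrix; writers return the
#'   path invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  assert_binary_matrix(genotypes)
  write_tsv(genotypes, path, row_col = "clone_id")
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  assert_binary_matrix(m, what = paste0("genotype file '", path, "'"))
  m
}

#' Read/write sample composition matrices as TSV
#'
#' @param composition Samples-by-clones frequency matrix.
#' @param path File path.
#' @return `read_composition` returns a numeric matrix.
#' @export
write_composition <- function(composition, path) {
  check_composition(composition)
  write_tsv(composition, path, row_col = "sample_id")
  invisible(path)
}

#' @rdname write_composition
#' @export
read_composition <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  rs <- rowSums(m)
  if (any(m < 0) || any(rs > 1 + 1e-8))
    stop("composition file '", path, "': frequencies must be >= 0 with row sums <= 1; ",
         "offending row: ", rownames(m)[which(rs > 1 + 1e-8 | apply(m < 0, 1, any))[1]])
  m
}

#' Read/write read-count tables as TSV
#'
#' The dialect has one row per SNV with columns `snv_id`, then
#' `<sample>:ref` and `<sample>:alt` integer columns per sample
#' (ref = total - mutant).  Round-trips are bit exact.
#'
#' @param reads A `read_count_table`.
#' @param path File path.
#' @return `read_read_counts` returns a `read_count_table` (without
#'   expected-value matrices).
#' @export
write_read_counts <- function(reads, path) {
  samples <- rownames(reads$total)
  df <- data.frame(snv_id = colnames(reads$total), stringsAsFactors = FALSE)
  for (s in samples) {
    df[[paste0(s, ":ref")]] <- reads$total[s, ] - reads$mutant[s, ]
    df[[paste0(s, ":alt")]] <- reads$mutant[s, ]
  }
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_read_counts
#' @export
read_read_counts <- function(path) {
  df <- read_tsv(path)
  cols <- names(df)[-1]
  samples <- unique(sub(":(ref|alt)$", "", cols))
  snvs <- df$snv_id
  mutant <- total <- matrix(0L, length(samples), length(snvs),
                            dimnames = list(samples, snvs))
  for (s in samples) {
    ref <- as.integer(df[[paste0(s, ":ref")]])
    alt <- as.integer(df[[paste0(s, ":alt")]])
    bad <- which(alt < 0 | ref < 0)
    if (length(bad))
      stop("read-count file '", path, "': negative count at row ", bad[1])
    mutant[s, ] <- alt
    total[s, ] <- ref + alt
  }
  structure(list(mutant = mutant, total = total,
                 expected_vaf = NULL, expected_depth = NULL),
            class = "read_count_table")
}

#' Read/write copy-state tables as long-form TSV
#'
#' Columns: `clone_id`, `snv_id`, `mutant_copies`, `wild_copies`.
#'
#' @param copy_states A `copy_state_table`.
#' @param path File path.
#' @return `read_copy_states` returns a `copy_state_table`.
#' @export
write_copy_states <- function(copy_states, path) {
  clones <- rownames(copy_states$mutant)
  snvs <- colnames(copy_states$mutant)
  df <- data.frame(
    clone_id = rep(clones, each = length(snvs)),
    snv_id = rep(snvs, times = length(clones)),
    mutant_copies = as.integer(t(copy_states$mutant)),
    wild_copies = as.integer(t(copy_states$wild)),
    stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_copy_states
#' @export
read_copy_states <- function(path) {
  df <- read_tsv(path)
  clones <- unique(df$clone_id)
  snvs <- unique(df$snv_id)
  mutant <- wild <- matrix(0L, length(clones), length(snvs),
                           dimnames = list(clones, snvs))
  mutant[cbind(df$clone_id, df$snv_id)] <- as.integer(df$mutant_copies)
  wild[cbind(df$clone_id, df$snv_id)] <- as.integer(df$wild_copies)
  if (any(mutant < 0) || any(wild < 0))
    stop("copy-state file '", path, "': negative copy counts")
  structure(list(mutant = mutant, wild = wild, log = character(0)),
            class = "copy_state_table")
}

#' Read/write mutational-tree tables as TSV
#'
#' @param tree A `clone_phylogeny`.
#' @param path File path.
#' @param universe SNV universe passed to [export_mutational_tree()].
#' @return `read_mutational_tree` returns a `clone_phylogeny` (with the
#'   root-listed unassigned SNVs in attribute `unassigned`).
#' @export
write_mutational_tree <- function(tree, path, universe = tree_snvs(tree)) {
  write_tsv(export_mutational_tree(tree, universe), path)
  invisible(path)
}

#' @rdname write_mutational_tree
#' @export
read_mutational_tree <- function(path) {
  parse_mutational_tree(read_tsv(path))
}

#' Read/write clone-tree topologies as Newick
#'
#' Serializes the topology of a clone phylogeny (mutations travel in the
#' mutational-tree table, not in Newick).  All clones appear as labels;
#' internal-node labels and multifurcations are allowed and the germline is
#' the root label `"Normal"`.
#'
#' @param tree A `clone_phylogeny`.
#' @param path File path.
#' @return `read_clone_newick` returns an `ape::phylo`.
#' @export
write_clone_newick <- function(tree, path) {
  validate_clone_phylogeny(tree)
  build <- function(node) {
    kids <- children_of(tree, node)
    if (!length(kids)) return(node)
    paste0("(", paste(vapply(kids, build, character(1)), collapse = ","), ")", node)
  }
  writeLines(paste0(build(tree$root_id), ";"), path)
  invisible(path)
}

#' @rdname write_clone_newick
#' @export
read_clone_newick <- function(path) {
  ape::read.tree(path)
}
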