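#' Build a pipeline run configuration
#'
#' A run configuration names a scenario preset, a master seed and an output
#' directory, plus preset-specific parameters.  Every stochastic stage of
#' the pipeline receives its own seed derived deterministically from the
#' master seed (see [derive_seed()]), so a configuration fully determines
#' the output bundle.  Configurations round-trip losslessly through JSON.
#'
#' @param preset One of `"localized"` (random phylogeny, one tip clone plus
#'   ancestors per sample), `"growth"` (3D lattice tumor, sector sampling,
#'   clone calling), `"cna-overlay"` (localized truth plus CNA/LOH copy
#'   states) or `"depth-regen"` (re-emit read counts for an existing truth
#'   at a new depth).
#' @param seed Master integer seed.
#' @param out_dir Output directory (created if absent).
#' @param ... Preset parameters overriding the defaults: `n_clones`,
#'   `n_samples`, `depth` (localized/cna); `model`, `N`, `n_sectors`,
#'   `cells_per_sector`, `maf_threshold` (growth); `truth_dir` (depth-regen).
#' @return An object of class `run_config`.
#' @export
run_config <- function(preset = c("localized", "growth", "cna-overlay", "depth-regen"),
                       seed, out_dir, ...) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    "localized" = list(n_clones = 10, n_samples = 6, depth = 100),
    "growth" = list(model = "constant", N = 10000, n_sectors = 8,
                    cells_per_sector = 100, maf_threshold = 0.05, depth = 100,
                    k = 10, rate = 1, mutation_mean = 1),
    "cna-overlay" = list(n_clones = 7, n_samples = 7, depth = 100,
                         per_chromosome_capacity = 30),
    "depth-regen" = list(truth_dir = NULL, depth = 50))
  params <- utils::modifyList(defaults, list(...))
  structure(list(preset = preset, seed = as.integer(seed),
                 out_dir = out_dir, params = params),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config: preset '", x$preset, "', seed ", x$seed, ", out '",
      x$out_dir, "'\n", sep = "")
  invisible(x)
}

#' Serialize / restore a run configuration
#' @param config A `run_config`.
#' @param path JSON file path.
#' @return `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, c(list(preset = raw$preset, seed = raw$seed,
                             out_dir = raw$out_dir), raw$params))
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
}

#' Run a simulation pipeline and write a dataset bundle
#'
#' Executes the scenario described by a [run_config()] and writes the truth
#' (Newick topology, mutational tree, genotypes, composition, copy states
#' where applicable) plus the observed read counts into the configured
#' output directory, together with a `manifest.json` listing every file
#' with an md5 checksum and a run log.  Outputs are deterministic given the
#' configuration.
#'
#' @param config A `run_config`.
#' @return Invisibly, the in-memory bundle (list with `truth`, `reads` and
#'   the written file paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  log_line(logf, "preset=", config$preset, " seed=", config$seed)
  p <- config$params
  files <- character(0)
  emit <- function(name, writer, ...) {
    path <- file.path(config$out_dir, name)
    writer(..., path = path)
    files <<- c(files, path)
    path
  }

  truth <- NULL
  reads <- NULL
  if (config$preset %in% c("localized", "cna-overlay")) {
    truth <- generate_random_dataset(p$n_clones, p$n_samples,
                                     seed = derive_seed(config$seed, "phylogeny"))
    emit("true_tree.nwk", write_clone_newick, truth$tree)
    emit("true_mutational_tree.tsv", write_mutational_tree, truth$tree)
    emit("true_genotypes.tsv", write_genotypes, truth$genotypes)
    emit("true_composition.tsv", write_composition, truth$composition)
    if (config$preset == "localized") {
      vaf <- expected_vaf_neutral(truth$composition, truth$genotypes)
      reads <- sample_read_counts(vaf, p$depth,
                                  seed = derive_seed(config$seed, "reads"))
    } else {
      assignment <- assign_snvs_to_haplotypes(
        tree_snvs(truth$tree), p$per_chromosome_capacity,
        seed = derive_seed(config$seed, "haplotypes"))
      events <- place_cna_events(truth$tree, unique(assignment$chromosome),
                                 seed = derive_seed(config$seed, "events"))
      states <- evolve_copy_states(truth$tree, events, assignment)
      truth$copy_states <- states
      emit("copy_states.tsv", write_copy_states, states)
      vaf <- expected_vaf_cna(truth$composition, states)
      depth <- expected_depth_cna(truth$composition, states, p$depth)
      reads <- sample_read_counts(vaf, depth,
                                  seed = derive_seed(config$seed, "reads"))
    }
  } else if (config$preset == "growth") {
    tumor <- grow_tumor(p$model, k = p$k, rate = p$rate, N = p$N,
                        mutation_mean = p$mutation_mean,
                        seed = derive_seed(config$seed, "growth"))
    sectors <- sample_sectors(tumor, p$n_sectors, p$cells_per_sector,
                              seed = derive_seed(config$seed, "sectors"))
    called <- call_clones(tumor, sectors, p$maf_threshold)
    tree <- tree_from_genotypes(rbind(Normal = 0L, called$genotypes))
    truth <- structure(list(tree = tree, genotypes = called$genotypes,
                            composition = called$composition),
                       class = "clone_dataset")
    emit("true_tree.nwk", write_clone_newick, tree)
    emit("true_genotypes.tsv", write_genotypes, called$genotypes)
    emit("true_composition.tsv", write_composition, called$composition)
    vaf <- expected_vaf_neutral(called$composition, called$genotypes)
    reads <- sample_read_counts(vaf, p$depth,
                                seed = derive_seed(config$seed, "reads"))
  } else { # depth-regen
    if (is.null(p$truth_dir)) stop("depth-regen preset needs truth_dir")
    genotypes <- read_genotypes(file.path(p$truth_dir, "true_genotypes.tsv"))
    composition <- read_composition(file.path(p$truth_dir, "true_composition.tsv"))
    truth <- list(genotypes = genotypes, composition = composition)
    reads <- regenerate_at_depth(
      genotypes[colnames(composition), , drop = FALSE], composition,
      p$depth, seed = derive_seed(config$seed, "reads"))
  }
  emit("read_counts.tsv", write_read_counts, reads)
  emit("config.json", write_run_config, config)

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       pretty = TRUE)
  log_line(logf, "wrote ", length(files), " files to ", config$out_dir)
  invisible(list(truth = truth, reads = reads, files = files))
}

#' Score an inference against a simulated truth
#'
#' Computes the full evaluation report for one (dataset, method) pair:
#' clone mapping and SNV assignment error, ordering error rates for
#' concurrent/sequential/parallel mutation pairs (with undefined flags on
#' degenerate inferences), multi-label TreeVec distance, pruned rooted RF
#' distance, ancestral-clone detection count, and the star/line failure
#' flag.  The inferred mutational tree defaults to the perfect phylogeny of
#' the inferred genotypes.
#'
#' @param truth A `clone_dataset` (tree, genotypes incl. germline row,
#'   composition).
#' @param inferred_genotypes Binary clones-by-SNVs matrix of a method's
#'   predicted clones (no germline row).
#' @param inferred_tree Optional `clone_phylogeny` for the inference.
#' @return An object of class `evaluation_report` (a list; see fields).
#' @export
evaluate_inference <- function(truth, inferred_genotypes, inferred_tree = NULL) {
  true_gen <- truth$genotypes[colnames(truth$composition), , drop = FALSE]
  # a germline row in the inference is the outgroup, not a predicted clone
  inferred_genotypes <-
    inferred_genotypes[rownames(inferred_genotypes) != "Normal", , drop = FALSE]
  if (is.null(inferred_tree))
    inferred_tree <- tree_from_genotypes(rbind(Normal = 0L, inferred_genotypes))
  mapping <- map_clones(true_gen, inferred_genotypes)

  true_pairs <- classify_mutation_pairs(truth$tree)
  inf_pairs <- classify_mutation_pairs(inferred_tree)
  rates <- ordering_error_rates(true_pairs, inf_pairs)

  true_phylo <- genotype_phylo(truth$genotypes)
  labels <- stats::setNames(mapping$true, mapping$inferred)
  inf_phylo_mapped <- genotype_phylo(rbind(Normal = 0L, inferred_genotypes),
                                     labels = c(labels, Normal = "Normal"))
  treevec <- treevec_distance(true_phylo, inf_phylo_mapped)

  inf_phylo_raw <- genotype_phylo(rbind(Normal = 0L, inferred_genotypes))
  rf <- tryCatch(
    rf_distance(ape::keep.tip(true_phylo, c(rownames(true_gen), "Normal")),
                prune_inferred_tips(inf_phylo_raw, mapping)),
    error = function(e) NA_real_)

  structure(list(
    mapping = mapping,
    snv_assignment_error = snv_assignment_error(true_gen, inferred_genotypes, mapping),
    ordering = rates,
    error_rates = vapply(rates, function(r) r$rate, numeric(1)),
    undefined = vapply(rates, function(r) r$undefined, logical(1)),
    treevec = treevec,
    rf = rf,
    ancestral_detected = count_detected_ancestral(truth, inferred_genotypes, mapping),
    ancestral_true = length(ancestral_clones(truth)),
    degenerate = detect_degenerate_topology(inferred_tree),
    failed = detect_degenerate_topology(inferred_tree) != "ok" ||
      any(vapply(rates, function(r) r$undefined, logical(1)))),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n",
      "  SNV assignment error: ", format(x$snv_assignment_error, digits = 4), "\n",
      "  ordering error rates: ",
      paste(names(x$error_rates),
            ifelse(x$undefined, "undefined", format(x$error_rates, digits = 3)),
            sep = "=", collapse = ", "), "\n",
      "  TreeVec: ", format(x$treevec, digits = 4),
      "  RF: ", format(x$rf, digits = 4), "\n",
      "  ancestral clones detected: ", x$ancestral_detected, "/",
      x$ancestral_true, "\n",
      "  topology flag: ", x$degenerate, "\n", sep = "")
  invisible(x)
}

#' Evaluate an inference from files on disk
#'
#' Reads a truth bundle written by [run_pipeline()] and a method's inferred
#' genotype TSV, scores them with [evaluate_inference()], and writes the
#' report as JSON.
#'
#' @param truth_dir Directory containing `true_genotypes.tsv`,
#'   `true_composition.tsv` and `true_mutational_tree.tsv` (or
#'   reconstructable genotypes).
#' @param inferred_path Path to the inferred genotype TSV.
#' @param out Path of the JSON report to write (optional).
#' @return The `evaluation_report`, invisibly when `out` is given.
#' @export
evaluate_files <- function(truth_dir, inferred_path, out = NULL) {
  genotypes <- read_genotypes(file.path(truth_dir, "true_genotypes.tsv"))
  composition <- read_composition(file.path(truth_dir, "true_composition.tsv"))
  mt_path <- file.path(truth_dir, "true_mutational_tree.tsv")
  tree <- if (file.exists(mt_path)) read_mutational_tree(mt_path)
          else tree_from_genotypes(genotypes)
  truth <- structure(list(tree = tree, genotypes = genotypes,
                          composition = composition),
                     class = "clone_dataset")
  report <- evaluate_inference(truth, read_genotypes(inferred_path))
  if (!is.null(out)) {
    flat <- list(snv_assignment_error = report$snv_assignment_error,
                 error_rates = as.list(report$error_rates),
                 undefined = as.list(report$undefined),
                 treevec = report$treevec, rf = report$rf,
                 ancestral_detected = report$ancestral_detected,
                 ancestral_true = report$ancestral_true,
                 degenerate = report$degenerate, failed = report$failed)
    jsonlite::write_json(flat, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(report))
  }
  report
}

#' Command-line entry point
#'
#' Verbs: `simulate --preset P --seed S --out DIR [--key value ...]` and
#' `evaluate --truth DIR --inferred FILE --out report.json`.  Installed as
#' the `clonebench` script under `inst/cli`.
#'
#' @param args Character vector of arguments (default: command line).
#' @return Exit status 0 invisibly.
#' @export
clonebench_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: clonebench simulate|evaluate [--key value ...]")
  verb <- args[1]
  opts <- list()
  rest <- args[-1]
  while (length(rest)) {
    if (!startsWith(rest[1], "--") || length(rest) < 2)
      stop("malformed option: ", rest[1])
    opts[[sub("^--", "", rest[1])]] <- rest[2]
    rest <- rest[-(1:2)]
  }
  if (verb == "simulate") {
    extra <- opts[setdiff(names(opts), c("preset", "seed", "out"))]
    extra <- lapply(extra, function(v) {
      suppressWarnings(num <- as.numeric(v))
      if (!is.na(num)) num else v
    })
    config <- do.call(run_config, c(list(preset = opts$preset,
                                         seed = as.integer(opts$seed),
                                         out_dir = opts$out), extra))
    run_pipeline(config)
  } else if (verb == "evaluate") {
    evaluate_files(opts$truth, opts$inferred, out = opts$out)
  } else {
    stop("unknown verb '", verb, "'")
  }
  invisible(0L)
}
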