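# Face-centered-cubic packing as the 3D "hexagonal" lattice: integer
# coordinates with even parity, 12 nearest neighbors (permutations of
# (+/-1, +/-1, 0)).
fcc_offsets <- local({
  m <- rbind(
    c( 1,  1, 0), c( 1, -1, 0), c(-1,  1, 0), c(-1, -1, 0),
    c( 1, 0,  1), c( 1, 0, -1), c(-1, 0,  1), c(-1, 0, -1),
    c(0,  1,  1), c(0,  1, -1), c(0, -1,  1), c(0, -1, -1))
  storage.mode(m) <- "integer"
  m
})

coord_key <- function(x, y, z) paste(x, y, z)

#' Grow a 3D lattice tumor under one of three cell-division models
#'
#' Event-driven agent-based growth on a face-centered-cubic lattice (one
#' cell per site).  Waiting times between division attempts are
#' Gamma(shape = k, mean = 1/rate).  Eligibility is re-evaluated when a
#' cell's clock fires:
#' \itemize{
#'   \item \code{constant}: the birth rate is constant regardless of
#'     crowding; a surrounded mother pushes a chain of cells outward along a
#'     uniformly random lattice direction to make room.
#'   \item \code{step}: a cell divides only when at least one neighboring
#'     site is empty; fully surrounded cells are permanently retired (sites
#'     never vacate without pushing).
#'   \item \code{linear}: the division rate is proportional to the
#'     emptiness of the neighborhood; implemented by thinning, accepting a
#'     firing with probability (empty neighbors)/12.
#' }
#' Each division creates one daughter carrying Poisson(`mutation_mean`)
#' brand-new mutations (infinite sites; the mother keeps her genotype).
#' There is no cell death and no migration; growth stops when exactly `N`
#' cells exist.  Intermixture of lineages is highest under `constant` and
#' lowest under `linear`.
#'
#' @param model One of `"constant"`, `"step"`, `"linear"`.
#' @param k Gamma shape parameter of the division waiting time (default 10).
#' @param rate Base potential division rate (default 1).
#' @param N Target extant cell count (default 10000).
#' @param mutation_mean Mean new mutations per division (default 1).
#' @param seed Integer seed.
#' @return An object of class `lattice_tumor`: list with `coords` (N x 3
#'   integer), `parent` (integer, 0 for the founder), `new_mutations`
#'   (list of integer mutation ids acquired at birth), `depth` (divisions
#'   since the founder), `n_mutations`, `model`, and the parameters.
#' @export
grow_tumor <- function(model = c("constant", "step", "linear"),
                       k = 10, rate = 1, N = 10000, mutation_mean = 1, seed) {
  model <- match.arg(model)
  stopifnot(N >= 2, k > 0, rate > 0)
  set.seed(seed)

  waiting <- function(m = 1L) stats::rgamma(m, shape = k, rate = k * rate)

  coords <- matrix(0L, N, 3)
  parent <- integer(N)
  depth <- integer(N)
  new_mutations <- vector("list", N)
  new_mutations[[1]] <- integer(0)
  times <- rep(Inf, N)
  times[1] <- waiting()
  occ <- new.env(hash = TRUE, parent = emptyenv())
  assign(coord_key(0L, 0L, 0L), 1L, envir = occ)
  mut_counter <- 0L
  n <- 1L

  neighbor_sites <- function(i) {
    nb <- sweep(fcc_offsets, 2, coords[i, ], "+")
    keys <- coord_key(nb[, 1], nb[, 2], nb[, 3])
    occupied <- vapply(keys, exists, logical(1), envir = occ, inherits = FALSE)
    list(sites = nb, keys = keys, occupied = occupied)
  }

  while (n < N) {
    i <- which.min(times[seq_len(n)])
    t <- times[i]
    if (!is.finite(t))
      stop("growth deadlock: no eligible cell remains under model '", model, "'")

    pos <- NULL
    if (model == "constant") {
      d <- fcc_offsets[sample.int(12L, 1L), ]
      # walk along d to the first empty site, shifting the chain outward
      chain <- list()
      p <- coords[i, ] + d
      key <- coord_key(p[1], p[2], p[3])
      while (exists(key, envir = occ, inherits = FALSE)) {
        chain[[length(chain) + 1L]] <- list(pos = p, key = key,
                                            id = get(key, envir = occ, inherits = FALSE))
        p <- p + d
        key <- coord_key(p[1], p[2], p[3])
      }
      for (j in rev(seq_along(chain))) {
        cell <- chain[[j]]
        newpos <- cell$pos + d
        coords[cell$id, ] <- newpos
        rm(list = cell$key, envir = occ)
        assign(coord_key(newpos[1], newpos[2], newpos[3]), cell$id, envir = occ)
      }
      pos <- coords[i, ] + d
    } else {
      nb <- neighbor_sites(i)
      n_empty <- sum(!nb$occupied)
      if (n_empty == 0L) {          # permanently surrounded: retire
        times[i] <- Inf
        next
      }
      if (model == "linear" && stats::runif(1) > n_empty / 12) {
        times[i] <- t + waiting()   # thinned attempt: reschedule
        next
      }
      empty_idx <- which(!nb$occupied)
      pick <- empty_idx[sample.int(length(empty_idx), 1L)]
      pos <- nb$sites[pick, ]
    }

    n <- n + 1L
    coords[n, ] <- pos
    parent[n] <- i
    depth[n] <- depth[i] + 1L
    nm <- stats::rpois(1, mutation_mean)
    new_mutations[[n]] <- if (nm > 0) mut_counter + seq_len(nm) else integer(0)
    mut_counter <- mut_counter + nm
    assign(coord_key(pos[1], pos[2], pos[3]), n, envir = occ)
    times[i] <- t + waiting()
    times[n] <- t + waiting()
  }

  structure(list(coords = coords, parent = parent, depth = depth,
                 new_mutations = new_mutations, n_mutations = mut_counter,
                 model = model, k = k, rate = rate, N = N,
                 mutation_mean = mutation_mean),
            class = "lattice_tumor")
}

#' @export
print.lattice_tumor <- function(x, ...) {
  cat("lattice_tumor: ", nrow(x$coords), " cells (", x$model, " model), ",
      x$n_mutations, " mutations\n", sep = "")
  invisible(x)
}

#' Genotype (mutation id set) of tumor cells
#'
#' @param tumor A `lattice_tumor`.
#' @param cells Integer vector of cell indices.
#' @return List of integer vectors, the mutation ids carried by each cell.
#' @export
cell_genotypes <- function(tumor, cells) {
  lapply(cells, function(i) {
    g <- integer(0)
    while (i != 0L) {
      g <- c(tumor$new_mutations[[i]], g)
      i <- tumor$parent[i]
    }
    g
  })
}

#' Sample spatially separated tumor sectors
#'
#' Chooses `n_sectors` anchor cells spread uniformly around the tumor
#' (greedy farthest-point selection among 200 random candidate cells,
#' seeded and deterministic) and assigns to each sector the
#' `cells_per_sector` unassigned cells nearest its anchor.  Sectors are
#' pairwise disjoint.
#'
#' @param tumor A `lattice_tumor`.
#' @param n_sectors Number of sectors (default 8).
#' @param cells_per_sector Cells sampled per sector (default 100).
#' @param n_candidates Candidate pool size for anchor placement.
#' @param seed Integer seed.
#' @return Named list (`T1`, `T2`, ...) of integer cell-index vectors, with
#'   the anchor coordinates in attribute `anchors`.
#' @export
sample_sectors <- function(tumor, n_sectors = 8, cells_per_sector = 100,
                           n_candidates = 200, seed) {
  ncell <- nrow(tumor$coords)
  if (ncell < n_sectors * cells_per_sector)
    stop("tumor has ", ncell, " cells; need at least ",
         n_sectors * cells_per_sector)
  set.seed(seed)
  cand <- sort(sample.int(ncell, min(n_candidates, ncell)))
  cc <- tumor$coords[cand, , drop = FALSE]
  centroid <- colMeans(tumor$coords)
  # greedy farthest-point anchors, seeded at the candidate farthest from the
  # tumor centroid
  d0 <- rowSums(sweep(cc, 2, centroid)^2)
  anchors <- which.max(d0)
  mind <- rowSums(sweep(cc, 2, cc[anchors[1], ])^2)
  while (length(anchors) < n_sectors) {
    nxt <- which.max(mind)
    anchors <- c(anchors, nxt)
    mind <- pmin(mind, rowSums(sweep(cc, 2, cc[nxt, ])^2))
  }
  anchor_coords <- cc[anchors, , drop = FALSE]

  assigned <- logical(ncell)
  sectors <- vector("list", n_sectors)
  for (s in seq_len(n_sectors)) {
    free <- which(!assigned)
    d <- rowSums(sweep(tumor$coords[free, , drop = FALSE], 2, anchor_coords[s, ])^2)
    take <- free[order(d, free)][seq_len(cells_per_sector)]
    sectors[[s]] <- sort(take)
    assigned[take] <- TRUE
  }
  names(sectors) <- sprintf("T%d", seq_len(n_sectors))
  attr(sectors, "anchors") <- anchor_coords
  sectors
}

#' Call clones from sampled tumor sectors
#'
#' Pools the sampled cells of all sectors, keeps SNV sites carried by
#' strictly more than `maf_threshold` of the pooled cells, restricts cell
#' genotypes to the retained sites, and merges cells with identical
#' restricted genotypes into clones.  Clone frequencies per sector are cell
#' counts divided by the sector size, so each sector's frequencies sum to 1.
#'
#' @param tumor A `lattice_tumor`.
#' @param sectors Output of [sample_sectors()].
#' @param maf_threshold Pooled-cell frequency cutoff (strict >; default 0.05).
#' @return List with `genotypes` (clones x SNVs binary matrix), `composition`
#'   (sectors x clones frequency matrix), `snvs` (retained SNV ids) and
#'   `cell_clone` (clone id per pooled cell).
#' @export
call_clones <- function(tumor, sectors, maf_threshold = 0.05) {
  if (!length(sectors) || !all(lengths(sectors) > 0))
    stop("sectors must be non-empty")
  cells <- unlist(sectors, use.names = FALSE)
  genos <- cell_genotypes(tumor, cells)
  counts <- table(unlist(genos))
  keep <- as.integer(names(counts)[counts > maf_threshold * length(cells)])
  keep <- sort(keep)
  snv_ids <- sprintf("s%d", keep)

  restricted <- lapply(genos, function(g) intersect(g, keep))
  keys <- vapply(restricted, function(g) paste(sort(g), collapse = ","), character(1))
  tab <- sort(table(keys), decreasing = TRUE)
  clone_keys <- names(tab)
  clone_ids <- sprintf("clone%d", seq_along(clone_keys))

  G <- matrix(0L, length(clone_keys), length(keep),
              dimnames = list(clone_ids, snv_ids))
  for (j in seq_along(clone_keys)) {
    if (nzchar(clone_keys[j])) {
      muts <- as.integer(strsplit(clone_keys[j], ",", fixed = TRUE)[[1]])
      G[j, match(muts, keep)] <- 1L
    }
  }

  cell_clone <- clone_ids[match(keys, clone_keys)]
  comp <- matrix(0, length(sectors), length(clone_ids),
                 dimnames = list(names(sectors), clone_ids))
  offset <- 0L
  for (s in seq_along(sectors)) {
    idx <- offset + seq_along(sectors[[s]])
    tt <- table(cell_clone[idx])
    comp[s, names(tt)] <- as.numeric(tt) / length(sectors[[s]])
    offset <- offset + length(sectors[[s]])
  }

  list(genotypes = G, composition = comp, snvs = snv_ids,
       cell_clone = cell_clone)
}
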