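# STR (microsatellite) haplotype front end: repeat-count tables, per-locus
# weighting from mutation rates, and a weighted stepwise distance.

#' Construct an STR haplotype table
#'
#' @param counts integer matrix of repeat counts, individuals in rows
#'   (rownames = identifiers) and loci in columns (colnames = locus names).
#' @param weights per-locus positive weights (default all 1).
#' @param populations optional per-individual population tag.
#' @param mutation_rates optional per-locus mutation rates (per generation),
#'   carried for provenance and re-weighting.
#' @return an object of class \code{"str_table"}.
#' @export
str_table <- function(counts, weights = NULL, populations = NULL,
                      mutation_rates = NULL) {
  if (!is.matrix(counts) || nrow(counts) < 1L || ncol(counts) < 1L)
    stop_validation("counts must be a non-empty matrix of repeat counts")
  if (anyNA(counts))
    stop_validation("missing repeat counts are not allowed")
  if (!is.numeric(counts) || any(counts != round(counts)) || any(counts < 0))
    stop_validation("repeat counts must be nonnegative integers")
  ids <- rownames(counts)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(counts)))
  if (anyDuplicated(ids))
    stop_validation("duplicate individual identifiers: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "))
  loci <- colnames(counts)
  if (is.null(loci)) loci <- paste0("locus", seq_len(ncol(counts)))
  if (is.null(weights)) weights <- rep(1, ncol(counts))
  if (length(weights) != ncol(counts) || any(weights <= 0))
    stop_validation("need one positive weight per locus")
  if (!is.null(populations) && length(populations) != nrow(counts))
    stop_validation("need one population tag per individual")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(ids, loci)
  structure(list(counts = counts, weights = as.numeric(weights),
    populations = populations, mutation_rates = mutation_rates),
    class = "str_table")
}

#' @export
print.str_table <- function(x, ...) {
  cat("STR haplotype table: ", nrow(x$counts), " individuals x ",
    ncol(x$counts), " loci\n", sep = "")
  cat("locus weights:", paste(format(x$weights), collapse = " "), "\n")
  if (!is.null(x$populations))
    cat("populations:", length(unique(x$populations)), "\n")
  invisible(x)
}

#' Per-locus weights from mutation rates
#'
#' Bins loci into terciles by mutation-rate rank and assigns the weights
#' 4, 2 and 1. Under the default \code{"slow-heavy"} orientation the
#' slowest-mutating tercile gets weight 4 and the fastest gets 1, reflecting
#' that a repeat-count difference at a stable locus is stronger evidence of
#' divergence than one at a volatile locus; \code{"fast-heavy"} reverses the
#' assignment (weight literally proportional to rate rank). Equal rates
#' always receive equal weights (tied ranks share a bin), so a set of loci
#' with identical rates collapses into the first bin -- all weight 4 under
#' the default orientation.
#'
#' @param mutation_rates positive per-locus mutation rates.
#' @param orientation \code{"slow-heavy"} (default) or \code{"fast-heavy"}.
#' @return numeric vector of weights in \{1, 2, 4\}, one per locus.
#' @examples
#' str_weights(c(0.001, 0.002, 0.004))  # 4 2 1
#' @export
str_weights <- function(mutation_rates,
                        orientation = c("slow-heavy", "fast-heavy")) {
  orientation <- match.arg(orientation)
  if (length(mutation_rates) < 1L || any(!is.finite(mutation_rates)) ||
      any(mutation_rates <= 0))
    stop_validation("mutation rates must be positive and finite")
  L <- length(mutation_rates)
  r <- rank(mutation_rates, ties.method = "min")
  bin <- floor(3 * (r - 1) / L) + 1L
  map <- if (orientation == "slow-heavy") c(4, 2, 1) else c(1, 2, 4)
  map[bin]
}

#' Weighted stepwise dissimilarity between STR haplotypes
#'
#' Builds the dissimilarity matrix
#' \deqn{W(i, j) = \sum_l w_l \, |c_{il} - c_{jl}|}
#' (per-locus weighted L1 distance on repeat counts, the natural distance
#' under the single-step mutation model: each unit of repeat-count difference
#' is one mutational step, weighted by the locus's informativeness). Note the
#' formula is this package's reconstruction of the standard stepwise
#' weighting, chosen because it is the usual choice for Y-STR data.
#'
#' Individuals with identical profiles would sit at distance zero, which a
#' dissimilarity does not allow; they are merged into a single vertex whose
#' label concatenates their identifiers with \code{"+"}.
#'
#' @param table an \code{"str_table"}.
#' @param weights optional per-locus weights overriding the table's; see
#'   [str_weights()].
#' @return a labeled dissimilarity matrix ready for [ultranet()].
#' @examples
#' tab <- str_table(matrix(c(10L, 11L, 7L, 7L), 2, 2,
#'   dimnames = list(c("i1", "i2"), c("L1", "L2"))), weights = c(1, 2))
#' str_dissimilarity(tab)  # W(i1, i2) = 1
#' @export
str_dissimilarity <- function(table, weights = NULL) {
  stopifnot(inherits(table, "str_table"))
  if (is.null(weights)) weights <- table$weights
  if (length(weights) != ncol(table$counts) || any(weights <= 0))
    stop_validation("need one positive weight per locus")
  counts <- table$counts
  prof <- apply(counts, 1L, paste, collapse = ",")
  grp <- match(prof, prof)  # first occurrence of each distinct profile
  ids <- rownames(counts)
  merged_labels <- vapply(unique(grp), function(g)
    paste(ids[grp == g], collapse = "+"), "")
  counts <- counts[unique(grp), , drop = FALSE]
  if (nrow(counts) < 2L)
    stop_validation("fewer than 2 distinct haplotypes; no dissimilarity to build")
  scaled <- sweep(counts, 2L, weights, `*`)
  W <- as.matrix(stats::dist(scaled, method = "manhattan"))
  dimnames(W) <- list(merged_labels, merged_labels)
  as_dissimilarity(W)
}

#' Synthetic STR haplotype table with population structure
#'
#' Generates a deterministic (given \code{seed}) haplotype table emulating a
#' multi-population Y-STR survey: each population has its own per-locus
#' repeat-count centroid, drawn far enough apart that between-population
#' distances dominate, and individuals scatter around their centroid by
#' single-repeat jitter (the stepwise mutation picture). Sampled individuals
#' are kept distinct: jitter is redrawn for any colliding profiles so every
#' row is a unique haplotype. Per-locus mutation rates are drawn log-uniform
#' in a realistic Y-STR range (about 5e-4 to 1e-2 per generation) and turned
#' into \{1, 2, 4\} weights with [str_weights()].
#'
#' @param n_individuals,n_loci,n_populations positive integers.
#' @param seed integer seed; the global RNG state is restored on exit.
#' @return an \code{"str_table"} with populations, mutation rates and
#'   weights filled in.
#' @examples
#' tab <- str_fixture(12, 5, 3, seed = 1)
#' table(tab$populations)
#' @export
str_fixture <- function(n_individuals, n_loci, n_populations, seed) {
  if (any(c(n_individuals, n_loci, n_populations) < 1L))
    stop_validation("all fixture dimensions must be positive")
  if (n_populations > n_individuals)
    stop_validation("more populations than individuals")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  pop <- sort(rep_len(seq_len(n_populations), n_individuals))
  centroids <- matrix(sample(8:24, n_populations * n_loci, replace = TRUE),
    n_populations, n_loci)
  jitter_row <- function(k)
    sample(c(-1L, 0L, 1L), k, replace = TRUE, prob = c(0.15, 0.7, 0.15))
  counts <- t(vapply(seq_len(n_individuals), function(i)
    pmax(centroids[pop[i], ] + jitter_row(n_loci), 0L), integer(n_loci)))
  # enforce distinct haplotypes: redraw jitter for later duplicates
  repeat {
    dup <- which(duplicated(apply(counts, 1L, paste, collapse = ",")))
    if (length(dup) == 0L) break
    for (i in dup)
      counts[i, ] <- pmax(centroids[pop[i], ] + jitter_row(n_loci), 0L)
  }
  within_pop_index <- stats::ave(seq_along(pop), pop, FUN = seq_along)
  ids <- sprintf("P%02d_%02d", pop, within_pop_index)
  rownames(counts) <- ids
  colnames(counts) <- sprintf("STR%02d", seq_len(n_loci))
  rates <- 10^stats::runif(n_loci, -3.3, -2)
  str_table(counts, weights = str_weights(rates),
    populations = sprintf("pop%02d", pop), mutation_rates = rates)
}
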