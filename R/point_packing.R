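#' Point-packing parameters
#'
#' Bundles the hyperparameters of the anchor-selection step. The minimum
#' distance between anchors is expressed as a ratio of the junction length
#' (`d_min = ceiling(min_distance_ratio * L)`), so one setting applies across
#' length strata. The defaults (ratio 0.6, population 1000, material rate 50,
#' 50 offspring with a 20-offspring stagnation stop) are the package defaults
#' for the whole pipeline.
#'
#' @param min_distance_ratio Minimum anchor-pair Hamming distance divided by
#'   junction length, in `(0, 1]`.
#' @param population_size Number of candidate packings in the evolutionary
#'   population.
#' @param random_material_rate Number of points drawn at random from the input
#'   set (without replacement) and injected into each recombination.
#' @param generations Number of offspring produced by the steady-state loop.
#' @param stagnation Stop early after this many consecutive offspring that did
#'   not improve the population.
#' @return A list of class `packing_params`.
#' @export
packing_params <- function(min_distance_ratio = 0.6, population_size = 1000,
                           random_material_rate = 50, generations = 50,
                           stagnation = 20) {
  stopifnot(min_distance_ratio > 0, min_distance_ratio <= 1,
            population_size >= 1, random_material_rate >= 0, generations >= 1)
  structure(
    list(min_distance_ratio = min_distance_ratio,
         population_size = as.integer(population_size),
         random_material_rate = as.integer(random_material_rate),
         generations = as.integer(generations),
         stagnation = as.integer(stagnation)),
    class = "packing_params"
  )
}

#' Greedy lexicode point packing
#'
#' Conway's lexicode construction: scan the points in the given order and
#' accept a point iff its Hamming distance to every previously accepted point
#' is at least `d_min`. Deterministic given the input order; permuting the
#' input may change membership but never violates the distance constraint.
#'
#' @param points Character vector of equal-length DNA strings.
#' @param d_min Minimum pairwise Hamming distance (integer >= 1).
#' @return Character vector of accepted points, in acceptance order.
#' @examples
#' conway_lexicode(c("AAAA", "AAAT", "AATT", "TTTT"), d_min = 2)
#' @export
conway_lexicode <- function(points, d_min) {
  stopifnot(d_min >= 1)
  if (length(points) == 0L) return(character(0))
  enc <- encode_sequences(points)
  points[cpp_lexicode(enc, as.integer(d_min))]
}

#' Recombine two packings (Conway's variation operator)
#'
#' Takes the union of two packings, augments it with `rate` points sampled
#' uniformly without replacement from `pool`, shuffles, and re-runs the
#' lexicode scan, so the offspring again satisfies the minimum-distance
#' constraint. Injected points come from the input point set itself — anchors
#' must be real sequences to serve as distance references.
#'
#' @param parent_a,parent_b Character vectors of anchors (same length, same
#'   `d_min` regime).
#' @param pool Character vector of candidate points to inject.
#' @param rate Number of pool points to inject (capped at `length(pool)`).
#' @param d_min Minimum pairwise Hamming distance.
#' @return Character vector of anchors satisfying the constraint.
#' @export
conway_variation <- function(parent_a, parent_b, pool, rate, d_min) {
  stopifnot(rate >= 0)
  extra <- if (rate > 0 && length(pool) > 0) {
    pool[sample.int(length(pool), min(rate, length(pool)))]
  } else character(0)
  cand <- unique(c(parent_a, parent_b, extra))
  conway_lexicode(cand[sample.int(length(cand))], d_min)
}

#' Select maximally spaced anchors by evolutionary point packing
#'
#' Initializes `population_size` packings by running the lexicode scan on
#' independent random orderings of the points, then runs a steady-state loop:
#' two parents are chosen uniformly at random, recombined with
#' [conway_variation()], and the offspring replaces the smallest member of the
#' population if it is strictly larger. Fitness is packing cardinality — more
#' anchors give a finer distance-vector embedding. Reproducible under a fixed
#' RNG state.
#'
#' @param points Character vector of equal-length DNA strings (the length
#'   stratum being partitioned). Duplicates are ignored.
#' @param params A [packing_params()] list.
#' @return Character vector of anchors; every pair is at Hamming distance
#'   `>= ceiling(min_distance_ratio * L)`.
#' @export
evolve_packing <- function(points, params = packing_params()) {
  points <- unique(points)
  if (length(points) == 0L) return(character(0))
  if (length(points) == 1L) return(points)
  L <- nchar(points[1L])
  d_min <- as.integer(ceiling(params$min_distance_ratio * L))
  enc <- encode_sequences(points)
  n <- length(points)

  orders <- vapply(seq_len(params$population_size), function(i) sample.int(n),
                   integer(n))
  pop <- lapply(cpp_lexicode_population(enc, orders, d_min),
                function(idx) points[idx])

  sizes <- lengths(pop)
  stagnant <- 0L
  for (g in seq_len(params$generations)) {
    if (stagnant >= params$stagnation) break
    pa <- sample.int(length(pop), 1L)
    pb <- sample.int(length(pop), 1L)
    child <- conway_variation(pop[[pa]], pop[[pb]], points,
                              params$random_material_rate, d_min)
    worst <- which.min(sizes)
    if (length(child) > sizes[worst]) {
      pop[[worst]] <- child
      sizes[worst] <- length(child)
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
    }
  }
  pop[[which.max(sizes)]]
}
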