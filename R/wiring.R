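#' Fixed in-degree random wiring
#'
#' Draws, for every target neuron, exactly `in_degree` distinct presynaptic
#' partners uniformly without replacement from the source population. When
#' source and target are the same population (`self = FALSE`, the default
#' for recurrent projections), self-connections are excluded. With fixed
#' in-degree, source out-degrees follow a binomial distribution.
#'
#' @param n_source number of source neurons
#' @param n_target number of target neurons
#' @param in_degree afferents per target neuron
#' @param self logical; may a neuron connect to itself when the populations
#'   coincide? Only consulted when `same_pop = TRUE`.
#' @param same_pop logical; are source and target the same population?
#' @return list of integer vectors, one per target, each of length
#'   `in_degree` with source indices in `1:n_source`
#' @export
wire_fixed_indegree <- function(n_source, n_target, in_degree,
                                same_pop = FALSE, self = FALSE) {
  n_avail <- if (same_pop && !self) n_source - 1L else n_source
  if (in_degree > n_avail)
    stop("in_degree (", in_degree, ") exceeds available sources (", n_avail, ")")
  if (in_degree == 0L)
    return(replicate(n_target, integer(0), simplify = FALSE))
  lapply(seq_len(n_target), function(j) {
    if (same_pop && !self) {
      pool <- seq_len(n_source)[-j]
      pool[sample.int(n_source - 1L, in_degree)]
    } else {
      sample.int(n_source, in_degree)
    }
  })
}

#' Realize the wiring of a network configuration
#'
#' Expands every projection of a `network_config` into explicit edge lists
#' (source id, target id, weight, delay in integration steps) using fixed
#' in-degree sampling. Projections may carry either a scalar delay or a
#' `[delay_min, delay_max]` range, in which case each connection draws its
#' delay uniformly from the range (rounded to the nearest step, floor one
#' step).
#'
#' Wiring is the only structural randomness; holding `seed` fixed while
#' varying trial seeds isolates input variability across trials.
#'
#' @param config a `network_config`
#' @param seed integer seed for the wiring stream
#' @param step_ms integration step used to discretize delays
#' @return object of class `network_wiring`: list of per-projection edge
#'   tables (`src`, `tgt` global 1-based ids, `w` nS, `delay_steps`)
#' @export
wire_network <- function(config, seed, step_ms = 0.1) {
  stopifnot(inherits(config, "network_config"))
  set.seed(seed)
  off <- population_offsets(config)
  edges <- lapply(seq_len(nrow(config$projections)), function(k) {
    pr <- config$projections[k, ]
    sp <- match(pr$src, names(config$populations))
    tp <- match(pr$tgt, names(config$populations))
    ns <- config$populations[[sp]]$n
    nt <- config$populations[[tp]]$n
    adj <- wire_fixed_indegree(ns, nt, pr$in_degree, same_pop = sp == tp)
    src <- unlist(adj, use.names = FALSE) + off[sp]
    tgt <- rep(seq_len(nt) + off[tp], lengths(adj))
    ne <- length(src)
    if (is.na(pr$delay_max) || pr$delay_max == pr$delay_min) {
      dsteps <- rep(max(1L, round(pr$delay_min / step_ms)), ne)
    } else {
      d <- runif(ne, pr$delay_min, pr$delay_max)
      dsteps <- pmax(1L, round(d / step_ms))
    }
    list(projection = k, src = src, tgt = tgt,
         w = rep(pr$weight, ne), delay_steps = as.integer(dsteps),
         channel = pr$channel, tgt_pop = tp)
  })
  structure(list(edges = edges, seed = seed, step_ms = step_ms),
            class = "network_wiring")
}
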