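# Independent brute-force oracles: naive loop-until-fixed-point expansion
# and a reachability-based seed definition.  Both deliberately ignore the
# package's worklist/condensation implementations.

oracle_expand <- function(seeds, network, order = NULL) {
  rxns <- network$reactions
  if (!is.null(order)) rxns <- rxns[order]
  scope <- unique(seeds)
  repeat {
    changed <- FALSE
    for (r in rxns) {
      if (all(r$substrates %in% scope)) {
        new <- setdiff(r$products, scope)
        if (length(new)) {
          scope <- c(scope, new)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sort(scope)
}

# compound c is a seed iff no reaction produces a member of c's strongly
# connected component from a compound outside that component
oracle_seed_set <- function(network) {
  cmps <- sort(unique(unlist(lapply(network$reactions, function(r) {
    c(r$substrates, r$products)
  }))))
  adj <- stats::setNames(vector("list", length(cmps)), cmps)
  for (r in network$reactions) {
    for (s in r$substrates) adj[[s]] <- union(adj[[s]], r$products)
  }
  reach <- lapply(cmps, function(c0) {
    seen <- c0
    queue <- c0
    while (length(queue)) {
      x <- queue[[1]]
      queue <- queue[-1]
      nb <- setdiff(adj[[x]], seen)
      seen <- c(seen, nb)
      queue <- c(queue, nb)
    }
    seen
  })
  names(reach) <- cmps
  seeds <- character()
  for (c0 in cmps) {
    comp <- cmps[vapply(cmps, function(v) {
      c0 %in% reach[[v]] && v %in% reach[[c0]]
    }, TRUE)]
    incoming <- FALSE
    for (r in network$reactions) {
      if (any(r$products %in% comp) && any(!r$substrates %in% comp)) {
        incoming <- TRUE
        break
      }
    }
    if (!incoming) seeds <- c(seeds, c0)
  }
  sort(seeds)
}
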