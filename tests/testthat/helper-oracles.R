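# Shared helpers: independent brute-force oracles and random generators.

# Independent single-event neighbour generator: nested loops over explicit
# event constructions, deduplicated on (type, neighbour text). Written
# separately from enumerate_events() so the two can cross-check.
oracle_neighbors <- function(profile, caps = arch_caps(),
                             gain_pool = character()) {
  res <- character(0)  # "type|neighbour-text"
  try_add <- function(ev) {
    nb <- tryCatch(apply_event(profile, ev, caps), error = function(e) NULL)
    if (!is.null(nb))
      res <<- union(res, paste(ev$type, profile_text(nb), sep = "|"))
  }
  n <- length(profile)
  for (i in seq_len(n)) {
    g <- profile[[i]]
    L <- length(arch_tokens(g))
    if (L >= 2L) for (at in 1:(L - 1L)) try_add(event_separation(g, at))
    for (from in seq_len(L)) for (to in from:L) {
      if (to - from + 1L < L) try_add(event_deletion(g, from, to))
      try_add(event_duplication(g, from, to))
    }
    try_add(event_gene_loss(g))
    for (j in seq_len(n)) if (j != i) try_add(event_fusion(g, profile[[j]]))
  }
  for (a in gain_pool) try_add(event_gene_gain(a))
  sort(res, method = "radix")
}

# Exhaustive minimum over all ancestral assignments of universe states to
# internal nodes, transition costs taken from a precomputed matrix D
# (rows/cols named by profile text). Independent of the Sankoff DP.
oracle_min_cost <- function(tree, tips, D) {
  ntip <- length(tree$tip.label)
  internals <- (ntip + 1L):(ntip + tree$Nnode)
  keys <- rownames(D)
  tip_keys <- vapply(tree$tip.label, function(nm)
    archevol::profile_text(tips[[nm]]), "")
  grid <- do.call(expand.grid,
                  c(rep(list(seq_along(keys)), length(internals)),
                    list(KEEP.OUT.ATTRS = FALSE)))
  edge <- tree$edge
  best <- Inf
  node_state <- integer(ntip + tree$Nnode)
  node_state[seq_len(ntip)] <- match(tip_keys, keys)
  for (r in seq_len(nrow(grid))) {
    node_state[internals] <- as.integer(unlist(grid[r, ]))
    cost <- 0
    for (e in seq_len(nrow(edge))) {
      cost <- cost + D[node_state[[edge[e, 1L]]], node_state[[edge[e, 2L]]]]
      if (cost >= best) break
    }
    if (cost < best) best <- cost
  }
  best
}

# random small profile over the default alphabet, within caps
random_profile <- function(max_genes = 2L, max_len = 3L) {
  repeat {
    k <- sample.int(max_genes + 1L, 1L) - 1L
    genes <- character(0)
    if (k > 0L) genes <- vapply(seq_len(k), function(i) {
      len <- sample.int(max_len, 1L)
      arch_from_tokens(sample(default_alphabet(), len, replace = TRUE))
    }, "")
    p <- canonical_profile(genes)
    if (profile_within_caps(p, arch_caps())) return(p)
  }
}

case_study_profiles <- function() {
  fx <- folate_fixture()
  profs <- unname(fx$amorphea_tips)
  profs[!duplicated(vapply(profs, profile_text, ""))]
}
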