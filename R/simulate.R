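# Continuous-time simulation of architecture evolution: per branch, a jump
# process whose total hazard is sum over event types of rate(type) times the
# number of applicable instances under the grammar and caps. Cap-violating
# instances are simply excluded from the applicable set (their contribution
# is zero), so hazards stay well-defined.

#' Default demo event rates
#'
#' Per applicable instance, per unit branch length. Defaults echo the
#' finding that fissions and losses occur at high relative rates: deletion
#' and separation types 0.2, gene loss 0.2, duplication and fusion 0.1, gain
#' 0 (off).
#'
#' @param ... Named overrides by event type.
#' @return Named nonnegative numeric vector over [event_types()].
#' @export
default_rates <- function(...) {
  rates <- c(fusion = 0.1, fission_separation = 0.2,
             fission_domain_loss = 0.2, domain_contraction = 0.2,
             domain_duplication = 0.1, gene_loss = 0.2, gene_gain = 0)
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(rates))
    if (length(bad))
      stop("unknown event type in rate model: ", paste(bad, collapse = ", "),
           call. = FALSE)
    rates[names(dots)] <- dots
  }
  if (any(rates < 0)) stop("event rates must be nonnegative", call. = FALSE)
  rates
}

#' Simulate architecture evolution along a tree
#'
#' Gillespie simulation: starting from `root_state`, each branch runs a jump
#' process with exponential waiting times; at each jump one applicable event
#' instance is chosen with probability proportional to its type rate times
#' its instance multiplicity (identical gene copies each count). Fully
#' reproducible for a fixed seed.
#'
#' @param tree Rooted `phylo` tree with branch lengths on every edge.
#' @param root_state Root profile (vector or profile string).
#' @param rates Named rate vector, see [default_rates()].
#' @param caps State caps.
#' @param seed Integer RNG seed.
#' @param gain_pool Architectures available to `gene_gain` (required when
#'   its rate is positive).
#' @return Object of class `arch_simulation`: `tip_profiles` (named list),
#'   `node_states` (profiles at every node), `true_events` (list of
#'   `list(branch, time, event, type)`), `seed`.
#' @export
simulate_evolution <- function(tree, root_state, rates = default_rates(),
                               caps = arch_caps(), seed = 1L,
                               gain_pool = character()) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("simulation requires a branch length on every edge", call. = FALSE)
  rates <- rates[event_types()]
  if (rates[["gene_gain"]] > 0 && !length(gain_pool))
    stop("a positive gene_gain rate requires a nonempty gain_pool",
         call. = FALSE)
  rs <- if (is.character(root_state) && length(root_state) == 1L)
    parse_profile(root_state) else canonical_profile(root_state)
  if (!profile_within_caps(rs, caps))
    stop("cap error: root state violates state caps", call. = FALSE)

  set.seed(seed)
  labels <- node_labels(tree)
  root <- root_node(tree)
  states <- vector("list", length(labels))
  states[[root]] <- rs
  events <- list()
  pool <- if (rates[["gene_gain"]] > 0) unique(gain_pool) else character(0)

  for (v in traverse_preorder(tree)) {
    if (v == root) next
    st <- states[[node_parent(tree, v)]]
    len <- branch_length_above(tree, v)
    t <- 0
    repeat {
      inst <- enumerate_instances(st, caps, gain_pool = pool)
      if (!length(inst)) break
      hz <- vapply(inst, function(x) rates[[x$type]] * x$mult, numeric(1L))
      total <- sum(hz)
      if (total <= 0) break
      dt <- stats::rexp(1L, total)
      if (t + dt > len) break
      t <- t + dt
      pick <- inst[[sample.int(length(inst), 1L, prob = hz)]]
      st <- pick$profile
      events[[length(events) + 1L]] <-
        list(branch = labels[[v]], time = t, event = pick$event,
             type = pick$type)
    }
    states[[v]] <- st
  }

  structure(list(tip_profiles = stats::setNames(
                   states[seq_along(tree$tip.label)], tree$tip.label),
                 node_states = stats::setNames(states, labels),
                 true_events = events, seed = seed, tree = tree),
            class = "arch_simulation")
}

#' @export
print.arch_simulation <- function(x, ...) {
  cat(sprintf("<simulation> seed %d: %d event(s) over %d branches\n",
              x$seed, length(x$true_events), nrow(x$tree$edge)))
  invisible(x)
}

#' Replay a simulation's event log from the root state
#'
#' Applies the recorded events branch by branch (in recorded order) starting
#' from `root_state`; used to check the replay invariant that the log
#' reproduces the simulated tip profiles exactly.
#'
#' @param tree The simulated tree.
#' @param root_state Root profile.
#' @param true_events Event log from [simulate_evolution()].
#' @param caps State caps.
#' @return Named list of tip profiles.
#' @export
replay_events <- function(tree, root_state, true_events,
                          caps = arch_caps()) {
  rs <- if (is.character(root_state) && length(root_state) == 1L)
    parse_profile(root_state) else canonical_profile(root_state)
  sc <- arch_scenario(rs, lapply(true_events, function(e)
    list(branch = e$branch, event = e$event)), label = "replay")
  states <- play_scenario(tree, sc, caps)
  states[tree$tip.label]
}

#' Scenario built from a simulation log
#'
#' @param sim An `arch_simulation`.
#' @return An `arch_scenario` whose placements are the simulation's true
#'   events.
#' @export
scenario_from_simulation <- function(sim) {
  stopifnot(inherits(sim, "arch_simulation"))
  arch_scenario(sim$node_states[[root_node(sim$tree)]],
                lapply(sim$true_events, function(e)
                  list(branch = e$branch, event = e$event)),
                label = sprintf("simulation seed %d", sim$seed))
}

universe_from_profiles <- function(profiles, provenance = "explicit list") {
  keys <- vapply(profiles, profile_text, "")
  keep <- !duplicated(keys)
  profiles <- profiles[keep]; keys <- keys[keep]
  ord <- order(keys, method = "radix")
  structure(list(states = profiles[ord], keys = keys[ord],
                 provenance = provenance),
            class = "state_universe")
}

#' Simulate-then-infer recovery experiment
#'
#' For each replicate: simulate architecture evolution, then run an
#' unconstrained Sankoff reconstruction over a universe containing the
#' simulated tip profiles plus every profile realised along the true
#' history (so the true scenario is always representable), and record the
#' true event count and cost, the inferred minimal cost, and whether the
#' inferred per-type counts of the first MPR match the truth. The parsimony
#' lower bound (inferred minimal cost is at most the true scenario cost) is
#' asserted on every replicate.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param root_state Root profile.
#' @param rates Rate model for simulation.
#' @param costs Cost model for inference.
#' @param replicates Number of replicates.
#' @param seed Base RNG seed (replicate r uses `seed + r`).
#' @param caps State caps.
#' @return Data frame with one row per replicate: `replicate`, `n_events`,
#'   `true_cost`, `inferred_cost`, `exact` (cost equality) and
#'   `counts_match`.
#' @export
recovery_experiment <- function(tree, root_state, rates = default_rates(),
                                costs = default_costs(), replicates = 20L,
                                seed = 1L, caps = arch_caps()) {
  stopifnot(replicates >= 1L)
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    sim <- simulate_evolution(tree, root_state, rates, caps,
                              seed = seed + r)
    true_types <- vapply(sim$true_events, `[[`, "", "type")
    true_cost <- if (length(true_types)) sum(costs[true_types]) else 0

    # every profile realised along the true history, including mid-branch
    mid <- list()
    for (v in traverse_preorder(sim$tree)) {
      if (v == root_node(sim$tree)) next
      st <- sim$node_states[[node_labels(sim$tree)[[node_parent(sim$tree, v)]]]]
      mid[[length(mid) + 1L]] <- st
      for (e in sim$true_events) {
        if (e$branch != node_labels(sim$tree)[[v]]) next
        st <- apply_event(st, e$event, caps)
        mid[[length(mid) + 1L]] <- st
      }
    }
    uni <- universe_from_profiles(
      c(unname(sim$tip_profiles), unname(sim$node_states), mid),
      provenance = "simulated tips + true history states")
    fit <- sankoff(tree, sim$tip_profiles, costs = costs, universe = uni,
                   max_mprs = 1L, caps = caps)
    if (fit$total_cost > true_cost + 1e-9)
      stop("parsimony lower bound violated in replicate ", r, call. = FALSE)
    inferred_counts <- count_by_type(extract_events(fit))
    true_counts <- count_by_type(lapply(sim$true_events, function(e)
      list(branch = e$branch, event = e$event, type = e$type)))
    rows[[r]] <- data.frame(
      replicate = r, n_events = length(sim$true_events),
      true_cost = true_cost, inferred_cost = fit$total_cost,
      exact = abs(fit$total_cost - true_cost) <= 1e-9,
      counts_match = identical(inferred_counts, true_counts))
  }
  do.call(rbind, rows)
}
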