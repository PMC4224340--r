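# Weighted-parsimony reconstruction of ancestral genome profiles: a Sankoff
# dynamic program over a finite state universe, with transition costs given
# by shortest event paths within the universe, and full enumeration of
# most-parsimonious reconstructions (MPRs) up to a cap.

as_profiles <- function(tips) {
  if (is.character(tips)) tips <- as.list(tips)
  stopifnot(is.list(tips), !is.null(names(tips)), all(nzchar(names(tips))))
  lapply(tips, function(p) {
    if (is.character(p) && length(p) == 1L) parse_profile(p)
    else canonical_profile(p)
  })
}

#' Build the ancestral state universe
#'
#' The finite set of genome profiles over which the parsimony dynamic
#' program runs: the distinct observed tip profiles (plus any root
#' constraint), closed under up to `depth` applications of single grammar
#' events. `gene_gain` is excluded from the closure; gains enter only as
#' transitions priced by the cost model.
#'
#' @param tips Named list of tip profiles (canonical character vectors) or a
#'   named character vector of profile strings.
#' @param root_constraint Optional profile (vector or string) that must be a
#'   member of the universe.
#' @param depth Closure depth, `0 <= depth <= 3`.
#' @param caps State caps.
#' @param max_states Guard on the universe size.
#' @return An object of class `state_universe`: list with `states` (list of
#'   profiles), `keys` (profile texts) and `provenance`.
#' @export
build_universe <- function(tips, root_constraint = NULL, depth = 1L,
                           caps = arch_caps(), max_states = 5000L) {
  stopifnot(length(tips) >= 1L)
  tips <- as_profiles(tips)
  if (depth < 0L || depth > 3L)
    stop("universe closure depth must be between 0 and 3", call. = FALSE)
  seeds <- tips
  if (!is.null(root_constraint)) {
    rc <- if (is.character(root_constraint) && length(root_constraint) == 1L)
      parse_profile(root_constraint) else canonical_profile(root_constraint)
    seeds <- c(seeds, list(rc))
  }
  states <- list()
  keys <- character(0)
  push <- function(p) {
    k <- profile_text(p)
    if (k %in% keys) return(FALSE)
    keys[[length(keys) + 1L]] <<- k
    states[[length(states) + 1L]] <<- p
    TRUE
  }
  for (p in seeds) push(p)
  frontier <- states
  d <- 0L
  while (d < depth && length(frontier)) {
    nxt <- list()
    for (p in frontier) {
      for (nb in memo_neighbors(p, caps, FALSE, character(0))) {
        if (push(nb$profile)) nxt[[length(nxt) + 1L]] <- nb$profile
        if (length(keys) > max_states)
          stop("state universe exceeds ", max_states,
               " profiles; reduce the closure depth", call. = FALSE)
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  ord <- order(keys, method = "radix")
  structure(list(states = states[ord], keys = keys[ord],
                 provenance = sprintf(
                   "%d observed tip profile(s)%s, closed to depth %d (gains excluded)",
                   length(unique(vapply(tips, profile_text, ""))),
                   if (is.null(root_constraint)) "" else " + root constraint",
                   depth)),
            class = "state_universe")
}

#' @export
print.state_universe <- function(x, ...) {
  cat(sprintf("<state universe> %d profiles (%s)\n", length(x$keys),
              x$provenance))
  invisible(x)
}

# All-pairs shortest-path matrix over universe states, where moves are
# single grammar events between universe members (paths never leave the
# universe). Gains are included as moves iff their cost is finite, drawing
# from the architectures present anywhere in the universe.
universe_distance_matrix <- function(universe, costs = default_costs(),
                                     caps = arch_caps(), max_cost = 12) {
  n <- length(universe$keys)
  costs <- costs[event_types()]
  allow_gain <- is.finite(costs[["gene_gain"]])
  pool <- sort(unique(unlist(universe$states, use.names = FALSE)),
               method = "radix")
  if (!allow_gain) pool <- character(0)
  idx <- seq_len(n)
  names(idx) <- universe$keys
  adj <- vector("list", n)       # per state: list(to = int vec, w = num vec)
  for (i in idx) {
    nbs <- memo_neighbors(universe$states[[i]], caps, allow_gain, pool)
    to <- integer(0); w <- numeric(0)
    for (nb in nbs) {
      j <- idx[profile_text(nb$profile)]
      if (is.na(j)) next
      to <- c(to, j); w <- c(w, costs[[nb$event$type]])
    }
    # parallel edges: keep the cheapest
    if (length(to)) {
      keep <- tapply(w, to, min)
      adj[[i]] <- list(to = as.integer(names(keep)), w = as.numeric(keep))
    } else adj[[i]] <- list(to = integer(0), w = numeric(0))
  }
  D <- matrix(Inf, n, n, dimnames = list(universe$keys, universe$keys))
  for (s in idx) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    done <- rep(FALSE, n)
    repeat {
      u <- which(!done & is.finite(dist))
      if (!length(u)) break
      u <- u[which.min(dist[u])]
      if (dist[u] > max_cost + 1e-9) break
      done[u] <- TRUE
      a <- adj[[u]]
      if (length(a$to)) {
        nd <- dist[u] + a$w
        upd <- nd < dist[a$to] - 1e-12
        dist[a$to[upd]] <- nd[upd]
      }
    }
    dist[dist > max_cost + 1e-9] <- Inf
    D[s, ] <- dist
  }
  D
}

#' Sankoff weighted-parsimony reconstruction
#'
#' Bottom-up dynamic program assigning a genome profile from a finite state
#' universe to every node of a rooted tree, minimising the total event-path
#' cost over all branches; top-down traceback enumerates all
#' most-parsimonious reconstructions up to `max_mprs`. Branch lengths are
#' ignored. Polytomies are handled (children contribute independently).
#'
#' @param tree A rooted `phylo` tree.
#' @param tips Named list/character of tip profiles; every tip of the tree
#'   must be present.
#' @param costs Event cost model.
#' @param universe A `state_universe`, or `NULL` to build one from the tips
#'   at `universe_depth`.
#' @param root_constraint Optional profile the root is fixed to (must lie in
#'   the universe); by default the root is free.
#' @param max_mprs Cap on enumerated reconstructions (truncation is
#'   flagged).
#' @param universe_depth Closure depth used when `universe` is `NULL`.
#' @param caps State caps.
#' @param max_cost Transition-cost cutoff (pairs farther apart are treated
#'   as unreachable).
#' @return An object of class `sankoff_fit`: total minimal cost, optimal
#'   root states, per-state root scores, and a list of `Reconstruction`s
#'   (`assignment`, `branch_paths`, `total_cost`).
#' @export
sankoff <- function(tree, tips, costs = default_costs(), universe = NULL,
                    root_constraint = NULL, max_mprs = 256L,
                    universe_depth = 1L, caps = arch_caps(), max_cost = 12) {
  stopifnot(inherits(tree, "phylo"))
  tips <- as_profiles(tips)
  missing_tips <- setdiff(tree$tip.label, names(tips))
  if (length(missing_tips))
    stop("tip missing from profile mapping: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)
  rc <- NULL
  if (!is.null(root_constraint)) {
    rc <- if (is.character(root_constraint) && length(root_constraint) == 1L)
      parse_profile(root_constraint) else canonical_profile(root_constraint)
  }
  if (is.null(universe))
    universe <- build_universe(tips, root_constraint = rc,
                               depth = universe_depth, caps = caps)
  keys <- universe$keys
  nst <- length(keys)
  if (!is.null(rc) && !(profile_text(rc) %in% keys))
    stop("root constraint outside the state universe", call. = FALSE)

  D <- universe_distance_matrix(universe, costs, caps, max_cost)

  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- root_node(tree)
  S <- matrix(Inf, nst, nnode, dimnames = list(keys, NULL))
  post <- traverse_postorder(tree)
  for (v in post) {
    if (v <= ntip) {
      k <- profile_text(tips[[tree$tip.label[[v]]]])
      if (!(k %in% keys))
        stop("tip profile '", k, "' missing from the state universe",
             call. = FALSE)
      S[k, v] <- 0
    } else {
      kids <- node_children(tree, v)
      acc <- numeric(nst)
      for (ch in kids) {
        # min over child states t of D[s, t] + S[t, ch], vectorised over s
        acc <- acc + apply(D + rep(S[, ch], each = nst), 1L, min)
      }
      S[, v] <- acc
    }
  }

  root_scores <- S[, root]
  if (!is.null(rc)) {
    total <- root_scores[[profile_text(rc)]]
    root_states <- profile_text(rc)
  } else {
    total <- min(root_scores)
    root_states <- keys[abs(root_scores - total) <= 1e-9]
  }
  if (!is.finite(total))
    stop("no finite-cost reconstruction: universe too small or max_cost too tight",
         call. = FALSE)

  # --- traceback: enumerate MPR assignments up to max_mprs ---
  truncated <- FALSE
  child_options <- function(s_idx, ch) {
    tot <- D[s_idx, ] + S[, ch]
    m <- min(tot)
    which(abs(tot - m) <= 1e-9)
  }
  assign_subtree <- function(v, s_idx, budget) {
    # returns list of assignments (named int vectors node->state idx)
    if (v <= ntip) return(list(stats::setNames(s_idx, v)))
    kids <- node_children(tree, v)
    combos <- list(stats::setNames(s_idx, v))
    for (ch in kids) {
      opts <- child_options(s_idx, ch)
      ch_lists <- list()
      for (t_idx in opts) {
        subs <- assign_subtree(ch, t_idx, budget)
        ch_lists <- c(ch_lists, subs)
        if (length(ch_lists) > budget) { truncated <<- TRUE; break }
      }
      new_combos <- list()
      for (a in combos) for (b in ch_lists) {
        new_combos[[length(new_combos) + 1L]] <- c(a, b)
        if (length(new_combos) > budget) { truncated <<- TRUE; break }
      }
      combos <- new_combos
      if (length(combos) > budget) combos <- combos[seq_len(budget)]
    }
    combos
  }

  assignments <- list()
  for (rk in root_states) {
    if (length(assignments) >= max_mprs) { truncated <- TRUE; break }
    budget <- max_mprs - length(assignments) + 1L
    subs <- assign_subtree(root, match(rk, keys), budget)
    assignments <- c(assignments, subs)
  }
  if (length(assignments) > max_mprs) {
    truncated <- TRUE
    assignments <- assignments[seq_len(max_mprs)]
  }

  labels <- node_labels(tree)
  path_memo <- new.env(parent = emptyenv())
  branch_path <- function(from_key, to_key) {
    mk <- paste(from_key, to_key, sep = "\r")
    hit <- path_memo[[mk]]
    if (!is.null(hit)) return(hit)
    p <- event_distance(parse_profile(from_key), parse_profile(to_key),
                        costs = costs, caps = caps, max_cost = max_cost)
    assign(mk, p, envir = path_memo)
    p
  }
  reconstructions <- lapply(assignments, function(a) {
    amap <- stats::setNames(keys[a], labels[as.integer(names(a))])
    paths <- list()
    tot <- 0
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      fk <- keys[a[[as.character(par)]]]
      tk <- keys[a[[as.character(ch)]]]
      p <- branch_path(fk, tk)
      paths[[labels[[ch]]]] <- p
      tot <- tot + p$cost
    }
    structure(list(assignment = amap, branch_paths = paths,
                   total_cost = tot),
              class = "arch_reconstruction")
  })

  structure(list(tree = tree, tips = tips, costs = costs,
                 universe = universe, distance_matrix = D,
                 root_scores = root_scores, total_cost = total,
                 root_states = sort(root_states, method = "radix"),
                 constrained = !is.null(rc),
                 reconstructions = reconstructions,
                 mpr_truncated = truncated),
            class = "sankoff_fit")
}

#' @export
print.sankoff_fit <- function(x, ...) {
  cat("Sankoff weighted-parsimony reconstruction\n")
  cat(sprintf("  tips: %d   universe: %d profiles\n",
              length(x$tree$tip.label), length(x$universe$keys)))
  cat(sprintf("  minimal total cost: %g (%s root)\n", x$total_cost,
              if (x$constrained) "constrained" else "free"))
  cat(sprintf("  optimal root state(s): %s\n",
              paste(x$root_states, collapse = "  ")))
  cat(sprintf("  MPRs enumerated: %d%s\n", length(x$reconstructions),
              if (x$mpr_truncated) " (truncated)" else ""))
  invisible(x)
}

#' Extract the per-branch events of a reconstruction
#'
#' Concatenates the minimal event paths of every branch of one
#' most-parsimonious reconstruction. Each event carries its grammar
#' classification (see [classify_event()]).
#'
#' @param rec An `arch_reconstruction` (one element of
#'   `sankoff_fit$reconstructions`), or a `sankoff_fit` (its first MPR is
#'   used).
#' @return A list of `list(branch = <child-node label>, event = <arch_event>,
#'   type = <EventType>)`.
#' @export
extract_events <- function(rec) {
  if (inherits(rec, "sankoff_fit")) rec <- rec$reconstructions[[1L]]
  stopifnot(inherits(rec, "arch_reconstruction"))
  out <- list()
  for (branch in names(rec$branch_paths)) {
    p <- rec$branch_paths[[branch]]
    if (!p$reachable) next
    for (ev in p$events) {
      parent_gene <- if (length(ev$inputs)) ev$inputs[[1L]] else NA_character_
      out[[length(out) + 1L]] <-
        list(branch = branch, event = ev,
             type = classify_event(parent_gene, ev))
    }
  }
  out
}

#' Count events by type
#'
#' @param events List of branch events as produced by [extract_events()] or
#'   [scenario_events()].
#' @return Named integer vector over [event_types()], plus `fissions_total`
#'   (= `fission_separation` + `fission_domain_loss`).
#' @export
count_by_type <- function(events) {
  counts <- stats::setNames(integer(length(event_types())), event_types())
  for (e in events) counts[[e$type]] <- counts[[e$type]] + 1L
  c(counts, fissions_total = counts[["fission_separation"]] +
      counts[["fission_domain_loss"]])
}
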