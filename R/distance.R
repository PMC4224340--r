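# Minimum-cost event paths between genome profiles. event_distance() is an
# A* search over the profile graph generated by enumerate_events(); with an
# admissible, consistent heuristic it returns the same optimum as plain
# uniform-cost search, with the canonical profile-text tie-break among
# equal-priority frontier entries.

.arch_memo <- new.env(parent = emptyenv())

memo_neighbors <- function(profile, caps, allow_gain, gain_pool) {
  key <- paste(profile_text(profile), caps$max_copies, caps$max_genes,
               allow_gain, paste(gain_pool, collapse = ","), sep = "\r")
  hit <- .arch_memo[[key]]
  if (!is.null(hit)) return(hit)
  val <- enumerate_events(profile, caps, allow_gain = allow_gain,
                          gain_pool = gain_pool)
  assign(key, val, envir = .arch_memo)
  val
}

# deterministic C-locale string ordering test: is a < b?
str_lt <- function(a, b) {
  if (a == b) return(FALSE)
  identical(sort(c(a, b), method = "radix")[[1L]], a)
}

# binary min-heap over (priority, key) with radix-order tie-break on key
heap_new <- function() {
  e <- new.env(parent = emptyenv())
  e$f <- numeric(0); e$k <- character(0)
  e
}
heap_lt <- function(h, i, j) {
  h$f[[i]] < h$f[[j]] || (h$f[[i]] == h$f[[j]] && str_lt(h$k[[i]], h$k[[j]]))
}
heap_swap <- function(h, i, j) {
  tf <- h$f[[i]]; h$f[[i]] <- h$f[[j]]; h$f[[j]] <- tf
  tk <- h$k[[i]]; h$k[[i]] <- h$k[[j]]; h$k[[j]] <- tk
}
heap_push <- function(h, f, k) {
  h$f[[length(h$f) + 1L]] <- f
  h$k[[length(h$k) + 1L]] <- k
  i <- length(h$f)
  while (i > 1L) {
    p <- i %/% 2L
    if (heap_lt(h, i, p)) { heap_swap(h, i, p); i <- p } else break
  }
}
heap_pop <- function(h) {
  n <- length(h$f)
  if (n == 0L) return(NULL)
  top <- list(f = h$f[[1L]], k = h$k[[1L]])
  h$f[[1L]] <- h$f[[n]]; h$k[[1L]] <- h$k[[n]]
  h$f <- h$f[-n]; h$k <- h$k[-n]
  i <- 1L; n <- n - 1L
  repeat {
    l <- 2L * i; r <- l + 1L; m <- i
    if (l <= n && heap_lt(h, l, m)) m <- l
    if (r <= n && heap_lt(h, r, m)) m <- r
    if (m == i) break
    heap_swap(h, i, m); i <- m
  }
  top
}

profile_token_counts <- function(profile, alphabet) {
  counts <- setNames(integer(length(alphabet)), alphabet)
  if (length(profile)) {
    tab <- table(unlist(lapply(profile, arch_tokens)))
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

# Admissible, consistent lower bound on remaining cost:
#  - a domain symbol present in the target but absent here can only appear
#    through gene_gain;
#  - each event changes the gene count by at most one;
#  - token surplus needs at least one removing event, deficit at least one
#    adding event; and any difference at all needs at least one event.
astar_heuristic <- function(key, target_key, tok, target_tok, ngenes,
                            target_ngenes, costs) {
  if (key == target_key) return(0)
  h <- min(costs)
  missing <- target_tok > 0L & tok == 0L
  if (any(missing)) h <- max(h, costs[["gene_gain"]])
  count_min <- min(costs[["fusion"]], costs[["fission_separation"]],
                   costs[["gene_loss"]], costs[["gene_gain"]])
  h <- max(h, abs(ngenes - target_ngenes) * count_min)
  if (any(tok > target_tok))
    h <- max(h, min(costs[["fission_domain_loss"]],
                    costs[["domain_contraction"]], costs[["gene_loss"]]))
  if (any(tok < target_tok))
    h <- max(h, min(costs[["domain_duplication"]], costs[["gene_gain"]]))
  h
}

event_path <- function(events, cost, reachable = TRUE, states = NULL) {
  structure(list(events = events, cost = cost, reachable = reachable,
                 states = states),
            class = "event_path")
}

#' @export
print.event_path <- function(x, ...) {
  if (!x$reachable) {
    cat("<event path> unreachable\n")
    return(invisible(x))
  }
  cat(sprintf("<event path> cost %g, %d event(s)\n", x$cost,
              length(x$events)))
  for (ev in x$events) print(ev)
  invisible(x)
}

#' Minimum-cost event path between two genome profiles
#'
#' Best-first search for a cheapest sequence of grammar events transforming
#' `source` into `target` under a cost model. `gene_gain` moves are enabled
#' only when their cost is finite; the gain pool defaults to the distinct
#' architectures of the target profile.
#'
#' @param source,target Canonical profiles (character vectors), or profile
#'   strings which are parsed.
#' @param costs Named cost vector, see [default_costs()].
#' @param caps State caps, see [arch_caps()].
#' @param max_cost Search cutoff; pairs farther apart are reported
#'   unreachable.
#' @param gain_pool Architectures available to `gene_gain`; default the
#'   target's architectures.
#' @param all_paths If `TRUE`, enumerate all minimum-cost paths (capped).
#' @param max_paths Cap on the number of enumerated optimal paths.
#' @return An object of class `event_path` with elements `events` (list of
#'   `arch_event`), `cost`, `reachable` and `states` (profile texts along the
#'   path). With `all_paths = TRUE`, additionally `paths` (a list of
#'   `event_path`) and `paths_truncated`. An unreachable pair yields
#'   `reachable = FALSE` and `cost = Inf`.
#' @examples
#' event_distance("B-B-K-P", "B-B;K-P")$cost  # one fission by separation
#' @export
event_distance <- function(source, target, costs = default_costs(),
                           caps = arch_caps(), max_cost = 12,
                           gain_pool = NULL, all_paths = FALSE,
                           max_paths = 64L) {
  if (is.character(source) && length(source) == 1L && grepl("[;.]", source))
    source <- parse_profile(source)
  if (is.character(target) && length(target) == 1L && grepl("[;.]", target))
    target <- parse_profile(target)
  source <- canonical_profile(source)
  target <- canonical_profile(target)
  if (!profile_within_caps(source, caps) || !profile_within_caps(target, caps))
    stop("cap error: source or target profile violates state caps",
         call. = FALSE)
  stopifnot(max_cost >= 0)
  costs <- costs[event_types()]
  allow_gain <- is.finite(costs[["gene_gain"]])
  if (is.null(gain_pool)) gain_pool <- unique(target)
  gain_pool <- sort(unique(gain_pool), method = "radix")

  src_key <- profile_text(source)
  tgt_key <- profile_text(target)
  if (src_key == tgt_key)
    return(event_path(list(), 0, states = src_key))

  alphabet <- sort(unique(c(unlist(lapply(c(source, target, gain_pool),
                                          arch_tokens)), default_alphabet())),
                   method = "radix")
  tgt_tok <- profile_token_counts(target, alphabet)
  tgt_n <- length(target)

  states <- new.env(parent = emptyenv())   # key -> profile vector
  gs <- new.env(parent = emptyenv())       # key -> best g
  prev <- new.env(parent = emptyenv())     # key -> list(list(key, event)) all opt preds
  closed <- new.env(parent = emptyenv())
  assign(src_key, source, envir = states)
  assign(src_key, 0, envir = gs)

  use_heuristic <- !all_paths
  h0 <- if (use_heuristic)
    astar_heuristic(src_key, tgt_key, profile_token_counts(source, alphabet),
                    tgt_tok, length(source), tgt_n, costs) else 0
  open <- heap_new()
  heap_push(open, h0, src_key)

  best <- Inf
  repeat {
    top <- heap_pop(open)
    if (is.null(top)) break
    key <- top$k
    if (!is.null(closed[[key]])) next
    g <- gs[[key]]
    if (top$f > max_cost + 1e-9) break
    if (all_paths && top$f > best + 1e-9) break
    if (key == tgt_key) {
      best <- g
      if (!all_paths) break
      # keep settling states to collect every optimal predecessor
    }
    assign(key, TRUE, envir = closed)
    prof <- states[[key]]
    for (nb in memo_neighbors(prof, caps, allow_gain, gain_pool)) {
      c_ev <- costs[[nb$event$type]]
      nkey <- profile_text(nb$profile)
      ng <- g + c_ev
      old <- gs[[nkey]]
      if (is.null(old) || ng < old - 1e-9) {
        assign(nkey, nb$profile, envir = states)
        assign(nkey, ng, envir = gs)
        assign(nkey, list(list(key = key, event = nb$event)), envir = prev)
        if (!is.null(closed[[nkey]])) rm(list = nkey, envir = closed)
        h <- if (use_heuristic)
          astar_heuristic(nkey, tgt_key,
                          profile_token_counts(nb$profile, alphabet),
                          tgt_tok, length(nb$profile), tgt_n, costs) else 0
        if (ng + h <= max_cost + 1e-9) heap_push(open, ng + h, nkey)
      } else if (all_paths && abs(ng - old) <= 1e-9) {
        links <- prev[[nkey]]
        dup <- any(vapply(links, function(l)
          l$key == key && identical(l$event, nb$event), logical(1L)))
        if (!dup)
          assign(nkey, c(links, list(list(key = key, event = nb$event))),
                 envir = prev)
      }
    }
  }

  if (!is.finite(best) && is.null(gs[[tgt_key]]))
    return(event_path(NULL, Inf, reachable = FALSE))
  if (!is.finite(best)) {
    best <- gs[[tgt_key]]
    if (is.null(closed[[tgt_key]]) && best > max_cost + 1e-9)
      return(event_path(NULL, Inf, reachable = FALSE))
  }
  if (best > max_cost + 1e-9)
    return(event_path(NULL, Inf, reachable = FALSE))

  walk_one <- function(key) {
    evs <- list(); sts <- key
    while (key != src_key) {
      link <- prev[[key]][[1L]]
      evs <- c(list(link$event), evs)
      key <- link$key
      sts <- c(key, sts)
    }
    event_path(evs, best, states = sts)
  }
  res <- walk_one(tgt_key)

  if (all_paths) {
    paths <- list()
    truncated <- FALSE
    recurse <- function(key, suffix_ev, suffix_st) {
      if (length(paths) >= max_paths) { truncated <<- TRUE; return() }
      if (key == src_key) {
        paths[[length(paths) + 1L]] <<-
          event_path(suffix_ev, best, states = c(key, suffix_st))
        return()
      }
      for (link in prev[[key]]) {
        if (length(paths) >= max_paths) { truncated <<- TRUE; return() }
        recurse(link$key, c(list(link$event), suffix_ev), c(key, suffix_st))
      }
    }
    recurse(tgt_key, list(), character(0))
    res$paths <- paths
    res$paths_truncated <- truncated
  }
  res
}

#' Brute-force event distance (test oracle)
#'
#' Exhaustive breadth-first enumeration of all event sequences of length at
#' most `max_depth`, tracking the cheapest cost at which each profile is
#' reached. Independent of the best-first search except for the shared
#' neighbour generator, which is part of the grammar itself.
#'
#' @inheritParams event_distance
#' @param max_depth Maximum number of events in a sequence (keep small).
#' @return An `event_path` (reachable or not).
#' @export
brute_force_distance <- function(source, target, costs = default_costs(),
                                 caps = arch_caps(), max_depth = 4L,
                                 gain_pool = NULL) {
  if (is.character(source) && length(source) == 1L && grepl("[;.]", source))
    source <- parse_profile(source)
  if (is.character(target) && length(target) == 1L && grepl("[;.]", target))
    target <- parse_profile(target)
  source <- canonical_profile(source)
  target <- canonical_profile(target)
  costs <- costs[event_types()]
  allow_gain <- is.finite(costs[["gene_gain"]])
  if (is.null(gain_pool)) gain_pool <- unique(target)
  gain_pool <- sort(unique(gain_pool), method = "radix")

  src_key <- profile_text(source)
  tgt_key <- profile_text(target)
  best <- new.env(parent = emptyenv())   # key -> cost
  prev <- new.env(parent = emptyenv())   # key -> list(key, event)
  profs <- new.env(parent = emptyenv())
  assign(src_key, 0, envir = best)
  assign(src_key, source, envir = profs)
  frontier <- src_key
  for (depth in seq_len(max_depth)) {
    nxt <- character(0)
    for (key in frontier) {
      g <- best[[key]]
      for (nb in memo_neighbors(profs[[key]], caps, allow_gain, gain_pool)) {
        nkey <- profile_text(nb$profile)
        ng <- g + costs[[nb$event$type]]
        old <- best[[nkey]]
        if (is.null(old) || ng < old - 1e-9) {
          assign(nkey, ng, envir = best)
          assign(nkey, nb$profile, envir = profs)
          assign(nkey, list(key = key, event = nb$event), envir = prev)
          nxt <- c(nxt, nkey)
        }
      }
    }
    frontier <- unique(nxt)
  }
  if (is.null(best[[tgt_key]]))
    return(event_path(NULL, Inf, reachable = FALSE))
  cost <- best[[tgt_key]]
  evs <- list(); sts <- tgt_key; key <- tgt_key
  while (key != src_key) {
    link <- prev[[key]]
    evs <- c(list(link$event), evs)
    key <- link$key
    sts <- c(key, sts)
  }
  event_path(evs, cost, states = sts)
}
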