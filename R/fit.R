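# Classed front end: arch_parsimony() is the one-call fit, returning a
# sankoff_fit subclass with summary/plot/simulate methods.

#' Fit a weighted-parsimony reconstruction of architecture evolution
#'
#' High-level interface to [sankoff()]: builds the ancestral state universe
#' from the observed tip profiles, runs the dynamic program, and returns a
#' fitted object with `print`, `summary`, `plot` and `simulate` methods.
#'
#' @inheritParams sankoff
#' @param profiles Named list/character of tip profiles (one per tip of
#'   `tree`).
#' @param root_state Optional root constraint (profile string or vector).
#' @return An object of classes `arch_parsimony` and `sankoff_fit`.
#' @examples
#' tree <- read_newick("((A,B),C);")
#' fit <- arch_parsimony(tree, c(A = "K-P", B = "K-P", C = "B-K-P"))
#' fit
#' summary(fit)
#' @export
arch_parsimony <- function(tree, profiles, costs = default_costs(),
                           root_state = NULL, universe_depth = 1L,
                           caps = arch_caps(), max_mprs = 256L,
                           max_cost = 12) {
  fit <- sankoff(tree, profiles, costs = costs,
                 root_constraint = root_state,
                 universe_depth = universe_depth, caps = caps,
                 max_mprs = max_mprs, max_cost = max_cost)
  fit$call <- match.call()
  class(fit) <- c("arch_parsimony", class(fit))
  fit
}

#' @export
print.arch_parsimony <- function(x, ...) {
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  NextMethod()
}

#' @export
summary.arch_parsimony <- function(object, ...) {
  count_mat <- t(vapply(object$reconstructions, function(r)
    count_by_type(extract_events(r)),
    numeric(length(event_types()) + 1L)))
  structure(list(fit = object, count_mat = count_mat),
            class = "summary.arch_parsimony")
}

#' @export
print.summary.arch_parsimony <- function(x, ...) {
  print(x$fit)
  cat("\nPer-type event counts across MPRs (min..max):\n")
  for (ty in colnames(x$count_mat)) {
    lo <- min(x$count_mat[, ty]); hi <- max(x$count_mat[, ty])
    if (hi > 0)
      cat(sprintf("  %-20s %s\n", ty,
                  if (lo == hi) sprintf("%d", lo)
                  else sprintf("%d..%d", lo, hi)))
  }
  invisible(x)
}

#' @export
plot.arch_parsimony <- function(x, mpr = 1L, cex = 0.7, ...) {
  rec <- x$reconstructions[[mpr]]
  labels <- node_labels(x$tree)
  ntip <- length(x$tree$tip.label)
  ape::plot.phylo(x$tree, cex = cex, ...)
  internal <- labels[(ntip + 1L):length(labels)]
  ape::nodelabels(text = unname(rec$assignment[internal]), cex = cex,
                  frame = "rect", bg = "lightyellow")
  tips <- vapply(x$tips[x$tree$tip.label], profile_text, "")
  ape::tiplabels(text = tips, adj = -0.1, cex = cex, frame = "none")
  invisible(x)
}

#' Simulate architecture evolution from a fitted reconstruction
#'
#' Forward-simulates the event process on the fitted tree, starting from the
#' first optimal root state. Trees without branch lengths are given unit
#' lengths (with a message), since parsimony itself ignores them.
#'
#' @param object An `arch_parsimony` fit.
#' @param nsim Number of replicates.
#' @param seed Base seed (replicate r uses `seed + r - 1`).
#' @param rates Rate model, see [default_rates()].
#' @param ... Unused.
#' @return A list of `arch_simulation` objects (length `nsim`).
#' @export
simulate.arch_parsimony <- function(object, nsim = 1L, seed = 1L,
                                    rates = default_rates(), ...) {
  tree <- object$tree
  if (is.null(tree$edge.length)) {
    message("tree has no branch lengths; using unit lengths for simulation")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  root_key <- object$root_states[[1L]]
  lapply(seq_len(nsim), function(r)
    simulate_evolution(tree, parse_profile(root_key), rates = rates,
                       seed = seed + r - 1L))
}
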