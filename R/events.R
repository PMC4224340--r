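# The event grammar. An event is a list(type, inputs, outputs, detail) of
# class "arch_event"; outputs are always derivable from inputs + detail, and
# apply_event() recomputes them rather than trusting the stored copy.

#' The closed set of event types
#'
#' Architecture evolution is modelled with seven transition types: `fusion`
#' (two genes joined N-to-C into one), `fission_separation` (one gene split
#' into two genes that together retain all domains), `fission_domain_loss`
#' (deletion of a contiguous domain run from a gene carrying at least two
#' distinct domain types), `domain_contraction` (deletion from a gene with a
#' single domain type, e.g. a folB-folB tandem collapsing to folB),
#' `domain_duplication` (tandem duplication of a contiguous run),
#' `gene_loss` (removal of a whole gene) and `gene_gain` (appearance of a
#' stated architecture, e.g. by horizontal transfer).
#'
#' @return Character vector of the seven event type names.
#' @export
event_types <- function() {
  c("fusion", "fission_separation", "fission_domain_loss",
    "domain_contraction", "domain_duplication", "gene_loss", "gene_gain")
}

#' Default event cost model
#'
#' Unit costs for all event types except `gene_gain`, which defaults to 10 so
#' that vertical inheritance is always preferred over invoking a gain unless
#' the data force one.
#'
#' @param ... Named overrides, e.g. `gene_gain = Inf` to forbid gains.
#' @return Named numeric vector over [event_types()].
#' @export
default_costs <- function(...) {
  costs <- c(fusion = 1, fission_separation = 1, fission_domain_loss = 1,
             domain_contraction = 1, domain_duplication = 1,
             gene_loss = 1, gene_gain = 10)
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(costs))
    if (length(bad))
      stop("unknown event type in cost model: ", paste(bad, collapse = ", "),
           call. = FALSE)
    costs[names(dots)] <- dots
  }
  if (any(costs < 0, na.rm = TRUE))
    stop("event costs must be nonnegative", call. = FALSE)
  costs
}

new_event <- function(type, inputs, outputs, detail = list()) {
  structure(list(type = type, inputs = inputs, outputs = outputs,
                 detail = detail),
            class = "arch_event")
}

#' Event constructors
#'
#' Build well-formed grammar events. Deletions are classified at construction
#' (`fission_domain_loss` when the parent gene carries two or more distinct
#' domain types, `domain_contraction` otherwise) and a deletion that would
#' empty the gene is rejected: total removal must be expressed as
#' `gene_loss`.
#'
#' @param g,g1,g2 Architecture strings (grammar inputs).
#' @param at Split boundary for a separation: the first `at` domains form the
#'   N-terminal product, the rest the C-terminal product (`1 <= at < length`).
#' @param from,to 1-based inclusive domain positions delimiting a contiguous
#'   run.
#' @param arch Architecture gained.
#' @return An object of class `arch_event`.
#' @name event-constructors
NULL

#' @rdname event-constructors
#' @export
event_fusion <- function(g1, g2) {
  new_event("fusion", c(g1, g2),
            arch_from_tokens(c(arch_tokens(g1), arch_tokens(g2))))
}

#' @rdname event-constructors
#' @export
event_separation <- function(g, at) {
  toks <- arch_tokens(g)
  n <- length(toks)
  if (n < 2L) stop("cannot separate a single-domain gene", call. = FALSE)
  if (at < 1L || at > n - 1L)
    stop("separation boundary out of range", call. = FALSE)
  new_event("fission_separation", g,
            c(arch_from_tokens(toks[seq_len(at)]),
              arch_from_tokens(toks[(at + 1L):n])),
            detail = list(split = as.integer(at)))
}

#' @rdname event-constructors
#' @export
event_deletion <- function(g, from, to) {
  toks <- arch_tokens(g)
  n <- length(toks)
  if (from < 1L || to > n || from > to)
    stop("deletion run out of range", call. = FALSE)
  if (to - from + 1L >= n)
    stop("deletion emptying a gene must be expressed as gene_loss",
         call. = FALSE)
  type <- if (length(unique(toks)) >= 2L) "fission_domain_loss"
          else "domain_contraction"
  new_event(type, g, arch_from_tokens(toks[-(from:to)]),
            detail = list(run = c(as.integer(from), as.integer(to))))
}

#' @rdname event-constructors
#' @export
event_duplication <- function(g, from, to) {
  toks <- arch_tokens(g)
  n <- length(toks)
  if (from < 1L || to > n || from > to)
    stop("duplication run out of range", call. = FALSE)
  run <- toks[from:to]
  new_event("domain_duplication", g,
            arch_from_tokens(append(toks, run, after = to)),
            detail = list(run = c(as.integer(from), as.integer(to))))
}

#' @rdname event-constructors
#' @export
event_gene_loss <- function(g) new_event("gene_loss", g, character(0))

#' @rdname event-constructors
#' @export
event_gene_gain <- function(arch) {
  new_event("gene_gain", character(0), arch, detail = list(arch = arch))
}

#' @export
print.arch_event <- function(x, ...) {
  lhs <- if (length(x$inputs)) paste(x$inputs, collapse = " + ") else "0"
  rhs <- if (length(x$outputs)) paste(x$outputs, collapse = " + ") else "0"
  cat(sprintf("<%s> %s -> %s\n", x$type, lhs, rhs))
  invisible(x)
}

# Recompute outputs from inputs + detail; the single source of truth for the
# grammar's transition semantics.
event_outputs <- function(event) {
  switch(event$type,
    fusion = arch_from_tokens(c(arch_tokens(event$inputs[[1L]]),
                                arch_tokens(event$inputs[[2L]]))),
    fission_separation = {
      toks <- arch_tokens(event$inputs[[1L]])
      at <- event$detail$split
      c(arch_from_tokens(toks[seq_len(at)]),
        arch_from_tokens(toks[(at + 1L):length(toks)]))
    },
    fission_domain_loss = ,
    domain_contraction = {
      toks <- arch_tokens(event$inputs[[1L]])
      run <- event$detail$run
      arch_from_tokens(toks[-(run[[1L]]:run[[2L]])])
    },
    domain_duplication = {
      toks <- arch_tokens(event$inputs[[1L]])
      run <- event$detail$run
      arch_from_tokens(append(toks, toks[run[[1L]]:run[[2L]]],
                              after = run[[2L]]))
    },
    gene_loss = character(0),
    gene_gain = event$detail$arch,
    stop("unknown event type: ", event$type, call. = FALSE)
  )
}

#' Apply one event to a genome profile
#'
#' Removes the event's input gene(s) from the profile (identical copies are
#' interchangeable), adds the grammar-derived output gene(s), and validates
#' the result against the state caps.
#'
#' @param profile Canonical profile (character vector of architectures).
#' @param event An `arch_event`.
#' @param caps State caps, see [arch_caps()].
#' @return The canonical successor profile.
#' @examples
#' apply_event(c("B-K-P"), event_duplication("B-K-P", 1, 1))
#' apply_event(c("B-B-K-P"), event_separation("B-B-K-P", 2))
#' @export
apply_event <- function(profile, event, caps = arch_caps()) {
  stopifnot(inherits(event, "arch_event"))
  remaining <- profile
  for (g in event$inputs) {
    hit <- match(g, remaining)
    if (is.na(hit))
      stop("event application error: input gene '", g,
           "' absent from profile '", profile_text(profile), "'",
           call. = FALSE)
    remaining <- remaining[-hit]
  }
  out <- canonical_profile(c(remaining, event_outputs(event)))
  if (!profile_within_caps(out, caps))
    stop("cap error: profile '", profile_text(out),
         "' violates state caps", call. = FALSE)
  out
}

#' Classify an event relative to its parent gene
#'
#' Pure, total classification: a split retaining all domains is
#' `fission_separation`; a deletion from a gene with two or more distinct
#' domain types is `fission_domain_loss`; a deletion from a single-type gene
#' is `domain_contraction`; all other types classify as themselves.
#'
#' @param parent_gene Architecture string the event acts on (ignored for
#'   `gene_gain`).
#' @param event An `arch_event`.
#' @return One of [event_types()].
#' @export
classify_event <- function(parent_gene, event) {
  stopifnot(inherits(event, "arch_event"))
  if (event$type %in% c("fission_domain_loss", "domain_contraction")) {
    if (length(unique(arch_tokens(parent_gene))) >= 2L)
      "fission_domain_loss" else "domain_contraction"
  } else {
    event$type
  }
}

# all proper contiguous runs (from,to) of a length-n sequence, excluding the
# full-length run
proper_runs <- function(n) {
  runs <- list()
  for (from in seq_len(n)) for (to in from:n) {
    if (to - from + 1L < n) runs[[length(runs) + 1L]] <- c(from, to)
  }
  runs
}

all_runs <- function(n) {
  runs <- list()
  for (from in seq_len(n)) for (to in from:n)
    runs[[length(runs) + 1L]] <- c(from, to)
  runs
}

#' Enumerate all single-event neighbours of a profile
#'
#' Generates every profile reachable by one grammar event under the caps.
#' Identical gene copies are interchangeable, and the listing is
#' duplicate-free over (event type, canonical neighbour): two details that
#' produce the same neighbour by the same type are listed once. For fusions
#' both concatenation orders are generated.
#'
#' @param profile Canonical profile.
#' @param caps State caps.
#' @param allow_gain Emit `gene_gain` neighbours?
#' @param gain_pool Architectures available for gain (required when
#'   `allow_gain` is `TRUE`).
#' @return A list of `list(event = <arch_event>, profile = <neighbour>)`,
#'   deterministically ordered by type then neighbour text.
#' @export
enumerate_events <- function(profile, caps = arch_caps(),
                             allow_gain = FALSE, gain_pool = character()) {
  out <- list()
  seen <- character(0)
  add <- function(event) {
    nb <- tryCatch(apply_event(profile, event, caps),
                   error = function(e) NULL)
    if (is.null(nb)) return(invisible())
    key <- paste(event$type, profile_text(nb), sep = "|")
    if (key %in% seen) return(invisible())
    seen[[length(seen) + 1L]] <<- key
    out[[length(out) + 1L]] <<- list(event = event, profile = nb)
    invisible()
  }

  uniq <- unique(profile)
  counts <- table(profile)

  for (g in uniq) {
    toks <- arch_tokens(g)
    n <- length(toks)
    if (n >= 2L) {
      for (at in seq_len(n - 1L)) add(event_separation(g, at))
      for (run in proper_runs(n))
        add(event_deletion(g, run[[1L]], run[[2L]]))
    }
    for (run in all_runs(n)) {
      ev <- event_duplication(g, run[[1L]], run[[2L]])
      if (gene_within_caps(ev$outputs, caps)) add(ev)
    }
    add(event_gene_loss(g))
  }
  for (g1 in uniq) for (g2 in uniq) {
    if (g1 == g2 && counts[[g1]] < 2L) next
    add(event_fusion(g1, g2))
  }
  if (allow_gain) {
    for (a in unique(gain_pool)) add(event_gene_gain(a))
  }

  if (length(out) == 0L) return(out)
  ord <- order(vapply(out, function(x) x$event$type, ""),
               vapply(out, function(x) profile_text(x$profile), ""),
               method = "radix")
  out[ord]
}

# Instance-level enumeration for the simulator: each element carries the
# event, its successor profile, the event type, and the number of physically
# distinct instances (copy multiplicity x distinct detail).
enumerate_instances <- function(profile, caps = arch_caps(),
                                gain_pool = character()) {
  out <- list()
  add <- function(event, mult) {
    nb <- tryCatch(apply_event(profile, event, caps),
                   error = function(e) NULL)
    if (is.null(nb)) return(invisible())
    out[[length(out) + 1L]] <<- list(event = event, profile = nb,
                                     type = event$type, mult = mult)
    invisible()
  }
  uniq <- unique(profile)
  counts <- table(profile)
  for (g in uniq) {
    m <- counts[[g]]
    toks <- arch_tokens(g)
    n <- length(toks)
    if (n >= 2L) {
      for (at in seq_len(n - 1L)) add(event_separation(g, at), m)
      for (run in proper_runs(n)) add(event_deletion(g, run[[1L]], run[[2L]]), m)
    }
    for (run in all_runs(n)) {
      ev <- event_duplication(g, run[[1L]], run[[2L]])
      if (gene_within_caps(ev$outputs, caps)) add(ev, m)
    }
    add(event_gene_loss(g), m)
  }
  for (g1 in uniq) for (g2 in uniq) {
    if (g1 == g2) {
      if (counts[[g1]] >= 2L)
        add(event_fusion(g1, g1), counts[[g1]] * (counts[[g1]] - 1L))
    } else {
      add(event_fusion(g1, g2), counts[[g1]] * counts[[g2]])
    }
  }
  for (a in unique(gain_pool)) add(event_gene_gain(a), 1L)
  out
}
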