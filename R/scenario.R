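# Stated per-branch event histories ("scenarios"): forward application down
# the tree, validation against observed tip profiles, and event-type
# summaries. Branches are addressed by the label of the child node (tip name
# or named internal node), which keeps scenario files robust to rearranging
# uniform clades.

#' Construct an event scenario
#'
#' @param root_state Profile at the root (vector or profile string).
#' @param placements List of `list(branch = <child-node label>, event =
#'   <arch_event>)`; events sharing a branch are applied in list order.
#' @param label Free-text description.
#' @return An object of class `arch_scenario`.
#' @export
arch_scenario <- function(root_state, placements = list(), label = "") {
  rs <- if (is.character(root_state) && length(root_state) == 1L)
    parse_profile(root_state) else canonical_profile(root_state)
  for (p in placements)
    stopifnot(is.character(p$branch), inherits(p$event, "arch_event"))
  structure(list(root_state = rs, placements = placements, label = label),
            class = "arch_scenario")
}

#' @export
print.arch_scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: root %s, %d event placement(s)\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              profile_text(x$root_state), length(x$placements)))
  invisible(x)
}

scenario_branch_ids <- function(tree, scenario) {
  labels <- node_labels(tree)
  ids <- match(vapply(scenario$placements, `[[`, "", "branch"), labels)
  if (anyNA(ids)) {
    bad <- unique(vapply(scenario$placements, `[[`, "", "branch")[is.na(ids)])
    stop("scenario references unknown branch(es): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ids
}

#' Play a scenario forward along a tree
#'
#' Propagates the root state down the tree, applying each branch's events in
#' order, and returns the implied genome profile at every node.
#'
#' @param tree A rooted `phylo` tree.
#' @param scenario An [arch_scenario()].
#' @param caps State caps.
#' @return Named list (by node label) of implied profiles.
#' @export
play_scenario <- function(tree, scenario, caps = arch_caps()) {
  stopifnot(inherits(tree, "phylo"), inherits(scenario, "arch_scenario"))
  labels <- node_labels(tree)
  ids <- scenario_branch_ids(tree, scenario)
  states <- vector("list", length(labels))
  root <- root_node(tree)
  states[[root]] <- scenario$root_state
  for (v in traverse_preorder(tree)) {
    if (v == root) next
    par <- node_parent(tree, v)
    st <- states[[par]]
    here <- which(ids == v)
    for (i in here) {
      ev <- scenario$placements[[i]]$event
      st <- tryCatch(apply_event(st, ev, caps),
                     error = function(e)
                       stop("scenario inconsistency on branch '",
                            labels[[v]], "' (", ev$type, "): ",
                            conditionMessage(e), call. = FALSE))
    }
    states[[v]] <- st
  }
  stats::setNames(states, labels)
}

#' Validate a scenario against observed tip profiles
#'
#' Plays the scenario forward (recording any grammar violation instead of
#' stopping) and compares the implied tip profiles with the observed ones.
#'
#' @inheritParams play_scenario
#' @param observed_tips Named list/character of observed tip profiles.
#' @return A list of class `scenario_report`: `valid` (logical),
#'   `tip_report` (data frame with implied/observed/match per tip) and
#'   `violations` (character vector of grammar failures).
#' @export
validate_scenario <- function(tree, scenario, observed_tips,
                              caps = arch_caps()) {
  stopifnot(inherits(tree, "phylo"), inherits(scenario, "arch_scenario"))
  observed_tips <- as_profiles(observed_tips)
  labels <- node_labels(tree)
  ids <- scenario_branch_ids(tree, scenario)
  states <- vector("list", length(labels))
  root <- root_node(tree)
  states[[root]] <- scenario$root_state
  violations <- character(0)
  for (v in traverse_preorder(tree)) {
    if (v == root) next
    par <- node_parent(tree, v)
    st <- states[[par]]
    for (i in which(ids == v)) {
      ev <- scenario$placements[[i]]$event
      st2 <- tryCatch(apply_event(st, ev, caps), error = function(e) NULL)
      if (is.null(st2)) {
        violations <- c(violations, sprintf(
          "branch '%s': %s event inapplicable to profile '%s'",
          labels[[v]], ev$type, profile_text(st)))
      } else st <- st2
    }
    states[[v]] <- st
  }
  ntip <- length(tree$tip.label)
  implied <- vapply(seq_len(ntip), function(i) profile_text(states[[i]]), "")
  obs <- vapply(tree$tip.label, function(nm) {
    if (is.null(observed_tips[[nm]])) NA_character_
    else profile_text(observed_tips[[nm]])
  }, "")
  tip_report <- data.frame(taxon = tree$tip.label, implied = implied,
                           observed = unname(obs),
                           match = implied == unname(obs),
                           stringsAsFactors = FALSE)
  structure(list(valid = all(tip_report$match, na.rm = FALSE) &&
                   !anyNA(tip_report$match) && length(violations) == 0L,
                 tip_report = tip_report, violations = violations),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("<scenario report> %s\n",
              if (x$valid) "valid" else "INVALID"))
  bad <- x$tip_report[!x$tip_report$match | is.na(x$tip_report$match), ,
                      drop = FALSE]
  if (nrow(bad)) {
    cat("  tip mismatches:\n")
    for (i in seq_len(nrow(bad)))
      cat(sprintf("    %s: implied %s, observed %s\n", bad$taxon[[i]],
                  bad$implied[[i]], bad$observed[[i]]))
  }
  for (v in x$violations) cat("  grammar violation:", v, "\n")
  invisible(x)
}

#' Events of a scenario in [count_by_type()] form
#'
#' @param scenario An `arch_scenario`.
#' @return List of `list(branch, event, type)`, classification via
#'   [classify_event()].
#' @export
scenario_events <- function(scenario) {
  lapply(scenario$placements, function(p) {
    parent_gene <- if (length(p$event$inputs)) p$event$inputs[[1L]]
                   else NA_character_
    list(branch = p$branch, event = p$event,
         type = classify_event(parent_gene, p$event))
  })
}

#' Summarise a scenario: per-type counts and total cost
#'
#' Counts the scenario's placements by grammar classification and prices the
#' scenario under a cost model. When `tree` (and optionally
#' `observed_tips`) are supplied the scenario is validated first and an
#' invalid scenario is refused.
#'
#' @param scenario An `arch_scenario`.
#' @param costs Event cost model.
#' @param tree Optional `phylo` tree for validation.
#' @param observed_tips Optional named tip profiles for validation.
#' @param caps State caps.
#' @return List with `counts` (named vector as [count_by_type()]) and
#'   `total_cost`.
#' @export
summarize_scenario <- function(scenario, costs = default_costs(),
                               tree = NULL, observed_tips = NULL,
                               caps = arch_caps()) {
  stopifnot(inherits(scenario, "arch_scenario"))
  if (!is.null(tree)) {
    if (!is.null(observed_tips)) {
      rep <- validate_scenario(tree, scenario, observed_tips, caps)
      if (!rep$valid)
        stop("scenario is invalid; run validate_scenario() for the full report",
             call. = FALSE)
    } else {
      play_scenario(tree, scenario, caps)  # errors on grammar violations
    }
  }
  evs <- scenario_events(scenario)
  counts <- count_by_type(evs)
  types <- vapply(evs, `[[`, "", "type")
  list(counts = counts,
       total_cost = if (length(types)) sum(costs[types]) else 0)
}

# ---- scenario TSV serialisation ----

event_detail_string <- function(event) {
  switch(event$type,
    fission_separation = paste0("split=", event$detail$split),
    fission_domain_loss = ,
    domain_contraction = ,
    domain_duplication = paste0("run=", event$detail$run[[1L]], ":",
                                event$detail$run[[2L]]),
    gene_gain = paste0("arch=", event$detail$arch),
    "")
}

event_from_row <- function(type, inputs, outputs, detail) {
  ins <- if (identical(inputs, ".") || !nzchar(inputs)) character(0)
         else trimws(strsplit(inputs, ";", fixed = TRUE)[[1L]])
  ev <- switch(type,
    fusion = event_fusion(ins[[1L]], ins[[2L]]),
    fission_separation = {
      at <- as.integer(sub("^split=", "", detail))
      event_separation(ins[[1L]], at)
    },
    fission_domain_loss = ,
    domain_contraction = {
      run <- as.integer(strsplit(sub("^run=", "", detail), ":",
                                 fixed = TRUE)[[1L]])
      event_deletion(ins[[1L]], run[[1L]], run[[2L]])
    },
    domain_duplication = {
      run <- as.integer(strsplit(sub("^run=", "", detail), ":",
                                 fixed = TRUE)[[1L]])
      event_duplication(ins[[1L]], run[[1L]], run[[2L]])
    },
    gene_loss = event_gene_loss(ins[[1L]]),
    gene_gain = event_gene_gain(sub("^arch=", "", detail)),
    stop("unknown event type in scenario file: ", type, call. = FALSE))
  if (!identical(ev$type, type))
    stop("scenario row classifies as ", ev$type, ", not ", type,
         call. = FALSE)
  want <- if (identical(outputs, ".") || !nzchar(outputs)) character(0)
          else trimws(strsplit(outputs, ";", fixed = TRUE)[[1L]])
  have <- event_outputs(ev)
  if (!identical(sort(want, method = "radix"),
                 sort(have, method = "radix")))
    stop("scenario row outputs '", outputs,
         "' disagree with the grammar ('",
         paste(have, collapse = ";"), "')", call. = FALSE)
  ev
}

#' Read / write a scenario TSV
#'
#' Tab-separated columns: `child_node`, `event_type`, `inputs`
#' (`";"`-joined input architectures, `.` if none), `outputs` (likewise) and
#' `detail` (`split=i`, `run=i:j`, `arch=A`, or empty). A `# root_state:`
#' header comment carries the root profile.
#'
#' @param path File path.
#' @param scenario An `arch_scenario` (for writing).
#' @param label Scenario label (for reading).
#' @return `read_scenario()` returns an `arch_scenario`;
#'   `write_scenario()` returns `path` invisibly.
#' @export
read_scenario <- function(path, label = basename(path)) {
  lines <- readLines(path)
  root_line <- grep("^#\\s*root_state:", lines, value = TRUE)
  if (!length(root_line))
    stop("scenario file lacks a '# root_state:' header", call. = FALSE)
  root_state <- trimws(sub("^#\\s*root_state:", "", root_line[[1L]]))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("child_node", "event_type", "inputs", "outputs", "detail")
  if (!all(need %in% names(df)))
    stop("scenario file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  placements <- lapply(seq_len(nrow(df)), function(i) {
    list(branch = df$child_node[[i]],
         event = event_from_row(df$event_type[[i]], df$inputs[[i]],
                                df$outputs[[i]], df$detail[[i]]))
  })
  arch_scenario(root_state, placements, label = label)
}

#' @rdname read_scenario
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "arch_scenario"))
  rows <- vapply(scenario$placements, function(p) {
    ev <- p$event
    paste(p$branch, ev$type,
          if (length(ev$inputs)) paste(ev$inputs, collapse = ";") else ".",
          if (length(ev$outputs)) paste(ev$outputs, collapse = ";") else ".",
          event_detail_string(ev), sep = "\t")
  }, "")
  writeLines(c(paste0("# root_state: ", profile_text(scenario$root_state)),
               paste("child_node", "event_type", "inputs", "outputs",
                     "detail", sep = "\t"),
               rows), path)
  invisible(path)
}
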