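# Plain-text formats: profile tables (TSV), cost/rate configs (key = value).

#' Read / write a profile table
#'
#' Tab-separated with columns `taxon` and `profile` (profile strings,
#' `"."` = pathway absent). Lines starting with `#` are comments.
#'
#' @param path File path.
#' @param profiles Named list of profiles (for writing).
#' @return `read_profiles()`: named list of canonical profiles.
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  if (!all(c("taxon", "profile") %in% names(df)))
    stop("profile table must have columns 'taxon' and 'profile'",
         call. = FALSE)
  if (anyDuplicated(df$taxon))
    stop("duplicate taxon in profile table: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "),
         call. = FALSE)
  stats::setNames(lapply(df$profile, parse_profile), df$taxon)
}

#' @rdname read_profiles
#' @export
write_profiles <- function(profiles, path) {
  writeLines(c("taxon\tprofile",
               vapply(names(profiles), function(nm)
                 paste(nm, profile_text(profiles[[nm]]), sep = "\t"), "")),
             path)
  invisible(path)
}

# key = value config keyed by event type; unknown keys are hard errors
read_typed_config <- function(path, base) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[[1L]]); val <- suppressWarnings(as.numeric(trimws(kv[[2L]])))
    if (!key %in% names(base))
      stop("unknown event type in config: '", key, "'", call. = FALSE)
    if (is.na(val))
      stop("non-numeric value for '", key, "' in config", call. = FALSE)
    base[[key]] <- val
  }
  base
}

#' Read an event cost / rate configuration
#'
#' Flat `key = value` text keyed by event type name; keys not in
#' [event_types()] are hard errors. Unmentioned types keep their defaults.
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_costs <- function(path) read_typed_config(path, default_costs())

#' @rdname read_costs
#' @export
read_rates <- function(path) read_typed_config(path, default_rates())
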