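# Architectures are canonical hyphen-joined token strings ("B-K-P"); genome
# profiles are sorted character vectors of architecture strings (a multiset;
# length 0 = pathway absent). Plain vectors keep the search layers fast.

#' Default domain alphabet
#'
#' The registered set of domain symbols. The default covers the three enzymes
#' of the pterin branch of folate biosynthesis: `B` (folB/DHNA), `K`
#' (folK/HPPK) and `P` (folP/DHPS).
#'
#' @return Character vector of allowed domain tokens.
#' @export
default_alphabet <- function() c("B", "K", "P")

#' Split an architecture string into its domain tokens
#' @param arch Architecture string, e.g. `"B-K-P"`.
#' @return Character vector of tokens, N-terminal first.
#' @export
arch_tokens <- function(arch) {
  strsplit(arch, "-", fixed = TRUE)[[1L]]
}

#' Join domain tokens into an architecture string
#' @param tokens Character vector of domain tokens.
#' @return Architecture string.
#' @export
arch_from_tokens <- function(tokens) {
  paste(tokens, collapse = "-")
}

#' Parse a gene architecture
#'
#' Parses a hyphen-joined domain string (N- to C-terminal) into its canonical
#' form, validating every token against the registered alphabet.
#'
#' @param text Architecture string such as `"B-B-K-P"`. Whitespace at token
#'   boundaries is tolerated.
#' @param alphabet Registered domain alphabet.
#' @return Canonical architecture string.
#' @examples
#' parse_architecture("B-K-P")
#' @export
parse_architecture <- function(text, alphabet = default_alphabet()) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text)))
    stop("architecture format error: empty architecture string", call. = FALSE)
  tokens <- trimws(strsplit(text, "-", fixed = TRUE)[[1L]])
  if (any(!nzchar(tokens)))
    stop("architecture format error: empty domain token in '", text, "'",
         call. = FALSE)
  bad <- setdiff(unique(tokens), alphabet)
  if (length(bad))
    stop("alphabet error: unknown domain token '", bad[[1L]], "' in '",
         text, "'", call. = FALSE)
  arch_from_tokens(tokens)
}

#' Parse a genome profile
#'
#' A profile is the multiset of pathway gene architectures carried by one
#' genome, written as `";"`-joined architecture strings; `"."` denotes an
#' empty profile (pathway absent).
#'
#' @param text Profile string, e.g. `"B-B;K-P"` or `"."`.
#' @param alphabet Registered domain alphabet.
#' @return Canonical profile: a sorted character vector of architecture
#'   strings (length 0 for the empty profile).
#' @examples
#' parse_profile("B-B;K-P")
#' parse_profile(".")
#' @export
parse_profile <- function(text, alphabet = default_alphabet()) {
  if (length(text) != 1L || is.na(text))
    stop("profile format error: expected a single string", call. = FALSE)
  text <- trimws(text)
  if (identical(text, ".") || !nzchar(text)) return(character(0))
  members <- trimws(strsplit(text, ";", fixed = TRUE)[[1L]])
  canonical_profile(vapply(members, parse_architecture, "",
                           alphabet = alphabet, USE.NAMES = FALSE))
}

#' Canonicalise a profile vector
#' @param genes Character vector of architecture strings.
#' @return The same multiset in canonical (radix-sorted) order.
#' @export
canonical_profile <- function(genes) {
  if (length(genes) == 0L) return(character(0))
  sort(genes, method = "radix")
}

#' Format a genome profile as text
#' @param profile Canonical profile (character vector).
#' @return Profile string; `"."` for the empty profile.
#' @export
profile_text <- function(profile) {
  if (length(profile) == 0L) "." else paste(profile, collapse = ";")
}

#' Count distinct fused architectures across profiles
#'
#' A fused architecture is a gene containing at least two distinct domain
#' types; single-type genes (`B`, `B-B`, ...) are excluded. Applied to the
#' eukaryote-wide folate table this reproduces the four fused architectures
#' observed across the sampled genomes.
#'
#' @param profiles A list of profiles (each a character vector of
#'   architecture strings).
#' @return Nonnegative integer count of distinct multi-type architectures.
#' @export
count_fused_architectures <- function(profiles) {
  archs <- unique(unlist(profiles, use.names = FALSE))
  if (is.null(archs) || length(archs) == 0L) return(0L)
  fused <- vapply(archs, function(a) {
    length(unique(arch_tokens(a))) >= 2L
  }, logical(1L))
  sum(fused)
}

#' State caps bounding the profile universe
#'
#' @param max_copies_per_type_per_gene Maximum copies of any one domain type
#'   within a single gene (default 2, matching the observed folB-folB tandem).
#' @param max_genes_per_profile Maximum number of genes in one profile
#'   (default 4).
#' @return A list of class `arch_caps`.
#' @export
arch_caps <- function(max_copies_per_type_per_gene = 2L,
                      max_genes_per_profile = 4L) {
  stopifnot(max_copies_per_type_per_gene >= 1L, max_genes_per_profile >= 1L)
  structure(list(max_copies = as.integer(max_copies_per_type_per_gene),
                 max_genes = as.integer(max_genes_per_profile)),
            class = "arch_caps")
}

# TRUE iff one gene respects the per-type copy cap.
gene_within_caps <- function(arch, caps) {
  all(table(arch_tokens(arch)) <= caps$max_copies)
}

#' Check a profile against state caps
#' @param profile Canonical profile.
#' @param caps An [arch_caps()] object.
#' @return Logical scalar.
#' @export
profile_within_caps <- function(profile, caps = arch_caps()) {
  if (length(profile) > caps$max_genes) return(FALSE)
  all(vapply(profile, gene_within_caps, logical(1L), caps = caps))
}
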