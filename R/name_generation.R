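#' The canonical alter taxonomy
#'
#' Loads the versioned taxonomy of influence sources ("alters") used when
#' canonicalising free-text nominations. The default taxonomy ships with the
#' package and reconstructs the study's 14-category inventory: GP, pharmacist,
#' allergist/immunologist, respiratory specialist, ENT specialist, practice
#' nurse, alternative therapist, parents/partner, family, friends/colleagues,
#' media, internet, own experience, and "other HCP" (the bucket the study used
#' for dermatologists, neurologists, optometrists and ophthalmologists).
#'
#' The file is tab-delimited with columns `code`, `display_name`, `group`
#' (one of HCP, non-HCP, self, media_internet) and `synonyms`
#' (pipe-separated raw labels). Alternative taxonomies for other studies can
#' be supplied via `path`; synonym sets must be disjoint across categories.
#'
#' @param path Path to a taxonomy TSV; `NULL` loads the packaged default.
#' @return data.frame with class `alter_taxonomy`.
#' @export
#' @examples
#' tax <- alter_taxonomy()
#' nrow(tax)  # 14
alter_taxonomy <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "alter_taxonomy.tsv", package = "arnet",
                        mustWork = TRUE)
  }
  tax <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("code", "display_name", "group", "synonyms")
  if (!all(required %in% names(tax))) {
    stop("taxonomy file must have columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  groups <- c("HCP", "non-HCP", "self", "media_internet")
  if (!all(tax$group %in% groups)) {
    stop("taxonomy groups must be one of: ", paste(groups, collapse = ", "),
         call. = FALSE)
  }
  syn <- taxonomy_synonym_map(tax)
  if (anyDuplicated(syn$norm_key)) {
    dup <- unique(syn$key[duplicated(syn$norm_key)])
    stop("synonym sets overlap across categories: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  attr(tax, "synonym_map") <- syn
  class(tax) <- c("alter_taxonomy", "data.frame")
  tax
}

# long lookup: normalised synonym/display/code -> category code; cached on
# the taxonomy object since it sits on the per-participant hot path
taxonomy_synonym_map <- function(tax) {
  cached <- attr(tax, "synonym_map")
  if (!is.null(cached)) return(cached)
  rows <- lapply(seq_len(nrow(tax)), function(i) {
    raw <- c(tax$code[i], tax$display_name[i],
             strsplit(tax$synonyms[i], "|", fixed = TRUE)[[1]])
    data.frame(key = unique(normalize_label(raw)), code = tax$code[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$norm_key <- normalize_label(gsub("[/_]", " ", out$key))
  # code and display name often normalise to the same key within a category;
  # cross-category collisions are caught by the disjointness check
  out[!duplicated(paste(out$code, out$norm_key)), , drop = FALSE]
}

#' Canonicalise free-text alter labels
#'
#' Maps raw nomination labels (e.g. "sibling", "neurologist", "Chemist") onto
#' the taxonomy's canonical category codes. Matching is case-insensitive and
#' whitespace-normalised but otherwise exact; an unmapped label is an error
#' listing the known categories — there is no silent catch-all bucket.
#' Canonical display names and codes map to themselves (idempotence).
#'
#' @param raw_label Character vector of labels.
#' @param taxonomy An [alter_taxonomy()].
#' @return Character vector of canonical category codes.
#' @export
#' @examples
#' canonicalize_alter(c("GP", "sibling", "neurologist"))
canonicalize_alter <- function(raw_label, taxonomy = alter_taxonomy()) {
  stopifnot(is.character(raw_label), length(raw_label) >= 1)
  if (any(!nzchar(trimws(raw_label)))) {
    stop("alter labels must be non-empty", call. = FALSE)
  }
  # slashes in labels like "allergist/immunologist" are part of the name;
  # normalise them to spaces on both sides of the match
  syn <- taxonomy_synonym_map(taxonomy)
  idx <- match(normalize_label(gsub("[/_]", " ", raw_label)), syn$norm_key)
  if (anyNA(idx)) {
    bad <- unique(raw_label[is.na(idx)])
    stop("unmapped alter label(s): ", paste(sQuote(bad), collapse = ", "),
         "; known categories: ", paste(taxonomy$code, collapse = ", "),
         call. = FALSE)
  }
  syn$code[idx]
}

#' First-appearance inventory of alter categories
#'
#' Walks the cohort in interview order and records, for each alter category,
#' the index of the first participant who nominated it — the bookkeeping the
#' name-generator technique uses to judge data saturation.
#'
#' @param cohort An `ar_cohort` in interview order.
#' @return data.frame with columns `alter` and `first_ego` (1-based index),
#'   ordered by first appearance.
#' @export
alter_inventory <- function(cohort) {
  cohort <- as_ar_cohort(cohort)
  if (length(cohort) == 0) stop("cohort must contain at least one participant",
                                call. = FALSE)
  seen <- character(0)
  first <- integer(0)
  for (i in seq_along(cohort)) {
    new <- setdiff(unique(cohort[[i]]$placements$alter), seen)
    if (length(new)) {
      seen <- c(seen, new)
      first <- c(first, rep.int(i, length(new)))
    }
  }
  data.frame(alter = seen, first_ego = first, stringsAsFactors = FALSE)
}

#' Detect name-generation data saturation
#'
#' Saturation is reached when no later participant introduces a
#' first-appearance alter category. The index returned is the position of the
#' last participant who introduced a new category: every participant after it
#' nominated only previously seen categories. When the final participant still
#' introduces a new category the index equals the cohort size (saturation not
#' demonstrated).
#'
#' @param cohort An `ar_cohort` in interview order.
#' @return List with `index` (integer) and `log` (a list, per participant, of
#'   the categories they newly introduced; empty character vector when none).
#' @export
saturation_index <- function(cohort) {
  cohort <- as_ar_cohort(cohort)
  if (length(cohort) == 0) stop("cohort must contain at least one participant",
                                call. = FALSE)
  inv <- alter_inventory(cohort)
  log <- lapply(seq_along(cohort), function(i) inv$alter[inv$first_ego == i])
  list(index = max(inv$first_ego), log = log)
}
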